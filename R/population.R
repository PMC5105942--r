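#' Specification of a synthetic virtual neuron population
#'
#' Describes a heterogeneous population of model neurons standing in for
#' dissociated DRG cells. Heterogeneity enters through the excitability
#' midpoint `beta_w`, drawn from a truncated normal distribution
#' (default mean -20 mV, SD 4 mV, truncated to `[-30, -5]` mV: centred on
#' the normal operating point and spanning the transition from
#' no-spiking through transient to repetitive regimes), optionally
#' augmented by lognormal multipliers on the leak and potassium
#' conductances. No claim is made that these defaults match the real DRG
#' distribution; they provide a plausible spread of excitability.
#'
#' Each condition of the condition matrix combines a GABA reversal
#' potential, a 4-AP-analog excitability shift `delta_beta_w` (mV, added
#' to each cell's `beta_w`) and an optional virtual sodium conductance
#' (nS/pF). The default matrix crosses E_GABA in \{-35, -20\} mV with
#' `delta_beta_w` in \{0, 10\} mV.
#'
#' @param n population size (>= 1).
#' @param beta_w_mean,beta_w_sd normal parameters of `beta_w` (mV).
#' @param beta_w_bounds truncation interval (mV).
#' @param g_leak_sdlog,g_K_sdlog SDs of lognormal multipliers (0 = off).
#' @param conditions data frame with columns `e_gaba`, `delta_beta_w`,
#'   `g_na_virtual`.
#' @param base base [neuron_params()] the cells are derived from.
#' @param seed integer RNG seed recorded in the spec.
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(n, beta_w_mean = -20, beta_w_sd = 4,
                            beta_w_bounds = c(-30, -5),
                            g_leak_sdlog = 0, g_K_sdlog = 0,
                            conditions = default_conditions(),
                            base = neuron_params(), seed = 1L) {
  if (n < 1) stop("population size n must be >= 1")
  if (beta_w_sd < 0 || g_leak_sdlog < 0 || g_K_sdlog < 0)
    stop("spread parameters must be >= 0")
  if (beta_w_bounds[2] <= beta_w_bounds[1])
    stop("beta_w_bounds must be an increasing interval")
  need <- c("e_gaba", "delta_beta_w", "g_na_virtual")
  if (!all(need %in% names(conditions)))
    stop("conditions must have columns: ", paste(need, collapse = ", "))
  structure(list(n = as.integer(n), beta_w_mean = beta_w_mean,
                 beta_w_sd = beta_w_sd, beta_w_bounds = beta_w_bounds,
                 g_leak_sdlog = g_leak_sdlog, g_K_sdlog = g_K_sdlog,
                 conditions = conditions, base = base,
                 seed = as.integer(seed)),
            class = "population_spec")
}

#' Default condition matrix: E_GABA x 4-AP-analog shift
#'
#' @param e_gaba reversal potentials tested (mV).
#' @param delta_beta_w excitability shifts tested (mV).
#' @param g_na_virtual virtual sodium density applied in all conditions
#'   (nS/pF).
#' @return data frame of conditions with descriptive row labels.
#' @export
default_conditions <- function(e_gaba = c(-35, -20),
                               delta_beta_w = c(0, 10),
                               g_na_virtual = 0) {
  cond <- expand.grid(e_gaba = e_gaba, delta_beta_w = delta_beta_w,
                      KEEP.OUT.ATTRS = FALSE)
  cond$g_na_virtual <- g_na_virtual
  cond$condition <- sprintf("E%+g_dbw%+g", cond$e_gaba, cond$delta_beta_w)
  cond
}

#' Sample a virtual neuron population
#'
#' Draws `spec$n` parameter sets deterministically from the seeded
#' distributions. Truncation is by resampling; if a cell cannot be drawn
#' inside the bounds (or fails the parameter invariants) within 10 times
#' `n` attempts overall, a distribution-misspecification error is
#' raised. The number of resampled draws is recorded.
#'
#' @param spec a [population_spec()] object.
#' @return a `population`: list with `cells` (list of `neuron_params`),
#'   `draws` (data frame of sampled values) and `n_resampled`.
#' @export
sample_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed)
  cells <- vector("list", spec$n)
  draws <- data.frame(cell = seq_len(spec$n), beta_w = NA_real_,
                      g_leak = NA_real_, g_K_bar = NA_real_)
  attempts <- 0L
  max_attempts <- 10L * spec$n
  for (i in seq_len(spec$n)) {
    repeat {
      attempts <- attempts + 1L
      if (attempts > max_attempts + spec$n)
        stop("distribution-misspecification error: could not sample ",
             "valid parameters within ", max_attempts, " draws")
      bw <- stats::rnorm(1, spec$beta_w_mean, spec$beta_w_sd)
      if (bw < spec$beta_w_bounds[1] || bw > spec$beta_w_bounds[2]) next
      gl <- spec$base$g_leak *
        if (spec$g_leak_sdlog > 0)
          stats::rlnorm(1, 0, spec$g_leak_sdlog) else 1
      gk <- spec$base$g_K_bar *
        if (spec$g_K_sdlog > 0) stats::rlnorm(1, 0, spec$g_K_sdlog) else 1
      p <- spec$base
      p$beta_w <- bw; p$g_leak <- gl; p$g_K_bar <- gk
      ok <- tryCatch({ validate_neuron_params(p); TRUE },
                     error = function(e) FALSE)
      if (ok) {
        cells[[i]] <- p
        draws$beta_w[i] <- bw
        draws$g_leak[i] <- gl
        draws$g_K_bar[i] <- gk
        break
      }
    }
  }
  structure(list(cells = cells, draws = draws,
                 n_resampled = attempts - spec$n, spec = spec),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat("<population>", length(x$cells), "cells; beta_w in [",
      round(min(x$draws$beta_w), 2), ",", round(max(x$draws$beta_w), 2),
      "] mV (seed", x$spec$seed, ")\n")
  invisible(x)
}

#' Run the titration protocol over a population and condition matrix
#'
#' For every cell and every condition, applies the condition (reversal
#' potential, excitability shift, virtual sodium), titrates the minimum
#' conductance density eliciting spiking with [find_min_ggaba()], and
#' summarizes the proportion of spiking cells per condition - the
#' in-silico analog of the proportion-of-neurons-responding tables.
#' The protocol itself is deterministic; all randomness lives in
#' [sample_population()].
#'
#' Cells whose titration errors are recorded (`label = "error"`) and
#' counted as non-spiking rather than aborting the batch.
#'
#' @param population a [sample_population()] result.
#' @param input conductance template titrated per condition (its `e_rev`
#'   is set from the condition); default fast synaptic waveform.
#' @param lower,upper,resolution titration settings (nS/pF).
#' @param ... passed to [find_min_ggaba()].
#' @return a `population_result`: `cells` data frame (cell, condition,
#'   `min_g_bar`, `label`), `summary` data frame (condition, proportion
#'   spiking), and the spec.
#' @export
run_population_protocol <- function(population,
                                    input = synaptic_fast(1, -35),
                                    lower = 0, upper = 10,
                                    resolution = 0.01, ...) {
  stopifnot(inherits(population, "population"))
  cond <- population$spec$conditions
  rows <- list()
  for (ci in seq_len(nrow(cond))) {
    for (k in seq_along(population$cells)) {
      par_k <- population$cells[[k]]
      par_k$beta_w <- par_k$beta_w + cond$delta_beta_w[ci]
      if (cond$g_na_virtual[ci] > 0)
        par_k <- add_virtual_sodium(par_k, cond$g_na_virtual[ci])
      inp <- input
      inp$e_rev <- cond$e_gaba[ci]
      res <- tryCatch(
        find_min_ggaba(par_k, inp, lower, upper, resolution, ...),
        error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        cell = k,
        condition = if ("condition" %in% names(cond))
          cond$condition[ci] else as.character(ci),
        e_gaba = cond$e_gaba[ci],
        delta_beta_w = cond$delta_beta_w[ci],
        min_g_bar = if (is.null(res)) NA_real_ else res$min_g_bar,
        label = if (is.null(res)) "error"
                else if (is.na(res$min_g_bar)) "none" else "spiking")
    }
  }
  cells <- do.call(rbind, rows)
  agg <- stats::aggregate(cells$label == "spiking",
                          by = list(condition = cells$condition),
                          FUN = mean)
  names(agg)[2] <- "proportion_spiking"
  structure(list(cells = cells, summary = agg,
                 spec = population$spec, input = input),
            class = "population_result")
}

#' @export
print.population_result <- function(x, ...) {
  cat("<population_result>\n")
  print(x$summary)
  invisible(x)
}
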