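#' @keywords internal
#' Apply an axis value to the (params, input) context.
#' Recognized axis names: "e_gaba" (reversal of the conductance input),
#' "g_bar" (its amplitude), or any numeric field of neuron_params
#' (e.g. "beta_w", "p").
apply_axis <- function(params, input, name, value) {
  if (name == "e_gaba") {
    input$e_rev <- value
  } else if (name == "g_bar") {
    input$g_bar <- value
  } else if (name %in% names(params)) {
    params[[name]] <- value
  } else {
    stop("unrecognized axis parameter: ", name)
  }
  list(params = params, input = input)
}

# Classify one grid cell; errors name the cell.
cell_response <- function(base, input, name1, v1, name2, v2, ...) {
  ctx <- apply_axis(base, input, name1, v1)
  ctx <- apply_axis(ctx$params, ctx$input, name2, v2)
  tryCatch(classify_trace(ctx$params, ctx$input, ...),
           error = function(e)
             stop(sprintf("cell (%s = %g, %s = %g): %s",
                          name1, v1, name2, v2, conditionMessage(e))))
}

#' Two-parameter region map of PAD-induced spiking
#'
#' Classifies the response to a GABA conductance input over a rectangular
#' grid of two parameters (typically E_GABA against the excitability
#' midpoint `beta_w`, or E_GABA against the inactivating sodium fraction
#' `p`). Each cell is simulated independently from rest - no state
#' carry-over between cells - and classified as none / transient /
#' repetitive. The module is fully deterministic.
#'
#' @param base a [neuron_params()] object (the fixed parameters).
#' @param input a `conductance_input` template; the axes override its
#'   fields where applicable.
#' @param axis1,axis2 lists `list(name =, values =)`; recognized names are
#'   `"e_gaba"`, `"g_bar"` and any `neuron_params` field.
#' @param ... passed to [classify_trace()] (solver and detection options).
#' @return a `region_map`: data frame with the two axis columns plus
#'   `label` and `n_spikes`; axis names, `base` and `input` are attached
#'   as attributes.
#' @export
sweep_spiking_2d <- function(base, input,
                             axis1 = list(name = "e_gaba",
                                          values = seq(-45, 0, 1)),
                             axis2 = list(name = "beta_w",
                                          values = seq(-25, 0, 0.5)),
                             ...) {
  stopifnot(is.character(axis1$name), is.numeric(axis1$values),
            is.character(axis2$name), is.numeric(axis2$values),
            all(is.finite(axis1$values)), all(is.finite(axis2$values)))
  grid <- expand.grid(a1 = axis1$values, a2 = axis2$values,
                      KEEP.OUT.ATTRS = FALSE)
  lab <- character(nrow(grid))
  nsp <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cl <- cell_response(base, input, axis1$name, grid$a1[i],
                        axis2$name, grid$a2[i], ...)
    lab[i] <- cl$label
    nsp[i] <- cl$n_spikes
  }
  out <- data.frame(grid$a1, grid$a2, label = lab, n_spikes = nsp)
  names(out)[1:2] <- c(axis1$name, axis2$name)
  structure(out, class = c("region_map", "data.frame"),
            axes = c(axis1$name, axis2$name), base = base, input = input,
            map_type = "spiking")
}

#' Minimum current-step amplitude driving repetitive spiking
#'
#' Bisection (to `resolution` pA/pF) for the smallest current-step
#' amplitude classified repetitive; used to auto-scale the stimulating
#' current in inhibition sweeps.
#'
#' @param params a [neuron_params()] object.
#' @param i_template `current_input` template (its amplitude is varied).
#' @param lower,upper bracket (pA/pF).
#' @param resolution bisection resolution (pA/pF).
#' @param ... passed to [classify_trace()].
#' @return amplitude in pA/pF, or `NA` if `upper` is insufficient.
#' @export
repetitive_current_threshold <- function(params,
                                         i_template = current_step(0),
                                         lower = 0, upper = 100,
                                         resolution = 0.25, ...) {
  is_rep <- function(a) {
    i_template$amplitude <- a
    classify_trace(params, i_template, ...)$label == "repetitive"
  }
  if (!is_rep(upper)) return(NA_real_)
  lo <- lower; hi <- upper
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    if (is_rep(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Two-parameter region map of PAD-mediated inhibition
#'
#' Over a grid of E_GABA and the inactivating sodium fraction `p`, tests
#' whether a GABA conductance step interposed during a current step stops
#' (or reduces) the current-driven repetitive spiking, and whether the
#' same step elicits PAD-induced spiking on its own. The base parameters
#' are conventionally run at `beta_w = 0` so that the current step drives
#' repetitive spiking.
#'
#' Two inhibition criteria are computed per cell. *Stopped*: no spikes in
#' the final 50\% of the conductance-overlap window. *Reduced*: the spike
#' rate during the overlap drops to at most half the rate in the matched
#' window of the current-alone simulation. Cells where the current alone
#' does not drive repetitive spiking (possible at large `p` through
#' inactivation alone) have `NA` inhibition flags.
#'
#' @param base a [neuron_params()] object, typically with `beta_w = 0`.
#' @param g_input `conductance_input` step template (amplitude and timing
#'   used as given; its `e_rev` is overridden by the axis).
#' @param i_input optional `current_input`; if `NULL`, a 1000 ms step at
#'   1.5x the repetitive-spiking threshold of `base` (at `p` = base value)
#'   is used, and the conductance step is centred within it.
#' @param e_gaba_values,p_values grid values.
#' @param rate_drop reduction factor for the *reduced* criterion.
#' @param ... passed to the simulator/detector.
#' @return a `region_map` data frame with columns `e_gaba`, `p`,
#'   `pad_spiking`, `baseline_repetitive`, `inhibited_stop`,
#'   `inhibited_reduce`, `n_overlap`, `n_baseline`.
#' @export
sweep_inhibition_2d <- function(base, g_input, i_input = NULL,
                                e_gaba_values = seq(-45, 0, 1),
                                p_values = seq(0, 1, 0.05),
                                rate_drop = 0.5, ...) {
  if (is.null(i_input)) {
    thr <- repetitive_current_threshold(base, ...)
    if (is.na(thr))
      stop("protocol error: no current step drives repetitive spiking ",
           "at the base parameters")
    i_input <- current_step(1.5 * thr, t_on = 100, duration = 1000)
    g_input$t_on <- 400
    g_input$duration <- 400
  }
  i_win <- stim_window(i_input)
  g_win <- stim_window(g_input)
  overlap <- c(max(i_win[1], g_win[1]), min(i_win[2], g_win[2]))
  if (overlap[2] <= overlap[1])
    stop("protocol error: g_GABA and I_stim windows do not overlap")
  base_cl <- classify_trace(base, i_input, ...)
  if (base_cl$label != "repetitive")
    stop("protocol error: I_stim alone does not drive repetitive spiking ",
         "at the base parameters (label: ", base_cl$label, ")")
  t_end <- i_win[2] + 100

  count_in <- function(cl, win) {
    sp <- attr(cl, "spikes")
    sum(sp$times >= win[1] & sp$times <= win[2])
  }
  half_win <- c(mean(overlap), overlap[2])

  rows <- vector("list", length(p_values) * length(e_gaba_values))
  k <- 0L
  for (p in p_values) {
    pb <- base; pb$p <- p
    bl <- classify_trace(pb, i_input, t_end = t_end, ...)
    n_base <- count_in(bl, overlap)
    base_rep <- bl$label == "repetitive"
    for (e in e_gaba_values) {
      gi <- g_input; gi$e_rev <- e
      alone <- classify_trace(pb, gi, t_end = t_end, ...)
      both <- classify_trace(pb, i_input, extra = list(gi),
                             t_end = t_end, ...)
      n_ov <- count_in(both, overlap)
      k <- k + 1L
      rows[[k]] <- data.frame(
        e_gaba = e, p = p,
        pad_spiking = alone$n_spikes > 0,
        baseline_repetitive = base_rep,
        inhibited_stop = if (base_rep) count_in(both, half_win) == 0
                         else NA,
        inhibited_reduce = if (base_rep && n_base > 0)
                             n_ov <= rate_drop * n_base else NA,
        n_overlap = n_ov, n_baseline = n_base)
    }
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("region_map", "data.frame"),
            axes = c("e_gaba", "p"), base = base, input = g_input,
            i_input = i_input, overlap = overlap,
            map_type = "inhibition")
}

#' @export
print.region_map <- function(x, ...) {
  ax <- attr(x, "axes")
  cat("<region_map>", attr(x, "map_type"), "map:",
      length(unique(x[[ax[1]]])), "x", length(unique(x[[ax[2]]])),
      "cells over (", ax[1], ",", ax[2], ")\n")
  if (attr(x, "map_type") == "spiking") print(table(x$label))
  invisible(x)
}

# region membership predicate for a label
region_member <- function(map, label) {
  if (label %in% c("any", "transient", "repetitive")) {
    if (attr(map, "map_type") != "spiking")
      stop("label '", label, "' applies to spiking maps only")
    switch(label,
           any = map$label != "none",
           transient = map$label == "transient",
           repetitive = map$label == "repetitive")
  } else if (label %in% names(map)) {
    isTRUE_vec <- map[[label]]
    !is.na(isTRUE_vec) & isTRUE_vec
  } else {
    stop("unknown region label: ", label)
  }
}

#' Extract a region boundary from a region map
#'
#' Localizes, for each value of the second axis, the boundary along the
#' first axis between cells inside and outside the region named by
#' `label` (for spiking maps: `"any"`, `"transient"`, `"repetitive"`; for
#' inhibition maps a logical column name such as `"inhibited_stop"` or
#' `"pad_spiking"`). The boundary point is the midpoint between the last
#' outside cell and the first inside cell scanning axis 1 upward; with
#' `refine = TRUE` (spiking maps) it is sharpened by bisection of fresh
#' simulations to tolerance `tol`.
#'
#' @param map a `region_map`.
#' @param label region name (see above).
#' @param refine logical; bisection refinement along axis 1.
#' @param tol refinement tolerance in axis-1 units (default 0.25 mV).
#' @param ... passed to the simulator during refinement.
#' @return a `boundary_curve` data frame with columns `axis2` value and
#'   `boundary` (axis-1 position); empty (with a warning) if the label
#'   never occurs.
#' @export
extract_boundary <- function(map, label = "any", refine = FALSE,
                             tol = 0.25, ...) {
  ax <- attr(map, "axes")
  inr <- region_member(map, label)
  if (!any(inr)) {
    warning("label '", label, "' absent from map; empty boundary")
    out <- data.frame(numeric(0), numeric(0))
    names(out) <- c(ax[2], "boundary")
    return(structure(out, class = c("boundary_curve", "data.frame"),
                     label = label, axes = ax, empty = TRUE))
  }
  a1 <- map[[ax[1]]]; a2 <- map[[ax[2]]]
  a2v <- sort(unique(a2))
  base <- attr(map, "base"); input <- attr(map, "input")
  res <- lapply(a2v, function(v2) {
    sel <- a2 == v2
    x <- a1[sel][order(a1[sel])]
    m <- inr[sel][order(a1[sel])]
    first <- which(m)[1]
    if (is.na(first)) return(NULL)
    if (first == 1L) return(data.frame(v2 = v2, boundary = x[1]))
    lo <- x[first - 1]; hi <- x[first]
    if (refine && attr(map, "map_type") == "spiking") {
      memb <- function(v1) {
        cl <- cell_response(base, input, ax[1], v1, ax[2], v2, ...)
        switch(label, any = cl$label != "none",
               transient = cl$label == "transient",
               repetitive = cl$label == "repetitive")
      }
      while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        if (memb(mid)) hi <- mid else lo <- mid
      }
      return(data.frame(v2 = v2, boundary = (lo + hi) / 2))
    }
    data.frame(v2 = v2, boundary = (lo + hi) / 2)
  })
  out <- do.call(rbind, res)
  names(out) <- c(ax[2], "boundary")
  structure(out, class = c("boundary_curve", "data.frame"),
            label = label, axes = ax, empty = FALSE,
            resolution = if (length(unique(diff(sort(unique(a1))))) >= 1)
              min(diff(sort(unique(a1)))) else NA_real_)
}

#' Family of region boundaries across GABA conductance density
#'
#' Repeats the two-parameter spiking sweep for several values of
#' `g_bar` and extracts the boundary of one region from each, producing
#' comparable boundary curves on shared axes (as in the boundary-family
#' analyses of the transient and repetitive regions).
#'
#' @param base,input,axis1,axis2 as in [sweep_spiking_2d()].
#' @param g_bars numeric vector (length >= 2) of conductance densities
#'   (nS/pF).
#' @param label region to trace (`"any"`, `"transient"`, `"repetitive"`).
#' @param ... passed to the sweep.
#' @return named list of `boundary_curve` objects (names = `g_bars`),
#'   with the corresponding `region_map`s attached as attribute `maps`.
#' @export
boundary_family <- function(base, input, g_bars,
                            axis1 = list(name = "e_gaba",
                                         values = seq(-45, 0, 1)),
                            axis2 = list(name = "beta_w",
                                         values = seq(-25, 0, 0.5)),
                            label = "repetitive", ...) {
  if (length(g_bars) < 2) stop("need at least two g_bar values")
  maps <- lapply(g_bars, function(g) {
    input$g_bar <- g
    sweep_spiking_2d(base, input, axis1, axis2, ...)
  })
  curves <- lapply(maps, function(m)
    suppressWarnings(extract_boundary(m, label)))
  names(curves) <- as.character(g_bars)
  attr(curves, "maps") <- maps
  curves
}

#' Monotone-region sanity check
#'
#' Within each row at fixed axis 2, checks that the set of axis-1 values
#' inside the region is an "up-set" (once inside when scanning upward,
#' never back outside). The region shapes imply this locally but do not
#' guarantee it globally, so violations are reported, not hidden.
#'
#' @param map a `region_map`.
#' @param label region name as in [extract_boundary()].
#' @return data frame of violating cells (zero rows if none).
#' @export
check_upset <- function(map, label = "any") {
  ax <- attr(map, "axes")
  inr <- region_member(map, label)
  a1 <- map[[ax[1]]]; a2 <- map[[ax[2]]]
  bad <- lapply(sort(unique(a2)), function(v2) {
    sel <- which(a2 == v2)
    sel <- sel[order(a1[sel])]
    m <- inr[sel]
    first <- which(m)[1]
    if (is.na(first)) return(NULL)
    off <- sel[which(!m & seq_along(m) > first)]
    if (!length(off)) return(NULL)
    map[off, c(ax[1], ax[2])]
  })
  out <- do.call(rbind, bad)
  if (is.null(out)) out <- data.frame(numeric(0), numeric(0)) |>
      stats::setNames(ax)
  out
}
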