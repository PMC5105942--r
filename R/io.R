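#' Read and write flat key-value configuration files
#'
#' Parameter presets and stimulus definitions are serialized in a flat
#' `key = value` format (a minimal TOML-style dialect): one assignment
#' per line, `#` comments, double-quoted strings, bare numbers and
#' `true`/`false`. Unknown structure (tables, arrays) is rejected so that
#' malformed configs fail fast with the offending line named.
#'
#' @param path file path.
#' @return named list of values.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(m) != 3)
      stop("config parse error at line ", i, ": '", lines[i], "'")
    key <- m[2]; val <- trimws(m[3])
    out[[key]] <-
      if (grepl('^".*"$', val)) sub('^"(.*)"$', "\\1", val)
      else if (val %in% c("true", "false")) val == "true"
      else {
        num <- suppressWarnings(as.numeric(val))
        if (is.na(num))
          stop("config parse error at line ", i,
               ": unsupported value '", val, "'")
        num
      }
  }
  out
}

#' @rdname read_config
#' @param config named list of scalar values.
#' @export
write_config <- function(config, path) {
  fmt <- vapply(config, function(v) {
    if (is.character(v)) sprintf('"%s"', v)
    else if (is.logical(v)) tolower(as.character(v))
    else format(v, digits = 17)
  }, character(1))
  writeLines(paste(names(config), "=", fmt), path)
  invisible(path)
}

#' Serialize neuron parameters to/from a config file
#'
#' Keys are named exactly as the [neuron_params()] fields.
#'
#' @param params a `neuron_params` object.
#' @param path file path.
#' @export
write_neuron_params <- function(params, path) {
  validate_neuron_params(params)
  write_config(params[vapply(params, is.numeric, logical(1))], path)
}

#' @rdname write_neuron_params
#' @export
read_neuron_params <- function(path) {
  cfg <- read_config(path)
  do.call(neuron_params, cfg[names(cfg) != "preset"])
}

#' Write a simulation trace as tidy CSV
#'
#' Columns `t`, `V`, `w`, `h`, `g_gaba`, `i_stim` at full precision.
#'
#' @param trace a `pad_trace`.
#' @param path file path.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Write a region map as long-format CSV plus a JSON context sidecar
#'
#' The CSV holds one row per grid cell (axis columns plus labels); the
#' sidecar `<path>.json` records the base parameters and stimulus
#' template so the sweep can be reproduced exactly.
#'
#' @param map a `region_map`.
#' @param path CSV path.
#' @export
write_region_map <- function(map, path) {
  utils::write.csv(as.data.frame(map), path, row.names = FALSE)
  ctx <- list(axes = attr(map, "axes"), map_type = attr(map, "map_type"),
              base = unclass(attr(map, "base")),
              input = unclass(attr(map, "input")))
  jsonlite::write_json(ctx, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

cli_usage <- paste(
  "usage: pad <subcommand> --config <file> [--out <dir>]",
  "subcommands: simulate sweep2d titrate rheobase inhibit",
  "             compare-kinetics cable population",
  sep = "\n")

cli_take <- function(cfg, keys, defaults = list()) {
  known <- c(keys, names(defaults))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in names(defaults))
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  cfg
}

cli_params <- function(cfg) {
  pk <- intersect(names(cfg), names(neuron_params()))
  preset <- if (!is.null(cfg$preset)) cfg$preset else "default"
  do.call(neuron_params, c(list(preset = preset), cfg[pk]))
}

cli_input <- function(cfg) {
  kind <- if (is.null(cfg$kind)) "step" else cfg$kind
  g <- if (is.null(cfg$g_bar)) 2 else cfg$g_bar
  e <- if (is.null(cfg$e_gaba)) -35 else cfg$e_gaba
  switch(kind,
         step = conductance_step(g, e),
         ramp = conductance_ramp(g, e),
         fast = synaptic_fast(g, e),
         slow = synaptic_slow(g, e),
         stop("unknown stimulus kind: ", kind))
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `sweep2d`, `titrate`,
#' `rheobase`, `inhibit`, `compare-kinetics`, `cable` and `population`
#' over the package functions, reading a flat config file and writing
#' CSV/JSON artifacts plus an echo of the effective configuration to the
#' output directory. Intended to be called from the thin wrapper script
#' `inst/cli/pad.R`; returns instead of exiting so it can be tested
#' in-process.
#'
#' @param argv character vector of command-line arguments.
#' @return integer exit status (0 on success), invisibly.
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(argv) < 1) stop(cli_usage)
    sub <- argv[1]
    opts <- argv[-1]
    getopt <- function(flag, default = NULL) {
      i <- which(opts == flag)
      if (length(i)) opts[i[1] + 1] else default
    }
    out_dir <- getopt("--out", ".")
    cfg_path <- getopt("--config")
    cfg <- if (!is.null(cfg_path)) read_config(cfg_path) else list()
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    pfields <- names(neuron_params())
    common <- c(pfields, "preset", "kind", "g_bar", "e_gaba")

    res_path <- file.path(out_dir, paste0(sub, ".json"))
    result <- switch(sub,
      simulate = {
        cfg <- cli_take(cfg, common, list(t_end = 1300))
        par <- cli_params(cfg)
        inp <- cli_input(cfg)
        tr <- simulate_neuron(par, inp, t_end = cfg$t_end)
        write_trace_csv(tr, file.path(out_dir, "trace.csv"))
        sp <- detect_spikes(tr)
        cl <- classify_response(sp, stim_window(inp))
        list(n_spikes = length(sp$times), label = cl$label)
      },
      sweep2d = {
        cfg <- cli_take(cfg, common,
                        list(e_gaba_min = -45, e_gaba_max = 0,
                             e_gaba_step = 1, beta_w_min = -25,
                             beta_w_max = 0, beta_w_step = 0.5))
        par <- cli_params(cfg)
        inp <- cli_input(cfg)
        map <- sweep_spiking_2d(par, inp,
          axis1 = list(name = "e_gaba",
                       values = seq(cfg$e_gaba_min, cfg$e_gaba_max,
                                    cfg$e_gaba_step)),
          axis2 = list(name = "beta_w",
                       values = seq(cfg$beta_w_min, cfg$beta_w_max,
                                    cfg$beta_w_step)))
        write_region_map(map, file.path(out_dir, "region_map.csv"))
        as.list(table(map$label))
      },
      titrate = {
        cfg <- cli_take(cfg, common,
                        list(lower = 0, upper = 10, resolution = 0.01,
                             target = "any"))
        res <- find_min_ggaba(cli_params(cfg), cli_input(cfg),
                              cfg$lower, cfg$upper, cfg$resolution,
                              target = cfg$target)
        list(min_g_bar = res$min_g_bar, resolution = res$resolution,
             target = res$target)
      },
      rheobase = {
        cfg <- cli_take(cfg, common,
                        list(lower = 0, upper = 100, resolution = 0.1))
        rb <- rheobase(cli_params(cfg),
                       g_bar = if (is.null(cfg$g_bar)) 0 else cfg$g_bar,
                       e_rev = if (is.null(cfg$e_gaba)) -35 else
                         cfg$e_gaba,
                       lower = cfg$lower, upper = cfg$upper,
                       resolution = cfg$resolution)
        list(rheobase_pA_per_pF = as.numeric(rb))
      },
      inhibit = {
        cfg <- cli_take(cfg, common,
                        list(i_amp = 30, ordering = "g_within_i"))
        res <- inhibition_assay(cli_params(cfg),
                                g_bar = if (is.null(cfg$g_bar)) 2 else
                                  cfg$g_bar,
                                e_rev = if (is.null(cfg$e_gaba)) -35 else
                                  cfg$e_gaba,
                                i_amp = cfg$i_amp,
                                ordering = cfg$ordering)
        res[c("spikes_before", "spikes_during", "spikes_after",
              "inhibited_stop", "inhibited_reduce")]
      },
      `compare-kinetics` = {
        cfg <- cli_take(cfg, common,
                        list(lower = 0, upper = 10, resolution = 0.01))
        res <- compare_kinetics(cli_params(cfg),
                                e_rev = if (is.null(cfg$e_gaba)) -20 else
                                  cfg$e_gaba,
                                lower = cfg$lower, upper = cfg$upper,
                                resolution = cfg$resolution)
        c(as.list(res$min_g_bar),
          list(rate_sensitive = res$rate_sensitive))
      },
      cable = {
        cfg <- cli_take(cfg, common,
                        list(p = 0, pulse_nA = 1, n_pulses = 1,
                             rate_hz = 20, d_lambda = 0.01))
        cab <- build_cable(cable_params(d_lambda = cfg$d_lambda))
        res <- conduction_assay(cab,
                                g_bar = if (is.null(cfg$g_bar)) 2 else
                                  cfg$g_bar,
                                e_gaba = if (is.null(cfg$e_gaba)) -35 else
                                  cfg$e_gaba,
                                p = cfg$p, pulse_nA = cfg$pulse_nA,
                                n_pulses = cfg$n_pulses,
                                rate_hz = cfg$rate_hz)
        utils::write.csv(res$per_pulse,
                         file.path(out_dir, "conduction.csv"),
                         row.names = FALSE)
        list(blocked = res$blocked,
             n_pad_spikes = nrow(res$pad_spikes))
      },
      population = {
        cfg <- cli_take(cfg, common,
                        list(n = 10, seed = 1, beta_w_mean = -20,
                             beta_w_sd = 4, resolution = 0.05))
        spec <- population_spec(cfg$n, beta_w_mean = cfg$beta_w_mean,
                                beta_w_sd = cfg$beta_w_sd,
                                seed = cfg$seed)
        pop <- sample_population(spec)
        res <- run_population_protocol(pop, resolution = cfg$resolution)
        utils::write.csv(res$cells,
                         file.path(out_dir, "population_cells.csv"),
                         row.names = FALSE)
        stats::setNames(as.list(res$summary$proportion_spiking),
                        res$summary$condition)
      },
      stop("unknown subcommand '", sub, "'\n", cli_usage)
    )
    jsonlite::write_json(result, res_path, auto_unbox = TRUE, digits = NA)
    if (length(cfg))
      write_config(cfg, file.path(out_dir, "config_echo.toml"))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
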