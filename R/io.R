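#' Read a scenario configuration file
#'
#' Builds an [invasion_model()] from a plain-text YAML (or JSON, which YAML
#' subsumes) configuration with optional top-level sections `params`,
#' `protocol`, `grids`, `init` and `solver`; omitted keys take the package
#' defaults. An example:
#'
#' ```yaml
#' params:   {alpha: 0.8, beta_l: 2, beta_h: 20}
#' protocol: {period: 10, bias: 0.5, t_final: 60}
#' grids:    {N: 201, M: 101}
#' ```
#'
#' @param path Path to the configuration file.
#' @return An [invasion_model()].
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  params <- do.call(model_params, cfg$params %||% list())
  protocol <- do.call(oxygen_protocol, cfg$protocol %||% list())
  gargs <- cfg$grids %||% list()
  # YAML 1.1 parses a bare key "N" as a boolean; map it back
  names(gargs)[names(gargs) %in% c("FALSE", "F")] <- "N"
  gargs$mu_hn0 <- params$mu_hn0
  grids <- do.call(sim_grids, gargs)
  settings <- do.call(solver_settings, cfg$solver %||% list())
  invasion_model(params, protocol, grids,
                 init = cfg$init %||% list(), settings = settings)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write run outputs to plain-text files
#'
#' `write_observables` writes the scalar observable record as tidy CSV (one
#' row per recorded time). `write_snapshots` writes any field snapshots in
#' long format (`time, x, mu, h`, with `mu = NA` rows carrying the `n` and
#' `e` profiles). Both prepend the exact scenario configuration as
#' `#`-commented YAML lines for provenance.
#'
#' @param sim An `invasion_sim`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_observables <- function(sim, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(config_header(sim$model), con)
  utils::write.csv(sim$obs, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observables
#' @export
write_snapshots <- function(sim, path) {
  g <- sim$model$grids
  rows <- lapply(sim$snapshots, function(s) {
    data.frame(time = s$time,
               x = rep(g$x, times = g$M + 1),
               mu = c(rep(g$mu, each = g$N), rep(NA_real_, g$N)),
               h = c(as.vector(s$h), rep(NA_real_, g$N)),
               n = c(rep(NA_real_, g$N * g$M), s$n),
               e = c(rep(NA_real_, g$N * g$M), s$e))
  })
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(config_header(sim$model), con)
  utils::write.csv(do.call(rbind, rows), con, row.names = FALSE)
  invisible(path)
}

config_header <- function(model) {
  cfg <- list(params = unclass(model$params),
              protocol = Filter(Negate(is.null), unclass(model$protocol)),
              grids = unclass(model$grids)[c("X", "N", "M")],
              init = model$init,
              solver = unclass(model$settings))
  paste0("# ", strsplit(yaml::as.yaml(cfg), "\n")[[1]])
}
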