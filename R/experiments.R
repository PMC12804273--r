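#' Constant-oxygen verification cases
#'
#' Runs the two constant-oxygen scenarios and compares the numerical totals
#' against their closed forms. In the oxygen-deprived case (`c = c_hypoxic`,
#' between the necrotic and hypoxic thresholds) the normoxic total must
#' follow exponential decay and the combined cell mass must be conserved; in
#' the oxygen-rich case (`c = c_rich`) no hypoxic cells may ever appear and
#' each node grows logistically toward its local free volume (the logistic
#' closed form applied nodewise and integrated).
#'
#' @param params A [model_params()] object.
#' @param grids A [sim_grids()] object.
#' @param settings A [solver_settings()] object.
#' @param t_final Final time.
#' @param c_hypoxic,c_rich Constant oxygen levels for the two cases.
#' @param mass_fractions Fractions of the initial normoxic mass whose
#'   first-crossing times are reported for the hypoxic case.
#' @return An object of class `case_studies`: per-case sup-errors against
#'   the closed forms, the conservation defect, crossing times, the final
#'   mean phenotype of the hypoxic case, and both `invasion_sim` objects.
#' @export
run_case_studies <- function(params = model_params(),
                             grids = sim_grids(mu_hn0 = params$mu_hn0),
                             settings = solver_settings(),
                             t_final = 60,
                             c_hypoxic = 0.4, c_rich = 1,
                             mass_fractions = 1e-3) {
  m1 <- invasion_model(params,
                       oxygen_protocol(mode = "constant", level = c_hypoxic,
                                       t_final = t_final),
                       grids, settings = settings)
  m2 <- invasion_model(params,
                       oxygen_protocol(mode = "constant", level = c_rich,
                                       t_final = t_final),
                       grids, settings = settings)
  sim1 <- simulate(m1)
  sim2 <- simulate(m2)

  st0 <- initialize_state(grids)
  N0 <- spatial_integral(st0$n, grids$dx)

  an1 <- analytic_hypoxic_decay(sim1$obs$time, N0, params$mu_nh)
  sup_hypoxic <- max(abs(sim1$obs$n_tot - an1$n_tot))
  conservation <- max(abs(sim1$obs$n_tot + sim1$obs$h_tot - N0))
  crossing <- vapply(mass_fractions, function(f)
    crossing_time(sim1$obs$time, sim1$obs$n_tot, f * N0), numeric(1))
  names(crossing) <- paste0("frac_", mass_fractions)

  an2 <- nodewise_logistic_total(st0, sim2$obs$time, params)
  sup_rich <- max(abs(sim2$obs$n_tot - an2))
  max_h_rich <- max(abs(sim2$obs$h_tot))

  structure(list(
    N0 = N0,
    hypoxic = list(sim = sim1, sup_error = sup_hypoxic,
                   conservation_defect = conservation,
                   crossing_times = crossing,
                   final_mean_phenotype =
                     sim1$obs$mean_phenotype[nrow(sim1$obs)]),
    rich = list(sim = sim2, sup_error = sup_rich, max_h_tot = max_h_rich)
  ), class = "case_studies")
}

# first time a recorded series falls below a level, linearly interpolated
crossing_time <- function(t, v, level) {
  below <- which(v < level)
  if (!length(below)) return(NA_real_)
  i <- below[1L]
  if (i == 1L) return(t[1L])
  t[i - 1L] + (t[i] - t[i - 1L]) * (v[i - 1L] - level) / (v[i - 1L] - v[i])
}

# space-integrated nodewise logistic solution for the oxygen-rich case
nodewise_logistic_total <- function(state0, t, params) {
  g <- state0$grids
  key <- paste(state0$n, state0$e)
  tot <- numeric(length(t))
  for (k in which(!duplicated(key))) {
    cnt <- sum(key == key[k])
    if (state0$n[k] == 0) next
    tot <- tot + cnt *
      analytic_normoxic_logistic(t, state0$n[k], state0$e[k],
                                 params$lambda_n)$n_tot
  }
  tot * g$dx
}

#' @export
print.case_studies <- function(x, ...) {
  cat("Constant-oxygen verification (N0 =", format(x$N0), ")\n")
  cat(sprintf("  oxygen-deprived: sup-error vs exp decay %.3g, conservation defect %.3g\n",
              x$hypoxic$sup_error, x$hypoxic$conservation_defect))
  cat(sprintf("    mass-fraction crossing times: %s\n",
              paste(names(x$hypoxic$crossing_times),
                    formatC(x$hypoxic$crossing_times, digits = 5,
                            format = "g"), sep = " = ", collapse = ", ")))
  cat(sprintf("    final mean phenotype %.4f\n",
              x$hypoxic$final_mean_phenotype))
  cat(sprintf("  oxygen-rich: sup-error vs logistic %.3g, max |h_tot| = %g\n",
              x$rich$sup_error, x$rich$max_h_tot))
  invisible(x)
}

# run one cyclic scenario and summarise it
run_arm <- function(period, bias, alpha, params, grids, settings, t_final,
                    hitting_target) {
  p <- params
  p$alpha <- alpha
  p <- do.call(model_params, unclass(p))
  m <- invasion_model(p, oxygen_protocol(period = period, bias = bias,
                                         t_final = t_final),
                      grids, settings = settings)
  sim <- simulate(m, keep_final_state = TRUE)
  last <- sim$obs[nrow(sim$obs), ]
  list(sim = sim,
       row = data.frame(
         period = period, bias = bias,
         arm = if (alpha > 0) "memory" else "memoryless",
         beta_l = p$beta_l, beta_h = p$beta_h,
         final_volume = last$volume,
         final_boundary = last$boundary,
         hitting_time = hitting_time(sim, hitting_target),
         mean_front_hypoxic_fraction = mean_front_hypoxic_fraction(sim)))
}

# join memory/memoryless rows of a sweep into percent-change summaries
memory_effect_table <- function(tab, by) {
  mem <- tab[tab$arm == "memory", ]
  base <- tab[tab$arm == "memoryless", ]
  idx <- match(do.call(paste, mem[by]), do.call(paste, base[by]))
  base <- base[idx, ]
  out <- mem[by]
  out$final_volume_memory <- mem$final_volume
  out$final_volume_memoryless <- base$final_volume
  out$pct_volume_change <- percent_change(mem$final_volume,
                                          base$final_volume)
  out$hitting_time_memory <- mem$hitting_time
  out$hitting_time_memoryless <- base$hitting_time
  out$pct_hitting_change <- percent_change(mem$hitting_time,
                                           base$hitting_time)
  out$pct_boundary_change <- percent_change(mem$final_boundary,
                                            base$final_boundary)
  rownames(out) <- NULL
  out
}

#' Cyclic-period sweep
#'
#' Runs the cyclic protocol over a set of full-cycle periods with symmetric
#' bias, in a hypoxic-memory arm and a memoryless arm (`alpha = 0`), and
#' summarises final volume, boundary hitting time, and mean front hypoxic
#' fraction per run, plus the percent changes of the memory arm relative to
#' the memoryless baseline and the period at which memory's effect is
#' largest.
#'
#' @param periods Full cycle lengths to sweep.
#' @param bias Hypoxic fraction of each cycle.
#' @param params A [model_params()] object; the memory arm uses its `alpha`
#'   and `beta` values, the baseline arm sets `alpha = 0`.
#' @param grids,settings Mesh and solver settings shared by all runs.
#' @param t_final Final time of every run.
#' @param hitting_target Boundary position whose hitting time is reported.
#' @return An object of class `period_sweep`: `$runs` (one row per run),
#'   `$effect` (percent changes per period), `$best_period_volume` and
#'   `$best_period_hitting` (periods of maximal absolute percent change).
#' @export
run_period_sweep <- function(periods = c(5, 10, 15, 20), bias = 0.5,
                             params = model_params(),
                             grids = sim_grids(mu_hn0 = params$mu_hn0),
                             settings = solver_settings(),
                             t_final = 60, hitting_target = 9.62) {
  stopifnot(length(periods) >= 1)
  rows <- list()
  for (P in periods) {
    for (alpha in c(params$alpha, 0)) {
      a <- run_arm(P, bias, alpha, params, grids, settings, t_final,
                   hitting_target)
      rows[[length(rows) + 1L]] <- a$row
    }
  }
  runs <- do.call(rbind, rows)
  eff <- memory_effect_table(runs, "period")
  argmax_period <- function(v)
    if (all(is.na(v))) NA_real_ else eff$period[which.max(abs(v))]
  structure(list(
    runs = runs, effect = eff,
    hitting_target = hitting_target,
    best_period_volume = argmax_period(eff$pct_volume_change),
    best_period_hitting = argmax_period(eff$pct_hitting_change),
    best_period_boundary = argmax_period(eff$pct_boundary_change)
  ), class = "period_sweep")
}

#' @export
print.period_sweep <- function(x, ...) {
  cat("Cyclic-period sweep (hitting target x =", x$hitting_target, ")\n")
  print(x$effect, digits = 4)
  cat(sprintf("memory effect maximal at period %g (volume), %g (hitting time)\n",
              x$best_period_volume, x$best_period_hitting))
  invisible(x)
}

#' Hypoxic-bias sweep
#'
#' Runs the cyclic protocol at a fixed period over a set of hypoxic-bias
#' values (fraction of each cycle spent hypoxic), in memory and memoryless
#' arms, summarising the same metrics as [run_period_sweep()].
#'
#' @param biases Hypoxic-bias values in (0, 1).
#' @param period Full cycle length.
#' @param params,grids,settings,t_final As in [run_period_sweep()].
#' @param hitting_target Boundary position whose hitting time is reported.
#' @return An object of class `bias_sweep` with `$runs` and `$effect`.
#' @export
run_bias_sweep <- function(biases = c(0.25, 0.4, 0.5, 0.6, 0.75), period = 5,
                           params = model_params(),
                           grids = sim_grids(mu_hn0 = params$mu_hn0),
                           settings = solver_settings(),
                           t_final = 60, hitting_target = 9.1) {
  stopifnot(length(biases) >= 1)
  rows <- list()
  for (b in biases) {
    for (alpha in c(params$alpha, 0)) {
      a <- run_arm(period, b, alpha, params, grids, settings, t_final,
                   hitting_target)
      rows[[length(rows) + 1L]] <- a$row
    }
  }
  runs <- do.call(rbind, rows)
  structure(list(runs = runs, effect = memory_effect_table(runs, "bias"),
                 hitting_target = hitting_target),
            class = "bias_sweep")
}

#' @export
print.bias_sweep <- function(x, ...) {
  cat("Hypoxic-bias sweep (hitting target x =", x$hitting_target, ")\n")
  print(x$effect, digits = 4)
  invisible(x)
}

#' Memory-timescale grid
#'
#' Sweeps the memory-induction (`beta_l`) and memory-erasure (`beta_h`)
#' timescales on a full factorial grid at fixed period and bias, reporting
#' final volume, hitting time and mean front hypoxic fraction per cell, and
#' the sensitivity (range of each metric) along each timescale axis.
#'
#' @param beta_l_values,beta_h_values Timescale grids.
#' @param period,bias Cycle length and hypoxic fraction.
#' @param params,grids,settings,t_final As in [run_period_sweep()].
#' @param hitting_target Boundary position whose hitting time is reported.
#' @return An object of class `beta_grid`: `$runs` (one row per cell, plus
#'   the memoryless baseline) and `$sensitivity` (metric ranges across each
#'   axis).
#' @export
run_beta_grid <- function(beta_l_values = c(2, 10),
                          beta_h_values = c(20, 50),
                          period = 5, bias = 0.5,
                          params = model_params(),
                          grids = sim_grids(mu_hn0 = params$mu_hn0),
                          settings = solver_settings(),
                          t_final = 60, hitting_target = 9.62) {
  rows <- list()
  for (bl in beta_l_values) {
    for (bh in beta_h_values) {
      p <- params
      p$beta_l <- bl
      p$beta_h <- bh
      p <- do.call(model_params, unclass(p))
      a <- run_arm(period, bias, p$alpha, p, grids, settings, t_final,
                   hitting_target)
      rows[[length(rows) + 1L]] <- a$row
    }
  }
  base <- run_arm(period, bias, 0, params, grids, settings, t_final,
                  hitting_target)
  runs <- rbind(do.call(rbind, rows), base$row)

  mem <- runs[runs$arm == "memory", ]
  axis_range <- function(split_by, metric) {
    g <- split(mem[[metric]], mem[[split_by]])
    # range of the metric when the OTHER axis varies, maximised over levels
    r <- vapply(g, function(v) {
      if (all(is.na(v))) NA_real_ else diff(range(v, na.rm = TRUE))
    }, numeric(1))
    if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE)
  }
  metrics <- c("final_volume", "final_boundary", "hitting_time")
  sensitivity <- data.frame(
    metric = metrics,
    range_across_beta_l = vapply(metrics, function(m)
      axis_range("beta_h", m), numeric(1)),
    range_across_beta_h = vapply(metrics, function(m)
      axis_range("beta_l", m), numeric(1)))
  rownames(sensitivity) <- NULL
  structure(list(runs = runs, sensitivity = sensitivity,
                 hitting_target = hitting_target),
            class = "beta_grid")
}

#' @export
print.beta_grid <- function(x, ...) {
  cat("Memory-timescale grid (hitting target x =", x$hitting_target, ")\n")
  print(x$runs[, c("beta_l", "beta_h", "arm", "final_volume",
                   "hitting_time", "mean_front_hypoxic_fraction")],
        digits = 4)
  cat("axis sensitivities (max metric range along each axis):\n")
  print(x$sensitivity, digits = 4)
  invisible(x)
}

#' Memory-structure snapshots
#'
#' For each combination of period and memory-induction timescale, runs the
#' cyclic protocol with field snapshots at the end of the last normoxic
#' phase and the end of the last hypoxic phase, and extracts the normalized
#' phenotype distributions in the bulk and front regions, their
#' strong-memory fractions, the front-to-bulk strong-memory ratio, and the
#' Jensen-Shannon divergence between front and bulk.
#'
#' @param periods Cycle lengths to examine.
#' @param beta_l_values Memory-induction timescales.
#' @param beta_h Memory-erasure timescale (fixed).
#' @param bias Hypoxic fraction of each cycle.
#' @param params,grids,settings,t_final As in [run_period_sweep()].
#' @param frontdef A [front_definition()].
#' @return An object of class `memory_structure`: `$summary` (one row per
#'   period x beta_l x cycle-end) and `$distributions` (the
#'   [phenotype_distribution()] objects, keyed
#'   `period<P>_bl<beta_l>_<cycle>_<region>`).
#' @export
run_memory_structure <- function(periods = c(5, 20), beta_l_values = c(2, 10),
                                 beta_h = 20, bias = 0.5,
                                 params = model_params(),
                                 grids = sim_grids(mu_hn0 = params$mu_hn0),
                                 settings = solver_settings(),
                                 t_final = 60,
                                 frontdef = front_definition()) {
  rows <- list()
  dists <- list()
  for (P in periods) {
    for (bl in beta_l_values) {
      p <- params
      p$beta_l <- bl
      p$beta_h <- beta_h
      p <- do.call(model_params, unclass(p))
      snap_times <- c(`end-of-normoxic` = t_final - bias * P,
                      `end-of-hypoxic` = t_final)
      s <- solver_settings(settings$cfl_safety, settings$output_every,
                           snapshot_times = unname(snap_times))
      m <- invasion_model(p, oxygen_protocol(period = P, bias = bias,
                                             t_final = t_final),
                          grids, settings = s)
      sim <- simulate(m)
      for (ci in seq_along(snap_times)) {
        cyc <- names(snap_times)[ci]
        snap <- sim$snapshots[[which.min(abs(
          vapply(sim$snapshots, `[[`, numeric(1), "requested_time") -
            snap_times[ci]))]]
        st <- structure(list(t = snap$time, n = snap$n, h = snap$h,
                             e = snap$e, grids = grids),
                        class = "tumor_state")
        pb <- phenotype_distribution(st, "bulk", frontdef, cyc)
        pf <- phenotype_distribution(st, "front", frontdef, cyc)
        key <- sprintf("period%g_bl%g_%s", P, bl, cyc)
        dists[[paste0(key, "_bulk")]] <- pb
        dists[[paste0(key, "_front")]] <- pf
        ok <- inherits(pb, "phenotype_distribution") &&
          inherits(pf, "phenotype_distribution")
        smf_b <- strong_memory_fraction(pb)
        smf_f <- strong_memory_fraction(pf)
        rows[[length(rows) + 1L]] <- data.frame(
          period = P, beta_l = bl, beta_h = beta_h, cycle = cyc,
          strong_memory_bulk = smf_b, strong_memory_front = smf_f,
          front_bulk_ratio = if (ok && smf_b > 0) smf_f / smf_b else NA_real_,
          jsd_front_bulk = if (ok) jensen_shannon_divergence(pf, pb)
                           else NA_real_)
      }
    }
  }
  structure(list(summary = do.call(rbind, rows), distributions = dists),
            class = "memory_structure")
}

#' @export
print.memory_structure <- function(x, ...) {
  cat("Memory-structure snapshots (front vs bulk)\n")
  print(x$summary, digits = 4)
  invisible(x)
}
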