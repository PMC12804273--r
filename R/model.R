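#' Phenotype-structured invasion model
#'
#' Bundles and cross-validates a complete scenario: dimensionless parameters,
#' oxygen protocol, meshes, initial condition and solver settings. This is
#' the single entry point for running the model; pass the result to
#' [simulate()].
#'
#' Cross-checks enforced here (beyond each component's own validation):
#' a cyclic protocol must straddle the hypoxic threshold (`c2 < c_H < c1`);
#' the phenotype mesh must contain the injection coordinate `mu_hn0`; and
#' when memory is active (`alpha > 0`) and the protocol visits a hypoxic
#' level `c2 < c_H`, the asymptotic trait `mu_hn0 - alpha * (1 - c2)` must be
#' strictly positive, so that the minimal attained transition rate stays
#' positive.
#'
#' @param params A [model_params()] object.
#' @param protocol An [oxygen_protocol()] object.
#' @param grids A [sim_grids()] object; defaults to the standard mesh built
#'   around `params$mu_hn0`.
#' @param init Named list with the initial-condition parameters `n0`, `e0`,
#'   `a`, `b` (see [initialize_state()]).
#' @param settings A [solver_settings()] object.
#' @return An object of class `invasion_model`.
#' @examples
#' m <- invasion_model(protocol = oxygen_protocol(period = 5))
#' sim <- simulate(m)
#' summary(sim)
#' @export
invasion_model <- function(params = model_params(),
                           protocol = oxygen_protocol(),
                           grids = sim_grids(mu_hn0 = params$mu_hn0),
                           init = list(n0 = 0.5, e0 = 0.5, a = 4, b = 6),
                           settings = solver_settings()) {
  stopifnot(inherits(params, "model_params"),
            inherits(protocol, "oxygen_protocol"),
            inherits(grids, "sim_grids"),
            inherits(settings, "solver_settings"))
  if (abs(grids$mu[grids$injection_index] - params$mu_hn0) > 1e-12)
    stop("phenotype mesh injection node does not match params$mu_hn0")
  hyp_levels <- if (protocol$mode == "constant") {
    if (protocol$level < params$c_H) protocol$level else numeric(0)
  } else {
    if (!(protocol$c2 < params$c_H && params$c_H < protocol$c1))
      stop("cyclic protocol must straddle the hypoxic threshold: ",
           "need c2 < c_H < c1")
    protocol$c2
  }
  if (params$alpha > 0 && length(hyp_levels)) {
    mu_star <- params$mu_hn0 - params$alpha * (1 - min(hyp_levels))
    if (mu_star <= 0)
      stop("memory strength too large: the asymptotic trait mu_hn0 - ",
           "alpha*(1 - c2) = ", mu_star, " must stay positive")
  }
  init <- utils::modifyList(list(n0 = 0.5, e0 = 0.5, a = 4, b = 6), init)
  structure(list(params = params, protocol = protocol, grids = grids,
                 init = init, settings = settings),
            class = "invasion_model")
}

#' @export
print.invasion_model <- function(x, ...) {
  cat("Phenotype-structured invasion model\n")
  print(x$protocol)
  print(x$grids)
  cat(sprintf("  memory: alpha = %g (beta_l = %g, beta_h = %g)%s\n",
              x$params$alpha, x$params$beta_l, x$params$beta_h,
              if (x$params$alpha == 0) " [memoryless]" else ""))
  cat(sprintf("  initial slab: n0 = %g on [%g, %g], e0 = %g outside\n",
              x$init$n0, x$init$a, x$init$b, x$init$e0))
  invisible(x)
}

#' Run the model
#'
#' Integrates the model to `t_final` with the CFL-limited forward-Euler
#' scheme, recording scalar observables on a regular stride and full field
#' snapshots at any requested times. The model has no stochastic component:
#' `nsim` and `seed` are accepted for compatibility with the generic and
#' ignored, and two runs of the same model are bit-for-bit identical.
#'
#' @param object An [invasion_model()].
#' @param nsim,seed Ignored (deterministic model).
#' @param t_final Final time; defaults to the protocol's `t_final`.
#' @param keep_final_state Keep the full final `tumor_state` on the result.
#' @param ... Unused.
#' @return An object of class `invasion_sim`: the model, the observable
#'   record (`$obs`, one row per recorded time with columns `time, oxygen,
#'   n_tot, h_tot, e_tot, volume, boundary, front_hypoxic_fraction,
#'   mean_phenotype`), any snapshots (`$snapshots`), the timestep `$dt`,
#'   step count and clip counter.
#' @export
simulate.invasion_model <- function(object, nsim = 1, seed = NULL,
                                    t_final = object$protocol$t_final,
                                    keep_final_state = TRUE, ...) {
  params <- object$params
  grids <- object$grids
  protocol <- object$protocol
  settings <- object$settings
  frontdef <- front_definition()

  state <- initialize_state(grids, object$init$n0, object$init$e0,
                            object$init$a, object$init$b)

  if (t_final <= 0) {
    obs <- as.data.frame(t(record_observables(state, protocol, frontdef)))
    return(structure(list(model = object, obs = obs, snapshots = list(),
                          dt = NA_real_, n_steps = 0L, clip_count = 0L,
                          final_state = if (keep_final_state) state),
                     class = "invasion_sim"))
  }

  dt0 <- as.numeric(cfl_timestep(grids, params, protocol, settings))
  n_steps <- as.integer(ceiling(t_final / dt0))
  dt <- t_final / n_steps                 # land exactly on t_final
  stride <- max(1L, floor(settings$output_every / dt + 1e-9))

  N <- grids$N
  M <- grids$M
  dx <- grids$dx
  dmu <- grids$dmu
  j0 <- grids$injection_index

  # trait columns that can ever hold mass: injection happens at mu_hn0 and
  # the drift above max(mu_hn0, attained equilibria) always points downward,
  # so higher columns stay identically zero and are skipped in the loop
  levels <- if (protocol$mode == "constant") protocol$level
            else c(protocol$c1, protocol$c2)
  mu_cap <- max(params$mu_hn0, params$mu_hn0 + params$alpha * (levels - 1))
  ja <- min(M, max(which(grids$mu <= mu_cap + 1e-12)) + 1L)
  mu_a <- grids$mu[seq_len(ja)]

  # per-oxygen-level precomputation: gates, escape weights and donor-cell
  # advection weights (dt/dmu * face velocity, split by upwind direction)
  level_cache <- lapply(levels, function(cc) {
    mu_face <- (mu_a[-ja] + mu_a[-1]) / 2
    vf <- phenotype_velocity(mu_face, cc, params)
    w <- dt / dmu * vf
    list(c = cc,
         gN = heaviside(cc - params$c_H) == 1,
         gH = heaviside(params$c_H - cc) == 1,
         gD = heaviside(params$c_N - cc) == 1,
         W1 = matrix(rep(w * (vf >= 0), each = N), nrow = N),
         W2 = matrix(rep(w * (vf < 0), each = N), nrow = N))
  })

  dtD <- dt * params$D_h / dx^2
  dtXi <- dt * params$xi_h / dx^2
  dtinj <- dt * params$mu_nh / dmu
  MUdt <- matrix(rep(dt * mu_a, each = N), nrow = N)

  n <- state$n
  e <- state$e
  h <- state$h[, seq_len(ja), drop = FALSE]

  n_rec <- length(seq(0L, n_steps, by = stride))
  if (n_steps %% stride != 0L) n_rec <- n_rec + 1L
  rec <- matrix(NA_real_, nrow = n_rec, ncol = 9L)
  colnames(rec) <- c("time", "oxygen", "n_tot", "h_tot", "e_tot", "volume",
                     "boundary", "front_hypoxic_fraction", "mean_phenotype")

  record <- function(t, c_now, n, h, e, Hx) {
    n_tot <- sum(n) * dx
    h_tot <- sum(Hx) * dx
    total <- n + Hx
    b <- boundary_from_profile(total, grids$x, frontdef$boundary_threshold)
    ff <- front_fraction_from_fields(n, Hx, grids$x, b, frontdef)
    hsum <- sum(h)
    mean_mu <- if (hsum > 0) sum(colSums(h) * mu_a) / hsum else NA_real_
    c(t, c_now, n_tot, h_tot, sum(e) * dx, n_tot + h_tot, b, ff, mean_mu)
  }

  Hx <- rowSums(h) * dmu
  rec[1L, ] <- record(0, oxygen_at(protocol, 0), n, h, e, Hx)
  irec <- 1L

  snaps <- list()
  snap_times <- settings$snapshot_times
  snap_times <- snap_times[snap_times <= t_final + 1e-9]
  isnap <- 1L
  embed_h <- function(h) {
    full <- matrix(0, nrow = N, ncol = M)
    full[, seq_len(ja)] <- h
    full
  }

  clip_count <- 0L
  t <- 0
  for (k in seq_len(n_steps)) {
    c_now <- oxygen_at(protocol, t)
    L <- level_cache[[which(vapply(level_cache, `[[`, numeric(1), "c")
                            == c_now)[1L]]]
    Hx <- rowSums(h) * dmu

    # spatial transport (volume-filling diffusion + haptotaxis), flux form
    phi <- 1 - n - Hx - e
    pf <- dtD * (phi[-N] + phi[-1]) / 2
    de <- dtXi * (e[-1] - e[-N])
    fl <- pf * (h[-1, , drop = FALSE] - h[-N, , drop = FALSE]) -
      de * (h[-1, , drop = FALSE] + h[-N, , drop = FALSE]) / 2
    hn <- h
    hn[-N, ] <- hn[-N, ] + fl
    hn[-1, ] <- hn[-1, ] - fl

    # conservative donor-cell trait advection
    fmu <- h[, -ja, drop = FALSE] * L$W1 + h[, -1, drop = FALSE] * L$W2
    hn[, -ja] <- hn[, -ja] - fmu
    hn[, -1] <- hn[, -1] + fmu

    # oxygen-gated reactions
    if (L$gH) {
      hn[, j0] <- hn[, j0] + dtinj * n
      n_new <- n - dt * params$mu_nh * n
    } else if (L$gN) {
      mom <- sum_cols_weighted(h, mu_a) * dmu
      hn <- hn - MUdt * h
      n_new <- n + dt * (params$lambda_n * n * phi + mom)
    } else {
      n_new <- n
    }
    if (L$gD) {
      hn <- hn - dt * params$gamma_h * h
      n_new <- n_new - dt * params$gamma_n * n
    }
    e_new <- e * (1 - params$delta * dt * Hx)

    # positivity guard: clip roundoff-level negativity, abort on worse
    mn <- min(min(n_new), min(hn), min(e_new))
    if (is.na(mn) || mn < -1e-12) {
      if (is.na(mn)) stop("non-finite state at t = ", t,
                          "; the explicit scheme has become unstable")
      stop("negative values beyond tolerance at t = ", t, " (min = ", mn,
           "); check the timestep bound")
    }
    if (mn < 0) {
      clip_count <- clip_count +
        sum(n_new < 0) + sum(hn < 0) + sum(e_new < 0)
      n_new[n_new < 0] <- 0
      hn[hn < 0] <- 0
      e_new[e_new < 0] <- 0
    }
    n <- n_new
    h <- hn
    e <- e_new
    t <- k * dt

    if (k %% stride == 0L || k == n_steps) {
      irec <- irec + 1L
      rec[irec, ] <- record(t, oxygen_at(protocol, t), n, h, e,
                            rowSums(h) * dmu)
    }
    while (isnap <= length(snap_times) && t >= snap_times[isnap] - 1e-9) {
      snaps[[length(snaps) + 1L]] <-
        list(requested_time = snap_times[isnap], time = t,
             n = n, h = embed_h(h), e = e)
      isnap <- isnap + 1L
    }
  }
  obs <- as.data.frame(rec[seq_len(irec), , drop = FALSE])
  final_state <- if (keep_final_state)
    structure(list(t = t, n = n, h = embed_h(h), e = e, grids = grids),
              class = "tumor_state")
  structure(list(model = object, obs = obs, snapshots = snaps,
                 dt = dt, n_steps = n_steps, clip_count = clip_count,
                 final_state = final_state),
            class = "invasion_sim")
}

# column-weighted row reduction: sum_j h[, j] * w[j], without building the
# weighted matrix (used for the phenotype first moment in the hot loop)
sum_cols_weighted <- function(h, w) drop(h %*% w)

record_observables <- function(state, protocol, frontdef) {
  g <- state$grids
  Hx <- integrated_H(state$h, g$dmu)
  n_tot <- spatial_integral(state$n, g$dx)
  h_tot <- spatial_integral(Hx, g$dx)
  e_tot <- spatial_integral(state$e, g$dx)
  total <- state$n + Hx
  b <- boundary_from_profile(total, g$x, frontdef$boundary_threshold)
  ff <- front_fraction_from_fields(state$n, Hx, g$x, b, frontdef)
  hsum <- sum(state$h)
  mean_mu <- if (hsum > 0) sum(colSums(state$h) * g$mu) / hsum else NA_real_
  c(time = state$t, oxygen = oxygen_at(protocol, state$t),
    n_tot = n_tot, h_tot = h_tot, e_tot = e_tot, volume = n_tot + h_tot,
    boundary = b, front_hypoxic_fraction = ff, mean_phenotype = mean_mu)
}

#' @export
print.invasion_sim <- function(x, ...) {
  o <- x$obs
  last <- o[nrow(o), ]
  cat(sprintf("Invasion simulation: t in [0, %g], %d steps (dt = %.4g)\n",
              last$time, x$n_steps, x$dt))
  cat(sprintf("  final volume = %.4f, boundary = %.3f, hypoxic share = %.3f\n",
              last$volume, last$boundary,
              if (last$volume > 0) last$h_tot / last$volume else NA))
  if (x$clip_count > 0)
    cat(sprintf("  %d roundoff-negative entries clipped to zero\n",
                x$clip_count))
  invisible(x)
}

#' @export
summary.invasion_sim <- function(object, ...) {
  o <- object$obs
  last <- o[nrow(o), ]
  out <- list(
    t_final = last$time,
    dt = object$dt,
    n_steps = object$n_steps,
    final_volume = last$volume,
    final_boundary = last$boundary,
    final_n_tot = last$n_tot,
    final_h_tot = last$h_tot,
    final_e_tot = last$e_tot,
    final_mean_phenotype = last$mean_phenotype,
    mean_front_hypoxic_fraction =
      mean(o$front_hypoxic_fraction, na.rm = TRUE),
    clip_count = object$clip_count
  )
  class(out) <- "summary.invasion_sim"
  out
}

#' @export
print.summary.invasion_sim <- function(x, ...) {
  cat(sprintf("Simulation to t = %g (%d steps, dt = %.4g)\n",
              x$t_final, x$n_steps, x$dt))
  cat(sprintf("  final tumor volume        %.4f\n", x$final_volume))
  cat(sprintf("  final right boundary      %.3f\n", x$final_boundary))
  cat(sprintf("  final totals  n / H / e   %.4f / %.4f / %.3f\n",
              x$final_n_tot, x$final_h_tot, x$final_e_tot))
  cat(sprintf("  final mean phenotype      %s\n",
              formatC(x$final_mean_phenotype, digits = 4, format = "g")))
  cat(sprintf("  mean front hypoxic frac.  %.4f\n",
              x$mean_front_hypoxic_fraction))
  invisible(x)
}

#' @export
as.data.frame.invasion_sim <- function(x, ...) x$obs

#' Plot a simulated trajectory
#'
#' Three base-graphics panels: population totals against time, the tumor
#' right boundary, and the oxygen schedule.
#'
#' @param x An `invasion_sim`.
#' @param ... Passed to [graphics::matplot()] for the totals panel.
#' @export
plot.invasion_sim <- function(x, ...) {
  o <- x$obs
  op <- graphics::par(mfrow = c(3, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::matplot(o$time, cbind(o$n_tot, o$h_tot, o$volume), type = "l",
                    lty = 1, col = c("forestgreen", "firebrick", "black"),
                    xlab = "time", ylab = "total mass", ...)
  graphics::legend("topleft", c("normoxic", "hypoxic", "total"), lty = 1,
                   col = c("forestgreen", "firebrick", "black"), bty = "n")
  graphics::plot(o$time, o$boundary, type = "l", xlab = "time",
                 ylab = "right boundary")
  graphics::plot(o$time, o$oxygen, type = "s", xlab = "time",
                 ylab = "oxygen", ylim = c(0, 1.05))
  invisible(x)
}
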