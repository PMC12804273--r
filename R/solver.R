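#' Solver settings for the explicit scheme
#'
#' @param cfl_safety Multiplier in (0, 1\] applied to the stability bound.
#' @param output_every Approximate recording stride for scalar observables,
#'   in time units (records fall on whole solver steps).
#' @param snapshot_times Times at which full `h(x, mu)` field snapshots are
#'   captured (each snapshot is taken at the first solver step reaching the
#'   requested time).
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(cfl_safety = 0.9, output_every = 0.1,
                            snapshot_times = numeric(0)) {
  stopifnot(cfl_safety > 0, cfl_safety <= 1, output_every > 0)
  structure(list(cfl_safety = cfl_safety, output_every = output_every,
                 snapshot_times = sort(unique(snapshot_times))),
            class = "solver_settings")
}

#' Front (tumor-edge) definition
#'
#' @param boundary_threshold Total cell density level defining the tumor
#'   right boundary.
#' @param front_depth Distance inward from the right boundary delimiting the
#'   front region.
#' @return An object of class `front_definition`.
#' @export
front_definition <- function(boundary_threshold = 1e-6, front_depth = 0.5) {
  stopifnot(boundary_threshold > 0, front_depth > 0)
  structure(list(boundary_threshold = boundary_threshold,
                 front_depth = front_depth),
            class = "front_definition")
}

#' Initial tumor state
#'
#' Builds the initial fields: normoxic cells at density `n0` on the slab
#' \[a, b\], ECM at density `e0` outside it, and no hypoxic cells. The two
#' interface nodes at `x = a` and `x = b` take the mean of the left and right
#' limits (`n0/2`, `e0/2`), the Riemann-consistent sampling of the
#' discontinuous profile: the rectangle-rule mass of the discrete initial
#' condition then equals the continuum mass `n0 * (b - a)` exactly, which the
#' conservation oracles use as the initial total `N0`.
#'
#' @param grids A [sim_grids()] object.
#' @param n0 Initial normoxic density inside \[a, b\].
#' @param e0 Initial ECM density outside \[a, b\].
#' @param a,b Left and right edges of the initial tumor slab, `0 <= a < b <= X`.
#' @return An object of class `tumor_state` with fields `t`, `n`, `h`
#'   (an `N x M` matrix), `e` and the embedded `grids`.
#' @examples
#' st <- initialize_state(sim_grids())
#' tumor_volume(st)  # 1
#' @export
initialize_state <- function(grids, n0 = 0.5, e0 = 0.5, a = 4, b = 6) {
  stopifnot(inherits(grids, "sim_grids"))
  if (!(a >= 0 && a < b && b <= grids$X))
    stop("initial slab must satisfy 0 <= a < b <= X")
  x <- grids$x
  n <- ifelse(x > a & x < b, n0, 0)
  e <- ifelse(x < a | x > b, e0, 0)
  on_a <- abs(x - a) < 1e-12
  on_b <- abs(x - b) < 1e-12
  n[on_a | on_b] <- n0 / 2
  e[on_a | on_b] <- e0 / 2
  # nodes not exactly on the interface keep the pure one-sided values
  n[x <= a & !on_a] <- 0
  n[x >= b & !on_b] <- 0
  h <- matrix(0, nrow = grids$N, ncol = grids$M)
  structure(list(t = 0, n = n, h = h, e = e, grids = grids),
            class = "tumor_state")
}

#' @export
print.tumor_state <- function(x, ...) {
  g <- x$grids
  cat(sprintf("Tumor state at t = %g: n_tot = %.6g, h_tot = %.6g, e_tot = %.6g\n",
              x$t, spatial_integral(x$n, g$dx),
              spatial_integral(integrated_H(x$h, g$dmu), g$dx),
              spatial_integral(x$e, g$dx)))
  invisible(x)
}

#' Stable timestep for the explicit scheme
#'
#' Computes the forward-Euler timestep from three bounds: the diffusion
#' bound `dx^2 / (2 D_h)`, the trait-advection bound `dmu / f_max`, and a
#' reaction-positivity bound `1 / max(delta, mu_nh + gamma_n, 1 + gamma_h)`
#' that keeps the pure-decay updates (ECM degradation, phenotype transitions,
#' necrosis) non-negative. `f_max` is the worst-case trait speed over the
#' whole run: the maximum of `|phenotype_velocity|` over `mu` in \[0, 1\] and
#' every oxygen level the protocol visits (the velocity is linear in `mu`, so
#' the maximum sits at a trait endpoint). With `alpha = 0` the advection
#' bound is dropped: the velocity vanishes at the injection coordinate and
#' all hypoxic mass remains there, so trait advection never moves anything.
#'
#' @param grids A [sim_grids()] object.
#' @param params A [model_params()] object.
#' @param protocol An [oxygen_protocol()] object.
#' @param settings A [solver_settings()] object.
#' @return The timestep `cfl_safety * min(bounds)`, with the computed
#'   `f_max` attached as an attribute.
#' @export
cfl_timestep <- function(grids, params, protocol,
                         settings = solver_settings()) {
  levels <- if (protocol$mode == "constant") protocol$level
            else c(protocol$c1, protocol$c2)
  f_max <- if (params$alpha == 0) 0 else {
    max(vapply(levels, function(cc)
      max(abs(phenotype_velocity(c(0, 1), cc, params))), numeric(1)))
  }
  bounds <- grids$dx^2 / (2 * params$D_h)
  if (f_max > 0) bounds <- c(bounds, grids$dmu / f_max)
  # positivity of the explicit decay updates (max escape rate is mu = 1)
  decay <- max(params$delta, params$mu_nh + params$gamma_n,
               1 + params$gamma_h)
  if (decay > 0) bounds <- c(bounds, 1 / decay)
  dt <- settings$cfl_safety * min(bounds)
  attr(dt, "f_max") <- f_max
  dt
}

#' Spatial transport rate of the hypoxic density
#'
#' Rate of change of `h` from volume-filling diffusion and haptotaxis, in
#' conservative flux form. Face coefficients use arithmetic means of the
#' neighbouring nodes; the total (diffusive plus haptotactic) flux is zeroed
#' at both domain ends, so the spatial integral of the update vanishes for
#' every trait node.
#'
#' @param state A `tumor_state`.
#' @param params A [model_params()] object.
#' @param grids A [sim_grids()] object (defaults to the state's own).
#' @return An `N x M` matrix of rates of change of `h`.
#' @export
spatial_flux_update <- function(state, params, grids = state$grids) {
  h <- state$h
  N <- grids$N
  Hx <- integrated_H(h, grids$dmu)
  phi <- 1 - state$n - Hx - state$e       # free-volume factor
  phi_face <- (phi[-N] + phi[-1]) / 2
  de <- (state$e[-1] - state$e[-N]) / grids$dx
  dh <- (h[-1, , drop = FALSE] - h[-N, , drop = FALSE]) / grids$dx
  h_face <- (h[-1, , drop = FALSE] + h[-N, , drop = FALSE]) / 2
  flux <- params$D_h * phi_face * dh - params$xi_h * h_face * de
  out <- matrix(0, nrow = N, ncol = grids$M)
  out[1, ] <- flux[1, ] / grids$dx
  out[N, ] <- -flux[N - 1, ] / grids$dx
  out[2:(N - 1), ] <- (flux[2:(N - 1), , drop = FALSE] -
                         flux[1:(N - 2), , drop = FALSE]) / grids$dx
  out
}

#' Trait-advection rate of the hypoxic density
#'
#' First-order upwind (donor-cell) discretization of the conservative trait
#' drift \eqn{-\partial_\mu (v h)}. Velocities are evaluated exactly at the
#' cell faces (the velocity law is linear in `mu`); the donor node is chosen
#' by the sign of the face velocity, and the boundary fluxes at `mu = 0` and
#' `mu = 1` are forced to zero, so the phenotype-integrated update vanishes
#' at every spatial node.
#'
#' @param state A `tumor_state`.
#' @param c Oxygen concentration (scalar, spatially homogeneous).
#' @param params A [model_params()] object.
#' @param grids A [sim_grids()] object (defaults to the state's own).
#' @return An `N x M` matrix of rates of change of `h`.
#' @export
phenotype_advection_update <- function(state, c, params, grids = state$grids) {
  h <- state$h
  M <- grids$M
  mu_face <- (grids$mu[-M] + grids$mu[-1]) / 2
  vf <- phenotype_velocity(mu_face, c, params)
  donor_right <- vf < 0                    # donor is node j+1 when v < 0
  # flux through interior face j+1/2, for j = 1..M-1
  flux <- h[, -M, drop = FALSE] * rep(vf * !donor_right, each = grids$N) +
    h[, -1, drop = FALSE] * rep(vf * donor_right, each = grids$N)
  out <- matrix(0, nrow = grids$N, ncol = M)
  out[, 1] <- -flux[, 1] / grids$dmu
  out[, M] <- flux[, M - 1] / grids$dmu
  out[, 2:(M - 1)] <- -(flux[, 2:(M - 1), drop = FALSE] -
                          flux[, 1:(M - 2), drop = FALSE]) / grids$dmu
  out
}

# Matrix form of the local hypoxic reactions; column j must agree with
# reaction_hypoxic_local() at mu = mu[j] (asserted in the test suite).
reaction_hypoxic_matrix <- function(h, n, c, params, grids) {
  r <- -(h * rep(grids$mu, each = grids$N)) * heaviside(c - params$c_H) -
    params$gamma_h * h * heaviside(params$c_N - c)
  inj <- params$mu_nh * n * heaviside(params$c_H - c) / grids$dmu
  r[, grids$injection_index] <- r[, grids$injection_index] + inj
  r
}

#' Advance the state by one forward-Euler step
#'
#' Combines the spatial transport, trait advection, oxygen-gated reactions
#' and ECM decay (`e_new = e * (1 - delta * dt * H)`) into one explicit
#' update. Oxygen is evaluated at the state's current time. Entries that
#' land in `[-1e-12, 0)` (roundoff-level negativity) are clipped to zero and
#' counted; anything more negative, or any non-finite entry, aborts with a
#' diagnostic since it signals a stability violation.
#'
#' @param state A `tumor_state`.
#' @param protocol An [oxygen_protocol()] object.
#' @param params A [model_params()] object.
#' @param grids A [sim_grids()] object (defaults to the state's own).
#' @param dt Timestep; must satisfy the bound from [cfl_timestep()].
#' @return The advanced `tumor_state`; attribute `"clipped"` carries the
#'   number of entries clipped this step.
#' @export
step_state <- function(state, protocol, params, grids = state$grids, dt) {
  c_now <- oxygen_at(protocol, state$t)
  Hx <- integrated_H(state$h, grids$dmu)
  mom <- phenotype_first_moment(state$h, grids$mu, grids$dmu)

  dn <- reaction_normoxic(state$n, Hx, state$e, mom, c_now, params)
  dh <- spatial_flux_update(state, params, grids) +
    phenotype_advection_update(state, c_now, params, grids) +
    reaction_hypoxic_matrix(state$h, state$n, c_now, params, grids)

  n_new <- state$n + dt * dn
  h_new <- state$h + dt * dh
  e_new <- state$e * (1 - params$delta * dt * Hx)

  clipped <- 0L
  fields <- list(n = n_new, h = h_new, e = e_new)
  for (nm in names(fields)) {
    f <- fields[[nm]]
    if (any(!is.finite(f)))
      stop("non-finite values in '", nm, "' at t = ", state$t,
           "; the explicit scheme has become unstable")
    neg <- f < 0
    if (any(neg)) {
      if (min(f) < -1e-12)
        stop("negative values beyond tolerance in '", nm, "' at t = ",
             state$t, " (min = ", min(f), "); check the timestep bound")
      clipped <- clipped + sum(neg)
      f[neg] <- 0
      fields[[nm]] <- f
    }
  }
  out <- structure(list(t = state$t + dt, n = fields$n, h = fields$h,
                        e = fields$e, grids = grids),
                   class = "tumor_state")
  attr(out, "clipped") <- clipped
  out
}
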