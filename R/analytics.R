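#' Closed-form totals under sustained hypoxia
#'
#' Under constant oxygen between the necrotic and hypoxic thresholds, the
#' only active process is the normoxic-to-hypoxic conversion, so the
#' space-integrated totals obey
#' \deqn{n_{tot}(t) = N_0 e^{-\mu_{nh} t}, \qquad
#'       h_{tot}(t) = N_0 (1 - e^{-\mu_{nh} t}),}
#' and their sum is conserved. Used as the verification oracle for the
#' oxygen-deprived constant case.
#'
#' @param t Time(s), non-negative.
#' @param N0 Initial total normoxic mass.
#' @param mu_nh Conversion rate.
#' @return Data frame with columns `t`, `n_tot`, `h_tot`.
#' @export
analytic_hypoxic_decay <- function(t, N0, mu_nh) {
  stopifnot(all(t >= 0), N0 >= 0)
  decay <- exp(-mu_nh * t)
  data.frame(t = t, n_tot = N0 * decay, h_tot = N0 * (1 - decay))
}

#' Closed-form logistic growth under sustained normoxia
#'
#' Under constant oxygen above the hypoxic threshold no hypoxic cells ever
#' form (`h_tot = 0`) and the normoxic density grows logistically toward the
#' free volume `1 - e_tot`:
#' \deqn{n_{tot}(t) = \frac{1 - e_{tot}}
#'   {1 + \frac{1 - N_0 - e_{tot}}{N_0} e^{-\lambda_n (1 - e_{tot}) t}}.}
#' The expression holds wherever the fields are uniform; because normoxic
#' cells are immobile it applies pointwise at every spatial node with
#' `N0 = n(x, 0)` and `e_tot = e(x, 0)`, which is how the Case-II
#' verification applies it (nodewise, then integrated).
#'
#' @param t Time(s), non-negative.
#' @param N0 Initial normoxic density/mass (`N0 = 0` gives the degenerate
#'   all-zero solution).
#' @param e_tot ECM density/mass blocking growth (constant: no hypoxic cells
#'   exist to degrade it). Requires `N0 + e_tot <= 1`.
#' @param lambda_n Proliferation rate.
#' @return Data frame with columns `t`, `n_tot`, `h_tot` (`h_tot` all zero).
#' @export
analytic_normoxic_logistic <- function(t, N0, e_tot, lambda_n) {
  stopifnot(all(t >= 0), N0 >= 0, e_tot >= 0, N0 + e_tot <= 1 + 1e-12)
  if (N0 == 0) {
    n <- rep(0, length(t))
  } else {
    K <- 1 - e_tot
    n <- K / (1 + ((1 - N0 - e_tot) / N0) * exp(-lambda_n * K * t))
  }
  data.frame(t = t, n_tot = n, h_tot = rep(0, length(t)))
}

#' Equilibrium phenotype under sustained hypoxia
#'
#' The stable zero of the trait velocity at hypoxic oxygen level `c2`:
#' \eqn{\mu^* = \mu_{hn0} - \alpha (1 - c2)}. All hypoxic mass converges to
#' this coordinate under prolonged hypoxia; with `alpha = 0` it is simply
#' the injection coordinate `mu_hn0`.
#'
#' @param c2 Hypoxic oxygen level, below `c_H`.
#' @param params A [model_params()] object.
#' @return The equilibrium trait coordinate (strictly positive).
#' @export
hypoxic_equilibrium_phenotype <- function(c2, params) {
  if (c2 >= params$c_H)
    stop("c2 must lie below the hypoxic threshold c_H")
  mu_star <- params$mu_hn0 - params$alpha * (1 - c2)
  if (mu_star <= 0)
    stop("alpha too large for this oxygen level: equilibrium trait ",
         mu_star, " is not positive")
  mu_star
}
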