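#' Dimensionless model parameters
#'
#' Constructs and validates the full set of dimensionless rate and threshold
#' constants of the phenotype-structured invasion model. Defaults are the
#' literature-derived values used throughout the package's experiments.
#'
#' The phenotype coordinate `mu` in \[0, 1\] is the hypoxic-to-normoxic
#' transition rate of a hypoxic cell; newly converted hypoxic cells enter at
#' the basal coordinate `mu_hn0` and drift toward lower `mu` (stronger
#' hypoxic memory) while oxygen stays below the hypoxic threshold `c_H`.
#'
#' @param D_h Diffusivity of hypoxic cells.
#' @param xi_h Haptotaxis coefficient (drift up ECM gradients).
#' @param lambda_n Proliferation rate of normoxic cells.
#' @param mu_nh Normoxic-to-hypoxic transition rate (active when `c < c_H`).
#' @param mu_hn0 Basal hypoxic-to-normoxic transition rate; also the
#'   phenotype coordinate at which new hypoxic cells are injected.
#' @param gamma_n,gamma_h Necrotic death rates of normoxic and hypoxic cells
#'   (active when `c < c_N`).
#' @param delta ECM degradation rate by hypoxic cells.
#' @param c_H Hypoxic oxygen threshold (oxygen scaled to the normoxic level).
#' @param c_N Necrotic oxygen threshold.
#' @param alpha Strength of memory induction; `alpha = 0` removes hypoxic
#'   memory entirely (the trait never leaves `mu_hn0`).
#' @param beta_l Memory-induction timescale, active while `c < c_H`.
#' @param beta_h Memory-erasure timescale, active while `c >= c_H`.
#'
#' @return An object of class `model_params` (a validated named list).
#' @seealso [oxygen_protocol()], [phenotype_velocity()], [invasion_model()]
#' @examples
#' p <- model_params()
#' p$mu_hn0
#' # memoryless variant
#' p0 <- model_params(alpha = 0)
#' @export
model_params <- function(D_h = 0.01, xi_h = 0.001, lambda_n = 0.1,
                         mu_nh = 0.5, mu_hn0 = 0.5,
                         gamma_n = 0.001, gamma_h = 0.001, delta = 15,
                         c_H = 0.5, c_N = 0.1,
                         alpha = 0.8, beta_l = 2, beta_h = 20) {
  p <- list(D_h = D_h, xi_h = xi_h, lambda_n = lambda_n, mu_nh = mu_nh,
            mu_hn0 = mu_hn0, gamma_n = gamma_n, gamma_h = gamma_h,
            delta = delta, c_H = c_H, c_N = c_N,
            alpha = alpha, beta_l = beta_l, beta_h = beta_h)
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                logical(1))
  if (!all(num))
    stop("all parameters must be finite numeric scalars: ",
         paste(names(p)[!num], collapse = ", "))
  nonneg <- c("D_h", "xi_h", "lambda_n", "mu_nh", "gamma_n", "gamma_h",
              "delta", "alpha")
  bad <- nonneg[vapply(nonneg, function(nm) p[[nm]] < 0, logical(1))]
  if (length(bad))
    stop("parameters must be non-negative: ", paste(bad, collapse = ", "))
  if (beta_l <= 0 || beta_h <= 0)
    stop("memory timescales beta_l and beta_h must be strictly positive")
  if (!(c_N >= 0 && c_N < c_H && c_H <= 1))
    stop("oxygen thresholds must satisfy 0 <= c_N < c_H <= 1")
  if (!(mu_hn0 > 0 && mu_hn0 <= 1))
    stop("mu_hn0 must lie in (0, 1]")
  class(p) <- "model_params"
  p
}

#' @export
print.model_params <- function(x, ...) {
  cat("Dimensionless model parameters\n")
  v <- unlist(x)
  cat(paste0("  ", format(names(v), width = 9), " = ", format(v)), sep = "\n")
  invisible(x)
}

#' Time-switched oxygen protocol
#'
#' Defines the spatially homogeneous oxygen schedule: either a constant level
#' (the two constant-oxygen verification cases) or a piecewise-constant cycle
#' alternating between a normoxic level `c1` and a hypoxic level `c2`. Each
#' cycle of length `period` starts normoxic; the hypoxic phase occupies the
#' final `bias` fraction of the cycle.
#'
#' @param c1 Normoxic oxygen level (oxygen is scaled so that `c1 = 1`).
#' @param c2 Hypoxic oxygen level; must lie below the model's `c_H`.
#' @param period Full cycle length (normoxic phase + hypoxic phase).
#' @param bias Fraction of each cycle spent at the hypoxic level, in (0, 1).
#' @param t_final Total simulated time.
#' @param mode `"cyclic"` or `"constant"`. In constant mode `level` is used.
#' @param level Constant oxygen level, for `mode = "constant"` only.
#'
#' @return An object of class `oxygen_protocol`.
#' @examples
#' pr <- oxygen_protocol(period = 10, bias = 0.5)
#' oxygen_at(pr, c(3, 5, 7))
#' @export
oxygen_protocol <- function(c1 = 1, c2 = 0.4, period = 10, bias = 0.5,
                            t_final = 60, mode = c("cyclic", "constant"),
                            level = NULL) {
  mode <- match.arg(mode)
  if (mode == "constant") {
    if (is.null(level)) stop("constant mode requires a 'level'")
    if (!is.numeric(level) || level < 0) stop("'level' must be >= 0")
  } else {
    if (!(is.numeric(period) && period > 0)) stop("'period' must be > 0")
    if (!(is.numeric(bias) && bias > 0 && bias < 1))
      stop("'bias' must lie strictly inside (0, 1)")
    if (!(c2 < c1)) stop("hypoxic level c2 must be below normoxic level c1")
  }
  if (!(is.numeric(t_final) && t_final >= 0)) stop("'t_final' must be >= 0")
  structure(list(c1 = c1, c2 = c2, period = period, bias = bias,
                 t_final = t_final, mode = mode, level = level),
            class = "oxygen_protocol")
}

#' @export
print.oxygen_protocol <- function(x, ...) {
  if (x$mode == "constant") {
    cat(sprintf("Oxygen protocol: constant c = %g, t_final = %g\n",
                x$level, x$t_final))
  } else {
    cat(sprintf(
      "Oxygen protocol: cyclic, c1 = %g / c2 = %g, period = %g, bias = %g, t_final = %g\n",
      x$c1, x$c2, x$period, x$bias, x$t_final))
  }
  invisible(x)
}

#' Oxygen level at a given time
#'
#' Evaluates the protocol's oxygen concentration. Cyclic intervals are
#' left-open / right-closed: each cycle `(k-1)*period < t <= k*period` is
#' normoxic (`c1`) on its first `(1 - bias)*period` and hypoxic (`c2`) on the
#' remainder, so the phase-switch instants belong to the phase they close.
#' `t = 0` is normoxic.
#'
#' @param protocol An [oxygen_protocol()].
#' @param t Time (vectorized); must be non-negative.
#' @return Oxygen concentration(s) at `t`.
#' @examples
#' pr <- oxygen_protocol(period = 10, bias = 0.25)
#' oxygen_at(pr, 8)  # hypoxic tail of the first cycle
#' @export
oxygen_at <- function(protocol, t) {
  stopifnot(inherits(protocol, "oxygen_protocol"))
  if (any(t < 0)) stop("time must be non-negative")
  if (protocol$mode == "constant")
    return(rep(protocol$level, length(t)))
  P <- protocol$period
  s <- t - P * floor(t / P)
  # t = k*P (k > 0) belongs to the closing hypoxic phase of cycle k
  s[s == 0 & t > 0] <- P
  ifelse(s <= (1 - protocol$bias) * P, protocol$c1, protocol$c2)
}

#' Memory timescale active at an oxygen level
#'
#' The trait-drift law uses one timescale symbol, but memory induction (under
#' hypoxia) and memory erasure (under normoxia) act on different experimental
#' timescales. The active timescale switches at the hypoxic threshold with
#' the same tie-break as the reaction gating (`c = c_H` counts as the
#' normoxic side).
#'
#' @param c Oxygen concentration (vectorized).
#' @param params A [model_params()] object.
#' @return `beta_l` where `c < c_H`, `beta_h` otherwise.
#' @export
select_beta <- function(c, params) {
  if (any(c < 0)) stop("oxygen concentration must be non-negative")
  ifelse(c < params$c_H, params$beta_l, params$beta_h)
}

#' Phenotype-space drift velocity
#'
#' Velocity of hypoxic-cell density in trait space,
#' \deqn{v(\mu, c) = -\frac{\alpha (1 - c) + \mu - \mu_{hn0}}{\beta},}
#' with \eqn{\beta} chosen by [select_beta()]. Under sustained hypoxia at
#' level `c2` the flow converges to the stable equilibrium
#' \eqn{\mu^* = \mu_{hn0} - \alpha (1 - c2)}; with `alpha = 0` the velocity
#' vanishes identically at `mu_hn0` for any oxygen level (no memory).
#'
#' @param mu Phenotype coordinate(s) in \[0, 1\].
#' @param c Oxygen concentration (scalar).
#' @param params A [model_params()] object.
#' @param beta Optional override of the timescale; defaults to
#'   `select_beta(c, params)`.
#' @return Trait velocity at `mu`.
#' @examples
#' p <- model_params()
#' phenotype_velocity(0.5, c = 0.4, p)  # drift toward stronger memory
#' @export
phenotype_velocity <- function(mu, c, params, beta = NULL) {
  if (is.null(beta)) beta <- select_beta(c, params)
  if (any(beta <= 0)) stop("timescale beta must be strictly positive")
  -(params$alpha * (1 - c) + mu - params$mu_hn0) / beta
}

#' Heaviside step used for oxygen gating
#'
#' `heaviside(m)` is 1 for `m > 0` and 0 otherwise (in particular
#' `heaviside(0) = 0`), so at `c = c_H` neither the normoxic nor the hypoxic
#' reaction branch is active.
#'
#' @param m Numeric vector.
#' @return 0/1 vector.
#' @keywords internal
heaviside <- function(m) as.numeric(m > 0)
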