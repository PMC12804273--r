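#' Tumor right boundary
#'
#' Locates the rightmost position where the total cell density `n + H`
#' reaches the threshold. The crossing is placed by linear interpolation
#' between the last node at or above the threshold and its right neighbour,
#' which makes front positions (and hence hitting times) insensitive to the
#' mesh; `interpolate = FALSE` returns the raw node position instead. If the
#' whole profile is below the threshold the domain's left edge (0) is
#' returned as a sentinel, and if the threshold is still exceeded at the
#' last node the domain's right edge is returned.
#'
#' @param state A `tumor_state`.
#' @param frontdef A [front_definition()].
#' @param interpolate Linearly interpolate the crossing (default) or return
#'   the raw node coordinate.
#' @return Boundary position in \[0, X\].
#' @export
tumor_right_boundary <- function(state, frontdef = front_definition(),
                                 interpolate = TRUE) {
  g <- state$grids
  total <- state$n + integrated_H(state$h, g$dmu)
  boundary_from_profile(total, g$x, frontdef$boundary_threshold, interpolate)
}

boundary_from_profile <- function(total, x, threshold, interpolate = TRUE) {
  above <- which(total >= threshold)
  if (!length(above)) return(0)
  i <- above[length(above)]
  if (i == length(x)) return(x[length(x)])
  if (!interpolate) return(x[i])
  f1 <- total[i]
  f2 <- total[i + 1]
  x[i] + (x[i + 1] - x[i]) * (f1 - threshold) / (f1 - f2)
}

#' Tumor volume
#'
#' One-dimensional tumor "volume": the spatial integral of the total cell
#' density `n + H` over the whole domain.
#'
#' @param state A `tumor_state`.
#' @return Non-negative total cell mass.
#' @export
tumor_volume <- function(state) {
  g <- state$grids
  spatial_integral(state$n + integrated_H(state$h, g$dmu), g$dx)
}

#' Hypoxic cell fraction at the tumor front
#'
#' Fraction of hypoxic cells in the front region, the strip extending
#' `front_depth` inward from the tumor right boundary:
#' \eqn{\int_{front} H \, dx / \int_{front} (n + H) \, dx}. Returns `NA`
#' (an explicit undefined marker, never 0) when the front's total cell mass
#' is below the boundary threshold.
#'
#' @param state A `tumor_state`.
#' @param frontdef A [front_definition()].
#' @return Fraction in \[0, 1\], or `NA`.
#' @export
front_hypoxic_fraction <- function(state, frontdef = front_definition()) {
  g <- state$grids
  Hx <- integrated_H(state$h, g$dmu)
  b <- boundary_from_profile(state$n + Hx, g$x, frontdef$boundary_threshold)
  front_fraction_from_fields(state$n, Hx, g$x, b, frontdef)
}

front_fraction_from_fields <- function(n, Hx, x, boundary, frontdef) {
  sel <- x >= boundary - frontdef$front_depth - 1e-12 &
    x <= boundary + 1e-12
  denom <- sum(n[sel] + Hx[sel])
  if (!any(sel) || denom < frontdef$boundary_threshold) return(NA_real_)
  sum(Hx[sel]) / denom
}

#' Time-averaged front hypoxic fraction of a run
#'
#' Mean of the recorded front hypoxic fractions over all recorded outputs,
#' ignoring records where the fraction is undefined.
#'
#' @param sim An `invasion_sim`.
#' @return Mean fraction, or `NA` if undefined at every record.
#' @export
mean_front_hypoxic_fraction <- function(sim) {
  v <- sim$obs$front_hypoxic_fraction
  if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
}

#' Boundary hitting time
#'
#' First time at which the recorded tumor right boundary reaches a target
#' position, linearly interpolated between the bracketing records. Returns
#' 0 if the initial boundary is already at or beyond the target, and `NA`
#' (not-reached marker) if the target is never attained.
#'
#' @param sim An `invasion_sim` (or any list with `$obs` holding `time` and
#'   `boundary` columns).
#' @param x_target Target position.
#' @return Hitting time, or `NA`.
#' @export
hitting_time <- function(sim, x_target) {
  o <- sim$obs
  hit <- which(o$boundary >= x_target)
  if (!length(hit)) return(NA_real_)
  i <- hit[1L]
  if (i == 1L) return(o$time[1L])
  b0 <- o$boundary[i - 1L]
  b1 <- o$boundary[i]
  if (b1 == b0) return(o$time[i])
  o$time[i - 1L] + (o$time[i] - o$time[i - 1L]) * (x_target - b0) / (b1 - b0)
}

#' Phenotype (memory) distribution of hypoxic cells
#'
#' Distribution of hypoxic-cell mass over the trait coordinate within a
#' spatial region: the bulk (whole population) or the front strip. Per-trait
#' mass is the spatial integral of `h` over the region, normalized to sum to
#' one; normoxic cells carry no trait and are excluded.
#'
#' @param state A `tumor_state`.
#' @param region `"bulk"` or `"front"`.
#' @param frontdef A [front_definition()].
#' @param cycle_label Optional label (e.g. `"end-of-normoxic"`) carried on
#'   the result.
#' @return An object of class `phenotype_distribution` (fields `support`,
#'   `mass`, `region_label`, `cycle_label`), or `NA` if the region holds no
#'   hypoxic mass.
#' @export
phenotype_distribution <- function(state, region = c("bulk", "front"),
                                   frontdef = front_definition(),
                                   cycle_label = NA_character_) {
  region <- match.arg(region)
  g <- state$grids
  if (region == "bulk") {
    sel <- rep(TRUE, g$N)
  } else {
    Hx <- integrated_H(state$h, g$dmu)
    b <- boundary_from_profile(state$n + Hx, g$x, frontdef$boundary_threshold)
    sel <- g$x >= b - frontdef$front_depth - 1e-12 & g$x <= b + 1e-12
  }
  w <- colSums(state$h[sel, , drop = FALSE]) * g$dx
  s <- sum(w)
  if (!any(sel) || s <= 0) return(NA)
  structure(list(support = g$mu, mass = w / s, region_label = region,
                 cycle_label = cycle_label),
            class = "phenotype_distribution")
}

#' @export
print.phenotype_distribution <- function(x, ...) {
  m <- sum(x$support * x$mass)
  cat(sprintf("Phenotype distribution (%s%s): mean mu = %.4f, strong-memory fraction = %.4f\n",
              x$region_label,
              if (is.na(x$cycle_label)) "" else paste0(", ", x$cycle_label),
              m, strong_memory_fraction(x)))
  invisible(x)
}

#' Strong-memory fraction of a phenotype distribution
#'
#' Total normalized mass at trait coordinates strictly below the cutoff
#' (default 0.25): the share of deeply memory-committed cells.
#'
#' @param dist A [phenotype_distribution()].
#' @param cutoff Trait cutoff.
#' @return Fraction in \[0, 1\].
#' @export
strong_memory_fraction <- function(dist, cutoff = 0.25) {
  if (!inherits(dist, "phenotype_distribution")) return(NA_real_)
  sum(dist$mass[dist$support < cutoff])
}

#' Front-to-bulk strong-memory ratio
#'
#' Convenience wrapper: ratio of the strong-memory fraction at the front to
#' that in the bulk of one state.
#'
#' @param state A `tumor_state`.
#' @param frontdef A [front_definition()].
#' @param cutoff Trait cutoff for "strong memory".
#' @return Ratio (>= 0), or `NA` if either region is empty or the bulk
#'   fraction is zero.
#' @export
strong_memory_ratio <- function(state, frontdef = front_definition(),
                                cutoff = 0.25) {
  pf <- phenotype_distribution(state, "front", frontdef)
  pb <- phenotype_distribution(state, "bulk", frontdef)
  if (!inherits(pf, "phenotype_distribution") ||
      !inherits(pb, "phenotype_distribution")) return(NA_real_)
  fb <- strong_memory_fraction(pb, cutoff)
  if (fb == 0) return(NA_real_)
  strong_memory_fraction(pf, cutoff) / fb
}

#' Jensen-Shannon divergence between phenotype distributions
#'
#' \eqn{JSD(p, q) = \frac12 KL(p \| m) + \frac12 KL(q \| m)} with
#' \eqn{m = (p + q)/2}, natural logarithm, and the convention
#' \eqn{0 \log 0 = 0}; the result lies in \[0, log 2\].
#'
#' @param p,q [phenotype_distribution()] objects or plain normalized weight
#'   vectors on a shared support.
#' @return Divergence in \[0, log 2\].
#' @export
jensen_shannon_divergence <- function(p, q) {
  if (inherits(p, "phenotype_distribution") &&
      inherits(q, "phenotype_distribution")) {
    if (length(p$support) != length(q$support) ||
        any(abs(p$support - q$support) > 1e-12))
      stop("distributions must share the same phenotype support")
    p <- p$mass
    q <- q$mass
  }
  if (length(p) != length(q))
    stop("distributions must share the same support length")
  stopifnot(all(p >= 0), all(q >= 0))
  if (abs(sum(p) - 1) > 1e-8 || abs(sum(q) - 1) > 1e-8)
    stop("distributions must be normalized to sum to 1")
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log(a[i] / b[i]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Percent change of a metric relative to a baseline
#'
#' `100 * (value - baseline) / baseline`. An `NA` in either argument (e.g. a
#' not-reached hitting time) or a zero baseline propagates as `NA`.
#'
#' @param memory_value Metric under the condition of interest.
#' @param memoryless_value Baseline metric.
#' @return Percent change (vectorized), or `NA`.
#' @export
percent_change <- function(memory_value, memoryless_value) {
  out <- 100 * (memory_value - memoryless_value) / memoryless_value
  out[!is.na(memoryless_value) & memoryless_value == 0] <- NA_real_
  out
}
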