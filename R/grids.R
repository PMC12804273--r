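#' Uniform space and phenotype meshes
#'
#' Builds the uniform spatial mesh on \[0, X\] with `N` nodes and the
#' phenotype mesh on \[0, 1\] with `M` nodes. The phenotype mesh must contain
#' the injection coordinate `mu_hn0` as an exact node: all hypoxic mass enters
#' trait space there, and representing it between nodes would smear the
#' injection.
#'
#' @param X Spatial extent of the domain.
#' @param N Number of spatial nodes (`dx = X / (N - 1)`).
#' @param M Number of phenotype nodes (`dmu = 1 / (M - 1)`).
#' @param mu_hn0 Injection phenotype coordinate that must be a mesh node.
#' @return An object of class `sim_grids` with fields `X, N, dx, x, M, dmu,
#'   mu, injection_index` (1-based index of the node at `mu_hn0`).
#' @examples
#' g <- sim_grids()
#' g$mu[g$injection_index]  # 0.5
#' @export
sim_grids <- function(X = 10, N = 201, M = 101, mu_hn0 = 0.5) {
  stopifnot(X > 0, N >= 3, M >= 3)
  dx <- X / (N - 1)
  dmu <- 1 / (M - 1)
  x <- seq(0, X, length.out = N)
  mu <- seq(0, 1, length.out = M)
  jinj <- which(abs(mu - mu_hn0) < 1e-12)
  if (length(jinj) != 1L)
    stop("phenotype mesh must contain mu_hn0 = ", mu_hn0,
         " as an exact node; choose M so that mu_hn0 / dmu is an integer")
  structure(list(X = X, N = N, dx = dx, x = x,
                 M = M, dmu = dmu, mu = mu, injection_index = jinj),
            class = "sim_grids")
}

#' @export
print.sim_grids <- function(x, ...) {
  cat(sprintf("Grids: x in [0, %g], N = %d (dx = %g); mu in [0, 1], M = %d (dmu = %g); injection node %d\n",
              x$X, x$N, x$dx, x$M, x$dmu, x$injection_index))
  invisible(x)
}

#' Quadrature of a phenotype-resolved density
#'
#' Integrates a density over the phenotype mesh by the rectangle rule
#' (`sum(h) * dmu`), the quadrature under which the discrete injection /
#' escape pair conserves mass exactly. `integrated_H` gives the total hypoxic
#' density \eqn{H = \int h \, d\mu}; `phenotype_first_moment` gives
#' \eqn{\int \mu h \, d\mu}, the rate at which hypoxic cells re-enter the
#' normoxic pool under normoxia.
#'
#' @param h Density values on the phenotype mesh: a vector (one spatial
#'   location) or an `N x M` matrix (rows are spatial nodes).
#' @param dmu Phenotype mesh width.
#' @param mu Phenotype node coordinates (first moment only).
#' @return Scalar (vector input) or length-`N` vector (matrix input).
#' @export
integrated_H <- function(h, dmu) {
  if (is.matrix(h)) rowSums(h) * dmu else sum(h) * dmu
}

#' @rdname integrated_H
#' @export
phenotype_first_moment <- function(h, mu, dmu) {
  if (is.matrix(h)) drop(h %*% mu) * dmu else sum(h * mu) * dmu
}

#' Quadrature over the spatial mesh
#'
#' Rectangle-rule spatial integral (`sum * dx`), the functional conserved
#' exactly by the flux-form transport scheme with no-flux boundaries.
#'
#' @param f Values on the spatial mesh.
#' @param dx Spatial mesh width.
#' @return Scalar integral.
#' @keywords internal
spatial_integral <- function(f, dx) sum(f) * dx
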