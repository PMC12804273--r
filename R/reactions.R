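#' Pointwise reaction rate of the normoxic density
#'
#' Right-hand side of the normoxic equation at one (or many) spatial nodes:
#' volume-filling logistic proliferation when `c > c_H`, gain from hypoxic
#' cells reverting at their trait-dependent rate (the first phenotype moment
#' of `h`) when `c > c_H`, loss to the hypoxic pool at rate `mu_nh` when
#' `c < c_H`, and necrosis at rate `gamma_n` when `c < c_N`. Gating uses the
#' Heaviside convention `H(0) = 0`, so at `c = c_H` exactly no branch is
#' active.
#'
#' @param n Normoxic density (vectorized over space).
#' @param H Integrated hypoxic density at the same nodes.
#' @param e ECM density at the same nodes.
#' @param phenotype_first_moment Precomputed \eqn{\int \mu h \, d\mu} at the
#'   same nodes (see [phenotype_first_moment()]).
#' @param c Oxygen concentration (scalar; oxygen is spatially homogeneous).
#' @param params A [model_params()] object.
#' @return Rate of change of `n`.
#' @export
reaction_normoxic <- function(n, H, e, phenotype_first_moment, c, params) {
  gN <- heaviside(c - params$c_H)   # normoxic-side gate
  gH <- heaviside(params$c_H - c)   # hypoxic-side gate
  gD <- heaviside(params$c_N - c)   # necrotic gate
  params$lambda_n * n * (1 - n - H - e) * gN +
    phenotype_first_moment * gN -
    params$mu_nh * n * gH -
    params$gamma_n * n * gD
}

#' Local (non-transport) reaction rate of the hypoxic density
#'
#' Right-hand side of the hypoxic equation at one space-trait node,
#' excluding spatial transport and trait advection: injection of newly
#' converted cells at the basal trait `mu_hn0` when `c < c_H`, escape back to
#' the normoxic pool at the trait-dependent rate `mu` when `c > c_H`, and
#' necrosis when `c < c_N`. The injection is a trait-space point source,
#' carried by the single mesh node at `mu_hn0` with weight `1/dmu` so that
#' its phenotype integral equals the normoxic loss `mu_nh * n` exactly
#' (discrete mass conservation).
#'
#' @param h_at_mu Hypoxic density at the node (vectorized over space).
#' @param mu Phenotype coordinate of the node.
#' @param n Normoxic density at the same spatial nodes.
#' @param c Oxygen concentration (scalar).
#' @param is_injection_node Logical: is this node the mesh node at `mu_hn0`?
#' @param dmu Phenotype mesh width.
#' @param params A [model_params()] object.
#' @return Rate of change of `h` at the node.
#' @export
reaction_hypoxic_local <- function(h_at_mu, mu, n, c, is_injection_node,
                                   dmu, params) {
  if (is_injection_node && abs(mu - params$mu_hn0) > dmu / 2)
    stop("injection node flagged at mu = ", mu,
         " but mu_hn0 = ", params$mu_hn0)
  r <- -mu * h_at_mu * heaviside(c - params$c_H) -
    params$gamma_h * h_at_mu * heaviside(params$c_N - c)
  if (is_injection_node)
    r <- r + params$mu_nh * n * heaviside(params$c_H - c) / dmu
  r
}
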