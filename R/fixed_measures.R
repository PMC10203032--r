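#' Evolvability measures for a fixed selection gradient
#'
#' Given a genetic covariance matrix `G` and a selection gradient `beta`
#' (with unit direction `u = beta / |beta|`), the Lande equation
#' `dz = G beta` induces the measures
#' * evolvability `e = u' G u`, the genetic variance along `u`;
#' * conditional evolvability `c = 1 / (u' ginv(G) u)` when `beta` lies in
#'   the range of `G` (0 otherwise), the variance along `u` when evolution in
#'   orthogonal directions is prevented;
#' * autonomy `a = c / e` in `[0, 1]` and integration `i = 1 - a`;
#' * respondability `r`, equal to `sqrt(u' G^2 u)`, the response length per
#'   unit selection;
#' * flexibility `f = e / r` in `(0, 1]`, the cosine between response and
#'   selection.
#'
#' All measures are invariant to rescaling of `beta`. Singular `G` is handled
#' through the Moore-Penrose generalized inverse; measures that are undefined
#' for the given inputs (e.g. `e = 0` for autonomy, or `beta` in the null
#' space of `G` for flexibility) return `NA` carrying a machine-readable
#' `reason` attribute (see [is_defined()]) instead of raising, so batch
#' pipelines can proceed.
#'
#' @param G,G1,G2 covariance matrices (matrix or `cov_matrix`).
#' @param beta nonzero numeric selection gradient of matching length.
#' @return A numeric scalar, or `NA` with a `reason` attribute when
#'   undefined.
#' @name fixed_measures
#' @examples
#' G <- diag(c(1, 4))
#' b <- c(1, 1)
#' evolvability(G, b)              # 2.5
#' conditional_evolvability(G, b)  # 1.6
#' autonomy(G, b)                  # 0.64
NULL

undefined_value <- function(reason) structure(NA_real_, reason = reason)

#' Is a measure value defined?
#'
#' @param x result of a fixed-measure function.
#' @return `TRUE` unless `x` is the distinguished undefined value.
#' @export
is_defined <- function(x) !is.na(x)

#' @rdname is_defined
#' @export
why_undefined <- function(x) attr(x, "reason")

check_beta <- function(beta, p) {
  beta <- as.numeric(beta)
  if (length(beta) != p) stop("'beta' must have length ", p)
  if (all(beta == 0)) stop("'beta' must not be the zero vector")
  beta
}

# relative norm of beta outside the range of G (residual vector form: free
# of the cancellation that a norm difference would suffer at full rank)
range_resid <- function(G, beta) {
  if (G$rank == G$p) return(0)
  keep <- seq_len(G$rank)
  if (!length(keep)) return(1)
  V <- G$eigenvectors[, keep, drop = FALSE]
  r <- beta - V %*% crossprod(V, beta)
  sqrt(sum(r^2) / sum(beta^2))
}

#' @rdname fixed_measures
#' @export
evolvability <- function(G, beta) {
  G <- as_cov_matrix(G)
  u <- check_beta(beta, G$p)
  u <- u / sqrt(sum(u^2))
  drop(crossprod(u, G$values %*% u))
}

#' @rdname fixed_measures
#' @export
conditional_evolvability <- function(G, beta) {
  G <- as_cov_matrix(G)
  u <- check_beta(beta, G$p)
  if (range_resid(G, u) > 1e-8) return(0)
  u <- u / sqrt(sum(u^2))
  1 / drop(crossprod(u, generalized_inverse(G) %*% u))
}

#' @rdname fixed_measures
#' @export
autonomy <- function(G, beta) {
  e <- evolvability(G, beta)
  if (e <= 0) return(undefined_value("zero_evolvability"))
  conditional_evolvability(G, beta) / e
}

#' @rdname fixed_measures
#' @export
integration <- function(G, beta) {
  a <- autonomy(G, beta)
  if (!is_defined(a)) return(a)
  1 - a
}

#' @rdname fixed_measures
#' @export
respondability <- function(G, beta) {
  G <- as_cov_matrix(G)
  u <- check_beta(beta, G$p)
  u <- u / sqrt(sum(u^2))
  sqrt(sum((G$values %*% u)^2))
}

#' @rdname fixed_measures
#' @export
flexibility <- function(G, beta) {
  G <- as_cov_matrix(G)
  u <- check_beta(beta, G$p)
  u <- u / sqrt(sum(u^2))
  dz <- G$values %*% u
  r <- sqrt(sum(dz^2))
  if (r == 0) return(undefined_value("beta_in_null_space"))
  drop(crossprod(u, dz)) / r
}

#' @rdname fixed_measures
#' @export
response_difference <- function(G1, G2, beta) {
  G1 <- as_cov_matrix(G1); G2 <- as_cov_matrix(G2)
  if (G1$p != G2$p) stop("'G1' and 'G2' must have the same dimension")
  u <- check_beta(beta, G1$p)
  u <- u / sqrt(sum(u^2))
  sqrt(sum(((G1$values - G2$values) %*% u)^2))
}

#' @rdname fixed_measures
#' @export
response_correlation <- function(G1, G2, beta) {
  G1 <- as_cov_matrix(G1); G2 <- as_cov_matrix(G2)
  if (G1$p != G2$p) stop("'G1' and 'G2' must have the same dimension")
  u <- check_beta(beta, G1$p)
  u <- u / sqrt(sum(u^2))
  z1 <- G1$values %*% u
  z2 <- G2$values %*% u
  n1 <- sqrt(sum(z1^2)); n2 <- sqrt(sum(z2^2))
  if (n1 == 0 || n2 == 0) return(undefined_value("zero_response_vector"))
  drop(crossprod(z1, z2)) / (n1 * n2)
}
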