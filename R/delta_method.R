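#' Delta-method (Hansen-Houle) approximations of average measures
#'
#' Closed-form second-order Taylor approximations of the average measures,
#' expressed through eigenvalue summaries of the argument matrix: the
#' arithmetic mean `E`, the harmonic mean `H`, and the relative-variance
#' functional `I(x) = PopVar(x) / mean(x)^2` (population variance, i.e.
#' divided by the count) applied to transforms of the spectrum:
#' * `delta_e = mean(lambda)` (exact);
#' * `delta_c = H * (1 + 2 * I(1/lambda) / (p + 2))`;
#' * `delta_r = sqrt(mean(lambda^2)) * (1 - I(lambda^2) / (4 * (p + 2)))`;
#' * `delta_d`: `delta_r` applied to the spectrum of `(G1 - G2)^2`;
#' * `delta_a`: second-order expansion of `E[c/e]` about the sphere moments,
#'   `delta_c/E - 2*H*(E - H)/((p + 2)*E^2) + 2*delta_c*I(lambda)/((p + 2)*E)`.
#'
#' These are fast comparators with no error control; deviations from the
#' converged series values can exceed 5% (notably for `delta_r`, `delta_d`,
#' `delta_a` on strongly integrated spectra). No delta approximation exists
#' for average flexibility or average response correlation, and none is
#' invented here.
#'
#' @param G,G1,G2 covariance matrices (matrix or `cov_matrix`);
#'   `delta_c` and `delta_a` require nonsingular `G`, `delta_d` requires
#'   `G1 != G2`.
#' @return A numeric scalar (`NA` with a `reason` attribute when undefined,
#'   see [is_defined()]).
#' @name delta_method
#' @examples
#' G <- diag(make_eigenvalues(eigen_profile("quadratic", 5)))
#' delta_c(G)   # 0.4456
#' delta_r(G)   # 1.2078
NULL

relvar <- function(x) mean((x - mean(x))^2) / mean(x)^2

#' @rdname delta_method
#' @export
delta_e <- function(G) mean(cm_eigenvalues(G))

#' @rdname delta_method
#' @export
delta_c <- function(G) {
  G <- as_cov_matrix(G)
  if (G$rank < G$p) return(undefined_value("singular_G"))
  lam <- G$eigenvalues
  H <- 1 / mean(1 / lam)
  H * (1 + 2 * relvar(1 / lam) / (G$p + 2))
}

#' @rdname delta_method
#' @export
delta_r <- function(G) {
  G <- as_cov_matrix(G)
  l2 <- G$eigenvalues^2
  sqrt(mean(l2)) * (1 - relvar(l2) / (4 * (G$p + 2)))
}

#' @rdname delta_method
#' @export
delta_d <- function(G1, G2) {
  G1 <- as_cov_matrix(G1); G2 <- as_cov_matrix(G2)
  if (G1$p != G2$p) stop("'G1' and 'G2' must have the same dimension")
  D <- G1$values - G2$values
  if (max(abs(D)) == 0) return(undefined_value("identical_matrices"))
  s <- eigen(D, symmetric = TRUE, only.values = TRUE)$values^2
  sqrt(mean(s)) * (1 - relvar(s) / (4 * (G1$p + 2)))
}

#' @rdname delta_method
#' @export
delta_a <- function(G) {
  G <- as_cov_matrix(G)
  if (G$rank < G$p) return(undefined_value("singular_G"))
  lam <- G$eigenvalues
  p <- G$p
  E <- mean(lam)
  H <- 1 / mean(1 / lam)
  chat <- H * (1 + 2 * relvar(1 / lam) / (p + 2))
  chat / E - 2 * H * (E - H) / ((p + 2) * E^2) +
    2 * chat * relvar(lam) / ((p + 2) * E)
}
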