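#' Moments of ratios of quadratic forms in normal variables
#'
#' Evaluates `E[(x' A x)^m / (x' B x)^n]` for `x ~ N(mu, I_p)`, `A` symmetric,
#' `B` positive definite and positive real `m`, `n`, as a series in top-order
#' invariant polynomial coefficients of `(I - alpha_A A, I - alpha_B B,
#' mu mu')`:
#' ```
#' 2^(m-n) alpha_A^-m alpha_B^n exp(-mu'mu/2) *
#'   sum_{i,j,k} (-m)_i (n)_j Gamma(p/2+m-n+k) /
#'               (2^k (1/2)_k Gamma(p/2+i+j+k)) * d_{i,j,k}
#' ```
#' with `alpha_A` in `(0, 2/lambda_max(A))` and `alpha_B` in
#' `(0, 2/lambda_max(B))`. The moment exists iff `p/2 + m > n` (positive
#' definite `B`); this is checked before evaluation. When `m` is a positive
#' integer, `(-m)_i` vanishes for `i > m`, so the first summation terminates
#' on its own; when `mu = 0` all `k > 0` terms vanish and the two-index
#' recursion is used. The average conditional evolvability and average
#' respondability series are the special cases `(A = I, B = solve(G),
#' m = n = 1)` and `(A = G^2, B = I, m = n = 1/2)`.
#'
#' The series is summed by total-order layers until the relative layer
#' increment stays below `tol` for 20 consecutive layers.
#'
#' @param A symmetric matrix with a positive largest eigenvalue.
#' @param B positive-definite matrix.
#' @param m,n positive real exponents.
#' @param mu mean vector of `x` (`NULL` or zeros for the central case).
#' @param tol relative stabilization tolerance.
#' @param alpha_A,alpha_B scaling constants; default `1/lambda_max` of the
#'   respective matrix.
#' @param max_order total-order truncation cap.
#' @return A `series_evaluation` object (see [avg_cond_evolvability()]);
#'   `terms` holds per-total-order layer sums.
#' @export
#' @examples
#' G <- diag(c(1, 4))
#' # E[(x'x) / (x' solve(G) x)] = average conditional evolvability of G
#' qf_ratio_moment(diag(2), solve(G), m = 1, n = 1)$value
qf_ratio_moment <- function(A, B, m = 1, n = 1, mu = NULL, tol = 1e-8,
                            alpha_A = NULL, alpha_B = NULL,
                            max_order = 2000L) {
  A <- as.matrix(A); B <- as.matrix(B)
  p <- nrow(A)
  if (ncol(A) != p || nrow(B) != p || ncol(B) != p)
    stop("'A' and 'B' must be square matrices of the same dimension")
  if (max(abs(A - t(A))) > 1e-8 * max(abs(A), 1))
    stop("'A' must be symmetric")
  if (m <= 0 || n <= 0) stop("'m' and 'n' must be positive")
  evB <- eigen((B + t(B)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(evB) <= 0)
    stop("'B' must be positive definite")
  if (!(p / 2 + m > n))
    stop("moment does not exist: requires p/2 + m > n for positive definite B")
  lmaxA <- max(eigen((A + t(A)) / 2, symmetric = TRUE,
                     only.values = TRUE)$values)
  if (lmaxA <= 0)
    stop("'A' must have a positive largest eigenvalue")
  if (is.null(alpha_A)) alpha_A <- 1 / lmaxA
  if (is.null(alpha_B)) alpha_B <- 1 / max(evB)
  if (alpha_A <= 0 || alpha_A >= 2 / lmaxA)
    stop("'alpha_A' must lie in (0, 2/lambda_max(A))")
  if (alpha_B <= 0 || alpha_B >= 2 / max(evB))
    stop("'alpha_B' must lie in (0, 2/lambda_max(B))")
  central <- is.null(mu) || all(mu == 0)
  mu2 <- if (central) 0 else sum(mu^2)
  A1 <- diag(p) - alpha_A * (A + t(A)) / 2
  A2 <- diag(p) - alpha_B * (B + t(B)) / 2
  lpre <- (m - n) * log(2) - m * log(alpha_A) + n * log(alpha_B) - mu2 / 2

  M <- 64L
  repeat {
    M <- min(M, max_order)
    if (central) {
      tab <- cpp_d2_mat_table(A1, A2, M)
      s_idx <- rep(0:M, times = 0:M + 1L)
      i_idx <- sequence(0:M + 1L) - 1L
      k_idx <- 0L
    } else {
      tab <- cpp_d3_mat_table(A1, A2, tcrossprod(mu), M)
      ncell_s <- (0:M + 1L) * (0:M + 2L) / 2L
      s_idx <- rep(0:M, times = ncell_s)
      k_idx <- unlist(lapply(0:M, function(s) rep(0:s, times = s:0 + 1L)),
                      use.names = FALSE)
      i_idx <- unlist(lapply(0:M, function(s)
        sequence(s:0 + 1L) - 1L), use.names = FALSE)
    }
    j_idx <- s_idx - k_idx - i_idx
    pm <- signed_poch(-m, max(i_idx))
    lterm <- lpre + pm$logabs[i_idx + 1] + lpoch(n, j_idx) +
      lgamma(p / 2 + m - n + k_idx) - k_idx * log(2) - lpoch(0.5, k_idx) -
      lgamma(p / 2 + s_idx) +
      log(abs(tab$mant)) + tab$ex * log(2)
    tsgn <- pm$sign[i_idx + 1] * sign(tab$mant)
    terms <- tsgn * exp(lterm)
    lay <- as.vector(rowsum(terms, s_idx))  # numeric group -> sorted by order
    Mu <- stabilized_at(lay, tol)
    if (!is.na(Mu))
      return(new_series_evaluation("qf_ratio_moment", lay[1:Mu],
                                   c(alpha_A = alpha_A, alpha_B = alpha_B),
                                   tol, converged = TRUE,
                                   criterion = "stabilized"))
    if (M >= max_order)
      return(new_series_evaluation("qf_ratio_moment", lay,
                                   c(alpha_A = alpha_A, alpha_B = alpha_B),
                                   tol, converged = FALSE,
                                   criterion = "stabilized",
                                   diagnostics = paste0(
                                     "order cap max_order = ", max_order,
                                     " reached; best partial sum returned")))
    M <- 2L * M
  }
}

# signed Pochhammer sequence (a)_0 .. (a)_kmax for possibly negative a
signed_poch <- function(a, kmax) {
  logabs <- numeric(kmax + 1)
  sgn <- numeric(kmax + 1)
  sgn[1] <- 1
  v <- 0; s <- 1
  for (k in seq_len(kmax)) {
    f <- a + k - 1
    s <- s * sign(f)
    v <- v + log(abs(f))           # -Inf once f == 0, stays -Inf
    logabs[k + 1] <- v
    sgn[k + 1] <- s
  }
  list(logabs = logabs, sign = sgn)
}
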