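#' Average evolvability measures under spherically distributed selection
#'
#' When the selection gradient `beta` is spherically distributed (equivalently
#' its direction `u` is uniform on the unit hypersphere), each fixed-gradient
#' measure has an expectation that is a moment of a (multiple) ratio of
#' quadratic forms in normal variables. Except for the average evolvability
#' `tr(G)/p`, these expectations are evaluated quasi-exactly as infinite
#' series in top-order zonal/invariant polynomial coefficients `d` of
#' arguments of the form `I - alpha * A`:
#' * average conditional evolvability:
#'   `cbar = alpha * sum_k (1)_k / (p/2)_k * d_k(I - alpha * solve(G))`;
#' * average autonomy: double series with weights `(1)_i (1)_j / (p/2)_{i+j}`
#'   over `d_{i,j}(I - alpha1 G, I - alpha2 solve(G))`;
#' * average respondability:
#'   `rbar = alpha^(-1/2) * sum_k (-1/2)_k / (p/2)_k * d_k(I - alpha G^2)`;
#' * average flexibility:
#'   `fbar = alpha^(1/2) * sum_k (1/2)_k / (p/2)_{k+1} * d_{k,1}(I - alpha G^2, G)`;
#' * average response difference: the respondability series with argument
#'   `(G1 - G2)^2`;
#' * average response correlation: double series with weights
#'   `(1/2)_i (1/2)_j / (p/2)_{i+j+1}` over
#'   `d_{i,j,1}(I - alpha1 G1^2, I - alpha2 G2^2, (G1 G2 + G2 G1)/2)`.
#'
#' Here `(a)_k` is the Pochhammer (rising factorial) symbol and `alpha` is a
#' free constant in `(0, 2/lambda_max)` of the relevant argument matrix
#' (`alpha_factor` scales the default `1/lambda_max`). For
#' `alpha <= 1/lambda_max` all polynomial coefficients are nonnegative, so
#' truncation underestimates `cbar`, `abar`, `fbar`, `rhobar` (their partial
#' sums are nondecreasing) and overestimates `rbar`, `dbar` (nonincreasing
#' after order 0), and hard truncation-error bounds are available for `cbar`,
#' `rbar`, `fbar`, `dbar` on nonsingular arguments. Where a bound exists the
#' series is truncated at the first order with `|bound| <= tol`; otherwise
#' (`abar`, `rhobar`, `alpha_factor > 1`, singular arguments) evaluation stops
#' once the relative increment stays below `tol` for 20 consecutive orders
#' ("stabilized"), or reports a structured non-convergence when `max_order`
#' is exhausted.
#'
#' Singular `G` short-circuits: `cbar` and `abar` are exactly 0 (the range
#' condition holds with probability 0), `ibar` is 1; `rbar`, `fbar`, `dbar`
#' remain well defined but without bounds.
#'
#' @param G,G1,G2 covariance matrices (matrix or `cov_matrix`).
#' @param tol requested accuracy: bound threshold, or relative-increment
#'   threshold for stabilization.
#' @param alpha_factor multiple of `1/lambda_max` used for `alpha`, in
#'   `(0, 2)`. Values above 1 void the error bounds (a warning is given and
#'   stabilization is used). Converged values do not depend on `alpha`.
#' @param max_order truncation cap; exceeding it yields `converged = FALSE`
#'   with the best partial sum, never an error.
#' @return A `series_evaluation` object: list with `measure`, `value`,
#'   `terms`, `partial_sums`, `error_bound` (signed; `NA` when unavailable),
#'   `alpha`, `M_used`, `converged`, `criterion`, `tol`, `diagnostics`.
#'   `avg_evolvability` returns a plain number.
#' @name average_measures
#' @examples
#' G <- diag(c(1, 4))
#' avg_evolvability(G)                 # 2.5
#' avg_cond_evolvability(G)$value      # 2, the geometric mean for p = 2
#' avg_autonomy(diag(2))$value         # 1
NULL

new_series_evaluation <- function(measure, terms, alpha, tol, converged,
                                  criterion, bounds = NULL,
                                  diagnostics = NULL) {
  ps <- cumsum(terms)
  structure(list(
    measure = measure,
    value = ps[length(ps)],
    terms = terms,
    partial_sums = ps,
    error_bound = if (is.null(bounds)) NA_real_ else bounds[length(bounds)],
    bounds = bounds,
    alpha = alpha,
    M_used = length(terms) - 1L,
    converged = converged,
    criterion = criterion,
    tol = tol,
    diagnostics = diagnostics), class = "series_evaluation")
}

exact_series_evaluation <- function(measure, value, alpha = NULL,
                                    tol = NA_real_, diagnostics = NULL) {
  new_series_evaluation(measure, terms = value, alpha = alpha, tol = tol,
                        converged = TRUE, criterion = "exact",
                        bounds = 0, diagnostics = diagnostics)
}

#' @export
print.series_evaluation <- function(x, ...) {
  cat("series_evaluation: ", x$measure, "\n", sep = "")
  cat("  estimate  ", format(x$value, digits = 10), "\n")
  if (!is.na(x$error_bound))
    cat("  bound     ", format(x$error_bound, digits = 4), "\n")
  cat("  M         ", x$M_used, "\n")
  cat("  converged ", x$converged, " (", x$criterion, ")\n", sep = "")
  if (!is.null(x$diagnostics)) cat("  note      ", x$diagnostics, "\n")
  invisible(x)
}

lpoch <- function(a, k) lgamma(a + k) - lgamma(a)

check_alpha_factor <- function(alpha_factor) {
  if (!is.numeric(alpha_factor) || length(alpha_factor) != 1 ||
      alpha_factor <= 0 || alpha_factor >= 2)
    stop("'alpha_factor' must lie in (0, 2)")
  if (alpha_factor > 1)
    warning("alpha_factor > 1: error bounds are void; using stabilization")
  alpha_factor
}

# detect index where the stabilization criterion (relative increment <= tol
# for nstab consecutive orders) is first met; NA if never
stabilized_at <- function(terms, tol, nstab = 20L) {
  ps <- cumsum(terms)
  ok <- abs(terms) <= tol * abs(ps) & ps != 0
  ok[1] <- FALSE
  run <- 0L
  for (k in seq_along(ok)) {
    run <- if (ok[k]) run + 1L else 0L
    if (run >= nstab) return(k)
  }
  NA_integer_
}

# shared driver for the single-index series (cbar, rbar, dbar):
# value = pref * sum_k sign_k exp(lw_k) d_k(arg); bound_fun(k0, csm, cse)
# returns per-order signed bounds or NULL
single_series <- function(measure, arg_eig, pref, lw_fun, sign_fun,
                          bound_fun, tol, max_order, alpha) {
  M <- min(512L, max_order)
  repeat {
    co <- cpp_d1_vec(arg_eig, M)
    k <- 0:M
    lw <- lw_fun(k)
    terms <- sign_fun(k) * sign(co$mant) *
      exp(lw + log(abs(co$mant)) + co$ex * log(2)) * pref
    bounds <- if (is.null(bound_fun)) NULL
      else bound_fun(k, co$csum_mant, co$csum_ex)
    if (!is.null(bounds)) {
      hit <- which(abs(bounds) <= tol)
      if (length(hit)) {
        Mu <- hit[1]
        return(new_series_evaluation(measure, terms[1:Mu], alpha, tol,
                                     converged = TRUE, criterion = "bound",
                                     bounds = bounds[1:Mu]))
      }
    } else {
      Mu <- stabilized_at(terms, tol)
      if (!is.na(Mu))
        return(new_series_evaluation(measure, terms[1:Mu], alpha, tol,
                                     converged = TRUE,
                                     criterion = "stabilized"))
    }
    if (M >= max_order)
      return(new_series_evaluation(measure, terms, alpha, tol,
                                   converged = FALSE,
                                   criterion = if (is.null(bounds))
                                     "stabilized" else "bound",
                                   bounds = bounds,
                                   diagnostics = paste0(
                                     "order cap max_order = ", max_order,
                                     " reached; best partial sum returned")))
    M <- min(2L * M, max_order)
  }
}

# log of the tail full_sum - partial_sum, from the scaled cumulative sum
tail_log <- function(log_full, csm, cse) {
  slog <- log(csm) + cse * log(2)
  ratio <- exp(slog - log_full)
  log_full + log1p(-pmin(ratio, 1))
}

#' @rdname average_measures
#' @export
avg_evolvability <- function(G) {
  G <- as_cov_matrix(G)
  mean(G$eigenvalues)
}

#' @rdname average_measures
#' @export
avg_cond_evolvability <- function(G, tol = 1e-8, alpha_factor = 1,
                                  max_order = 50000L) {
  G <- as_cov_matrix(G)
  af <- check_alpha_factor(alpha_factor)
  if (G$rank < G$p)
    return(exact_series_evaluation("avg_cond_evolvability", 0,
                                   diagnostics = "singular G: cbar = 0 exactly"))
  lam <- G$eigenvalues
  p <- G$p
  al <- af * min(lam)              # alpha_factor / lambda_max(solve(G))
  arg <- 1 - al / lam
  bound_fun <- NULL
  if (af <= 1) {
    log_full <- -(p / 2) * log(al) + 0.5 * sum(log(lam))
    bound_fun <- function(k, csm, cse)
      exp(lgamma(k + 2) - lpoch(p / 2, k + 1) + log(al) +
            tail_log(log_full, csm, cse))
  }
  single_series("avg_cond_evolvability", arg, al,
                lw_fun = function(k) lpoch(1, k) - lpoch(p / 2, k),
                sign_fun = function(k) 1,
                bound_fun = bound_fun, tol = tol, max_order = max_order,
                alpha = c(alpha = al))
}

#' @rdname average_measures
#' @export
avg_respondability <- function(G, tol = 1e-8, alpha_factor = 1,
                               max_order = 50000L) {
  G <- as_cov_matrix(G)
  af <- check_alpha_factor(alpha_factor)
  lam <- G$eigenvalues
  p <- G$p
  al <- af / max(lam)^2
  arg <- 1 - al * lam^2
  bound_fun <- NULL
  if (af <= 1 && G$rank == G$p) {
    log_full <- -(p / 2) * log(al) - sum(log(lam))
    bound_fun <- function(k, csm, cse)
      -exp(log(0.5) + lgamma(k + 0.5) - lgamma(0.5) - lpoch(p / 2, k + 1) -
             0.5 * log(al) + tail_log(log_full, csm, cse))
  }
  single_series("avg_respondability", arg, al^(-0.5),
                lw_fun = function(k)
                  ifelse(k == 0, 0, log(0.5) + lgamma(pmax(k, 1) - 0.5) -
                           lgamma(0.5)) - lpoch(p / 2, k),
                sign_fun = function(k) ifelse(k == 0, 1, -1),
                bound_fun = bound_fun, tol = tol, max_order = max_order,
                alpha = c(alpha = al))
}

#' @rdname average_measures
#' @export
avg_flexibility <- function(G, tol = 1e-8, alpha_factor = 1,
                            max_order = 50000L) {
  G <- as_cov_matrix(G)
  af <- check_alpha_factor(alpha_factor)
  lam <- G$eigenvalues
  if (all(lam == 0)) stop("'G' must be nonzero for average flexibility")
  p <- G$p
  al <- af / max(lam)^2
  arg <- 1 - al * lam^2            # I - alpha G^2, in G's eigenbasis
  bdiag <- lam                     # diag of G in the same basis
  M <- min(512L, max_order)
  pref <- sqrt(al)
  bounded <- af <= 1 && G$rank == G$p
  if (bounded)
    log_full <- -((p + 2) / 2) * log(al) - sum(log(lam)) +
      log(sum(1 / lam) / 2)
  repeat {
    co <- cpp_d2h_vec(arg, bdiag, M)
    k <- 0:M
    lw <- lpoch(0.5, k) - lpoch(p / 2, k + 1)
    terms <- sign(co$mant) * exp(lw + log(abs(co$mant)) + co$ex * log(2)) *
      pref
    bounds <- NULL
    if (bounded) {
      bounds <- exp(lpoch(0.5, k + 1) - lpoch(p / 2, k + 2) +
                      0.5 * log(al) +
                      tail_log(log_full, co$csum_mant, co$csum_ex))
      hit <- which(abs(bounds) <= tol)
      if (length(hit)) {
        Mu <- hit[1]
        return(new_series_evaluation("avg_flexibility", terms[1:Mu],
                                     c(alpha = al), tol, converged = TRUE,
                                     criterion = "bound",
                                     bounds = bounds[1:Mu]))
      }
    } else {
      Mu <- stabilized_at(terms, tol)
      if (!is.na(Mu))
        return(new_series_evaluation("avg_flexibility", terms[1:Mu],
                                     c(alpha = al), tol, converged = TRUE,
                                     criterion = "stabilized"))
    }
    if (M >= max_order)
      return(new_series_evaluation("avg_flexibility", terms, c(alpha = al),
                                   tol, converged = FALSE,
                                   criterion = if (bounded) "bound"
                                     else "stabilized",
                                   bounds = bounds,
                                   diagnostics = paste0(
                                     "order cap max_order = ", max_order,
                                     " reached; best partial sum returned")))
    M <- min(2L * M, max_order)
  }
}

#' @rdname average_measures
#' @export
avg_response_difference <- function(G1, G2, tol = 1e-8, alpha_factor = 1,
                                    max_order = 50000L) {
  G1 <- as_cov_matrix(G1); G2 <- as_cov_matrix(G2)
  if (G1$p != G2$p) stop("'G1' and 'G2' must have the same dimension")
  af <- check_alpha_factor(alpha_factor)
  D <- G1$values - G2$values
  if (max(abs(D)) == 0)
    return(exact_series_evaluation("avg_response_difference", 0,
                                   diagnostics = "G1 = G2: dbar = 0 exactly"))
  p <- G1$p
  s <- eigen(D, symmetric = TRUE, only.values = TRUE)$values^2
  al <- af / max(s)
  arg <- 1 - al * s
  bound_fun <- NULL
  if (af <= 1 && min(s) > 100 * .Machine$double.eps * max(s) * p) {
    log_full <- -(p / 2) * log(al) - 0.5 * sum(log(s))
    bound_fun <- function(k, csm, cse)
      -exp(log(0.5) + lgamma(k + 0.5) - lgamma(0.5) - lpoch(p / 2, k + 1) -
             0.5 * log(al) + tail_log(log_full, csm, cse))
  }
  single_series("avg_response_difference", arg, al^(-0.5),
                lw_fun = function(k)
                  ifelse(k == 0, 0, log(0.5) + lgamma(pmax(k, 1) - 0.5) -
                           lgamma(0.5)) - lpoch(p / 2, k),
                sign_fun = function(k) ifelse(k == 0, 1, -1),
                bound_fun = bound_fun, tol = tol, max_order = max_order,
                alpha = c(alpha = al))
}

# wrap a C++ streamed double-series result
double_series_result <- function(measure, res, pref, alpha, tol, max_order) {
  terms <- pref * res$layer_terms
  diagnostics <- NULL
  if (!res$converged)
    diagnostics <- paste0("order cap max_order = ", max_order,
                          " reached; best partial sum returned ",
                          "(memory/order-limited, as for ill-conditioned ",
                          "spectra at large p)")
  new_series_evaluation(measure, terms, alpha, tol,
                        converged = res$converged, criterion = "stabilized",
                        diagnostics = diagnostics)
}

#' @rdname average_measures
#' @export
avg_autonomy <- function(G, tol = 1e-8, alpha_factor = 1, max_order = 5000L) {
  G <- as_cov_matrix(G)
  af <- check_alpha_factor(alpha_factor)
  if (G$rank < G$p)
    return(exact_series_evaluation("avg_autonomy", 0,
                                   diagnostics = "singular G: abar = 0 exactly"))
  lam <- G$eigenvalues
  p <- G$p
  a1 <- af / max(lam)
  a2 <- af * min(lam)
  res <- cpp_d2_vec_series(1 - a1 * lam, 1 - a2 / lam,
                           ai = 1, aj = 1, as = p / 2, sdelta = 0,
                           Mmax = max_order, tol = tol, nstab = 20L)
  double_series_result("avg_autonomy", res, a1 * a2,
                       c(alpha1 = a1, alpha2 = a2), tol, max_order)
}

#' @rdname average_measures
#' @export
avg_integration <- function(G, tol = 1e-8, alpha_factor = 1,
                            max_order = 5000L) {
  a <- avg_autonomy(G, tol = tol, alpha_factor = alpha_factor,
                    max_order = max_order)
  a$measure <- "avg_integration"
  a$terms <- c(1 - a$terms[1], -a$terms[-1])
  a$partial_sums <- cumsum(a$terms)
  a$value <- a$partial_sums[length(a$partial_sums)]
  a
}

#' @rdname average_measures
#' @export
avg_response_correlation <- function(G1, G2, tol = 1e-8, alpha_factor = 1,
                                     max_order = 5000L) {
  G1 <- as_cov_matrix(G1); G2 <- as_cov_matrix(G2)
  if (G1$p != G2$p) stop("'G1' and 'G2' must have the same dimension")
  if (max(abs(G1$values)) == 0 || max(abs(G2$values)) == 0)
    stop("average response correlation is undefined for a zero matrix")
  af <- check_alpha_factor(alpha_factor)
  p <- G1$p
  a1 <- af / max(G1$eigenvalues)^2
  a2 <- af / max(G2$eigenvalues)^2
  # commuting pair: run the recursion on joint eigenvalues
  comm <- G1$values %*% G2$values
  comm_rel <- max(abs(comm - t(comm))) /
    max(max(abs(comm)), .Machine$double.xmin)
  vecpath <- FALSE
  if (comm_rel < 1e-12) {
    Q <- G1$eigenvectors
    D2 <- crossprod(Q, G2$values %*% Q)
    if (max(abs(D2 - diag(diag(D2)))) < 1e-10 * max(abs(D2))) {
      l1 <- G1$eigenvalues
      l2 <- diag(D2)
      vecpath <- TRUE
    }
  }
  if (vecpath) {
    res <- cpp_d3l_vec_series(1 - a1 * l1^2, 1 - a2 * l2^2, l1 * l2,
                              ai = 0.5, aj = 0.5, as = p / 2, sdelta = 1,
                              Mmax = max_order, tol = tol, nstab = 20L)
  } else {
    B <- (G1$values %*% G2$values + G2$values %*% G1$values) / 2
    res <- cpp_d3l_mat_series(diag(p) - a1 * G1$values %*% G1$values,
                              diag(p) - a2 * G2$values %*% G2$values, B,
                              ai = 0.5, aj = 0.5, as = p / 2, sdelta = 1,
                              Mmax = max_order, tol = tol, nstab = 20L)
  }
  double_series_result("avg_response_correlation", res, sqrt(a1 * a2),
                       c(alpha1 = a1, alpha2 = a2), tol, max_order)
}
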