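#' Monte Carlo ("random skewers") estimation of average measures
#'
#' Draws selection gradients uniformly on the unit hypersphere (normalized
#' independent standard normal vectors), applies the fixed-gradient measure
#' to each draw, and summarizes with the sample mean, its empirical standard
#' error `sd/sqrt(n)` and the normal-approximation 95% confidence interval
#' `mean +/- 1.96 SE`. Draws where the measure is undefined are excluded
#' (with a warning); for continuous sampling this has probability zero,
#' except for conditional evolvability and autonomy on singular `G`, where
#' the exact-zero convention applies before sampling (`c = a = 0`, `i = 1`,
#' almost surely).
#'
#' @param measure one of `"e"`, `"c"`, `"a"`, `"i"`, `"r"`, `"f"` (one
#'   matrix) or `"d"`, `"rho"` (two matrices).
#' @param G,G2 covariance matrices; `G2` only for `"d"` and `"rho"`.
#' @param n_iter number of draws (at least 2).
#' @param seed integer seed; identical seeds give bitwise-identical
#'   estimates. The caller's RNG state is restored afterwards.
#' @return An object of class `mc_estimate`: list with `mean`, `se`,
#'   `ci_low`, `ci_high`, `n_iter`, `n_defined`, `seed`, `measure`.
#' @export
#' @examples
#' mc_average("e", diag(c(1, 2, 3)), n_iter = 1000, seed = 1)
mc_average <- function(measure = c("e", "c", "a", "i", "r", "f", "d", "rho"),
                       G, G2 = NULL, n_iter = 10000L, seed = 1L) {
  measure <- match.arg(measure)
  G <- as_cov_matrix(G)
  p <- G$p
  if (n_iter < 2) stop("'n_iter' must be at least 2")
  two <- measure %in% c("d", "rho")
  if (two) {
    if (is.null(G2)) stop("'G2' is required for measure '", measure, "'")
    G2 <- as_cov_matrix(G2)
    if (G2$p != p) stop("'G' and 'G2' must have the same dimension")
  }
  # exact-zero convention for c/a/i on singular G
  if (!two && measure %in% c("c", "a", "i") && G$rank < p) {
    val <- if (measure == "i") 1 else 0
    return(structure(list(mean = val, se = 0, ci_low = val, ci_high = val,
                          n_iter = as.integer(n_iter),
                          n_defined = as.integer(n_iter),
                          seed = as.integer(seed), measure = measure),
                     class = "mc_estimate"))
  }
  u <- with_local_seed(seed, {
    x <- matrix(stats::rnorm(p * n_iter), p, n_iter)
    x / rep(sqrt(colSums(x^2)), each = p)
  })
  vals <- switch(measure,
    e = colSums(u * (G$values %*% u)),
    c = 1 / colSums(u * (generalized_inverse(G) %*% u)),
    a = {
      e <- colSums(u * (G$values %*% u))
      (1 / colSums(u * (generalized_inverse(G) %*% u))) / e
    },
    i = {
      e <- colSums(u * (G$values %*% u))
      1 - (1 / colSums(u * (generalized_inverse(G) %*% u))) / e
    },
    r = sqrt(colSums((G$values %*% u)^2)),
    f = {
      z <- G$values %*% u
      r <- sqrt(colSums(z^2))
      ifelse(r == 0, NA_real_, colSums(u * z) / r)
    },
    d = sqrt(colSums(((G$values - G2$values) %*% u)^2)),
    rho = {
      z1 <- G$values %*% u; z2 <- G2$values %*% u
      den <- sqrt(colSums(z1^2) * colSums(z2^2))
      ifelse(den == 0, NA_real_, colSums(z1 * z2) / den)
    })
  defined <- !is.na(vals)
  nd <- sum(defined)
  if (nd == 0) stop("measure undefined on every draw")
  if (nd < n_iter)
    warning(n_iter - nd, " draws excluded (measure undefined)")
  v <- vals[defined]
  mn <- mean(v)
  se <- stats::sd(v) / sqrt(nd)
  structure(list(mean = mn, se = se,
                 ci_low = mn - 1.96 * se, ci_high = mn + 1.96 * se,
                 n_iter = as.integer(n_iter), n_defined = as.integer(nd),
                 seed = as.integer(seed), measure = measure),
            class = "mc_estimate")
}

#' @export
print.mc_estimate <- function(x, ...) {
  cat("mc_estimate: ", x$measure, "\n", sep = "")
  cat("  mean ", format(x$mean, digits = 8), " (SE ",
      format(x$se, digits = 4), ")\n", sep = "")
  cat("  95% CI [", format(x$ci_low, digits = 8), ", ",
      format(x$ci_high, digits = 8), "]  n = ", x$n_defined, "/", x$n_iter,
      "\n", sep = "")
  invisible(x)
}
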