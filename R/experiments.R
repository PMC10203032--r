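#' Numerical-experiment grid over test conformations
#'
#' Runs the series, Monte Carlo and (where defined) delta-method evaluations
#' of average measures over a grid of eigenvalue conformations, dimensions
#' and eigenvector modes, and returns a tidy result table. One-matrix
#' measures get one row per (conformation, p, eigenvectors); two-matrix
#' measures one row per pair of conformations (same eigenvectors pairs the
#' i-th largest eigenvalue with the i-th largest; `"givens_correlation"`
#' pairs are built with distinct seeds, so also same-conformation pairs are
#' compared). Cells that exceed the order caps are recorded as non-converged
#' with their best partial sum, never as errors.
#'
#' @param profiles list of [eigen_profile()] specifications (dimension taken
#'   from each profile).
#' @param evec_modes subset of `c("diagonal", "givens_correlation")`.
#' @param measures subset of `c("e", "c", "a", "i", "r", "f", "d", "rho")`.
#' @param tol series accuracy passed to the `avg_*` functions.
#' @param mc_n,mc_seed Monte Carlo draws and base seed.
#' @param max_order_single,max_order_double truncation caps for single and
#'   double series.
#' @param givens_seed base seed for the Givens construction.
#' @return `data.frame` with columns `conformation`, `p`, `evecs`,
#'   `measure`, `estimate`, `bound`, `M`, `mc_mean`, `mc_se`, `delta`,
#'   `pct_dev`, `converged`.
#' @export
#' @examples
#' g <- run_grid(list(eigen_profile("one_large", 5, v_rel = 0.1),
#'                    eigen_profile("quadratic", 5)),
#'               measures = c("c", "r"), mc_n = 1000)
run_grid <- function(profiles,
                     evec_modes = "diagonal",
                     measures = c("e", "c", "a", "r", "f", "d", "rho"),
                     tol = 1e-8, mc_n = 10000L, mc_seed = 1L,
                     max_order_single = 50000L, max_order_double = 5000L,
                     givens_seed = 1L) {
  stopifnot(all(vapply(profiles, inherits, TRUE, "eigen_profile")))
  evec_modes <- match.arg(evec_modes,
                          c("diagonal", "givens_correlation"),
                          several.ok = TRUE)
  conf_label <- function(pr) switch(pr$kind,
    one_large = paste0("one_large_", pr$v_rel),
    quadratic = "quadratic",
    explicit = "explicit")
  rows <- list()
  add_row <- function(conformation, p, evecs, measure, est, bound, M,
                      mc, delta, converged) {
    pct <- if (is.na(delta) || est == 0) NA_real_
      else 100 * (delta - est) / est
    rows[[length(rows) + 1L]] <<- data.frame(
      conformation = conformation, p = p, evecs = evecs, measure = measure,
      estimate = est, bound = bound, M = M, mc_mean = mc$mean,
      mc_se = mc$se, delta = delta, pct_dev = pct, converged = converged)
  }
  one_mats <- list()
  seed_i <- givens_seed
  for (em in evec_modes) {
    for (pr in profiles) {
      Gm <- if (em == "diagonal") make_covariance(pr, "diagonal")
        else make_covariance(pr, "givens_correlation", seed = seed_i)
      if (em == "givens_correlation") seed_i <- seed_i + 1L
      one_mats[[length(one_mats) + 1L]] <-
        list(G = Gm, conformation = conf_label(pr), p = pr$p, evecs = em)
    }
  }
  one_measures <- intersect(measures, c("e", "c", "a", "i", "r", "f"))
  for (cell in one_mats) {
    for (ms in one_measures) {
      ev <- switch(ms,
        e = NULL,
        c = avg_cond_evolvability(cell$G, tol, max_order = max_order_single),
        a = avg_autonomy(cell$G, tol, max_order = max_order_double),
        i = avg_integration(cell$G, tol, max_order = max_order_double),
        r = avg_respondability(cell$G, tol, max_order = max_order_single),
        f = avg_flexibility(cell$G, tol, max_order = max_order_single))
      est <- if (ms == "e") avg_evolvability(cell$G) else ev$value
      bound <- if (ms == "e") 0 else ev$error_bound
      M <- if (ms == "e") 0L else ev$M_used
      conv <- if (ms == "e") TRUE else ev$converged
      mc <- mc_average(ms, cell$G, n_iter = mc_n, seed = mc_seed)
      delta <- switch(ms, e = delta_e(cell$G), c = delta_c(cell$G),
                      a = delta_a(cell$G), r = delta_r(cell$G),
                      NA_real_)
      add_row(cell$conformation, cell$p, cell$evecs, ms, est, bound, M,
              mc, as.numeric(delta), conv)
    }
  }
  two_measures <- intersect(measures, c("d", "rho"))
  if (length(two_measures)) {
    pair_idx <- list()
    np <- length(one_mats)
    for (i in seq_len(np)) for (j in seq_len(np)) {
      if (j <= i) next
      ci <- one_mats[[i]]; cj <- one_mats[[j]]
      if (ci$p != cj$p) next
      # diagonal-vs-diagonal pairs of distinct conformations; Givens pairs
      # (any conformations, distinct seeds) for different-eigenvector cells
      same_diag <- ci$evecs == "diagonal" && cj$evecs == "diagonal"
      both_giv <- ci$evecs == "givens_correlation" &&
        cj$evecs == "givens_correlation"
      if ((same_diag && ci$conformation != cj$conformation) || both_giv)
        pair_idx[[length(pair_idx) + 1L]] <- c(i, j)
    }
    for (ix in pair_idx) {
      ci <- one_mats[[ix[1]]]; cj <- one_mats[[ix[2]]]
      lbl <- paste0(ci$conformation, "_vs_", cj$conformation)
      ev_lbl <- if (ci$evecs == "diagonal") "same" else "different"
      for (ms in two_measures) {
        ev <- if (ms == "d")
          avg_response_difference(ci$G, cj$G, tol,
                                  max_order = max_order_single)
        else avg_response_correlation(ci$G, cj$G, tol,
                                      max_order = max_order_double)
        mc <- mc_average(ms, ci$G, cj$G, n_iter = mc_n, seed = mc_seed)
        delta <- if (ms == "d") as.numeric(delta_d(ci$G, cj$G)) else NA_real_
        add_row(lbl, ci$p, ev_lbl, ms, ev$value, ev$error_bound, ev$M_used,
                mc, delta, ev$converged)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
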