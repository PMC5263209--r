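#' Fit the founder-effect mixed model by REML
#'
#' Fits `y = X b + sum_j Z_j u_j + e` where each `Z_j` is a block of
#' founder-probability columns, `u_j ~ N(0, s2_j I)` is an independent
#' random founder-effect vector, and residuals have cross-specific
#' variances `e_i ~ N(0, s2_eps[cross_i])`. The restricted log-likelihood
#' is maximized over log-variances by quasi-Newton iteration; fixed effects
#' are profiled analytically inside the objective.
#'
#' @param y numeric response (one value per line, typically replicate means).
#' @param X fixed-effect design matrix (cross-mean indicators).
#' @param Zlist list of random-term design matrices (may be empty).
#' @param cross factor/character of cross labels per observation.
#' @param init optional warm-start vector of log-variances
#'   (terms then residuals).
#' @param reltol convergence tolerance for the optimizer (default 1e-10).
#' @param max_iter iteration cap (default 200).
#' @return List with `loglik` (restricted), `beta`, `beta_cov`, `blup`
#'   (list per term), `pev` (list of per-term prediction-error covariance),
#'   `s2_terms`, `s2_resid`, `converged`, `par`.
#' @export
fit_founder_mm <- function(y, X, Zlist = list(), cross,
                           init = NULL, reltol = 1e-10, max_iter = 200L) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  cross <- as.factor(cross)
  n_cross <- nlevels(cross)
  cross_i <- as.integer(cross) - 1L
  n_terms <- length(Zlist)
  if (n_terms) {
    U <- do.call(cbind, Zlist)
    term <- rep(seq_len(n_terms), vapply(Zlist, ncol, 1L)) - 1L
  } else {
    U <- matrix(0, length(y), 0)
    term <- integer(0)
  }
  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  lo <- log(vy * 1e-8)
  hi <- log(vy * 1e6)
  if (is.null(init)) {
    init <- c(rep(log(vy * 0.1), n_terms), rep(log(vy * 0.5), n_cross))
  }
  init <- pmin(pmax(init, lo), hi)
  obj <- function(p)
    reml_eval_cpp(p, y, X, U, term, cross_i, n_terms, n_cross, FALSE)$nll
  opt <- stats::nlminb(init, obj, lower = lo, upper = hi,
                       control = list(rel.tol = reltol,
                                      iter.max = max_iter,
                                      eval.max = 4L * max_iter))
  comp <- reml_eval_cpp(opt$par, y, X, U, term, cross_i,
                        n_terms, n_cross, TRUE)
  blup <- pev <- vector("list", n_terms)
  if (n_terms) {
    off <- 0L
    for (j in seq_len(n_terms)) {
      qj <- ncol(Zlist[[j]])
      idx <- off + seq_len(qj)
      blup[[j]] <- stats::setNames(as.numeric(comp$blup[idx]),
                                   colnames(Zlist[[j]]))
      pev[[j]] <- comp$pev[idx, idx, drop = FALSE]
      off <- off + qj
    }
  }
  list(loglik = -opt$objective,
       beta = stats::setNames(as.numeric(comp$beta), colnames(X)),
       beta_cov = comp$beta_cov,
       blup = blup, pev = pev,
       s2_terms = as.numeric(comp$s2_terms)[seq_len(n_terms)],
       s2_resid = stats::setNames(as.numeric(comp$s2_resid), levels(cross)),
       converged = opt$convergence == 0,
       par = opt$par, n = length(y))
}

# p-value of a variance component from the boundary-corrected LRT:
# the null distribution is the 1/2 chi2_0 + 1/2 chi2_1 mixture.
mixture_lrt_p <- function(loglik_full, loglik_null) {
  lrt <- 2 * (loglik_full - loglik_null)
  if (!is.finite(lrt) || lrt <= 1e-10) return(1)
  0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE)
}
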