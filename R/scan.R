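#' @name qtlscan
#' @title Three-stage mixed-model QTL analysis
#'
#' @description
#' The genome scan models the line-mean phenotype of RIL i in cross k as
#' `y_ik = mu_k + sum_c x_ikc' b_c + x_ikl' b_l + e_ik`, with fixed cross
#' means, an independent random 4-vector of wild-founder effects for every
#' cofactor c and for the tested locus l (variances s2_c, s2_l), and
#' cross-specific residual variances. `x_ikl` holds the HMM founder-origin
#' probabilities. Locus significance is the likelihood-ratio test of
#' `s2_l = 0` against the boundary-corrected 1/2 chi2_0 + 1/2 chi2_1
#' mixture null, reported as -log10(p).
#'
#' Stage one ([scan_sim()]) scans with no cofactors (simple interval
#' mapping); stage two ([scan_mqm()]) iteratively adds the strongest QTL as
#' a background cofactor and rescans, excluding cofactors within a window
#' of the tested locus, until nothing exceeds the threshold; stage three
#' ([fit_final()]) fits all detected QTLs jointly and reports shrunken
#' founder effects (deviations from the recipient) with prediction
#' standard errors.
NULL

# align tensor and phenotypes; X = cross-mean indicators
.scan_data <- function(fp, phenos) {
  ym <- line_means(phenos)
  ids <- intersect(fp$line_id, names(ym))
  if (!length(ids)) stop("no phenotyped lines found in the tensor")
  rows <- match(ids, fp$line_id)
  cross <- factor(fp$cross_id[rows])
  X <- stats::model.matrix(~ 0 + cross)
  colnames(X) <- levels(cross)
  wild <- setdiff(fp$founders, fp$recipient)
  list(y = unname(ym[ids]), X = X, cross = cross, rows = rows,
       wild = wild, ids = ids)
}

# wild-founder probability block at one locus (n x 4)
.locus_Z <- function(fp, rows, wild, l) {
  Z <- fp$prob[rows, l, wild]
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = length(rows))
  colnames(Z) <- wild
  Z
}

.locus_index <- function(fp, locus) {
  if (is.numeric(locus)) return(as.integer(locus))
  i <- match(locus, fp$loci$locus)
  if (anyNA(i)) stop("unknown locus: ", paste(locus[is.na(i)], collapse = ", "))
  i
}

# informative test: any variation in the locus probability block
.locus_informative <- function(Z) {
  any(apply(Z, 2, function(col) diff(range(col))) > 1e-10)
}

#' Fit the locus model at a single position
#'
#' REML fit of the cofactor-adjusted founder-effect model at one locus and
#' the mixture-LRT significance of its founder-effect variance component.
#' An uninformative locus (probability block constant across lines, e.g.
#' all mass on the recipient) returns p = 1 exactly.
#'
#' @param fp a `founder_probs` tensor.
#' @param phenos a [phenotype_table()]; line means are analysed.
#' @param locus locus name or index.
#' @param cofactors locus names/indices used as background random terms.
#' @return List with `fit` (full model), `null_fit`, `p`, `minus_log10_p`.
#' @export
fit_locus_model <- function(fp, phenos, locus, cofactors = integer(0)) {
  sd <- .scan_data(fp, phenos)
  l <- .locus_index(fp, locus)
  cf <- .locus_index(fp, cofactors)
  Zc <- lapply(cf, function(i) .locus_Z(fp, sd$rows, sd$wild, i))
  null_fit <- fit_founder_mm(sd$y, sd$X, Zc, sd$cross)
  Zl <- .locus_Z(fp, sd$rows, sd$wild, l)
  if (!.locus_informative(Zl)) {
    return(list(fit = null_fit, null_fit = null_fit, p = 1,
                minus_log10_p = 0))
  }
  fit <- fit_founder_mm(sd$y, sd$X, c(Zc, list(Zl)), sd$cross,
                        init = c(null_fit$par[seq_along(cf)],
                                 log(stats::var(sd$y) * 0.1),
                                 null_fit$par[length(cf) + seq_len(nlevels(sd$cross))]))
  p <- mixture_lrt_p(fit$loglik, null_fit$loglik)
  list(fit = fit, null_fit = null_fit, p = p, minus_log10_p = -log10(p))
}

# core scan over loci given a fixed cofactor index set, with the
# per-locus exclusion window; returns the -log10 p profile
.scan_profile <- function(fp, sd, cofactors, window, loci = NULL) {
  if (is.null(loci)) loci <- seq_len(nrow(fp$loci))
  n_cross <- nlevels(sd$cross)
  cof_pos <- fp$loci$position[cofactors]
  cof_chr <- fp$loci$chromosome[cofactors]
  Zcof <- lapply(cofactors, function(i) .locus_Z(fp, sd$rows, sd$wild, i))

  # cache null fits per distinct active-cofactor subset
  null_cache <- list()
  get_null <- function(active) {
    key <- paste0("c", paste(active, collapse = ","))
    if (is.null(null_cache[[key]])) {
      null_cache[[key]] <<- fit_founder_mm(sd$y, sd$X, Zcof[active],
                                           sd$cross)
    }
    null_cache[[key]]
  }

  mlp <- numeric(length(loci))
  warm <- NULL
  for (j in seq_along(loci)) {
    l <- loci[j]
    active <- which(!(cof_chr == fp$loci$chromosome[l] &
                        abs(cof_pos - fp$loci$position[l]) <= window))
    nf0 <- get_null(active)
    Zl <- .locus_Z(fp, sd$rows, sd$wild, l)
    if (!.locus_informative(Zl)) {
      mlp[j] <- 0
      next
    }
    # warm-start cofactor/residual variances from the previous locus but
    # always restart the tested-locus variance away from the boundary
    init <- c(nf0$par[seq_along(active)], log(stats::var(sd$y) * 0.1),
              nf0$par[length(active) + seq_len(n_cross)])
    if (!is.null(warm) && length(warm) == length(init)) {
      init <- warm
      init[length(active) + 1L] <- log(stats::var(sd$y) * 0.1)
    }
    fit <- fit_founder_mm(sd$y, sd$X, c(Zcof[active], list(Zl)), sd$cross,
                          init = init)
    # guard against a bad warm start trapping the optimizer
    if (fit$loglik < nf0$loglik - 1e-6) {
      fit2 <- fit_founder_mm(sd$y, sd$X, c(Zcof[active], list(Zl)),
                             sd$cross)
      if (fit2$loglik > fit$loglik) fit <- fit2
    }
    warm <- fit$par
    mlp[j] <- -log10(mixture_lrt_p(fit$loglik, nf0$loglik))
  }
  prof <- data.frame(locus = fp$loci$locus[loci],
                     chromosome = fp$loci$chromosome[loci],
                     position = fp$loci$position[loci],
                     minus_log10_p = mlp, stringsAsFactors = FALSE)
  attr(prof, "cofactors") <- fp$loci$locus[cofactors]
  class(prof) <- c("scan_profile", "data.frame")
  prof
}

#' Simple interval mapping scan
#'
#' Single-locus genome scan with no background cofactors.
#'
#' @inheritParams fit_locus_model
#' @return A `scan_profile` data.frame (locus, chromosome, position,
#'   minus_log10_p).
#' @export
scan_sim <- function(fp, phenos) {
  sd <- .scan_data(fp, phenos)
  .scan_profile(fp, sd, integer(0), window = 0)
}

# deterministic peak pick: highest -log10 p, ties to lowest chromosome
# (map order) then lowest cM. Loci within `window` cM of an already
# selected QTL are not candidates: inside that window the cofactor is
# excluded from the model, so the profile shows the known QTL again, not
# a new one.
.pick_peak <- function(fp, prof, exclude = integer(0), window = 0) {
  idx <- match(prof$locus, fp$loci$locus)
  cand <- setdiff(seq_len(nrow(prof)), match(exclude, idx))
  if (length(exclude) && window > 0) {
    near <- vapply(cand, function(r) {
      any(fp$loci$chromosome[exclude] == prof$chromosome[r] &
            abs(fp$loci$position[exclude] - prof$position[r]) <= window)
    }, logical(1))
    cand <- cand[!near]
  }
  cand <- cand[is.finite(prof$minus_log10_p[cand])]
  if (!length(cand)) return(NA_integer_)
  best <- max(prof$minus_log10_p[cand])
  at <- cand[prof$minus_log10_p[cand] == best]
  ord <- order(match(prof$chromosome[at], map_chromosomes(fp$panel$map)),
               prof$position[at])
  idx[at[ord[1]]]
}

#' Multi-QTL genome scan with iterative cofactor selection
#'
#' Repeats: scan all loci with the current background QTLs as random
#' cofactors (cofactors within `window` cM of the tested locus are
#' excluded), then add the strongest locus above the threshold as a new
#' cofactor. Stops when no locus exceeds the threshold, or after
#' `max_iter` rounds. A locus can be selected only once.
#'
#' @inheritParams fit_locus_model
#' @param threshold significance threshold in -log10(p) units
#'   (default 3.2).
#' @param window cofactor exclusion window in cM (default 10).
#' @param max_iter iteration cap (default 20).
#' @param verbose log each detection via [message()].
#' @return An object of class `qtl_scan`: list with `qtls` (data.frame in
#'   detection order), `profile` (final cofactor-adjusted profile),
#'   `threshold`, `window`.
#' @export
scan_mqm <- function(fp, phenos, threshold = 3.2, window = 10,
                     max_iter = 20L, verbose = FALSE) {
  sd <- .scan_data(fp, phenos)
  selected <- integer(0)
  det_mlp <- numeric(0)
  prof <- NULL
  for (it in seq_len(max_iter)) {
    prof <- .scan_profile(fp, sd, selected, window)
    peak <- .pick_peak(fp, prof, exclude = selected, window = window)
    if (is.na(peak)) break
    peak_mlp <- prof$minus_log10_p[match(fp$loci$locus[peak], prof$locus)]
    if (peak_mlp < threshold) break
    selected <- c(selected, peak)
    det_mlp <- c(det_mlp, peak_mlp)
    if (verbose)
      message(sprintf("QTL %d: %s (%s %.1f cM), -log10(p) = %.2f",
                      length(selected), fp$loci$locus[peak],
                      fp$loci$chromosome[peak], fp$loci$position[peak],
                      peak_mlp))
  }
  qtls <- data.frame(
    name = qtl_names(fp, selected),
    locus = fp$loci$locus[selected],
    chromosome = fp$loci$chromosome[selected],
    position = fp$loci$position[selected],
    minus_log10_p = det_mlp, stringsAsFactors = FALSE)
  structure(list(qtls = qtls, profile = prof, threshold = threshold,
                 window = window, founders = fp$founders,
                 recipient = fp$recipient),
            class = "qtl_scan")
}

# QTL names by chromosome in map order: Q<chrom>.<counter>
qtl_names <- function(fp, loci_idx) {
  if (!length(loci_idx)) return(character(0))
  ch <- fp$loci$chromosome[loci_idx]
  pos <- fp$loci$position[loci_idx]
  ord <- order(match(ch, map_chromosomes(fp$panel$map)), pos)
  nm <- character(length(loci_idx))
  cnt <- stats::setNames(integer(length(unique(ch))), unique(ch))
  for (i in ord) {
    cnt[ch[i]] <- cnt[ch[i]] + 1L
    nm[i] <- sprintf("Q%s.%d", ch[i], cnt[ch[i]])
  }
  nm
}

# peak and flanking marker names around a locus ("End" past the last)
.flanking_markers <- function(fp, l) {
  mk <- fp$loci[fp$loci$is_marker & fp$loci$chromosome == fp$loci$chromosome[l], ]
  pos <- fp$loci$position[l]
  peak <- mk$locus[which.min(abs(mk$position - pos))]
  left <- mk$locus[mk$position < pos]
  right <- mk$locus[mk$position > pos]
  c(peak = peak,
    flank1 = if (length(left)) left[length(left)] else "End",
    flank2 = if (length(right)) right[1] else "End")
}

#' Final joint QTL model with founder effects
#'
#' Fits all detected QTLs jointly as random founder-effect terms. Per QTL
#' it reports the predicted (shrunken) wild-founder effects as deviations
#' from the recipient, their prediction standard errors, and a
#' -log10(p) from dropping that QTL's variance component (mixture LRT
#' against the model without it).
#'
#' @inheritParams fit_locus_model
#' @param qtls a `qtl_scan` object or vector of locus names/indices.
#' @param window minimum same-chromosome spacing between QTLs in cM;
#'   closer pairs are refused (merge them first). Default 10.
#' @return An object of class `qtl_fit`: list with `table` (one row per
#'   QTL: name, position, peak/flanking markers, minus_log10_p), `effects`
#'   (QTL x wild founder matrix), `se`, `model` (joint REML fit), plus the
#'   aligned data for methods.
#' @export
fit_final <- function(fp, phenos, qtls, window = 10) {
  loci <- if (inherits(qtls, "qtl_scan")) qtls$qtls$locus else qtls
  li <- .locus_index(fp, loci)
  if (!length(li)) stop("at least one QTL required")
  ch <- fp$loci$chromosome[li]
  pos <- fp$loci$position[li]
  if (length(li) > 1) {
    for (i in seq_along(li)) for (j in seq_len(i - 1)) {
      if (ch[i] == ch[j] && abs(pos[i] - pos[j]) < window)
        stop("QTLs ", fp$loci$locus[li[j]], " and ", fp$loci$locus[li[i]],
             " are < ", window, " cM apart; merge them before the final fit")
    }
  }
  sd <- .scan_data(fp, phenos)
  Z <- lapply(li, function(i) .locus_Z(fp, sd$rows, sd$wild, i))
  full <- fit_founder_mm(sd$y, sd$X, Z, sd$cross)
  mlp <- numeric(length(li))
  for (j in seq_along(li)) {
    red <- fit_founder_mm(sd$y, sd$X, Z[-j], sd$cross,
                          init = full$par[-j])
    mlp[j] <- -log10(mixture_lrt_p(full$loglik, red$loglik))
  }
  eff <- do.call(rbind, full$blup)
  se <- do.call(rbind, lapply(full$pev, function(m) sqrt(pmax(diag(m), 0))))
  nm <- qtl_names(fp, li)
  dimnames(eff) <- dimnames(se) <- list(nm, sd$wild)
  fl <- t(vapply(li, function(l) .flanking_markers(fp, l), character(3)))
  tab <- data.frame(name = nm, chromosome = ch, position = pos,
                    peak_marker = fl[, "peak"], flank1 = fl[, "flank1"],
                    flank2 = fl[, "flank2"], minus_log10_p = mlp,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, effects = eff, se = se, model = full,
                 loci = fp$loci$locus[li], data = sd,
                 recipient = fp$recipient, units = attr(phenos, "units")),
            class = "qtl_fit")
}

#' Pairwise epistasis tests between detected QTLs
#'
#' For every QTL pair, adds to the joint additive model a random
#' interaction term whose design columns are the elementwise products of
#' the two loci's wild-founder probability columns, and tests its variance
#' component by the mixture LRT. Raw p-values are Bonferroni-corrected
#' over all pairs.
#'
#' @inheritParams fit_final
#' @return data.frame (qtl1, qtl2, p_raw, p_bonferroni).
#' @export
test_epistasis <- function(fp, phenos, qtls, window = 10) {
  loci <- if (inherits(qtls, "qtl_scan")) qtls$qtls$locus else qtls
  li <- .locus_index(fp, loci)
  if (length(li) < 2) stop("at least two QTLs required for epistasis tests")
  sd <- .scan_data(fp, phenos)
  Z <- lapply(li, function(i) .locus_Z(fp, sd$rows, sd$wild, i))
  base <- fit_founder_mm(sd$y, sd$X, Z, sd$cross)
  nm <- qtl_names(fp, li)
  pairs <- utils::combn(seq_along(li), 2)
  n_pairs <- ncol(pairs)
  p_raw <- numeric(n_pairs)
  for (k in seq_len(n_pairs)) {
    i <- pairs[1, k]; j <- pairs[2, k]
    Zint <- do.call(cbind, lapply(seq_len(ncol(Z[[i]])), function(a)
      Z[[i]][, a] * Z[[j]]))
    fit <- fit_founder_mm(sd$y, sd$X, c(Z, list(Zint)), sd$cross,
                          init = c(base$par[seq_along(li)],
                                   log(stats::var(sd$y) * 0.01),
                                   base$par[length(li) +
                                              seq_len(nlevels(sd$cross))]))
    p_raw[k] <- mixture_lrt_p(fit$loglik, base$loglik)
  }
  data.frame(qtl1 = nm[pairs[1, ]], qtl2 = nm[pairs[2, ]],
             p_raw = p_raw,
             p_bonferroni = pmin(p_raw * n_pairs, 1),
             stringsAsFactors = FALSE)
}
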