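#' Select heterozygous lines for HIF construction
#'
#' Heterogeneous inbred families start from RILs still heterozygous at the
#' target QTL marker in the final SSD generation: their selfed progeny
#' segregate only locally and provide near-isogenic contrasts.
#'
#' @param genotypes a [genotype_table()] or a plain lines x markers matrix.
#' @param marker marker name.
#' @return Character vector of line ids heterozygous (code 1) at `marker`.
#' @export
select_hif_lines <- function(genotypes, marker) {
  g <- if (inherits(genotypes, "genotype_table")) genotypes$genotypes
       else as.matrix(genotypes)
  if (!marker %in% colnames(g)) stop("marker not genotyped: ", marker)
  col <- g[, marker]
  if (all(is.na(col))) stop("marker ", marker, " has no genotype calls")
  rownames(g)[!is.na(col) & col == 1L]
}

#' Screen selfed progeny for recombinants between two flanking markers
#'
#' A progeny plant is a recombinant iff its genotype class (0/1/2) differs
#' between the two flanks. Plants with a missing call at either flank are
#' unscreenable and excluded.
#'
#' @param progeny lines x markers genotype matrix (codes 0/1/2/NA).
#' @param left,right flanking marker names.
#' @return An object of class `recombinant_set`: list with `recombinants`
#'   (ids), `classes` (table of non-recombinant flank classes),
#'   `unscreenable` (ids), `n_screened`.
#' @export
find_recombinants <- function(progeny, left, right) {
  progeny <- as.matrix(progeny)
  for (m in c(left, right)) {
    if (!m %in% colnames(progeny)) stop("flanking marker not genotyped: ", m)
  }
  gl <- progeny[, left]
  gr <- progeny[, right]
  unscreen <- is.na(gl) | is.na(gr)
  rec <- !unscreen & gl != gr
  nonrec <- !unscreen & gl == gr
  structure(list(
    recombinants = rownames(progeny)[rec],
    classes = table(factor(gl[nonrec], levels = 0:2)),
    unscreenable = rownames(progeny)[unscreen],
    n_screened = sum(!unscreen),
    flanks = c(left, right)),
    class = "recombinant_set")
}

#' @export
print.recombinant_set <- function(x, ...) {
  cat("Recombinant screen between", x$flanks[1], "and", x$flanks[2], ":",
      length(x$recombinants), "recombinant(s) of", x$n_screened,
      "screened\n")
  invisible(x)
}

#' Haldane map function and its inverse
#'
#' `haldane_r(d)` converts a cM distance to a recombination fraction under
#' no interference; `haldane_cM(r)` inverts it.
#'
#' @param d map distance in cM.
#' @return Recombination fraction in [0, 0.5).
#' @export
haldane_r <- function(d) (1 - exp(-2 * d / 100)) / 2

#' @rdname haldane_r
#' @param r recombination fraction.
#' @export
haldane_cM <- function(r) -50 * log(1 - 2 * r)

#' Two-point recombination fraction from selfed (F2-type) progeny
#'
#' Maximum-likelihood estimate of the recombination fraction between two
#' codominant markers from the 3x3 genotype-class table of selfed progeny
#' of a double heterozygote in known coupling phase. The double
#' heterozygote class is ambiguous (0 or 2 recombinant gametes) and is
#' resolved by EM.
#'
#' @param counts 3x3 matrix of joint genotype counts; rows = marker A
#'   codes 0/1/2, columns = marker B codes 0/1/2, coupling phase (parental
#'   gametes 00 and 22).
#' @param tol EM convergence tolerance (default 1e-10).
#' @return List with `rf` (estimate, clamped to [0, 0.5]), `cM` (Haldane),
#'   `n` (total progeny), `iterations`.
#' @export
estimate_two_point_rf <- function(counts, tol = 1e-10) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(3, 3))) stop("counts must be a 3x3 table")
  n <- sum(counts)
  if (n <= 0) stop("empty count table")
  # recombinant gametes per class under coupling (AB/ab): double het
  # (1,1) is ambiguous and handled by EM
  R <- matrix(c(0, 1, 2,
                1, NA, 1,
                2, 1, 0), 3, 3, byrow = TRUE)
  r <- 0.25
  for (it in 1:1000) {
    # posterior expected recombinant gametes in the double-het class
    e11 <- 2 * r^2 / (r^2 + (1 - r)^2)
    num <- sum(counts * ifelse(is.na(R), 0, R)) + counts[2, 2] * e11
    r_new <- min(num / (2 * n), 0.5)
    if (abs(r_new - r) < tol) { r <- r_new; break }
    r <- r_new
  }
  clamped <- FALSE
  if (r >= 0.5) {
    r <- 0.5
    clamped <- TRUE
    warning("count table consistent only with free recombination; rf clamped to 0.5")
  }
  list(rf = r, cM = if (r < 0.5) haldane_cM(r) else Inf, n = n,
       iterations = it, clamped = clamped)
}

#' Delimit a QTL interval from recombinant NIL co-segregation
#'
#' Given homozygous recombinant NILs genotyped at the interval markers and
#' assigned a phenotype class, a marker co-segregates when every NIL's
#' genotype class at it (recipient- vs donor-homozygous) matches its
#' phenotype class. The QTL interval is delimited by the nearest
#' non-co-segregating marker on each side of the co-segregating run (or
#' the outermost genotyped marker when no recombinant separates that
#' side).
#'
#' @param genotypes NILs x markers matrix with codes 0 (recipient
#'   homozygote) and 2 (donor homozygote); markers in map order.
#' @param pheno_class character vector per NIL: `"recipient"` or
#'   `"donor"` (as from [assign_phenotype_class()]).
#' @param positions optional named cM positions of the markers (for the
#'   interval width).
#' @return An object of class `interval_call`: list with `left`, `right`
#'   (marker names), `width_cM` (NA without positions), `cosegregating`
#'   (marker names).
#' @export
delimit_interval <- function(genotypes, pheno_class, positions = NULL) {
  genotypes <- as.matrix(genotypes)
  markers <- colnames(genotypes)
  if (is.null(markers)) stop("genotype matrix must have marker names")
  if (length(pheno_class) != nrow(genotypes))
    stop("one phenotype class per NIL required")
  if (nrow(genotypes) > 0)
    pheno_class <- match.arg(pheno_class, c("recipient", "donor"),
                             several.ok = TRUE)
  geno_class <- matrix(NA_character_, nrow(genotypes), ncol(genotypes))
  geno_class[genotypes == 0] <- "recipient"
  geno_class[genotypes == 2] <- "donor"
  if (nrow(genotypes) == 0) {
    return(structure(list(left = markers[1],
                          right = markers[length(markers)],
                          width_cM = .interval_width(positions, markers[1],
                                                     markers[length(markers)]),
                          cosegregating = markers),
                     class = "interval_call"))
  }
  consistent <- vapply(seq_along(markers), function(j) {
    ok <- geno_class[, j] == pheno_class
    all(ok, na.rm = FALSE) && !anyNA(geno_class[, j])
  }, logical(1))
  if (!any(consistent)) {
    bad <- rownames(genotypes)
    stop("no marker interval explains all phenotype classes; conflicting lines: ",
         paste(bad, collapse = ", "))
  }
  runs <- rle(consistent)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1
  best <- which(runs$values)[which.max(runs$lengths[runs$values])]
  i0 <- run_start[best]
  i1 <- run_end[best]
  left <- if (i0 > 1) markers[i0 - 1] else markers[1]
  right <- if (i1 < length(markers)) markers[i1 + 1] else markers[length(markers)]
  structure(list(left = left, right = right,
                 width_cM = .interval_width(positions, left, right),
                 cosegregating = markers[i0:i1]),
            class = "interval_call")
}

.interval_width <- function(positions, left, right) {
  if (is.null(positions)) return(NA_real_)
  unname(positions[right] - positions[left])
}

#' @export
print.interval_call <- function(x, ...) {
  cat("QTL interval: (", x$left, ", ", x$right, ")",
      if (!is.na(x$width_cM)) sprintf(", %.2f cM", x$width_cM), "\n",
      sep = "")
  cat("  co-segregating marker(s):",
      paste(x$cosegregating, collapse = ", "), "\n")
  invisible(x)
}

#' Write interval results as JSON
#'
#' Serializes an [delimit_interval()] call or a
#' [detect_segregating_intervals()] table to a JSON file.
#'
#' @param x an `interval_call` or `segregating_intervals` object.
#' @param path output file path.
#' @export
write_interval_json <- function(x, path) {
  obj <- if (inherits(x, "interval_call")) {
    list(left = x$left, right = x$right, width_cM = x$width_cM,
         cosegregating = as.list(x$cosegregating))
  } else {
    lapply(seq_len(nrow(x)), function(i)
      list(chromosome = x$chromosome[i], start = x$start[i],
           end = x$end[i], width = x$width[i],
           genes = as.list(x$genes[[i]])))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Assign NILs to homozygous phenotype reference classes
#'
#' Each NIL's replicate phenotypes are compared to every homozygous
#' reference group by a two-sided t-test; the NIL is assigned to the
#' single class it does not differ from at `alpha`. A NIL differing from
#' all classes, or compatible with several, is `"unclassified"`.
#'
#' @param nil_values named list: per NIL, a numeric vector of replicate
#'   phenotypes.
#' @param reference named list: per class label, replicate phenotypes of
#'   the homozygous reference group (>= 2 classes).
#' @param alpha test level (default 0.05).
#' @return Named character vector of class labels (or "unclassified").
#' @export
assign_phenotype_class <- function(nil_values, reference, alpha = 0.05) {
  if (length(reference) < 2)
    stop("at least two reference classes required")
  out <- character(length(nil_values))
  names(out) <- names(nil_values)
  for (i in seq_along(nil_values)) {
    v <- nil_values[[i]]
    if (length(v) < 2) {
      warning("NIL ", names(nil_values)[i],
              " has < 2 replicates; unclassified")
      out[i] <- "unclassified"
      next
    }
    compat <- vapply(reference, function(ref)
      stats::t.test(v, ref)$p.value > alpha, logical(1))
    out[i] <- if (sum(compat) == 1) names(reference)[compat] else
      "unclassified"
  }
  out
}
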