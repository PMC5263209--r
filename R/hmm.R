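#' HMM parameters for founder-probability inference
#'
#' The founder-origin chain of a RIL is approximated per chromosome by a
#' three-state homozygous mosaic (recipient, donor p, donor q). The
#' stationary prior reflects the breeding design (one backcross to the
#' recipient followed by a pairwise intercross: 0.75 / 0.125 / 0.125); the
#' transition kernel over a map gap of d cM stays in the current state with
#' probability exp(-0.01 * map_expansion * d) and otherwise jumps to the
#' stationary prior, which preserves stationarity by construction.
#'
#' @param genotyping_error probability mass an observed call places on the
#'   "wrong" homozygote given the state (default 0.01).
#' @param recipient_prior stationary probability of the recipient state
#'   (default 0.75); the remainder is split equally over the two donors.
#' @param map_expansion multiplier converting map cM into mosaic transition
#'   intensity; selfing-derived RILs accumulate extra crossovers relative to
#'   a single meiosis, so the default is 2.
#' @param residual_het_rate emission mass on a heterozygous (1) call when
#'   the state expects a homozygote; default 1/32, the residual
#'   heterozygosity after five selfing generations.
#' @return An object of class `hmm_params`.
#' @export
hmm_params <- function(genotyping_error = 0.01, recipient_prior = 0.75,
                       map_expansion = 2, residual_het_rate = 1 / 32) {
  if (genotyping_error < 0 || genotyping_error > 1)
    stop("genotyping_error must be in [0,1]")
  if (genotyping_error + residual_het_rate >= 1)
    stop("genotyping_error + residual_het_rate must be < 1")
  if (recipient_prior <= 0 || recipient_prior >= 1)
    stop("recipient_prior must be in (0,1)")
  if (!is.finite(map_expansion) || map_expansion <= 0)
    stop("map_expansion must be positive and finite")
  structure(list(genotyping_error = genotyping_error,
                 recipient_prior = recipient_prior,
                 map_expansion = map_expansion,
                 residual_het_rate = residual_het_rate),
            class = "hmm_params")
}

# parse "AxB" subpopulation labels into donor pairs, validating against panel
.cross_donors <- function(cross_labels, panel, cross_donors = NULL) {
  labs <- unique(cross_labels)
  out <- vector("list", length(labs))
  names(out) <- labs
  for (lab in labs) {
    d <- if (!is.null(cross_donors)) cross_donors[[lab]] else
      strsplit(lab, "x", fixed = TRUE)[[1]]
    if (is.null(d) || length(d) != 2 || !all(d %in% panel$founders))
      stop("cross label '", lab,
           "' does not identify two panel founders; supply cross_donors")
    out[[lab]] <- d
  }
  out
}

# emission array for one cross on one chromosome:
# lines x loci x 3 states; virtual loci (allele row NA-masked) emit 1.
.emission_array <- function(obs, state_alleles, e, h) {
  n <- nrow(obs); L <- ncol(obs)
  E <- array(1, c(n, L, 3))
  for (s in 1:3) {
    exp_g <- 2L * state_alleles[s, ]            # 0 or 2, NA if uninformative
    for (l in seq_len(L)) {
      if (is.na(exp_g[l])) next                  # uninformative locus/state
      g <- obs[, l]
      em <- rep(e, n)                            # wrong homozygote
      em[is.na(g)] <- 1                          # missing call
      em[!is.na(g) & g == 1L] <- h               # residual heterozygote
      em[!is.na(g) & g == exp_g[l]] <- 1 - e - h # expected homozygote
      E[, l, s] <- em
    }
  }
  E
}

# vectorized forward-backward for the 3-state jump-to-stationary chain.
# E: lines x loci x 3 emissions; gaps: length L-1 cM distances.
# returns lines x loci x 3 posterior array.
.fb_smooth <- function(E, gaps, prior, lambda) {
  n <- dim(E)[1]; L <- dim(E)[2]
  a <- exp(-lambda * gaps)
  Fm <- array(0, dim(E))
  x <- sweep(E[, 1, , drop = FALSE], 3, prior, "*")[, 1, , drop = TRUE]
  if (n == 1) x <- matrix(x, 1)
  x <- x / pmax(rowSums(x), .Machine$double.xmin)
  Fm[, 1, ] <- x
  if (L > 1) for (l in 2:L) {
    pred <- a[l - 1] * x + (1 - a[l - 1]) * outer(rowSums(x), prior)
    x <- pred * E[, l, ]
    x <- x / pmax(rowSums(x), .Machine$double.xmin)
    Fm[, l, ] <- x
  }
  Bm <- array(0, dim(E))
  b <- matrix(1, n, 3)
  Bm[, L, ] <- b
  if (L > 1) for (l in (L - 1):1) {
    V <- E[, l + 1, ] * b
    b <- a[l] * V + (1 - a[l]) * outer(as.vector(V %*% prior), rep(1, 3))
    b <- b / pmax(rowSums(b), .Machine$double.xmin)
    Bm[, l, ] <- b
  }
  post <- Fm * Bm
  den <- apply(post, c(1, 2), sum)
  den[den <= 0] <- 1
  sweep(post, c(1, 2), den, "/")
}

#' Compute founder-origin probabilities by HMM smoothing
#'
#' For every line, the posterior probability that its genome at each locus
#' descends from each of the panel founders, given its SNP genotypes. Lines
#' are processed per cross with a three-state chain (recipient and the
#' cross's two donors); posteriors are embedded into the full founder
#' vector with exact zeros for founders outside the line's pedigree.
#'
#' @param genotypes a [genotype_table()]; cross labels must identify the
#'   two donors (either as "donorAxdonorB" labels or via `cross_donors`).
#' @param panel a [founder_panel()].
#' @param params an [hmm_params()].
#' @param cross_donors optional named list mapping cross label to the two
#'   donor names.
#' @param positions optional data.frame (chromosome, position) of extra
#'   scan positions to smooth over as silent loci (used by
#'   [interpolate_to_grid()]).
#' @return An object of class `founder_probs`: list with `prob`
#'   (lines x loci x founders array), `loci` (data.frame locus, chromosome,
#'   position, is_marker), `line_id`, `cross_id`, `founders`.
#' @export
compute_founder_probs <- function(genotypes, panel, params = hmm_params(),
                                  cross_donors = NULL, positions = NULL) {
  map <- panel$map
  founders <- panel$founders
  nf <- length(founders)
  ridx <- match(panel$recipient, founders)
  donors_by_cross <- .cross_donors(genotypes$cross_id, panel, cross_donors)
  lambda <- 0.01 * params$map_expansion
  prior <- c(params$recipient_prior, rep((1 - params$recipient_prior) / 2, 2))

  # locus frame: markers plus any virtual positions, ordered within chromosome
  loci <- data.frame(locus = map$marker, chromosome = map$chromosome,
                     position = map$position, is_marker = TRUE,
                     stringsAsFactors = FALSE)
  if (!is.null(positions)) {
    keep <- !mapply(function(ch, p)
      any(map$chromosome == ch & abs(map$position - p) < 1e-9),
      positions$chromosome, positions$position)
    if (any(keep)) {
      virt <- data.frame(
        locus = sprintf("grid_%s_%.4g", positions$chromosome[keep],
                        positions$position[keep]),
        chromosome = as.character(positions$chromosome[keep]),
        position = as.numeric(positions$position[keep]),
        is_marker = FALSE, stringsAsFactors = FALSE)
      loci <- rbind(loci, virt)
    }
    loci <- loci[order(match(loci$chromosome, map_chromosomes(map)),
                       loci$position), ]
    rownames(loci) <- NULL
  }

  n <- length(genotypes$line_id)
  post <- array(0, c(n, nrow(loci), nf),
                dimnames = list(genotypes$line_id, loci$locus, founders))
  all_missing <- rowSums(!is.na(genotypes$genotypes)) == 0
  if (any(all_missing))
    warning("line(s) with no genotype calls get the prior everywhere: ",
            paste(genotypes$line_id[all_missing], collapse = ", "))

  for (lab in names(donors_by_cross)) {
    rows <- which(genotypes$cross_id == lab)
    didx <- match(donors_by_cross[[lab]], founders)
    sidx <- c(ridx, didx)                      # state -> founder index
    for (ch in map_chromosomes(map)) {
      lsel <- which(loci$chromosome == ch)
      if (!length(lsel)) next
      pos <- loci$position[lsel]
      # observation matrix aligned to the locus frame (NA at virtual loci)
      obs <- matrix(NA_integer_, length(rows), length(lsel))
      msel <- loci$is_marker[lsel]
      obs[, msel] <- genotypes$genotypes[rows,
        loci$locus[lsel][msel], drop = FALSE]
      state_alleles <- matrix(NA_integer_, 3, length(lsel))
      state_alleles[, msel] <- rbind(
        panel$alleles[ridx, loci$locus[lsel][msel]],
        panel$alleles[didx[1], loci$locus[lsel][msel]],
        panel$alleles[didx[2], loci$locus[lsel][msel]])
      E <- .emission_array(obs, state_alleles,
                           params$genotyping_error, params$residual_het_rate)
      sm <- .fb_smooth(E, diff(pos), prior, lambda)
      for (s in 1:3) post[rows, lsel, sidx[s]] <- sm[, , s]
    }
  }
  structure(list(prob = post, loci = loci, line_id = genotypes$line_id,
                 cross_id = genotypes$cross_id, founders = founders,
                 recipient = panel$recipient, params = params,
                 genotypes = genotypes, panel = panel,
                 cross_donors = donors_by_cross),
            class = "founder_probs")
}

#' @export
print.founder_probs <- function(x, ...) {
  cat("Founder probabilities:", length(x$line_id), "lines x",
      nrow(x$loci), "loci x", length(x$founders), "founders\n")
  invisible(x)
}

#' Re-smooth founder probabilities onto a cM grid
#'
#' Inserts silent (uninformative) loci at multiples of `step` per
#' chromosome and reruns forward-backward smoothing, so scan positions
#' between markers carry properly interpolated probability vectors.
#'
#' @param fp a `founder_probs` object from [compute_founder_probs()].
#' @param step grid step in cM (> 0).
#' @return A `founder_probs` object whose loci include the grid positions.
#' @export
interpolate_to_grid <- function(fp, step) {
  if (step <= 0) stop("step must be > 0")
  map <- fp$panel$map
  lens <- map_chrom_lengths(map)
  grid <- do.call(rbind, lapply(names(lens), function(ch) {
    data.frame(chromosome = ch,
               position = seq(0, lens[[ch]], by = step))
  }))
  compute_founder_probs(fp$genotypes, fp$panel, fp$params,
                        cross_donors = fp$cross_donors, positions = grid)
}

#' Write founder probabilities as long-format TSV
#' @param fp a `founder_probs` object.
#' @param path output file path.
#' @export
write_founder_probs <- function(fp, path) {
  long <- data.frame(
    line_id = rep(fp$line_id, times = nrow(fp$loci) * length(fp$founders)),
    locus = rep(rep(fp$loci$locus, each = length(fp$line_id)),
                times = length(fp$founders)),
    founder = rep(fp$founders,
                  each = length(fp$line_id) * nrow(fp$loci)),
    probability = as.vector(fp$prob), stringsAsFactors = FALSE)
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
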