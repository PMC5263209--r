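#' Define a multiparent RIL crossing design
#'
#' The design emulated is the backcross-intercross scheme used in barley
#' multiparent pre-breeding populations: each donor is crossed to the
#' recipient, the F1 is backcrossed to the recipient once, the resulting
#' BC1F1 plants are intercrossed pairwise (every donor pair giving one
#' subpopulation), and each intercross progeny is taken through single seed
#' descent (SSD) selfing.
#'
#' @param donor_pairs list of length-2 character vectors naming the two
#'   donors of each subpopulation; `NULL` (default at simulation time) means
#'   all unordered donor pairs.
#' @param lines_per_subpop integer vector (recycled) of RIL counts per
#'   subpopulation.
#' @param ssd_generations number of selfing generations after the intercross
#'   (default 5, giving F6).
#' @param backcrosses_to_recipient number of backcrosses of the F1 to the
#'   recipient before intercrossing (default 1).
#' @return An object of class `cross_design`.
#' @export
cross_design <- function(donor_pairs, lines_per_subpop,
                         ssd_generations = 5L,
                         backcrosses_to_recipient = 1L) {
  for (p in donor_pairs) {
    if (length(p) != 2) stop("each donor pair must name exactly two donors")
    if (p[1] == p[2])
      stop("donor pair with identical donors is not a valid intercross: ",
           p[1])
  }
  lines_per_subpop <- rep_len(as.integer(lines_per_subpop),
                              length(donor_pairs))
  structure(list(donor_pairs = donor_pairs,
                 lines_per_subpop = lines_per_subpop,
                 ssd_generations = as.integer(ssd_generations),
                 backcrosses_to_recipient = as.integer(backcrosses_to_recipient)),
            class = "cross_design")
}

#' All-pairs design over a panel's donors
#'
#' @param panel a [founder_panel()].
#' @param lines_per_subpop lines per subpopulation (recycled over pairs).
#' @param ... passed to [cross_design()].
#' @return A `cross_design` with one subpopulation per unordered donor pair.
#' @export
all_pairs_design <- function(panel, lines_per_subpop = 153L, ...) {
  donors <- setdiff(panel$founders, panel$recipient)
  pairs <- utils::combn(donors, 2, simplify = FALSE)
  cross_design(pairs, lines_per_subpop, ...)
}

subpop_label <- function(pair) paste(pair, collapse = "x")

#' Simulate a multiparent RIL population
#'
#' Runs the full breeding design per line: F1 = donor x recipient, backcross
#' to the recipient, intercross of the two designated BC1F1 plants, then SSD
#' selfing. Genotypes are read off the founder mosaics via the panel
#' alleles, optionally perturbed by symmetric per-call genotyping error and
#' missing-completely-at-random dropout.
#'
#' @param design a [cross_design()].
#' @param panel a [founder_panel()].
#' @param genotyping_error per-call probability that a genotype is replaced
#'   by one of the other two codes (default 0).
#' @param missing_rate per-call probability of a missing genotype (default 0).
#' @return An object of class `ril_population`: list with elements
#'   `mosaics` (list of line mosaics), `genotypes` (a [genotype_table()]),
#'   `truth` (lines x founders matrix of genome proportions), `panel`,
#'   `design`.
#' @export
simulate_population <- function(design, panel, genotyping_error = 0,
                                missing_rate = 0) {
  map <- panel$map
  donors <- setdiff(panel$founders, panel$recipient)
  for (p in unlist(design$donor_pairs)) {
    if (!p %in% donors)
      stop("design donor not a (non-recipient) panel founder: ", p)
  }
  nf <- length(panel$founders)
  ridx <- match(panel$recipient, panel$founders)
  recipient_mosaic <- mosaic_pure(ridx, map, panel$founders)

  n_total <- sum(design$lines_per_subpop)
  mosaics <- vector("list", n_total)
  line_id <- character(n_total)
  cross_id <- character(n_total)
  truth <- matrix(0, n_total, nf, dimnames = list(NULL, panel$founders))
  k <- 0L
  for (s in seq_along(design$donor_pairs)) {
    pair <- design$donor_pairs[[s]]
    lab <- subpop_label(pair)
    pidx <- match(pair, panel$founders)
    for (i in seq_len(design$lines_per_subpop[s])) {
      bc <- lapply(pidx, function(d) {
        f1 <- .zygote(simulate_gamete(mosaic_pure(d, map, panel$founders)),
                      simulate_gamete(recipient_mosaic), panel$founders)
        gen <- f1
        for (b in seq_len(design$backcrosses_to_recipient)) {
          gen <- .zygote(simulate_gamete(gen),
                         simulate_gamete(recipient_mosaic), panel$founders)
        }
        gen
      })
      ind <- .zygote(simulate_gamete(bc[[1]]), simulate_gamete(bc[[2]]),
                     panel$founders)
      for (g in seq_len(design$ssd_generations)) {
        ind <- .zygote(simulate_gamete(ind), simulate_gamete(ind),
                       panel$founders)
      }
      k <- k + 1L
      mosaics[[k]] <- ind
      line_id[k] <- sprintf("%s_%03d", lab, i)
      cross_id[k] <- lab
      truth[k, ] <- founder_proportions(ind, nf)
    }
  }
  names(mosaics) <- line_id
  rownames(truth) <- line_id

  geno <- t(vapply(mosaics, .mosaic_genotypes, integer(nrow(map)),
                   panel = panel))
  if (genotyping_error > 0) {
    err <- matrix(stats::runif(length(geno)) < genotyping_error,
                  nrow(geno), ncol(geno))
    if (any(err)) {
      shift <- sample.int(2L, sum(err), replace = TRUE)
      geno[err] <- (geno[err] + shift) %% 3L
    }
  }
  if (missing_rate > 0) {
    geno[matrix(stats::runif(length(geno)) < missing_rate,
                nrow(geno), ncol(geno))] <- NA_integer_
  }
  gt <- genotype_table(line_id, cross_id, geno, map)
  structure(list(mosaics = mosaics, genotypes = gt, truth = truth,
                 panel = panel, design = design),
            class = "ril_population")
}

#' @export
print.ril_population <- function(x, ...) {
  cat("Simulated RIL population:", length(x$mosaics), "lines in",
      length(x$design$donor_pairs), "subpopulation(s)\n")
  cat(sprintf("  mean recipient (%s) genome proportion: %.3f\n",
              x$panel$recipient, mean(x$truth[, x$panel$recipient])))
  invisible(x)
}

#' Specify QTLs and noise for phenotype simulation
#'
#' @param chromosome,position location of each QTL on the map.
#' @param effects matrix (QTLs x donor founders) of additive effects, in
#'   trait units per founder-genome dose, relative to the recipient; column
#'   names are donor founder names.
#' @param cross_means named numeric vector of per-subpopulation intercepts
#'   (trait units); unnamed scalar is recycled.
#' @param residual_sd residual standard deviation per replicate observation;
#'   ignored when `heritability_target` is set.
#' @param replicates number of replicate observations per line (default 4).
#' @param heritability_target optional broad-sense heritability on the
#'   single-plot basis; when set, the residual SD is solved from the
#'   realized genetic variance so that Var(G)/(Var(G)+Var(E)) equals it.
#' @return An object of class `qtl_spec`.
#' @export
qtl_spec <- function(chromosome, position, effects, cross_means = 0,
                     residual_sd = 1, replicates = 4L,
                     heritability_target = NULL) {
  effects <- as.matrix(effects)
  if (length(chromosome) != nrow(effects) ||
      length(position) != nrow(effects))
    stop("one chromosome/position per QTL (row of effects) required")
  if (!is.null(heritability_target) &&
      (heritability_target <= 0 || heritability_target > 1))
    stop("heritability_target must be in (0, 1]")
  structure(list(chromosome = as.character(chromosome),
                 position = as.numeric(position), effects = effects,
                 cross_means = cross_means, residual_sd = residual_sd,
                 replicates = as.integer(replicates),
                 heritability_target = heritability_target),
            class = "qtl_spec")
}

#' Simulate replicated phenotypes from founder mosaics
#'
#' Each line's genetic value is the subpopulation mean plus the sum over
#' QTLs of founder-dose-weighted additive effects (dose 0, 0.5 or 1 of each
#' donor genome at the QTL position); replicate observations add Gaussian
#' residual noise. With a heritability target set, the residual SD is
#' calibrated so the plot-basis ratio Var(G)/(Var(G)+Var(E)) over the
#' simulated lines equals the target.
#'
#' @param pop a `ril_population` from [simulate_population()].
#' @param qtl a [qtl_spec()].
#' @return A [phenotype_table()]; the per-line genetic values are attached
#'   as attribute `genetic_values`.
#' @export
simulate_phenotypes <- function(pop, qtl) {
  panel <- pop$panel
  nf <- length(panel$founders)
  n <- length(pop$mosaics)
  cross <- pop$genotypes$cross_id
  mu_line <- if (is.null(names(qtl$cross_means))) {
    rep(qtl$cross_means[1], n)
  } else {
    if (!all(cross %in% names(qtl$cross_means)))
      stop("cross_means must name every subpopulation")
    unname(qtl$cross_means[cross])
  }
  donors <- colnames(qtl$effects)
  if (is.null(donors)) stop("effects matrix must have donor founder names")
  didx <- match(donors, panel$founders)
  bad <- setdiff(qtl$chromosome, map_chromosomes(panel$map))
  if (length(bad))
    stop("QTL chromosome(s) not on the map: ", paste(bad, collapse = ", "))
  g <- mu_line
  for (q in seq_along(qtl$position)) {
    for (i in seq_len(n)) {
      d <- founder_dose(pop$mosaics[[i]], qtl$chromosome[q],
                        qtl$position[q], nf)
      g[i] <- g[i] + sum(d[didx] * qtl$effects[q, ])
    }
  }
  var_g <- stats::var(g)
  if (!is.null(qtl$heritability_target)) {
    h2 <- qtl$heritability_target
    if (var_g <= 0 && h2 > 0 && h2 < 1)
      stop("heritability target unreachable: simulated genetic variance is zero")
    sd_e <- if (h2 == 1) 0 else sqrt(var_g * (1 - h2) / h2)
  } else {
    sd_e <- qtl$residual_sd
  }
  r <- qtl$replicates
  vals <- rep(g, each = r) +
    if (sd_e > 0) stats::rnorm(n * r, 0, sd_e) else 0
  pt <- phenotype_table(rep(pop$genotypes$line_id, each = r),
                        rep(cross, each = r),
                        rep(seq_len(r), times = n), vals)
  attr(pt, "genetic_values") <- stats::setNames(g, pop$genotypes$line_id)
  attr(pt, "residual_sd") <- sd_e
  pt
}

#' True founder doses of simulated lines at map loci
#'
#' Reads the simulation truth off the founder mosaics: for every line and
#' map position, the proportion (0, 0.5, 1) of the two homologs inherited
#' from each founder.
#'
#' @param pop a `ril_population`.
#' @param loci optional data.frame (chromosome, position); defaults to the
#'   map markers.
#' @return lines x loci x founders array of doses.
#' @export
truth_doses <- function(pop, loci = NULL) {
  map <- pop$panel$map
  if (is.null(loci))
    loci <- data.frame(chromosome = map$chromosome, position = map$position,
                       locus = map$marker, stringsAsFactors = FALSE)
  if (is.null(loci$locus))
    loci$locus <- sprintf("%s_%.4g", loci$chromosome, loci$position)
  nf <- length(pop$panel$founders)
  n <- length(pop$mosaics)
  out <- array(0, c(n, nrow(loci), nf),
               dimnames = list(names(pop$mosaics), loci$locus,
                               pop$panel$founders))
  for (i in seq_len(n)) {
    mos <- pop$mosaics[[i]]
    for (ch in unique(loci$chromosome)) {
      sel <- which(loci$chromosome == ch)
      f1 <- .founder_at(mos[[ch]]$h1, loci$position[sel])
      f2 <- .founder_at(mos[[ch]]$h2, loci$position[sel])
      for (j in seq_along(sel)) {
        out[i, sel[j], f1[j]] <- out[i, sel[j], f1[j]] + 0.5
        out[i, sel[j], f2[j]] <- out[i, sel[j], f2[j]] + 0.5
      }
    }
  }
  out
}

#' Simulate selfed progeny of a single line
#'
#' Each offspring is the union of two independent gametes of the parent —
#' the screening generation of a heterogeneous inbred family (HIF).
#'
#' @param parent a line mosaic (see [founder_mosaic]).
#' @param n number of progeny (>= 1).
#' @param panel a [founder_panel()] used to read off genotypes.
#' @return List with `mosaics` (length n) and `genotypes`
#'   (n x markers integer matrix).
#' @export
simulate_self_progeny <- function(parent, n, panel) {
  if (n < 1) stop("n must be >= 1")
  mos <- vector("list", n)
  for (i in seq_len(n)) {
    mos[[i]] <- .zygote(simulate_gamete(parent), simulate_gamete(parent),
                        panel$founders)
  }
  geno <- t(vapply(mos, .mosaic_genotypes, integer(nrow(panel$map)),
                   panel = panel))
  rownames(geno) <- sprintf("prog_%04d", seq_len(n))
  list(mosaics = mos, genotypes = geno)
}

#' Default five-founder barley-like panel
#'
#' Convenience constructor for a panel in the image of the study system:
#' recipient `Morex` plus four wild donors (`HID4`, `HID64`, `HID369`,
#' `HID382`). Founder alleles are drawn so the recipient carries the
#' reference allele everywhere and each donor carries the alternate allele
#' with probability `donor_alt_freq` independently per marker.
#'
#' @param map a [genetic_map()].
#' @param donor_alt_freq probability a donor is polymorphic vs the
#'   recipient at a marker (default 0.5, the ascertainment of a biallelic
#'   SNP chip).
#' @return A [founder_panel()].
#' @export
barley_panel <- function(map, donor_alt_freq = 0.5) {
  founders <- c("Morex", "HID4", "HID64", "HID369", "HID382")
  a <- matrix(0L, length(founders), nrow(map),
              dimnames = list(founders, map$marker))
  for (f in founders[-1]) {
    a[f, ] <- as.integer(stats::runif(nrow(map)) < donor_alt_freq)
  }
  founder_panel(founders, a, map, recipient = "Morex")
}

#' Evenly spaced synthetic genetic map
#'
#' @param n_chrom number of chromosomes (default 7, labelled 1H..nH).
#' @param length_cM chromosome length in cM (default 150).
#' @param spacing_cM marker spacing in cM (default 5).
#' @return A [genetic_map()] with a `chrom_lengths` attribute.
#' @export
uniform_map <- function(n_chrom = 7, length_cM = 150, spacing_cM = 5) {
  chroms <- paste0(seq_len(n_chrom), "H")
  pos <- seq(0, length_cM, by = spacing_cM)
  gm <- genetic_map(
    marker = as.vector(t(outer(chroms, seq_along(pos),
                               function(c, i) sprintf("%s_m%02d", c, i)))),
    chromosome = rep(chroms, each = length(pos)),
    position = rep(pos, n_chrom))
  attr(gm, "chrom_lengths") <- stats::setNames(rep(length_cM, n_chrom), chroms)
  gm
}
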