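#' @name founder_mosaic
#' @title Founder mosaic representation
#'
#' @description
#' A simulated line's genome is represented as a founder mosaic: per
#' chromosome, two homologs, each a piecewise-constant sequence of founder
#' origins. A homolog is a two-column matrix `(end, founder)` whose segment
#' ends are strictly increasing and terminate at the chromosome length (cM);
#' `founder` is an integer index into the founder panel. A line mosaic is a
#' list of `list(h1, h2)` per chromosome with attributes `chrom_lengths`
#' and `founders`.
#'
#' This is the simulation truth underlying founder-probability inference:
#' genotypes can be read off a mosaic deterministically given founder
#' alleles.
NULL

# single-founder homolog for a chromosome of length L
.homolog_pure <- function(founder_idx, L) {
  matrix(c(L, founder_idx), nrow = 1,
         dimnames = list(NULL, c("end", "founder")))
}

# collapse adjacent segments sharing a founder
.homolog_simplify <- function(h) {
  if (nrow(h) <= 1) return(h)
  keep <- c(h[-nrow(h), 2] != h[-1, 2], TRUE)
  h[keep, , drop = FALSE]
}

# piece of homolog h covering (a, b], re-expressed with ends relative to
# the full chromosome (ends unchanged, just clipped)
.homolog_clip <- function(h, a, b) {
  ends <- h[, 1]
  i0 <- findInterval(a, ends, left.open = TRUE) + 1L
  i1 <- findInterval(b, ends, left.open = TRUE) + 1L
  i1 <- min(i1, nrow(h))
  seg <- h[i0:i1, , drop = FALSE]
  seg[nrow(seg), 1] <- b
  seg
}

#' Whole-genome mosaic of a pure (fully inbred) founder
#'
#' @param founder_idx integer index of the founder in the panel.
#' @param map a [genetic_map()].
#' @param founders character vector of founder names (stored as attribute).
#' @return A line mosaic (see [founder_mosaic]).
#' @export
mosaic_pure <- function(founder_idx, map, founders = NULL) {
  lens <- map_chrom_lengths(map)
  mos <- lapply(lens, function(L)
    list(h1 = .homolog_pure(founder_idx, L),
         h2 = .homolog_pure(founder_idx, L)))
  names(mos) <- names(lens)
  attr(mos, "chrom_lengths") <- lens
  attr(mos, "founders") <- founders
  class(mos) <- "founder_mosaic"
  mos
}

# gamete for ONE chromosome: list(h1,h2) -> single homolog matrix.
# Crossover count ~ Poisson(L/100), positions uniform (Haldane, no
# interference); the gamete alternates between parental homologs at each
# crossover, starting from a homolog chosen with probability 1/2.
.gamete_chrom <- function(pair, L) {
  start <- sample.int(2L, 1L)
  if (L <= 0) return(pair[[start]])
  nxo <- stats::rpois(1L, L / 100)
  if (nxo == 0L) return(pair[[start]])
  pos <- sort(stats::runif(nxo, 0, L))
  pos <- pos[pos > 0 & pos < L]
  if (!length(pos)) return(pair[[start]])
  bounds <- c(0, pos, L)
  active <- rep(c(start, 3L - start), length.out = length(bounds) - 1L)
  pieces <- vector("list", length(active))
  for (j in seq_along(active)) {
    pieces[[j]] <- .homolog_clip(pair[[active[j]]], bounds[j], bounds[j + 1])
  }
  .homolog_simplify(do.call(rbind, pieces))
}

#' Simulate a gamete from a parent mosaic
#'
#' Meiosis under the Haldane model: per chromosome the crossover count is
#' Poisson(length/100) with uniform positions and no interference; the
#' returned single-homolog mosaic alternates between the two parental
#' homologs at crossovers. A zero-length chromosome never recombines: one
#' homolog is copied with probability 1/2.
#'
#' @param parent a line mosaic (see [founder_mosaic]).
#' @return A list of single-homolog matrices, one per chromosome.
#' @export
simulate_gamete <- function(parent) {
  lens <- attr(parent, "chrom_lengths")
  out <- vector("list", length(parent))
  names(out) <- names(parent)
  for (i in seq_along(parent)) {
    out[[i]] <- .gamete_chrom(parent[[i]], lens[[i]])
  }
  attr(out, "chrom_lengths") <- lens
  out
}

# zygote from two gametes
.zygote <- function(g1, g2, founders = NULL) {
  mos <- mapply(function(a, b) list(h1 = a, h2 = b),
                g1, g2, SIMPLIFY = FALSE)
  attr(mos, "chrom_lengths") <- attr(g1, "chrom_lengths")
  attr(mos, "founders") <- founders
  class(mos) <- "founder_mosaic"
  mos
}

# founder index at positions pos (vector) on one homolog
.founder_at <- function(h, pos) {
  idx <- findInterval(pos, h[, 1], left.open = TRUE) + 1L
  idx[idx > nrow(h)] <- nrow(h)
  h[idx, 2]
}

#' Founder-dose vector of a line at a map position
#'
#' @param mosaic a line mosaic.
#' @param chromosome chromosome label.
#' @param position cM position.
#' @param n_founders number of founders in the panel.
#' @return Numeric vector of length `n_founders`; each entry is the
#'   proportion (0, 0.5 or 1) of the two homologs carrying that founder.
#' @export
founder_dose <- function(mosaic, chromosome, position, n_founders) {
  pair <- mosaic[[chromosome]]
  f1 <- .founder_at(pair$h1, position)
  f2 <- .founder_at(pair$h2, position)
  d <- numeric(n_founders)
  d[f1] <- d[f1] + 0.5
  d[f2] <- d[f2] + 0.5
  d
}

#' Genome-wide founder proportions of a line
#'
#' @param mosaic a line mosaic.
#' @param n_founders number of founders.
#' @return Numeric vector of length `n_founders` summing to 1: the fraction
#'   of total (diploid) genome length inherited from each founder.
#' @export
founder_proportions <- function(mosaic, n_founders) {
  lens <- attr(mosaic, "chrom_lengths")
  tot <- 2 * sum(lens)
  acc <- numeric(n_founders)
  for (chr in seq_along(mosaic)) {
    for (h in mosaic[[chr]]) {
      ends <- h[, 1]
      w <- diff(c(0, ends))
      for (j in seq_len(nrow(h))) acc[h[j, 2]] <- acc[h[j, 2]] + w[j]
    }
  }
  if (tot == 0) return(rep(NA_real_, n_founders))
  acc / tot
}

# genotype (alt-allele dosage) of a line at all map markers, given panel
.mosaic_genotypes <- function(mosaic, panel) {
  map <- panel$map
  nf <- length(panel$founders)
  g <- integer(nrow(map))
  for (ch in map_chromosomes(map)) {
    sel <- which(map$chromosome == ch)
    pos <- map$position[sel]
    pair <- mosaic[[ch]]
    f1 <- .founder_at(pair$h1, pos)
    f2 <- .founder_at(pair$h2, pos)
    a1 <- panel$alleles[cbind(f1, sel)]
    a2 <- panel$alleles[cbind(f2, sel)]
    g[sel] <- a1 + a2
  }
  names(g) <- map$marker
  g
}
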