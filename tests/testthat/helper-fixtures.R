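# shared fixtures, built in code at test time

# reference wild-founder additive effects (mm) used across scan tests
al71_effects <- function() {
  matrix(c(-3.5, -19.0, -1.0, -24.7), 1,
         dimnames = list(NULL, c("HID4", "HID64", "HID369", "HID382")))
}

# small simulated population: n_chrom chromosomes, 5 founders, all pairs
small_pop <- function(seed, n_chrom = 2, length_cM = 100, spacing_cM = 5,
                      lines_per_subpop = 25, genotyping_error = 0,
                      missing_rate = 0) {
  set.seed(seed)
  map <- uniform_map(n_chrom, length_cM, spacing_cM)
  panel <- barley_panel(map)
  pop <- simulate_population(all_pairs_design(panel, lines_per_subpop),
                             panel, genotyping_error = genotyping_error,
                             missing_rate = missing_rate)
  list(map = map, panel = panel, pop = pop)
}

# phenotypes with one QTL at (chrom, pos) and the reference effect sizes
qtl_phenos <- function(pop, chrom, pos, h2 = 0.75, replicates = 4,
                       effects = al71_effects()) {
  simulate_phenotypes(pop, qtl_spec(chrom, pos, effects,
                                    cross_means = 150,
                                    replicates = replicates,
                                    heritability_target = h2))
}

# a parent mosaic heterozygous donor/recipient across one chromosome,
# plus a two-marker panel with flanks `gap_cM` apart
het_parent_fixture <- function(gap_cM, donor = "HID64") {
  map <- genetic_map(c("fL", "fR"), c("7H", "7H"), c(0, gap_cM))
  attr(map, "chrom_lengths") <- c("7H" = gap_cM)
  founders <- c("Morex", "HID4", "HID64", "HID369", "HID382")
  alleles <- matrix(0L, 5, 2, dimnames = list(founders, map$marker))
  alleles[donor, ] <- 1L
  panel <- founder_panel(founders, alleles, map, recipient = "Morex")
  didx <- match(donor, founders)
  h_donor <- matrix(c(gap_cM, didx), 1,
                    dimnames = list(NULL, c("end", "founder")))
  h_rec <- matrix(c(gap_cM, 1), 1,
                  dimnames = list(NULL, c("end", "founder")))
  parent <- structure(list(`7H` = list(h1 = h_donor, h2 = h_rec)),
                      chrom_lengths = c(`7H` = gap_cM),
                      founders = founders, class = "founder_mosaic")
  list(map = map, panel = panel, parent = parent)
}

# brute-force posterior for the 3-state chain by path enumeration;
# transition: stay with exp(-lambda d), otherwise jump to the prior
enumerate_posterior <- function(E, gaps, prior, lambda) {
  L <- nrow(E)
  a <- exp(-lambda * gaps)
  Tm <- lapply(a, function(ai) ai * diag(3) + (1 - ai) *
                 matrix(prior, 3, 3, byrow = TRUE))
  paths <- as.matrix(expand.grid(rep(list(1:3), L)))
  w <- apply(paths, 1, function(s) {
    p <- prior[s[1]] * E[1, s[1]]
    if (L > 1) for (l in 2:L) p <- p * Tm[[l - 1]][s[l - 1], s[l]] * E[l, s[l]]
    p
  })
  post <- matrix(0, L, 3)
  for (l in 1:L) for (st in 1:3)
    post[l, st] <- sum(w[paths[, l] == st])
  post / rowSums(post)
}

# emission row for one observed call given the three states' expected
# founder alleles (independent restatement of the emission rule)
emission_row <- function(obs, state_alleles, e, h) {
  vapply(state_alleles, function(a) {
    if (is.na(a) || is.na(obs)) return(1)
    expg <- 2 * a
    if (obs == expg) 1 - e - h else if (obs == 1) h else e
  }, numeric(1))
}
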