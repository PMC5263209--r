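# shared fixture: 2 chromosomes, one strong QTL at 2H 30 cM
fx <- small_pop(seed = 41, n_chrom = 2, length_cM = 60, spacing_cM = 5,
                lines_per_subpop = 25)
ph <- qtl_phenos(fx$pop, "2H", 30)
fp <- compute_founder_probs(fx$pop$genotypes, fx$panel, hmm_params())

test_that("REML matches closed-form ANOVA on a balanced one-way layout", {
  set.seed(42)
  g <- 12; r <- 6
  u <- rnorm(g, 0, 3)
  y <- 50 + rep(u, each = r) + rnorm(g * r, 0, 1.5)
  grp <- rep(seq_len(g), each = r)
  Z <- outer(grp, seq_len(g), "==") * 1
  fit <- fit_founder_mm(y, matrix(1, g * r, 1), list(Z),
                        cross = rep("k", g * r), reltol = 1e-12)
  a <- stats::anova(stats::lm(y ~ factor(grp)))
  ms_b <- a$`Mean Sq`[1]; ms_w <- a$`Mean Sq`[2]
  s2u_anova <- (ms_b - ms_w) / r
  expect_lt(abs(fit$s2_terms - s2u_anova) / s2u_anova, 1e-6)
  expect_lt(abs(fit$s2_resid - ms_w) / ms_w, 1e-6)
})

test_that("an all-recipient locus carries no evidence", {
  # far from the simulated QTL on the other chromosome, construct a locus
  # where all probability mass sits on the recipient
  fp0 <- fp
  fp0$prob[, 1, ] <- 0
  fp0$prob[, 1, "Morex"] <- 1
  res <- fit_locus_model(fp0, ph, 1)
  expect_identical(res$p, 1)
  expect_identical(res$minus_log10_p, 0)
})

test_that("locus LRT holds its size under the null", {
  # pure-noise phenotypes at a single locus: the mixture-LRT p-value is
  # uniform-with-mass-at-one; empirical P(p <= 0.05) <= 0.06
  set.seed(43)
  n <- 120
  founder <- sample(1:3, n, replace = TRUE, prob = c(0.75, 0.125, 0.125))
  Z <- cbind(founder == 2, founder == 3) * 1
  X <- matrix(1, n, 1)
  cross <- rep("k", n)
  n_sim <- 1000
  hits <- 0
  for (s in seq_len(n_sim)) {
    y <- rnorm(n)
    f0 <- fit_founder_mm(y, X, list(), cross)
    f1 <- fit_founder_mm(y, X, list(Z), cross)
    p <- mixture_lrt_p(f1$loglik, f0$loglik)
    hits <- hits + (p <= 0.05)
  }
  expect_lte(hits / n_sim, 0.06)
})

test_that("profiles are invariant to per-cross phenotype shifts", {
  shift <- stats::setNames(seq_along(unique(ph$cross_id)) * 37,
                           unique(ph$cross_id))
  ph2 <- ph
  ph2$value <- ph$value + shift[ph$cross_id]
  p1 <- scan_sim(fp, ph)
  p2 <- scan_sim(fp, ph2)
  expect_lt(max(abs(p1$minus_log10_p - p2$minus_log10_p)), 1e-6)
})

test_that("effects and SEs are scale-equivariant, p-values unchanged", {
  f1 <- fit_final(fp, ph, "2H_m07")
  ph3 <- ph
  ph3$value <- ph$value * 3
  f3 <- fit_final(fp, ph3, "2H_m07")
  expect_equal(unname(coef(f3)), unname(3 * coef(f1)), tolerance = 1e-6)
  # prediction SEs sit one chain rule deeper in the variance estimates;
  # allow an order of magnitude for optimizer termination noise
  expect_equal(unname(f3$se), unname(3 * f1$se), tolerance = 1e-5)
  expect_equal(f3$table$minus_log10_p, f1$table$minus_log10_p,
               tolerance = 1e-6)
})

test_that("the MQM scan finds a single simulated QTL exactly once", {
  sc <- scan_mqm(fp, ph)
  expect_equal(nrow(sc$qtls), 1)
  expect_equal(sc$qtls$chromosome, "2H")
  expect_lte(abs(sc$qtls$position - 30), 5)
  # final profile shows nothing new above threshold away from the QTL
  away <- sc$profile$chromosome != "2H" |
    abs(sc$profile$position - sc$qtls$position) > sc$window
  expect_true(all(sc$profile$minus_log10_p[away] < sc$threshold))
})

test_that("raising the threshold never yields more QTLs", {
  n_det <- vapply(c(3.2, 10, 40, 200), function(thr)
    nrow(scan_mqm(fp, ph, threshold = thr)$qtls), numeric(1))
  expect_true(all(diff(n_det) <= 0))
})

test_that("null phenotypes yield an empty QTL list", {
  set.seed(44)
  ph0 <- phenotype_table(rep(fp$line_id, each = 2),
                         rep(fp$cross_id, each = 2),
                         rep(1:2, length(fp$line_id)),
                         rnorm(2 * length(fp$line_id), 150, 5))
  sc0 <- scan_mqm(fp, ph0)
  expect_equal(nrow(sc0$qtls), 0)
})

test_that("two linked QTLs 30 cM apart are both recovered", {
  set.seed(45)
  map <- uniform_map(1, 90, 5)
  panel <- barley_panel(map)
  pop <- simulate_population(all_pairs_design(panel, 40), panel)
  eff2 <- rbind(al71_effects(), -al71_effects())
  ph2 <- simulate_phenotypes(pop, qtl_spec(c("1H", "1H"), c(25, 55), eff2,
                                           cross_means = 150,
                                           replicates = 4,
                                           heritability_target = 0.8))
  fp2 <- compute_founder_probs(pop$genotypes, panel, hmm_params())
  sc2 <- scan_mqm(fp2, ph2)
  expect_gte(nrow(sc2$qtls), 2)
  hits <- vapply(c(25, 55), function(p)
    any(abs(sc2$qtls$position - p) <= 10), logical(1))
  expect_true(all(hits))
})

test_that("the SIM peak recovers the QTL position across simulations", {
  ok_pos <- 0
  ok_null <- 0
  n_sim <- 10
  for (s in seq_len(n_sim)) {
    sim <- small_pop(seed = 500 + s, n_chrom = 2, length_cM = 60,
                     spacing_cM = 5, lines_per_subpop = 20)
    phs <- qtl_phenos(sim$pop, "1H", 30)
    fps <- compute_founder_probs(sim$pop$genotypes, sim$panel, hmm_params())
    prof <- scan_sim(fps, phs)
    peak <- prof[which.max(prof$minus_log10_p), ]
    if (peak$chromosome == "1H" && abs(peak$position - 30) <= 5)
      ok_pos <- ok_pos + 1
    # matched null scan: permuted phenotypes kill the signal genome-wide
    set.seed(9000 + s)
    phn <- phs
    phn$value <- sample(phn$value)
    profn <- scan_sim(fps, phn)
    if (max(profn$minus_log10_p) < 3.2) ok_null <- ok_null + 1
  }
  expect_gte(ok_pos, 0.9 * n_sim)
  expect_gte(ok_null, 0.9 * n_sim)
})

test_that("final-model founder effects recover the generating values", {
  # single strong QTL: >90% of true wild-founder effects within 2 SE
  true_eff <- al71_effects()[1, ]
  # marker spacing 2.5 cM, the density of the genotyped study population;
  # sparser maps leave founder-assignment error that the model SE cannot
  # see and calibration degrades
  n_sim <- 12
  n_eff <- 0; n_ok <- 0
  mlp_at_qtl <- numeric(n_sim)
  for (s in seq_len(n_sim)) {
    sim <- small_pop(seed = 600 + s, n_chrom = 1, length_cM = 60,
                     spacing_cM = 2.5, lines_per_subpop = 100)
    phs <- qtl_phenos(sim$pop, "1H", 30)
    fps <- compute_founder_probs(sim$pop$genotypes, sim$panel, hmm_params())
    ft <- fit_final(fps, phs, "1H_m13")
    n_eff <- n_eff + length(true_eff)
    n_ok <- n_ok + sum(abs(coef(ft)[1, names(true_eff)] - true_eff) <=
                         2 * ft$se[1, names(true_eff)])
    mlp_at_qtl[s] <- ft$table$minus_log10_p
  }
  expect_gte(n_ok / n_eff, 0.9)
  # a major QTL at n in the hundreds is far beyond the 3.2 threshold
  expect_true(all(mlp_at_qtl > 3.2))

  # a dummy QTL forced through null data shows no effects beyond noise:
  # across several null datasets, the (shrunken) effects stay within
  # 2 SE of zero at their nominal rate
  sim <- small_pop(seed = 647, n_chrom = 1, length_cM = 60,
                   spacing_cM = 10, lines_per_subpop = 20)
  fpn <- compute_founder_probs(sim$pop$genotypes, sim$panel, hmm_params())
  n_line <- length(sim$pop$genotypes$line_id)
  inside <- 0
  for (s in 1:10) {
    set.seed(46 + s)
    phn <- phenotype_table(rep(sim$pop$genotypes$line_id, each = 2),
                           rep(sim$pop$genotypes$cross_id, each = 2),
                           rep(1:2, n_line), rnorm(2 * n_line, 150, 5))
    ftn <- fit_final(fpn, phn, "1H_m04")
    inside <- inside + sum(abs(coef(ftn)) <= 2 * ftn$se + 1e-3)
  }
  expect_gte(inside / 40, 0.9)
})

test_that("prediction SE shrinks roughly as 1/sqrt(n)", {
  med_se <- function(lines, seed) {
    sim <- small_pop(seed = seed, n_chrom = 1, length_cM = 60,
                     spacing_cM = 10, lines_per_subpop = lines)
    phs <- qtl_phenos(sim$pop, "1H", 30)
    fps <- compute_founder_probs(sim$pop$genotypes, sim$panel, hmm_params())
    stats::median(fit_final(fps, phs, "1H_m04")$se)
  }
  ratios <- vapply(1:5, function(s)
    med_se(48, 700 + s) / med_se(24, 700 + s), numeric(1))
  expect_gt(stats::median(ratios), 0.55)
  expect_lt(stats::median(ratios), 0.85)
})

test_that("fit_final refuses QTLs closer than the exclusion window", {
  expect_error(fit_final(fp, ph, c("2H_m07", "2H_m08")), "merge")
})

test_that("epistasis testing is calibrated and powered", {
  # purely additive QTLs: nothing significant after Bonferroni
  set.seed(47)
  map <- uniform_map(2, 80, 10)
  panel <- barley_panel(map)
  pop <- simulate_population(all_pairs_design(panel, 30), panel)
  eff <- rbind(al71_effects(), -0.6 * al71_effects())
  pha <- simulate_phenotypes(pop, qtl_spec(c("1H", "2H"), c(20, 60), eff,
                                           cross_means = 150,
                                           replicates = 4,
                                           heritability_target = 0.75))
  fpa <- compute_founder_probs(pop$genotypes, panel, hmm_params())
  loci <- c("1H_m03", "2H_m07")
  epa <- test_epistasis(fpa, pha, loci)
  expect_true(all(epa$p_bonferroni > 0.05))

  # planted multiplicative interaction between the wild doses at the two
  # loci (any donor; single-founder-pair doses are vanishingly rare in
  # this design) is detected
  doses <- truth_doses(pop)
  wild <- setdiff(panel$founders, "Morex")
  w1 <- rowSums(doses[, "1H_m03", wild])
  w2 <- rowSums(doses[, "2H_m07", wild])
  n_hit <- 0
  n_sim <- 6
  for (s in seq_len(n_sim)) {
    set.seed(800 + s)
    g <- attr(pha, "genetic_values")
    sd_e <- attr(pha, "residual_sd")
    y <- rep(g + 2 * sd_e * w1 * w2, each = 2) +
      rnorm(2 * length(g), 0, sd_e)
    phi <- phenotype_table(rep(names(g), each = 2),
                           rep(pop$genotypes$cross_id, each = 2),
                           rep(1:2, length(g)), y)
    epi <- test_epistasis(fpa, phi, loci)
    if (any(epi$p_bonferroni < 0.05)) n_hit <- n_hit + 1
  }
  expect_gte(n_hit, 0.8 * n_sim)

  # pure-noise phenotypes at two arbitrary loci: raw p rarely significant
  n_null_ok <- 0
  for (s in seq_len(10)) {
    set.seed(830 + s)
    yn <- rnorm(length(pop$genotypes$line_id), 150, 5)
    phn <- phenotype_table(pop$genotypes$line_id, pop$genotypes$cross_id,
                           1, yn)
    epn <- test_epistasis(fpa, phn, loci)
    if (all(epn$p_raw > 0.05)) n_null_ok <- n_null_ok + 1
  }
  expect_gte(n_null_ok, 9)
})
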