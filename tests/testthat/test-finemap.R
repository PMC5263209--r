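test_that("HIF selection returns exactly the heterozygous lines", {
  g <- matrix(c(0L, 2L, 1L, 0L, 1L, 2L, 0L, 1L), 4, 2,
              dimnames = list(paste0("l", 1:4), c("mA", "mB")))
  expect_identical(select_hif_lines(g, "mA"), "l3")
  expect_identical(select_hif_lines(g, "mB"), c("l1", "l4"))
  expect_identical(select_hif_lines(g[c(1, 2), ], "mA"), character(0))
  gna <- g; gna[, "mA"] <- NA_integer_
  expect_error(select_hif_lines(gna, "mA"), "no genotype calls")
  expect_error(select_hif_lines(g, "mZ"), "not genotyped")
})

test_that("HIF frequency in a simulated F6 population matches SSD decay", {
  # heterozygosity at a locus: 7/16 at the intercross, halved per selfing
  fx <- small_pop(seed = 51, n_chrom = 1, length_cM = 60, spacing_cM = 10,
                  lines_per_subpop = 120)
  gt <- fx$pop$genotypes
  # count het lines at informative markers (donor allele differs from
  # recipient for both donors of the line's cross)
  p_exp <- (7 / 16) * (1 / 2)^5
  n_het <- 0; n_tot <- 0
  for (m in fx$map$marker) {
    ids <- select_hif_lines(gt, m)
    # restrict to lines whose cross is fully informative at m
    al <- fx$panel$alleles[, m]
    for (lab in unique(gt$cross_id)) {
      donors <- strsplit(lab, "x")[[1]]
      if (all(al[donors] == 1) && al["Morex"] == 0) {
        sel <- gt$line_id[gt$cross_id == lab]
        n_het <- n_het + sum(ids %in% sel)
        n_tot <- n_tot + length(sel)
      }
    }
  }
  se <- sqrt(p_exp * (1 - p_exp) / n_tot)
  expect_lt(abs(n_het / n_tot - p_exp), 4 * se)
})

test_that("recombinant screening matches the Haldane binomial expectation", {
  # progeny of a homozygous parent: no recombinants
  fx <- het_parent_fixture(5.4)
  founders <- c("Morex", "HID4", "HID64", "HID369", "HID382")
  hom <- mosaic_pure(1, fx$map, founders)
  set.seed(52)
  pr0 <- simulate_self_progeny(hom, 50, fx$panel)
  rs0 <- find_recombinants(pr0$genotypes, "fL", "fR")
  expect_length(rs0$recombinants, 0)

  # het parent: fraction with distinct flank classes approx 1-(1-r)^2
  for (d in c(1.4, 5.4, 10)) {
    fxd <- het_parent_fixture(d)
    set.seed(520 + d)
    n <- 5000
    pr <- simulate_self_progeny(fxd$parent, n, fxd$panel)
    rs <- find_recombinants(pr$genotypes, "fL", "fR")
    r <- haldane_r(d)
    p_exp <- 1 - (1 - r)^2
    se <- sqrt(p_exp * (1 - p_exp) / n)
    expect_lt(abs(length(rs$recombinants) / n - p_exp), 3 * se)
  }

  # missing flank calls are counted unscreenable, not recombinant
  g <- matrix(c(0L, NA, 2L, 1L), 2, 2,
              dimnames = list(c("p1", "p2"), c("fL", "fR")))
  rs <- find_recombinants(g, "fL", "fR")
  expect_identical(rs$unscreenable, "p2")
  expect_identical(rs$recombinants, "p1")
})

test_that("two-point rf estimation is consistent and monotone", {
  # counts only in coupling classes: rf = 0
  cp <- matrix(0, 3, 3)
  cp[1, 1] <- 30; cp[2, 2] <- 50; cp[3, 3] <- 20
  est <- estimate_two_point_rf(cp)
  expect_equal(est$rf, 0, tolerance = 1e-8)
  expect_equal(est$cM, 0, tolerance = 1e-6)

  # simulation recovery at r = 0.10 (n = 2000 selfed progeny)
  r_true <- 0.10
  d <- haldane_cM(r_true)
  fx <- het_parent_fixture(d)
  cover <- 0
  for (s in 1:20) {
    set.seed(530 + s)
    pr <- simulate_self_progeny(fx$parent, 2000, fx$panel)
    tab <- table(factor(pr$genotypes[, "fL"], levels = 0:2),
                 factor(pr$genotypes[, "fR"], levels = 0:2))
    est <- estimate_two_point_rf(tab)
    # 95% Wald band on the gamete scale (2n gametes)
    se <- sqrt(est$rf * (1 - est$rf) / (2 * 2000))
    if (abs(est$rf - r_true) <= 1.96 * se) cover <- cover + 1
  }
  expect_gte(cover, 0.9 * 20)

  # unlinked markers: rf -> 0.5 within 0.02
  set.seed(54)
  n <- 4000
  gA <- sample(0:2, n, TRUE, prob = c(1, 2, 1) / 4)
  gB <- sample(0:2, n, TRUE, prob = c(1, 2, 1) / 4)
  tab <- table(factor(gA, levels = 0:2), factor(gB, levels = 0:2))
  expect_gt(suppressWarnings(estimate_two_point_rf(tab)$rf), 0.48)

  # monotone in the recombinant-class counts
  base <- matrix(0, 3, 3); base[1, 1] <- 400; base[3, 3] <- 400
  base[2, 2] <- 200
  rfs <- vapply(c(0, 20, 60, 120), function(k) {
    m <- base; m[1, 2] <- k; m[2, 3] <- k
    estimate_two_point_rf(m)$rf
  }, numeric(1))
  expect_true(all(diff(rfs) > 0))

  expect_error(estimate_two_point_rf(matrix(0, 3, 3)), "empty")
})

test_that("interval delimitation reproduces the co-segregation logic", {
  # recombinants with breakpoints on both sides of the central marker;
  # phenotype tracks the central marker's genotype: the flanks recombine
  # with the trait, the central marker co-segregates
  markers <- c("3_0593", "2_0483", "3_1489", "2_0117", "1_0999")
  geno <- rbind(
    r1 = c(0, 0, 2, 2, 2),   # breakpoint between 2_0483 and 3_1489
    r2 = c(2, 2, 2, 0, 0),   # breakpoint between 3_1489 and 2_0117
    r3 = c(2, 2, 0, 0, 0),   # breakpoint between 2_0483 and 3_1489
    r4 = c(0, 0, 0, 2, 2))   # breakpoint between 3_1489 and 2_0117
  colnames(geno) <- markers
  cls <- c(r1 = "donor", r2 = "donor", r3 = "recipient", r4 = "recipient")
  pos <- stats::setNames(c(128.5, 132.0, 133.4, 134.2, 136.1), markers)
  call <- delimit_interval(geno, cls, pos)
  expect_identical(call$left, "2_0483")
  expect_identical(call$right, "2_0117")
  expect_identical(call$cosegregating, "3_1489")
  expect_equal(call$width_cM, 134.2 - 132.0)

  # zero recombinants: full flank-to-flank range
  call0 <- delimit_interval(geno[0, , drop = FALSE], character(0), pos)
  expect_identical(call0$left, "3_0593")
  expect_identical(call0$right, "1_0999")

  # contradictory lines are reported
  bad <- rbind(x1 = c(0, 0, 0, 0, 0), x2 = c(2, 2, 2, 2, 2))
  colnames(bad) <- markers
  expect_error(delimit_interval(bad, c(x1 = "donor", x2 = "recipient"),
                                pos),
               "x1")
})

test_that("delimited interval equals the brute-force smallest interval", {
  # oracle: each single-breakpoint recombinant admits a QTL region (left
  # of its breakpoint if the phenotype matches its left segment, right of
  # it otherwise); the delimited interval is the intersection over lines
  brute_force <- function(geno, cls) {
    mk <- colnames(geno)
    lo <- 1L; hi <- length(mk)
    for (i in seq_len(nrow(geno))) {
      gc <- ifelse(geno[i, ] == 0, "recipient", "donor")
      bp <- which(gc[-1] != gc[-length(gc)])   # index of last left marker
      if (!length(bp)) next                    # non-recombinant
      bp <- bp[1]
      if (cls[i] == gc[1]) hi <- min(hi, bp + 1L) else lo <- max(lo, bp)
    }
    if (lo > hi) return(NULL)
    mk[c(lo, hi)]
  }
  set.seed(55)
  for (rep in 1:50) {
    n_mk <- sample(4:8, 1)
    mk <- paste0("m", seq_len(n_mk))
    qtl_at <- sample(2:(n_mk - 1), 1)
    n_rec <- sample(2:6, 1)
    # single-breakpoint recombinants: 0s then 2s (or reverse)
    geno <- t(vapply(seq_len(n_rec), function(i) {
      bp <- sample(seq_len(n_mk - 1), 1)
      ori <- sample(c(0, 2), 1)
      v <- c(rep(ori, bp), rep(2 - ori, n_mk - bp))
      v
    }, numeric(n_mk)))
    colnames(geno) <- mk
    rownames(geno) <- paste0("r", seq_len(n_rec))
    cls <- ifelse(geno[, qtl_at] == 2, "donor", "recipient")
    oracle <- brute_force(geno, cls)
    got <- delimit_interval(geno, cls)
    if (is.null(oracle)) next
    expect_identical(c(got$left, got$right), oracle)
    # the true QTL marker is always inside or at the reported interval
    li <- match(got$left, mk); ri <- match(got$right, mk)
    expect_true(li <= qtl_at && qtl_at <= ri)
  }
})

test_that("interval calls serialize to JSON faithfully", {
  markers <- c("2_0483", "3_1489", "2_0117")
  geno <- rbind(r1 = c(0, 2, 2), r2 = c(2, 2, 0))
  colnames(geno) <- markers
  call <- delimit_interval(geno, c(r1 = "donor", r2 = "donor"),
                           stats::setNames(c(132.0, 133.4, 134.2), markers))
  f <- withr::local_tempfile(fileext = ".json")
  write_interval_json(call, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$left, call$left)
  expect_equal(back$width_cM, call$width_cM)
  expect_equal(unlist(back$cosegregating), call$cosegregating)
})

test_that("NIL phenotype classification follows the t-test rule", {
  set.seed(56)
  refs <- list(M = c(148, 150, 152, 149, 151, 150),
               D = c(108, 110, 112, 109, 111, 110))

  # clear membership
  cls <- assign_phenotype_class(list(n1 = rnorm(8, 150, 3),
                                     n2 = rnorm(8, 110, 3)), refs)
  expect_identical(unname(cls), c("M", "D"))

  # exactly midway with huge variance: compatible with both -> unclassified
  cls2 <- assign_phenotype_class(list(nx = c(90, 170, 110, 150, 130, 130)),
                                 refs)
  expect_identical(unname(cls2), "unclassified")

  # single replicate: warning and unclassified
  expect_warning(cls3 <- assign_phenotype_class(list(ny = 150), refs),
                 "replicates")
  expect_identical(unname(cls3), "unclassified")

  expect_error(assign_phenotype_class(list(nz = rnorm(5)),
                                      refs["M"]), "two reference")

  # power: NIL drawn from the shifted donor distribution at the major-QTL
  # effect size is classified as donor in >= 90% of cases (n = 10 reps)
  hits <- 0
  for (s in 1:20) {
    set.seed(560 + s)
    refs_s <- list(M = rnorm(10, 150, 8), D = rnorm(10, 150 - 24.7, 8))
    cls_s <- assign_phenotype_class(list(nd = rnorm(10, 150 - 24.7, 8)),
                                    refs_s)
    if (cls_s == "D") hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("printed recombinant counts are reproduced by the design", {
  # 475 progeny with flanks 5.4 cM apart -> about 47 recombinants;
  # 452 progeny with flanks 1.4 cM apart -> about 13
  cases <- list(list(n = 475, d = 5.4, printed = 47),
                list(n = 452, d = 1.4, printed = 13))
  for (cs in cases) {
    fx <- het_parent_fixture(cs$d)
    set.seed(57)
    counts <- vapply(1:20, function(i) {
      pr <- simulate_self_progeny(fx$parent, cs$n, fx$panel)
      length(find_recombinants(pr$genotypes, "fL", "fR")$recombinants)
    }, numeric(1))
    r <- haldane_r(cs$d)
    p <- 1 - (1 - r)^2
    se_one <- sqrt(cs$n * p * (1 - p))
    # the printed count is one binomial draw from this design
    expect_lt(abs(mean(counts) - cs$printed), 3 * se_one)
  }
})
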