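#' Pipeline run configuration
#'
#' Flat key-value configuration for [run_pipeline()]. All values have
#' defaults mirroring the study conditions; every field is echoed to the
#' run log for provenance.
#'
#' @param significance_threshold QTL threshold, -log10(p) units
#'   (default 3.2).
#' @param cofactor_exclusion_window cofactor exclusion window, cM
#'   (default 10).
#' @param scan_step optional scan grid step in cM (`NA` scans marker
#'   positions only).
#' @param rng_seed integer seed propagated (with stage offsets) to every
#'   stochastic stage.
#' @param genotyping_error simulated/assumed per-call error rate.
#' @param max_scan_iterations MQM iteration cap.
#' @param n_chrom,chrom_length_cM,marker_spacing_cM simulated map shape.
#' @param lines_per_subpop simulated RILs per donor pair.
#' @param replicates phenotype replicates per line.
#' @param heritability plot-basis broad-sense heritability target.
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(significance_threshold = 3.2,
                       cofactor_exclusion_window = 10,
                       scan_step = NA, rng_seed = 1L,
                       genotyping_error = 0.01,
                       max_scan_iterations = 20L,
                       n_chrom = 7L, chrom_length_cM = 150,
                       marker_spacing_cM = 5,
                       lines_per_subpop = 153L, replicates = 4L,
                       heritability = 0.75) {
  cfg <- list(significance_threshold = significance_threshold,
              cofactor_exclusion_window = cofactor_exclusion_window,
              scan_step = scan_step, rng_seed = as.integer(rng_seed),
              genotyping_error = genotyping_error,
              max_scan_iterations = as.integer(max_scan_iterations),
              n_chrom = as.integer(n_chrom),
              chrom_length_cM = chrom_length_cM,
              marker_spacing_cM = marker_spacing_cM,
              lines_per_subpop = as.integer(lines_per_subpop),
              replicates = as.integer(replicates),
              heritability = heritability)
  if (cfg$significance_threshold <= 0) stop("threshold must be > 0")
  if (cfg$cofactor_exclusion_window < 0) stop("window must be >= 0")
  if (cfg$genotyping_error < 0 || cfg$genotyping_error > 1)
    stop("genotyping_error must be in [0,1]")
  class(cfg) <- "run_config"
  cfg
}

#' Read a flat key-value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); unknown keys are
#' rejected. Missing keys keep their defaults.
#'
#' @param path configuration file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "\\s*[=:]\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  defaults <- run_config()
  unknown <- setdiff(trimws(keys), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  args <- as.list(utils::type.convert(trimws(vals), as.is = TRUE))
  names(args) <- trimws(keys)
  do.call(run_config, args)
}

#' Write a configuration as flat key-value text
#' @param config a [run_config()].
#' @param path output file path.
#' @export
write_run_config <- function(config, path) {
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, format, "")), path)
  invisible(path)
}

# derive a stage sub-seed (< 2^31) from the master seed; always logged
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 101L, phenotype = 211L, founderprob = 307L,
               scan = 401L)
  (as.integer(seed) * 1009L + offsets[[stage]]) %% 2147483647L
}

#' Run the simulate -> founder-probability -> QTL-scan pipeline
#'
#' With no input files, simulates a population under the configured
#' breeding design (all donor pairs of the five-founder barley-like
#' panel), a single major QTL on 7H at 133.9 cM with the reference wild
#' founder effects, and replicated phenotypes at the configured
#' heritability; then computes founder probabilities and runs the
#' multi-QTL scan and final fit. With `genotypes_file` and
#' `phenotypes_file` (plus `map_file`) supplied, skips simulation and
#' scans the provided data. All stages write TSV outputs and a log to
#' `out_dir`; rerunning with the same seed and inputs reproduces the
#' outputs byte-identically.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param map_file,genotypes_file,phenotypes_file,panel_file optional
#'   input TSVs; supplying genotype/phenotype/panel/map files switches the
#'   pipeline to scan-only mode on those data.
#' @return Invisibly, a list with the scan (`qtl_scan`), final fit
#'   (`qtl_fit` or NULL if nothing detected) and output paths.
#' @export
run_pipeline <- function(config = run_config(), out_dir,
                         map_file = NULL, genotypes_file = NULL,
                         phenotypes_file = NULL, panel_file = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("pipeline started")
  for (k in names(config)) logf("config %s = %s", k, format(config[[k]]))

  stage <- "input"
  result <- tryCatch({
    if (is.null(genotypes_file)) {
      stage <- "simulate"
      s <- stage_seed(config$rng_seed, "simulate")
      logf("stage simulate: sub-seed %d", s)
      set.seed(s)
      map <- uniform_map(config$n_chrom, config$chrom_length_cM,
                         config$marker_spacing_cM)
      panel <- barley_panel(map)
      design <- all_pairs_design(panel, config$lines_per_subpop)
      pop <- simulate_population(design, panel,
                                 genotyping_error = config$genotyping_error)
      s <- stage_seed(config$rng_seed, "phenotype")
      logf("stage phenotype: sub-seed %d", s)
      set.seed(s)
      qtl_chrom <- if ("7H" %in% map$chromosome) "7H" else
        utils::tail(map_chromosomes(map), 1)
      qtl_pos <- min(133.9, 0.9 * config$chrom_length_cM)
      spec <- qtl_spec(qtl_chrom, qtl_pos,
                      matrix(c(-3.5, -19.0, -1.0, -24.7), 1,
                             dimnames = list(NULL, c("HID4", "HID64",
                                                     "HID369", "HID382"))),
                       cross_means = 150,
                       replicates = config$replicates,
                       heritability_target = config$heritability)
      phenos <- simulate_phenotypes(pop, spec)
      write_genetic_map(map, file.path(out_dir, "map.tsv"))
      write_genotypes(pop$genotypes, file.path(out_dir, "genotypes.tsv"))
      write_phenotypes(phenos, file.path(out_dir, "phenotypes.tsv"))
      truth <- data.frame(line_id = rownames(pop$truth), pop$truth,
                          check.names = FALSE)
      utils::write.table(truth, file.path(out_dir, "truth_proportions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      td <- truth_doses(pop)
      long <- data.frame(
        line_id = rep(dimnames(td)[[1]], times = dim(td)[2]),
        marker = rep(dimnames(td)[[2]], each = dim(td)[1]),
        matrix(td, dim(td)[1] * dim(td)[2], dim(td)[3],
               dimnames = list(NULL, dimnames(td)[[3]])),
        check.names = FALSE, stringsAsFactors = FALSE)
      utils::write.table(long, file.path(out_dir, "truth_doses.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      geno <- pop$genotypes
    } else {
      logf("stage input: reading user files")
      if (is.null(map_file) || is.null(phenotypes_file) ||
          is.null(panel_file))
        stop("map_file, panel_file and phenotypes_file are required ",
             "with genotypes_file")
      map <- read_genetic_map(map_file)
      geno <- read_genotypes(genotypes_file, map)
      phenos <- read_phenotypes(phenotypes_file)
      panel <- read_founder_panel(panel_file, map)
    }

    stage <- "founderprob"
    s <- stage_seed(config$rng_seed, "founderprob")
    logf("stage founderprob: sub-seed %d (deterministic stage)", s)
    fp <- compute_founder_probs(geno, panel,
                                hmm_params(genotyping_error =
                                             max(config$genotyping_error, 0.005)))
    if (!is.na(config$scan_step)) fp <- interpolate_to_grid(fp, config$scan_step)

    stage <- "scan"
    s <- stage_seed(config$rng_seed, "scan")
    logf("stage scan: sub-seed %d (deterministic stage)", s)
    scan <- scan_mqm(fp, phenos,
                     threshold = config$significance_threshold,
                     window = config$cofactor_exclusion_window,
                     max_iter = config$max_scan_iterations)
    utils::write.table(scan$profile, file.path(out_dir, "scan_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    fit <- NULL
    if (nrow(scan$qtls)) {
      fit <- fit_final(fp, phenos, scan,
                       window = config$cofactor_exclusion_window)
      write_qtl_table(fit, file.path(out_dir, "qtl_table.tsv"))
    }
    logf("stage scan: %d QTL(s) detected", nrow(scan$qtls))
    logf("pipeline finished")
    list(scan = scan, fit = fit, out_dir = out_dir,
         founder_probs = fp, phenotypes = phenos)
  }, error = function(e) {
    logf("stage %s FAILED: %s", stage, conditionMessage(e))
    stop("pipeline failed in stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(result)
}
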