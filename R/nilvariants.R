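#' Read transcript variant records from a VCF subset
#'
#' Reads a VCF v4.2 file (CHROM, POS, QUAL, FILTER, INFO keys FS/QD/DP,
#' first sample GT) into the flat record table consumed by the hard
#' filters. The gene id is taken from the CHROM column (transcript
#' reference) unless an INFO `GENE` key is present.
#'
#' @param path VCF file path.
#' @return data.frame of class `variant_records` with columns `gene`,
#'   `pos`, `qual`, `fs`, `qd`, `dp`, `gt` (one of `hom_ref`, `het`,
#'   `hom_alt`), `ref`, `alt`.
#' @export
read_variant_records <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  info_num <- function(key) {
    x <- vcfR::extract.info(v, element = key, as.numeric = TRUE)
    as.numeric(x)
  }
  gene <- vcfR::extract.info(v, element = "GENE")
  if (all(is.na(gene))) gene <- fix[, "CHROM"]
  gt_raw <- if (ncol(v@gt) >= 2) vcfR::extract.gt(v, element = "GT")[, 1]
            else rep(NA_character_, nrow(fix))
  gt <- rep(NA_character_, length(gt_raw))
  a <- sub("[/|].*", "", gt_raw)
  b <- sub(".*[/|]", "", gt_raw)
  gt[a == b & a == "0"] <- "hom_ref"
  gt[a == b & a != "0" & !is.na(a)] <- "hom_alt"
  gt[!is.na(a) & !is.na(b) & a != b] <- "het"
  out <- data.frame(gene = as.character(gene),
                    pos = as.numeric(fix[, "POS"]),
                    qual = as.numeric(fix[, "QUAL"]),
                    fs = info_num("FS"), qd = info_num("QD"),
                    dp = info_num("DP"), gt = gt,
                    ref = fix[, "REF"], alt = fix[, "ALT"],
                    stringsAsFactors = FALSE)
  class(out) <- c("variant_records", "data.frame")
  out
}

#' Hard-filter transcript variant records
#'
#' Keeps a record iff QUAL >= 30, FS <= 30.0, QD >= 2.0 and DP > 4 (read
#' coverage strictly exceeding four reads). A missing FS or QD passes that
#' criterion (logged); a missing QUAL or DP fails. Order is preserved and
#' the operation is idempotent.
#'
#' @param records data.frame with columns `qual`, `fs`, `qd`, `dp` (as
#'   from [read_variant_records()]).
#' @return The passing subset, same columns and order.
#' @export
filter_variants <- function(records) {
  if (!nrow(records)) return(records)
  if (any(records$dp < 0, na.rm = TRUE))
    stop("malformed record: negative DP")
  miss <- is.na(records$fs) | is.na(records$qd)
  if (any(miss))
    message(sum(miss), " record(s) missing FS or QD: criterion passed by default")
  keep <- !is.na(records$qual) & records$qual >= 30 &
    (is.na(records$fs) | records$fs <= 30.0) &
    (is.na(records$qd) | records$qd >= 2.0) &
    !is.na(records$dp) & records$dp > 4
  records[keep, , drop = FALSE]
}

#' Classify per-gene allele origin from filtered variants
#'
#' With the recipient as reference genome, a gene is called wild-derived
#' iff it carries at least one passing homozygous-alternate SNP; genes
#' with only heterozygous variants are recipient with a `segregating`
#' flag.
#'
#' @param records passing records (see [filter_variants()]) with columns
#'   `gene` and `gt`.
#' @param genes optional character vector of the full expressed-gene
#'   universe; genes without records are recipient.
#' @return data.frame of class `gene_origin`: columns `gene`, `origin`
#'   (`recipient`/`wild`), `n_support` (hom-alt SNPs), `het_only` flag.
#' @export
classify_gene_origin <- function(records, genes = NULL) {
  if (is.null(genes)) genes <- unique(records$gene)
  n_hom <- table(factor(records$gene[records$gt == "hom_alt"],
                        levels = genes))
  n_het <- table(factor(records$gene[records$gt == "het"], levels = genes))
  out <- data.frame(
    gene = genes,
    origin = ifelse(as.integer(n_hom) >= 1, "wild", "recipient"),
    n_support = as.integer(n_hom),
    het_only = as.integer(n_hom) == 0 & as.integer(n_het) > 0,
    stringsAsFactors = FALSE)
  class(out) <- c("gene_origin", "data.frame")
  out
}

#' Detect segregating intervals between a NIL pair
#'
#' Genes whose allele origin differs between the two NILs are polymorphic;
#' runs of polymorphic genes along the genetic map are merged into
#' intervals whenever the gap to the next polymorphic gene is below
#' `gap_tolerance`. Interval boundaries are the outermost polymorphic gene
#' positions.
#'
#' @param origin_a,origin_b `gene_origin` tables of the two NILs (shared
#'   gene universe).
#' @param gene_positions data.frame (gene, chromosome, position
#'   [, confidence_class]) placing genes on the genetic map; genes absent
#'   from it are unassigned and ignored for interval detection.
#' @param gap_tolerance maximum within-interval gap between consecutive
#'   polymorphic genes, cM (default 1.0).
#' @return data.frame of class `segregating_intervals`: columns
#'   `chromosome`, `start`, `end`, `width`, `n_genes`, `genes`
#'   (list-column), and HC/LC counts when a confidence class is supplied.
#' @export
detect_segregating_intervals <- function(origin_a, origin_b, gene_positions,
                                         gap_tolerance = 1.0) {
  shared <- intersect(origin_a$gene, origin_b$gene)
  oa <- origin_a$origin[match(shared, origin_a$gene)]
  ob <- origin_b$origin[match(shared, origin_b$gene)]
  poly <- shared[oa != ob]
  gp <- gene_positions[gene_positions$gene %in% poly &
                         !is.na(gene_positions$position), ]
  res <- list()
  for (ch in unique(gp$chromosome)) {
    sub <- gp[gp$chromosome == ch, ]
    sub <- sub[order(sub$position), ]
    brk <- c(0, cumsum(diff(sub$position) >= gap_tolerance))
    for (b in unique(brk)) {
      blk <- sub[brk == b, ]
      row <- data.frame(chromosome = ch, start = min(blk$position),
                        end = max(blk$position),
                        width = max(blk$position) - min(blk$position),
                        n_genes = nrow(blk), stringsAsFactors = FALSE)
      if ("confidence_class" %in% names(blk)) {
        row$n_HC <- sum(blk$confidence_class == "HC")
        row$n_LC <- sum(blk$confidence_class == "LC")
      }
      row$genes <- I(list(blk$gene))
      res[[length(res) + 1]] <- row
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(chromosome = character(0), start = numeric(0),
               end = numeric(0), width = numeric(0), n_genes = integer(0))
  class(out) <- c("segregating_intervals", "data.frame")
  out
}

#' Candidate-gene shortlist within a fine-mapped interval
#'
#' Funnel: interval genes with a detected transcript AND (polymorphic
#' between the NIL pair OR differentially expressed). Ranked
#' polymorphic+DE first, then polymorphic, then DE only.
#'
#' @param genes character vector of interval gene ids.
#' @param detected,polymorphic,de logical vectors aligned with `genes`.
#' @return List with `candidates` (ranked data.frame gene, polymorphic,
#'   de, rank_class) and `counts` (funnel: interval, detected,
#'   polymorphic, de, candidates).
#' @export
candidate_shortlist <- function(genes, detected, polymorphic, de) {
  stopifnot(length(detected) == length(genes),
            length(polymorphic) == length(genes),
            length(de) == length(genes))
  cand <- detected & (polymorphic | de)
  rank_class <- ifelse(polymorphic & de, 1L, ifelse(polymorphic, 2L, 3L))
  tab <- data.frame(gene = genes[cand], polymorphic = polymorphic[cand],
                    de = de[cand], rank_class = rank_class[cand],
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$rank_class, tab$gene), ]
  rownames(tab) <- NULL
  list(candidates = tab,
       counts = c(interval = length(genes),
                  detected = sum(detected),
                  polymorphic = sum(detected & polymorphic),
                  de = sum(detected & de),
                  candidates = sum(cand)))
}

#' Effect of an insertion on a coding sequence
#'
#' Classifies an insertion as in-frame or frameshift (length mod 3) and
#' reports the first premature stop codon of the mutated coding sequence.
#' The insertion is placed *after* `position - 1` bases, i.e. starting at
#' the given 1-based nucleotide.
#'
#' @param cds coding sequence (character, A/C/G/T), length divisible by 3,
#'   beginning with a start codon.
#' @param position 1-based nucleotide position at which the insertion
#'   starts.
#' @param insertion inserted sequence (e.g. `"AG"`).
#' @return List with `frame` (`"in_frame"` or `"frameshift"`),
#'   `premature_stop` (codon index of the first new stop, or `NA`),
#'   `protein` (mutated translation up to and excluding the stop).
#' @export
indel_effect <- function(cds, position, insertion) {
  cds <- toupper(cds)
  insertion <- toupper(insertion)
  n <- nchar(cds)
  if (n %% 3 != 0) stop("CDS length must be divisible by 3")
  if (substr(cds, 1, 3) != "ATG") stop("CDS must begin with a start codon")
  if (position < 1 || position > n) stop("insertion position outside CDS")
  mutated <- paste0(substr(cds, 1, position - 1), insertion,
                    substr(cds, position, n))
  frame <- if (nchar(insertion) %% 3 == 0) "in_frame" else "frameshift"
  code <- Biostrings::GENETIC_CODE
  n_codon_orig <- n / 3
  m <- nchar(mutated)
  codons <- substring(mutated, seq(1, m - 2, by = 3), seq(3, m, by = 3))
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  stop_at <- which(aa == "*")
  premature <- if (length(stop_at) && stop_at[1] < n_codon_orig)
    stop_at[1] else NA_integer_
  prot <- if (length(stop_at)) paste(aa[seq_len(stop_at[1] - 1)],
                                     collapse = "") else
    paste(aa, collapse = "")
  list(frame = frame, premature_stop = premature, protein = prot)
}
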