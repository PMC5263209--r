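#' Construct a founder panel
#'
#' The founder panel holds the SNP alleles of the population founders: one
#' recurrent (recipient) parent and the donor parents. Alleles are coded 0/1
#' (reference/alternate) with NA for missing; rows are founders, columns are
#' the markers of the genetic map, in map order.
#'
#' @param founders character vector of founder names; the recipient first by
#'   convention (see `recipient`).
#' @param alleles founders x markers matrix with entries in \{0, 1, NA\};
#'   column names must equal `map$marker` (any order; reordered to map order).
#' @param map a [genetic_map()].
#' @param recipient name of the recurrent parent (default: first founder).
#' @return An object of class `founder_panel`.
#' @export
founder_panel <- function(founders, alleles, map, recipient = founders[1]) {
  founders <- as.character(founders)
  if (anyDuplicated(founders)) stop("founder names must be unique")
  if (!recipient %in% founders) stop("recipient must be one of the founders")
  alleles <- as.matrix(alleles)
  if (nrow(alleles) != length(founders))
    stop("alleles must have one row per founder")
  if (is.null(colnames(alleles)) || !setequal(colnames(alleles), map$marker))
    stop("allele matrix columns must match map markers")
  alleles <- alleles[, map$marker, drop = FALSE]
  ok <- alleles %in% c(0, 1) | is.na(alleles)
  if (!all(ok)) stop("founder alleles must be 0, 1 or NA")
  storage.mode(alleles) <- "integer"
  rownames(alleles) <- founders
  structure(list(founders = founders, recipient = recipient,
                 alleles = alleles, map = map),
            class = "founder_panel")
}

#' @export
print.founder_panel <- function(x, ...) {
  cat("Founder panel:", length(x$founders), "founders (recipient:",
      x$recipient, "),", ncol(x$alleles), "markers\n")
  invisible(x)
}

#' Read a founder panel from delimited text
#'
#' Expects a `founder` column followed by one 0/1 allele column per map
#' marker; the first row is taken as the recipient unless `recipient`
#' names another founder.
#'
#' @param path file path.
#' @param map a [genetic_map()].
#' @param recipient recipient founder name (default: first row).
#' @return A [founder_panel()].
#' @export
read_founder_panel <- function(path, map, recipient = NULL) {
  tab <- read_delim_auto(path)
  if (!"founder" %in% names(tab))
    stop("founder panel file must have a 'founder' column")
  a <- as.matrix(tab[, setdiff(names(tab), "founder"), drop = FALSE])
  suppressWarnings(storage.mode(a) <- "numeric")
  founder_panel(tab$founder, a, map,
                recipient = if (is.null(recipient)) tab$founder[1]
                            else recipient)
}

#' Write a founder panel as TSV
#' @param panel a [founder_panel()].
#' @param path output file path.
#' @export
write_founder_panel <- function(panel, path) {
  out <- data.frame(founder = panel$founders, panel$alleles,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a marker genotype table
#'
#' Genotypes are coded as the count of the alternate allele (0/1/2) with NA
#' for missing calls. Every line carries a cross (subpopulation) label.
#'
#' @param line_id character vector of line names (unique).
#' @param cross_id character vector of cross labels, one per line.
#' @param genotypes lines x markers matrix with entries in \{0, 1, 2, NA\};
#'   columns must match `map$marker`.
#' @param map a [genetic_map()].
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(line_id, cross_id, genotypes, map) {
  line_id <- as.character(line_id)
  cross_id <- as.character(cross_id)
  if (anyDuplicated(line_id)) stop("line ids must be unique")
  if (length(cross_id) != length(line_id))
    stop("one cross label per line required")
  genotypes <- as.matrix(genotypes)
  if (nrow(genotypes) != length(line_id))
    stop("genotype matrix must have one row per line")
  if (is.null(colnames(genotypes)) || !all(colnames(genotypes) %in% map$marker))
    stop("genotype columns absent from map: ",
         paste(setdiff(colnames(genotypes), map$marker), collapse = ", "))
  if (!all(map$marker %in% colnames(genotypes)))
    stop("genotype table missing map marker(s): ",
         paste(setdiff(map$marker, colnames(genotypes)), collapse = ", "))
  genotypes <- genotypes[, map$marker, drop = FALSE]
  bad <- which(!(genotypes %in% c(0, 1, 2) | is.na(genotypes)))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(genotypes)) + 1
    j <- ((bad[1] - 1) %/% nrow(genotypes)) + 1
    stop("invalid genotype code '", genotypes[bad[1]], "' for line ",
         line_id[i], " at marker ", colnames(genotypes)[j],
         " (allowed: 0, 1, 2, NA)")
  }
  storage.mode(genotypes) <- "integer"
  rownames(genotypes) <- line_id
  structure(list(line_id = line_id, cross_id = cross_id,
                 genotypes = genotypes, map = map),
            class = "genotype_table")
}

#' Read a genotype table from delimited text
#'
#' Expects header columns `line_id`, `cross_id`, then one column per marker.
#'
#' @param path file path.
#' @param map a [genetic_map()] whose markers the columns must match.
#' @return A [genotype_table()].
#' @export
read_genotypes <- function(path, map) {
  tab <- read_delim_auto(path)
  if (!all(c("line_id", "cross_id") %in% names(tab)))
    stop("genotype file must have line_id and cross_id columns")
  gcols <- setdiff(names(tab), c("line_id", "cross_id"))
  geno <- as.matrix(tab[, gcols, drop = FALSE])
  suppressWarnings(storage.mode(geno) <- "numeric")
  genotype_table(tab$line_id, tab$cross_id, geno, map)
}

#' Write a genotype table as TSV
#' @param gt a [genotype_table()].
#' @param path output file path.
#' @export
write_genotypes <- function(gt, path) {
  out <- data.frame(line_id = gt$line_id, cross_id = gt$cross_id,
                    gt$genotypes, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("Genotype table:", length(x$line_id), "lines x", ncol(x$genotypes),
      "markers;", length(unique(x$cross_id)), "cross(es)\n")
  invisible(x)
}

#' Construct a phenotype table
#'
#' Long-format replicated phenotypes: one record per (line, replicate).
#'
#' @param line_id character vector.
#' @param cross_id character vector (cross label per record).
#' @param replicate_id integer or character replicate labels.
#' @param value numeric trait values (finite).
#' @param units unit string recorded as an attribute (default "mm").
#' @return An object of class `phenotype_table` (a data.frame).
#' @export
phenotype_table <- function(line_id, cross_id, replicate_id, value,
                            units = "mm") {
  value <- as.numeric(value)
  if (any(!is.finite(value))) stop("phenotype values must be finite")
  pt <- data.frame(line_id = as.character(line_id),
                   cross_id = as.character(cross_id),
                   replicate_id = as.character(replicate_id),
                   value = value, stringsAsFactors = FALSE)
  attr(pt, "units") <- units
  class(pt) <- c("phenotype_table", "data.frame")
  pt
}

#' Read a phenotype table (columns line_id, cross_id, replicate_id, value)
#' @param path file path.
#' @return A [phenotype_table()].
#' @export
read_phenotypes <- function(path) {
  tab <- read_delim_auto(path)
  need <- c("line_id", "cross_id", "replicate_id", "value")
  if (!all(need %in% names(tab)))
    stop("phenotype file must have columns ", paste(need, collapse = ", "))
  phenotype_table(tab$line_id, tab$cross_id, tab$replicate_id,
                  as.numeric(tab$value))
}

#' Write a phenotype table as TSV
#' @param pt a [phenotype_table()].
#' @param path output file path.
#' @export
write_phenotypes <- function(pt, path) {
  utils::write.table(as.data.frame(pt), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# per-line replicate means, named by line id (mapping is done on line means)
line_means <- function(phenos) {
  tapply(phenos$value, phenos$line_id, mean)
}
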