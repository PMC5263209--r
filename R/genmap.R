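#' Construct a genetic map
#'
#' A genetic map is the coordinate system for the whole package: an ordered
#' set of markers with a chromosome label and a centimorgan position.
#' Markers are sorted within chromosome by position; chromosome order follows
#' first appearance.
#'
#' @param marker character vector of unique marker names.
#' @param chromosome character vector of chromosome labels (e.g. "1H".."7H").
#' @param position numeric vector of cM positions, all >= 0.
#' @return An object of class `genetic_map`: a data.frame with columns
#'   `marker`, `chromosome`, `position`, sorted per chromosome.
#' @examples
#' gm <- genetic_map(c("m1", "m2", "m3"), c("1H", "1H", "2H"), c(0, 5, 0))
#' @export
genetic_map <- function(marker, chromosome, position) {
  marker <- as.character(marker)
  chromosome <- as.character(chromosome)
  position <- as.numeric(position)
  if (length(marker) != length(chromosome) || length(marker) != length(position))
    stop("marker, chromosome and position must have equal length")
  if (anyNA(position) || any(!is.finite(position)))
    stop("non-numeric or missing cM position in genetic map")
  if (any(position < 0))
    stop("cM positions must be >= 0")
  dup <- unique(marker[duplicated(marker)])
  if (length(dup))
    stop("duplicate marker name(s) in genetic map: ", paste(dup, collapse = ", "))
  chrom_order <- unique(chromosome)
  ord <- order(match(chromosome, chrom_order), position)
  gm <- data.frame(marker = marker[ord], chromosome = chromosome[ord],
                   position = position[ord], stringsAsFactors = FALSE)
  class(gm) <- c("genetic_map", "data.frame")
  gm
}

#' Read a genetic map from delimited text
#'
#' Expects a header with columns `marker`, `chromosome`, `position`
#' (tab- or comma-delimited; detected from the header line).
#'
#' @param path file path.
#' @return A [genetic_map()].
#' @export
read_genetic_map <- function(path) {
  tab <- read_delim_auto(path)
  need <- c("marker", "chromosome", "position")
  if (!all(need %in% names(tab)))
    stop("genetic map file must have columns marker, chromosome, position")
  pos <- suppressWarnings(as.numeric(tab$position))
  bad <- which(is.na(pos) & !is.na(tab$position) & tab$position != "NA")
  if (length(bad))
    stop("non-numeric position at data line ", bad[1],
         " of ", path, ": '", tab$position[bad[1]], "'")
  genetic_map(tab$marker, tab$chromosome, pos)
}

#' Write a genetic map as TSV
#' @param map a [genetic_map()].
#' @param path output file path.
#' @export
write_genetic_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("Genetic map:", nrow(x), "markers on",
      length(unique(x$chromosome)), "chromosome(s)\n")
  for (ch in unique(x$chromosome)) {
    p <- x$position[x$chromosome == ch]
    cat(sprintf("  %-4s %3d markers, %.1f-%.1f cM\n", ch, length(p),
                min(p), max(p)))
  }
  invisible(x)
}

# chromosome lengths in cM; by default the last marker position (a map can
# carry an explicit length attribute set by the simulator)
map_chrom_lengths <- function(map) {
  len <- attr(map, "chrom_lengths")
  if (!is.null(len)) return(len)
  vapply(split(map$position, factor(map$chromosome,
                                    levels = unique(map$chromosome))),
         max, numeric(1))
}

map_chromosomes <- function(map) unique(map$chromosome)

# internal: sniff delimiter (tab wins if present in header) and read
read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = "NA")
}
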