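#' Broad-sense heritability from replicated lines
#'
#' One-way random-effects ANOVA on line: the genetic variance component is
#' `max(0, (MS_line - MS_error) / r)` with `r` the harmonic-mean replicate
#' count, and the plot-basis heritability is
#' `H2 = s2_G / (s2_G + s2_E)` with `s2_E = MS_error`.
#'
#' @param phenos a [phenotype_table()] (or data.frame with `line_id` and
#'   `value`). Lines with a single replicate are excluded with a warning.
#' @return An object of class `heritability`: list with `h2`, `s2_G`,
#'   `s2_E`, `n_lines`, `r_harmonic`.
#' @export
broad_h2 <- function(phenos) {
  reps <- table(phenos$line_id)
  single <- names(reps)[reps < 2]
  if (length(single)) {
    warning(length(single), " line(s) with a single replicate excluded")
    phenos <- phenos[!phenos$line_id %in% single, , drop = FALSE]
  }
  if (length(unique(phenos$line_id)) < 2)
    stop("at least two lines with >= 2 replicates required")
  # one-way mean squares computed directly (anova() F statistics are not
  # needed and warn on noise-free fits)
  reps <- table(phenos$line_id)
  ybar <- tapply(phenos$value, phenos$line_id, mean)
  grand <- mean(phenos$value)
  ss_line <- sum(as.numeric(reps) * (ybar[names(reps)] - grand)^2)
  ss_err <- sum((phenos$value - ybar[phenos$line_id])^2)
  ms_line <- ss_line / (length(reps) - 1)
  ms_err <- ss_err / (nrow(phenos) - length(reps))
  r_h <- length(reps) / sum(1 / as.numeric(reps))
  s2_g <- max(0, (ms_line - ms_err) / r_h)
  h2 <- s2_g / (s2_g + ms_err)
  structure(list(h2 = min(max(h2, 0), 1), s2_G = s2_g, s2_E = ms_err,
                 n_lines = length(reps), r_harmonic = r_h),
            class = "heritability")
}

#' @export
print.heritability <- function(x, ...) {
  cat(sprintf(
    "Broad-sense heritability (plot basis): H2 = %.3f\n  s2_G = %.3f, s2_E = %.3f (%d lines, harmonic-mean r = %.2f)\n",
    x$h2, x$s2_G, x$s2_E, x$n_lines, x$r_harmonic))
  invisible(x)
}

#' Group means relative to a reference group
#'
#' Per group: mean, SD, n and the percentage of the reference group's mean
#' (reference = 100), rounded half-up to one decimal.
#'
#' @param values numeric phenotype values.
#' @param group group label per value.
#' @param reference label of the reference (control) group.
#' @return data.frame (group, mean, sd, n, percent_of_reference) with the
#'   reference first.
#' @export
relative_trait <- function(values, group, reference) {
  group <- as.character(group)
  if (!reference %in% group) stop("reference group not present")
  labs <- c(reference, setdiff(unique(group), reference))
  ref_mean <- mean(values[group == reference])
  if (ref_mean == 0) stop("reference group mean is zero")
  out <- do.call(rbind, lapply(labs, function(g) {
    v <- values[group == g]
    data.frame(group = g, mean = mean(v), sd = stats::sd(v),
               n = length(v),
               percent_of_reference = round_half_up(
                 100 * mean(v) / ref_mean, 1),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# round half away from zero at `digits` (base round() is half-to-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
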