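#' @export
print.scan_profile <- function(x, ...) {
  cat("Genome scan profile:", nrow(x), "loci on",
      length(unique(x$chromosome)), "chromosome(s)\n")
  top <- x[which.max(x$minus_log10_p), ]
  cat(sprintf("  max -log10(p) = %.2f at %s (%s, %.1f cM)\n",
              top$minus_log10_p, top$locus, top$chromosome, top$position))
  cf <- attr(x, "cofactors")
  if (length(cf)) cat("  cofactors:", paste(cf, collapse = ", "), "\n")
  invisible(x)
}

#' Plot a genome-scan profile
#'
#' -log10(p) against cumulative map position, one panel colour block per
#' chromosome, with an optional horizontal significance threshold.
#'
#' @param x a `scan_profile`.
#' @param threshold significance line in -log10(p) units (default 3.2).
#' @param ... passed to [graphics::plot()].
#' @export
plot.scan_profile <- function(x, threshold = 3.2, ...) {
  chroms <- unique(x$chromosome)
  offs <- stats::setNames(numeric(length(chroms)), chroms)
  run <- 0
  for (ch in chroms) {
    offs[ch] <- run
    run <- run + max(x$position[x$chromosome == ch]) + 5
  }
  gx <- x$position + offs[x$chromosome]
  graphics::plot(gx, x$minus_log10_p, type = "n",
                 xlab = "map position (cM, chromosomes concatenated)",
                 ylab = expression(-log[10](p)), ...)
  for (ch in chroms) {
    sel <- x$chromosome == ch
    graphics::lines(gx[sel], x$minus_log10_p[sel],
                    col = if (match(ch, chroms) %% 2) "grey25" else "steelblue")
  }
  graphics::abline(h = threshold, lty = 2, col = "firebrick")
  graphics::mtext(chroms, side = 3, at = offs + c(by_chrom_mid <- vapply(
    chroms, function(ch) max(x$position[x$chromosome == ch]) / 2,
    numeric(1))), cex = 0.7)
  invisible(x)
}

#' @export
print.qtl_scan <- function(x, ...) {
  cat("Multi-QTL scan:", nrow(x$qtls), "QTL(s) at threshold",
      x$threshold, "\n")
  if (nrow(x$qtls)) print(x$qtls, row.names = FALSE)
  invisible(x)
}

#' @export
summary.qtl_scan <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
print.qtl_fit <- function(x, digits = 2, ...) {
  cat("Joint founder-effect QTL model (", length(x$loci), " QTL, ",
      x$model$n, " lines)\n", sep = "")
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-7s %s %6.1f cM  -log10(p) = %5.1f  [%s | %s]\n",
                tab$name[i], tab$chromosome[i], tab$position[i],
                tab$minus_log10_p[i], tab$flank1[i], tab$flank2[i]))
    eff <- x$effects[i, ]
    se <- x$se[i, ]
    cat("    effects vs ", x$recipient, ": ",
        paste(sprintf("%s %+.*f +/- %.*f", names(eff), digits, eff,
                      digits, se), collapse = ", "),
        if (!is.null(x$units)) paste0(" (", x$units, ")"), "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.qtl_fit <- function(object, ...) {
  cat("Residual SD per cross:\n")
  print(round(sqrt(object$model$s2_resid), 3))
  cat("Cross means:\n")
  print(round(object$model$beta, 3))
  print(object)
  invisible(object)
}

#' Founder-effect estimates of a fitted QTL model
#'
#' @param object a `qtl_fit`.
#' @param ... unused.
#' @return QTL x wild-founder matrix of effects (deviations from the
#'   recipient, trait units).
#' @export
coef.qtl_fit <- function(object, ...) object$effects

#' Fitted line means from the joint QTL model
#'
#' @param object a `qtl_fit`.
#' @param fp the `founder_probs` tensor the model was fitted on.
#' @param ... unused.
#' @return Named vector of fitted line means (fixed cross means plus
#'   predicted founder-effect contributions of every QTL).
#' @export
predict.qtl_fit <- function(object, fp, ...) {
  sd <- object$data
  li <- .locus_index(fp, object$loci)
  yhat <- as.vector(sd$X %*% object$model$beta)
  for (j in seq_along(li)) {
    Z <- .locus_Z(fp, sd$rows, sd$wild, li[j])
    yhat <- yhat + as.vector(Z %*% object$model$blup[[j]])
  }
  stats::setNames(yhat, sd$ids)
}

#' Residual line means of the joint QTL model
#'
#' @param object a `qtl_fit`.
#' @param fp the `founder_probs` tensor the model was fitted on.
#' @param ... unused.
#' @export
residuals.qtl_fit <- function(object, fp, ...) {
  object$data$y - predict(object, fp)
}

#' Write a QTL result table as TSV (one row per QTL, founder effects and
#' standard errors in columns)
#'
#' @param fit a `qtl_fit`.
#' @param path output file path.
#' @export
write_qtl_table <- function(fit, path) {
  eff <- fit$effects
  se <- fit$se
  colnames(eff) <- paste0("effect_", colnames(eff))
  colnames(se) <- paste0("se_", colnames(se))
  out <- cbind(fit$table, as.data.frame(eff), as.data.frame(se))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
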