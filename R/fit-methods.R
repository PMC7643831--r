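#' @export
print.barseq_fit <- function(x, ...) {
  cat("BarSeq phage-selection fitness fit\n")
  if (!is.null(x$call)) {
    cat("Call: ")
    print(x$call)
  }
  res <- x$results
  cat(sprintf("%d genes scored (%d dropped by the <%d-barcode filter, %d unmapped barcodes)\n",
              nrow(res), x$n_genes_filtered, x$min_barcodes, x$n_unmapped))
  if (!is.null(x$thresholds)) {
    thr <- x$thresholds
    cat(sprintf("Significance band: [%.4g, %.4g] = bootstrapped mean %.4g +/- %g x SD %.4g (%s)\n",
                thr$lower, thr$upper, thr$m_star, thr$k_sd, thr$s,
                thr$sd_method))
    cat(sprintf("Calls: %d resistant, %d sensitive\n",
                sum(res$significant == "resistant"),
                sum(res$significant == "sensitive")))
  }
  if (nrow(res)) {
    cat("Top genes by fitness:\n")
    print(head(res, 5L), digits = 4)
  }
  invisible(x)
}

#' Summarize a BarSeq fitness fit
#'
#' @param object A `barseq_fit`.
#' @param ... Unused.
#' @return A list of class `summary.barseq_fit` with the per-gene table,
#'   the thresholds, and call counts.
#' @method summary barseq_fit
#' @export
summary.barseq_fit <- function(object, ...) {
  res <- object$results
  out <- list(
    n_genes = nrow(res),
    n_resistant = sum(res$significant == "resistant"),
    n_sensitive = sum(res$significant == "sensitive"),
    fitness_range = if (nrow(res)) range(res$fitness[is.finite(res$fitness)])
                    else c(NA_real_, NA_real_),
    thresholds = object$thresholds,
    significant_genes = res[res$significant != "none", , drop = FALSE]
  )
  class(out) <- "summary.barseq_fit"
  out
}

#' @export
print.summary.barseq_fit <- function(x, ...) {
  cat(sprintf("%d genes scored; fitness range [%.3f, %.3f]\n",
              x$n_genes, x$fitness_range[1], x$fitness_range[2]))
  if (!is.null(x$thresholds))
    cat(sprintf("Thresholds: lower %.4f, upper %.4f\n",
                x$thresholds$lower, x$thresholds$upper))
  cat(sprintf("Significant: %d resistant, %d sensitive\n",
              x$n_resistant, x$n_sensitive))
  if (nrow(x$significant_genes)) {
    cat("Significant genes:\n")
    print(x$significant_genes, digits = 4)
  }
  invisible(x)
}

#' Extract per-gene fitness scores
#'
#' @param object A `barseq_fit`.
#' @param ... Unused.
#' @return Named numeric vector of log2 fitness scores, sorted descending.
#' @method coef barseq_fit
#' @export
coef.barseq_fit <- function(object, ...) {
  setNames(object$results$fitness, object$results$gene_id)
}

#' Plot the fitness-score distribution of a fit
#'
#' Histogram of finite per-gene fitness scores with the bootstrap
#' significance band marked; genes beyond the band are the significant
#' calls.
#'
#' @param x A `barseq_fit`.
#' @param ... Passed to [graphics::hist()].
#' @method plot barseq_fit
#' @export
plot.barseq_fit <- function(x, ...) {
  f <- x$results$fitness[is.finite(x$results$fitness)]
  graphics::hist(f, breaks = 50, main = "Gene fitness scores",
                 xlab = expression(log[2] ~ "fitness score"), ...)
  if (!is.null(x$thresholds)) {
    graphics::abline(v = c(x$thresholds$lower, x$thresholds$upper),
                     col = "red", lty = 2)
    graphics::abline(v = x$thresholds$m_star, col = "grey40", lty = 3)
  }
  invisible(x)
}

#' Write the per-gene fitness table and thresholds to disk
#'
#' @param fit A `barseq_fit`.
#' @param fitness_path Output TSV path for the per-gene table.
#' @param thresholds_path Optional JSON path for the threshold parameters.
#' @return `fitness_path`, invisibly.
#' @export
write_fitness <- function(fit, fitness_path, thresholds_path = NULL) {
  stopifnot(inherits(fit, "barseq_fit"))
  res <- fit$results
  names(res)[names(res) == "fitness"] <- "fitness_log2"
  write.table(res, fitness_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(thresholds_path) && !is.null(fit$thresholds))
    jsonlite::write_json(unclass(fit$thresholds), thresholds_path,
                         auto_unbox = TRUE, digits = NA)
  invisible(fitness_path)
}
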