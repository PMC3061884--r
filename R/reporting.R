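#' Summarize a co-occurrence screen
#'
#' Screen-level counts in the layout used for cohort statistics tables:
#' total tested associations, intra-chromosomal count, cutoff, empirical
#' FDR at the cutoff, number of associations passing, and the
#' inter-chromosomal share of those.
#'
#' @param results an `association_table` from [run_screen()].
#' @param alpha p-value cutoff; defaults to the one recorded in the
#'   table's config.
#' @return list of class `screen_summary`.
#' @export
summarize_screen <- function(results, alpha = NULL) {
  if (is.null(alpha)) {
    cfg <- attr(results, "config")
    alpha <- if (!is.null(cfg)) cfg$alpha else 0.05
  }
  passing <- results$p_value <= alpha
  structure(list(
    total = nrow(results),
    intra = sum(results$class == "intra"),
    alpha = alpha,
    fdr = estimate_fdr(alpha, nrow(results), sum(passing)),
    passing = sum(passing),
    inter_passing = sum(passing & results$class == "inter")
  ), class = "screen_summary")
}

#' @export
print.screen_summary <- function(x, ...) {
  cat("co-occurrence screen summary\n",
      "  associations tested: ", x$total,
      " (intra-chromosomal: ", x$intra, ")\n",
      "  p-value cutoff:      ", x$alpha, "\n",
      "  passing cutoff:      ", x$passing,
      " (inter-chromosomal: ", x$inter_passing, ")\n",
      "  empirical FDR:       ",
      if (is.na(x$fdr)) "NA (no discoveries)" else sprintf("%.4f", x$fdr),
      "\n", sep = "")
  invisible(x)
}

#' Select the strongest associations of a screen
#'
#' Applies the requested filters, then sorts by co-occurrence frequency
#' (descending) with a deterministic id-lexicographic tie-break, and
#' truncates to the first `N` rows.
#'
#' @param results an `association_table`.
#' @param N maximum rows returned.
#' @param inter_only keep only inter-chromosomal pairs.
#' @param significant_only keep only pairs flagged significant.
#' @return filtered, sorted data.frame (possibly shorter than `N`).
#' @export
select_top <- function(results, N = 100L, inter_only = FALSE,
                       significant_only = TRUE) {
  x <- as.data.frame(results)
  if (inter_only) x <- x[x$class == "inter", , drop = FALSE]
  if (significant_only) x <- x[x$significant, , drop = FALSE]
  ord <- order(-x$frequency, x$cat_a, x$cat_b, method = "radix")
  x <- x[ord, , drop = FALSE]
  rownames(x) <- NULL
  head(x, N)
}

#' Write / read an association table as TSV
#'
#' Tab-delimited with the screen columns; provenance (package version,
#' seed, config) is written as leading `#` comment lines so the file is
#' self-describing while staying machine-readable.
#'
#' @param results an `association_table`.
#' @param path output file.
#' @param header_lines extra provenance lines; the config line is added
#'   automatically when the table carries one.
#' @return the path, invisibly.
#' @export
write_association_table <- function(results, path, header_lines = NULL) {
  cfg <- attr(results, "config")
  prov <- c(paste0("cdcoca ", as.character(utils::packageVersion("cdcoca"))),
            if (!is.null(cfg)) {
              paste0("config: mode=", cfg$mode, " S=", cfg$S,
                     " seed=", cfg$seed, " alpha=", cfg$alpha,
                     " min_cooccurrence=", cfg$min_cooccurrence,
                     " smooth_p=", cfg$smooth_p)
            },
            header_lines)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", prov), con)
  out <- as.data.frame(results)
  num <- vapply(out, is.double, TRUE)
  out[num] <- lapply(out[num], function(v) format(v, digits = 15, trim = TRUE))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_association_table
#' @export
read_association_table <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Export significant pairs as a SIF edge list
#'
#' One line per significant association, `cat_a co cat_b`, for network
#' viewers such as Cytoscape.
#'
#' @param results an `association_table`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_sif <- function(results, path) {
  sig <- results[results$significant, , drop = FALSE]
  writeLines(paste(sig$cat_a, "co", sig$cat_b), path)
  invisible(path)
}
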