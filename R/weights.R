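#' Per-sample complexity weights
#'
#' The prior probability weight of sample r is its share of the cohort's
#' alterations,
#' \deqn{Pw_r = \sum_j D_{rj} / \sum_i \sum_j D_{ij},}
#' computed on the full post-filter status matrix (the pair of columns
#' under test is never excluded). Samples without any CNA get weight 0;
#' the weights of altered samples sum to 1. Under the complexity-corrected
#' null, carriers are redrawn with probability proportional to these
#' weights, so overlaps concentrated in high-burden ("CNA complex")
#' samples are expected and discounted.
#'
#' @param D a `cna_matrix`.
#' @return named numeric vector of weights aligned to the sample ids.
#' @export
sample_weights <- function(D) {
  validate_status_matrix(D)
  rs <- rowSums(unclass(D))
  tot <- sum(rs)
  if (tot == 0) stop("no alterations in matrix")
  setNames(rs / tot, rownames(D))
}

#' Arm-level genomic complexity score
#'
#' A descriptive surrogate for genomic complexity: each chromosome arm is
#' scored independently for the presence of gains and of losses (1 point
#' each), so a chromosome contributes at most 4 (both directions on both
#' arms); arm scores are summed over the genome per sample.
#'
#' @param D a `cna_matrix`, or a long data.frame with columns `sample`,
#'   `chrom`, `arm`, `direction`.
#' @return named integer vector of per-sample scores.
#' @export
complexity_score <- function(D) {
  if (is.matrix(D)) {
    validate_status_matrix(D)
    info <- parse_category(colnames(D))
    long <- data.frame(
      sample = rownames(D)[row(D)[D == 1L]],
      chrom = info$chrom[col(D)[D == 1L]],
      arm = info$arm[col(D)[D == 1L]],
      direction = info$direction[col(D)[D == 1L]],
      stringsAsFactors = FALSE
    )
    samples <- rownames(D)
  } else {
    long <- as.data.frame(D, stringsAsFactors = FALSE)
    need <- c("sample", "chrom", "arm", "direction")
    if (!all(need %in% names(long))) {
      stop("need columns: ", paste(need, collapse = ", "))
    }
    if (!all(long$arm %in% c("p", "q"))) {
      stop("unknown arm label(s): ",
           paste(unique(long$arm[!long$arm %in% c("p", "q")]), collapse = ", "))
    }
    samples <- unique(long$sample)
  }
  units <- unique(long[, c("sample", "chrom", "arm", "direction")])
  score <- table(factor(units$sample, levels = samples))
  setNames(as.integer(score), samples)
}
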