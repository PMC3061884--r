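#' Jaccard index of two binary columns
#'
#' `J = N11 / (N11 + N10 + N01)` where the counts come from the 2x2
#' contingency table of the two carrier sets. Both columns all-zero
#' returns 0 by convention (such columns are filtered out upstream).
#'
#' @param a,b binary vectors of equal length.
#' @return J in \[0, 1\].
#' @export
jaccard_index <- function(a, b) {
  if (length(a) != length(b)) stop("column length mismatch")
  n11 <- sum(a == 1L & b == 1L)
  den <- sum(a == 1L | b == 1L)
  if (den == 0L) return(0)
  n11 / den
}

#' Observed statistics for one category pair
#'
#' Fills the contingency counts (`N11`, `N10`, `N01`), the Jaccard index,
#' the co-occurrence frequency `F_jk = N11 / n`, and the pair
#' classification for categories j and k of a status matrix.
#'
#' @param D a `cna_matrix`.
#' @param j,k category ids or column indices; must differ.
#' @return list with fields `cat_a`, `cat_b`, `N11`, `N10`, `N01`,
#'   `F_a`, `F_b`, `jaccard`, `frequency`, `class`, `bidirectional`.
#' @export
pair_statistics <- function(D, j, k) {
  validate_status_matrix(D)
  if (!is.character(j)) j <- colnames(D)[j]
  if (!is.character(k)) k <- colnames(D)[k]
  if (identical(j, k)) stop("self-pair: ", j)
  a <- D[, j]
  b <- D[, k]
  n11 <- sum(a & b)
  n10 <- sum(a & !b)
  n01 <- sum(!a & b)
  cls <- classify_pair(j, k)
  list(cat_a = j, cat_b = k, N11 = n11, N10 = n10, N01 = n01,
       F_a = n11 + n10, F_b = n11 + n01,
       jaccard = if (n11 + n10 + n01 > 0) n11 / (n11 + n10 + n01) else 0,
       frequency = n11 / nrow(D),
       class = cls$class, bidirectional = cls$bidirectional)
}

#' Enumerate the pair universe of a screen
#'
#' All unordered category pairs (j < k in the matrix's genome order) whose
#' observed co-occurrence count `N11` reaches a threshold. The default
#' threshold of 1 restricts the screen to pairs observed together at least
#' once; `min_cooccurrence = 0` yields all m(m-1)/2 pairs.
#'
#' @param D a `cna_matrix`.
#' @param min_cooccurrence integer >= 0.
#' @return data.frame with columns `cat_a`, `cat_b`, `N11`.
#' @export
enumerate_pairs <- function(D, min_cooccurrence = 1L) {
  validate_status_matrix(D)
  if (min_cooccurrence < 0L) stop("min_cooccurrence must be >= 0")
  M <- unclass(D)
  co <- crossprod(M) # N11 for every ordered pair
  idx <- which(upper.tri(co), arr.ind = TRUE)
  keep <- co[idx] >= min_cooccurrence
  idx <- idx[keep, , drop = FALSE]
  out <- data.frame(
    cat_a = colnames(D)[idx[, 1L]],
    cat_b = colnames(D)[idx[, 2L]],
    N11 = as.integer(co[idx]),
    stringsAsFactors = FALSE
  )
  out[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}

#' Classify a category pair
#'
#' A pair is intra-chromosomal iff both categories sit on the same
#' chromosome; an intra-chromosomal pair of opposite directions (a gain
#' and a loss on the same chromosome, e.g. loss of 8p with gain of 8q) is
#' additionally flagged as a "bidirectional" change.
#'
#' @param j,k category ids.
#' @return list with `class` (`"intra"` or `"inter"`) and logical
#'   `bidirectional`.
#' @export
classify_pair <- function(j, k) {
  p <- parse_category(c(j, k))
  intra <- p$chrom[1L] == p$chrom[2L]
  list(class = if (intra) "intra" else "inter",
       bidirectional = intra && p$direction[1L] != p$direction[2L])
}
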