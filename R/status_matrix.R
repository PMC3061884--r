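#' Construct a binary CNA status matrix
#'
#' The status matrix `D` is the n x m binary sample-by-category matrix all
#' co-occurrence statistics run on. Each cytogenetic band contributes up to
#' two categories, a gain (`"g-<band>"`) and a loss (`"l-<band>"`); entry
#' `D[i, j] = 1` iff sample i carries category j.
#'
#' @param x either a long data.frame of flagged statuses with columns
#'   `sample`, `band` (full label, e.g. `"c1p11"`) and `direction`
#'   (`"g"`/`"l"`) — as produced by [map_segments_to_bands()] — or a wide
#'   sample-by-band table with values in \{-1, 0, +1\} (row names or a
#'   first column `sample` as sample ids; column names are band labels).
#' @param drop_sex drop all X/Y categories before any other filtering.
#' @param drop_empty drop categories altered in zero samples after the sex
#'   filter, so every remaining column has frequency `F_j >= 1`.
#' @param samples optional character vector fixing the sample roster and
#'   row order; samples without any alteration are kept (all-zero rows,
#'   zero complexity weight). Defaults to the samples present in the
#'   input (all rows for wide input, flagged samples for long input).
#' @return An integer matrix of class `cna_matrix` with sample ids as row
#'   names and category ids as column names, columns in deterministic
#'   genome order (all gains, then all losses).
#' @export
build_status_matrix <- function(x, drop_sex = TRUE, drop_empty = TRUE,
                                samples = NULL) {
  if (is.data.frame(x) && all(c("sample", "band", "direction") %in% names(x))) {
    long <- data.frame(sample = as.character(x$sample),
                       category = paste0(x$direction, "-", x$band),
                       stringsAsFactors = FALSE)
  } else {
    wl <- wide_to_long(x)
    long <- wl$long
    if (is.null(samples)) samples <- wl$samples
  }
  long <- unique(long) # duplicate flags collapse to a single 1
  if (is.null(samples)) {
    samples <- unique(long$sample)
  } else {
    if (anyDuplicated(samples)) stop("duplicate sample id(s)")
    missing <- setdiff(long$sample, samples)
    if (length(missing)) {
      stop("flagged sample(s) not in roster: ", paste(missing, collapse = ", "))
    }
  }
  cats <- unique(long$category)
  info <- parse_category(cats) # validates ids
  if (drop_sex) {
    keep <- !(info$chrom %in% c("X", "Y"))
    cats <- cats[keep]
    long <- long[long$category %in% cats, , drop = FALSE]
  }
  if (length(cats) == 0L) stop("no categories left after filtering")
  D <- matrix(0L, length(samples), length(cats),
              dimnames = list(samples, cats))
  D[cbind(match(long$sample, samples), match(long$category, cats))] <- 1L
  if (drop_empty) D <- D[, colSums(D) >= 1L, drop = FALSE]
  D <- D[, order_categories(colnames(D)), drop = FALSE]
  as_cna_matrix(D)
}

# wide sample x band table with -1/0/+1 entries -> long (sample, category)
wide_to_long <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if ("sample" %in% names(x)) {
    ids <- as.character(x$sample)
    x <- x[, setdiff(names(x), "sample"), drop = FALSE]
  } else {
    ids <- rownames(x)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sample id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  m <- as.matrix(x)
  mode(m) <- "numeric"
  bad <- which(array(!(m %in% c(-1, 0, 1)), dim(m)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("value outside {-1,0,1} at sample '", ids[bad[1, 1]],
         "', band '", colnames(m)[bad[1, 2]], "'")
  }
  g <- which(m == 1, arr.ind = TRUE)
  l <- which(m == -1, arr.ind = TRUE)
  list(long = data.frame(
    sample = c(ids[g[, 1]], ids[l[, 1]]),
    category = c(paste0("g-", colnames(m)[g[, 2]]),
                 paste0("l-", colnames(m)[l[, 2]])),
    stringsAsFactors = FALSE
  ), samples = ids)
}

as_cna_matrix <- function(D) {
  storage.mode(D) <- "integer"
  class(D) <- c("cna_matrix", class(D))
  validate_status_matrix(D)
  D
}

#' Validate a status matrix
#'
#' Checks the `cna_matrix` invariants: binary entries, unique sample and
#' category ids, parseable category ids.
#'
#' @param D matrix to validate.
#' @return `D`, invisibly; stops on violation.
#' @export
validate_status_matrix <- function(D) {
  if (!is.matrix(D) || nrow(D) == 0L) stop("no samples")
  if (ncol(D) == 0L) stop("no categories")
  if (is.null(rownames(D)) || is.null(colnames(D))) {
    stop("sample and category ids required as dimnames")
  }
  if (!all(D %in% c(0L, 1L))) stop("non-binary entries in status matrix")
  if (anyDuplicated(rownames(D))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(D))) stop("duplicate category ids")
  parse_category(colnames(D))
  invisible(D)
}

#' Per-category alteration frequency
#'
#' `F_j`, the number of samples carrying category j, recomputed from the
#' matrix.
#'
#' @param D a `cna_matrix`.
#' @return named integer vector of column sums.
#' @export
category_freq <- function(D) {
  f <- colSums(unclass(D))
  storage.mode(f) <- "integer"
  f
}

#' @export
print.cna_matrix <- function(x, ...) {
  cat("CNA status matrix: ", nrow(x), " samples x ", ncol(x),
      " categories, ", sum(x), " alterations\n", sep = "")
  invisible(x)
}

#' Read / write a status matrix as TSV
#'
#' The on-disk format is a tab-delimited table: header row of category ids,
#' first column of sample ids (header `sample`), body entries in \{0, 1\}.
#' Comment lines starting with `#` are ignored on read. The round trip
#' `write` then `read` is bit-exact.
#'
#' @param path file path.
#' @return `read_status_matrix` returns a `cna_matrix`.
#' @export
read_status_matrix <- function(path) {
  tab <- read.delim(path, header = TRUE, check.names = FALSE,
                    comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("no samples in ", path)
  if (ncol(tab) < 2L) stop("no categories in ", path)
  ids <- as.character(tab[[1L]])
  D <- as.matrix(tab[, -1L, drop = FALSE])
  mode(D) <- "numeric"
  bad <- which(array(!(D %in% c(0, 1)), dim(D)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-binary cell in ", path, " at data row ", bad[1, 1],
         " (sample '", ids[bad[1, 1]], "'), column '",
         colnames(D)[bad[1, 2]], "'")
  }
  rownames(D) <- ids
  as_cna_matrix(D)
}

#' @param D a `cna_matrix`.
#' @param header_lines optional character vector of provenance lines written
#'   as leading `#` comments.
#' @rdname read_status_matrix
#' @export
write_status_matrix <- function(D, path, header_lines = NULL) {
  validate_status_matrix(D)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  writeLines(paste(c("sample", colnames(D)), collapse = "\t"), con)
  body <- apply(unclass(D), 1L, paste, collapse = "\t")
  writeLines(paste(rownames(D), body, sep = "\t"), con)
  invisible(path)
}
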