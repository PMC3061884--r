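#' Load a cytoband scheme from a UCSC cytoBand-format table
#'
#' Reads a tab-delimited table in UCSC `cytoBand.txt` layout
#' (`chrom`, `chromStart`, `chromEnd`, `name`, `gieStain`; 0-based
#' half-open coordinates) and validates it as a genome scaffold for
#' band-level CNA calling. Chromosome labels are normalized by stripping
#' a leading `"chr"`.
#'
#' @param source path to the table, or a data.frame with the five UCSC
#'   columns (header optional in the file; UCSC ships the file headerless).
#' @param genome free-text genome label stored on the scheme.
#' @return An object of class `cytoband_scheme`: a data.frame with columns
#'   `chrom`, `start`, `end`, `name`, `arm`, plus attribute `genome`.
#'   Rows are sorted by genome position.
#' @export
load_cytobands <- function(source, genome = "custom") {
  if (is.character(source)) {
    first <- readLines(source, n = 1L)
    has_header <- grepl("chromStart|\\bstart\\b", first, ignore.case = TRUE)
    tab <- read.delim(source, header = has_header, stringsAsFactors = FALSE)
  } else {
    tab <- as.data.frame(source, stringsAsFactors = FALSE)
  }
  if (ncol(tab) < 4L) stop("cytoband table needs >= 4 columns (chrom, start, end, name)")
  tab <- tab[, 1:4]
  names(tab) <- c("chrom", "start", "end", "name")
  tab$chrom <- sub("^chr", "", as.character(tab$chrom))
  tab$start <- as.numeric(tab$start)
  tab$end <- as.numeric(tab$end)
  tab$name <- as.character(tab$name)
  chrom_rank(unique(tab$chrom)) # validates labels

  bad_len <- which(!(tab$start < tab$end))
  if (length(bad_len)) {
    stop("zero-length or inverted band(s) at row(s): ",
         paste(bad_len, collapse = ", "))
  }
  tab$arm <- substr(tab$name, 1L, 1L)
  if (!all(tab$arm %in% c("p", "q"))) {
    stop("band name(s) not starting with p/q arm: ",
         paste(unique(tab$name[!tab$arm %in% c("p", "q")]), collapse = ", "))
  }
  tab <- tab[order(chrom_rank(tab$chrom), tab$start), , drop = FALSE]
  rownames(tab) <- NULL

  # non-overlap within chromosome (half-open intervals)
  for (ch in unique(tab$chrom)) {
    b <- tab[tab$chrom == ch, , drop = FALSE]
    if (nrow(b) > 1L) {
      ov <- which(b$start[-1L] < b$end[-nrow(b)])
      if (length(ov)) {
        stop("overlapping bands on chromosome ", ch, ": ",
             paste(b$name[ov], "/", b$name[ov + 1L], collapse = "; "))
      }
    }
    if (anyDuplicated(b$name)) {
      stop("duplicate band name(s) on chromosome ", ch, ": ",
           paste(unique(b$name[duplicated(b$name)]), collapse = ", "))
    }
  }
  structure(tab, genome = genome, class = c("cytoband_scheme", "data.frame"))
}

#' @export
print.cytoband_scheme <- function(x, ...) {
  cat("cytoband scheme (", attr(x, "genome"), "): ", nrow(x), " bands on ",
      length(unique(x$chrom)), " chromosomes\n", sep = "")
  invisible(x)
}

# full band label used in category ids: "c<chrom><band>", e.g. "c1p11"
band_label <- function(chrom, name) {
  if (length(chrom) == 0L) return(character(0)) # paste0 would recycle "c"
  paste0("c", chrom, name)
}

#' Map per-sample segment calls onto cytogenetic bands
#'
#' A band is flagged as gained and/or lost for a sample iff any segment of
#' that direction overlaps the band by at least one base pair (half-open
#' interval intersection, matching the UCSC 0-based half-open convention).
#' A band may carry both directions for the same sample.
#'
#' @param calls data.frame with columns `sample`, `chrom`, `start`, `end`,
#'   `status` (`"gain"`/`"loss"`, or `+1`/`-1`).
#' @param scheme a [load_cytobands()] scheme.
#' @return data.frame with columns `sample`, `chrom`, `band` (full label,
#'   e.g. `"c1p11"`), `direction` (`"g"`/`"l"`); one row per flagged
#'   (sample, band, direction), deduplicated.
#' @export
map_segments_to_bands <- function(calls, scheme) {
  calls <- as.data.frame(calls, stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "start", "end", "status")
  if (!all(need %in% names(calls))) {
    stop("segment calls need columns: ", paste(need, collapse = ", "))
  }
  calls$chrom <- sub("^chr", "", as.character(calls$chrom))
  st <- as.character(calls$status)
  dir <- ifelse(st %in% c("gain", "1", "+1"), "g",
                ifelse(st %in% c("loss", "-1"), "l", NA))
  if (anyNA(dir)) {
    stop("status values must be gain/loss or +1/-1; offending: ",
         paste(unique(st[is.na(dir)]), collapse = ", "))
  }
  if (any(!(calls$start < calls$end))) stop("segment(s) with start >= end")
  unknown <- setdiff(unique(calls$chrom), unique(scheme$chrom))
  if (length(unknown)) {
    stop("chromosome(s) not in scheme: ", paste(unknown, collapse = ", "))
  }

  # half-open -> 1-based closed for IRanges
  seg_gr <- GenomicRanges::GRanges(
    calls$chrom, IRanges::IRanges(calls$start + 1L, calls$end))
  band_gr <- GenomicRanges::GRanges(
    scheme$chrom, IRanges::IRanges(scheme$start + 1L, scheme$end))
  hits <- GenomicRanges::findOverlaps(seg_gr, band_gr, minoverlap = 1L)
  qh <- S4Vectors::queryHits(hits)
  if (length(setdiff(seq_len(nrow(calls)), qh))) {
    orphans <- setdiff(seq_len(nrow(calls)), qh)
    warning(length(orphans), " segment(s) overlap no band and were ignored")
  }
  sh <- S4Vectors::subjectHits(hits)
  out <- data.frame(
    sample = as.character(calls$sample)[qh],
    chrom = scheme$chrom[sh],
    band = band_label(scheme$chrom[sh], scheme$name[sh]),
    direction = dir[qh],
    stringsAsFactors = FALSE
  )
  unique(out)
}

#' Synthetic cytoband scheme shipped with the package
#'
#' Returns the packaged synthetic 320-band scheme (303 autosomal bands plus
#' 17 on X/Y). The scheme is an artificial scaffold with round-number
#' coordinates, built to mirror the granularity of band-resolution CGH
#' data; it is not a real genome assembly's ideogram.
#'
#' @return A `cytoband_scheme`.
#' @export
example_cytobands <- function() {
  path <- system.file("extdata", "cytobands_synthetic_320.tsv",
                      package = "cdcoca", mustWork = TRUE)
  load_cytobands(path, genome = "synthetic-320")
}
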