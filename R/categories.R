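#' Parse CNA category identifiers
#'
#' Category ids encode one (cytogenetic band, direction) pair as
#' `"g-c<chrom><band>"` for gains and `"l-c<chrom><band>"` for losses,
#' e.g. `"g-c1p11"` is a gain of band 1p11 and `"l-c8p23"` a loss of 8p23.
#'
#' @param ids character vector of category ids.
#' @return A data.frame with columns `id`, `direction` (`"g"`/`"l"`),
#'   `chrom` (character, e.g. `"1"`, `"X"`), `arm` (`"p"`/`"q"`) and
#'   `band` (the arm-local band label, e.g. `"p11"`).
#' @examples
#' parse_category(c("g-c1p11", "l-c8q24.1"))
#' @export
parse_category <- function(ids) {
  m <- regmatches(ids, regexec("^([gl])-c([0-9]+|X|Y)([pq][0-9.]*)$", ids))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) {
    stop("unparseable category id(s): ", paste(ids[bad], collapse = ", "))
  }
  data.frame(
    id = ids,
    direction = vapply(m, `[`, "", 2L),
    chrom = vapply(m, `[`, "", 3L),
    arm = substr(vapply(m, `[`, "", 4L), 1L, 1L),
    band = vapply(m, `[`, "", 4L),
    stringsAsFactors = FALSE
  )
}

# deterministic genome order of chromosome labels: 1..22, X, Y
chrom_rank <- function(chrom) {
  r <- suppressWarnings(as.integer(chrom))
  r[chrom == "X"] <- 23L
  r[chrom == "Y"] <- 24L
  if (anyNA(r)) stop("unknown chromosome label(s): ",
                     paste(unique(chrom[is.na(r)]), collapse = ", "))
  r
}

# deterministic ordering of category ids: gains block first, then losses,
# each in genome order (chromosome, p before q, band label)
order_categories <- function(ids) {
  p <- parse_category(ids)
  order(match(p$direction, c("g", "l")), chrom_rank(p$chrom),
        match(p$arm, c("p", "q")), p$band, method = "radix")
}
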