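# Shared fixtures, built in code.

# 6-sample, 3-band worked example (both directions per band); the same
# small matrix used throughout the documentation.
worked_example_matrix <- function() {
  D <- matrix(c(0, 0, 1, 1, 1, 0,
                0, 0, 0, 0, 0, 1,
                0, 0, 1, 1, 0, 0,
                1, 1, 1, 0, 0, 0,
                1, 1, 1, 0, 0, 0,
                0, 0, 0, 0, 1, 1),
              nrow = 6, byrow = TRUE,
              dimnames = list(as.character(1:6),
                              c("g-c1p11", "g-c1p12", "g-c1p13",
                                "l-c1p11", "l-c1p12", "l-c1p13")))
  cdcoca:::as_cna_matrix(D)
}

# 3-sample instance: s1 carries the pair, s2 one unrelated CNA, s3 nothing
tiny_pair_matrix <- function() {
  D <- matrix(c(1, 1, 0,
                0, 0, 1,
                0, 0, 0),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"),
                              c("g-c1p11", "l-c2q11", "g-c3p11")))
  cdcoca:::as_cna_matrix(D)
}

# random binary matrix with valid category ids, for property tests
random_cna_matrix <- function(n, m, density = 0.3) {
  bands <- cdcoca:::synthetic_band_labels(ceiling(m / 2))
  cats <- c(paste0("g-", bands), paste0("l-", bands))[seq_len(m)]
  D <- matrix(rbinom(n * m, 1L, density), n, m,
              dimnames = list(sprintf("S%02d", seq_len(n)), cats))
  # ensure matrix invariants: every column altered somewhere, some CNA
  for (j in which(colSums(D) == 0L)) D[sample.int(n, 1L), j] <- 1L
  cdcoca:::as_cna_matrix(D)
}

# independent brute-force contingency of two binary vectors
brute_pair_counts <- function(a, b) {
  list(n11 = sum(a == 1 & b == 1), n10 = sum(a == 1 & b == 0),
       n01 = sum(a == 0 & b == 1))
}

# write a UCSC-style cytoband file for given rows
write_cytoband_file <- function(rows, path = tempfile(fileext = ".tsv")) {
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
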