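test_that("load_cytobands parses UCSC-format tables and normalizes labels", {
  rows <- data.frame(
    chrom = c("chr1", "chr1", "chr1"),
    chromStart = c(0, 2300000, 243700000),
    chromEnd = c(2300000, 5400000, 248956422),
    name = c("p36.3", "p36.2", "q44"),
    gieStain = c("gneg", "gpos25", "gneg"))
  scheme <- load_cytobands(write_cytoband_file(rows))
  expect_s3_class(scheme, "cytoband_scheme")
  expect_equal(nrow(scheme), 3L)
  expect_equal(sum(scheme$arm == "p"), 2L)
  expect_equal(unique(scheme$chrom), "1")
})

test_that("load_cytobands rejects overlapping and zero-length bands", {
  rows <- data.frame(chrom = "chr1",
                     chromStart = c(0, 2299999),
                     chromEnd = c(2300000, 5400000),
                     name = c("p36.3", "p36.2"),
                     gieStain = "gneg")
  expect_error(load_cytobands(write_cytoband_file(rows)), "overlap")
  rows2 <- data.frame(chrom = "chr2", chromStart = 100, chromEnd = 100,
                      name = "p11", gieStain = "gneg")
  expect_error(load_cytobands(write_cytoband_file(rows2)), "zero-length")
})

test_that("packaged synthetic scheme has 320 bands, 303 autosomal", {
  scheme <- example_cytobands()
  expect_equal(nrow(scheme), 320L)
  # brute-force filter over the fixture
  expect_equal(sum(!scheme$chrom %in% c("X", "Y")), 303L)
  expect_equal(sum(scheme$chrom %in% c("X", "Y")), 17L)
})

test_that("segments map to bands by >= 1 bp half-open overlap", {
  rows <- data.frame(chrom = "chr1",
                     chromStart = c(0, 1000, 3000),
                     chromEnd = c(1000, 3000, 5000),
                     name = c("p12", "p11", "q11"),
                     gieStain = "gneg")
  scheme <- load_cytobands(write_cytoband_file(rows))

  # exact containment: only that band flagged
  hit <- map_segments_to_bands(
    data.frame(sample = "a", chrom = "1", start = 0, end = 1000,
               status = "gain"), scheme)
  expect_equal(hit$band, "c1p12")
  expect_equal(hit$direction, "g")

  # straddling segment flags both bands
  hit2 <- map_segments_to_bands(
    data.frame(sample = "a", chrom = "1", start = 900, end = 1100,
               status = "loss"), scheme)
  expect_setequal(hit2$band, c("c1p12", "c1p11"))

  # 1 bp short of the next band: single flag (half-open boundary)
  hit3 <- map_segments_to_bands(
    data.frame(sample = "a", chrom = "1", start = 0, end = 999,
               status = "gain"), scheme)
  expect_equal(hit3$band, "c1p12")

  # gain and loss both overlapping one band in one sample: both kept
  hit4 <- map_segments_to_bands(
    data.frame(sample = "a", chrom = c("1", "1"), start = c(1000, 1500),
               end = c(2000, 2500), status = c("gain", "loss")), scheme)
  expect_setequal(paste(hit4$direction, hit4$band), c("g c1p11", "l c1p11"))

  expect_error(map_segments_to_bands(
    data.frame(sample = "a", chrom = "9", start = 0, end = 10,
               status = "gain"), scheme), "9")
  expect_warning(map_segments_to_bands(
    data.frame(sample = "a", chrom = "1", start = 6000, end = 7000,
               status = "gain"), scheme), "no band")
})

test_that("mapping is idempotent under segment splitting", {
  scheme <- example_cytobands()
  set.seed(42)
  for (rep in 1:5) {
    # every autosome in the fixture spans at least 35 Mb
    start <- sort(sample.int(35000000L, 2L))
    seg <- data.frame(sample = "s", chrom = as.character(sample(1:22, 1)),
                      start = start[1], end = start[2], status = "gain")
    mid <- floor((seg$start + seg$end) / 2)
    halves <- data.frame(sample = "s", chrom = seg$chrom,
                         start = c(seg$start, mid), end = c(mid, seg$end),
                         status = "gain")
    whole <- map_segments_to_bands(seg, scheme)
    split <- map_segments_to_bands(halves, scheme)
    expect_identical(whole[order(whole$band), ],
                     split[order(split$band), ],
                     ignore_attr = TRUE)
  }
})

test_that("build_status_matrix splits directions, filters, and orders columns", {
  long <- data.frame(
    sample = c("a", "a", "b", "b", "c"),
    band = c("c1p11", "c1p11", "c2q11", "cXp11", "c2q11"),
    direction = c("g", "l", "l", "g", "l"))
  D <- build_status_matrix(long, drop_sex = TRUE, drop_empty = TRUE)
  expect_setequal(colnames(D), c("g-c1p11", "l-c1p11", "l-c2q11"))
  # gains block before losses
  expect_equal(colnames(D), c("g-c1p11", "l-c1p11", "l-c2q11"))
  expect_equal(unname(category_freq(D)), c(1L, 1L, 2L))

  # a band lost in three samples and gained in none -> only the l- column
  long2 <- data.frame(sample = c("a", "b", "c"), band = "c5q31",
                      direction = "l")
  D2 <- build_status_matrix(long2)
  expect_equal(colnames(D2), "l-c5q31")

  # duplicate flags collapse to a single 1
  expect_true(all(D %in% c(0L, 1L)))
})

test_that("a full-coverage autosomal cohort yields 2 x 303 = 606 categories", {
  scheme <- example_cytobands()
  auto <- scheme[!scheme$chrom %in% c("X", "Y"), ]
  long <- data.frame(
    sample = rep(c("gainer", "loser"), each = nrow(auto)),
    band = rep(cdcoca:::band_label(auto$chrom, auto$name), 2),
    direction = rep(c("g", "l"), each = nrow(auto)))
  D <- build_status_matrix(long, drop_sex = TRUE, drop_empty = TRUE)
  expect_equal(ncol(D), 606L)
})

test_that("wide -1/0/+1 input is split and validated", {
  wide <- data.frame(sample = c("s1", "s2"),
                     c1p11 = c(1, -1), c2q11 = c(0, 1))
  D <- build_status_matrix(wide)
  expect_setequal(colnames(D), c("g-c1p11", "g-c2q11", "l-c1p11"))
  expect_equal(D["s2", "l-c1p11"], 1L, ignore_attr = TRUE)

  # an unaltered sample keeps its all-zero row and the input row order
  wide0 <- data.frame(sample = c("s1", "s2", "s3"), c1p11 = c(1, 0, -1))
  D0 <- build_status_matrix(wide0)
  expect_equal(rownames(D0), c("s1", "s2", "s3"))
  expect_equal(sum(D0["s2", ]), 0L)

  bad <- data.frame(sample = c("s1", "s2"), c1p11 = c(2, 0))
  expect_error(build_status_matrix(bad), "s1.*c1p11")
  dup <- data.frame(sample = c("s1", "s1"), c1p11 = c(1, 0))
  expect_error(build_status_matrix(dup), "duplicate sample")
})

test_that("status matrix TSV round trip is bit-exact", {
  D <- worked_example_matrix()
  path <- tempfile(fileext = ".tsv")
  write_status_matrix(D, path, header_lines = "provenance test")
  D2 <- read_status_matrix(path)
  expect_identical(unclass(D2), unclass(D))

  # non-binary cell reported with location
  lines <- readLines(path)
  lines[3] <- sub("\t0", "\t2", lines[3])
  writeLines(lines, path)
  expect_error(read_status_matrix(path), "non-binary")

  # degenerate: no samples
  writeLines(lines[2], path)
  expect_error(read_status_matrix(path), "no samples")
})

test_that("category count is at most twice the band count", {
  set.seed(7)
  for (rep in 1:5) {
    n_bands <- sample(3:10, 1)
    bands <- cdcoca:::synthetic_band_labels(n_bands)
    long <- data.frame(
      sample = sample(letters[1:5], 30, replace = TRUE),
      band = sample(bands, 30, replace = TRUE),
      direction = sample(c("g", "l"), 30, replace = TRUE))
    D <- build_status_matrix(long)
    expect_lte(ncol(D), 2L * n_bands)
  }
})
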