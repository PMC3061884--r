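#' Specify a synthetic CNA cohort
#'
#' Describes a cohort with heterogeneous genomic complexity: a mixture of
#' "CNA simple" samples (few events) and "CNA complex" samples (many
#' events), with optional planted co-occurring category pairs on top of
#' the random background. Event counts per sample are drawn from a
#' negative binomial (overdispersed, like real per-tumor CNA burdens);
#' each sample's events are then placed uniformly over the category
#' universe without replacement, so the realized event count equals the
#' drawn count.
#'
#' @param n_samples cohort size.
#' @param n_bands number of cytogenetic bands; the category universe is
#'   the 2 x `n_bands` gain/loss split, spread over chromosomes 1..22.
#' @param complex_frac fraction of samples in the complex class.
#' @param simple_mean,complex_mean mean background event count per class
#'   (defaults 2 and 20, the orders of magnitude separating low- and
#'   high-complexity tumor genomes).
#' @param dispersion negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param planted data.frame with columns `cat_a`, `cat_b`, `carriers`,
#'   `class` (`"simple"`/`"complex"`): each row plants one co-occurring
#'   pair carried by `carriers` samples of that class. Complex-class
#'   carriers are the most complex samples of the realization.
#' @param plant_exclusive if `TRUE` (default) background events are never
#'   placed on planted categories, so planted columns carry exactly the
#'   chosen carriers (observed J = 1 and F = carriers by construction).
#' @param seed integer seed; generation is bit-reproducible.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 60L, n_bands = 40L, complex_frac = 0.3,
                        simple_mean = 2, complex_mean = 20, dispersion = 2,
                        planted = NULL, plant_exclusive = TRUE, seed = 1L) {
  if (n_samples < 1L || n_bands < 1L) stop("n_samples and n_bands must be >= 1")
  if (complex_frac < 0 || complex_frac > 1) stop("complex_frac must be in [0, 1]")
  if (simple_mean < 0 || complex_mean < 0) stop("class means must be >= 0")
  if (!is.null(planted)) {
    planted <- as.data.frame(planted, stringsAsFactors = FALSE)
    need <- c("cat_a", "cat_b", "carriers", "class")
    if (!all(need %in% names(planted))) {
      stop("planted needs columns: ", paste(need, collapse = ", "))
    }
    if (!all(planted$class %in% c("simple", "complex"))) {
      stop("planted class must be 'simple' or 'complex'")
    }
    if (any(planted$carriers < 0)) stop("carrier counts must be >= 0")
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_bands = as.integer(n_bands),
                 complex_frac = complex_frac, simple_mean = simple_mean,
                 complex_mean = complex_mean, dispersion = dispersion,
                 planted = planted, plant_exclusive = isTRUE(plant_exclusive),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# deterministic pseudo-genome band labels, spread over chromosomes 1..22
synthetic_band_labels <- function(n_bands, n_chrom = 22L) {
  n_chrom <- min(n_chrom, n_bands)
  chrom <- rep(seq_len(n_chrom), length.out = n_bands)
  chrom <- sort(chrom)
  idx <- unlist(lapply(split(seq_len(n_bands), chrom), seq_along),
                use.names = FALSE)
  arm <- ifelse(idx %% 2L == 1L, "p", "q")
  band_label(chrom, paste0(arm, 10L + (idx - 1L) %/% 2L))
}

#' Generate a synthetic CNA cohort
#'
#' Realizes a [cohort_spec()]: class labels are assigned, per-sample
#' background event counts are drawn from the class's negative binomial,
#' events are placed uniformly over the (non-reserved) category universe,
#' and planted pairs overwrite their carriers' entries. Empty categories
#' are dropped, so the result satisfies all status-matrix invariants.
#'
#' @param spec a [cohort_spec()].
#' @return a `cna_matrix` with attributes `truth` (the planted-pair record
#'   with resolved carrier ids) and `classes` (per-sample class labels).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  samples <- sprintf("S%03d", seq_len(n))
  n_complex <- round(spec$complex_frac * n)
  classes <- rep(c("complex", "simple"), c(n_complex, n - n_complex))
  bands <- synthetic_band_labels(spec$n_bands)
  universe <- c(paste0("g-", bands), paste0("l-", bands))

  planted <- spec$planted
  if (!is.null(planted)) {
    unknown <- setdiff(c(planted$cat_a, planted$cat_b), universe)
    if (length(unknown)) {
      stop("planted categories outside the band universe: ",
           paste(unknown, collapse = ", "))
    }
    for (cl in c("simple", "complex")) {
      if (max(c(0, planted$carriers[planted$class == cl])) > sum(classes == cl)) {
        stop("infeasible spec: planted carriers exceed ", cl, " class size")
      }
    }
  }
  background_universe <- universe
  if (!is.null(planted) && spec$plant_exclusive) {
    background_universe <- setdiff(universe, c(planted$cat_a, planted$cat_b))
  }

  mu <- ifelse(classes == "complex", spec$complex_mean, spec$simple_mean)
  counts <- rnbinom(n, size = spec$dispersion, mu = mu)
  counts <- pmin(counts, length(background_universe))

  D <- matrix(0L, n, length(universe), dimnames = list(samples, universe))
  for (i in seq_len(n)) {
    if (counts[i] > 0L) {
      hit <- sample(background_universe, counts[i])
      D[i, hit] <- 1L
    }
  }

  truth <- NULL
  if (!is.null(planted) && nrow(planted)) {
    carrier_ids <- vector("list", nrow(planted))
    for (r in seq_len(nrow(planted))) {
      pool <- which(classes == planted$class[r])
      carriers <- if (planted$class[r] == "complex") {
        # the most complex samples of the realization
        pool[order(counts[pool], decreasing = TRUE)][seq_len(planted$carriers[r])]
      } else {
        sample(pool, planted$carriers[r])
      }
      D[carriers, planted$cat_a[r]] <- 1L
      D[carriers, planted$cat_b[r]] <- 1L
      carrier_ids[[r]] <- samples[carriers]
    }
    truth <- planted
    truth$carrier_ids <- vapply(carrier_ids, paste, "", collapse = ",")
  }

  D <- D[, colSums(D) >= 1L, drop = FALSE]
  if (ncol(D) == 0L) stop("generated cohort has no alterations; increase means")
  D <- D[, order_categories(colnames(D)), drop = FALSE]
  D <- as_cna_matrix(D)
  attr(D, "truth") <- truth
  attr(D, "classes") <- setNames(classes, samples)
  D
}
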