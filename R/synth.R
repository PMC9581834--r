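#' Synthetic cohort specification
#'
#' The package is exercised exclusively on artificial cohorts — no real
#' patient data is involved anywhere. The generator emulates the shape of
#' the benchmark databases: 100 to 20,000 records, genotypes of 100-200
#' mutation-indicator bits, and on the order of 100 treatments. Genotype
#' bit j is an independent Bernoulli(\eqn{\pi_j}) draw (default 0.05 at
#' every position, reflecting that resistance-associated mutations are
#' individually uncommon); treatments are uniform over the manifest; TTF
#' is exponential with mean 365 days, rounded to whole days and truncated
#' at `ttf_max`.
#'
#' @param m number of records.
#' @param N genotype length in bits (default 150).
#' @param T_ number of treatments (default 100).
#' @param pi per-position mutation probability: a scalar or a length-N
#'   profile vector in `[0, 1]`.
#' @param ttf_mean mean TTF in days (default 365).
#' @param ttf_max truncation ceiling in days (default 3650).
#' @param seed integer seed; the cohort is a pure function of the spec.
#' @param planted_effect if `TRUE`, each treatment gets a hidden archetype
#'   genotype and a record's expected TTF shrinks with its distance from
#'   the archetype of its treatment, so end-to-end demos produce
#'   interpretable averages. Off by default.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(m, N = 150L, T_ = 100L, pi = 0.05, ttf_mean = 365,
                        ttf_max = 3650, seed = 1L, planted_effect = FALSE) {
  if (length(pi) == 1L) pi <- rep(pi, N)
  stopifnot(
    m >= 0, N >= 1, T_ >= 1, length(pi) == N,
    all(pi >= 0), all(pi <= 1), ttf_mean > 0, ttf_max >= 1
  )
  structure(
    list(
      m = as.integer(m), N = as.integer(N), T_ = as.integer(T_), pi = pi,
      ttf_mean = ttf_mean, ttf_max = ttf_max, seed = as.integer(seed),
      planted_effect = isTRUE(planted_effect)
    ),
    class = "cohort_spec"
  )
}

default_manifest <- function(T_) sprintf("TRT%03d", seq_len(T_))

#' Generate a synthetic cohort
#'
#' @param spec a [cohort_spec()].
#' @param manifest optional treatment labels (length `T_`); defaults to
#'   `TRT001..TRTnnn`.
#' @return a cohort data.frame (`patient_id`, `genotype`, `treatment`,
#'   `ttf_days`) with the manifest attached as an attribute.
#' @examples
#' cohort <- generate_cohort(cohort_spec(m = 5, N = 10, T_ = 3, seed = 42))
#' cohort
#' @export
generate_cohort <- function(spec, manifest = default_manifest(spec$T_)) {
  stopifnot(inherits(spec, "cohort_spec"), length(manifest) == spec$T_)
  rng <- mpc_rng(spec$seed, "cohort")
  m <- spec$m
  N <- spec$N
  if (m == 0L) {
    out <- data.frame(
      patient_id = character(0), genotype = character(0),
      treatment = character(0), ttf_days = numeric(0),
      stringsAsFactors = FALSE
    )
    return(validate_cohort(out, manifest))
  }
  geno_u <- matrix(rng_draw_unit(rng, m * N), nrow = m, byrow = TRUE)
  geno <- sweep(geno_u, 2L, spec$pi, "<") * 1L
  geno_str <- apply(geno, 1L, paste, collapse = "")
  trt_idx <- floor(rng_draw_unit(rng, m) * spec$T_) + 1L
  trt_idx[trt_idx > spec$T_] <- spec$T_
  u <- rng_draw_unit(rng, m)
  mean_ttf <- rep(spec$ttf_mean, m)
  if (spec$planted_effect) {
    arche_u <- matrix(rng_draw_unit(rng, spec$T_ * N), nrow = spec$T_, byrow = TRUE)
    arche <- sweep(arche_u, 2L, spec$pi, "<") * 1L
    d <- rowSums(geno != arche[trt_idx, , drop = FALSE])
    # expected TTF halves every N/4 mismatches from the treatment archetype
    mean_ttf <- spec$ttf_mean * 2^(-d / (N / 4))
  }
  ttf <- pmin(round(-mean_ttf * log(1 - u)), spec$ttf_max)
  out <- data.frame(
    patient_id = sprintf("P%06d", seq_len(m)),
    genotype = geno_str,
    treatment = manifest[trt_idx],
    ttf_days = as.numeric(ttf),
    stringsAsFactors = FALSE
  )
  validate_cohort(out, manifest)
}

#' Cohort and manifest CSV round trip
#'
#' The cohort CSV has header `patient_id,genotype,treatment,ttf_days` with
#' the genotype as a 0/1 string; the manifest file lists one treatment
#' label per line, in one-hot order. Reading validates genotype strings
#' (length and alphabet, with the offending line reported) and checks
#' every treatment label against the manifest.
#'
#' @param cohort a cohort data.frame.
#' @param path CSV file path.
#' @return `write_cohort`/`write_manifest`: the path, invisibly;
#'   `read_cohort`: the validated cohort; `read_manifest`: a character
#'   vector of labels.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(
    cohort[, c("patient_id", "genotype", "treatment", "ttf_days")],
    path,
    row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_cohort
#' @param manifest character vector of treatment labels.
#' @export
read_cohort <- function(path, manifest) {
  df <- utils::read.csv(path, colClasses = c(
    patient_id = "character", genotype = "character",
    treatment = "character", ttf_days = "numeric"
  ))
  if (nrow(df) > 0L) {
    bad <- grep("^[01]+$", df$genotype, invert = TRUE)
    if (length(bad) > 0L) {
      stop("malformed genotype string at line ", bad[1L] + 1L, " of ", path,
        call. = FALSE)
    }
    lens <- nchar(df$genotype)
    if (length(unique(lens)) > 1L) {
      stop("genotype length mismatch at line ",
        which(lens != lens[1L])[1L] + 1L, " of ", path, call. = FALSE)
    }
  }
  validate_cohort(df, manifest)
}

#' @rdname write_cohort
#' @export
write_manifest <- function(manifest, path) {
  writeLines(manifest, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_manifest <- function(path) {
  readLines(path)
}
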