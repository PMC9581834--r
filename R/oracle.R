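#' Plaintext reference oracle
#'
#' Clear-text implementation of the estimand the secure pipeline computes:
#' per treatment, the sum and count of time-to-treatment-failure over all
#' records whose genotype lies within Hamming distance strictly below `B`
#' of the query genotype. The secure pipeline must agree with this oracle
#' exactly (integer equality) on every cohort — that is the primary
#' correctness surface of the package.
#'
#' @param v1,v2 0/1 integer vectors or 0/1 strings of equal length.
#' @return `oracle_hamming`: the number of mismatching positions.
#' @examples
#' oracle_hamming("1010", "1110") # 1
#' @export
oracle_hamming <- function(v1, v2) {
  v1 <- as_bits(v1)
  v2 <- as_bits(v2)
  if (length(v1) != length(v2)) stop("bit vectors have different lengths", call. = FALSE)
  sum(v1 != v2)
}

as_bits <- function(v) {
  if (is.character(v)) {
    stopifnot(length(v) == 1L)
    if (!grepl("^[01]*$", v)) stop("not a 0/1 string", call. = FALSE)
    v <- as.integer(strsplit(v, "")[[1L]])
  }
  stopifnot(all(v %in% c(0L, 1L)))
  as.integer(v)
}

#' @rdname oracle_hamming
#' @param records a cohort data.frame (columns `genotype`, `treatment`,
#'   `ttf_days`).
#' @param manifest public ordered treatment labels.
#' @param v query genotype (0/1 string or vector).
#' @param B public integer threshold; records with distance `< B` match.
#' @return `oracle_query`: a `query_result` data.frame with `treatment`,
#'   `sum_days`, `count`, `average_days` (`NA` for treatments with no
#'   similar patients).
#' @examples
#' records <- data.frame(
#'   patient_id = 1:4,
#'   genotype = c("1010", "1110", "0101", "1010"),
#'   treatment = c("A", "A", "A", "B"),
#'   ttf_days = c(100, 200, 50, 300)
#' )
#' oracle_query(records, c("A", "B"), "1010", B = 2)
#' @export
oracle_query <- function(records, manifest, v, B) {
  records <- validate_cohort(records, manifest)
  v <- as_bits(v)
  if (nrow(records) > 0L && attr(records, "N") != length(v)) {
    stop("query genotype length does not match the cohort", call. = FALSE)
  }
  if (B < 0 || B > length(v)) stop("threshold B must lie in [0, N]", call. = FALSE)
  if (nrow(records) > 0L) {
    d <- vapply(
      strsplit(as.character(records$genotype), ""),
      function(g) sum(as.integer(g) != v), numeric(1)
    )
    sim <- d < B
    S <- vapply(manifest, function(t) {
      sum(records$ttf_days[sim & records$treatment == t])
    }, numeric(1))
    C <- vapply(manifest, function(t) {
      sum(sim & records$treatment == t)
    }, numeric(1))
  } else {
    S <- C <- rep(0, length(manifest))
  }
  out <- data.frame(
    treatment = manifest,
    sum_days = unname(S),
    count = unname(C),
    average_days = ifelse(C > 0, unname(S) / unname(C), NA_real_),
    stringsAsFactors = FALSE
  )
  class(out) <- c("query_result", "data.frame")
  out
}
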