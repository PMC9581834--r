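#' End-to-end demonstration run
#'
#' Executes the full pipeline in one process: generate a synthetic cohort,
#' deal the preprocessing, secret-share database and query, run the
#' oblivious query, reconstruct at the client, and print the per-treatment
#' averages together with the cost ledger.
#'
#' @param spec a [cohort_spec()], or a cohort data.frame (then `manifest`
#'   must be given).
#' @param B public similarity threshold.
#' @param query_genotype the query genotype (0/1 string); default: the
#'   genotype of the first record, the natural "patient like mine" query.
#' @param config a [protocol_config()].
#' @param manifest treatment manifest when `spec` is a data.frame.
#' @param quiet suppress printing.
#' @return invisibly, a list with the reconstructed `result`, the `ledger`
#'   data.frame, the plaintext `cohort` and the query genotype.
#' @examples
#' run_demo(cohort_spec(m = 20, N = 20, T_ = 4, seed = 3), B = 5,
#'   config = protocol_config(field = prime_field(2^61 - 1), kappa = 10, l = 5))
#' @export
run_demo <- function(spec, B, query_genotype = NULL,
                     config = protocol_config(), manifest = NULL,
                     quiet = FALSE) {
  if (inherits(spec, "cohort_spec")) {
    manifest <- manifest %||% default_manifest(spec$T_)
    cohort <- generate_cohort(spec, manifest)
  } else {
    stopifnot(is.data.frame(spec), !is.null(manifest))
    cohort <- validate_cohort(spec, manifest)
  }
  m <- nrow(cohort)
  N <- attr(cohort, "N")
  if (is.null(query_genotype)) {
    if (m == 0L) stop("empty cohort needs an explicit query genotype", call. = FALSE)
    query_genotype <- as.character(cohort$genotype[1L])
  }
  s <- mpc_session(config)
  on.exit(close_session(s))
  if (m > 0L) {
    deal_for_query(s$store, m, N, length(manifest),
      l = config$l, kappa = config$kappa
    )
  }
  db <- share_database(s, cohort, manifest)
  q <- make_query(s, query_genotype, B)
  res_shares <- run_query(s, db, q)
  result <- client_reconstruct(res_shares)
  ledger <- as.data.frame(s$ledger)
  if (!quiet) {
    cat(sprintf(
      "Similar-patient query: m=%d records, N=%s bits, T=%d treatments, B=%d\n\n",
      m, ifelse(is.na(N), "?", N), length(manifest), B
    ))
    print(result)
    cat("\nOnline-phase cost ledger:\n")
    print(ledger, row.names = FALSE)
  }
  invisible(list(
    result = result, ledger = ledger, cohort = cohort,
    query_genotype = query_genotype, B = B
  ))
}

#' Scaling benchmark over database sizes
#'
#' Reports the per-query resource footprint for a list of database sizes.
#' In dry-run mode the closed-form [estimate_query_cost()] is used; in
#' live mode a query is actually executed at each size and the real ledger
#' reported — the two agree exactly, and the triple counts are affine in
#' the record count (the circuit is a per-record template).
#'
#' @param sizes integer vector of database sizes m.
#' @param dry_run logical; `FALSE` executes real queries.
#' @param N genotype length.
#' @param T_ number of treatments.
#' @param B threshold used in live runs.
#' @param config a [protocol_config()].
#' @param seed cohort seed for live runs.
#' @return a data.frame with one row per size: `m`, `triples_used`,
#'   `random_bits_used`, `triple_equivalents`, `openings`, `rounds`,
#'   `bytes_sent`.
#' @examples
#' run_bench(c(100, 200, 400), N = 200, T_ = 100)
#' @export
run_bench <- function(sizes, dry_run = TRUE, N = 150L, T_ = 100L, B = 20L,
                      config = protocol_config(), seed = 1L) {
  stopifnot(length(sizes) >= 1L, all(sizes >= 0))
  rows <- lapply(sizes, function(m) {
    if (dry_run) {
      est <- estimate_query_cost(m, N, T_,
        l = config$l, kappa = config$kappa,
        n = config$n, field = config$field
      )
    } else {
      res <- run_demo(
        cohort_spec(m = m, N = N, T_ = T_, seed = seed),
        B = B, config = config, quiet = TRUE
      )
      est <- res$ledger
    }
    cbind(data.frame(m = m), est)
  })
  do.call(rbind, rows)
}
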