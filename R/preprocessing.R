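#' Trusted-dealer preprocessing (offline phase)
#'
#' The online protocol consumes correlated randomness that is independent of
#' all inputs: Beaver multiplication triples \eqn{(a, b, c = ab)} and shared
#' random bits. Here a trusted dealer generates and secret-shares them ahead
#' of time; this stands in for a cryptographic offline phase and leaves the
#' online-phase semantics unchanged. Each unit is consumed at most once;
#' exhaustion is a hard error, never silently recycled.
#'
#' @param field a [prime_field()].
#' @param n number of computing parties.
#' @param rng the dealer's [mpc_rng()].
#' @return a `preprocessing_store` environment.
#' @export
preprocessing_store <- function(field, n = 2L, rng) {
  e <- new.env(parent = emptyenv())
  e$field <- field
  e$n <- as.integer(n)
  e$rng <- rng
  e$ta <- e$tb <- e$tc <- matrix("0", nrow = n, ncol = 0)
  e$bits <- matrix("0", nrow = n, ncol = 0)
  e$triples_dealt <- 0
  e$bits_dealt <- 0
  e$triple_cursor <- 0
  e$bit_cursor <- 0
  class(e) <- "preprocessing_store"
  e
}

#' @export
print.preprocessing_store <- function(x, ...) {
  cat(sprintf(
    "<preprocessing store: %d/%d triples and %d/%d random bits unconsumed (%d parties)>\n",
    x$triples_dealt - x$triple_cursor, x$triples_dealt,
    x$bits_dealt - x$bit_cursor, x$bits_dealt, x$n
  ))
  invisible(x)
}

#' Deal Beaver multiplication triples
#'
#' Generates `k` triples \eqn{(a, b, c = ab)} with `a`, `b` uniform in
#' \eqn{F_p}, secret-shares each component among the parties, and queues
#' them for consumption.
#'
#' @param store a [preprocessing_store()].
#' @param k number of triples (non-negative).
#' @return the store, invisibly.
#' @export
deal_triples <- function(store, k) {
  stopifnot(inherits(store, "preprocessing_store"), k >= 0)
  k <- as.integer(k)
  if (k == 0L) return(invisible(store))
  f <- store$field
  a <- rng_draw_below(store$rng, k, f$p_hex)
  b <- rng_draw_below(store$rng, k, f$p_hex)
  cc <- fp_mul_cpp(a, b, f$p_hex)
  store$ta <- cbind(store$ta, share_mat(a, store$n, f, store$rng))
  store$tb <- cbind(store$tb, share_mat(b, store$n, f, store$rng))
  store$tc <- cbind(store$tc, share_mat(cc, store$n, f, store$rng))
  store$triples_dealt <- store$triples_dealt + k
  invisible(store)
}

#' Deal shared random bits
#'
#' Each unit is a secret sharing of a uniform bit \eqn{b \in \{0, 1\}},
#' consumed by the statistically-masked comparison protocol.
#'
#' @inheritParams deal_triples
#' @return the store, invisibly.
#' @export
deal_random_bits <- function(store, k) {
  stopifnot(inherits(store, "preprocessing_store"), k >= 0)
  k <- as.integer(k)
  if (k == 0L) return(invisible(store))
  f <- store$field
  b <- as.character(rng_draw_bits(store$rng, k))
  store$bits <- cbind(store$bits, share_mat(b, store$n, f, store$rng))
  store$bits_dealt <- store$bits_dealt + k
  invisible(store)
}

take_triples <- function(store, k) {
  if (store$triple_cursor + k > store$triples_dealt) {
    stop("preprocessing exhausted: ", k, " triples requested, ",
      store$triples_dealt - store$triple_cursor, " available",
      call. = FALSE
    )
  }
  idx <- store$triple_cursor + seq_len(k)
  store$triple_cursor <- store$triple_cursor + k
  list(
    a = store$ta[, idx, drop = FALSE],
    b = store$tb[, idx, drop = FALSE],
    c = store$tc[, idx, drop = FALSE]
  )
}

take_bits <- function(store, k) {
  if (store$bit_cursor + k > store$bits_dealt) {
    stop("preprocessing exhausted: ", k, " random bits requested, ",
      store$bits_dealt - store$bit_cursor, " available",
      call. = FALSE
    )
  }
  idx <- store$bit_cursor + seq_len(k)
  store$bit_cursor <- store$bit_cursor + k
  store$bits[, idx, drop = FALSE]
}

#' Dry-run cost of one similar-patient query
#'
#' Closed-form count of the correlated randomness and communication one
#' query consumes, without executing any cryptography. The same constants
#' drive the engine, and a property test pins the two together: the dry-run
#' estimate equals the ledger of a real execution exactly.
#'
#' Per record the circuit costs `N` triples (one XOR per genotype position),
#' `l - 1` triples (comparison borrow chain), 1 triple (mask x TTF) and
#' `2 T` triples (per-treatment sum and count), plus `l + kappa` dealer
#' random bits for the statistical mask. In the headline total each random
#' bit is counted as one triple-equivalent, matching the standard
#' square-and-open generation cost.
#'
#' @param m number of database records.
#' @param N genotype length in bits.
#' @param T_ number of treatments.
#' @param l comparison bit width; defaults to `ceiling(log2(N + 1))` so that
#'   any Hamming distance in `[0, N]` fits.
#' @param kappa statistical security parameter (bits).
#' @param n number of computing parties.
#' @param field the prime field (sets the wire width of one element).
#' @return a one-row data.frame: `triples_used`, `random_bits_used`,
#'   `triple_equivalents`, `openings`, `rounds`, `bytes_sent`.
#' @examples
#' estimate_query_cost(m = 20000, N = 200, T_ = 100, kappa = 40)
#' @export
estimate_query_cost <- function(m, N, T_, l = ceiling(log2(N + 1)), kappa = 40,
                                n = 2L, field = default_prime()) {
  stopifnot(m >= 0, N >= 1, T_ >= 1, l >= 1, kappa >= 1, n >= 2)
  if (m == 0) {
    return(data.frame(
      triples_used = 0, random_bits_used = 0, triple_equivalents = 0,
      openings = 0, rounds = 0, bytes_sent = 0
    ))
  }
  w <- field$bytes
  triples <- m * (N + l + 2 * T_)
  bits <- m * (l + kappa)
  openings <- 2 * triples + m
  rounds <- l + 3
  elements <- m * (2 * N + 2 * l + 1 + 4 * T_)
  bytes <- n * (n - 1) * (FRAME_HEADER_BYTES * rounds + w * elements)
  data.frame(
    triples_used = triples, random_bits_used = bits,
    triple_equivalents = triples + bits,
    openings = openings, rounds = rounds, bytes_sent = bytes
  )
}

#' Provision a store for a query of known shape
#'
#' Deals exactly the triples and random bits [estimate_query_cost()]
#' predicts for one query over `m` records.
#'
#' @inheritParams estimate_query_cost
#' @param store a [preprocessing_store()].
#' @return the store, invisibly.
#' @export
deal_for_query <- function(store, m, N, T_, l = ceiling(log2(N + 1)), kappa = 40) {
  est <- estimate_query_cost(m, N, T_, l, kappa, n = store$n, field = store$field)
  deal_triples(store, est$triples_used)
  deal_random_bits(store, est$random_bits_used)
  invisible(store)
}

# ---------------------------------------------------------------------------
# plain-text preprocessing files, one per party

#' Write or read per-party preprocessing files
#'
#' One tab-separated file per party (`preproc_party<i>.tsv`) with columns
#' `kind` (`triple_a`, `triple_b`, `triple_c`, `bit`), `label`, `value`
#' (hex share). `read_preprocessing` reassembles a store from all party
#' files (a test and orchestration convenience; a deployed party would read
#' only its own file).
#'
#' @param store a [preprocessing_store()] with unconsumed material.
#' @param dir directory for the party files.
#' @return `write_preprocessing`: the file paths, invisibly;
#'   `read_preprocessing`: a `preprocessing_store`.
#' @export
write_preprocessing <- function(store, dir) {
  stopifnot(inherits(store, "preprocessing_store"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(store$n)
  kt <- store$triples_dealt
  kb <- store$bits_dealt
  for (i in seq_len(store$n)) {
    df <- data.frame(
      kind = c(
        rep(c("triple_a", "triple_b", "triple_c"), each = kt),
        rep("bit", kb)
      ),
      label = c(
        paste0("t", rep(seq_len(kt), 3L)),
        if (kb > 0) paste0("r", seq_len(kb)) else character(0)
      ),
      value = c(store$ta[i, ], store$tb[i, ], store$tc[i, ], store$bits[i, ]),
      stringsAsFactors = FALSE
    )
    paths[i] <- file.path(dir, sprintf("preproc_party%d.tsv", i - 1L))
    utils::write.table(df, paths[i], sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(paths)
}

#' @rdname write_preprocessing
#' @param field the prime field the material was dealt in.
#' @param n number of party files to read.
#' @export
read_preprocessing <- function(dir, field, n = 2L) {
  store <- preprocessing_store(field, n, mpc_rng(0, "reader"))
  per_party <- lapply(seq_len(n) - 1L, function(i) {
    path <- file.path(dir, sprintf("preproc_party%d.tsv", i))
    if (!file.exists(path)) stop("missing preprocessing file: ", path, call. = FALSE)
    utils::read.table(path, header = TRUE, sep = "\t", colClasses = "character")
  })
  pick <- function(kind) {
    do.call(rbind, lapply(per_party, function(df) df$value[df$kind == kind]))
  }
  ta <- pick("triple_a")
  store$ta <- if (is.null(ta)) matrix("0", n, 0) else ta
  tb <- pick("triple_b")
  store$tb <- if (is.null(tb)) matrix("0", n, 0) else tb
  tc <- pick("triple_c")
  store$tc <- if (is.null(tc)) matrix("0", n, 0) else tc
  bits <- pick("bit")
  store$bits <- if (is.null(bits)) matrix("0", n, 0) else bits
  store$triples_dealt <- ncol(store$ta)
  store$bits_dealt <- ncol(store$bits)
  store
}
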