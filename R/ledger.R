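#' Protocol cost ledger
#'
#' Counts the resources a protocol run consumes: Beaver multiplication
#' triples, dealer random bits, opened field elements, communication rounds
#' and bytes sent (totalled over all ordered party pairs, at the wire frame
#' format). Because the computation path is oblivious, every entry is a
#' function of the circuit shape and the protocol parameters only — never
#' of secret values. The ledger is the instrument behind the obliviousness
#' and linear-scaling checks, and behind the offline-phase triple budget.
#'
#' @return `cost_ledger()` returns a fresh ledger (an environment) with all
#'   counters zero.
#' @export
cost_ledger <- function() {
  e <- new.env(parent = emptyenv())
  e$triples_used <- 0
  e$random_bits_used <- 0
  e$openings <- 0
  e$rounds <- 0
  e$bytes_sent <- 0
  class(e) <- "cost_ledger"
  e
}

ledger_bump <- function(ledger, what, by) {
  if (by < 0) stop("ledger counters are monotone", call. = FALSE)
  assign(what, get(what, envir = ledger) + by, envir = ledger)
  invisible(ledger)
}

#' @param x a `cost_ledger`.
#' @param ... unused.
#' @rdname cost_ledger
#' @export
as.data.frame.cost_ledger <- function(x, ...) {
  data.frame(
    triples_used = x$triples_used,
    random_bits_used = x$random_bits_used,
    triple_equivalents = x$triples_used + x$random_bits_used,
    openings = x$openings,
    rounds = x$rounds,
    bytes_sent = x$bytes_sent
  )
}

#' @export
print.cost_ledger <- function(x, ...) {
  cat("<cost ledger>\n")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

ledger_equal <- function(a, b) {
  identical(as.data.frame(a), as.data.frame(b))
}
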