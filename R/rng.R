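#' Deterministic per-actor random generators
#'
#' Each protocol actor (dealer, each computing party, the querying client,
#' the cohort generator) owns an independent deterministic stream, derived
#' from an explicit integer seed and an actor tag. Runs are therefore fully
#' reproducible from the configured seeds, which is essential for testing a
#' randomized protocol. The generator is xoshiro256** seeded through
#' splitmix64 — a statistical PRNG for reproducible experiments, not a
#' cryptographically secure one; a deployment would swap in a CSPRNG behind
#' the same interface.
#'
#' @param seed a non-negative integer seed.
#' @param actor a short tag (e.g. `"dealer"`, `"party1"`, `"client"`) mixed
#'   into the seed so actors get distinct streams from one master seed.
#' @return an `mpc_rng` handle.
#' @examples
#' r <- mpc_rng(7, "dealer")
#' random_element(prime_field(101), r, 3)
#' @export
mpc_rng <- function(seed, actor = "") {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0, seed == floor(seed))
  structure(
    list(ptr = rng_new_cpp(seed, actor), seed = seed, actor = actor),
    class = "mpc_rng"
  )
}

#' @export
print.mpc_rng <- function(x, ...) {
  cat(sprintf("<mpc rng: seed=%s actor='%s'>\n", format(x$seed), x$actor))
  invisible(x)
}

rng_draw_below <- function(rng, k, bound_hex) {
  stopifnot(inherits(rng, "mpc_rng"))
  if (k == 0L) return(character(0))
  rng_below_cpp(rng$ptr, as.integer(k), bound_hex)
}

rng_draw_bits <- function(rng, k) {
  stopifnot(inherits(rng, "mpc_rng"))
  if (k == 0L) return(integer(0))
  rng_bits_cpp(rng$ptr, as.integer(k))
}

rng_draw_unit <- function(rng, k) {
  stopifnot(inherits(rng, "mpc_rng"))
  if (k == 0L) return(numeric(0))
  rng_unit_cpp(rng$ptr, as.integer(k))
}
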