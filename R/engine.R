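#' Protocol configuration
#'
#' Bundles the public parameters of the online phase. The field must
#' satisfy \eqn{p > 2^{l + \kappa + 1}} so that the statistically masked
#' opening in the comparison protocol cannot wrap around the modulus.
#'
#' @param n number of computing parties (default 2, the deployment
#'   topology; the paradigm is n-party).
#' @param field a [prime_field()]; default the 128-bit production prime.
#' @param kappa statistical security parameter: masked openings leak at
#'   most about \eqn{2^{-\kappa}} (default 40).
#' @param l comparison bit width: compared values must lie in
#'   \eqn{[0, 2^l)}. Default 8, enough for genotype lengths up to 255. Use
#'   `NA` for a session that performs no comparisons (then no field-size
#'   constraint applies and [lt_public()] is unavailable).
#' @param transport `"inproc"` or `"socket"`.
#' @param seed master integer seed; dealer, parties and client derive
#'   distinct deterministic streams from it.
#' @return a `protocol_config` list.
#' @export
protocol_config <- function(n = 2L, field = default_prime(), kappa = 40L,
                            l = 8L, transport = c("inproc", "socket"),
                            seed = 1L) {
  transport <- match.arg(transport)
  n <- as.integer(n)
  kappa <- as.integer(kappa)
  l <- as.integer(l)
  stopifnot(inherits(field, "prime_field"), n >= 2L, kappa >= 2L, is.na(l) || l >= 1L)
  if (!is.na(l) && field$bit_length < l + kappa + 2L) {
    stop(sprintf(
      "field too small for comparison parameters: need p > 2^(l+kappa+1) = 2^%d, have %d-bit p",
      l + kappa + 1L, field$bit_length
    ), call. = FALSE)
  }
  structure(
    list(n = n, field = field, kappa = kappa, l = l,
         transport = transport, seed = seed),
    class = "protocol_config"
  )
}

#' Start an online-phase session
#'
#' A session holds the computing parties' runtime state: the preprocessing
#' store, the cost ledger, the transport and the deterministic actor
#' streams. All interactive operations ([mpc_open()], [beaver_mul()],
#' [lt_public()], ...) run against a session.
#'
#' @param config a [protocol_config()].
#' @return an `mpc_session` environment.
#' @examples
#' s <- mpc_session(protocol_config(field = prime_field(2^61 - 1), seed = 4))
#' deal_triples(s$store, 5)
#' x <- share_secret(fe(s$cfg$field, 12), rng = s$client_rng)
#' y <- share_secret(fe(s$cfg$field, 9), rng = s$client_rng)
#' as.numeric(mpc_open(s, beaver_mul(s, x, y))) # 108
#' @export
mpc_session <- function(config = protocol_config()) {
  stopifnot(inherits(config, "protocol_config"))
  s <- new.env(parent = emptyenv())
  s$cfg <- config
  s$dealer_rng <- mpc_rng(config$seed, "dealer")
  s$client_rng <- mpc_rng(config$seed, "client")
  s$store <- preprocessing_store(config$field, config$n, s$dealer_rng)
  s$ledger <- cost_ledger()
  s$transport <- if (config$transport == "socket") socket_transport() else inproc_transport()
  session_rng <- mpc_rng(config$seed, "session")
  s$session_id <- as.raw(as.integer(rng_draw_unit(session_rng, 16L) * 256) %% 256L)
  s$seqs <- rep(0, config$n)
  s$transcript_lengths <- integer(0)
  class(s) <- "mpc_session"
  s
}

#' @export
print.mpc_session <- function(x, ...) {
  cat(sprintf(
    "<mpc session: %d parties, %d-bit field, kappa=%d, l=%d, %s transport>\n",
    x$cfg$n, x$cfg$field$bit_length, x$cfg$kappa, x$cfg$l, x$transport$type
  ))
  print(x$ledger)
  invisible(x)
}

#' End a session and release its transport
#'
#' @param session an [mpc_session()].
#' @export
close_session <- function(session) {
  session$transport$close()
  invisible(NULL)
}

as_share_mat <- function(x, session) {
  stopifnot(inherits(x, "shared_value"))
  check_same_field(x$field, session$cfg$field)
  if (x$n != session$cfg$n) stop("party count mismatch", call. = FALSE)
  x$shares
}

# the single interactive primitive: every party broadcasts its share row,
# everyone sums. Frames are built, delivered over the transport, decoded,
# and the public value is computed from the received bytes.
open_mat <- function(session, mat) {
  k <- ncol(mat)
  f <- session$cfg$field
  if (k == 0L) return(character(0))
  n <- session$cfg$n
  w <- f$bytes
  frames <- list()
  for (i in seq_len(n)) {
    session$seqs[i] <- session$seqs[i] + 1
    bytes <- frame_encode(session$session_id, session$seqs[i], OP_OPEN, mat[i, ], w)
    for (j in seq_len(n)[-i]) {
      frames[[length(frames) + 1L]] <- list(from = i, to = j, bytes = bytes)
    }
  }
  delivered <- session$transport$deliver(frames)
  lens <- vapply(delivered, function(fr) length(fr$bytes), integer(1))
  session$transcript_lengths <- c(session$transcript_lengths, lens)
  ledger_bump(session$ledger, "openings", k)
  ledger_bump(session$ledger, "rounds", 1)
  ledger_bump(session$ledger, "bytes_sent", sum(lens))
  # reconstruct at party 1 from what actually arrived, plus its own row
  inbound <- Filter(function(fr) fr$to == 1L, delivered)
  acc <- mat[1L, ]
  for (fr in inbound) {
    acc <- fp_add_cpp(acc, frame_decode(fr$bytes, w)$values, f$p_hex)
  }
  acc
}

#' Open a shared value
#'
#' Every party broadcasts its share; all parties learn the plaintext.
#'
#' @param session an [mpc_session()].
#' @param x a `shared_value`.
#' @return the public value as a field element vector.
#' @export
mpc_open <- function(session, x) {
  new_fe(open_mat(session, as_share_mat(x, session)), session$cfg$field)
}

# Beaver multiplication on raw share matrices (k = ncol elementwise products)
beaver_mul_mat <- function(session, xmat, ymat) {
  k <- ncol(xmat)
  stopifnot(ncol(ymat) == k)
  f <- session$cfg$field
  if (k == 0L) return(xmat)
  tr <- take_triples(session$store, k)
  ledger_bump(session$ledger, "triples_used", k)
  d_e <- open_mat(session, cbind(
    mat_sub(xmat, tr$a, f),
    mat_sub(ymat, tr$b, f)
  ))
  d <- d_e[seq_len(k)]
  e <- d_e[k + seq_len(k)]
  # z = c + d*[b] + e*[a] + d*e (public product absorbed by party 1)
  z <- mat_add(tr$c, mat_scale_cols(tr$b, d, f), f)
  z <- mat_add(z, mat_scale_cols(tr$a, e, f), f)
  mat_add_pub(z, fp_mul_cpp(d, e, f$p_hex), f)
}

#' Secure multiplication via Beaver triples
#'
#' Consumes one triple per element and opens the two masked differences
#' \eqn{d = x - a}, \eqn{e = y - b}; the product share is the local
#' combination \eqn{c + d b + e a + d e}.
#'
#' @param session an [mpc_session()] with sufficient dealt triples.
#' @param x,y `shared_value`s of equal length.
#' @return a `shared_value` reconstructing to the elementwise product.
#' @export
beaver_mul <- function(session, x, y) {
  new_shared(
    beaver_mul_mat(session, as_share_mat(x, session), as_share_mat(y, session)),
    session$cfg$field
  )
}

xor_mat <- function(session, xmat, ymat) {
  f <- session$cfg$field
  prod <- beaver_mul_mat(session, xmat, ymat)
  # x + y - 2xy
  mat_sub(mat_add(xmat, ymat, f), mat_scale_cols(prod, unclass(fe(f, 2)), f), f)
}

#' XOR of shared bits
#'
#' Arithmetized as \eqn{x \oplus y = x + y - 2xy}; one triple per element.
#'
#' @inheritParams beaver_mul
#' @return a `shared_value` of bits.
#' @export
xor_bits <- function(session, x, y) {
  new_shared(
    xor_mat(session, as_share_mat(x, session), as_share_mat(y, session)),
    session$cfg$field
  )
}

#' Secure Hamming distance between shared bit vectors
#'
#' XORs the vectors positionwise (one triple per position) and sums the
#' mismatch indicators locally. With `records > 1` the inputs are treated
#' as `records` concatenated vectors of equal length and one distance is
#' returned per record — the batched layout the query circuit uses.
#'
#' @inheritParams beaver_mul
#' @param records number of concatenated bit vectors.
#' @return a `shared_value` of length `records` holding the distances.
#' @export
hamming_distance <- function(session, x, y, records = 1L) {
  xmat <- as_share_mat(x, session)
  ymat <- as_share_mat(y, session)
  if (ncol(xmat) != ncol(ymat)) stop("bit vectors have different lengths", call. = FALSE)
  if (records < 1L || ncol(xmat) %% records != 0L) {
    stop("vector length is not a multiple of the record count", call. = FALSE)
  }
  N <- ncol(xmat) %/% records
  f <- session$cfg$field
  mm <- xor_mat(session, xmat, ymat)
  sums <- mat_group_cols(mm, rep(seq_len(records), each = N), records, f)
  new_shared(sums, f)
}

# group-sum columns of an n x k share matrix into an n x ngroups matrix
mat_group_cols <- function(mat, col_groups, ngroups, field) {
  n <- nrow(mat)
  groups <- rep((col_groups - 1L) * n, each = n) + seq_len(n)
  matrix(fp_group_sum_cpp(as.vector(mat), groups, ngroups * n, field$p_hex), nrow = n)
}

mat_neg <- function(mat, field) {
  matrix(fp_neg_cpp(as.vector(mat), field$p_hex), nrow = nrow(mat))
}

pow2_hex <- function(j, field) {
  fp_pow_cpp(unclass(fe(field, 2)), fp_from_num_cpp(j, "ffffffffffffffff"), field$p_hex)
}

# weighted recomposition of bitwise shares: columns of `bitmat` are grouped
# per element, bit i scaled by 2^i, then summed per element
recompose_bits <- function(bitmat, nbits, k, field) {
  weights <- vapply(seq_len(nbits) - 1L, pow2_hex, character(1), field = field)
  scaled <- mat_scale_cols(bitmat, rep(weights, times = k), field)
  mat_group_cols(scaled, rep(seq_len(k), each = nbits), k, field)
}

#' Secure comparison with a public threshold
#'
#' Computes a shared bit equal to 1 iff the shared value is strictly below
#' the public threshold `B`. Realized by statistically masked bit
#' extraction: with \eqn{x \in [0, 2^l)} and \eqn{0 \le B \le 2^l}, set
#' \eqn{y = 2^l + x - B}, so \eqn{x < B} exactly when bit \eqn{l} of
#' \eqn{y} is 0. The parties open \eqn{y} additively masked by a dealer
#' random value whose low \eqn{l} bits are individually shared (plus
#' \eqn{\kappa} shared high bits), recover \eqn{y \bmod 2^l} with a
#' public-versus-shared borrow chain, and take bit \eqn{l} locally.
#' Correctness is exact; the opening leaks at most about
#' \eqn{2^{-\kappa}}. Costs are a fixed function of \eqn{(l, \kappa)}:
#' \eqn{l + \kappa} random bits, \eqn{l - 1} triples and one extra opening
#' per compared element.
#'
#' @param session an [mpc_session()].
#' @param x a `shared_value` with all entries in \eqn{[0, 2^l)}.
#' @param B public integer threshold, \eqn{0 \le B \le 2^l}.
#' @param l bit width; defaults to the session configuration.
#' @return a `shared_value` of indicator bits.
#' @export
lt_public <- function(session, x, B, l = session$cfg$l) {
  xmat <- as_share_mat(x, session)
  f <- session$cfg$field
  if (is.na(l)) stop("session was configured without a comparison bit width", call. = FALSE)
  l <- as.integer(l)
  kappa <- session$cfg$kappa
  stopifnot(B >= 0, B <= 2^l, l >= 1L)
  if (f$bit_length < l + kappa + 2L) {
    stop("field too small for comparison parameters p > 2^(l+kappa+1)", call. = FALSE)
  }
  k <- ncol(xmat)
  if (k == 0L) return(new_shared(xmat, f))

  low_bits <- take_bits(session$store, k * l)
  high_bits <- take_bits(session$store, k * kappa)
  ledger_bump(session$ledger, "random_bits_used", k * (l + kappa))
  r_low <- recompose_bits(low_bits, l, k, f) # n x k
  r_high <- recompose_bits(high_bits, kappa, k, f)

  # y = 2^l + x - B  (public constant to party 1);  open y + r_low + 2^l r'
  pub_y <- unclass(fe(f, 2^l - B))
  ymat <- mat_add_pub(xmat, rep(pub_y, k), f)
  masked <- mat_add(ymat, mat_add(r_low, mat_scale_cols(r_high, pow2_hex(l, f), f), f), f)
  c_pub <- open_mat(session, masked)
  cbits <- fp_bits_cpp(c_pub, l) # l x k, row i+1 = bit i
  c_low_num <- as.numeric(2^(seq_len(l) - 1) %*% cbits) # c mod 2^l, public

  # borrow of (c mod 2^l) - r_low, from LSB up; c-bit public per element
  bit_cols <- function(i) low_bits[, (seq_len(k) - 1L) * l + i, drop = FALSE]
  one <- unclass(fe(f, 1))
  b <- mat_scale_cols(bit_cols(1L), unclass(fe(f, 1 - cbits[1L, ])), f)
  if (l > 1L) {
    for (i in seq_len(l - 1L)) {
      Ri <- bit_cols(i + 1L)
      tt <- beaver_mul_mat(session, Ri, b)
      ci <- cbits[i + 1L, ]
      # ci == 1: borrow iff r_i & b ; ci == 0: borrow iff r_i | b
      or_term <- mat_sub(mat_add(Ri, b, f), tt, f)
      b <- mat_add(
        mat_scale_cols(tt, unclass(fe(f, ci)), f),
        mat_scale_cols(or_term, unclass(fe(f, 1 - ci)), f), f
      )
    }
  }

  # y mod 2^l = c_low - r_low + 2^l * borrow ; bit l = (y - y mod 2^l) / 2^l
  y_mod <- mat_add(mat_scale_cols(b, pow2_hex(l, f), f), mat_neg(r_low, f), f)
  y_mod <- mat_add_pub(y_mod, unclass(fe(f, c_low_num)), f)
  inv2l <- fp_inv_cpp(pow2_hex(l, f), f$p_hex)
  bit_l <- mat_scale_cols(mat_sub(ymat, y_mod, f), inv2l, f)
  s <- mat_add_pub(mat_neg(bit_l, f), rep(one, k), f)
  new_shared(s, f)
}

#' Multiply a list of shared values by one shared mask bit
#'
#' Element \eqn{i} of the result reconstructs to
#' \eqn{\mathrm{mask} \cdot \mathrm{value}_i}; one triple per value. This
#' is the conditional-inclusion step of the query circuit: a record's
#' contributions survive only if its similarity indicator is 1.
#'
#' @param session an [mpc_session()].
#' @param mask a `shared_value` of length 1 reconstructing to 0 or 1.
#' @param values a `shared_value` vector.
#' @return a `shared_value` of the masked values.
#' @export
masked_aggregate <- function(session, mask, values) {
  mmat <- as_share_mat(mask, session)
  vmat <- as_share_mat(values, session)
  stopifnot(ncol(mmat) == 1L)
  rep_mask <- mmat[, rep(1L, ncol(vmat)), drop = FALSE]
  new_shared(beaver_mul_mat(session, rep_mask, vmat), session$cfg$field)
}
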