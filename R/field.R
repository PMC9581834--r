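#' Prime fields for secret sharing
#'
#' All protocol values live in a prime field \eqn{F_p}. The production
#' default is the 128-bit pseudo-Mersenne prime \eqn{2^{128} - 159}
#' (see [default_prime()]); unit work typically uses small primes such as
#' 101 so that distributions and exhaustive properties can be checked.
#'
#' @param p the modulus, as a numeric (exact below 2^53) or a hex string
#'   (optionally `0x`-prefixed). Must be an odd prime of at most 128 bits.
#' @return an object of class `prime_field` with elements `p_hex` (canonical
#'   lowercase hex), `bit_length`, `bytes` (serialization width
#'   `ceiling(bit_length/8)`) and `p_num` (exact numeric value when the
#'   modulus is below 2^53, otherwise `NA`).
#' @examples
#' f <- prime_field(101)
#' fe(f, 99) + fe(f, 5)
#' @export
prime_field <- function(p) {
  p_hex <- as_hex_scalar(p)
  if (!fp_is_prime_cpp(p_hex)) {
    stop("modulus is not prime: ", p_hex, call. = FALSE)
  }
  nbits <- nchar_bits(p_hex)
  p_num <- if (nbits <= 53) fp_to_num_cpp(p_hex, "ffffffffffffffff", FALSE) else NA_real_
  if (!is.na(p_num) && p_num == 2) stop("modulus must be odd", call. = FALSE)
  structure(
    list(
      p_hex = canonical_hex(p_hex),
      bit_length = nbits,
      bytes = as.integer(ceiling(nbits / 8)),
      p_num = p_num
    ),
    class = "prime_field"
  )
}

as_hex_scalar <- function(p) {
  if (is.character(p)) {
    stopifnot(length(p) == 1L)
    canonical_hex(p)
  } else if (is.numeric(p)) {
    stopifnot(length(p) == 1L, p > 0, p == floor(p))
    canonical_hex(fp_from_num_cpp(p, "ffffffffffffffff"))
  } else {
    stop("modulus must be numeric or a hex string", call. = FALSE)
  }
}

canonical_hex <- function(x) {
  # normalize via a no-op C++ round trip (strips 0x, upper case, zeros)
  hex_canon_cpp(x)
}

nchar_bits <- function(p_hex) {
  bits <- fp_bits_cpp(p_hex, 256L)
  top <- which(bits[, 1] == 1L)
  if (length(top) == 0L) 0L else max(top)
}

#' @export
print.prime_field <- function(x, ...) {
  cat(sprintf("<prime field: p = 0x%s (%d bits)>\n", x$p_hex, x$bit_length))
  invisible(x)
}

#' The default 128-bit production prime
#'
#' \eqn{p = 2^{128} - 159}, the largest pseudo-Mersenne prime below
#' \eqn{2^{128}}. It satisfies the comparison-protocol requirement
#' \eqn{p > 2^{l + \kappa + 1}} for the default bit width `l = 8` and
#' statistical security `kappa = 40` with a wide margin.
#'
#' @return a `prime_field` object.
#' @export
default_prime <- function() {
  prime_field("ffffffffffffffffffffffffffffff61")
}

same_field <- function(f1, f2) {
  identical(f1$p_hex, f2$p_hex)
}

check_same_field <- function(f1, f2) {
  if (!same_field(f1, f2)) {
    stop("operands belong to different prime fields", call. = FALSE)
  }
}

#' Construct field elements
#'
#' @param field a [prime_field()].
#' @param x integer values (numeric, exact below 2^53; negatives are reduced
#'   mod p) or hex strings.
#' @return a classed character vector (`fe`) of canonical hex values with the
#'   field attached; standard arithmetic operators (`+`, `-`, `*`, `/`, `^`)
#'   dispatch to exact modular arithmetic.
#' @export
fe <- function(field, x) {
  stopifnot(inherits(field, "prime_field"))
  v <- if (is.character(x)) {
    fp_add_cpp(x, "0", field$p_hex)
  } else {
    fp_from_num_cpp(as.numeric(x), field$p_hex)
  }
  new_fe(v, field)
}

new_fe <- function(hex, field) {
  structure(hex, field = field, class = "fe")
}

fe_field <- function(x) attr(x, "field", exact = TRUE)

#' @export
print.fe <- function(x, ...) {
  f <- fe_field(x)
  cat(sprintf("<%d field element(s) mod 0x%s>\n", length(x), f$p_hex))
  print(unclass(`attr<-`(x, "field", NULL)))
  invisible(x)
}

#' @export
Ops.fe <- function(e1, e2) {
  if (.Generic %in% c("==", "!=")) {
    h1 <- if (inherits(e1, "fe")) unclass(e1) else fe(fe_field(e2), e1)
    h2 <- if (inherits(e2, "fe")) unclass(e2) else fe(fe_field(e1), e2)
    return(get(.Generic)(as.character(h1), as.character(h2)))
  }
  if (!.Generic %in% c("+", "-", "*", "/", "^")) {
    stop("operator '", .Generic, "' is not defined for field elements", call. = FALSE)
  }
  if (.Generic == "-" && missing(e2)) {
    f <- fe_field(e1)
    return(new_fe(fp_neg_cpp(unclass(e1), f$p_hex), f))
  }
  f1 <- if (inherits(e1, "fe")) fe_field(e1) else NULL
  f2 <- if (inherits(e2, "fe")) fe_field(e2) else NULL
  f <- if (!is.null(f1)) f1 else f2
  if (!is.null(f1) && !is.null(f2)) check_same_field(f1, f2)
  h1 <- if (inherits(e1, "fe")) unclass(e1) else unclass(fe(f, e1))
  h2 <- if (inherits(e2, "fe")) unclass(e2) else unclass(fe(f, e2))
  p <- f$p_hex
  out <- switch(.Generic,
    "+" = fp_add_cpp(h1, h2, p),
    "-" = fp_sub_cpp(h1, h2, p),
    "*" = fp_mul_cpp(h1, h2, p),
    "/" = fp_mul_cpp(h1, fp_inv_cpp(h2, p), p),
    "^" = fp_pow_cpp(h1, h2, p)
  )
  new_fe(out, f)
}

#' Elementary field arithmetic
#'
#' Functional form of the field operations, mirroring the operator interface:
#' `add`, `sub`, `mul` are binary; `inv` is unary (the second operand is
#' ignored); `pow` raises `a` to the integer exponent `b`.
#'
#' @param a,b field elements created with [fe()] (for `pow`, `b` may be a
#'   plain non-negative integer exponent).
#' @param op one of `"add"`, `"sub"`, `"mul"`, `"inv"`, `"pow"`.
#' @return a field element vector.
#' @examples
#' f <- prime_field(101)
#' arith(fe(f, 12), fe(f, 9), "mul") # 108 mod 101 = 7
#' @export
arith <- function(a, b = NULL, op = c("add", "sub", "mul", "inv", "pow")) {
  op <- match.arg(op)
  stopifnot(inherits(a, "fe"))
  if (op == "inv") {
    f <- fe_field(a)
    return(new_fe(fp_inv_cpp(unclass(a), f$p_hex), f))
  }
  if (op == "pow" && !inherits(b, "fe")) {
    f <- fe_field(a)
    b <- fe(f, b)
  }
  stopifnot(inherits(b, "fe"))
  switch(op, add = a + b, sub = a - b, mul = a * b, pow = a^b)
}

#' Signed integer encoding into a prime field
#'
#' Centered lift: integers in \eqn{[-(p-1)/2, (p-1)/2]} map bijectively onto
#' \eqn{F_p}, with negative values represented as \eqn{p - |x|}. This is how
#' intermediate differences such as \eqn{x - B} stay representable during the
#' comparison protocol.
#'
#' @param field a [prime_field()].
#' @param x integer vector with `|x| <= (p-1)/2`.
#' @return `encode_signed`: field elements; `decode_signed`: a numeric vector
#'   of exact integers.
#' @examples
#' f <- prime_field(101)
#' encode_signed(f, -1) # 100
#' decode_signed(fe(f, 100)) # -1
#' @export
encode_signed <- function(field, x) {
  stopifnot(inherits(field, "prime_field"), is.numeric(x))
  half_ok <- if (is.na(field$p_num)) {
    all(abs(x) < 2^53) # field bound implied: (p-1)/2 > 2^53 for p > 2^54
  } else {
    all(abs(x) <= (field$p_num - 1) / 2)
  }
  if (!half_ok) stop("value out of signed range |x| <= (p-1)/2", call. = FALSE)
  fe(field, x)
}

#' @rdname encode_signed
#' @param e a field element vector.
#' @export
decode_signed <- function(e) {
  stopifnot(inherits(e, "fe"))
  fp_to_num_cpp(unclass(e), fe_field(e)$p_hex, TRUE)
}

#' @export
as.double.fe <- function(x, ...) {
  fp_to_num_cpp(unclass(x), fe_field(x)$p_hex, FALSE)
}

#' Uniform random field elements
#'
#' Draws are uniform over \eqn{[0, p)} by rejection sampling from the
#' actor's deterministic generator, so every actor's stream is reproducible
#' from its seed.
#'
#' @param field a [prime_field()].
#' @param rng an [mpc_rng()] generator.
#' @param k number of draws.
#' @return a field element vector of length `k`.
#' @export
random_element <- function(field, rng, k = 1L) {
  stopifnot(inherits(field, "prime_field"))
  new_fe(rng_draw_below(rng, k, field$p_hex), field)
}
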