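#' Additive n-out-of-n secret sharing
#'
#' A secret \eqn{x \in F_p} is dispersed into \eqn{n} shares
#' \eqn{x_1, \dots, x_n} with \eqn{\sum_i x_i \equiv x \pmod p}: the first
#' \eqn{n-1} shares are independent uniform field elements and the last is
#' the difference. Any strict subset of shares is jointly uniform and so
#' carries no information about the secret; all \eqn{n} shares reconstruct
#' it exactly.
#'
#' @name secret_sharing
NULL

# internal: share a hex vector into an n x k matrix (row i = party i's shares)
share_mat <- function(hex, n, field, rng) {
  k <- length(hex)
  m <- matrix("0", nrow = n, ncol = k)
  if (k == 0L) return(m)
  if (n > 1L) {
    r <- matrix(rng_draw_below(rng, (n - 1L) * k, field$p_hex), nrow = n - 1L)
    m[seq_len(n - 1L), ] <- r
    tot <- if (n == 2L) r[1L, ] else apply_col_sum(r, field)
    m[n, ] <- fp_sub_cpp(hex, tot, field$p_hex)
  } else {
    m[1L, ] <- hex
  }
  m
}

apply_col_sum <- function(mat, field) {
  k <- ncol(mat)
  if (k == 0L) return(character(0))
  fp_group_sum_cpp(as.vector(mat), rep(seq_len(k), each = nrow(mat)), k, field$p_hex)
}

reconstruct_mat <- function(mat, field) {
  apply_col_sum(mat, field)
}

#' Share a secret among n parties
#'
#' @param x a field element vector ([fe()]) of secrets (each column of the
#'   result shares one secret).
#' @param n number of computing parties (at least 2).
#' @param rng the input owner's [mpc_rng()] generator.
#' @param label optional opaque identifier tying the shares of this secret
#'   together in share files.
#' @return a `shared_value`: list with `shares` (an `n` x `length(x)`
#'   character matrix of hex share values, row i held by party i), `field`,
#'   `n` and `label`.
#' @examples
#' f <- prime_field(101)
#' rng <- mpc_rng(1, "client")
#' sv <- share_secret(fe(f, 42), n = 2, rng = rng)
#' reconstruct(sv) # 42
#' @export
share_secret <- function(x, n = 2L, rng, label = NULL) {
  stopifnot(inherits(x, "fe"))
  n <- as.integer(n)
  if (n < 2L) stop("at least 2 parties are required", call. = FALSE)
  field <- fe_field(x)
  new_shared(share_mat(unclass(x), n, field, rng), field, label)
}

new_shared <- function(mat, field, label = NULL) {
  structure(
    list(shares = mat, field = field, n = nrow(mat), label = label),
    class = "shared_value"
  )
}

#' @export
print.shared_value <- function(x, ...) {
  cat(sprintf(
    "<shared value: %d secret(s) among %d parties mod 0x%s%s>\n",
    ncol(x$shares), x$n, x$field$p_hex,
    if (is.null(x$label)) "" else paste0(", label '", x$label, "'")
  ))
  invisible(x)
}

#' @export
length.shared_value <- function(x) ncol(x$shares)

#' Reconstruct a shared secret from all n shares
#'
#' @param x a `shared_value`, or a list of per-party share records as read
#'   from a share file (each with `party_index` and `value`).
#' @param field required when `x` is a bare list of share records.
#' @return the secret as a field element vector.
#' @export
reconstruct <- function(x, field = NULL) {
  if (inherits(x, "shared_value")) {
    return(new_fe(reconstruct_mat(x$shares, x$field), x$field))
  }
  # list of Share records: validate indices and labels
  stopifnot(is.list(x), !is.null(field))
  idx <- vapply(x, function(s) as.integer(s$party_index), integer(1))
  if (anyDuplicated(idx) || !setequal(idx, seq_along(x) - 1L)) {
    stop("shares must carry distinct party indices 0..n-1", call. = FALSE)
  }
  labs <- unique(vapply(x, function(s) as.character(s$label %||% ""), character(1)))
  if (length(labs) > 1L) stop("shares carry mismatched labels", call. = FALSE)
  vals <- vapply(x, function(s) as.character(s$value), character(1))
  new_fe(fp_sum_cpp(vals, field$p_hex), field)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Local linear combination of shared values
#'
#' Addition and public-scalar multiplication are non-interactive: each party
#' combines its own shares. A public additive constant is absorbed by party
#' 1 (index 0) by convention.
#'
#' @param terms list of `list(coef, sv)` pairs: a public coefficient
#'   (numeric or [fe()]) and a `shared_value`; all over the same field and
#'   party count.
#' @param constant public additive constant (numeric or [fe()]), default 0.
#' @return a `shared_value` reconstructing to
#'   \eqn{\sum_i c_i x_i + \mathrm{constant}}.
#' @export
linear_combine <- function(terms, constant = 0) {
  stopifnot(length(terms) >= 1L)
  field <- terms[[1L]]$sv$field
  n <- terms[[1L]]$sv$n
  k <- ncol(terms[[1L]]$sv$shares)
  acc <- matrix("0", nrow = n, ncol = k)
  for (tm in terms) {
    sv <- tm$sv
    stopifnot(inherits(sv, "shared_value"))
    check_same_field(field, sv$field)
    if (sv$n != n || ncol(sv$shares) != k) {
      stop("shared values have mismatched shape", call. = FALSE)
    }
    cf <- unclass(fe(field, tm$coef))
    scaled <- fp_mul_cpp(as.vector(sv$shares), rep(cf, length.out = n * k), field$p_hex)
    acc <- matrix(fp_add_cpp(as.vector(acc), scaled, field$p_hex), nrow = n)
  }
  cst <- unclass(fe(field, constant))
  acc[1L, ] <- fp_add_cpp(acc[1L, ], rep(cst, length.out = max(k, 1L))[seq_len(k)], field$p_hex)
  new_shared(acc, field)
}

# internal matrix-level linear ops used by the engine -------------------------

mat_add <- function(a, b, field) {
  matrix(fp_add_cpp(as.vector(a), as.vector(b), field$p_hex), nrow = nrow(a))
}

mat_sub <- function(a, b, field) {
  matrix(fp_sub_cpp(as.vector(a), as.vector(b), field$p_hex), nrow = nrow(a))
}

# multiply each column j of the n x k share matrix by public scalar pub[j]
mat_scale_cols <- function(a, pub, field) {
  matrix(fp_mul_cpp(as.vector(a), rep(pub, each = nrow(a)), field$p_hex), nrow = nrow(a))
}

# add public vector pub[j] to column j at party 1 only (row 1 convention)
mat_add_pub <- function(a, pub, field) {
  if (ncol(a) > 0L) a[1L, ] <- fp_add_cpp(a[1L, ], pub, field$p_hex)
  a
}
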