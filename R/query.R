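#' Patient cohorts
#'
#' A cohort is a data.frame with columns `patient_id`, `genotype` (a 0/1
#' string of fixed length N: presence/absence of a resistance-associated
#' mutation at each position), `treatment` (a label from the public
#' treatment manifest) and `ttf_days` (time-to-treatment-failure in days:
#' days from therapy start to switch, discontinuation or death). The
#' manifest — the ordered list of treatment labels — is public and defines
#' the one-hot encoding of treatments.
#'
#' @param records a cohort data.frame.
#' @param manifest character vector of treatment labels.
#' @return the validated cohort (invisibly), with genotype length `N` and
#'   the manifest attached as attributes.
#' @export
validate_cohort <- function(records, manifest) {
  req <- c("patient_id", "genotype", "treatment", "ttf_days")
  if (!all(req %in% names(records))) {
    stop("cohort must have columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(manifest)) stop("treatment manifest has duplicate labels", call. = FALSE)
  geno <- as.character(records$genotype)
  if (nrow(records) > 0L) {
    lens <- nchar(geno)
    if (length(unique(lens)) > 1L) {
      stop("ragged cohort: genotypes have differing lengths", call. = FALSE)
    }
    bad <- grep("^[01]+$", geno, invert = TRUE)
    if (length(bad) > 0L) {
      stop("invalid genotype at record ", bad[1L],
        ": must be a 0/1 string", call. = FALSE)
    }
    unknown <- !records$treatment %in% manifest
    if (any(unknown)) {
      stop("treatment label not in manifest at record ", which(unknown)[1L],
        ": '", records$treatment[which(unknown)[1L]], "'", call. = FALSE)
    }
    if (any(records$ttf_days < 0) || any(records$ttf_days != floor(records$ttf_days))) {
      stop("ttf_days must be non-negative integers", call. = FALSE)
    }
  }
  attr(records, "N") <- if (nrow(records) > 0L) nchar(geno[1L]) else NA_integer_
  attr(records, "manifest") <- manifest
  invisible(records)
}

genotype_bits <- function(geno_strings) {
  if (length(geno_strings) == 0L) return(matrix(0L, 0L, 0L))
  do.call(rbind, lapply(strsplit(geno_strings, ""), as.integer))
}

#' Secret-share a patient database among the computing parties
#'
#' Every scalar of every record — N genotype bits, T one-hot treatment
#' bits, and the TTF value — is additively shared with the client's
#' generator. Only the shape (m, N, T) is public; a computing party's rows
#' are uniformly random field elements.
#'
#' @param session an [mpc_session()].
#' @param records a cohort data.frame (see [validate_cohort()]).
#' @param manifest the public ordered treatment manifest.
#' @param rng the input owner's generator; defaults to the session client
#'   stream.
#' @return a `shared_database`: shared genotype bits, one-hot bits and TTF
#'   values plus the public shape.
#' @export
share_database <- function(session, records, manifest, rng = session$client_rng) {
  records <- validate_cohort(records, manifest)
  f <- session$cfg$field
  n <- session$cfg$n
  m <- nrow(records)
  N <- attr(records, "N")
  T_ <- length(manifest)
  if (m > 0L) {
    max_ttf <- max(records$ttf_days, 0)
    bound <- if (is.na(f$p_num)) 2^53 else (f$p_num - 1) / 2
    if (m * max_ttf >= bound) {
      stop("ttf values too large: per-treatment sums could wrap the field",
        call. = FALSE)
    }
  }
  geno <- genotype_bits(as.character(records$genotype))
  onehot <- matrix(0L, nrow = m, ncol = T_)
  if (m > 0L) onehot[cbind(seq_len(m), match(records$treatment, manifest))] <- 1L
  # record-major flattening: record r occupies columns (r-1)*N + 1 .. r*N
  geno_flat <- unclass(fe(f, as.vector(t(geno))))
  onehot_flat <- unclass(fe(f, as.vector(t(onehot))))
  ttf <- unclass(fe(f, records$ttf_days))
  structure(
    list(
      geno = new_shared(share_mat(geno_flat, n, f, rng), f),
      onehot = new_shared(share_mat(onehot_flat, n, f, rng), f),
      ttf = new_shared(share_mat(ttf, n, f, rng), f),
      m = m, N = if (is.na(N)) NA_integer_ else as.integer(N), T_ = T_,
      manifest = manifest, field = f
    ),
    class = "shared_database"
  )
}

#' @export
print.shared_database <- function(x, ...) {
  cat(sprintf(
    "<shared database: m=%d records, N=%s genotype bits, T=%d treatments>\n",
    x$m, ifelse(is.na(x$N), "?", x$N), x$T_
  ))
  invisible(x)
}

#' Build a secret-shared similarity query
#'
#' The query genotype is secret-shared like a database record; the
#' similarity threshold `B` is a public parameter chosen by the querying
#' clinician.
#'
#' @param session an [mpc_session()].
#' @param genotype the query genotype: a 0/1 string or an integer 0/1
#'   vector of length N.
#' @param B public integer threshold, `0 <= B <= N`; records at Hamming
#'   distance strictly below `B` count as similar.
#' @param rng the clinician's generator; defaults to the session client
#'   stream.
#' @return an `mpc_query` with shared genotype bits and public `B`.
#' @export
make_query <- function(session, genotype, B, rng = session$client_rng) {
  if (is.character(genotype)) {
    stopifnot(length(genotype) == 1L)
    if (!grepl("^[01]+$", genotype)) stop("genotype must be a 0/1 string", call. = FALSE)
    genotype <- as.integer(strsplit(genotype, "")[[1L]])
  }
  stopifnot(all(genotype %in% c(0L, 1L)))
  N <- length(genotype)
  if (B < 0 || B > N) stop("threshold B must lie in [0, N]", call. = FALSE)
  f <- session$cfg$field
  structure(
    list(
      geno = new_shared(share_mat(unclass(fe(f, genotype)), session$cfg$n, f, rng), f),
      B = as.integer(B), N = N
    ),
    class = "mpc_query"
  )
}

#' Run the oblivious similar-patient query
#'
#' For each record i the parties compute the shared Hamming distance
#' \eqn{d_i} between the query genotype and the record genotype, the
#' similarity indicator \eqn{s_i = [d_i < B]}, and the masked TTF
#' \eqn{u_i = s_i \cdot ttf_i}; per treatment t they accumulate
#' \eqn{S_t = \sum_i u_i \cdot \mathrm{onehot}_{i,t}} and
#' \eqn{C_t = \sum_i s_i \cdot \mathrm{onehot}_{i,t}}. The parties output
#' only shares of \eqn{(S_t, C_t)} and reconstruct nothing themselves;
#' distances are computed once per record and reused across all T
#' treatments. The whole path is oblivious: which records match, and the
#' value of any secret, never influences control flow, message counts or
#' bytes.
#'
#' @param session an [mpc_session()] provisioned with enough preprocessing
#'   (see [deal_for_query()]); the run aborts upfront, before any opening,
#'   if the store cannot cover the circuit.
#' @param db a [share_database()] result.
#' @param query a [make_query()] result with matching genotype length.
#' @return an `mpc_result`: per-party shares of the per-treatment sums and
#'   counts, for the client to reconstruct.
#' @export
run_query <- function(session, db, query) {
  stopifnot(inherits(db, "shared_database"), inherits(query, "mpc_query"))
  f <- session$cfg$field
  n <- session$cfg$n
  m <- db$m
  T_ <- db$T_
  if (m > 0L && query$N != db$N) {
    stop("query genotype length does not match the database", call. = FALSE)
  }
  if (m == 0L) {
    zero <- new_shared(matrix("0", n, T_), f)
    return(structure(
      list(S = zero, C = zero, manifest = db$manifest, B = query$B, m = 0L),
      class = "mpc_result"
    ))
  }
  N <- db$N
  l <- session$cfg$l
  if (is.na(l)) stop("session was configured without a comparison bit width", call. = FALSE)
  if (N >= 2^l) stop("genotype length exceeds the comparison bit width 2^l", call. = FALSE)
  est <- estimate_query_cost(m, N, T_,
    l = l, kappa = session$cfg$kappa,
    n = n, field = f
  )
  if (session$store$triples_dealt - session$store$triple_cursor < est$triples_used ||
    session$store$bits_dealt - session$store$bit_cursor < est$random_bits_used) {
    stop("insufficient preprocessing for this query: need ",
      est$triples_used, " triples and ", est$random_bits_used,
      " random bits (see deal_for_query)",
      call. = FALSE
    )
  }

  q_rep <- new_shared(query$geno$shares[, rep(seq_len(N), m), drop = FALSE], f)
  dist <- hamming_distance(session, db$geno, q_rep, records = m)
  s_ind <- lt_public(session, dist, query$B, l = l)
  u <- beaver_mul(session, s_ind, db$ttf)

  # one batched layer: S_t terms then C_t terms against the one-hot bits
  su_rep <- cbind(
    u$shares[, rep(seq_len(m), each = T_), drop = FALSE],
    s_ind$shares[, rep(seq_len(m), each = T_), drop = FALSE]
  )
  oh2 <- cbind(db$onehot$shares, db$onehot$shares)
  prod <- beaver_mul_mat(session, su_rep, oh2)
  tgroups <- rep(seq_len(T_), m)
  S <- mat_group_cols(prod[, seq_len(m * T_), drop = FALSE], tgroups, T_, f)
  C <- mat_group_cols(prod[, m * T_ + seq_len(m * T_), drop = FALSE], tgroups, T_, f)
  structure(
    list(S = new_shared(S, f), C = new_shared(C, f),
         manifest = db$manifest, B = query$B, m = m),
    class = "mpc_result"
  )
}

#' @export
print.mpc_result <- function(x, ...) {
  cat(sprintf(
    "<shared query result: %d treatments, threshold B=%d (only the querying client can reconstruct)>\n",
    length(x$manifest), x$B
  ))
  invisible(x)
}

#' Reconstruct the query result at the querying clinician
#'
#' The client combines all parties' result shares and decodes, per
#' treatment, the TTF sum (days) and the count of similar patients, then
#' divides locally: the average TTF is \eqn{S_t / C_t} when
#' \eqn{C_t > 0} and undefined ("no similar patients") otherwise — no
#' division is ever attempted under MPC. Revealing the count alongside the
#' sum is a deliberate, documented disclosure: sum and count jointly
#' determine the average and the similar-cohort size.
#'
#' @param result an `mpc_result` from [run_query()].
#' @return a `query_result` data.frame with columns `treatment`,
#'   `sum_days`, `count`, `average_days` (`NA` when `count` is 0).
#' @export
client_reconstruct <- function(result) {
  stopifnot(inherits(result, "mpc_result"))
  S <- as.numeric(reconstruct(result$S))
  C <- as.numeric(reconstruct(result$C))
  out <- data.frame(
    treatment = result$manifest,
    sum_days = S,
    count = C,
    average_days = ifelse(C > 0, S / C, NA_real_),
    stringsAsFactors = FALSE
  )
  class(out) <- c("query_result", "data.frame")
  out
}

#' @export
print.query_result <- function(x, ...) {
  y <- x
  class(y) <- "data.frame"
  y$average_days <- ifelse(is.na(y$average_days), "no similar patients",
    format(y$average_days, digits = 6))
  print(y, row.names = FALSE)
  invisible(x)
}

#' Write a query result as CSV
#'
#' Columns `treatment,sum_days,count,average_days`, with an empty average
#' field when the count is zero.
#'
#' @param result a `query_result`.
#' @param path output file.
#' @export
write_query_result <- function(result, path) {
  out <- as.data.frame(result)
  out$average_days <- ifelse(is.na(out$average_days), "", format(out$average_days))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
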