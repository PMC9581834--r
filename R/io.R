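#' Share files
#'
#' A share file holds one party's share of each shared scalar, one record
#' per line: `label`, `party_index`, `value` (hex). The input client (or
#' the dealer) writes one file per party; each computing party reads only
#' its own. `read_shares` reassembles a `shared_value` from all party
#' files, which is how the orchestration layer (and tests) rebuild a
#' shared database from disk.
#'
#' @param sv a `shared_value`.
#' @param dir directory for the per-party files.
#' @param name base name; files are `<name>_party<i>.tsv`.
#' @param labels optional per-scalar labels (default `name.1`, `name.2`,
#'   ...).
#' @return `write_shares`: the paths, invisibly; `read_shares`: a
#'   `shared_value`.
#' @export
write_shares <- function(sv, dir, name, labels = NULL) {
  stopifnot(inherits(sv, "shared_value"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  k <- ncol(sv$shares)
  if (is.null(labels)) labels <- paste0(name, ".", seq_len(k))
  stopifnot(length(labels) == k)
  paths <- character(sv$n)
  for (i in seq_len(sv$n)) {
    df <- data.frame(
      label = labels, party_index = i - 1L, value = sv$shares[i, ],
      stringsAsFactors = FALSE
    )
    paths[i] <- file.path(dir, sprintf("%s_party%d.tsv", name, i - 1L))
    utils::write.table(df, paths[i], sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(paths)
}

#' @rdname write_shares
#' @param field the prime field of the shares.
#' @param n number of parties.
#' @export
read_shares <- function(dir, name, field, n = 2L) {
  rows <- lapply(seq_len(n) - 1L, function(i) {
    path <- file.path(dir, sprintf("%s_party%d.tsv", name, i))
    if (!file.exists(path)) stop("missing share file: ", path, call. = FALSE)
    df <- utils::read.table(path, header = TRUE, sep = "\t", colClasses = "character")
    if (any(as.integer(df$party_index) != i)) {
      stop("share file ", path, " carries a foreign party index", call. = FALSE)
    }
    df
  })
  labels <- rows[[1L]]$label
  for (df in rows[-1L]) {
    if (!identical(df$label, labels)) {
      stop("share files disagree on scalar labels", call. = FALSE)
    }
  }
  mat <- do.call(rbind, lapply(rows, function(df) df$value))
  new_shared(matrix(mat, nrow = n), field, label = name)
}

#' Persist a shared database as per-party share files
#'
#' Writes the genotype, one-hot and TTF share components plus a public
#' metadata file (shape and manifest). The counterpart of
#' [share_database()] for the file-based workflow.
#'
#' @param db a `shared_database`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_database_shares <- function(db, dir) {
  stopifnot(inherits(db, "shared_database"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_shares(db$geno, dir, "geno")
  write_shares(db$onehot, dir, "onehot")
  write_shares(db$ttf, dir, "ttf")
  meta <- c(
    paste0("m: ", db$m),
    paste0("N: ", ifelse(is.na(db$N), 0L, db$N)),
    paste0("T: ", db$T_),
    paste0("p: ", db$field$p_hex),
    paste0("n: ", db$geno$n)
  )
  writeLines(meta, file.path(dir, "db_meta.txt"))
  write_manifest(db$manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' @rdname write_database_shares
#' @export
read_database_shares <- function(dir) {
  meta_lines <- readLines(file.path(dir, "db_meta.txt"))
  meta <- as.list(stats::setNames(
    sub("^[^:]+: *", "", meta_lines),
    sub(":.*$", "", meta_lines)
  ))
  field <- prime_field(meta$p)
  n <- as.integer(meta$n)
  manifest <- read_manifest(file.path(dir, "manifest.txt"))
  structure(
    list(
      geno = read_shares(dir, "geno", field, n),
      onehot = read_shares(dir, "onehot", field, n),
      ttf = read_shares(dir, "ttf", field, n),
      m = as.integer(meta$m),
      N = if (as.integer(meta$m) == 0L) NA_integer_ else as.integer(meta$N),
      T_ = as.integer(meta$T),
      manifest = manifest, field = field
    ),
    class = "shared_database"
  )
}
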