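# Shared fixtures: small fields and the 4-record worked example.

f11 <- function() prime_field(11)
f101 <- function() prime_field(101)
m61 <- function() prime_field("1fffffffffffffff") # Mersenne prime 2^61 - 1

# session over a field with no comparison constraint (for open/beaver tests)
plain_session <- function(field, seed = 1) {
  mpc_session(protocol_config(field = field, l = NA, seed = seed))
}

cmp_session <- function(field = m61(), kappa = 10L, l = 5L, seed = 1) {
  mpc_session(protocol_config(field = field, kappa = kappa, l = l, seed = seed))
}

# share a plain numeric vector with the session's client stream
share_num <- function(s, x) {
  share_secret(fe(s$cfg$field, x), n = s$cfg$n, rng = s$client_rng)
}

open_num <- function(s, sv) as.numeric(mpc_open(s, sv))

# decode a raw hex share vector numerically
new_fe_test <- function(hex, field) ppcdss:::new_fe(hex, field)

# the 4-record hand-enumerable cohort: query 1010, B = 2 ->
# A: sum 300 over 2 similar patients; B: sum 300 over 1
worked_records <- function() {
  data.frame(
    patient_id = c("p1", "p2", "p3", "p4"),
    genotype = c("1010", "1110", "0101", "1010"),
    treatment = c("A", "A", "A", "B"),
    ttf_days = c(100, 200, 50, 300),
    stringsAsFactors = FALSE
  )
}

worked_manifest <- function() c("A", "B")

run_secure_query <- function(cohort, manifest, genotype, B, config) {
  s <- mpc_session(config)
  on.exit(close_session(s))
  if (nrow(cohort) > 0L) {
    deal_for_query(s$store, nrow(cohort), nchar(cohort$genotype[1L]),
      length(manifest),
      l = config$l, kappa = config$kappa
    )
  }
  db <- share_database(s, cohort, manifest)
  q <- make_query(s, genotype, B)
  res <- run_query(s, db, q)
  list(result = client_reconstruct(res), ledger = as.data.frame(s$ledger),
       transcript = s$transcript_lengths)
}
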