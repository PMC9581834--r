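worked_cfg <- function(seed = 21) {
  protocol_config(field = m61(), kappa = 10, l = 3, seed = seed)
}

test_that("database sharing round-trips and hides contents", {
  cfg <- worked_cfg()
  s <- mpc_session(cfg)
  records <- worked_records()
  db <- share_database(s, records, worked_manifest())
  expect_equal(db$m, 4L)
  expect_equal(db$N, 4L)
  expect_equal(db$T_, 2L)
  f <- cfg$field
  geno <- as.numeric(reconstruct(db$geno))
  expect_equal(geno, as.vector(t(ppcdss:::genotype_bits(records$genotype))))
  expect_equal(as.numeric(reconstruct(db$ttf)), records$ttf_days)
  onehot <- matrix(as.numeric(reconstruct(db$onehot)), ncol = 2, byrow = TRUE)
  expect_equal(onehot, cbind(c(1, 1, 1, 0), c(0, 0, 0, 1)))
  # a single party's rows carry no structure: re-sharing under a different
  # seed changes every share but reconstructs identically
  s2 <- mpc_session(worked_cfg(seed = 22))
  db2 <- share_database(s2, records, worked_manifest())
  expect_false(any(db$ttf$shares[1, ] == db2$ttf$shares[1, ]))
  expect_equal(as.numeric(reconstruct(db2$ttf)), records$ttf_days)
})

test_that("sharing an empty cohort yields shape (0, N, T)", {
  s <- mpc_session(worked_cfg())
  empty <- worked_records()[0, ]
  db <- share_database(s, empty, worked_manifest())
  expect_equal(db$m, 0L)
  res <- run_query(s, db, make_query(s, "1010", 2))
  out <- client_reconstruct(res)
  expect_equal(out$count, c(0, 0))
  expect_true(all(is.na(out$average_days)))
  expect_equal(as.data.frame(s$ledger)$bytes_sent, 0)
})

test_that("malformed cohorts are rejected", {
  s <- mpc_session(worked_cfg())
  bad_len <- worked_records()
  bad_len$genotype[2] <- "10101"
  expect_error(share_database(s, bad_len, worked_manifest()), "ragged")
  bad_chr <- worked_records()
  bad_chr$genotype[3] <- "10a0"
  expect_error(share_database(s, bad_chr, worked_manifest()), "0/1 string")
  bad_trt <- worked_records()
  bad_trt$treatment[1] <- "Z"
  expect_error(share_database(s, bad_trt, worked_manifest()), "manifest")
  big_ttf <- worked_records()
  big_ttf$ttf_days[1] <- 2^60
  expect_error(share_database(s, big_ttf, worked_manifest()), "wrap")
})

test_that("the worked example reconstructs averages 150 and 300 days", {
  out <- run_secure_query(worked_records(), worked_manifest(), "1010", 2, worked_cfg())
  expect_equal(out$result$sum_days, c(300, 300))
  expect_equal(out$result$count, c(2, 1))
  expect_equal(out$result$average_days, c(150, 300))
})

test_that("B = 0 matches no one (strict inequality)", {
  out <- run_secure_query(worked_records(), worked_manifest(), "1010", 0, worked_cfg())
  expect_equal(out$result$sum_days, c(0, 0))
  expect_equal(out$result$count, c(0, 0))
  expect_true(all(is.na(out$result$average_days)))
})

test_that("a single similar patient returns that patient's TTF", {
  records <- worked_records()
  out <- run_secure_query(records, worked_manifest(), "0101", 1, worked_cfg())
  expect_equal(out$result$count, c(1, 0))
  expect_equal(out$result$average_days[1], 50)
})

test_that("secure pipeline equals the oracle on a seeded cohort", {
  cohort <- generate_cohort(cohort_spec(m = 60, N = 24, T_ = 5, pi = 0.2, seed = 17))
  manifest <- attr(cohort, "manifest")
  qg <- as.character(cohort$genotype[7])
  cfg <- protocol_config(field = m61(), kappa = 10, l = 5, seed = 23)
  out <- run_secure_query(cohort, manifest, qg, B = 6, config = cfg)
  orc <- oracle_query(cohort, manifest, qg, B = 6)
  expect_identical(out$result$sum_days, orc$sum_days)
  expect_identical(out$result$count, orc$count)
})

test_that("queries without sufficient preprocessing abort before any opening", {
  cfg <- worked_cfg()
  s <- mpc_session(cfg)
  db <- share_database(s, worked_records(), worked_manifest())
  q <- make_query(s, "1010", 2)
  expect_error(run_query(s, db, q), "insufficient preprocessing")
  expect_equal(as.data.frame(s$ledger)$openings, 0)
})

test_that("query construction validates genotype and threshold", {
  s <- mpc_session(worked_cfg())
  expect_error(make_query(s, "10a0", 1), "0/1 string")
  expect_error(make_query(s, "1010", 5), "\\[0, N\\]")
  db <- share_database(s, worked_records(), worked_manifest())
  q3 <- make_query(s, "101", 1)
  expect_error(run_query(s, db, q3), "length does not match")
})
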