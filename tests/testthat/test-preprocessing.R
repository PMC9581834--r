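test_that("dealt triples satisfy c = ab and a is uniform", {
  f <- f11()
  store <- preprocessing_store(f, 2, mpc_rng(6, "dealer"))
  deal_triples(store, 1000)
  tr <- ppcdss:::take_triples(store, 1000)
  a <- as.numeric(new_fe_test(ppcdss:::reconstruct_mat(tr$a, f), f))
  b <- as.numeric(new_fe_test(ppcdss:::reconstruct_mat(tr$b, f), f))
  cc <- as.numeric(new_fe_test(ppcdss:::reconstruct_mat(tr$c, f), f))
  expect_equal(cc, (a * b) %% 11)
  expect_gt(stats::chisq.test(tabulate(a + 1, nbins = 11))$p.value, 0.01)
})

test_that("empty deals leave an empty store", {
  f <- f101()
  store <- preprocessing_store(f, 2, mpc_rng(1, "dealer"))
  deal_triples(store, 0)
  deal_random_bits(store, 0)
  expect_equal(store$triples_dealt, 0)
  expect_equal(store$bits_dealt, 0)
})

test_that("dealt random bits are bits with mean near one half", {
  f <- f101()
  store <- preprocessing_store(f, 2, mpc_rng(2, "dealer"))
  deal_random_bits(store, 1e4)
  bits <- as.numeric(new_fe_test(
    ppcdss:::reconstruct_mat(ppcdss:::take_bits(store, 1e4), f), f
  ))
  expect_true(all(bits %in% c(0, 1)))
  ci <- stats::qbinom(c(0.005, 0.995), 1e4, 0.5) / 1e4
  expect_gte(mean(bits), ci[1])
  expect_lte(mean(bits), ci[2])
})

test_that("store exhaustion and reuse are impossible", {
  f <- f101()
  store <- preprocessing_store(f, 2, mpc_rng(3, "dealer"))
  deal_triples(store, 5)
  ppcdss:::take_triples(store, 5)
  expect_error(ppcdss:::take_triples(store, 1), "exhausted")
  expect_error(ppcdss:::take_bits(store, 1), "exhausted")
})

test_that("query cost is zero for an empty database and affine in m", {
  z <- estimate_query_cost(0, 150, 100)
  expect_true(all(as.numeric(z) == 0))
  c1 <- estimate_query_cost(100, 150, 100)
  c2 <- estimate_query_cost(200, 150, 100)
  c3 <- estimate_query_cost(300, 150, 100)
  for (col in names(c1)[names(c1) != "rounds"]) {
    expect_equal(c2[[col]] - c1[[col]], c3[[col]] - c2[[col]])
  }
  expect_equal(c1$rounds, c3$rounds) # round count is size-independent
})

test_that("full-scale query stays within the offline triple budget", {
  est <- estimate_query_cost(m = 20000, N = 200, T_ = 100, kappa = 40)
  expect_lte(est$triple_equivalents, 40e6)
})

test_that("dry-run estimate equals the executed ledger exactly", {
  for (shape in list(c(m = 7, N = 6, T_ = 3), c(m = 20, N = 12, T_ = 5))) {
    cfg <- protocol_config(field = m61(), kappa = 8, l = 4, seed = 30 + shape[["m"]])
    cohort <- generate_cohort(cohort_spec(
      m = shape[["m"]], N = shape[["N"]], T_ = shape[["T_"]],
      pi = 0.3, seed = 5
    ))
    out <- run_secure_query(cohort, attr(cohort, "manifest"),
      as.character(cohort$genotype[1]),
      B = 3, config = cfg
    )
    est <- estimate_query_cost(shape[["m"]], shape[["N"]], shape[["T_"]],
      l = 4, kappa = 8, field = m61()
    )
    expect_equal(out$ledger, est)
  }
})

test_that("preprocessing files round-trip through disk", {
  f <- f101()
  store <- preprocessing_store(f, 2, mpc_rng(11, "dealer"))
  deal_triples(store, 8)
  deal_random_bits(store, 6)
  dir <- withr::local_tempdir()
  write_preprocessing(store, dir)
  back <- read_preprocessing(dir, f, n = 2)
  expect_equal(back$triples_dealt, 8)
  expect_equal(back$bits_dealt, 6)
  tr1 <- ppcdss:::take_triples(store2 <- back, 8)
  a <- as.numeric(new_fe_test(ppcdss:::reconstruct_mat(tr1$a, f), f))
  b <- as.numeric(new_fe_test(ppcdss:::reconstruct_mat(tr1$b, f), f))
  cc <- as.numeric(new_fe_test(ppcdss:::reconstruct_mat(tr1$c, f), f))
  expect_equal(cc, (a * b) %% 101)
  bits <- as.numeric(new_fe_test(
    ppcdss:::reconstruct_mat(ppcdss:::take_bits(back, 6), f), f
  ))
  expect_true(all(bits %in% c(0, 1)))
})
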