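test_that("sharing round-trips for any secret and party count", {
  f <- f101()
  rng <- mpc_rng(3, "client")
  for (n in c(2L, 3L, 5L)) {
    x <- fe(f, c(0, 1, 42, 100))
    sv <- share_secret(x, n = n, rng = rng)
    expect_equal(nrow(sv$shares), n)
    expect_true(all(reconstruct(sv) == x))
  }
  expect_error(share_secret(fe(f, 1), n = 1, rng = rng), "at least 2")
})

test_that("reconstruction round-trips exhaustively over F_11", {
  f <- f11()
  rng <- mpc_rng(9, "client")
  x <- fe(f, 0:10)
  sv <- share_secret(x, n = 2, rng = rng)
  expect_equal(as.numeric(reconstruct(sv)), 0:10)
})

test_that("share-record reconstruction validates indices and labels", {
  f <- f101()
  expect_equal(as.numeric(reconstruct(
    list(
      list(party_index = 0, value = "5", label = "x"),
      list(party_index = 1, value = "63", label = "x") # 5 + 99 = 104 = 3
    ),
    field = f
  )), 3)
  expect_error(reconstruct(
    list(
      list(party_index = 0, value = "5", label = "x"),
      list(party_index = 0, value = "63", label = "x")
    ),
    field = f
  ), "distinct party indices")
  expect_error(reconstruct(
    list(
      list(party_index = 0, value = "5", label = "x"),
      list(party_index = 1, value = "63", label = "y")
    ),
    field = f
  ), "mismatched labels")
})

test_that("additivity of shares holds exhaustively over F_11", {
  f <- f11()
  rng <- mpc_rng(4, "client")
  grid <- expand.grid(x = 0:10, y = 0:10)
  sx <- share_secret(fe(f, grid$x), rng = rng)
  sy <- share_secret(fe(f, grid$y), rng = rng)
  sum_sv <- linear_combine(list(list(coef = 1, sv = sx), list(coef = 1, sv = sy)))
  expect_equal(as.numeric(reconstruct(sum_sv)), (grid$x + grid$y) %% 11)
})

test_that("linear combinations reconstruct to the plaintext combination", {
  f <- f101()
  rng <- mpc_rng(5, "client")
  x <- share_secret(fe(f, 3), rng = rng)
  y <- share_secret(fe(f, 4), rng = rng)
  z <- linear_combine(list(list(coef = 2, sv = x), list(coef = 1, sv = y)), constant = 5)
  expect_equal(as.numeric(reconstruct(z)), 15)
  expect_equal(as.numeric(reconstruct(linear_combine(list(list(coef = 1, sv = x))))), 3)
  # randomized cases against plaintext evaluation, small field
  f2 <- f11()
  set.seed(1)
  for (i in 1:100) {
    xs <- sample(0:10, 3)
    cs <- sample(0:10, 3, replace = TRUE)
    k <- sample(0:10, 1)
    svs <- lapply(xs, function(v) share_secret(fe(f2, v), rng = rng))
    terms <- Map(function(cf, sv) list(coef = cf, sv = sv), cs, svs)
    got <- as.numeric(reconstruct(linear_combine(terms, constant = k)))
    expect_equal(got, (sum(cs * xs) + k) %% 11)
  }
})

test_that("a single party's share of a fixed secret is uniform", {
  f <- f101()
  rng <- mpc_rng(8, "client")
  sv <- share_secret(fe(f, rep(42, 2e4)), n = 2, rng = rng)
  first <- as.numeric(new_fe_test(sv$shares[1, ], f))
  counts <- tabulate(first + 1, nbins = 101)
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
  # and the second share is determined but also marginally uniform
  second <- as.numeric(new_fe_test(sv$shares[2, ], f))
  expect_gt(stats::chisq.test(tabulate(second + 1, nbins = 101))$p.value, 0.01)
  expect_true(all((first + second) %% 101 == 42))
})
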