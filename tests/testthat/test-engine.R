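test_that("opening reveals the same value at every party", {
  s <- plain_session(f11(), seed = 2)
  # exhaustive over all secrets in F_11
  sv <- share_num(s, 0:10)
  expect_equal(open_num(s, sv), 0:10)
  expect_equal(open_num(s, share_num(s, 0)), 0)
  expect_equal(open_num(s, share_num(s, 7)), 7)
  expect_equal(s$ledger$openings, 13)
})

test_that("Beaver multiplication matches the plaintext product", {
  # exhaustive over all 121 pairs of F_11
  s <- plain_session(f11(), seed = 3)
  grid <- expand.grid(x = 0:10, y = 0:10)
  deal_triples(s$store, nrow(grid))
  z <- beaver_mul(s, share_num(s, grid$x), share_num(s, grid$y))
  expect_equal(open_num(s, z), (grid$x * grid$y) %% 11)
  expect_equal(s$ledger$triples_used, 121)

  # randomized cases at the 128-bit production prime
  f <- default_prime()
  s2 <- plain_session(f, seed = 4)
  deal_triples(s2$store, 100)
  xr <- random_element(f, mpc_rng(50, "a"), 100)
  yr <- random_element(f, mpc_rng(51, "b"), 100)
  sx <- share_secret(xr, rng = s2$client_rng)
  sy <- share_secret(yr, rng = s2$client_rng)
  got <- mpc_open(s2, beaver_mul(s2, sx, sy))
  expect_identical(unclass(got), unclass(xr * yr))
})

test_that("multiplying by a shared zero absorbs", {
  s <- plain_session(f101(), seed = 5)
  deal_triples(s$store, 20)
  y <- share_num(s, sample(0:100, 20, replace = TRUE))
  z <- beaver_mul(s, share_num(s, rep(0, 20)), y)
  expect_equal(open_num(s, z), rep(0, 20))
})

test_that("Beaver multiplication without triples aborts", {
  s <- plain_session(f101(), seed = 6)
  expect_error(
    beaver_mul(s, share_num(s, 1), share_num(s, 2)),
    "exhausted"
  )
})

test_that("shared XOR realizes the truth table", {
  s <- plain_session(f101(), seed = 7)
  deal_triples(s$store, 16)
  grid <- expand.grid(x = 0:1, y = 0:1)
  z <- xor_bits(s, share_num(s, grid$x), share_num(s, grid$y))
  expect_equal(open_num(s, z), as.numeric(xor(grid$x, grid$y)))
  # identity with zero
  b <- c(0, 1)
  expect_equal(open_num(s, xor_bits(s, share_num(s, rep(0, 2)), share_num(s, b))), b)
})

test_that("secure Hamming distance equals the plaintext distance", {
  s <- cmp_session(seed = 8)
  deal_triples(s$store, 5000)
  # identical vectors are at distance zero
  v <- c(1, 0, 1, 0)
  expect_equal(
    open_num(s, hamming_distance(s, share_num(s, v), share_num(s, v))), 0
  )
  expect_equal(
    open_num(s, hamming_distance(s, share_num(s, c(1, 0, 1, 0)), share_num(s, c(1, 1, 1, 0)))),
    1
  )
  # random 20-bit pairs vs the plaintext oracle, batched
  set.seed(99)
  m <- 100
  a <- matrix(rbinom(m * 20, 1, 0.5), nrow = m)
  b <- matrix(rbinom(m * 20, 1, 0.5), nrow = m)
  da <- share_num(s, as.vector(t(a)))
  db <- share_num(s, as.vector(t(b)))
  got <- open_num(s, hamming_distance(s, da, db, records = m))
  expect_equal(got, rowSums(a != b))
  expect_error(
    hamming_distance(s, share_num(s, c(0, 1)), share_num(s, c(0, 1, 1))),
    "different lengths"
  )
})

test_that("threshold comparison matches the strict plaintext predicate", {
  s <- cmp_session(field = m61(), kappa = 10, l = 5, seed = 9)
  deal_triples(s$store, 20000)
  deal_random_bits(s$store, 20000)
  # exhaustive at a reduced width: x in [0, 32), B in [0, 32]
  grid <- expand.grid(x = 0:31, B = 0:32)
  for (B in 0:32) {
    xs <- grid$x[grid$B == B]
    got <- open_num(s, lt_public(s, share_num(s, xs), B))
    expect_equal(got, as.numeric(xs < B))
  }
  # boundary cases on their own
  expect_equal(open_num(s, lt_public(s, share_num(s, 0), 1)), 1)
  expect_equal(open_num(s, lt_public(s, share_num(s, 13), 13)), 0)
})

test_that("comparison parameter violations are configuration errors", {
  expect_error(
    protocol_config(field = f101(), kappa = 8, l = 8),
    "field too small"
  )
  s <- cmp_session(seed = 10)
  expect_error(lt_public(s, share_num(s, 1), B = 40), "B")
})

test_that("masked aggregation gates values by the mask bit", {
  s <- plain_session(f101(), seed = 11)
  deal_triples(s$store, 40)
  vals <- share_num(s, c(10, 20, 30))
  z0 <- masked_aggregate(s, share_num(s, 0), vals)
  expect_equal(open_num(s, z0), c(0, 0, 0))
  z1 <- masked_aggregate(s, share_num(s, 1), vals)
  expect_equal(open_num(s, z1), c(10, 20, 30))
  # random cases against plaintext products
  set.seed(3)
  for (i in 1:10) {
    m <- rbinom(1, 1, 0.5)
    v <- sample(0:100, 2)
    got <- open_num(s, masked_aggregate(s, share_num(s, m), share_num(s, v)))
    expect_equal(got, m * v)
  }
})

test_that("ledger counts depend on circuit shape only, never on contents", {
  run_one <- function(xs, B, seed) {
    s <- cmp_session(field = m61(), kappa = 10, l = 5, seed = seed)
    deal_triples(s$store, 500)
    deal_random_bits(s$store, 500)
    sv <- share_num(s, xs)
    d <- lt_public(s, sv, B)
    p <- beaver_mul(s, d, share_num(s, xs))
    mpc_open(s, p)
    list(ledger = as.data.frame(s$ledger), transcript = s$transcript_lengths)
  }
  a <- run_one(c(0, 5, 31, 2), B = 7, seed = 12)
  b <- run_one(c(30, 30, 30, 30), B = 31, seed = 13) # all satisfied vs mixed
  expect_identical(a$ledger, b$ledger)
  expect_identical(a$transcript, b$transcript)
})
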