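test_that("basic modular arithmetic is exact", {
  f <- f101()
  expect_equal(as.numeric(arith(fe(f, 12), fe(f, 9), "mul")), 7) # 108 mod 101
  expect_equal(as.numeric(arith(fe(f, 99), fe(f, 5), "add")), 3)
  expect_equal(as.numeric(arith(fe(f, 3), fe(f, 7), "sub")), 97)
  f7 <- prime_field(7)
  expect_equal(as.numeric(arith(fe(f7, 3), op = "inv")), 5) # 3*5 = 15 = 1 mod 7
  x <- fe(f, 0:100)
  expect_true(all(as.numeric(x + fe(f, 0)) == 0:100)) # additive identity
  expect_true(all(as.numeric(x * fe(f, 1)) == 0:100)) # multiplicative identity
})

test_that("field axioms hold exhaustively over F_11", {
  f <- f11()
  vals <- 0:10
  grid <- expand.grid(a = vals, b = vals)
  a <- fe(f, grid$a)
  b <- fe(f, grid$b)
  expect_equal(as.numeric(a + b), (grid$a + grid$b) %% 11)
  expect_equal(as.numeric(a * b), (grid$a * grid$b) %% 11)
  expect_equal(as.numeric(a - b), (grid$a - grid$b) %% 11)
  expect_true(all((a + b) == (b + a)))
  expect_true(all((a * b) == (b * a)))
  # associativity and distributivity over all triples
  tri <- expand.grid(a = vals, b = vals, c = vals)
  ta <- fe(f, tri$a); tb <- fe(f, tri$b); tc <- fe(f, tri$c)
  expect_true(all(((ta + tb) + tc) == (ta + (tb + tc))))
  expect_true(all(((ta * tb) * tc) == (ta * (tb * tc))))
  expect_true(all((ta * (tb + tc)) == (ta * tb + ta * tc)))
  # every nonzero element has an inverse
  nz <- fe(f, 1:10)
  expect_true(all(as.numeric(nz * arith(nz, op = "inv")) == 1))
})

test_that("128-bit production prime arithmetic is consistent", {
  f <- default_prime()
  expect_equal(f$bit_length, 128L)
  pm1 <- fe(f, "ffffffffffffffffffffffffffffff60") # p - 1
  expect_equal(as.character(unclass(pm1 * pm1)), "1") # (-1)^2 = 1
  rng <- mpc_rng(5, "t")
  x <- random_element(f, rng, 20)
  expect_true(all((x * arith(x, op = "inv")) == fe(f, rep(1, 20))))
  expect_true(all((x + (-x)) == fe(f, rep(0, 20))))
})

test_that("signed encode/decode round-trips and mirrors negation", {
  f <- f101()
  xs <- -50:50
  e <- encode_signed(f, xs)
  expect_equal(decode_signed(e), as.numeric(xs))
  expect_equal(as.numeric(encode_signed(f, -1)), 100)
  expect_equal(as.numeric(encode_signed(f, 0)), 0)
  # encode(-x) = p - encode(x) for x != 0
  pos <- encode_signed(f, 1:50)
  neg <- encode_signed(f, -(1:50))
  expect_equal(as.numeric(neg), 101 - as.numeric(pos))
  expect_error(encode_signed(f, 51), "signed range")
})

test_that("invalid field usage is rejected", {
  expect_error(prime_field(100), "not prime")
  f <- f101()
  g <- prime_field(103)
  expect_error(fe(f, 1) + fe(g, 1), "different prime fields")
  expect_error(arith(fe(f, 0), op = "inv"), "invert zero")
  expect_error(fe(f, "10a0zz"), "invalid hex")
})

test_that("random field elements are seed-deterministic, in range, and uniform", {
  f <- f101()
  a <- random_element(f, mpc_rng(42, "x"), 50)
  b <- random_element(f, mpc_rng(42, "x"), 50)
  expect_identical(unclass(a), unclass(b))
  expect_false(identical(
    unclass(random_element(f, mpc_rng(43, "x"), 50)),
    unclass(a)
  ))
  # distinct actor tags give distinct streams from one master seed
  expect_false(identical(
    unclass(random_element(f, mpc_rng(42, "y"), 50)),
    unclass(a)
  ))
  draws <- as.numeric(random_element(f, mpc_rng(7, "u"), 1e4))
  expect_true(all(draws >= 0 & draws < 101))
  counts <- tabulate(draws + 1, nbins = 101)
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})
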