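seq9 <- function(...) make_sequence(c(...), min_scale = 1, max_scale = 9)

test_that("digram_counts honors lag and the wrap policy", {
  s <- make_sequence(c(1, 2, 1, 2, 1), min_scale = 1, max_scale = 2)
  nowrap <- digram_counts(s, lag = 1, wrap = FALSE)
  expect_equal(attr(nowrap$counts, "total"), 4L)
  expect_equal(as.integer(nowrap$counts[c("1>2", "2>1")]), c(2L, 2L))

  wrapped <- digram_counts(s, lag = 1, wrap = TRUE)
  expect_equal(attr(wrapped$counts, "total"), 5L)
  expect_equal(as.integer(wrapped$counts["1>1"]), 1L)

  lag2 <- digram_counts(seq9(1, 2, 3, 4, 5), lag = 2, wrap = FALSE)
  expect_equal(attr(lag2$counts, "total"), 3L)
  expect_setequal(names(lag2$counts), c("1>3", "2>4", "3>5"))

  expect_error(digram_counts(seq9(1, 2), lag = 2), "too short")
})

test_that("redundancy matches the direct Shannon-entropy oracle", {
  expect_equal(redundancy(construct_fixture("constant", n = 10)), 1)
  expect_equal(redundancy(construct_fixture("constant", n = 10), "classical"),
               100)
  balanced <- seq9(rep(1:9, each = 2))
  expect_equal(redundancy(balanced), 0)
  # counts (3,1) over a binary alphabet: frozen from the oracle
  skew <- make_sequence(c(1, 1, 1, 2), min_scale = 1, max_scale = 2)
  expect_equal(redundancy(skew), 0.1887218755408672)
  expect_equal(redundancy(skew), shannon_redundancy(c(3, 1), 2))
  expect_error(redundancy(make_sequence(1, alternatives = 1)), "at least 2")
})

test_that("RNG index uses digram-marginal denominators and wraps only classically", {
  s <- make_sequence(c(1, 2, 1, 2, 1), min_scale = 1, max_scale = 2)
  expect_equal(rng_index(s), 1)
  expect_equal(rng_index(seq9(1, 2, 1, 2, 3)), 0.5)
  # all digrams distinct (but first members repeating) -> numerator 0
  expect_equal(rng_index(seq9(1, 2, 1, 3, 1, 4)), 0)
  # all digram first members distinct too -> denominator 0, not computable
  expect_true(is_not_computable(rng_index(seq9(1, 2, 3, 4, 5))))
  # wrapping changes the classical value on a sequence whose ends join
  expect_equal(rng_index(s, "classical"),
               (2 * log2(2) + 2 * log2(2)) / (3 * log2(3) + 2 * log2(2)))
})

test_that("RNG2 works at lag 2 and never wraps", {
  s <- make_sequence(c(1, 2, 1, 2, 1), min_scale = 1, max_scale = 2)
  expect_equal(rng2_index(s), 1)
  # all lag-2 pairs distinct with a repeating first member -> 0
  expect_equal(rng2_index(seq9(1, 2, 3, 1, 4, 1)), 0)
  expect_true(is_not_computable(rng2_index(seq9(1, 2, 3, 4, 5))))
  for (seed in 1:5) {
    r <- generate_iid(digits9, 40, seed)
    expect_identical(rng2_index(r, "default"), rng2_index(r, "classical"))
  }
})

test_that("NSQ counts unobserved digram types over a^2 - 1", {
  two <- make_sequence(c(1, 2), min_scale = 1, max_scale = 2)
  expect_equal(nsq(two), 1)
  s <- construct_fixture("digram_count", n = 50, a = 9, d = 37)
  expect_equal(nsq(s, "classical"), 55)
  expect_equal(nsq(s, "default"), 0.55)
})

test_that("coupon means completed cycles and flags unusable input", {
  three <- alphabet(min_scale = 1, max_scale = 3)
  expect_equal(coupon(make_sequence(c(1, 2, 3), alphabet = three)), 3)
  expect_equal(coupon(make_sequence(c(1, 1, 2, 3, 3, 2, 1), alphabet = three)),
               3.5)
  no7 <- seq9(rep(c(1:6, 8, 9), 4))
  expect_true(is_not_computable(coupon(no7)))
  # shorter than the alphabet -> not computable
  expect_true(is_not_computable(coupon(seq9(1, 2, 3))))
})

test_that("fod_table tallies signed ordinal differences with total n - 1", {
  ft <- fod_table(seq9(1, 3, 2))
  expect_equal(as.integer(ft[c("-1", "2")]), c(1L, 1L))
  expect_equal(attr(ft, "total"), 2L)
  const <- fod_table(construct_fixture("constant", n = 5))
  expect_equal(as.integer(const["0"]), 4L)
  coin <- make_sequence(c("head", "tail", "head"),
                        alternatives = c("head", "tail"))
  ftc <- fod_table(coin)
  expect_equal(as.integer(ftc[c("-1", "1")]), c(1L, 1L))
})

test_that("adjacency splits ascending/descending with denominator n", {
  a <- adjacency(seq9(1, 2, 3, 5))
  expect_equal(unname(a["ascending"]), 0.5)
  expect_equal(unname(a["descending"]), 0)
  expect_equal(unname(a["combined"]), 0.5)
  d <- adjacency(seq9(9, 8, 1))
  expect_equal(unname(d["descending"]), 1 / 3)
  for (seed in 1:5) {
    r <- generate_iid(digits9, 60, seed)
    v <- adjacency(r)
    expect_equal(unname(v["combined"]),
                 unname(v["ascending"] + v["descending"]))
  }
})

test_that("turning points collapse plateaus and ignore endpoints", {
  expect_equal(turning_points(seq9(1, 2, 3, 4, 5)), 0L)
  expect_equal(turning_points(seq9(1, 3, 2, 4)), 2L)
  expect_equal(turning_points(seq9(1, 3, 3, 2)), 1L)
  expect_equal(turning_points(construct_fixture("constant", n = 5)), 0L)
})

test_that("TPI centers on the 2/3(n-2) expectation", {
  s <- construct_fixture("turning_points", n = 50, tp = 33)
  expect_equal(tpi(s, "classical"), 103.125)
  expect_equal(tpi(s, "default"), 0.03125)
  expect_equal(tpi(seq9(1, 2, 3, 4, 5)), -1)
  expect_equal(tpi(seq9(1, 3, 2, 4)), 0.5)
})

test_that("phase lengths split by peak/trough endings; runs is their variance", {
  pl <- phase_lengths(seq9(1, 3, 2, 4, 1))
  expect_equal(as.integer(pl$ascending["1"]), 1L)
  expect_equal(as.integer(pl$descending["1"]), 1L)
  expect_equal(pl$lengths, c(1L, 1L))

  alt <- construct_fixture("alternating", n = 10)
  pla <- phase_lengths(alt)
  expect_true(all(pla$lengths == 1L))

  mono <- phase_lengths(seq9(1, 2, 3, 4, 5))
  expect_length(mono$lengths, 0L)

  expect_equal(runs(seq9(1, 3, 2, 4, 1)), 0)
  expect_equal(runs(alt), 0)
  expect_true(is_not_computable(runs(seq9(1, 3, 2, 4, 1), "classical")))
  expect_true(is_not_computable(runs(seq9(1, 2, 3))))
  # hand case with unequal phases: lengths {1, 2} -> population variance 0.25
  expect_equal(runs(seq9(1, 3, 2, 4, 5, 1)), 0.25)
})

test_that("repetition distances and gap summaries", {
  expect_equal(as.integer(repetition_distances(seq9(1, 2, 1))["2"]), 1L)
  expect_equal(as.integer(repetition_distances(seq9(1, 1))["1"]), 1L)
  rd <- repetition_distances(make_sequence(c(1, 2, 1, 2, 1),
                                           min_scale = 1, max_scale = 2))
  expect_equal(as.integer(rd["2"]), 3L)
  expect_equal(attr(rd, "total"), 3L)

  g <- repetition_gap(make_sequence(c(1, 2, 1, 2, 1),
                                    min_scale = 1, max_scale = 2))
  expect_equal(unname(g), c(2, 2, 2))
  # distances {1, 3}: even-count median midpoint, modal tie -> smallest
  g2 <- repetition_gap(seq9(2, 2, 5, 1, 3, 5))
  expect_equal(unname(g2["mean"]), 2)
  expect_equal(unname(g2["median"]), 2)
  expect_equal(unname(g2["mode"]), 1)
  expect_true(is_not_computable(repetition_gap(seq9(1, 2, 3))))
})

test_that("response frequencies include zero counts and sum to n", {
  three <- alphabet(min_scale = 1, max_scale = 3)
  rf <- response_frequencies(make_sequence(c(1, 1, 2), alphabet = three))
  expect_equal(as.integer(rf), c(2L, 1L, 0L))
  expect_equal(attr(rf, "total"), 3L)
  const <- response_frequencies(construct_fixture("constant", n = 7))
  expect_equal(max(as.integer(const)), 7L)
  expect_equal(sum(as.integer(const)), 7L)
})

test_that("phi indices standardize repeat counts against the IID null", {
  # every repeat at distance exactly 3: cycling three symbols
  s3 <- make_sequence(rep(1:3, 20), min_scale = 1, max_scale = 3)
  null3 <- phi_null(s3$alphabet, 60, lags = 2:4, reps = 400, seed = 11)
  phi <- phi_indices(s3, lags = 2:4, null = null3)
  expect_gt(phi[["phi3"]], 0)
  expect_lt(phi[["phi2"]], 0)
  # lag >= n is not computable
  short <- make_sequence(c(1, 2, 1), min_scale = 1, max_scale = 2)
  p <- phi_indices(short, lags = c(2, 5), reps = 50, seed = 3)
  expect_true(is.na(p[["phi5"]]))
  # identical in both modes, deterministic under a fixed seed
  r <- generate_iid(digits9, 80, seed = 9)
  expect_identical(phi_indices(r, reps = 100, seed = 5),
                   phi_indices(r, reps = 100, seed = 5, mode = "classical"))
})

test_that("all_rng composes measures and isolates failures", {
  s <- generate_iid(digits9, 100, seed = 3)
  res <- all_rng(s, phi_reps = 100)
  expect_setequal(names(res), rng_measure_names())
  expect_equal(attr(res, "mode"), "default")
  expect_equal(attr(res, "tp_observed"), turning_points(s))

  only <- all_rng(s, enabled = "Coupon")
  expect_equal(names(only), "Coupon")

  no7 <- all_rng(make_sequence(rep(c(1:6, 8, 9), 6), min_scale = 1,
                               max_scale = 9),
                 enabled = c("Coupon", "Redundancy", "NSQ"))
  expect_true(is_not_computable(no7$Coupon))
  expect_false(is_not_computable(no7$Redundancy))
  expect_false(is_not_computable(no7$NSQ))

  expect_error(all_rng(s, enabled = "NotAMeasure"), "unknown measure")
})
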