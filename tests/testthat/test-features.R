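test_that("DFT features match the direct-summation oracle", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(8:50, 1)
    x <- rnorm(n, 80, 10)
    f <- fft_features(x)
    for (k in 0:min(9, floor(n / 2))) {
      expect_equal(unname(f[paste0("fft__abs_", k)]), Mod(oracle_dft(x, k)),
                   tolerance = 1e-9)
      dang <- unname(f[paste0("fft__ang_", k)]) - Arg(oracle_dft(x, k))
      expect_lt(abs(((dang + pi) %% (2 * pi)) - pi), 1e-9)  # branch-cut safe
    }
  }
})

test_that("DFT features recognise constants and pure tones", {
  f <- fft_features(rep(7, 32))
  expect_equal(unname(f[paste0("fft__abs_", 1:9)]), rep(0, 9), tolerance = 1e-10)
  n <- 32
  tone <- cos(2 * pi * (0:(n - 1)) / n)
  ft <- fft_features(tone)
  expect_equal(unname(ft["fft__abs_1"]), n / 2, tolerance = 1e-9)
  others <- ft[paste0("fft__abs_", c(0, 2:9))]
  expect_true(all(abs(others) < 1e-9))
  expect_true(all(is.na(fft_features(c(1, 2, 3)))))
})

test_that("Ricker CWT coefficients match a direct convolution oracle", {
  set.seed(32)
  for (i in 1:40) {
    n <- sample(16:50, 1)
    x <- rnorm(n, 80, 10)
    f <- ricker_cwt_features(x)
    pos <- round(c(0.25, 0.5, 0.75) * (n - 1)) + 1
    for (w in c(2, 5, 10, 20)) {
      for (j in 1:3) {
        expect_equal(unname(f[sprintf("cwt__w%g_p%d", w, c(25, 50, 75)[j])]),
                     oracle_cwt_coef(x, w, pos[j]), tolerance = 1e-9)
      }
    }
  }
})

test_that("Ricker CWT vanishes on constants and ramps, peaks on a spike", {
  expect_equal(unname(ricker_cwt_features(rep(5, 40))), rep(0, 12))
  # linear ramp: zero 0th and 1st kernel moments => ~0 away from boundaries
  ramp <- seq(0, 10, length.out = 101)
  f <- ricker_cwt_features(ramp)
  # zero 0th moment holds only up to kernel truncation, hence the loose bound
  expect_lt(abs(f[["cwt__w2_p50"]]), 1e-3)
  expect_lt(abs(f[["cwt__w5_p50"]]), 1e-3)
  # centred spike: mid-position coefficient dominates the other positions
  spike <- rep(0, 41); spike[21] <- 1
  fs <- ricker_cwt_features(spike)
  for (w in c(2, 5, 10)) {
    trio <- fs[sprintf("cwt__w%g_p%d", w, c(25, 50, 75))]
    expect_equal(which.max(trio), 2L, ignore_attr = TRUE)
  }
})

test_that("LZ76 parsing matches the exhaustive-history oracle", {
  expect_equal(lz76_phrases(rep(0L, 10)), 2L)
  expect_equal(oracle_lz76(rep(0L, 10)), 2L)
  set.seed(33)
  for (i in 1:100) {
    s <- sample(0:1, sample(5:60, 1), replace = TRUE)
    expect_identical(as.integer(lz76_phrases(s)), as.integer(oracle_lz76(s)))
  }
  for (i in 1:20) {
    s <- sample(0:3, sample(10:50, 1), replace = TRUE)
    expect_identical(as.integer(lz76_phrases(s)), as.integer(oracle_lz76(s)))
  }
})

test_that("alternating sequences are less LZ-complex than random ones", {
  n <- 64
  alt <- lempel_ziv_complexity(rep(c(0, 1), n / 2))
  set.seed(34)
  rnd <- replicate(100, lempel_ziv_complexity(rnorm(n)))
  expect_lt(alt, median(rnd))
})

test_that("approximate entropy equals the brute-force template counter", {
  set.seed(35)
  for (i in 1:100) {
    n <- sample(10:40, 1)
    x <- rnorm(n)
    r <- 0.2 * sd(x)
    expect_equal(unname(approximate_entropy(x)), oracle_apen(x, 2, r),
                 tolerance = 1e-9)
  }
})

test_that("entropies order regular series below their shuffles", {
  per <- rep(c(1, 2), 25)
  set.seed(36)
  sh_ap <- replicate(30, {
    y <- sample(per)
    unname(approximate_entropy(y, r = 0.2 * sd(per)))
  })
  expect_lt(unname(approximate_entropy(per, r = 0.2 * sd(per))), median(sh_ap))
  sh_pe <- replicate(30, unname(permutation_entropy(sample(per) + rnorm(50, 0, 1e-6))))
  expect_lt(unname(permutation_entropy(per)), median(sh_pe))
  expect_equal(unname(approximate_entropy(rep(4, 20))), 0)
})

test_that("permutation entropy counts ordinal patterns exactly", {
  expect_equal(unname(permutation_entropy(1:25)), 0)
  expect_equal(unname(permutation_entropy(exp(seq(-2, 2, length.out = 30)))), 0)
  # frozen sequence whose six ordinal triples are uniform over all patterns
  u <- c(1, 4, 1, 5, 6, 4, 2, 2)
  expect_equal(unname(permutation_entropy(u)), 1)
  set.seed(37)
  for (i in 1:100) {
    x <- rnorm(sample(5:30, 1))
    expect_equal(unname(permutation_entropy(x)), oracle_pe(x), tolerance = 1e-12)
  }
  # ties broken by order of appearance, matching the oracle
  xt <- c(2, 2, 1, 3, 3, 3, 2)
  expect_equal(unname(permutation_entropy(xt)), oracle_pe(xt), tolerance = 1e-12)
})

test_that("block-aggregated linear trends match the normal-equations oracle", {
  x <- 3 * (0:19)
  f <- agg_linear_trend(x)
  expect_equal(unname(f["alt__c5_mean_slope"]), 15)
  expect_equal(unname(f["alt__c5_mean_intercept"]), 6)
  expect_equal(unname(f["alt__c5_mean_stderr"]), 0)

  fc <- agg_linear_trend(rep(4.5, 30))
  expect_equal(unname(fc["alt__c10_max_slope"]), 0)
  expect_equal(unname(fc["alt__c10_max_intercept"]), 4.5)
  expect_equal(unname(fc["alt__c10_max_stderr"]), 0)

  set.seed(38)
  for (i in 1:100) {
    n <- sample(12:50, 1)
    x <- rnorm(n)
    f <- agg_linear_trend(x)
    for (cs in c(5, 10)) {
      nb <- n %/% cs
      if (nb < 2) { expect_true(all(is.na(f[grepl(paste0("c", cs), names(f))]))); next }
      for (ag in c("mean", "min", "max")) {
        y <- apply(matrix(x[1:(nb * cs)], nrow = cs), 2, match.fun(ag))
        o <- oracle_ols(0:(nb - 1), y)
        got <- f[sprintf("alt__c%d_%s_%s", cs, ag, c("slope", "intercept", "stderr"))]
        if (nb == 2) {
          expect_equal(unname(got[1:2]), unname(o[1:2]), tolerance = 1e-9)
        } else {
          expect_equal(unname(got), unname(o), tolerance = 1e-9)
        }
      }
    }
  }
})

test_that("duplicate fractions count repeated values after rounding", {
  f <- duplicate_fractions(c(1, 1, 2, 3))
  expect_equal(unname(f["dup__pct_dup"]), 0.5)
  expect_equal(unname(f["dup__pct_nondup"]), 0.5)
  expect_equal(unname(duplicate_fractions(c(1, 2, 3, 4))["dup__pct_dup"]), 0)
  fa <- duplicate_fractions(rep(2.5, 6))
  expect_equal(unname(fa["dup__pct_dup"]), 1)
  expect_equal(unname(fa["dup__min"]), 1)
  expect_equal(unname(fa["dup__max"]), 1)
  # rounding at 6 decimals merges near-equal values
  fb <- duplicate_fractions(c(1, 1 + 1e-9, 2))
  expect_equal(unname(fb["dup__pct_dup"]), 2 / 3)
})

test_that("channel extraction is pure, deterministic and fully named", {
  s <- random_series(40, seed = 9)
  v1 <- extract_series_features(s)
  v2 <- extract_series_features(s)
  expect_identical(v1, v2)
  expect_equal(length(v1), 5 * 59)
  expect_false(any(duplicated(names(v1))))
  expect_true(all(grepl("^(sbp|dbp|hr|pulse|map)__", names(v1))))
  expect_false(anyNA(v1))
})
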