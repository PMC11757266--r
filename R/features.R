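#' @name ts_features
#' @title Time-series feature families for circulation channels
#'
#' @description
#' Seven feature families quantify a single vital-sign channel sampled on
#' the regular intraoperative grid: discrete Fourier coefficients, Ricker
#' (Mexican-hat) continuous wavelet coefficients, Lempel-Ziv (LZ76)
#' complexity, approximate entropy, permutation entropy, linear trends of
#' block aggregates, and duplicate-value fractions. Series too short for a
#' family return `NA` sentinels; the modelling layer imputes these as 0
#' after normalization.
#'
#' @param x numeric vector, one channel of a circulation series.
NULL

#' @describeIn ts_features Magnitude and phase of the DFT coefficients
#'   k = 0..9 plus the spectral centroid and spectral variance of the
#'   magnitude spectrum over the non-negative frequencies (frequency in
#'   cycles per sample). Needs length >= 4; coefficients beyond the Nyquist
#'   index are `NA`.
#' @export
fft_features <- function(x) {
  kmax <- 9L
  nm <- c(paste0("fft__abs_", 0:kmax), paste0("fft__ang_", 0:kmax),
          "fft__centroid", "fft__var")
  n <- length(x)
  if (n < 4L || anyNA(x)) return(sentinel(nm))
  co <- stats::fft(x)
  half <- floor(n / 2)
  keep <- 0:min(kmax, half)
  out <- rep(NA_real_, length(nm))
  names(out) <- nm
  out[paste0("fft__abs_", keep)] <- Mod(co[keep + 1L])
  out[paste0("fft__ang_", keep)] <- Arg(co[keep + 1L])
  mag <- Mod(co[1:(half + 1L)])
  freq <- (0:half) / n
  if (sum(mag) > 0) {
    cen <- sum(freq * mag) / sum(mag)
    out["fft__centroid"] <- cen
    out["fft__var"] <- sum((freq - cen)^2 * mag) / sum(mag)
  } else {
    out["fft__centroid"] <- 0
    out["fft__var"] <- 0
  }
  out
}

#' Ricker (Mexican-hat) wavelet kernel
#'
#' `psi(t) = 2 / (sqrt(3 a) pi^(1/4)) (1 - t^2/a^2) exp(-t^2 / (2 a^2))`
#' sampled at `points` integer positions centred on zero.
#'
#' @param points number of samples.
#' @param a wavelet width parameter.
#' @return Numeric vector of length `points`.
#' @export
ricker_wavelet <- function(points, a) {
  t <- seq_len(points) - 1 - (points - 1) / 2
  amp <- 2 / (sqrt(3 * a) * pi^0.25)
  amp * (1 - (t / a)^2) * exp(-t^2 / (2 * a^2))
}

#' @describeIn ts_features Continuous wavelet transform with the Ricker
#'   kernel at widths 2, 5, 10 and 20; features are the CWT coefficients at
#'   the 25%, 50% and 75% positions of the series. The signal is demeaned
#'   before convolution so the transform of a constant series is exactly
#'   zero even where the truncated kernel loses its zero-sum property.
#'   Needs length >= 8.
#' @param widths Ricker width parameters.
#' @export
ricker_cwt_features <- function(x, widths = c(2, 5, 10, 20)) {
  nm <- as.vector(outer(c(25, 50, 75), widths,
                        function(p, w) sprintf("cwt__w%g_p%d", w, p)))
  n <- length(x)
  if (n < 8L || anyNA(x)) return(sentinel(nm))
  xc <- x - mean(x)
  pos <- round(c(0.25, 0.50, 0.75) * (n - 1)) + 1L
  out <- numeric(0)
  for (w in widths) {
    m <- min(10L * w, n)
    kern <- ricker_wavelet(m, w)
    full <- conv_full(xc, kern)
    same <- full[((m - 1L) %/% 2L + 1L):((m - 1L) %/% 2L + n)]
    out <- c(out, same[pos])
  }
  names(out) <- nm
  out
}

# linear convolution (full), direct O(n m) — series are short
conv_full <- function(x, y) {
  n <- length(x); m <- length(y)
  out <- numeric(n + m - 1L)
  for (j in seq_len(m)) {
    idx <- j:(j + n - 1L)
    out[idx] <- out[idx] + y[j] * x
  }
  out
}

#' @describeIn ts_features Lempel-Ziv (LZ76) complexity of the symbolized
#'   series: values are discretized into `n_bins` bins (a median split for
#'   the default 2 bins, equal-width otherwise), parsed with the LZ76
#'   scheme, and the phrase count is normalized by `n / log2(n)`. A
#'   constant series is valid input (its minimal parse has 2 phrases for
#'   n >= 2).
#' @param n_bins number of discretization bins (default 2).
#' @export
lempel_ziv_complexity <- function(x, n_bins = 2L) {
  n <- length(x)
  if (n < 2L || anyNA(x)) return(sentinel("lz__c"))
  if (n_bins == 2L) {
    s <- as.integer(x > stats::median(x))
  } else {
    rng <- range(x)
    if (rng[1] == rng[2]) {
      s <- rep(0L, n)
    } else {
      s <- as.integer(cut(x, breaks = seq(rng[1], rng[2], length.out = n_bins + 1L),
                          include.lowest = TRUE))
    }
  }
  c(lz__c = lz76_phrases(s) * log2(n) / n)
}

#' LZ76 phrase count of a symbol sequence
#'
#' Kaspar-Schuster sequential parse; returns the number of phrases in the
#' exhaustive production history of the sequence.
#'
#' @param s integer/character vector of symbols.
#' @return Integer phrase count (>= 1).
#' @export
lz76_phrases <- function(s) {
  n <- length(s)
  if (n == 0L) return(0L)
  i <- 0L; c <- 1L; u <- 1L; v <- 1L; vmax <- 1L
  while (u + v <= n) {
    if (s[i + v] == s[u + v]) {
      v <- v + 1L
    } else {
      vmax <- max(v, vmax)
      i <- i + 1L
      if (i == u) {
        c <- c + 1L
        u <- u + vmax
        i <- 0L; v <- 1L; vmax <- 1L
      } else {
        v <- 1L
      }
    }
  }
  if (v != 1L) c <- c + 1L
  c
}

#' @describeIn ts_features Approximate entropy ApEn(m, r) with embedding
#'   dimension `m` (default 2) and tolerance `r` (default 0.2 x SD),
#'   Chebyshev distance, self-matches included (the classic definition).
#'   A constant series (SD = 0) returns 0. Needs length >= m + 2.
#' @param m embedding dimension.
#' @param r match tolerance; default 0.2 times the series SD.
#' @export
approximate_entropy <- function(x, m = 2L, r = 0.2 * stats::sd(x)) {
  n <- length(x)
  if (n < m + 2L || anyNA(x)) return(sentinel("apen__m2"))
  if (stats::sd(x) == 0) return(c(apen__m2 = 0))
  c(apen__m2 = apen_phi(x, m, r) - apen_phi(x, m + 1L, r))
}

apen_phi <- function(x, m, r) {
  n <- length(x)
  nt <- n - m + 1L
  # Chebyshev distance between all template pairs, built coordinate-wise
  dmax <- matrix(0, nt, nt)
  for (j in seq_len(m)) {
    v <- x[(j):(j + nt - 1L)]
    dmax <- pmax(dmax, abs(outer(v, v, `-`)))
  }
  ci <- rowSums(dmax <= r) / nt
  mean(log(ci))
}

#' @describeIn ts_features Permutation entropy: Shannon entropy (natural
#'   log) of the ordinal-pattern distribution of windows of length `order`
#'   with lag `delay`, normalized by `log(order!)` to \[0, 1\]. Ties are
#'   broken by order of appearance. Needs length >= order * delay + 1.
#' @param order ordinal pattern length.
#' @param delay embedding lag.
#' @export
permutation_entropy <- function(x, order = 3L, delay = 1L) {
  n <- length(x)
  if (n < order * delay + 1L || anyNA(x)) return(sentinel("pe__o3d1"))
  nw <- n - (order - 1L) * delay
  emb <- matrix(vapply(0:(order - 1L), function(j) x[seq_len(nw) + j * delay],
                       numeric(nw)), nrow = nw)
  # ranks with ties broken by order of appearance, vectorized over windows
  rk <- matrix(1L, nw, order)
  for (j in seq_len(order)) {
    for (k in seq_len(order)) {
      if (k == j) next
      rk[, j] <- rk[, j] + ((emb[, k] < emb[, j]) |
                              (emb[, k] == emb[, j] & k < j))
    }
  }
  code <- as.vector(rk %*% (order + 1)^(0:(order - 1L)))
  p <- tabulate(match(code, unique(code))) / nw
  h <- -sum(p * log(p))
  c(pe__o3d1 = h / log(factorial(order)))
}

#' @describeIn ts_features Slope, intercept and slope standard error of an
#'   ordinary least-squares fit of block aggregates (mean, min, max over
#'   consecutive non-overlapping blocks of each chunk size) against the
#'   block index. Trailing partial blocks are dropped; fewer than 2
#'   complete blocks yields `NA` sentinels for that chunk size.
#' @param chunk_sizes block lengths.
#' @param aggs aggregate functions applied within blocks.
#' @export
agg_linear_trend <- function(x, chunk_sizes = c(5L, 10L),
                             aggs = c("mean", "min", "max")) {
  out <- numeric(0)
  for (cs in chunk_sizes) {
    nb <- length(x) %/% cs
    for (ag in aggs) {
      nm <- sprintf("alt__c%d_%s_%s", cs, ag, c("slope", "intercept", "stderr"))
      if (nb < 2L || anyNA(x)) {
        out <- c(out, sentinel(nm))
        next
      }
      blocks <- matrix(x[seq_len(nb * cs)], nrow = cs)
      y <- apply(blocks, 2L, match.fun(ag))
      out <- c(out, stats::setNames(ols_line(seq_len(nb) - 1, y), nm))
    }
  }
  out
}

ols_line <- function(t, y) {
  n <- length(t)
  tb <- mean(t); yb <- mean(y)
  sxx <- sum((t - tb)^2)
  slope <- sum((t - tb) * (y - yb)) / sxx
  intercept <- yb - slope * tb
  if (n > 2L) {
    rss <- sum((y - intercept - slope * t)^2)
    se <- sqrt(max(rss, 0) / (n - 2L) / sxx)
  } else {
    se <- NA_real_   # zero residual dof
  }
  c(slope, intercept, se)
}

#' @describeIn ts_features Fraction of positions whose value occurs more
#'   than once in the series (and its complement), plus indicator flags for
#'   a duplicated minimum and maximum. Equality is tested after rounding to
#'   6 decimals so the notion is meaningful on continuous channels.
#' @export
duplicate_fractions <- function(x) {
  nm <- c("dup__pct_dup", "dup__pct_nondup", "dup__min", "dup__max")
  if (length(x) < 1L || anyNA(x)) return(sentinel(nm))
  xr <- round(x, 6)
  cnt <- table(xr)
  dup <- cnt[as.character(xr)] > 1L
  stats::setNames(c(mean(dup), 1 - mean(dup),
                    as.numeric(cnt[as.character(min(xr))] > 1L),
                    as.numeric(cnt[as.character(max(xr))] > 1L)), nm)
}

sentinel <- function(nm) stats::setNames(rep(NA_real_, length(nm)), nm)

#' All quantified features for one channel
#'
#' Runs the seven feature families on a single numeric series with the
#' default parameter grid.
#'
#' @param x numeric vector (one channel).
#' @return Named numeric vector (59 features).
#' @export
ts_feature_vector <- function(x) {
  c(fft_features(x), ricker_cwt_features(x), lempel_ziv_complexity(x),
    approximate_entropy(x), permutation_entropy(x), agg_linear_trend(x),
    duplicate_fractions(x))
}

#' Quantified features for every channel of a circulation series
#'
#' Applies [ts_feature_vector()] to the four recorded channels and the
#' derived MAP channel. Column names follow the
#' `"<channel>__<family>__<params>"` convention.
#'
#' @param series a complete [circulation_series].
#' @param channels channels to quantify.
#' @return Named numeric vector (59 features per channel).
#' @export
extract_series_features <- function(series,
                                    channels = c("sbp", "dbp", "hr", "pulse", "map")) {
  out <- lapply(channels, function(ch) {
    v <- ts_feature_vector(series[[ch]])
    stats::setNames(v, paste0(ch, "__", names(v)))
  })
  unlist(out)
}
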