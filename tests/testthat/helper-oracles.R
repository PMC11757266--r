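# Independent brute-force oracles used to pin down the analytic
# implementations. Each is written as the most literal possible evaluation
# of the defining formula, with no shared code with the package internals.

oracle_dft <- function(x, k) {
  n <- length(x)
  s <- 0 + 0i
  for (j in 0:(n - 1)) s <- s + x[j + 1] * exp(-2i * pi * k * j / n)
  s
}

oracle_arv <- function(t, map) {
  Ttot <- t[length(t)] - t[1]
  acc <- 0
  for (k in 1:(length(t) - 1)) {
    acc <- acc + (t[k + 1] - t[k]) * abs(map[k + 1] - map[k])
  }
  acc / Ttot
}

oracle_arvs <- function(t, map) {
  Ttot <- t[length(t)] - t[1]
  acc <- 0
  for (k in 1:(length(t) - 1)) {
    acc <- acc + (map[k + 1] - map[k])^2 / (t[k + 1] - t[k])
  }
  acc / Ttot
}

oracle_tw <- function(t, excess) {
  # trapezoid rule over the clamped excess, interval by interval
  acc <- 0
  for (k in 1:(length(t) - 1)) {
    acc <- acc + (t[k + 1] - t[k]) * (excess[k] + excess[k + 1]) / 2
  }
  acc
}

oracle_apen <- function(x, m, r) {
  phi <- function(mm) {
    n <- length(x)
    nt <- n - mm + 1
    csum <- 0
    for (i in 1:nt) {
      cnt <- 0
      for (j in 1:nt) {
        d <- max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)]))
        if (d <= r) cnt <- cnt + 1
      }
      csum <- csum + log(cnt / nt)
    }
    csum / nt
  }
  phi(m) - phi(m + 1)
}

oracle_pe <- function(x, order = 3, delay = 1) {
  nw <- length(x) - (order - 1) * delay
  pats <- character(nw)
  for (i in 1:nw) {
    w <- x[i + (0:(order - 1)) * delay]
    pats[i] <- paste(rank(w, ties.method = "first"), collapse = "-")
  }
  p <- table(pats) / nw
  -sum(p * log(p)) / log(factorial(order))
}

# LZ76 parse by the exhaustive-history definition: grow a candidate phrase
# until it is not a substring of everything before its last symbol.
oracle_lz76 <- function(s) {
  contains <- function(hay, needle) {
    lh <- length(hay); ln <- length(needle)
    if (ln > lh) return(FALSE)
    for (st in 1:(lh - ln + 1)) {
      if (all(hay[st:(st + ln - 1)] == needle)) return(TRUE)
    }
    FALSE
  }
  n <- length(s)
  c <- 0L
  p <- 1L
  while (p <= n) {
    q <- p
    while (q <= n) {
      if (q == 1L || !contains(s[1:(q - 1)], s[p:q])) break
      q <- q + 1L
    }
    c <- c + 1L
    p <- q + 1L
  }
  c
}

oracle_ols <- function(t, y) {
  X <- cbind(1, t)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  df <- length(y) - 2
  se <- if (df > 0) {
    sqrt(drop(t(res) %*% res) / df * solve(t(X) %*% X)[2, 2])
  } else NA_real_
  c(slope = beta[2], intercept = beta[1], stderr = se)
}

oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# direct CWT coefficient: sum_k x[k] psi[(k - pos) shifted], same-mode conv
oracle_cwt_coef <- function(x, width, pos) {
  n <- length(x)
  m <- min(10 * width, n)
  kern <- intracirc::ricker_wavelet(m, width)
  xc <- x - mean(x)
  acc <- 0
  off <- (m - 1) %/% 2
  for (j in 1:m) {
    idx <- pos + off - j + 1   # full-conv index pos+off = sum over x[idx]*kern[j]
    if (idx >= 1 && idx <= n) acc <- acc + xc[idx] * kern[j]
  }
  acc
}

# a random but physiologically plausible circulation series on the grid
random_series <- function(n = 30, seed = NULL, dt = 5) {
  if (!is.null(seed)) set.seed(seed)
  t <- (0:(n - 1)) * dt
  map <- 85 + cumsum(rnorm(n, 0, 3))
  pp <- pmax(15, rnorm(n, 40, 5))
  hr <- pmax(35, 75 + cumsum(rnorm(n, 0, 1.5)))
  circulation_series(t, map + 2 / 3 * pp, map - 1 / 3 * pp, hr,
                     hr + rnorm(n, 0, 1))
}

# minimal cohort shim for modelling tests that bypass series generation
quick_cohort <- function(n = 120, seed = 1, len = 40, ...) {
  simulate_cohort(sim_config(n_patients = n, seed = seed,
                             series_len_range = c(len, len), ...))
}
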