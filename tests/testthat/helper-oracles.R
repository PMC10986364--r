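# Independent brute-force oracles, O(N^2) template enumeration written
# directly from the defining formulas. Deliberately naive and kept separate
# from the package implementations they cross-check.

oracle_higuchi <- function(x, kmax) {
  N <- length(x)
  L <- numeric(kmax)
  for (k in seq_len(kmax)) {
    Lm <- numeric(k)
    for (m0 in seq_len(k)) {
      idx <- seq(m0, N, by = k)
      M <- length(idx) - 1
      Lm[m0] <- if (M < 1) NA_real_ else
        sum(abs(diff(x[idx]))) * (N - 1) / (M * k) / k
    }
    L[k] <- mean(Lm, na.rm = TRUE)
  }
  lk <- log(1 / seq_len(kmax))
  stats::cov(lk, log(L)) / stats::var(lk)
}

oracle_templates <- function(x, m, center = FALSE) {
  n <- length(x) - m + 1
  t(vapply(seq_len(n), function(i) {
    v <- x[i:(i + m - 1)]
    if (center) v - mean(v) else v
  }, numeric(m)))
}

oracle_apen <- function(x, m, r_frac) {
  N <- length(x); r <- r_frac * stats::sd(x)
  phi <- function(mm) {
    tpl <- oracle_templates(x, mm)
    n <- nrow(tpl)
    ci <- vapply(seq_len(n), function(i) {
      sum(vapply(seq_len(n), function(j) {
        max(abs(tpl[i, ] - tpl[j, ])) <= r
      }, logical(1)))
    }, 0)
    mean(log(ci / n))
  }
  phi(m) - phi(m + 1)
}

oracle_sampen <- function(x, m, r_frac) {
  N <- length(x); r <- r_frac * stats::sd(x)
  Bm <- function(mm) {
    tpl <- oracle_templates(x, mm)
    n <- nrow(tpl)
    mean(vapply(seq_len(n), function(i) {
      sum(vapply(setdiff(seq_len(n), i), function(j) {
        max(abs(tpl[i, ] - tpl[j, ])) < r
      }, logical(1))) / (N - mm)
    }, 0))
  }
  -log(Bm(m + 1) / Bm(m))
}

oracle_fuzzyen <- function(x, m, r_frac, nexp = 2) {
  r <- r_frac * stats::sd(x)
  Phi <- function(mm) {
    tpl <- oracle_templates(x, mm, center = TRUE)
    n <- nrow(tpl)
    mean(vapply(seq_len(n), function(i) {
      sum(vapply(setdiff(seq_len(n), i), function(j) {
        exp(-max(abs(tpl[i, ] - tpl[j, ]))^nexp / r)
      }, 0)) / (n - 1)
    }, 0))
  }
  log(Phi(m)) - log(Phi(m + 1))
}

# Random autocorrelated series on which all estimators (incl. SampEn's
# match requirement) are well defined.
oracle_series <- function(n) {
  as.numeric(stats::arima.sim(list(ar = 0.8), n)) + 0.3 * sin(seq_len(n) / 4)
}

# Exhaustive mRMR: recompute the incremental criterion from scratch at every
# step using the package's MI estimator but an independent search.
oracle_mrmr <- function(X, y) {
  vars <- colnames(X)
  remaining <- vars
  selected <- character(0)
  while (length(remaining) > 0) {
    scores <- vapply(remaining, function(v) {
      rel <- mutual_information(X[, v], y)
      if (length(selected) == 0) return(rel)
      red <- mean(vapply(selected, function(s) {
        mutual_information(X[, s], X[, v])
      }, 0))
      rel - red
    }, 0)
    ord <- order(-scores, remaining)
    selected <- c(selected, remaining[ord[1]])
    remaining <- setdiff(remaining, remaining[ord[1]])
  }
  selected
}

# Scalar LSTM (no convolution, 1 hidden unit) coded independently.
oracle_scalar_lstm <- function(xs, Wx, Wh, b) {
  h <- 0; cc <- 0
  for (xt in xs) {
    z <- xt * Wx + h * Wh + b
    i <- stats::plogis(z[1]); f <- stats::plogis(z[2])
    g <- tanh(z[3]); o <- stats::plogis(z[4])
    cc <- f * cc + i * g
    h <- o * tanh(cc)
  }
  c(h = h, c = cc)
}
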