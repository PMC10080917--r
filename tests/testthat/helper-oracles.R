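# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from first principles (explicit loops, lm() fits,
# textbook formulas) so they share no code with the implementations.

# grayscale opening with the range-scaled semicircular ball, explicit
# min/max window scans, replication padding
oracle_rolling_ball <- function(x, r) {
  n <- length(x)
  rng <- max(x) - min(x)
  if (rng == 0) return(x)
  xn <- (x - min(x)) * r / rng
  ball <- sqrt(r^2 - (-r:r)^2) - r
  g <- function(i) xn[min(max(i, 1), n)]
  ero <- sapply((1 - r):(n + r), function(p) {
    min(sapply(-r:r, function(j) g(p + j) - ball[j + r + 1]))
  })
  op <- sapply(1:n, function(p) {
    max(sapply(-r:r, function(j) ero[p + r + j] + ball[j + r + 1]))
  })
  op * rng / r + min(x)
}

# per-window least-squares polynomial fit via lm(), truncated at the edges
oracle_savgol <- function(x, window, polyorder) {
  n <- length(x)
  h <- (window - 1) / 2
  sapply(seq_len(n), function(i) {
    lo <- max(1, i - h)
    hi <- min(n, i + h)
    tt <- (lo:hi) - i
    fit <- stats::lm(x[lo:hi] ~ poly(tt, polyorder, raw = TRUE))
    unname(stats::coef(fit)[1])
  })
}

# textbook Pearson correlation by explicit loops
oracle_pearson <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n
  mb <- sum(b) / n
  num <- 0
  va <- 0
  vb <- 0
  for (i in seq_len(n)) {
    num <- num + (a[i] - ma) * (b[i] - mb)
    va <- va + (a[i] - ma)^2
    vb <- vb + (b[i] - mb)^2
  }
  num / sqrt(va * vb)
}

# Pearson chi-square by the expected-count hand formula
oracle_chisq <- function(tab) {
  tab <- as.matrix(tab)
  N <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- sum(tab[i, ]) * sum(tab[, j]) / N
      stat <- stat + (tab[i, j] - e)^2 / e
    }
  }
  as.numeric(stat)
}

# exhaustive between-class-variance maximizer over a 256-bin histogram
oracle_otsu <- function(img, levels = 256) {
  rng <- range(img)
  breaks <- seq(rng[1], rng[2], length.out = levels + 1)
  h <- hist(img, breaks = breaks, plot = FALSE)$counts
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(levels + 1)]) / 2
  best <- -Inf
  best_t <- mids[1]
  for (k in 1:(levels - 1)) {
    w0 <- sum(p[1:k])
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(p[1:k] * mids[1:k]) / w0
    m1 <- sum(p[(k + 1):levels] * mids[(k + 1):levels]) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best) {
      best <- v
      best_t <- breaks[k + 1]
    }
  }
  best_t
}

# Grubbs critical value from the Student-t quantile, derived independently
oracle_grubbs_critical <- function(n, alpha) {
  t2 <- qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)^2
  (n - 1) / sqrt(n) * sqrt(t2 / (n - 2 + t2))
}

# a noiseless generator configuration used wherever exact renders are needed
noiseless_config <- function(...) {
  generator_config(
    noise = noise_model(background_level = 0,
                        background_gradient = c(0, 0),
                        poisson_scale = 0, gaussian_sigma = 0),
    ...
  )
}
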