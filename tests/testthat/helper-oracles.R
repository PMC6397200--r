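# Independent brute-force oracles. These deliberately avoid rle() and any
# code path shared with the implementation: every segment finder scans
# element by element.

# Maximal runs of speeds strictly below `thr`, kept if length >= min_len.
oracle_stops <- function(speeds, thr = 0.1, min_len = 3) {
  below <- speeds < thr
  out <- data.frame(start_step = integer(), n_steps = integer())
  i <- 1L
  n <- length(below)
  while (i <= n) {
    if (below[i]) {
      j <- i
      while (j < n && below[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_len) {
        out <- rbind(out, data.frame(start_step = i, n_steps = j - i + 1L))
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

# O(n^2) time-averaged MSD by explicit double loop.
oracle_msd <- function(x, max_lag) {
  vapply(seq_len(max_lag), function(k) {
    total <- 0
    count <- 0L
    for (i in seq_len(length(x) - k)) {
      total <- total + (x[i + k] - x[i])^2
      count <- count + 1L
    }
    total / count
  }, numeric(1))
}

# Maximal windows of frames with |xa - xb| < dist, kept if >= min_frames.
oracle_cotransport <- function(xa, xb, dist, min_frames) {
  close_enough <- abs(xa - xb) < dist
  out <- data.frame(start_frame = integer(), n_frames = integer())
  i <- 1L
  n <- length(close_enough)
  while (i <= n) {
    if (close_enough[i]) {
      j <- i
      while (j < n && close_enough[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_frames) {
        out <- rbind(out, data.frame(start_frame = i, n_frames = j - i + 1L))
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

# Maximal runs of |dev| > thr, kept if >= min_frames.
oracle_bursts <- function(dev, thr, min_frames = 2) {
  over <- abs(dev) > thr
  out <- data.frame(start_frame = integer(), n_frames = integer())
  i <- 1L
  n <- length(over)
  while (i <= n) {
    if (over[i]) {
      j <- i
      while (j < n && over[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_frames) {
        out <- rbind(out, data.frame(start_frame = i, n_frames = j - i + 1L))
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

# Hand-coded pooled-variance two-sample t test (reference for student_t).
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(statistic = t, df = na + nb - 2,
       p_value = 2 * pt(-abs(t), na + nb - 2))
}

# Exact central 99% binomial interval for an observed proportion.
expect_within_binom_ci99 <- function(k, n, p) {
  lo <- qbinom(0.005, n, p)
  hi <- qbinom(0.995, n, p)
  expect_gte(k, lo)
  expect_lte(k, hi)
}

# Exact central 99% Poisson interval for a sum of counts with mean mu_total.
expect_within_pois_ci99 <- function(total, mu_total) {
  expect_gte(total, qpois(0.005, mu_total))
  expect_lte(total, qpois(0.995, mu_total))
}
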