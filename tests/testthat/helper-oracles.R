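# Independent oracles used by the unit and acceptance tests.  These are
# deliberately naive implementations on a different computational route
# from the package code.

# Full-pairwise dispersion of a point set (diameter).
oracle_dispersion <- function(x, y) {
  if (length(x) < 2L) return(0)
  max(stats::dist(cbind(x, y)))
}

# Brute-force greedy dispersion-window scan: for each start, the maximal
# window is found by binary search over the full-pairwise dispersion
# (monotone in window growth), recomputed from scratch at every probe.
oracle_idt <- function(t, x, y, diameter, min_duration) {
  n <- length(t)
  starts <- ends <- integer(0)
  s <- 1L
  while (s <= n) {
    lo <- s; hi <- n
    while (lo < hi) {
      mid <- (lo + hi + 1L) %/% 2L
      if (oracle_dispersion(x[s:mid], y[s:mid]) <= diameter) lo <- mid
      else hi <- mid - 1L
    }
    e <- lo
    if (t[e] - t[s] >= min_duration) {
      starts <- c(starts, s); ends <- c(ends, e)
      s <- e + 1L
    } else {
      s <- s + 1L
    }
  }
  data.frame(start = starts, end = ends)
}

# Fuzzed small recording: drifting noise with occasional large jumps.
fuzz_recording <- function(n, seed) {
  set.seed(seed)
  t <- (0:(n - 1)) / 100
  n_jump <- max(1L, rpois(1, n / 60))
  jump_at <- sort(sample(2:n, min(n_jump, n - 1)))
  dx <- rnorm(n, 0, 0.05); dy <- rnorm(n, 0, 0.05)
  dx[jump_at] <- dx[jump_at] + sample(c(-1, 1), length(jump_at), TRUE) *
    runif(length(jump_at), 2, 8)
  dy[jump_at] <- dy[jump_at] + sample(c(-1, 1), length(jump_at), TRUE) *
    runif(length(jump_at), 2, 8)
  gaze_recording(t, cumsum(dx) * 0.2, cumsum(dy) * 0.2)
}

# Exact two-sided rank-sum p-value by full enumeration of group
# assignments (tie-free inputs).
oracle_wilcoxon_exact <- function(a, b) {
  m <- length(a); n <- length(b); N <- m + n
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combs <- utils::combn(N, m)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Kendall tau-b by explicit concordant/discordant pair counting.
oracle_kendall_tau <- function(x, y) {
  n <- length(x)
  conc <- disc <- tie_x <- tie_y <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) { tie_x <- tie_x + 1; tie_y <- tie_y + 1 }
      else if (dx == 0) tie_x <- tie_x + 1
      else if (dy == 0) tie_y <- tie_y + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tie_x) * (n0 - tie_y))
}

# Percentile by explicit sort-and-linear-interpolation (type-7 rule).
oracle_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Build a noiseless recording from stationary epochs: each row of `epochs`
# is (x, y, n_samples); epochs are separated by one-sample jumps.
epoch_recording <- function(epochs, rate = 100) {
  xs <- unlist(lapply(seq_len(nrow(epochs)), function(i) {
    rep(epochs[i, 1], epochs[i, 3])
  }))
  ys <- unlist(lapply(seq_len(nrow(epochs)), function(i) {
    rep(epochs[i, 2], epochs[i, 3])
  }))
  t <- (seq_along(xs) - 1) / rate
  gaze_recording(t, xs, ys)
}

# Default study shapes shared by tests and the acceptance script.
session_schedule <- function(p, d, s, design) {
  if (design$sessions_per_day > 1) (s - 1) / (design$sessions_per_day - 1)
  else 0
}
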