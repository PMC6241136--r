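# Independent oracles used across the suite. These deliberately use naive
# enumeration / stats::lm so they share no code with the implementation paths
# they check.

# Exhaustive windowed log-linear fit via lm(): best R^2, ties broken toward
# the longest then earliest window.
oracle_window_fit <- function(areas, times, min_points = 4) {
  n <- length(areas)
  best <- NULL
  for (s in seq_len(n - min_points + 1)) {
    for (e in seq(s + min_points - 1, n)) {
      y <- log(areas[s:e])
      t <- times[s:e]
      if (var(y) == 0) next
      fit <- stats::lm(y ~ t)
      r2 <- summary(fit)$r.squared
      len <- e - s + 1
      cand <- list(rate = unname(stats::coef(fit)[2]), r2 = r2,
                   s = s, e = e, len = len)
      if (is.null(best) ||
          r2 > best$r2 + 1e-9 ||
          (abs(r2 - best$r2) <= 1e-9 &&
           (len > best$len || (len == best$len && s < best$s)))) {
        best <- cand
      }
    }
  }
  best
}

# k-medoid (k = 1) by exhaustive search over candidate medoids.
oracle_medoid1 <- function(mat) {
  d <- as.matrix(stats::dist(mat))
  which.min(rowSums(d))
}

# Occupancy by literal restatement of the rule, independent of the package
# implementation (sorting and indexing done differently).
oracle_occupancy <- function(x, k) {
  x <- x[!is.na(x)]
  lows <- sort(x)[seq_len(k)]
  baseline <- mean(lows)
  # remove exactly the k lowest values (by value, first occurrences)
  rest <- x
  for (v in lows) rest <- rest[-which(rest == v)[1]]
  sum(rest - baseline) / length(rest)
}

small_cfg <- function(n = 400, seed = 1, ...) {
  sim_config(n_colonies = n, seed = seed, ...)
}

# statsmodels medcouple values for the even-n fixture samples (no median
# ties, where every kernel convention coincides); computed externally once.
mc_reference <- list(
  n20 = 0.18508304, n50 = 0.13726432, n100 = 0.32071698, n144 = 0.3618067
)

read_mc_fixture <- function(n) {
  scan(test_path("fixtures", sprintf("mc_sample_n%d.txt", n)), quiet = TRUE)
}
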