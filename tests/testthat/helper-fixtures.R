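# Shared fixtures and independent oracles.

# Random paired-CO table (positive values).
random_pairs <- function(n, seed) {
  set.seed(seed)
  paired_co(
    patient_id = seq_len(n), timepoint = 1L,
    co_ref = exp(rnorm(n, log(6), 0.25)),
    co_test = exp(rnorm(n, log(6), 0.25))
  )
}

# Random delta set with changes large enough to straddle typical zones.
random_deltas <- function(n, seed) {
  set.seed(seed)
  d <- data.frame(
    patient_id = seq_len(n),
    d_ref = rnorm(n, 0, 1.2),
    d_test = rnorm(n, 0, 1.2)
  )
  base <- runif(n, 4, 8)
  d$pct_ref <- 100 * d$d_ref / base
  d$pct_test <- 100 * d$d_test / base
  class(d) <- c("delta_pairs", "data.frame")
  d
}

# Brute-force oracles, kept deliberately naive and separate from the
# implementation code paths.
oracle_pearson <- function(x, y) {
  n <- length(x)
  cx <- x - mean(x); cy <- y - mean(y)
  sum(cx * cy) / (n - 1) / (sd(x) * sd(y))
}

oracle_four_quadrant <- function(deltas, zone) {
  inc <- 0; conc <- 0
  for (i in seq_len(nrow(deltas))) {
    a <- deltas$pct_ref[i]; b <- deltas$pct_test[i]
    if (abs(a) < zone && abs(b) < zone) next
    inc <- inc + 1
    if (sign(a) == sign(b)) conc <- conc + 1
  }
  if (inc == 0) return(NULL)
  list(concordance_pct = 100 * conc / inc, n_included = inc)
}

# AUC by exhaustive pair enumeration, ties counted 1/2.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  tot / (length(pos) * length(neg))
}

# Polar angle recomputed trigonometrically, one point at a time.
oracle_polar_angle <- function(d_ref, d_test) {
  phi <- atan2(d_test, d_ref) * 180 / pi
  theta <- phi - 45
  if ((d_ref + d_test) / 2 < 0) theta <- theta + 180
  theta <- ((theta + 180) %% 360) - 180
  if (theta == -180) theta <- 180
  theta
}
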