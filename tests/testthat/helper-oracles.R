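# Independent oracles used across the suite. Each is a deliberately naive
# implementation kept separate from the package code paths it checks.

# chi-square statistic by the textbook O/E sum
oracle_chisq <- function(counts) {
  E <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  stat <- sum((counts - E)^2 / E)
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  list(statistic = stat, df = df, p_value = pchisq(stat, df, lower.tail = FALSE))
}

# BH step-up by the explicit min-over-suffix loop
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# exhaustive two-group rank-sum permutation distribution (tiny n only)
oracle_ranksum_p <- function(x, y) {
  vals <- c(x, y)
  r <- rank(vals)
  n1 <- length(x)
  obs <- sum(r[seq_len(n1)])
  idx <- utils::combn(length(vals), n1)
  sums <- apply(idx, 2, function(i) sum(r[i]))
  mean(abs(sums - mean(sums)) >= abs(obs - mean(sums)) - 1e-12)
}

# type-7 quantile by the interpolation formula, written independently
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# simulate one complete balanced two-visit dataset directly from the
# random-intercept generative model (bypasses generate_power_dataset)
sim_prepost <- function(n_per_group = 62, betas = c(51, 2.6, 2.6, 2.6),
                        sd_total = 3.3, icc = 0.55) {
  n <- 2 * n_per_group
  g <- rep(c(0, 1), each = n_per_group)
  b <- rnorm(n, 0, sd_total * sqrt(icc))
  mu <- function(t) betas[1] + betas[2] * t + betas[3] * g + betas[4] * t * g
  y0 <- mu(0) + b + rnorm(n, 0, sd_total * sqrt(1 - icc))
  y1 <- mu(1) + b + rnorm(n, 0, sd_total * sqrt(1 - icc))
  id <- sprintf("P%04d", seq_len(n))
  grp <- ifelse(g == 1, "PDTA_CAD", "PDTA")
  data.frame(subject_id = c(id, id), group = c(grp, grp),
             visit = rep(c("baseline", "followup"), each = n),
             days_from_baseline = rep(c(0, 370), each = n),
             y = c(y0, y1), stringsAsFactors = FALSE)
}

# tiny complete balanced fixture with hand-computable GLS estimates
hand_fixture <- function() {
  data.frame(
    subject_id = rep(c("a", "b", "c", "d"), 2),
    group = rep(c("PDTA", "PDTA", "PDTA_CAD", "PDTA_CAD"), 2),
    visit = rep(c("baseline", "followup"), each = 4),
    days_from_baseline = rep(c(0, 370), each = 4),
    y = c(10, 14, 20, 22, 12, 16, 25, 27),
    stringsAsFactors = FALSE)
}
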