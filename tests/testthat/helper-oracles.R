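# Independent brute-force oracles used to cross-check the implementation.

# Exhaustive-distance k-NN: one query at a time, plain loops, same tie-break
# contract (vote tie -> nearest neighbour's label; distance tie -> lower
# training index).
oracle_knn <- function(train_x, train_y, query, k) {
  d <- numeric(nrow(train_x))
  for (i in seq_len(nrow(train_x)))
    d[i] <- sqrt(sum((train_x[i, ] - query)^2))
  ord <- order(d, seq_along(d))
  nn <- ord[seq_len(k)]
  counts <- table(train_y[nn])
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1L) top else train_y[nn[1]]
}

# Counting oracle for confusion-matrix entries.
oracle_confusion <- function(truth, pred, positive) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(truth)) {
    if (truth[i] == positive && pred[i] == positive) tp <- tp + 1L
    else if (truth[i] == positive) fn <- fn + 1L
    else if (pred[i] == positive) fp <- fp + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

# Full-enumeration two-sided rank-sum p-value: every C(n1+n2, n1) assignment
# of the pooled tie-free sample to group 1, Mann-Whitney U as the statistic.
oracle_ranksum_p <- function(g1, g2) {
  pooled <- c(g1, g2)
  n1 <- length(g1)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  sets <- utils::combn(length(pooled), n1)
  us <- apply(sets, 2L, u_of)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(1, p)
}

# Brute-force segment statistics (loops, textbook formulas).
oracle_segment_stats <- function(x) {
  n <- length(x)
  m <- 0
  for (v in x) m <- m + v
  m <- m / n
  ss <- 0
  for (v in x) ss <- ss + (v - m)^2
  sorted <- sort(x)
  med <- if (n %% 2L == 1L) sorted[(n + 1L) / 2L]
  else (sorted[n / 2L] + sorted[n / 2L + 1L]) / 2
  c(mean = m, std = sqrt(ss / (n - 1)), median = med)
}

expect_landmarks_equal <- function(lm, truth, tol = 0L) {
  expect_true(all(abs(unlist(lm[c("a","b","c","d","e","f")]) -
                      unlist(truth[c("a","b","c","d","e","f")])) <= tol))
}
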