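# Independent brute-force oracles, written against the metric definitions
# and kept free of the package's vectorised implementations.

oracle_drift <- function(xy, alpha) {
  F <- dim(xy)[1]; K <- dim(xy)[2]
  out <- numeric(K)
  for (k in seq_len(K)) {
    n <- 0
    for (i in 2:F) {
      d <- sqrt(sum((xy[i, k, ] - xy[i - 1, k, ])^2))
      if (d > alpha) n <- n + 1
    }
    out[k] <- n / F
  }
  out
}

oracle_miss <- function(conf, cutoff) {
  apply(conf, 2, function(col) sum(col <= cutoff) / length(col))
}

oracle_change_rate <- function(centers, alpha) {
  F <- dim(centers)[1]; n <- dim(centers)[2]
  rates <- numeric(n)
  for (j in seq_len(n)) {
    cnt <- 0
    for (i in 2:F) {
      if (sqrt(sum((centers[i, j, ] - centers[i - 1, j, ])^2)) > alpha) cnt <- cnt + 1
    }
    rates[j] <- cnt / F
  }
  mean(rates)
}

oracle_oks <- function(pred, gt, area, s, v) {
  num <- 0; den <- 0
  for (i in seq_len(nrow(gt))) {
    if (v[i]) {
      d2 <- sum((pred[i, ] - gt[i, ])^2)
      num <- num + exp(-d2 / (2 * area * (2 * s)^2))
      den <- den + 1
    }
  }
  num / den
}

oracle_map <- function(oks_values, thresholds) {
  ap <- sapply(thresholds, function(a) sum(oks_values > a) / length(oks_values))
  list(ap = ap, map = mean(ap))
}

oracle_rmse <- function(pred, gt) {
  sqrt(mean(sapply(seq_len(nrow(gt)), function(i) sum((pred[i, ] - gt[i, ])^2))))
}

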