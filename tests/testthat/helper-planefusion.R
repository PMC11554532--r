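# Shared test fixtures, all generated in code.

# A tiny planted feature matrix (see planted_feature_spec).
tiny_planted <- function(n = 200, d = 30, informative = 1:6, effect = 2,
                         k = 4, seed = 3) {
  generate_feature_matrix(planted_feature_spec(n = n, d = d,
                                               informative = informative,
                                               effect = effect, k = k,
                                               seed = seed))
}

# One-hot probability matrix from hard predictions.
onehot_probs <- function(pred, k) {
  p <- matrix(0, length(pred), k)
  p[cbind(seq_along(pred), pred)] <- 1
  p
}

# Brute-force macro metrics straight from the label vectors, written
# independently of the package's confusion-matrix route.
brute_metrics <- function(truth, pred, k) {
  acc <- 100 * mean(truth == pred)
  prec <- rec <- f1 <- numeric(k)
  for (c in seq_len(k)) {
    tp <- sum(truth == c & pred == c)
    prec[c] <- if (sum(pred == c) == 0) 0 else tp / sum(pred == c)
    rec[c] <- if (sum(truth == c) == 0) 0 else tp / sum(truth == c)
    f1[c] <- if (prec[c] + rec[c] == 0) 0
             else 2 * prec[c] * rec[c] / (prec[c] + rec[c])
  }
  present <- vapply(seq_len(k), function(c) any(truth == c), TRUE)
  # MCC via the covariance of one-hot encodings (Gorodkin's definition)
  X <- onehot_probs(truth, k); Y <- onehot_probs(pred, k)
  covf <- function(A, B) sum(diag(stats::cov(A, B)))
  den <- sqrt(covf(X, X) * covf(Y, Y))
  mcc <- if (den == 0) 0 else covf(X, Y) / den
  list(accuracy = acc, precision = 100 * mean(prec[present]),
       recall = 100 * mean(rec[present]), f1 = 100 * mean(f1[present]),
       mcc = mcc)
}
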