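# Independent oracles used across test files.

# Tau-b by sign products plus the tie-group denominator (distinct route
# from the package's pair-classification implementation).
oracle_tau_b <- function(x, y) {
  x <- unname(x)
  y <- unname(y)
  n <- length(x)
  num <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      num <- num + sign(x[i] - x[j]) * sign(y[i] - y[j])
    }
  }
  t1 <- sum(vapply(table(x), function(t) t * (t - 1) / 2, numeric(1)))
  t2 <- sum(vapply(table(y), function(t) t * (t - 1) / 2, numeric(1)))
  n0 <- n * (n - 1) / 2
  num / sqrt((n0 - t1) * (n0 - t2))
}

# Exact one-sided clustering p-value by enumerating every arrangement of
# the two labels over positions (feasible for short sequences).
oracle_runs_pvalue <- function(labels, observed = length(rle(labels)$values)) {
  labs <- sort(unique(labels))
  stopifnot(length(labs) == 2)
  n <- length(labels)
  n1 <- sum(labels == labs[1])
  combos <- utils::combn(n, n1)
  runs <- apply(combos, 2, function(pos) {
    v <- rep(labs[2], n)
    v[pos] <- labs[1]
    length(rle(v)$values)
  })
  mean(runs <= observed)
}

# Minimal class_sequence for toy inputs.
make_class_seq <- function(labels, ids = paste0("e", seq_along(labels))) {
  out <- data.frame(id = ids, group = "AU_RICH",
                    column = seq_along(labels), rank = seq_along(labels),
                    label = labels, stringsAsFactors = FALSE)
  class(out) <- c("class_sequence", "data.frame")
  out
}

# Random tied ranking over n items (for property-style tau tests).
random_tied_ranking <- function(n) {
  k <- sample(seq_len(n), 1)
  sort(sample(seq_len(k), n, replace = TRUE))[sample(n)]
}
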