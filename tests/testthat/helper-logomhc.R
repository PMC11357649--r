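# Shared fixtures and independent oracles for the suite.

AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
        "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

QB <- published_qm("binder")
QNB <- published_qm("non-binder")

random_nonamers <- function(n, seed) {
  set.seed(seed)
  replicate(n, paste(sample(AA, 9, replace = TRUE), collapse = ""))
}

# Independent scoring oracle: residue-by-residue lookup in a loop, no
# vectorization shared with score_nonamers().
brute_force_score <- function(qm, nonamer) {
  res <- strsplit(nonamer, "")[[1]]
  vals <- numeric(9)
  for (p in 1:9) vals[p] <- unclass(qm)[res[p], paste0("p", p)]
  sum(vals)
}

# Independent metrics oracle: rebuild 0/1 truth/prediction vectors from the
# confusion counts and compute each statistic from those vectors. MCC is the
# Pearson correlation of the two binary vectors (phi coefficient identity).
vector_metrics <- function(tp, fp, tn, fn) {
  truth <- c(rep(1, tp + fn), rep(0, tn + fp))
  pred <- c(rep(1, tp), rep(0, fn), rep(0, tn), rep(1, fp))
  list(sensitivity = mean(pred[truth == 1]),
       specificity = mean(1 - pred[truth == 0]),
       accuracy = mean(pred == truth),
       precision = mean(truth[pred == 1]),
       mcc = suppressWarnings(stats::cor(truth, pred)),
       f1 = 2 * sum(pred * truth) / (sum(pred) + sum(truth)))
}
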