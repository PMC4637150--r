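# Independent exhaustive-search kNN oracle: full distance sort in R with
# the documented tie rule (vote tie -> class of the nearest neighbour;
# exact-distance ties -> smaller class code). Kept deliberately separate
# from the package's C++ path so the two can be compared bit-for-bit.
knn_oracle <- function(train_feat, train_lab, targets, k) {
  train_feat <- as.matrix(train_feat)
  targets <- as.matrix(targets)
  apply(targets, 1, function(x) {
    d2 <- rowSums(sweep(train_feat, 2, x)^2)
    ord <- order(d2, train_lab)       # lexicographic (distance, class code)
    nn <- ord[seq_len(k)]
    votes <- table(train_lab[nn])
    top <- as.integer(names(votes)[votes == max(votes)])
    for (i in nn) if (train_lab[i] %in% top) return(train_lab[i])
  })
}

# closed-form Bayes error for two equal-prior unit-variance Gaussians at
# +/- mu: Phi(-mu)
bayes_error_two_gaussians <- function(mu) pnorm(-mu)
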