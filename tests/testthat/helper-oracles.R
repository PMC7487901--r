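# Independent oracles used across the suite (kept deliberately naive).

# Exhaustive strict 8-neighbour local-maximum scan, independent of the
# package's image ops.
brute_local_maxima <- function(img, floor) {
  hits <- NULL
  nr <- nrow(img); nc <- ncol(img)
  for (r in 2:(nr - 1)) for (c in 2:(nc - 1)) {
    v <- img[r, c]
    if (v <= floor) next
    nb <- img[(r - 1):(r + 1), (c - 1):(c + 1)]
    nb[2, 2] <- -Inf
    if (v > max(nb)) hits <- rbind(hits, c(r, c))
  }
  hits
}

# Distance from each detection to its nearest true centre.
nearest_truth_dist <- function(det, centers) {
  vapply(seq_len(nrow(det)), function(i)
    min(sqrt((centers[, 1] - det$row[i])^2 + (centers[, 2] - det$col[i])^2)),
    numeric(1))
}

expect_all_lt <- function(x, bound) expect_true(all(x < bound))
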