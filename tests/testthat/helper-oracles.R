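# Independent brute-force oracles for the metric panel, written from the
# set-theoretic definitions rather than the confusion-count formulas.

oracle_overlap <- function(pred, ref) {
  A <- as.vector(pred) == 1
  B <- as.vector(ref) == 1
  inter <- sum(A & B)
  list(dsc = 2 * inter / (sum(A) + sum(B)),
       jaccard = inter / sum(A | B),
       fn_rate = 1 - inter / sum(B),
       # phi coefficient: Pearson correlation of the binary indicators
       mcc = suppressWarnings(stats::cor(as.numeric(A), as.numeric(B))),
       vs = 1 - abs(sum(A) - sum(B)) / (sum(A) + sum(B)))
}

# Boundary voxels by explicit 6-neighbour inspection with padding.
oracle_boundary <- function(mask) {
  d <- dim(mask)
  pad <- array(0L, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  coords <- which(mask == 1, arr.ind = TRUE)
  keep <- vapply(seq_len(nrow(coords)), function(t) {
    i <- coords[t, 1] + 1L; j <- coords[t, 2] + 1L; k <- coords[t, 3] + 1L
    pad[i - 1, j, k] == 0 || pad[i + 1, j, k] == 0 ||
      pad[i, j - 1, k] == 0 || pad[i, j + 1, k] == 0 ||
      pad[i, j, k - 1] == 0 || pad[i, j, k + 1] == 0
  }, logical(1))
  coords[keep, , drop = FALSE]
}

oracle_hd95 <- function(pred, ref, spacing = c(1, 1, 1)) {
  bp <- sweep(oracle_boundary(pred), 2, spacing, "*")
  br <- sweep(oracle_boundary(ref), 2, spacing, "*")
  cross <- function(a, b) {
    apply(a, 1, function(pt)
      sqrt(min(colSums((t(b) - pt)^2))))
  }
  stats::quantile(c(cross(bp, br), cross(br, bp)), 0.95, names = FALSE)
}

oracle_auc <- function(prob, ref) {
  s <- as.vector(prob); y <- as.vector(ref)
  pos <- s[y == 1]; neg <- s[y == 0]
  gr <- outer(pos, neg, ">")
  eq <- outer(pos, neg, "==")
  (sum(gr) + 0.5 * sum(eq)) / (length(pos) * length(neg))
}

# Random mask pair guaranteed to contain both classes and non-empty masks.
random_mask_pair <- function(dims = c(8, 8, 8)) {
  repeat {
    p <- random_mask_array(dims, stats::runif(1, 0.2, 0.5))
    r <- random_mask_array(dims, stats::runif(1, 0.2, 0.5))
    if (sum(p) > 0 && sum(r) > 0 && sum(p) < prod(dims) &&
        sum(r) < prod(dims)) return(list(pred = p, ref = r))
  }
}
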