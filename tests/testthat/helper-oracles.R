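# Independent oracles used across the suite. These deliberately avoid the
# package's own traversal code paths: dense linear algebra, exhaustive
# enumeration, and double-loop counting.

# GLS ancestral estimates from the dense tip covariance matrix:
# est(k) = mu + c_k' V^-1 (x - mu), mu the phylogenetic mean,
# c_k the vector of shared path lengths between node k and each tip.
dense_gls_asr <- function(tree, x) {
  n <- length(tree$tip.label)
  V <- ape::vcv(tree)
  xo <- x[rownames(V)]
  Vi <- solve(V)
  mu <- sum(Vi %*% xo) / sum(Vi)
  dep <- renschkit:::node_depths(tree)
  D <- ape::dist.nodes(tree)
  est <- vapply((n + 1):(n + tree$Nnode), function(k) {
    ck <- (dep[seq_len(n)] + dep[k] - D[seq_len(n), k]) / 2
    names(ck) <- tree$tip.label
    mu + drop(ck[rownames(V)] %*% Vi %*% (xo - mu))
  }, numeric(1))
  est
}

# Exhaustive parsimony length: minimum mismatch count over all 2^Nnode
# internal labelings of a binary character.
brute_force_parsimony <- function(tree, states) {
  n <- length(tree$tip.label)
  m <- tree$Nnode
  s <- states[tree$tip.label]
  best <- Inf
  for (code in 0:(2^m - 1)) {
    lab <- c(s, as.integer(intToBits(code)[seq_len(m)]))
    cost <- sum(lab[tree$edge[, 1L]] != lab[tree$edge[, 2L]])
    best <- min(best, cost)
  }
  best
}

# Double-loop box counting oracle.
brute_force_box_count <- function(img, s) {
  nr <- nrow(img); nc <- ncol(img)
  cnt <- 0L
  for (i in seq(1L, nr, by = s)) {
    for (j in seq(1L, nc, by = s)) {
      blk <- img[i:min(i + s - 1L, nr), j:min(j + s - 1L, nc)]
      if (any(blk)) cnt <- cnt + 1L
    }
  }
  cnt
}

# Random tree with uniform branch lengths, reproducible.
random_tree <- function(n, seed) {
  set.seed(seed)
  ape::rtree(n)
}

random_named_values <- function(tree, seed, mean = 0, sd = 1) {
  set.seed(seed)
  stats::setNames(stats::rnorm(length(tree$tip.label), mean, sd),
                  tree$tip.label)
}
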