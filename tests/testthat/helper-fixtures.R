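# small in-code fixtures shared across test files

# tiny all-positive count matrix with known structure
tiny_counts <- function(seed = 1, ng = 8, n = 6) {
  set.seed(seed)
  m <- matrix(rpois(ng * n, lambda = 50) + 1, ng, n,
              dimnames = list(sprintf("g%02d", seq_len(ng)),
                              sprintf("s%02d", seq_len(n))))
  m
}

two_class_design <- function(nc, ns) {
  data.frame(sample_id = c(sprintf("ctrl_%02d", seq_len(nc)),
                           sprintf("strs_%02d", seq_len(ns))),
             condition = rep(c("control", "stress"), c(nc, ns)),
             study = "study1", stringsAsFactors = FALSE)
}

# independent median-of-ratios oracle (straight from the definition)
median_ratio_oracle <- function(K) {
  geo <- apply(K, 1, function(x) exp(mean(log(x))))
  ok <- apply(K, 1, function(x) all(x > 0))
  s <- apply(K, 2, function(col) median((col / geo)[ok]))
  s / exp(mean(log(s)))
}

# independent symmetric-uncertainty oracle from an explicit joint table
su_oracle <- function(g, y) {
  H <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  j <- table(g, y) / length(g)
  hg <- H(rowSums(j)); hy <- H(colSums(j)); hj <- H(as.numeric(j))
  mi <- hg + hy - hj
  2 * mi / (hg + hy)
}

# independent Relief oracle: explicit nested loops over instances
relief_oracle <- function(X, y01) {
  rng <- apply(X, 1, range)
  span <- rng[2, ] - rng[1, ]
  Z <- (X - rng[1, ]) / ifelse(span == 0, 1, span)
  n <- ncol(Z); W <- numeric(nrow(Z))
  for (i in seq_len(n)) {
    dh <- Inf; dm <- Inf; hit <- NA; miss <- NA
    for (j in seq_len(n)) {
      if (j == i) next
      d <- sum(abs(Z[, i] - Z[, j]))
      if (y01[j] == y01[i] && d < dh) { dh <- d; hit <- j }
      if (y01[j] != y01[i] && d < dm) { dm <- d; miss <- j }
    }
    W <- W + (abs(Z[, i] - Z[, miss]) - abs(Z[, i] - Z[, hit])) / n
  }
  W
}
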