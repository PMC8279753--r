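# Independent oracles and small fixture builders shared across test files.
# These deliberately re-derive results through different code paths (table()
# based MI, loop-based greedy selection, eigendecomposition-based SVD) so
# they can stand as cross-checks of the package implementations.

# plain table()-based mutual information in nats
oracle_mi <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  p <- tab / n
  pa <- rowSums(p)
  pb <- colSums(p)
  total <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (p[i, j] > 0)
      total <- total + p[i, j] * log(p[i, j] / (pa[i] * pb[j]))
  }
  unname(total)
}

# loop-based three-bin discretization at mean +/- sd
oracle_discretize <- function(x) {
  apply(x, 2, function(col) {
    mu <- mean(col)
    s <- stats::sd(col)
    ifelse(col < mu - s, 1L, ifelse(col > mu + s, 3L, 2L))
  })
}

# exhaustive greedy mRMR (MID scheme), scoring every candidate at every step
oracle_mrmr <- function(x, y, m) {
  D <- oracle_discretize(x)
  p <- ncol(x)
  relevance <- vapply(seq_len(p), function(f) oracle_mi(D[, f], y), numeric(1))
  selected <- integer(0)
  for (step in seq_len(m)) {
    best_score <- -Inf
    best_f <- NA_integer_
    for (f in setdiff(seq_len(p), selected)) {
      red <- if (length(selected) == 0) 0 else
        mean(vapply(selected, function(s) oracle_mi(D[, f], D[, s]),
                    numeric(1)))
      score <- relevance[f] - red
      if (score > best_score + 1e-9) {   # same lowest-index tie rule
        best_score <- score
        best_f <- f
      }
    }
    selected <- c(selected, best_f)
  }
  colnames(x)[selected]
}

# leading singular pair via eigendecomposition of M M^T
oracle_svd_vector <- function(M) {
  M <- as.matrix(M)
  e <- eigen(M %*% t(M), symmetric = TRUE)
  v <- sqrt(max(e$values[1], 0)) * e$vectors[, 1]
  if (v[which.max(abs(v))] < 0) v <- -v
  v
}

# write a small FASTA file from raw header/sequence pairs
write_raw_fasta <- function(headers, seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(as.vector(rbind(paste0(">", headers), seqs)), path)
  path
}

# cheap pipeline settings for model_eval structure tests: short peptides,
# tiny selection, fast deterministic tree classifier
cheap_cv_args <- function() {
  list(l_x = 12, m = 10, classifier = classifier_spec("dt"), folds = 3L)
}

tiny_dataset <- function(seed = 5, n = 15) {
  generate_dataset(n, n, length_range = c(8, 14), signal_strength = 0.9,
                   seed = seed)
}
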