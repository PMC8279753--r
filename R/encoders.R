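#' Binary profile features of the N-terminus
#'
#' One-hot encodes the first `k` residues over the alphabetically ordered
#' 20-letter alphabet: residue `A` maps to `(1, 0, ..., 0)`, `C` to
#' `(0, 1, 0, ..., 0)`, and so on. The padding letter `X` maps to the
#' all-zero vector, so the number of ones equals the number of non-X
#' residues among the first `k`.
#'
#' @param sequence A single peptide sequence with at least `k` residues.
#' @param k Number of N-terminal residues to encode (default 7, giving
#'   20 x 7 = 140 features).
#' @return Named numeric vector of length `20 * k`
#'   (names `bpf_pos{j}_{residue}`).
#' @export
encode_bpf <- function(sequence, k = 7) {
  if (nchar(sequence) < k)
    stop(sprintf("sequence length %d is shorter than k = %d",
                 nchar(sequence), k), call. = FALSE)
  aa <- aa_alphabet()
  ch <- seq_chars(substr(sequence, 1L, k))[[1]]
  v <- numeric(20L * k)
  hit <- match(ch, aa)                      # NA for X
  pos <- which(!is.na(hit))
  v[(pos - 1L) * 20L + hit[pos]] <- 1
  names(v) <- bpf_feature_names(k)
  v
}

bpf_feature_names <- function(k) {
  as.vector(vapply(seq_len(k),
                   function(j) sprintf("bpf_pos%d_%s", j, aa_alphabet()),
                   character(20)))
}

#' Per-position AAindex features
#'
#' Encodes an equal-length (normalized) peptide as the position-major
#' concatenation of physicochemical index values: for each position `j`, the
#' values of all table indices for residue `p_j`. The padding letter `X`
#' contributes zeros. With the default 531-index table and a target length
#' of 40 this yields the 21,240-dimensional descriptor block.
#'
#' @param sequence A normalized peptide (see [normalize_length()]).
#' @param table Index-by-residue matrix from [aaindex_table()] (the
#'   default) or a compatible substitute.
#' @param l_x Expected sequence length; defaults to the actual length, pass
#'   it explicitly to assert the pipeline's configured length.
#' @return Named numeric vector of length `nrow(table) * l_x`
#'   (names `aai_pos{j}_{index_id}`).
#' @export
encode_aaindex <- function(sequence, table = aaindex_table(),
                           l_x = nchar(sequence)) {
  table <- validate_aaindex_table(table)
  if (nchar(sequence) != l_x)
    stop(sprintf("sequence length %d does not match configured length %d",
                 nchar(sequence), l_x), call. = FALSE)
  ch <- seq_chars(sequence)[[1]]
  hit <- match(ch, colnames(table))
  m <- matrix(0, nrow = nrow(table), ncol = l_x)
  ok <- !is.na(hit)
  m[, ok] <- table[, hit[ok]]
  v <- as.vector(m)                         # column = position => position-major
  names(v) <- aaindex_feature_names(l_x, rownames(table))
  v
}

aaindex_feature_names <- function(l_x, index_ids) {
  as.vector(vapply(seq_len(l_x),
                   function(j) sprintf("aai_pos%d_%s", j, index_ids),
                   character(length(index_ids))))
}

#' Reduced-alphabet k-mer configuration
#'
#' The 20 residues are partitioned into 7 physicochemical classes so a
#' k-mer draws from `7^K` possibilities. The default grouping —
#' \{A,G,V\}, \{I,L,F,P\}, \{Y,M,T,S\}, \{H,N,Q,W\}, \{R,K\}, \{D,E\},
#' \{C\} — is a standard small/hydrophobic/polar/charged partition; any
#' disjoint cover of the 20 residues in 7 groups may be supplied.
#'
#' @param K k-mer length (default 3, giving 343 rows).
#' @param alphabet_classes List of 7 disjoint character vectors covering the
#'   20 standard residues.
#' @return A `kmer_config` list.
#' @export
kmer_config <- function(K = 3,
                        alphabet_classes = list(
                          c("A", "G", "V"),
                          c("I", "L", "F", "P"),
                          c("Y", "M", "T", "S"),
                          c("H", "N", "Q", "W"),
                          c("R", "K"),
                          c("D", "E"),
                          c("C"))) {
  if (!is.numeric(K) || length(K) != 1L || K < 1)
    stop("K must be a single integer >= 1", call. = FALSE)
  all_res <- sort(unlist(alphabet_classes))
  if (!identical(all_res, sort(aa_alphabet())))
    stop("alphabet classes must disjointly cover the 20 standard residues",
         call. = FALSE)
  structure(list(K = as.integer(K), alphabet_classes = alphabet_classes),
            class = "kmer_config")
}

# residue -> class index lookup (X and any non-standard -> NA)
class_lookup <- function(config) {
  map <- integer(0)
  for (i in seq_along(config$alphabet_classes))
    map[config$alphabet_classes[[i]]] <- i
  map
}

#' Build the k-mer sparse occurrence matrix of one peptide
#'
#' Maps each residue to its reduced-alphabet class and marks, for every
#' window start `t`, the class k-mer beginning there: entry
#' `(row(kmer), t) = 1`. Rows index class k-mers as base-7 numbers (first
#' window position most significant). Windows containing the padding letter
#' `X` produce all-zero columns: padding must not create spurious k-mers.
#'
#' @param sequence A peptide of length `L >= K`.
#' @param config A [kmer_config()].
#' @return A sparse 0/1 matrix of shape `7^K x (L - K + 1)`
#'   (class [Matrix::sparseMatrix()]).
#' @export
build_kmer_matrix <- function(sequence, config = kmer_config()) {
  K <- config$K
  L <- nchar(sequence)
  if (L < K)
    stop(sprintf("sequence length %d is shorter than K = %d", L, K),
         call. = FALSE)
  n_class <- length(config$alphabet_classes)
  cls <- class_lookup(config)[seq_chars(sequence)[[1]]]
  n_win <- L - K + 1L
  # mixed-radix row index; any NA (X) in the window voids the column
  row <- rep(0L, n_win)
  valid <- rep(TRUE, n_win)
  for (j in seq_len(K)) {
    cj <- cls[j:(j + n_win - 1L)]
    valid <- valid & !is.na(cj)
    row <- row * n_class + (ifelse(is.na(cj), 1L, cj) - 1L)
  }
  Matrix::sparseMatrix(i = row[valid] + 1L, j = which(valid), x = 1,
                       dims = c(n_class^K, n_win),
                       dimnames = list(kmer_feature_names(config), NULL))
}

kmer_feature_names <- function(config) {
  K <- config$K
  n_class <- length(config$alphabet_classes)
  grid <- do.call(expand.grid, rev(replicate(K, seq_len(n_class),
                                             simplify = FALSE)))
  # column-major expand.grid varies the first column fastest; reversed so the
  # first k-mer position is the most significant digit, matching the row index
  sprintf("kmer_%s", apply(grid[, rev(seq_len(K)), drop = FALSE], 1, paste,
                           collapse = ""))
}

#' Compress a k-mer matrix to a fixed-length vector by SVD
#'
#' Returns the leading left singular vector scaled by the leading singular
#' value (`sigma_1 * u_1`), with the sign fixed so the entry of largest
#' magnitude is positive. This summarizes the positional occurrence matrix
#' in a length-`7^K` vector regardless of peptide length.
#'
#' @param M A k-mer matrix from [build_kmer_matrix()].
#' @return Named numeric vector with one entry per class k-mer.
#' @export
svd_reduce_kmer <- function(M) {
  dense <- as.matrix(M)
  if (all(dense == 0))
    stop("degenerate input: all-zero k-mer matrix", call. = FALSE)
  dec <- svd(dense, nu = 1, nv = 0)
  v <- dec$d[1] * dec$u[, 1]
  if (v[which.max(abs(v))] < 0) v <- -v
  names(v) <- rownames(M)
  v
}

#' Encode a dataset into a block-tagged feature matrix
#'
#' Per-sample concatenation of the requested encodings in the fixed order
#' `bpf | aaindex | kmer`. The AAindex block is the full (unselected) block;
#' reduction to the most informative columns happens downstream via
#' [fit_mrmr()] / [apply_selection()], inside each training fold.
#'
#' @param dataset A labeled or unlabeled [peptide_dataset()].
#' @param l_x Target length; sequences are normalized internally.
#' @param feature_set Non-empty subset of `c("bpf", "aaindex", "kmer")`.
#' @param k N-terminal width of the binary profile block.
#' @param table AAindex table (defaults to [aaindex_table()]).
#' @param config A [kmer_config()].
#' @return A [feature_matrix()] with one row per record.
#' @export
encode_dataset <- function(dataset, l_x = 40,
                           feature_set = c("bpf", "aaindex"),
                           k = 7, table = NULL, config = kmer_config()) {
  feature_set <- match.arg(feature_set, c("bpf", "aaindex", "kmer"),
                           several.ok = TRUE)
  n <- nrow(dataset)
  if (n == 0L) stop("empty dataset", call. = FALSE)
  seqs <- normalize_length(dataset$sequence, l_x)
  parts <- list()
  tags <- list()
  if ("bpf" %in% feature_set) {
    m <- t(vapply(seqs, encode_bpf, numeric(20L * k), k = k,
                  USE.NAMES = FALSE))
    colnames(m) <- bpf_feature_names(k)
    parts$bpf <- m
    tags$bpf <- rep("bpf", ncol(m))
  }
  if ("aaindex" %in% feature_set) {
    if (is.null(table)) table <- aaindex_table()
    table <- validate_aaindex_table(table)
    m <- matrix(0, nrow = n, ncol = nrow(table) * l_x)
    chars <- matrix(unlist(seq_chars(seqs)), nrow = n, byrow = TRUE)
    for (j in seq_len(l_x)) {
      hit <- match(chars[, j], colnames(table))
      block <- matrix(0, nrow = nrow(table), ncol = n)
      ok <- !is.na(hit)
      block[, ok] <- table[, hit[ok]]
      m[, ((j - 1L) * nrow(table) + 1L):(j * nrow(table))] <- t(block)
    }
    colnames(m) <- aaindex_feature_names(l_x, rownames(table))
    parts$aaindex <- m
    tags$aaindex <- rep("aaindex", ncol(m))
  }
  if ("kmer" %in% feature_set) {
    width <- length(config$alphabet_classes)^config$K
    m <- t(vapply(seqs, function(s)
      svd_reduce_kmer(build_kmer_matrix(s, config)), numeric(width),
      USE.NAMES = FALSE))
    colnames(m) <- kmer_feature_names(config)
    parts$kmer <- m
    tags$kmer <- rep("kmer", ncol(m))
  }
  ord <- intersect(c("bpf", "aaindex", "kmer"), names(parts))
  x <- do.call(cbind, parts[ord])
  rownames(x) <- dataset$id
  feature_matrix(x, unlist(tags[ord], use.names = FALSE),
                 labels = if (!all(is.na(dataset$label))) dataset$label)
}
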