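#' Feature matrix container
#'
#' Samples-by-features numeric matrix with a per-feature block tag
#' (`"bpf"`, `"aaindex"` or `"kmer"`), per-sample binary labels (optional)
#' and a per-sample provenance field (`"-"` for original samples, the source
#' sample id for pseudosamples created by [augment_training_set()]).
#'
#' @param x Numeric matrix with sample ids as row names and feature names as
#'   column names.
#' @param blocks Character vector, one tag per column of `x`.
#' @param labels Optional 0/1 integer vector, one per row.
#' @param source Optional character provenance vector, one per row.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(x, blocks, labels = NULL, source = NULL) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (length(blocks) != ncol(x))
    stop("blocks must tag every feature column", call. = FALSE)
  if (!all(blocks %in% c("bpf", "aaindex", "kmer")))
    stop("unknown block tag(s): ",
         paste(setdiff(blocks, c("bpf", "aaindex", "kmer")), collapse = ", "),
         call. = FALSE)
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(x) || any(!labels %in% c(0L, 1L)))
      stop("labels must be one 0/1 value per sample", call. = FALSE)
  }
  if (is.null(source)) source <- rep("-", nrow(x))
  structure(list(x = x, blocks = blocks, labels = labels, source = source),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  tab <- table(factor(x$blocks, levels = c("bpf", "aaindex", "kmer")))
  cat(sprintf("feature_matrix: %d samples x %d features (bpf %d | aaindex %d | kmer %d)\n",
              nrow(x$x), ncol(x$x), tab["bpf"], tab["aaindex"], tab["kmer"]))
  if (!is.null(x$labels))
    cat(sprintf("  labels: %d positive, %d negative\n",
                sum(x$labels == 1L), sum(x$labels == 0L)))
  n_pseudo <- sum(x$source != "-")
  if (n_pseudo > 0L)
    cat(sprintf("  pseudosamples: %d\n", n_pseudo))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$x)

#' Subset a feature matrix by sample and/or feature
#'
#' @param fm A [feature_matrix()].
#' @param rows,cols Index vectors (any form accepted by matrix subsetting).
#' @return A [feature_matrix()].
#' @export
fm_subset <- function(fm, rows = NULL, cols = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(fm$x))
  if (is.null(cols)) cols <- seq_len(ncol(fm$x))
  if (is.character(cols)) cols <- match(cols, colnames(fm$x))
  feature_matrix(fm$x[rows, cols, drop = FALSE], fm$blocks[cols],
                 labels = fm$labels[rows],
                 source = fm$source[rows])
}

#' Extract one feature block
#'
#' @param fm A [feature_matrix()].
#' @param tag Block tag (`"bpf"`, `"aaindex"` or `"kmer"`).
#' @return Numeric matrix of the tagged columns.
#' @export
fm_block <- function(fm, tag) fm$x[, fm$blocks == tag, drop = FALSE]

#' Write / read a feature matrix as annotated TSV
#'
#' Plain TSV with `#blocks` (and, when present, `#labels` / `#source`)
#' comment lines ahead of the header, so feature provenance survives a
#' round trip through text files.
#'
#' @param fm A [feature_matrix()].
#' @param path File path.
#' @return `path` (write) or a [feature_matrix()] (read).
#' @export
write_feature_matrix <- function(fm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#blocks\t", paste(fm$blocks, collapse = "\t")), con)
  if (!is.null(fm$labels))
    writeLines(paste0("#labels\t", paste(fm$labels, collapse = "\t")), con)
  writeLines(paste0("#source\t", paste(fm$source, collapse = "\t")), con)
  utils::write.table(
    data.frame(sample_id = rownames(fm$x), fm$x, check.names = FALSE),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  lines <- readLines(path)
  meta <- grepl("^#", lines)
  parse_meta <- function(key) {
    hit <- grep(paste0("^#", key, "\t"), lines, value = TRUE)
    if (length(hit) == 0L) return(NULL)
    strsplit(sub(paste0("^#", key, "\t"), "", hit[1]), "\t")[[1]]
  }
  tab <- utils::read.table(text = lines[!meta], header = TRUE, sep = "\t",
                           check.names = FALSE)
  x <- as.matrix(tab[, -1, drop = FALSE])
  rownames(x) <- tab$sample_id
  labels <- parse_meta("labels")
  feature_matrix(x, parse_meta("blocks"),
                 labels = if (!is.null(labels)) as.integer(labels),
                 source = parse_meta("source"))
}
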