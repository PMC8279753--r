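#' Construct a peptide dataset
#'
#' A `peptide_dataset` is a data frame with columns `id`, `sequence` and
#' `label` (1 = ACP / positive, 0 = non-ACP / negative, `NA` = unlabeled).
#' Sequences are validated against the 21-letter alphabet (20 standard
#' residues plus the padding letter `X`) and ids must be unique — the
#' benchmark sets this package targets are non-redundant, so a duplicate id
#' is treated as a data error rather than silently suffixed.
#'
#' @param id Character vector of record identifiers.
#' @param sequence Character vector of peptide sequences (upper case).
#' @param label Optional integer/numeric vector of 0/1 class labels.
#' @return A data frame of class `peptide_dataset`.
#' @export
peptide_dataset <- function(id, sequence, label = NA) {
  id <- as.character(id)
  sequence <- as.character(sequence)
  if (length(id) != length(sequence))
    stop("id and sequence must have the same length", call. = FALSE)
  if (anyDuplicated(id))
    stop("duplicate record id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  if (any(!nzchar(sequence)))
    stop("record(s) with empty sequence: ",
         paste(id[!nzchar(sequence)], collapse = ", "), call. = FALSE)
  lower <- sequence != toupper(sequence)
  if (any(lower)) {
    warning("lower-case residues upper-cased in record(s): ",
            paste(id[lower], collapse = ", "), call. = FALSE)
    sequence <- toupper(sequence)
  }
  validate_sequences(sequence, id)
  label <- suppressWarnings(as.integer(label))
  if (any(!is.na(label) & !label %in% c(0L, 1L)))
    stop("labels must be 0, 1 or NA", call. = FALSE)
  out <- data.frame(id = id, sequence = sequence,
                    label = rep_len(label, length(id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("peptide_dataset", "data.frame")
  out
}

#' @export
print.peptide_dataset <- function(x, ...) {
  cat(sprintf("peptide_dataset: %d records (%d positive, %d negative, %d unlabeled)\n",
              nrow(x), n_pos(x), n_neg(x), sum(is.na(x$label))))
  lens <- nchar(x$sequence)
  cat(sprintf("  lengths: %d-%d residues\n", min(lens), max(lens)))
  invisible(x)
}

#' Class counts of a labeled dataset
#' @param dataset A [peptide_dataset()].
#' @return Integer count.
#' @export
n_pos <- function(dataset) sum(dataset$label == 1L, na.rm = TRUE)

#' @rdname n_pos
#' @export
n_neg <- function(dataset) sum(dataset$label == 0L, na.rm = TRUE)

#' Read peptide records from a FASTA file
#'
#' Multi-line sequences are concatenated, sequences are upper-cased (with a
#' warning, as a dialect tolerance) and validated against the 21-letter
#' alphabet; any character outside it is reported with the offending record
#' id.
#'
#' @param path Path to a plain FASTA file (`>`-headers; sequence lines may be
#'   wrapped).
#' @return An unlabeled [peptide_dataset()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path))
    stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L)
    stop("FASTA file contains no records: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  peptide_dataset(id = ids, sequence = as.character(set))
}

#' Write peptide records to a FASTA file
#'
#' Inverse of [read_fasta()]: `read_fasta(write_fasta(x, f))` reproduces `x`
#' up to the (unstored) labels.
#'
#' @param dataset A [peptide_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(dataset, path) {
  set <- Biostrings::BStringSet(dataset$sequence)
  names(set) <- dataset$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Load a labeled peptide dataset
#'
#' Binary ACP / non-ACP labels are not part of the FASTA format, so three
#' on-disk conventions are supported:
#' \describe{
#'   \item{`two-file`}{(default) positives and negatives in separate FASTA
#'     files — how the public benchmark repositories distribute their data.}
#'   \item{`header-token`}{one FASTA file; a header containing
#'     `positive_marker` (default `"ACP"`) without the token `"non"` is
#'     positive, a header containing `"non"` is negative.}
#'   \item{`sidecar-table`}{one FASTA file plus a two-column TSV
#'     (`id`, `label` in \{1, 0\}).}
#' }
#'
#' @param path FASTA file; for `two-file` the positive-class file.
#' @param label_convention One of `"two-file"`, `"header-token"`,
#'   `"sidecar-table"`.
#' @param negative_path Negative-class FASTA (`two-file` only).
#' @param labels_path Sidecar TSV path (`sidecar-table` only).
#' @param positive_marker Header substring marking positives
#'   (`header-token` only).
#' @return A fully labeled [peptide_dataset()].
#' @export
load_labeled_dataset <- function(path,
                                 label_convention = c("two-file", "header-token",
                                                      "sidecar-table"),
                                 negative_path = NULL,
                                 labels_path = NULL,
                                 positive_marker = "ACP") {
  label_convention <- match.arg(label_convention)
  switch(label_convention,
    "two-file" = {
      if (is.null(negative_path))
        stop("two-file convention requires `negative_path`", call. = FALSE)
      pos <- read_fasta(path)
      neg <- read_fasta(negative_path)
      peptide_dataset(id = c(pos$id, neg$id),
                      sequence = c(pos$sequence, neg$sequence),
                      label = c(rep(1L, nrow(pos)), rep(0L, nrow(neg))))
    },
    "header-token" = {
      x <- read_fasta(path)
      is_non <- grepl("non", x$id, ignore.case = TRUE)
      is_pos <- grepl(positive_marker, x$id, fixed = TRUE) & !is_non
      unmatched <- !is_pos & !is_non
      if (any(unmatched))
        stop("record(s) matching no labeling rule: ",
             paste(x$id[unmatched], collapse = ", "), call. = FALSE)
      x$label <- ifelse(is_pos, 1L, 0L)
      x
    },
    "sidecar-table" = {
      if (is.null(labels_path))
        stop("sidecar-table convention requires `labels_path`", call. = FALSE)
      x <- read_fasta(path)
      tab <- utils::read.table(labels_path, header = FALSE, sep = "\t",
                               col.names = c("id", "label"),
                               colClasses = c("character", "integer"))
      idx <- match(x$id, tab$id)
      if (anyNA(idx))
        stop("record(s) matching no labeling rule: ",
             paste(x$id[is.na(idx)], collapse = ", "), call. = FALSE)
      x$label <- tab$label[idx]
      x
    })
}

#' Write a labeled dataset as FASTA plus a sidecar label table
#'
#' @param dataset A labeled [peptide_dataset()].
#' @param fasta_path,labels_path Output paths.
#' @return `fasta_path`, invisibly.
#' @export
write_labeled_dataset <- function(dataset, fasta_path, labels_path) {
  write_fasta(dataset, fasta_path)
  utils::write.table(dataset[, c("id", "label")], labels_path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(fasta_path)
}
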