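#' Normalize peptides to a fixed length
#'
#' The per-position AAindex encoder requires equal-length inputs, so every
#' peptide is brought to exactly `l_x` residues: shorter sequences are padded
#' at the C-terminus with the letter `X`, longer ones are truncated to their
#' first `l_x` residues. Truncation keeps the N-terminus because the
#' positional features of this pipeline (binary profiles of the first seven
#' residues) are N-anchored. The operation is idempotent.
#'
#' @param sequence Character vector of peptide sequences.
#' @param l_x Target length in residues (the published sweep uses 40, 50
#'   or 60; any positive integer is accepted).
#' @return Character vector of sequences, each exactly `l_x` long.
#' @examples
#' normalize_length("FAKLL", 8)   # "FAKLLXXX"
#' @export
normalize_length <- function(sequence, l_x) {
  if (!is.numeric(l_x) || length(l_x) != 1L || is.na(l_x) || l_x < 1)
    stop("l_x must be a single integer >= 1", call. = FALSE)
  l_x <- as.integer(l_x)
  len <- nchar(sequence)
  pad <- vapply(pmax(l_x - len, 0L),
                function(n) strrep("X", n), character(1))
  substr(paste0(sequence, pad), 1L, l_x)
}

#' @rdname normalize_length
#' @param dataset A [peptide_dataset()]; sequences are normalized in place.
#' @export
normalize_dataset <- function(dataset, l_x) {
  dataset$sequence <- normalize_length(dataset$sequence, l_x)
  dataset
}

#' Peptide length distribution
#'
#' Tabulates sequence lengths, the statistic used to choose the target
#' length `l_x` (most benchmark peptides are shorter than 60 residues).
#'
#' @param dataset A [peptide_dataset()].
#' @return A data frame with columns `length` and `count`, sorted by length;
#'   counts sum to the number of records. Write with [utils::write.table()]
#'   for plotting.
#' @export
length_histogram <- function(dataset) {
  if (nrow(dataset) == 0L) stop("empty dataset", call. = FALSE)
  tab <- table(nchar(dataset$sequence))
  data.frame(length = as.integer(names(tab)),
             count = as.integer(tab))
}
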