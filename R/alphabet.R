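#' Amino-acid alphabets used throughout the package
#'
#' `aa_alphabet()` returns the 20 standard residues in the alphabetical order
#' used by the binary-profile encoder; `peptide_alphabet()` additionally
#' contains the padding letter `"X"`, which is a first-class alphabet member:
#' it is appended by [normalize_length()] and maps to all-zero features in
#' every encoder.
#'
#' @return Character vector of single-letter residue codes.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' @rdname aa_alphabet
#' @export
peptide_alphabet <- function() c(aa_alphabet(), "X")

# Split sequences into residue character matrices / lists.
seq_chars <- function(sequences) strsplit(sequences, "", fixed = TRUE)

validate_sequences <- function(sequences, ids) {
  ok <- peptide_alphabet()
  bad <- lapply(seq_chars(sequences), function(ch) unique(ch[!ch %in% ok]))
  hits <- which(lengths(bad) > 0L)
  if (length(hits) > 0L) {
    msgs <- vapply(hits, function(i) {
      sprintf("record '%s' contains illegal character(s): %s",
              ids[i], paste(bad[[i]], collapse = ", "))
    }, character(1))
    stop("invalid peptide sequence(s): ", paste(msgs, collapse = "; "),
         call. = FALSE)
  }
  invisible(TRUE)
}
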