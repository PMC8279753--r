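#' Physicochemical amino-acid index table
#'
#' Builds the per-residue physicochemical descriptor table from the AAindex-1
#' collection shipped with the \pkg{seqinr} package: the 531 indices with a
#' complete value for every standard residue (indices with gaps are dropped
#' at table-build time). Columns follow the binary-profile alphabet order
#' `A C D E F G H I K L M N P Q R S T V W Y`; row names are AAindex
#' accessions. Any other gap-free index-by-residue matrix with these column
#' names may be substituted wherever a `table` argument is accepted.
#'
#' @return Numeric matrix, 531 rows (indices) by 20 columns (residues), with
#'   no missing values.
#' @export
aaindex_table <- function() {
  cached <- .aaindex_cache$table
  if (!is.null(cached)) return(cached)
  env <- new.env()
  utils::data("aaindex", package = "seqinr", envir = env)
  aai <- env$aaindex
  three_to_one <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
                    Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
                    Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
                    Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")
  vals <- t(vapply(aai, function(e) e$I, numeric(20)))
  rownames(vals) <- vapply(aai, function(e) e$H, character(1))
  colnames(vals) <- three_to_one[colnames(vals)]
  vals <- vals[stats::complete.cases(vals), aa_alphabet(), drop = FALSE]
  stopifnot(!anyNA(vals))
  .aaindex_cache$table <- vals
  vals
}

.aaindex_cache <- new.env(parent = emptyenv())

validate_aaindex_table <- function(table) {
  if (!is.matrix(table) || !is.numeric(table))
    stop("AAindex table must be a numeric matrix", call. = FALSE)
  if (!identical(colnames(table), aa_alphabet()))
    stop("AAindex table columns must be the 20 residues in order ",
         paste(aa_alphabet(), collapse = ""), call. = FALSE)
  if (anyNA(table))
    stop("AAindex table must be gap-free", call. = FALSE)
  if (is.null(rownames(table)))
    rownames(table) <- sprintf("idx%d", seq_len(nrow(table)))
  table
}
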