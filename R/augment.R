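#' Configuration for feature-space noise-adding oversampling
#'
#' Pseudosamples are generated from training samples by the masked
#' multiplicative perturbation `F_new = F_i (1 + a V)` (elementwise), where
#' `V` is zero on the binary-profile block and uniform on `[0, 1)` on the
#' AAindex block. Binary features are 0/1 codes for which a perturbation is
#' meaningless, so they are copied unchanged; every AAindex entry moves away
#' from zero by a relative amount in `[0, a)`.
#'
#' @param a Perturbation coefficient (default 0.005, the published
#'   setting).
#' @param n_fraction Pseudosample count per class, as a fraction of that
#'   class's size (the published sweep uses 1, 2 or 3, i.e. 100–300%).
#' @param seed Optional integer seed making the augmentation
#'   bit-reproducible.
#' @return An `augmentation_config` list.
#' @export
augmentation_config <- function(a = 0.005, n_fraction = 1, seed = NULL) {
  if (!is.numeric(a) || length(a) != 1L || a < 0)
    stop("a must be a single non-negative number", call. = FALSE)
  if (!is.numeric(n_fraction) || length(n_fraction) != 1L || n_fraction < 0)
    stop("n_fraction must be a single non-negative number", call. = FALSE)
  structure(list(a = a, n_fraction = n_fraction, seed = seed),
            class = "augmentation_config")
}

#' Draw one perturbation vector
#'
#' The first `bpf_width` entries are exactly zero (the mask over binary
#' features); the remaining `aaindex_width` entries are i.i.d. uniform on
#' `[0, 1)`. Uses the current RNG state.
#'
#' @param bpf_width,aaindex_width Block widths (non-negative integers).
#' @return Numeric vector of length `bpf_width + aaindex_width`.
#' @export
make_perturbation_vector <- function(bpf_width, aaindex_width) {
  if (bpf_width < 0 || aaindex_width < 0)
    stop("block widths must be non-negative", call. = FALSE)
  c(numeric(bpf_width), stats::runif(aaindex_width))
}

round_half_up <- function(x) floor(x + 0.5)

#' Generate pseudosamples for one class
#'
#' Each pseudosample draws a source row uniformly with replacement and a
#' fresh perturbation vector, then applies
#' `F_new = F_i * (1 + a V)` elementwise. Only `aaindex`-tagged columns are
#' perturbed; `bpf` (and any `kmer`) columns are bit-identical copies of the
#' source row. The number of pseudosamples is
#' `round(n_fraction * nrow(x_class))` (half-up).
#'
#' @param x_class Numeric matrix of one class's feature rows (row names =
#'   sample ids).
#' @param config An [augmentation_config()].
#' @param block_tags Character vector tagging each column (`"bpf"`,
#'   `"aaindex"`, `"kmer"`).
#' @return List with `x` (pseudosample matrix) and `source` (source sample
#'   id per pseudosample). Uses the current RNG state; seed handling lives
#'   in [augment_training_set()].
#' @export
augment_class <- function(x_class, config, block_tags) {
  if (nrow(x_class) == 0L)
    stop("cannot augment an empty class", call. = FALSE)
  if (length(block_tags) != ncol(x_class))
    stop("block_tags must tag every column", call. = FALSE)
  if (!all(block_tags %in% c("bpf", "aaindex", "kmer")))
    stop("unknown block tag(s): ",
         paste(setdiff(block_tags, c("bpf", "aaindex", "kmer")),
               collapse = ", "), call. = FALSE)
  n_new <- round_half_up(config$n_fraction * nrow(x_class))
  perturb <- block_tags == "aaindex"
  out <- matrix(0, nrow = n_new, ncol = ncol(x_class),
                dimnames = list(NULL, colnames(x_class)))
  src <- character(n_new)
  for (r in seq_len(n_new)) {
    i <- sample.int(nrow(x_class), 1L)
    v <- numeric(ncol(x_class))
    v[perturb] <- stats::runif(sum(perturb))
    out[r, ] <- x_class[i, ] * (1 + config$a * v)
    src[r] <- rownames(x_class)[i]
  }
  list(x = out, source = src)
}

#' Augment a labeled training feature matrix
#'
#' Positives and negatives are augmented independently with the same
#' configuration, so applying the same `n_fraction` to both preserves the
#' class ratio. The result holds the original rows followed by the
#' pseudosamples; pseudosamples carry their class label and the id of their
#' source row in the `source` field (`"-"` marks originals). Apply this to
#' training folds only, after feature selection — the perturbation operates
#' on the selected representation.
#'
#' @param fm A labeled [feature_matrix()].
#' @param config An [augmentation_config()]; its `seed`, when non-NULL,
#'   makes the output bit-reproducible.
#' @return A [feature_matrix()] with `nrow + 2 * round(n_fraction * class
#'   sizes)` rows.
#' @export
augment_training_set <- function(fm, config = augmentation_config()) {
  if (is.null(fm$labels))
    stop("augmentation requires a labeled feature matrix", call. = FALSE)
  if (config$n_fraction == 0) return(fm)
  if (!is.null(config$seed)) set.seed(config$seed)
  parts <- lapply(c(1L, 0L), function(cl) {
    rows <- which(fm$labels == cl)
    aug <- augment_class(fm$x[rows, , drop = FALSE], config, fm$blocks)
    aug$label <- rep(cl, nrow(aug$x))
    aug
  })
  new_x <- rbind(fm$x, parts[[1]]$x, parts[[2]]$x)
  n_new <- nrow(parts[[1]]$x) + nrow(parts[[2]]$x)
  rownames(new_x) <- c(rownames(fm$x),
                       sprintf("pseudo_%d", seq_len(n_new)))
  feature_matrix(new_x, fm$blocks,
                 labels = c(fm$labels, parts[[1]]$label, parts[[2]]$label),
                 source = c(fm$source, parts[[1]]$source, parts[[2]]$source))
}
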