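#' Mutual information between a discretized feature and binary labels
#'
#' Plug-in estimator from the empirical joint distribution, in nats. Zero
#' for in-sample independent variables (in particular for any constant
#' feature) and symmetric in its arguments.
#'
#' @param x Integer vector of discretized feature values (any finite number
#'   of levels; see [discretize_columns()]).
#' @param y Integer vector of the same length; for label use, 0/1.
#' @return Non-negative mutual information in nats.
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("x and y must have equal length >= 2", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("degenerate labels: y is constant", call. = FALSE)
  counts <- table(x, y)
  mi_from_counts(counts)
}

mi_from_counts <- function(counts) {
  n <- sum(counts)
  p <- counts / n
  px <- rowSums(p)
  py <- colSums(p)
  terms <- p * log(p / outer(px, py))
  sum(terms[p > 0])
}

#' Discretize feature columns into three bins at mean +/- sd
#'
#' Standard mRMR discretization: per feature, values below `mu - sigma` fall
#' in bin 1, above `mu + sigma` in bin 3, the rest in bin 2. Constant
#' features land entirely in bin 2 (and thus carry zero mutual
#' information).
#'
#' @param x Numeric matrix (samples x features).
#' @param edges Optional list with `lo`/`hi` per-feature cut points, e.g.
#'   from a previous call (attribute `edges`); computed from `x` otherwise.
#' @return Integer matrix of bin codes in \{1, 2, 3\} with attribute
#'   `edges`.
#' @export
discretize_columns <- function(x, edges = NULL) {
  if (is.null(edges)) {
    mu <- colMeans(x)
    sdev <- sqrt(pmax(colMeans(x^2) - mu^2, 0) * nrow(x) / max(nrow(x) - 1L, 1L))
    edges <- list(lo = mu - sdev, hi = mu + sdev)
  }
  d <- 2L + (x > rep(edges$hi, each = nrow(x))) -
    (x < rep(edges$lo, each = nrow(x)))
  storage.mode(d) <- "integer"
  dimnames(d) <- dimnames(x)
  attr(d, "edges") <- edges
  d
}

# MI of every column of D (bins 1..3) against one indicator matrix Z
# (n x levels). Three crossprod calls give all joint counts at once, so the
# greedy search stays tractable at 21,240 candidate features.
mi_all_columns <- function(D, Z) {
  n <- nrow(D)
  counts <- lapply(1:3, function(b) crossprod((D == b) * 1, Z))  # F x levels
  pz <- colSums(Z) / n
  mi <- numeric(ncol(D))
  for (b in 1:3) {
    pb <- counts[[b]] / n                       # F x levels
    pxb <- rowSums(pb)
    for (l in seq_along(pz)) {
      p <- pb[, l]
      term <- p * log(p / (pxb * pz[l]))
      term[!is.finite(term)] <- 0
      mi <- mi + term
    }
  }
  pmax(mi, 0)
}

indicator <- function(v, levels) {
  Z <- matrix(0, nrow = length(v), ncol = length(levels))
  Z[cbind(seq_along(v), match(v, levels))] <- 1
  Z
}

#' Fit a minimum-redundancy maximum-relevance feature selection
#'
#' Greedy forward selection over the AAindex block: the first feature
#' maximizes relevance `MI(x; y)`; each subsequent feature maximizes the
#' MID (difference) criterion `MI(x; y) - mean(MI(x; s))` over the already
#' selected set `s`. Features are discretized into three bins at
#' `mu +/- sigma` (labels are already binary); ties are broken toward the
#' lowest column index, making the selection fully deterministic. Fit this
#' on training data only — [run_cv()] refits it inside every fold.
#'
#' @param x A [feature_matrix()] (its `aaindex` block is used) or a plain
#'   numeric matrix.
#' @param y Binary labels (taken from `x$labels` when `x` is a
#'   [feature_matrix()]).
#' @param m Number of features to select (default 50).
#' @param scheme `"MID"` (difference, default) or `"MIQ"` (quotient).
#' @return A `selection_model`: selected names in pick order, bin edges,
#'   scheme, and a fingerprint of the training sample ids.
#' @export
fit_mrmr <- function(x, y = NULL, m = 50, scheme = c("MID", "MIQ")) {
  scheme <- match.arg(scheme)
  if (inherits(x, "feature_matrix")) {
    if (is.null(y)) y <- x$labels
    ids <- rownames(x$x)
    x <- fm_block(x, "aaindex")
  } else {
    ids <- rownames(x)
  }
  if (is.null(y)) stop("labels are required to fit mRMR", call. = FALSE)
  if (m > ncol(x))
    stop(sprintf("m = %d exceeds the %d available features", m, ncol(x)),
         call. = FALSE)
  if (min(table(y)) < 2L)
    stop("need at least 2 samples per class", call. = FALSE)
  D <- discretize_columns(x)
  Y <- indicator(y, sort(unique(y)))
  relevance <- mi_all_columns(D, Y)
  p <- ncol(x)
  selected <- integer(m)
  redundancy_sum <- numeric(p)
  available <- rep(TRUE, p)
  for (step in seq_len(m)) {
    score <- if (step == 1L) {
      relevance
    } else if (scheme == "MID") {
      relevance - redundancy_sum / (step - 1L)
    } else {
      relevance / pmax(redundancy_sum / (step - 1L), .Machine$double.eps)
    }
    score[!available] <- -Inf
    # ties broken toward the lowest feature index; the tolerance guards the
    # deterministic tie-break against float noise in equivalent MI sums
    pick <- which(score >= max(score) - 1e-9)[1]
    selected[step] <- pick
    available[pick] <- FALSE
    if (step < m) {
      Zs <- indicator(D[, pick], 1:3)
      redundancy_sum <- redundancy_sum + mi_all_columns(D, Zs)
    }
  }
  edges <- attr(D, "edges")
  structure(list(selected_names = colnames(x)[selected],
                 m = m,
                 scheme = scheme,
                 discretization = list(lo = edges$lo[selected],
                                       hi = edges$hi[selected]),
                 fit_fingerprint = fingerprint(ids)),
            class = "selection_model")
}

#' @export
print.selection_model <- function(x, ...) {
  cat(sprintf("selection_model: %d features (%s scheme), fingerprint %s\n",
              x$m, x$scheme, x$fit_fingerprint))
  cat("  first picks:", paste(utils::head(x$selected_names, 5), collapse = ", "),
      "\n")
  invisible(x)
}

# polynomial rolling hash over the concatenated sample ids; ties a selection
# to the training set it was fitted on
fingerprint <- function(ids) {
  if (is.null(ids)) return("unkeyed")
  bytes <- utf8ToInt(paste(ids, collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Serialize a selection model to JSON
#'
#' Stores the selected names (in pick order), `m`, the scheme, the
#' per-feature discretization edges and the training-set fingerprint, so a
#' fitted selection can be applied across sessions.
#'
#' @param model A `selection_model` from [fit_mrmr()].
#' @param path JSON file path.
#' @return `path` (write) or a `selection_model` (read).
#' @export
write_selection_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_selection_model
#' @export
read_selection_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$m <- as.integer(raw$m)
  structure(raw, class = "selection_model")
}

#' Project a feature matrix onto a fitted selection
#'
#' Reduces the `aaindex` block to the selected columns in model order,
#' leaving `bpf` and `kmer` blocks untouched. Selection indexes raw feature
#' values — the discretization used during fitting is not applied.
#' Idempotent: re-applying the same model is a no-op.
#'
#' @param fm A [feature_matrix()] containing every selected feature.
#' @param model A `selection_model` from [fit_mrmr()].
#' @return A [feature_matrix()].
#' @export
apply_selection <- function(fm, model) {
  missing_names <- setdiff(model$selected_names, colnames(fm$x))
  if (length(missing_names) > 0L)
    stop(sprintf("feature matrix lacks %d selected feature(s) (model fingerprint %s): %s",
                 length(missing_names), model$fit_fingerprint,
                 paste(utils::head(missing_names, 3), collapse = ", ")),
         call. = FALSE)
  keep_other <- which(fm$blocks != "aaindex")
  sel <- match(model$selected_names, colnames(fm$x))
  # preserve the fixed block order bpf | aaindex | kmer
  before <- keep_other[fm$blocks[keep_other] == "bpf"]
  after <- keep_other[fm$blocks[keep_other] == "kmer"]
  cols <- c(before, sel, after)
  fm_subset(fm, cols = cols)
}
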