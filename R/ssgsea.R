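#' Single-sample gene-set enrichment score (ssGSEA)
#'
#' Rank-based per-sample enrichment: genes are ranked by expression (average
#' ranks for ties) and walked in descending order; the score is the sum over
#' positions of the difference between the weighted in-set empirical CDF and
#' the unweighted out-set ECDF. In-set weights are `|z|^alpha` where `z` is
#' the centered rank statistic `rank - (n + 1) / 2`, so the score depends on
#' the expression column only through its ranks and is antisymmetric under
#' swapping the in-set and out-set on a rank-symmetric profile.
#'
#' @param expr_column Named numeric vector: one sample's expression over all
#'   genes (log2 scale; only ranks matter). No missing values.
#' @param gene_set Character vector of gene symbols; intersected with the
#'   names of `expr_column`.
#' @param alpha Rank weighting exponent (default 0.25).
#' @return A single numeric score, or `NA` with a warning when no set gene is
#'   present in the expression rows.
#' @export
ssgsea_sample <- function(expr_column, gene_set, alpha = 0.25) {
  stopifnot(!is.null(names(expr_column)))
  if (anyNA(expr_column)) {
    stop("missing values in expression are not allowed", call. = FALSE)
  }
  n <- length(expr_column)
  in_set <- names(expr_column) %in% gene_set
  m <- sum(in_set)
  if (m == 0L) {
    warning("no overlap between gene set and expression rows", call. = FALSE)
    return(NA_real_)
  }
  r <- rank(expr_column, ties.method = "average")
  z <- r - (n + 1) / 2
  ord <- order(-r, names(expr_column))
  in_ord <- in_set[ord]
  w <- abs(z[ord])^alpha
  wi <- w * in_ord
  wsum <- sum(wi)
  if (wsum == 0) { # every in-set gene sits exactly at the median rank
    wi <- as.numeric(in_ord)
    wsum <- m
  }
  p_in <- cumsum(wi) / wsum
  p_out <- if (n > m) cumsum(!in_ord) / (n - m) else rep(0, n)
  sum(p_in - p_out)
}

#' Score a cohort on a gene-set collection
#'
#' Computes [ssgsea_sample()] for every sample and every set. With
#' `normalize = TRUE` all scores are divided by the global range
#' (max - min) across the whole matrix, the common single-sample
#' normalization; rank order within and across features is unchanged.
#'
#' @param expr Numeric genes x samples matrix (log2 scale) with unique
#'   rownames and colnames; no missing values.
#' @param sets A `tcms_registry` or a named list of gene vectors.
#' @param alpha Rank weighting exponent.
#' @param normalize Apply global range normalization.
#' @return Samples x features numeric matrix of class `tcms_scores`, with a
#'   `normalization` attribute (`"raw"` or `"range-normalized"`).
#' @export
score_matrix <- function(expr, sets, alpha = 0.25, normalize = FALSE) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  if (anyDuplicated(rownames(expr))) {
    stop("duplicate gene identifiers; resolve duplicates upstream",
         call. = FALSE)
  }
  if (anyNA(expr)) {
    stop("missing values in expression are not allowed", call. = FALSE)
  }
  if (inherits(sets, "tcms_registry")) sets <- registry_gene_sets(sets)
  if (length(sets) == 0L) stop("empty gene-set collection", call. = FALSE)
  stopifnot(!is.null(names(sets)))

  n <- nrow(expr)
  genes <- rownames(expr)
  membership <- vapply(sets, function(s) genes %in% s, logical(n))
  overlap <- colSums(membership)
  if (any(overlap == 0L)) {
    warning("gene sets with no overlap: ",
            paste(names(sets)[overlap == 0L], collapse = ", "), call. = FALSE)
  }
  out <- matrix(NA_real_, ncol(expr), length(sets),
                dimnames = list(colnames(expr), names(sets)))
  for (j in seq_len(ncol(expr))) {
    v <- expr[, j]
    r <- rank(v, ties.method = "average")
    z <- r - (n + 1) / 2
    ord <- order(-r, genes)
    w <- abs(z[ord])^alpha
    for (s in seq_along(sets)) {
      m <- overlap[s]
      if (m == 0L) next
      in_ord <- membership[ord, s]
      wi <- w * in_ord
      wsum <- sum(wi)
      if (wsum == 0) {
        wi <- as.numeric(in_ord)
        wsum <- m
      }
      p_in <- cumsum(wi) / wsum
      p_out <- if (n > m) cumsum(!in_ord) / (n - m) else rep(0, n)
      out[j, s] <- sum(p_in - p_out)
    }
  }
  tag <- "raw"
  if (normalize) {
    rng <- range(out, na.rm = TRUE)
    span <- rng[2] - rng[1]
    if (span > 0) out <- out / span
    tag <- "range-normalized"
  }
  structure(out, class = c("tcms_scores", "matrix", "array"),
            normalization = tag)
}

#' Z-score the feature columns of a score matrix
#'
#' Standardizes each feature to mean 0 and SD 1 across samples, the default
#' pre-clustering transformation. Constant features become all-zero columns
#' with a warning.
#'
#' @param scores Samples x features matrix (e.g. from [score_matrix()]).
#' @return Matrix of the same shape, `normalization` attribute `"z-scored"`.
#' @export
zscale_features <- function(scores) {
  stopifnot(is.matrix(scores), nrow(scores) >= 2)
  mu <- colMeans(scores)
  sdv <- apply(scores, 2, stats::sd)
  const <- sdv == 0
  if (any(const)) {
    warning("constant feature(s) set to zero: ",
            paste(colnames(scores)[const], collapse = ", "), call. = FALSE)
    sdv[const] <- 1
  }
  z <- sweep(sweep(scores, 2, mu, "-"), 2, sdv, "/")
  structure(z, class = c("tcms_scores", "matrix", "array"),
            normalization = "z-scored")
}
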