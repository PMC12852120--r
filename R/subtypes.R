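#' Map k=4 consensus clusters to the LPI/IMD/IME/HPI subtypes
#'
#' The four subtypes are anchored biologically on the per-cluster mean
#' z-scores of three feature groups:
#' \describe{
#'   \item{aggression}{mean of solid/micropapillary, metastasis, tumor
#'     proliferation rate, and matrix remodeling — highest in HPI.}
#'   \item{indolence}{the GGO/lepidic score — highest in LPI among the
#'     non-HPI clusters.}
#'   \item{immunity}{mean of CD8 T cells, NK cells, and B cells — separates
#'     the remaining two clusters into IME (higher) and IMD (lower).}
#' }
#' An exact tie in any argmax stops with an error demanding a manual mapping;
#' ties are never broken silently.
#'
#' @param run A `tcms_consensus` containing a k=4 solution, or an integer
#'   cluster vector named by sample.
#' @param scores Z-scored samples x features score matrix with the canonical
#'   TCMS feature names.
#' @param k Number of clusters (must be 4).
#' @return Object of class `tcms_subtypes`: `labels` (factor LPI/IMD/IME/HPI
#'   named by sample), `cluster_map` (cluster id -> subtype), and
#'   `cluster_means` (clusters x features mean z-scores).
#' @export
label_subtypes <- function(run, scores, k = 4) {
  stopifnot(k == 4, is.matrix(scores))
  cl <- if (inherits(run, "tcms_consensus")) {
    if (!"4" %in% names(run$labels)) {
      stop("consensus run has no k=4 solution", call. = FALSE)
    }
    run$labels[["4"]]
  } else {
    run
  }
  if (length(cl) != nrow(scores)) {
    stop("cluster labels and score rows differ in length", call. = FALSE)
  }
  if (length(unique(cl)) != 4L) {
    stop("expected exactly 4 clusters, got ", length(unique(cl)),
         call. = FALSE)
  }
  need <- c("solid_micropapillary", "metastasis", "Tumor_proliferation",
            "Matrix_remodeling", "GGO_lepidic", "CD8_T_cells", "NK_cells",
            "B_cells")
  miss <- setdiff(need, colnames(scores))
  if (length(miss) > 0L) {
    stop("score matrix lacks features: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cl_ids <- sort(unique(cl))
  cm <- t(vapply(cl_ids, function(g) colMeans(scores[cl == g, , drop = FALSE]),
                 numeric(ncol(scores))))
  rownames(cm) <- as.character(cl_ids)
  colnames(cm) <- colnames(scores)

  aggression <- rowMeans(cm[, c("solid_micropapillary", "metastasis",
                                "Tumor_proliferation", "Matrix_remodeling")])
  indolence <- cm[, "GGO_lepidic"]
  immunity <- rowMeans(cm[, c("CD8_T_cells", "NK_cells", "B_cells")])

  argmax_strict <- function(x, what) {
    top <- which(x == max(x))
    if (length(top) > 1L) {
      stop("exact tie in ", what,
           " between clusters; manual cluster -> subtype mapping required",
           call. = FALSE)
    }
    top
  }
  map <- character(4)
  names(map) <- as.character(cl_ids)
  i_hpi <- argmax_strict(aggression, "aggression score")
  map[i_hpi] <- "HPI"
  rest <- setdiff(seq_len(4), i_hpi)
  i_lpi <- rest[argmax_strict(indolence[rest], "indolence score")]
  map[i_lpi] <- "LPI"
  last2 <- setdiff(rest, i_lpi)
  if (immunity[last2[1]] == immunity[last2[2]]) {
    stop("exact tie in immunity score between clusters; ",
         "manual cluster -> subtype mapping required", call. = FALSE)
  }
  i_ime <- last2[which.max(immunity[last2])]
  map[i_ime] <- "IME"
  map[setdiff(last2, i_ime)] <- "IMD"

  labels <- factor(map[as.character(cl)], levels = tcms_subtype_levels())
  names(labels) <- names(cl)
  structure(list(labels = labels, cluster_map = map, cluster_means = cm),
            class = "tcms_subtypes")
}

#' @return Character vector of the four subtype labels in canonical order.
#' @rdname label_subtypes
#' @export
tcms_subtype_levels <- function() c("LPI", "IMD", "IME", "HPI")

#' @export
print.tcms_subtypes <- function(x, ...) {
  cat("<tcms_subtypes>\n")
  print(table(x$labels))
  invisible(x)
}

#' Subtype centroids and nearest-centroid classification
#'
#' `fit_centroids()` computes the per-subtype mean z-score profile over the
#' training cohort. `classify_external()` scores a new cohort on the same
#' registry, matches features by name, and assigns each sample the subtype of
#' its nearest centroid (default: highest Spearman correlation; Euclidean
#' distance optional), reporting the margin between the best and second-best
#' centroid.
#'
#' @param assignment A `tcms_subtypes` (or factor of subtype labels).
#' @param scores Z-scored samples x features matrix used for training.
#' @return `fit_centroids()`: object of class `tcms_centroids` — a 4 x
#'   features matrix plus feature names.
#' @export
fit_centroids <- function(assignment, scores) {
  labels <- if (inherits(assignment, "tcms_subtypes")) {
    assignment$labels
  } else {
    assignment
  }
  stopifnot(is.matrix(scores), length(labels) == nrow(scores))
  lv <- tcms_subtype_levels()
  cen <- t(vapply(lv, function(s) {
    colMeans(scores[labels == s, , drop = FALSE])
  }, numeric(ncol(scores))))
  colnames(cen) <- colnames(scores)
  structure(list(centroids = cen, features = colnames(scores)),
            class = "tcms_centroids")
}

#' @rdname fit_centroids
#' @param new_scores Z-scored samples x features matrix for the new cohort.
#' @param centroids A `tcms_centroids`.
#' @param metric `"spearman"` (default) or `"euclidean"`.
#' @return `classify_external()`: data frame with `sample`, `subtype`,
#'   `margin` (best minus second-best affinity).
#' @export
classify_external <- function(new_scores, centroids,
                              metric = c("spearman", "euclidean")) {
  metric <- match.arg(metric)
  stopifnot(inherits(centroids, "tcms_centroids"), is.matrix(new_scores))
  miss <- setdiff(centroids$features, colnames(new_scores))
  if (length(miss) > 0L) {
    stop("new cohort lacks features: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x <- new_scores[, centroids$features, drop = FALSE]
  cen <- centroids$centroids
  lv <- rownames(cen)
  aff <- matrix(NA_real_, nrow(x), length(lv), dimnames = list(rownames(x), lv))
  for (s in lv) {
    aff[, s] <- if (metric == "spearman") {
      apply(x, 1, function(v) stats::cor(v, cen[s, ], method = "spearman"))
    } else {
      -sqrt(rowSums(sweep(x, 2, cen[s, ])^2))
    }
  }
  best <- apply(aff, 1, function(a) {
    top <- which(a == max(a))
    if (length(top) > 1L) {
      warning("centroid affinity tie; using canonical subtype order",
              call. = FALSE)
      top <- top[1]
    }
    top
  })
  margin <- apply(aff, 1, function(a) {
    s <- sort(a, decreasing = TRUE)
    s[1] - s[2]
  })
  data.frame(sample = rownames(x), subtype = factor(lv[best], levels = lv),
             margin = margin, row.names = NULL, stringsAsFactors = FALSE)
}
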