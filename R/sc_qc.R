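#' Single-cell QC thresholds
#'
#' Defaults follow the standard scRNA-seq filtering recipe: keep genes
#' expressed in at least 3 cells, cells expressing at least 200 genes, cells
#' with mitochondrial count fraction at most 5%, and cells with strictly
#' fewer than 2500 detected genes (doublet guard).
#'
#' @param min_cells_per_gene,min_genes_per_cell,max_mito_fraction,max_genes_per_cell
#'   Threshold values; all must be positive.
#' @return A list of class `tcms_sc_thresholds`.
#' @export
sc_qc_thresholds <- function(min_cells_per_gene = 3,
                             min_genes_per_cell = 200,
                             max_mito_fraction = 0.05,
                             max_genes_per_cell = 2500) {
  stopifnot(min_cells_per_gene > 0, min_genes_per_cell > 0,
            max_mito_fraction > 0, max_genes_per_cell > 0)
  structure(list(min_cells_per_gene = min_cells_per_gene,
                 min_genes_per_cell = min_genes_per_cell,
                 max_mito_fraction = max_mito_fraction,
                 max_genes_per_cell = max_genes_per_cell),
            class = "tcms_sc_thresholds")
}

#' Filter a single-cell count matrix
#'
#' Applies, in order: (1) gene filter — genes expressed (count > 0) in at
#' least `min_cells_per_gene` cells; (2) cell filter — cells expressing at
#' least `min_genes_per_cell` of the retained genes; (3) mitochondrial
#' filter — cells whose mitochondrial count fraction exceeds
#' `max_mito_fraction` are removed; (4) upper filter — cells are retained only
#' with detected-gene count strictly below `max_genes_per_cell`.
#'
#' @param counts Nonnegative integer cells x genes matrix with dimnames.
#' @param mito_genes Character vector of mitochondrial gene names.
#' @param thresholds A [sc_qc_thresholds()].
#' @return List with `counts` (the filtered matrix, possibly 0-row/0-column),
#'   and `removed`, a named integer vector of cells/genes removed per step.
#' @export
qc_filter_cells <- function(counts, mito_genes = character(0),
                            thresholds = sc_qc_thresholds()) {
  stopifnot(is.matrix(counts))
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  removed <- c(genes_low_cells = 0L, cells_low_genes = 0L,
               cells_high_mito = 0L, cells_high_genes = 0L)

  keep_g <- colSums(counts > 0) >= thresholds$min_cells_per_gene
  removed["genes_low_cells"] <- sum(!keep_g)
  counts <- counts[, keep_g, drop = FALSE]

  det <- rowSums(counts > 0)
  keep_c <- det >= thresholds$min_genes_per_cell
  removed["cells_low_genes"] <- sum(!keep_c)
  counts <- counts[keep_c, , drop = FALSE]

  mito <- intersect(mito_genes, colnames(counts))
  tot <- rowSums(counts)
  mfrac <- if (length(mito) > 0L) {
    rowSums(counts[, mito, drop = FALSE]) / pmax(tot, 1)
  } else {
    rep(0, nrow(counts))
  }
  keep_c <- mfrac <= thresholds$max_mito_fraction
  removed["cells_high_mito"] <- sum(!keep_c)
  counts <- counts[keep_c, , drop = FALSE]

  det <- rowSums(counts > 0)
  keep_c <- det < thresholds$max_genes_per_cell
  removed["cells_high_genes"] <- sum(!keep_c)
  counts <- counts[keep_c, , drop = FALSE]

  list(counts = counts, removed = removed)
}
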