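#' Two-group differential expression on log2 expression
#'
#' Per-gene log2 fold change is `mean(A) - mean(B)` on the log2 scale, with a
#' two-sided test per gene and Benjamini-Hochberg adjustment over all tested
#' genes. The default test is Welch's t on the log2 values; `method =
#' "moderated"` fits the limma moderated linear model instead (same contrast,
#' empirical-Bayes variance shrinkage).
#'
#' Degenerate genes are handled explicitly: a gene with zero variance in both
#' groups gets p = 1 when the group means are equal and p = 0 otherwise
#' (never NaN).
#'
#' @param expr Numeric genes x samples matrix on log2 scale, with rownames
#'   (genes) and colnames (samples). Missing values are not allowed.
#' @param group_a,group_b Disjoint character vectors of sample ids, each with
#'   at least 2 samples.
#' @param method `"welch"` (default) or `"moderated"` (requires limma).
#' @return Data frame with one row per gene: `gene`, `log2fc`, `mean_a`,
#'   `mean_b`, `p`, `p_adj`.
#' @export
differential_expression <- function(expr, group_a, group_b,
                                    method = c("welch", "moderated")) {
  method <- match.arg(method)
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  if (anyNA(expr)) stop("expression matrix contains missing values", call. = FALSE)
  group_a <- as.character(group_a)
  group_b <- as.character(group_b)
  if (length(intersect(group_a, group_b)) > 0L) {
    stop("groups must be disjoint", call. = FALSE)
  }
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs >= 2 samples", call. = FALSE)
  }
  miss <- setdiff(c(group_a, group_b), colnames(expr))
  if (length(miss) > 0L) {
    stop("samples not in matrix: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  a <- expr[, group_a, drop = FALSE]
  b <- expr[, group_b, drop = FALSE]
  ma <- rowMeans(a)
  mb <- rowMeans(b)
  lfc <- ma - mb

  if (method == "welch") {
    na <- ncol(a); nb <- ncol(b)
    va <- apply(a, 1, stats::var)
    vb <- apply(b, 1, stats::var)
    se2 <- va / na + vb / nb
    tstat <- lfc / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
    zero <- se2 == 0
    if (any(zero)) p[zero] <- ifelse(lfc[zero] == 0, 1, 0)
    p[is.na(p)] <- 1
  } else {
    if (!requireNamespace("limma", quietly = TRUE)) {
      stop("method 'moderated' requires the limma package", call. = FALSE)
    }
    g <- factor(rep(c("A", "B"), c(ncol(a), ncol(b))), levels = c("B", "A"))
    design <- stats::model.matrix(~g)
    fit <- limma::eBayes(limma::lmFit(cbind(a, b), design))
    p <- fit$p.value[, 2]
    p[is.na(p)] <- 1
  }
  data.frame(
    gene = rownames(expr),
    log2fc = unname(lfc),
    mean_a = unname(ma),
    mean_b = unname(mb),
    p = unname(p),
    p_adj = stats::p.adjust(unname(p), method = "BH"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Derive a DE-based gene signature
#'
#' Selects genes with `log2fc >= lfc_min` and (raw or BH-adjusted) p below
#' `p_max`, removes any gene on the exclusion list, and orders by descending
#' log2 fold change (ties broken by gene symbol). This is the construction
#' used for the clinico-pathological signatures: raw p for GGO/lepidic and
#' metastasis, adjusted p for solid/micropapillary with a curated exclusion
#' list (e.g. histone genes).
#'
#' @param result Data frame from [differential_expression()].
#' @param name Name for the resulting signature.
#' @param lfc_min Minimum log2 fold change (default 1).
#' @param p_max p-value threshold (default 0.05, strict `<`).
#' @param use_adjusted Use `p_adj` instead of raw `p`.
#' @param exclusion_list Genes removed after thresholding.
#' @param category Signature category.
#' @return A [gene_signature()]; an empty selection returns `NULL` with a
#'   warning rather than an error.
#' @export
derive_de_signature <- function(result, name, lfc_min = 1, p_max = 0.05,
                                use_adjusted = FALSE,
                                exclusion_list = character(0),
                                category = "clinical") {
  pv <- if (use_adjusted) result$p_adj else result$p
  pass <- result$log2fc >= lfc_min & pv < p_max
  genes <- result$gene[pass]
  genes <- setdiff(genes, exclusion_list)
  if (length(genes) == 0L) {
    warning("no genes pass the filters for signature '", name, "'",
            call. = FALSE)
    return(NULL)
  }
  lfc <- result$log2fc[match(genes, result$gene)]
  genes <- genes[order(-lfc, genes)]
  gene_signature(name, genes, category)
}
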