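read_tsv_checked <- function(path, required, what) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(x))
  if (length(miss) > 0) {
    stop(what, " table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x
}

#' Read the plain-text cohort tables
#'
#' Lightweight readers for the TSV formats the package writes and consumes:
#' a MAF-like mutation table (`sample`, `gene`, `protein_change`, `exon`,
#' `variant_class`), a fusion table (`sample`, `gene_a`, `gene_b`), a
#' clinical table (`sample`, endpoint time/event columns, `stage`,
#' `relapse`, `adjuvant`), a genes x samples expression or thresholded CNV
#' matrix with rownames in the first column, and a 32-row SV catalog in
#' canonical category order.
#'
#' @param path File path.
#' @return A data frame (tables) or numeric matrix (matrices).
#' @export
read_mutations_tsv <- function(path) {
  x <- read_tsv_checked(path, c("sample", "gene", "protein_change",
                                "exon", "variant_class"), "mutation")
  x$exon <- as.integer(x$exon)
  x
}

#' @rdname read_mutations_tsv
#' @export
read_fusions_tsv <- function(path) {
  read_tsv_checked(path, c("sample", "gene_a", "gene_b"), "fusion")
}

#' @rdname read_mutations_tsv
#' @export
read_clinical_tsv <- function(path) {
  read_tsv_checked(path, "sample", "clinical")
}

#' @rdname read_mutations_tsv
#' @export
read_matrix_tsv <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                         check.names = FALSE)
  as.matrix(x)
}

#' @rdname read_mutations_tsv
#' @export
read_cnv_tsv <- function(path) {
  m <- read_matrix_tsv(path)
  if (!all(m %in% -2:2)) {
    stop("CNV values must be integers in -2..2", call. = FALSE)
  }
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_mutations_tsv
#' @export
read_sv_catalog_tsv <- function(path) {
  m <- read_matrix_tsv(path)
  if (nrow(m) != 32) {
    stop("SV catalog must have 32 rows in canonical category order",
         call. = FALSE)
  }
  if (!identical(rownames(m), sv_category_names())) {
    stop("SV catalog rownames must be the canonical category names",
         call. = FALSE)
  }
  m
}

#' @rdname read_mutations_tsv
#' @param x Matrix to write.
#' @export
write_matrix_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = TRUE,
                     col.names = NA)
  invisible(path)
}
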