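#' Canonical TCMS feature names
#'
#' The 20 features of the Tumor Characteristics and Microenvironment Score
#' (TCMS): three clinico-pathological expression signatures (ground-glass
#' opacity / lepidic growth, solid/micropapillary growth, metastasis) and 17
#' tumor-microenvironment signatures (nine consensus-voted immune/stromal cell
#' types, three literature-voted cell types, four single-source features, and
#' an EMT signature voted across the EMT literature).
#'
#' @return Character vector of length 20, the canonical feature names.
#' @export
tcms_feature_names <- function() {
  c(
    "GGO_lepidic", "solid_micropapillary", "metastasis",
    "CD8_T_cells", "CD4_T_cells", "B_cells", "Tregs", "NK_cells",
    "Macrophages", "CAFs", "Endothelial_cells", "Neutrophils",
    "T_helper_cells", "M1_macrophages", "Dendritic_cells",
    "Myeloid_cells", "Tumor_proliferation", "Matrix_remodeling",
    "Angiogenesis", "EMT"
  )
}

#' @return Named character vector mapping each TCMS feature to its category:
#'   `clinical`, `tme_cell`, or `tme_process`.
#' @rdname tcms_feature_names
#' @export
tcms_feature_categories <- function() {
  nm <- tcms_feature_names()
  cat <- c(
    rep("clinical", 3),
    rep("tme_cell", 9),
    rep("tme_cell", 3),
    "tme_cell", "tme_process", "tme_process",
    "tme_process", "tme_process"
  )
  stats::setNames(cat, nm)
}

#' Construct a gene signature
#'
#' @param name Feature label.
#' @param genes Character vector of gene symbols; made unique, order kept.
#' @param category One of `"clinical"`, `"tme_cell"`, `"tme_process"`.
#' @param provenance Optional data frame recording, per gene, the sources that
#'   contributed it (as produced by [vote_markers()]).
#' @return An object of class `tcms_signature`.
#' @export
gene_signature <- function(name, genes,
                           category = c("clinical", "tme_cell", "tme_process"),
                           provenance = NULL) {
  category <- match.arg(category)
  genes <- unique(as.character(genes))
  if (length(genes) == 0L) {
    stop("signature '", name, "' has no genes", call. = FALSE)
  }
  structure(
    list(name = name, genes = genes, category = category,
         provenance = provenance),
    class = "tcms_signature"
  )
}

#' @export
print.tcms_signature <- function(x, ...) {
  cat(sprintf("<tcms_signature> %s [%s]: %d genes\n",
              x$name, x$category, length(x$genes)))
  invisible(x)
}

#' Construct a signature registry
#'
#' @param signatures List of [gene_signature()] objects with unique names.
#' @param version Free-form version tag.
#' @return An object of class `tcms_registry`.
#' @export
signature_registry <- function(signatures, version = "custom") {
  stopifnot(is.list(signatures), length(signatures) > 0L)
  ok <- vapply(signatures, inherits, logical(1), "tcms_signature")
  if (!all(ok)) stop("all elements must be tcms_signature objects", call. = FALSE)
  nm <- vapply(signatures, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate signature names", call. = FALSE)
  names(signatures) <- nm
  structure(list(signatures = signatures, version = version),
            class = "tcms_registry")
}

#' @export
print.tcms_registry <- function(x, ...) {
  cat(sprintf("<tcms_registry> %s: %d signatures\n",
              x$version, length(x$signatures)))
  for (s in x$signatures) {
    cat(sprintf("  %-22s %-11s %3d genes\n",
                s$name, s$category, length(s$genes)))
  }
  invisible(x)
}

#' @rdname signature_registry
#' @param registry A `tcms_registry`.
#' @return `registry_names()`: the feature names; `registry_gene_sets()`: a
#'   named list of gene vectors.
#' @export
registry_names <- function(registry) names(registry$signatures)

#' @rdname signature_registry
#' @export
registry_gene_sets <- function(registry) {
  lapply(registry$signatures, `[[`, "genes")
}

#' Marker source set
#'
#' One source of cell-type marker genes: a deconvolution method's marker list,
#' a single-cell dataset's per-cluster DE genes, or a publication.
#'
#' @param source_id Unique label for the source.
#' @param kind One of `"deconvolution"`, `"single_cell"`, `"publication"`.
#' @param sets Named list mapping cell type / feature name to a character
#'   vector of genes. Empty vectors are allowed.
#' @return An object of class `tcms_marker_source`.
#' @export
marker_source_set <- function(source_id,
                              kind = c("deconvolution", "single_cell",
                                       "publication"),
                              sets) {
  kind <- match.arg(kind)
  stopifnot(is.list(sets), !is.null(names(sets)))
  structure(list(source_id = source_id, kind = kind,
                 sets = lapply(sets, as.character)),
            class = "tcms_marker_source")
}

#' Voting rule for marker-gene consensus
#'
#' Exactly one of `min_sources` / `min_fraction` must be set. A gene is
#' selected when its vote count over the rule's source pool meets the
#' threshold, boundary inclusive: `count >= min_sources`, or
#' `count / n_sources >= min_fraction`.
#'
#' @param feature Feature name the rule selects genes for.
#' @param min_sources Integer absolute vote threshold (e.g. 4 of 9 sources).
#' @param min_fraction Fractional threshold (e.g. 1/5 of the EMT literature).
#' @param pool Optional character vector of source ids the rule applies to;
#'   `NULL` means all provided sources.
#' @return An object of class `tcms_voting_rule`.
#' @export
voting_rule <- function(feature, min_sources = NULL, min_fraction = NULL,
                        pool = NULL) {
  if (is.null(min_sources) == is.null(min_fraction)) {
    stop("exactly one of min_sources / min_fraction must be set",
         call. = FALSE)
  }
  structure(list(feature = feature, min_sources = min_sources,
                 min_fraction = min_fraction, pool = pool),
            class = "tcms_voting_rule")
}

#' Consensus-vote marker genes for one cell type
#'
#' Counts, over the sources in the rule's pool, how many sources list each
#' gene for `celltype`, and keeps genes meeting the rule's threshold
#' (boundary inclusive). The denominator for fractional rules is the number
#' of pooled sources, not the number of sources mentioning the cell type.
#'
#' @param celltype Cell type / feature name to look up in each source.
#' @param sources List of [marker_source_set()] objects.
#' @param rule A [voting_rule()].
#' @param category Category for the resulting signature.
#' @return A [gene_signature()] whose `provenance` records, per selected gene,
#'   the contributing source ids and the vote count.
#' @export
vote_markers <- function(celltype, sources, rule,
                         category = c("tme_cell", "tme_process", "clinical")) {
  category <- match.arg(category)
  if (length(sources) == 0L) stop("empty source list", call. = FALSE)
  ids <- vapply(sources, `[[`, character(1), "source_id")
  if (!is.null(rule$pool)) {
    missing_pool <- setdiff(rule$pool, ids)
    if (length(missing_pool) > 0L) {
      stop("rule pool references unknown sources: ",
           paste(missing_pool, collapse = ", "), call. = FALSE)
    }
    sources <- sources[ids %in% rule$pool]
    ids <- ids[ids %in% rule$pool]
  }
  n_src <- length(sources)
  votes <- list()
  for (i in seq_len(n_src)) {
    g <- unique(sources[[i]]$sets[[celltype]])
    for (gene in g) votes[[gene]] <- c(votes[[gene]], ids[[i]])
  }
  if (length(votes) == 0L) {
    stop("no source lists genes for '", celltype, "'", call. = FALSE)
  }
  counts <- lengths(votes)
  keep <- if (!is.null(rule$min_sources)) {
    counts >= rule$min_sources
  } else {
    counts / n_src >= rule$min_fraction
  }
  genes <- names(votes)[keep]
  if (length(genes) == 0L) {
    stop("no gene met the voting threshold for '", celltype, "'",
         call. = FALSE)
  }
  # stable order: vote count desc, then symbol
  genes <- genes[order(-counts[keep], genes)]
  prov <- data.frame(
    gene = genes,
    n_votes = as.integer(counts[genes]),
    sources = vapply(votes[genes], paste, character(1), collapse = ";"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  gene_signature(rule$feature, genes, category, provenance = prov)
}

# The registry layout: which TME features are filled by which voting regime.
tcms_registry_slots <- function() {
  list(
    voted_4_of_9 = c("CD8_T_cells", "CD4_T_cells", "B_cells", "Tregs",
                     "NK_cells", "Macrophages", "CAFs", "Endothelial_cells",
                     "Neutrophils"),
    voted_2_pubs = c("T_helper_cells", "M1_macrophages", "Dendritic_cells"),
    single_source = c("Myeloid_cells", "Tumor_proliferation",
                      "Matrix_remodeling", "Angiogenesis"),
    fraction_voted = "EMT"
  )
}

#' Build the default 20-feature registry
#'
#' Assembles the TCMS registry: 3 clinical signatures (GGO/lepidic,
#' solid/micropapillary, metastasis) plus 17 TME signatures filled by
#' consensus voting — nine cell types at >= 4 of 9 sources, three cell types
#' at >= 2 publications, four features taken from a single source, and EMT by
#' a fraction-of-literature vote.
#'
#' @param clinical_sigs List of three [gene_signature()]s named
#'   `GGO_lepidic`, `solid_micropapillary`, `metastasis`.
#' @param source_sets List of [marker_source_set()]s covering every TME slot.
#' @param rules Named list of [voting_rule()]s, one per TME feature.
#' @param version Registry version tag.
#' @return A `tcms_registry` with exactly 20 signatures in canonical order.
#' @export
build_default_registry <- function(clinical_sigs, source_sets, rules,
                                   version = "default") {
  slots <- tcms_registry_slots()
  cats <- tcms_feature_categories()
  cl_names <- vapply(clinical_sigs, `[[`, character(1), "name")
  for (nm in tcms_feature_names()[1:3]) {
    if (!nm %in% cl_names) {
      stop("missing clinical signature slot: ", nm, call. = FALSE)
    }
  }
  tme_features <- unlist(slots, use.names = FALSE)
  sigs <- clinical_sigs[match(tcms_feature_names()[1:3], cl_names)]
  for (feat in tme_features) {
    rule <- rules[[feat]]
    if (is.null(rule)) stop("missing voting rule slot: ", feat, call. = FALSE)
    has_feat <- vapply(source_sets, function(s) feat %in% names(s$sets),
                       logical(1))
    if (!is.null(rule$pool)) {
      ids <- vapply(source_sets, `[[`, character(1), "source_id")
      has_feat <- has_feat & ids %in% rule$pool
    }
    if (!any(has_feat)) stop("missing source slot: ", feat, call. = FALSE)
    sigs[[length(sigs) + 1L]] <- vote_markers(
      feat, source_sets, rule,
      category = if (cats[[feat]] == "tme_process") "tme_process" else "tme_cell"
    )
  }
  reg <- signature_registry(sigs, version = version)
  if (length(reg$signatures) != 20L) {
    stop("default registry must have exactly 20 signatures, got ",
         length(reg$signatures), call. = FALSE)
  }
  if (!identical(registry_names(reg), tcms_feature_names())) {
    stop("registry feature names do not match the canonical layout",
         call. = FALSE)
  }
  reg
}

#' Synthetic marker sources for the default registry
#'
#' Fabricates placeholder gene lists and source sets with the structure the
#' voting rules expect (7 deconvolution methods + 2 single-cell datasets for
#' the nine voted cell types; publication sources for the rest), so a complete
#' 20-feature registry can be built without the original marker supplements.
#' Gene symbols are synthetic (`<feature>_g01`, ...).
#'
#' @param genes_per_signature Number of genes fabricated per feature.
#' @return List with elements `clinical_sigs`, `source_sets`, `rules`,
#'   ready for [build_default_registry()].
#' @export
synthetic_marker_inputs <- function(genes_per_signature = 15) {
  stopifnot(genes_per_signature >= 1)
  slots <- tcms_registry_slots()
  feat_genes <- function(feat) sprintf("%s_g%02d", feat,
                                       seq_len(genes_per_signature))

  clinical_sigs <- lapply(tcms_feature_names()[1:3], function(f) {
    gene_signature(f, feat_genes(f), "clinical")
  })

  nine <- slots$voted_4_of_9
  nine_sets <- stats::setNames(lapply(nine, feat_genes), nine)
  src <- list()
  for (i in 1:7) {
    src[[length(src) + 1L]] <- marker_source_set(
      sprintf("deconv_%d", i), "deconvolution", nine_sets)
  }
  for (i in 1:2) {
    src[[length(src) + 1L]] <- marker_source_set(
      sprintf("scdata_%d", i), "single_cell", nine_sets)
  }
  nine_pool <- c(sprintf("deconv_%d", 1:7), sprintf("scdata_%d", 1:2))

  for (f in slots$voted_2_pubs) {
    for (i in 1:2) {
      src[[length(src) + 1L]] <- marker_source_set(
        sprintf("pub_%s_%d", f, i), "publication",
        stats::setNames(list(feat_genes(f)), f))
    }
  }
  single_sets <- stats::setNames(lapply(slots$single_source, feat_genes),
                                 slots$single_source)
  src[[length(src) + 1L]] <- marker_source_set("pub_single_source",
                                               "publication", single_sets)
  emt_pool <- sprintf("pub_EMT_%d", 1:5)
  for (i in 1:5) {
    src[[length(src) + 1L]] <- marker_source_set(
      emt_pool[i], "publication",
      stats::setNames(list(feat_genes("EMT")), "EMT"))
  }

  rules <- c(
    stats::setNames(lapply(nine, voting_rule, min_sources = 4,
                           pool = nine_pool), nine),
    stats::setNames(lapply(slots$voted_2_pubs, function(f) {
      voting_rule(f, min_sources = 2, pool = sprintf("pub_%s_%d", f, 1:2))
    }), slots$voted_2_pubs),
    stats::setNames(lapply(slots$single_source, voting_rule, min_sources = 1,
                           pool = "pub_single_source"), slots$single_source),
    stats::setNames(list(voting_rule("EMT", min_fraction = 1 / 5,
                                     pool = emt_pool)), "EMT")
  )
  list(clinical_sigs = clinical_sigs, source_sets = src, rules = rules)
}

#' Default registry built from synthetic marker inputs
#'
#' @inheritParams synthetic_marker_inputs
#' @return A 20-feature `tcms_registry`.
#' @export
default_registry <- function(genes_per_signature = 15) {
  inp <- synthetic_marker_inputs(genes_per_signature)
  build_default_registry(inp$clinical_sigs, inp$source_sets, inp$rules,
                         version = "synthetic-default")
}

#' Read / write gene signatures in GMT format
#'
#' One tab-separated line per set: name, description, genes. The description
#' field carries the signature category so a registry round-trips.
#'
#' @param registry A `tcms_registry`.
#' @param path File path.
#' @return `read_gmt()`: a `tcms_registry` (provenance is not stored in GMT).
#' @export
write_gmt <- function(registry, path) {
  lines <- vapply(registry$signatures, function(s) {
    paste(c(s$name, s$category, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @param version Version tag for the registry read back.
#' @export
read_gmt <- function(path, version = "gmt") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sigs <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("malformed GMT line: ", ln, call. = FALSE)
    cat <- if (f[2] %in% c("clinical", "tme_cell", "tme_process")) {
      f[2]
    } else {
      "tme_cell"
    }
    gene_signature(f[1], f[-(1:2)], cat)
  })
  signature_registry(sigs, version = version)
}
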