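make_sources <- function(votes, celltype = "CD8_T_cells") {
  # votes: named list gene -> number of sources listing it (out of 9)
  src <- lapply(1:9, function(i) {
    genes <- names(votes)[vapply(votes, function(v) i <= v, logical(1))]
    marker_source_set(paste0("src_", i),
                      if (i <= 7) "deconvolution" else "single_cell",
                      stats::setNames(list(genes), celltype))
  })
  src
}

test_that("marker voting is boundary-inclusive at 4 of 9 sources", {
  src <- make_sources(list(gA = 9, gB = 4, gC = 3))
  sig <- vote_markers("CD8_T_cells", src,
                      voting_rule("CD8_T_cells", min_sources = 4))
  expect_setequal(sig$genes, c("gA", "gB"))
  expect_false("gC" %in% sig$genes)
  expect_equal(sig$provenance$n_votes[sig$provenance$gene == "gB"], 4L)
})

test_that("fractional voting over 84 publications draws the line at 17", {
  src <- lapply(1:84, function(i) {
    genes <- character(0)
    if (i <= 17) genes <- c(genes, "gIn")
    if (i <= 16) genes <- c(genes, "gOut")
    marker_source_set(paste0("pub_", i), "publication",
                      stats::setNames(list(genes), "EMT"))
  })
  sig <- vote_markers("EMT", src, voting_rule("EMT", min_fraction = 1 / 5),
                      category = "tme_process")
  expect_true("gIn" %in% sig$genes)   # 17/84 >= 1/5
  expect_false("gOut" %in% sig$genes) # 16/84 < 1/5
})

test_that("voting is monotone: adding a source never drops a gene", {
  withr::with_seed(42, {
    for (rep in 1:5) {
      votes <- stats::setNames(as.list(sample(0:9, 12, replace = TRUE)),
                               paste0("g", 1:12))
      votes[[1]] <- max(votes[[1]], 4) # keep at least one selected gene
      src <- make_sources(votes)
      rule <- voting_rule("CD8_T_cells", min_sources = 4)
      before <- vote_markers("CD8_T_cells", src, rule)$genes
      extra <- marker_source_set("extra", "publication",
                                 list(CD8_T_cells = paste0("g", 1:12)))
      after <- vote_markers("CD8_T_cells", c(src, list(extra)), rule)$genes
      expect_true(all(before %in% after))
    }
  })
})

test_that("empty source list is an error", {
  expect_error(vote_markers("CD8_T_cells", list(),
                            voting_rule("CD8_T_cells", min_sources = 4)),
               "empty source")
  expect_error(voting_rule("x", min_sources = 4, min_fraction = 0.2),
               "exactly one")
})

test_that("differential expression matches Welch t and the DE thresholds", {
  withr::with_seed(7, {
    n <- 20
    expr <- matrix(rnorm(50 * 2 * n, mean = 5, sd = 0.5), 50,
                   dimnames = list(sprintf("g%02d", 1:50),
                                   sprintf("s%02d", 1:(2 * n))))
    a <- colnames(expr)[1:n]
    b <- colnames(expr)[(n + 1):(2 * n)]
    expr["g01", a] <- rnorm(n, 7, 0.1)   # +2 log2 shift
    expr["g01", b] <- rnorm(n, 5, 0.1)
    expr["g02", a] <- rnorm(n, 5.9, 0.1) # +0.9 shift: fails the lfc filter
    expr["g02", b] <- rnorm(n, 5, 0.1)
  })
  res <- differential_expression(expr, a, b)
  expect_equal(res$p[res$gene == "g03"],
               stats::t.test(expr["g03", a], expr["g03", b])$p.value,
               tolerance = 1e-12)
  g1 <- res[res$gene == "g01", ]
  expect_true(g1$log2fc >= 1 && g1$p_adj < 0.05)
  g2 <- res[res$gene == "g02", ]
  expect_true(g2$log2fc < 1)
  expect_true(all(res$p_adj >= res$p - 1e-15))
  sig <- derive_de_signature(res, "shifted", use_adjusted = TRUE)
  expect_true("g01" %in% sig$genes)
  expect_false("g02" %in% sig$genes)
})

test_that("a zero-variance gene with equal means gets p = 1, not NaN", {
  expr <- rbind(flat = rep(3, 8), vary = c(rnorm(8)))
  colnames(expr) <- paste0("s", 1:8)
  res <- differential_expression(expr, paste0("s", 1:4), paste0("s", 5:8))
  expect_equal(res$p[res$gene == "flat"], 1)
})

test_that("DE p-values are uniform under the null", {
  withr::with_seed(11, {
    expr <- matrix(rnorm(400 * 30, 5, 1), 400,
                   dimnames = list(paste0("g", 1:400), paste0("s", 1:30)))
  })
  res <- differential_expression(expr, paste0("s", 1:15), paste0("s", 16:30))
  ks <- suppressWarnings(stats::ks.test(res$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the signature construction arithmetic removes the exclusion list", {
  # 32 genes passing both filters, 11 on the curated exclusion list
  res <- data.frame(gene = sprintf("G%03d", 1:40),
                    log2fc = c(seq(3, 1.05, length.out = 32), rep(0.2, 8)),
                    mean_a = 6, mean_b = 5,
                    p = c(rep(0.001, 32), rep(0.5, 8)),
                    p_adj = c(rep(0.01, 32), rep(0.9, 8)))
  excl <- sprintf("G%03d", 1:11)
  sig <- derive_de_signature(res, "solid_micropapillary", use_adjusted = TRUE,
                             exclusion_list = excl)
  expect_length(sig$genes, 21)
  expect_false(any(excl %in% sig$genes))
  # descending log2fc order
  lfc <- res$log2fc[match(sig$genes, res$gene)]
  expect_true(all(diff(lfc) <= 0))
  # vacuous p threshold -> empty signature with warning
  expect_warning(empty <- derive_de_signature(res, "none", p_max = 0),
                 "no genes pass")
  expect_null(empty)
})

test_that("single-cell QC applies each filter at its stated boundary", {
  n_genes <- 3000
  genes <- sprintf("g%04d", seq_len(n_genes))
  mito <- c("MT-1", "MT-2")
  genes[1:2] <- mito
  base <- matrix(0L, 8, n_genes, dimnames = list(paste0("c", 1:8), genes))
  base["c1", 3:302] <- 1L                   # 300 genes, clean
  base["c1", mito] <- 1L                    # trace mito, < 5%
  base["c2", 3:152] <- 1L                   # 150 genes: below 200
  base["c3", 3:302] <- 1L                   # 6% mito counts
  base["c3", mito] <- c(10L, 9L)            # 19 / (300 + 19) ~ 6%
  base["c4", 3:2502] <- 1L                  # exactly 2500 detected
  base["c5", 3:2501] <- 1L                  # 2499 detected
  base["c6", 3:302] <- 1L
  base["c6", mito] <- 1L                    # keeps mito genes in >= 3 cells
  base["c7", 3:2502] <- 1L                  # props so high-count genes
  base["c8", 3:2502] <- 1L                  # survive the gene filter
  res <- qc_filter_cells(base, mito_genes = mito)
  kept <- rownames(res$counts)
  expect_false("c2" %in% kept)  # < 200 genes
  expect_false("c3" %in% kept)  # > 5% mito
  expect_false("c4" %in% kept)  # 2500 detected genes is not < 2500
  expect_true(all(c("c1", "c5", "c6") %in% kept))
  expect_equal(unname(res$removed["cells_low_genes"]), 1L)
  expect_equal(unname(res$removed["cells_high_genes"]), 3L)
})

test_that("QC filtering is idempotent on generated data", {
  sc <- generate_single_cell(n_cells = 300, n_genes = 350, seed = 5,
                             frac_low_quality = 0.1, frac_high_mito = 0.1)
  once <- qc_filter_cells(sc$counts, sc$mito_genes)
  twice <- qc_filter_cells(once$counts, sc$mito_genes)
  expect_identical(once$counts, twice$counts)
  expect_true(all(twice$removed == 0L))
})

test_that("default registry has the canonical 20-feature layout", {
  reg <- default_registry(genes_per_signature = 6)
  expect_length(reg$signatures, 20)
  expect_identical(registry_names(reg), tcms_feature_names())
  cats <- vapply(reg$signatures, `[[`, character(1), "category")
  expect_equal(unname(table(cats)["clinical"]), 3L)
})

test_that("omitting the EMT sources fails naming the slot", {
  inp <- synthetic_marker_inputs(6)
  keep <- !grepl("^pub_EMT", vapply(inp$source_sets, `[[`, character(1),
                                    "source_id"))
  expect_error(
    build_default_registry(inp$clinical_sigs, inp$source_sets[keep],
                           inp$rules),
    "EMT")
})

test_that("registry construction is order-independent in its sources", {
  inp <- synthetic_marker_inputs(6)
  reg1 <- build_default_registry(inp$clinical_sigs, inp$source_sets,
                                 inp$rules)
  reg2 <- build_default_registry(inp$clinical_sigs, rev(inp$source_sets),
                                 inp$rules)
  expect_identical(lapply(registry_gene_sets(reg1), sort),
                   lapply(registry_gene_sets(reg2), sort))
})

test_that("a registry round-trips through GMT unchanged", {
  reg <- default_registry(genes_per_signature = 5)
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(reg, path)
  back <- read_gmt(path)
  expect_identical(registry_names(back), registry_names(reg))
  expect_identical(registry_gene_sets(back), registry_gene_sets(reg))
  expect_identical(vapply(back$signatures, `[[`, character(1), "category"),
                   vapply(reg$signatures, `[[`, character(1), "category"))
})
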