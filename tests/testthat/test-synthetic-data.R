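test_that("the cohort generator is deterministic given its seed", {
  reg <- small_registry()
  cfg <- generator_config(n_samples = 40, n_genes = 400,
                          genes_per_signature = 8, seed = 77)
  c1 <- generate_bulk_cohort(cfg, reg)
  c2 <- generate_bulk_cohort(cfg, reg)
  expect_identical(c1$expression, c2$expression)
  expect_identical(c1$truth_labels, c2$truth_labels)
  expect_identical(c1$clinical, c2$clinical)
  expect_identical(c1$svs, c2$svs)
  expect_identical(c1$mutations, c2$mutations)
})

test_that("a degenerate simplex yields a single subtype", {
  reg <- small_registry()
  cfg <- generator_config(n_samples = 30, n_genes = 400,
                          genes_per_signature = 8,
                          subtype_proportions = c(LPI = 1, IMD = 0,
                                                  IME = 0, HPI = 0),
                          seed = 5)
  coh <- generate_bulk_cohort(cfg, reg)
  expect_true(all(coh$truth_labels == "LPI"))
  expect_error(generator_config(subtype_proportions = c(0.5, 0.2, 0.2, 0.2)),
               "sum to 1")
})

test_that("undersized gene space is a sizing error", {
  reg <- small_registry()
  cfg <- generator_config(n_samples = 10, n_genes = 100,
                          genes_per_signature = 8, seed = 1)
  expect_error(generate_bulk_cohort(cfg, reg), "signature genes")
})

test_that("effect_size = 0 leaves signature genes at the null", {
  reg <- small_registry()
  cfg <- generator_config(n_samples = 120, n_genes = 400,
                          genes_per_signature = 8, effect_size = 0,
                          seed = 19)
  coh <- generate_bulk_cohort(cfg, reg)
  sig_genes <- unlist(registry_gene_sets(reg), use.names = FALSE)
  g1 <- names(coh$truth_labels)[coh$truth_labels == "LPI"]
  g2 <- names(coh$truth_labels)[coh$truth_labels == "HPI"]
  res <- differential_expression(coh$expression[sig_genes, ], g1, g2)
  expect_gte(mean(res$p > 0.01), 0.97)
})

test_that("survival generation matches the exponential model", {
  prof <- subtype_profiles()
  for (nm in names(prof)) prof[[nm]]$hazard_os <- 1
  lab <- stats::setNames(rep(names(prof), each = 500),
                         sprintf("P%04d", 1:2000))
  sd <- generate_survival(lab, prof, base_rate = 0.02, censor_rate = 0,
                          seed = 3)
  expect_true(all(sd$event == 1))
  km <- km_estimate(sd$time, sd$event)
  expect_equal(km$median, log(2) / 0.02, tolerance = 0.12)
  # full censoring -> no events
  sd0 <- generate_survival(lab, prof, base_rate = 0.02, censor_rate = 1,
                           seed = 3)
  expect_true(all(sd0$event == 0))
  expect_true(all(sd0$time > 0))
  expect_error(generate_survival(c(a = "XX"), prof, 0.02, 0, 1),
               "no profile")
})

test_that("Cox recovers a planted hazard ratio of 4", {
  prof <- subtype_profiles()
  prof$LPI$hazard_os <- 1
  prof$HPI$hazard_os <- 4
  lab <- stats::setNames(rep(c("LPI", "HPI"), each = 500),
                         sprintf("P%04d", 1:1000))
  sd <- generate_survival(lab, prof, base_rate = 0.01, censor_rate = 0,
                          seed = 4)
  cf <- cox_fit(sd$time, sd$event,
                data.frame(g = as.integer(sd$group == "HPI")))
  expect_equal(unname(cf$coef), log(4), tolerance = 0.2 / log(4))
})

test_that("a strongly planted pair is detected as co-occurrent", {
  reg <- small_registry()
  hits <- vapply(1:20, function(s) {
    cfg <- generator_config(
      n_samples = 300,
      event_rates = c(A_mut = 0.3, B_mut = 0.3, C_mut = 0.2),
      cooccurrence_pairs = data.frame(a = "A_mut", b = "B_mut", odds = 50),
      hotspot_rate = 0, seed = s)
    alt <- generate_alterations(cfg, stats::setNames(rep("LPI", 300),
                                                     sprintf("S%03d", 1:300)),
                                seed = s)
    pa <- pairwise_association(alt$presence)
    row <- pa[pa$event_a == "A_mut" & pa$event_b == "B_mut", ]
    row$p < 0.05 && row$odds_ratio > 1
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("null pairs show no excess of small Fisher p-values", {
  ps <- vapply(1:300, function(s) {
    withr::with_seed(s, {
      a <- stats::rbinom(150, 1, 0.25)
      b <- stats::rbinom(150, 1, 0.25)
    })
    m <- rbind(A = a, B = b)
    colnames(m) <- sprintf("S%03d", 1:150)
    pairwise_association(m)$p[1]
  }, numeric(1))
  # exact tests are conservative: the level never exceeds the nominal alpha
  expect_lte(mean(ps < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 300))
  expect_lte(mean(ps < 0.2), 0.2 + 3 * sqrt(0.2 * 0.8 / 300))
})

test_that("zero baseline rates give empty alteration tables", {
  cfg <- generator_config(n_samples = 20,
                          event_rates = c(A_mut = 0, B_amp = 0),
                          cooccurrence_pairs = NULL, hotspot_rate = 0,
                          seed = 2)
  alt <- generate_alterations(cfg, stats::setNames(rep("LPI", 20),
                                                   paste0("S", 1:20)),
                              seed = 2)
  expect_equal(nrow(alt$mutations), 0)
  expect_equal(nrow(alt$fusions), 0)
  expect_true(all(alt$cnv == 0))
  expect_error(
    generate_alterations(
      generator_config(n_samples = 10,
                       event_rates = c(A_mut = 0.1, B_mut = 0.1),
                       cooccurrence_pairs = data.frame(a = "A_mut",
                                                       b = "B_mut",
                                                       odds = -2),
                       seed = 1),
      stats::setNames(rep("LPI", 10), paste0("S", 1:10))),
    "odds")
})

test_that("planted co-occurrence preserves the marginal frequencies", {
  cfg <- generator_config(
    n_samples = 4000,
    event_rates = c(A_mut = 0.3, B_mut = 0.2),
    cooccurrence_pairs = data.frame(a = "A_mut", b = "B_mut", odds = 10),
    hotspot_rate = 0, seed = 9)
  alt <- generate_alterations(cfg, stats::setNames(rep("LPI", 4000),
                                                   sprintf("S%04d", 1:4000)),
                              seed = 9)
  expect_equal(mean(alt$presence["A_mut", ]), 0.3, tolerance = 0.1)
  expect_equal(mean(alt$presence["B_mut", ]), 0.2, tolerance = 0.12)
  # realized odds ratio near the planted value
  a <- sum(alt$presence["A_mut", ] & alt$presence["B_mut", ])
  b <- sum(alt$presence["A_mut", ] & !alt$presence["B_mut", ])
  cc <- sum(!alt$presence["A_mut", ] & alt$presence["B_mut", ])
  d <- 4000 - a - b - cc
  expect_gt(a * d / (b * cc), 5)
})

test_that("SV generation conserves expected totals and respects zero", {
  sig <- default_sv_signatures()
  expo0 <- matrix(0, 3, 4, dimnames = list(NULL, paste0("S", 1:4)))
  expect_equal(nrow(generate_sv_events(sig, expo0, seed = 1)), 0)
  expo <- matrix(30, 3, 10, dimnames = list(NULL, paste0("S", 1:10)))
  rec <- generate_sv_events(sig, expo, seed = 8)
  expected <- sum(sig %*% expo)
  expect_lt(abs(nrow(rec) - expected), 5 * sqrt(expected))
  expect_error(generate_sv_events(-sig, expo, seed = 1), "nonnegative")
  expect_error(generate_sv_events(sig[1:10, ], expo, seed = 1), "32 rows")
})

test_that("planted single-category SV signatures round-trip the classifier", {
  for (cat_i in c(3, 18, 16, 32)) { # non-clustered DEL, clustered DEL,
    sig <- matrix(0, 32, 1)         # non-clustered TRA, clustered TRA
    sig[cat_i, 1] <- 1
    expo <- matrix(100, 1, 3, dimnames = list(NULL, paste0("P", 1:3)))
    rec <- generate_sv_events(sig, expo, seed = 5)
    hit <- unlist(lapply(split(rec, rec$sample), function(r) {
      classify_sv(r) == cat_i
    }))
    expect_gte(mean(hit), 0.99)
  }
})

test_that("single-cell generation is deterministic and QC-calibrated", {
  s1 <- generate_single_cell(n_cells = 200, n_genes = 300, seed = 3)
  s2 <- generate_single_cell(n_cells = 200, n_genes = 300, seed = 3)
  expect_identical(s1$counts, s2$counts)
  # planted 10% high-mito cells are removed by QC at about that rate
  sc <- generate_single_cell(n_cells = 600, n_genes = 400, seed = 4,
                             frac_high_mito = 0.10)
  res <- qc_filter_cells(sc$counts, sc$mito_genes)
  removed_frac <- 1 - nrow(res$counts) / 600
  expect_equal(removed_frac, 0.10, tolerance = 0.5)
  expect_gte(removed_frac, 0.05)
  # without marker inflation, per-type DE finds no markers
  sc0 <- generate_single_cell(n_cells = 200, n_genes = 300, seed = 6,
                              marker_fold = 1)
  lg <- t(log2(sc0$counts + 1))
  ty <- sc0$labels
  cells_a <- rownames(sc0$counts)[ty == ty[1]]
  cells_b <- rownames(sc0$counts)[ty != ty[1]]
  de <- differential_expression(lg, cells_a, cells_b)
  expect_equal(sum(de$log2fc >= 1 & de$p < 0.05), 0)
  expect_error(generate_single_cell(type_markers = list()), "marker map")
  expect_error(generate_single_cell(type_markers = list(T = "MT-CO1")),
               "disjoint")
})

test_that("a cohort writes to plain-text tables consistently", {
  reg <- small_registry()
  cfg <- generator_config(n_samples = 15, n_genes = 400,
                          genes_per_signature = 8, seed = 30)
  coh <- generate_bulk_cohort(cfg, reg)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(all(file.exists(file.path(
    dir, c("expression.tsv", "clinical.tsv", "mutations.maf.tsv",
           "fusions.tsv", "cnv.tsv", "svs.bedpe.tsv", "truth.tsv")))))
  back <- read_bedpe(file.path(dir, "svs.bedpe.tsv"))
  expect_equal(nrow(back), nrow(coh$svs))
  expect_equal(back$pos1, coh$svs$pos1)
  expr <- read_matrix_tsv(file.path(dir, "expression.tsv"))
  expect_equal(expr, coh$expression, tolerance = 1e-6)
  mu <- read_mutations_tsv(file.path(dir, "mutations.maf.tsv"))
  expect_equal(nrow(mu), nrow(coh$mutations))
  cnv <- read_cnv_tsv(file.path(dir, "cnv.tsv"))
  expect_identical(unname(cnv), unname(coh$cnv))
  cat32 <- build_sv_catalog(coh$svs)
  path <- file.path(dir, "catalog.tsv")
  write_matrix_tsv(cat32, path)
  expect_equal(unname(read_sv_catalog_tsv(path)), unname(cat32))
})
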