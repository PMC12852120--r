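mut_row <- function(gene, p, exon = NA, cls = "missense") {
  data.frame(gene = gene, protein_change = p, exon = as.integer(exon),
             variant_class = cls, stringsAsFactors = FALSE)
}

test_that("the hotspot engine classifies the guideline variants", {
  pos <- function(mut = NULL, fus = NULL) {
    call_hotspot_status(mut, fus)$status
  }
  expect_equal(pos(mut_row("EGFR", "p.L858R", 21)), "positive")
  expect_equal(pos(mut_row("KRAS", "p.G12C")), "positive")
  expect_equal(pos(mut_row("KRAS", "p.G12D")), "negative") # only G12C listed
  expect_equal(pos(mut_row("BRAF", "p.V600E")), "positive")
  expect_equal(pos(mut_row("EGFR", "p.G719A", 18)), "positive") # any alt
  expect_equal(pos(mut_row("EGFR", "p.G719A", 18)), "positive")
  expect_equal(pos(mut_row("EGFR", "p.E746_A750del", 19, "inframe_del")),
               "positive")
  expect_equal(pos(mut_row("EGFR", "p.L861Q")), "positive")
  expect_equal(pos(mut_row("ERBB2", "p.Y772_A775dup", 20, "inframe_ins")),
               "positive")
  expect_equal(pos(fus = data.frame(gene_a = "EML4", gene_b = "ALK")),
               "positive") # either partner matches
  expect_equal(pos(fus = data.frame(gene_a = "RET", gene_b = "CCDC6")),
               "positive")
  expect_equal(pos(), "negative") # no qualifying events
  expect_equal(pos(mut_row("TP53", "p.R175H", 5)), "negative")
})

test_that("ERBB2 exon-20 non-insertions and unparseable changes are flagged", {
  expect_message(
    res <- call_hotspot_status(mut_row("ERBB2", "p.L755S", 20)),
    "ERBB2")
  expect_equal(res$status, "negative")
  expect_warning(
    res2 <- call_hotspot_status(mut_row("EGFR", "c.2573T>G", 21)),
    "unparseable")
  expect_equal(res2$status, "negative")
})

test_that("hotspot calls are monotone in the record set", {
  withr::with_seed(55, {
    for (rep in 1:5) {
      base <- mut_row(sample(c("TP53", "STK11", "RB1"), 1), "p.R100W", 3)
      st0 <- call_hotspot_status(base)$status
      extra <- rbind(base, mut_row("KEAP1", "p.G333C", 3))
      expect_equal(call_hotspot_status(extra)$status, st0)
      # removing records from a negative sample never creates a positive
      expect_equal(call_hotspot_status(base[0, ])$status, "negative")
    }
  })
  # cohort-level wrapper
  mu <- cbind(sample = c("s1", "s2"),
              rbind(mut_row("EGFR", "p.L858R", 21),
                    mut_row("TP53", "p.R175H", 5)))
  hs <- hotspot_status(c("s1", "s2", "s3"), mu)
  expect_equal(hs$status, c("positive", "negative", "negative"))
})

test_that("Fisher p matches the closed forms and the base-R oracle", {
  # perfectly concordant 2x2: p = 2 / C(20, 10)
  expect_equal(fisher_exact_p(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(fisher_exact_p(5, 5, 5, 5), 1, tolerance = 1e-12)
  expect_equal(fisher_exact_p(0, 10, 10, 0), 2 / choose(20, 10),
               tolerance = 1e-12)
  withr::with_seed(14, {
    for (rep in 1:200) {
      n <- sample(4:40, 1)
      cells <- stats::rmultinom(1, n, runif(4))[, 1]
      p_pkg <- fisher_exact_p(cells[1], cells[2], cells[3], cells[4])
      tab <- matrix(cells, 2, byrow = TRUE)
      p_ref <- stats::fisher.test(tab)$p.value
      expect_equal(p_pkg, p_ref, tolerance = 1e-12)
    }
  })
})

test_that("pairwise association reports direction and handles constants", {
  m <- rbind(A = c(rep(1, 10), rep(0, 10)),
             B = c(rep(1, 10), rep(0, 10)),
             C = c(rep(0, 10), rep(1, 10)),
             K = rep(1, 20))
  colnames(m) <- paste0("s", 1:20)
  pa <- pairwise_association(m)
  ab <- pa[pa$event_a == "A" & pa$event_b == "B", ]
  expect_equal(ab$odds_ratio, Inf)
  expect_equal(ab$p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(ab$direction, "co-occurrent")
  ac <- pa[pa$event_a == "A" & pa$event_b == "C", ]
  expect_equal(ac$odds_ratio, 0)
  expect_equal(ac$direction, "exclusive")
  ak <- pa[pa$event_a == "A" & pa$event_b == "K", ]
  expect_equal(ak$direction, "none")
  expect_true(is.na(ak$p))
  expect_match(ak$note, "constant")
})

test_that("group frequency comparison detects planted differences", {
  withr::with_seed(88, {
    hits <- vapply(1:20, function(i) {
      ev <- rbind(X = c(stats::rbinom(100, 1, 0.40),
                        stats::rbinom(100, 1, 0.05)))
      colnames(ev) <- sprintf("s%03d", 1:200)
      res <- compare_event_frequencies(ev, colnames(ev)[1:100],
                                       colnames(ev)[101:200])
      res$p < 0.001
    }, logical(1))
    expect_gte(mean(hits), 0.99)
  })
  # identical frequency patterns -> p = 1
  ev <- rbind(X = rep(c(1, 0, 0, 0), 10))
  colnames(ev) <- paste0("s", 1:40)
  res <- compare_event_frequencies(ev, paste0("s", 1:20), paste0("s", 21:40))
  expect_equal(res$p, 1)
  # absent event -> p = 1, OR reported as 1 with a note
  ev0 <- rbind(X = rep(0, 20))
  colnames(ev0) <- paste0("s", 1:20)
  res0 <- compare_event_frequencies(ev0, paste0("s", 1:10),
                                    paste0("s", 11:20))
  expect_equal(res0$p, 1)
  expect_equal(res0$odds_ratio, 1)
  expect_match(res0$note, "constant")
  expect_error(compare_event_frequencies(ev0, character(0), "s1"), "empty")
})

test_that("CNV events apply the GISTIC +/-2 thresholds", {
  cnv <- matrix(c(2, 1, 0, -1, -2, 0), 3, 2,
                dimnames = list(c("RRM2B", "VOPP1", "CDKN2A"),
                                c("s1", "s2")))
  ev <- cnv_gene_events(cnv)
  expect_true(ev["RRM2B_amp", "s1"] == 1)
  expect_false("VOPP1_amp" %in% rownames(ev)) # value 1 is not an event
  expect_true(ev["VOPP1_del", "s2"] == 1)     # -2 is a deep deletion
  expect_equal(nrow(cnv_gene_events(matrix(0L, 2, 2,
                                           dimnames = list(c("a", "b"),
                                                           NULL)))), 0)
  cnv[1, 1] <- 5
  expect_error(cnv_gene_events(cnv), "-2..2")
})

test_that("the SV taxonomy has 32 categories over 5 size bins", {
  expect_length(sv_category_names(), 32)
  expect_equal(anyDuplicated(sv_category_names()), 0L)
  expect_length(sv_size_bin_labels(), 5)
})

test_that("SV classification respects size bins and TRA handling", {
  iso <- function(size, type = "DEL") {
    # one target record plus two distant events so gaps are defined
    data.frame(type = c(type, "DUP", "DUP"),
               chrom1 = c("chr1", "chr2", "chr2"),
               pos1 = c(5e6, 1e7, 9e7),
               chrom2 = c("chr1", "chr2", "chr2"),
               pos2 = c(5e6 + size, 1e7 + 5e4, 9e7 + 5e4))
  }
  expect_equal(unname(classify_sv(iso(5000))[1]),
               which(sv_category_names() == "non-clustered:DEL:1-10Kb"))
  expect_equal(unname(classify_sv(iso(500))[1]), 1L)   # sub-1Kb folds down
  expect_equal(unname(classify_sv(iso(9999))[1]), 1L)
  expect_equal(unname(classify_sv(iso(10000))[1]), 2L) # half-open boundary
  expect_equal(unname(classify_sv(iso(2e7, "INV"))[1]),
               which(sv_category_names() == "non-clustered:INV:>10Mb"))
  tra <- data.frame(type = "TRA", chrom1 = "chr1", pos1 = 1e6,
                    chrom2 = "chr2", pos2 = 2e6)
  expect_true(unname(classify_sv(tra)) %in% c(16L, 32L))
  expect_error(classify_sv(data.frame(type = "BND", chrom1 = "chr1",
                                      pos1 = 1, chrom2 = "chr1", pos2 = 2)),
               "unknown SV type")
})

test_that("a tight breakpoint cluster is called clustered under the tau rule", {
  # 10 DELs with all breakpoints within 200 Kb on chr1; sparse elsewhere
  starts <- 5e6 + (0:9) * 2e4
  rec <- data.frame(type = "DEL", chrom1 = "chr1", pos1 = starts,
                    chrom2 = "chr1", pos2 = starts + 5e3)
  far <- data.frame(type = "DUP", chrom1 = "chr2",
                    pos1 = c(1e7, 6e7, 11e7), chrom2 = "chr2",
                    pos2 = c(1e7, 6e7, 11e7) + 5e4)
  all_rec <- rbind(rec, far)
  flags <- sv_clustered_flags(all_rec)
  expect_true(all(flags[1:10]))
  expect_false(any(flags[11:13]))
})

test_that("catalogs conserve record counts", {
  expect_true(all(build_sv_catalog(
    data.frame(sample = character(0), type = character(0),
               chrom1 = character(0), pos1 = numeric(0),
               chrom2 = character(0), pos2 = numeric(0)),
    samples = "empty") == 0))
  sig <- default_sv_signatures()
  expo <- matrix(20, 3, 5, dimnames = list(NULL, paste0("S", 1:5)))
  rec <- generate_sv_events(sig, expo, seed = 3)
  cat32 <- build_sv_catalog(rec)
  expect_equal(sum(cat32), nrow(rec))
  expect_equal(nrow(cat32), 32)
  expect_equal(unname(colSums(cat32)),
               unname(table(rec$sample)[colnames(cat32)]),
               ignore_attr = TRUE)
})

test_that("NMF recovers an exact planted factorization", {
  withr::with_seed(101, {
    W <- matrix(0, 32, 2)
    W[1:6, 1] <- runif(6, 1, 3)
    W[20:28, 2] <- runif(9, 1, 3)
    W <- sweep(W, 2, colSums(W), "/")
    H <- matrix(rgamma(2 * 20, 3, 0.05), 2, 20)
    # pure-exposure samples make the planted factorization identifiable
    H[2, 1:3] <- 0
    H[1, 4:6] <- 0
    V <- W %*% H
  })
  fit <- extract_signatures_nmf(V, rank_range = 1:4, replicates = 6,
                                seed = 2)
  expect_equal(fit$rank, 2)
  expect_true(fit$monotone)
  mm <- match_signatures(fit$signatures, W)
  expect_gte(min(mm$cosine), 0.99)
  expect_equal(unname(colSums(fit$signatures)), rep(1, 2), tolerance = 1e-9)
  # rank-1 data selects rank 1
  V1 <- W[, 1, drop = FALSE] %*% H[1, , drop = FALSE]
  fit1 <- extract_signatures_nmf(V1, rank_range = 1:3, replicates = 5,
                                 seed = 3)
  expect_equal(fit1$rank, 1)
  expect_error(extract_signatures_nmf(matrix(0, 32, 5)), "all-zero")
})

test_that("NNLS refitting satisfies the generative and KKT conditions", {
  withr::with_seed(7, {
    C <- matrix(runif(32 * 4), 32, 4)
    C <- sweep(C, 2, colSums(C), "/")
    colnames(C) <- paste0("R", 1:4)
  })
  # exact generative case
  fit <- refit_exposures(C[, 2] * 100, C)
  expect_equal(unname(fit$exposures), c(0, 100, 0, 0), tolerance = 1e-6)
  expect_lt(fit$residual, 1e-8)
  # zero catalog
  fit0 <- refit_exposures(rep(0, 32), C)
  expect_true(all(fit0$exposures == 0))
  # random nonnegative combination is recovered
  withr::with_seed(8, w <- runif(4, 1, 10))
  fitw <- refit_exposures(as.numeric(C %*% w), C)
  expect_equal(unname(fitw$exposures), w, tolerance = 1e-6)
  # KKT: residual orthogonal to active columns
  withr::with_seed(9, d <- as.numeric(C %*% runif(4)) + runif(32, 0, 0.01))
  fitn <- refit_exposures(d, C)
  r <- d - C %*% fitn$exposures
  active <- fitn$exposures > 1e-10
  if (any(active)) {
    expect_lt(max(abs(crossprod(C[, active, drop = FALSE], r))), 1e-8)
  }
  expect_error(refit_exposures(c(-1, rep(0, 31)), C), "negative")
  expect_error(refit_exposures(rep(1, 32), C * 2), "sum to 1")
})
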