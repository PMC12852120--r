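# Fixed seed offsets: one master seed, one substream per generated table, so
# adding a table never perturbs the others.
.seed_offsets <- c(labels = 101L, expression = 202L, os = 303L, rfs = 404L,
                   stage = 505L, alterations = 606L, sv = 707L, sc = 808L)

#' Subtype profiles for the synthetic cohort generator
#'
#' Each profile carries the per-feature mean z-shift (scaled by the
#' generator's `effect_size`) and relative hazard multipliers for OS and
#' RFS. The default four profiles encode the phenotype pattern of the
#' subtypes: LPI high on GGO/lepidic with low proliferation; IMD
#' immune-depleted ("cold"); IME immune-enriched (CD8 T, NK, B cells high);
#' HPI high on solid/micropapillary growth, metastasis, proliferation, and
#' matrix remodeling. Hazards are ordered LPI < IME < IMD < HPI, matching
#' the qualitative prognosis of the subtypes.
#'
#' @param name Subtype label.
#' @param feature_means Named numeric vector of mean z-shifts; names must be
#'   a subset of the registry feature names.
#' @param hazard_os,hazard_rfs Positive relative hazard multipliers.
#' @return `subtype_profile()`: a `tcms_profile`. `subtype_profiles()`: the
#'   default list of four, named LPI/IMD/IME/HPI.
#' @export
subtype_profile <- function(name, feature_means, hazard_os = 1,
                            hazard_rfs = hazard_os) {
  stopifnot(hazard_os > 0, hazard_rfs > 0)
  if (length(feature_means) > 0) stopifnot(!is.null(names(feature_means)))
  structure(list(name = name, feature_means = feature_means,
                 hazard_os = hazard_os, hazard_rfs = hazard_rfs),
            class = "tcms_profile")
}

#' @rdname subtype_profile
#' @export
subtype_profiles <- function() {
  imm_all <- c("CD8_T_cells", "CD4_T_cells", "B_cells", "Tregs", "NK_cells",
               "Macrophages", "T_helper_cells", "M1_macrophages",
               "Dendritic_cells", "Neutrophils", "Myeloid_cells")
  list(
    LPI = subtype_profile("LPI", c(
      GGO_lepidic = 1, solid_micropapillary = -0.6, metastasis = -0.6,
      Tumor_proliferation = -1, Matrix_remodeling = -0.6, EMT = -0.4),
      hazard_os = 0.3, hazard_rfs = 0.3),
    IMD = subtype_profile("IMD", c(
      stats::setNames(rep(-1, length(imm_all)), imm_all),
      GGO_lepidic = -0.5),
      hazard_os = 1.2, hazard_rfs = 1.2),
    IME = subtype_profile("IME", c(
      CD8_T_cells = 1, CD4_T_cells = 0.8, B_cells = 1, NK_cells = 1,
      T_helper_cells = 0.8, M1_macrophages = 0.8, Dendritic_cells = 0.8,
      Tregs = 0.5, Macrophages = 0.5, Neutrophils = 0.3,
      Myeloid_cells = 0.3, GGO_lepidic = -0.5),
      hazard_os = 0.8, hazard_rfs = 0.8),
    HPI = subtype_profile("HPI", c(
      solid_micropapillary = 1, metastasis = 1, Tumor_proliferation = 1,
      Matrix_remodeling = 1, EMT = 0.8, Angiogenesis = 0.6,
      GGO_lepidic = -1, CD8_T_cells = -0.3, B_cells = -0.3,
      NK_cells = -0.3),
      hazard_os = 2.5, hazard_rfs = 2.5)
  )
}

default_event_rates <- function() {
  c(TP53_mut = 0.40, KRAS_mut = 0.25, STK11_mut = 0.15, KEAP1_mut = 0.12,
    DYNC2H1_mut = 0.10, RRM2B_amp = 0.15, VOPP1_amp = 0.12,
    CDKN2A_del = 0.10)
}

default_cooccurrence_pairs <- function() {
  data.frame(a = c("STK11_mut", "RRM2B_amp"),
             b = c("KEAP1_mut", "VOPP1_amp"),
             odds = c(8, 8), stringsAsFactors = FALSE)
}

#' Synthetic cohort generator configuration
#'
#' @param n_samples,n_genes,genes_per_signature Cohort sizing; all positive.
#' @param effect_size Mean z-shift magnitude multiplying the profile
#'   feature means (default 1.5 expression SDs).
#' @param noise_sd Per-gene expression SD on the log2 scale.
#' @param subtype_proportions Length-4 simplex over LPI/IMD/IME/HPI
#'   (must sum to 1 within 1e-9).
#' @param censor_rate Fraction of censored subjects in [0, 1].
#' @param base_rate_os,base_rate_rfs Baseline event rates (events per
#'   time unit, e.g. per month).
#' @param event_rates Named baseline Bernoulli rates for alteration events
#'   (`<gene>_mut`, `<gene>_amp`, `<gene>_del`, `<gene>_fus`).
#' @param cooccurrence_pairs Data frame `a`, `b`, `odds`: pairs whose joint
#'   law is inflated to the stated odds ratio (marginals preserved).
#' @param hotspot_rate Fraction of samples planted hotspot-positive.
#' @param sv_signatures,sv_exposures Optional 32 x r and r x n nonnegative
#'   matrices driving SV generation; defaults are built when `NULL`.
#' @param seed Master integer seed; per-table substreams use fixed offsets.
#' @return A `tcms_generator_config`.
#' @export
generator_config <- function(n_samples = 400, n_genes = 2000,
                             genes_per_signature = 15, effect_size = 1.5,
                             noise_sd = 1,
                             subtype_proportions = c(LPI = 0.25, IMD = 0.25,
                                                     IME = 0.25, HPI = 0.25),
                             censor_rate = 0.3, base_rate_os = 0.01,
                             base_rate_rfs = 0.015,
                             event_rates = default_event_rates(),
                             cooccurrence_pairs = default_cooccurrence_pairs(),
                             hotspot_rate = 0.6,
                             sv_signatures = NULL, sv_exposures = NULL,
                             seed = 1) {
  stopifnot(n_samples > 0, n_genes > 0, genes_per_signature > 0,
            noise_sd >= 0, censor_rate >= 0, censor_rate <= 1,
            length(subtype_proportions) == 4)
  if (abs(sum(subtype_proportions) - 1) > 1e-9) {
    stop("subtype_proportions must sum to 1", call. = FALSE)
  }
  if (is.null(names(subtype_proportions))) {
    names(subtype_proportions) <- tcms_subtype_levels()
  }
  if (!is.null(sv_signatures) && any(sv_signatures < 0)) {
    stop("sv_signatures must be nonnegative", call. = FALSE)
  }
  if (!is.null(sv_exposures) && any(sv_exposures < 0)) {
    stop("sv_exposures must be nonnegative", call. = FALSE)
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 genes_per_signature = as.integer(genes_per_signature),
                 effect_size = effect_size, noise_sd = noise_sd,
                 subtype_proportions = subtype_proportions,
                 censor_rate = censor_rate, base_rate_os = base_rate_os,
                 base_rate_rfs = base_rate_rfs, event_rates = event_rates,
                 cooccurrence_pairs = cooccurrence_pairs,
                 hotspot_rate = hotspot_rate,
                 sv_signatures = sv_signatures, sv_exposures = sv_exposures,
                 seed = as.integer(seed)),
            class = "tcms_generator_config")
}

#' Generate survival data from subtype labels and profiles
#'
#' Event times are exponential with rate `base_rate * hazard multiplier`;
#' censoring is independent: each subject is censored with probability
#' `censor_rate`, and a censored subject's observed time is uniform on
#' (0, T) of its latent event time.
#'
#' @param labels Named vector mapping sample to subtype.
#' @param profiles List of [subtype_profile()]s covering every label.
#' @param base_rate Baseline event rate (events per time unit).
#' @param censor_rate Fraction censored in [0, 1].
#' @param seed Integer seed.
#' @param endpoint Which hazard multiplier to use (`"os"` or `"rfs"`).
#' @return Data frame `sample`, `time`, `event`, `group`.
#' @export
generate_survival <- function(labels, profiles, base_rate = 0.01,
                              censor_rate = 0, seed = 1,
                              endpoint = c("os", "rfs")) {
  endpoint <- match.arg(endpoint)
  labels <- stats::setNames(as.character(labels),
                            names(labels) %||% paste0("S", seq_along(labels)))
  prof_names <- vapply(profiles, `[[`, character(1), "name")
  names(profiles) <- prof_names
  unknown <- setdiff(unique(labels), prof_names)
  if (length(unknown) > 0) {
    stop("no profile for label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  mult <- vapply(profiles, function(p) {
    if (endpoint == "os") p$hazard_os else p$hazard_rfs
  }, numeric(1))
  n <- length(labels)
  withr::with_seed(seed, {
    t_latent <- stats::rexp(n, rate = base_rate * mult[labels])
    ev <- stats::rbinom(n, 1, 1 - censor_rate)
    u <- stats::runif(n)
    time <- ifelse(ev == 1, t_latent, t_latent * u)
  })
  data.frame(sample = names(labels), time = time, event = ev,
             group = unname(labels), stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Joint P(A=1, B=1) for given marginals and odds ratio (marginals fixed).
joint_p11 <- function(pa, pb, odds) {
  if (odds <= 0) stop("odds multiplier must be > 0", call. = FALSE)
  if (odds == 1) return(pa * pb)
  s <- 1 + (pa + pb) * (odds - 1)
  (s - sqrt(s^2 - 4 * odds * (odds - 1) * pa * pb)) / (2 * (odds - 1))
}

# Fixed non-hotspot variant templates for mutation events.
.background_variants <- list(
  TP53 = list(p = "p.R175H", exon = 5L),
  KRAS = list(p = "p.Q61H", exon = 3L),
  STK11 = list(p = "p.D194Y", exon = 4L),
  KEAP1 = list(p = "p.G333C", exon = 3L),
  DYNC2H1 = list(p = "p.R1800W", exon = 12L)
)

.fusion_partners <- c(ALK = "EML4", ROS1 = "CD74", MET = "KIF5B",
                      RET = "CCDC6")

#' Generate alteration tables with planted co-occurrence and hotspots
#'
#' Baseline events are Bernoulli with the configured rates; each
#' co-occurrence pair's joint law is inflated to the stated odds ratio with
#' the marginal frequencies preserved. Samples planted hotspot-positive
#' (probability `hotspot_rate`) receive one variant drawn uniformly from
#' the hotspot rule list, with well-formed protein-change/exon/fusion
#' fields.
#'
#' @param config A [generator_config()].
#' @param labels Named sample -> subtype vector (defines the sample set).
#' @param rules Hotspot rules (default [nccn_hotspot_rules()]).
#' @param seed Integer seed.
#' @return List: `mutations`, `fusions`, `cnv` (genes x samples in -2..2),
#'   `presence` (binary truth matrix events x samples), `hotspot_truth`
#'   (data frame `sample`, `planted`).
#' @export
generate_alterations <- function(config, labels,
                                 rules = nccn_hotspot_rules(), seed = 1) {
  samples <- names(labels) %||% paste0("S", seq_along(labels))
  n <- length(samples)
  rates <- config$event_rates
  pairs <- config$cooccurrence_pairs
  if (!is.null(pairs) && nrow(pairs) > 0) {
    ref <- c(pairs$a, pairs$b)
    unknown <- setdiff(ref, names(rates))
    if (length(unknown) > 0) {
      stop("co-occurrence pair references undefined event(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (anyDuplicated(ref)) {
      stop("an event may appear in at most one co-occurrence pair",
           call. = FALSE)
    }
    if (any(pairs$odds <= 0)) {
      stop("odds multiplier must be > 0", call. = FALSE)
    }
  }
  presence <- matrix(0L, length(rates), n,
                     dimnames = list(names(rates), samples))
  hot <- logical(n)
  mut_rows <- list(); fus_rows <- list()
  withr::with_seed(seed, {
    paired <- if (!is.null(pairs) && nrow(pairs) > 0) c(pairs$a, pairs$b)
              else character(0)
    if (!is.null(pairs) && nrow(pairs) > 0) {
      for (i in seq_len(nrow(pairs))) {
        pa <- rates[[pairs$a[i]]]; pb <- rates[[pairs$b[i]]]
        p11 <- joint_p11(pa, pb, pairs$odds[i])
        pr <- c(p11, pa - p11, pb - p11, 1 - pa - pb + p11)
        cell <- sample.int(4, n, replace = TRUE, prob = pmax(pr, 0))
        presence[pairs$a[i], ] <- as.integer(cell %in% c(1, 2))
        presence[pairs$b[i], ] <- as.integer(cell %in% c(1, 3))
      }
    }
    for (ev in setdiff(names(rates), paired)) {
      presence[ev, ] <- stats::rbinom(n, 1, rates[[ev]])
    }
    hot <- stats::runif(n) < config$hotspot_rate
    hot_rule <- sample.int(nrow(rules), n, replace = TRUE)

    for (j in seq_len(n)) {
      s <- samples[j]
      for (ev in names(rates)[presence[, j] == 1]) {
        gene <- sub("_(mut|amp|del|fus)$", "", ev)
        kind <- sub(".*_", "", ev)
        if (kind == "mut") {
          tmpl <- .background_variants[[gene]] %||%
            list(p = "p.A100V", exon = 5L)
          mut_rows[[length(mut_rows) + 1L]] <- data.frame(
            sample = s, gene = gene, protein_change = tmpl$p,
            exon = tmpl$exon, variant_class = "missense",
            stringsAsFactors = FALSE)
        } else if (kind == "fus") {
          fus_rows[[length(fus_rows) + 1L]] <- data.frame(
            sample = s, gene_a = gene, gene_b = "PARTNER1",
            stringsAsFactors = FALSE)
        }
      }
      if (hot[j]) {
        ru <- rules[hot_rule[j], ]
        if (ru$kind == "fusion") {
          fus_rows[[length(fus_rows) + 1L]] <- data.frame(
            sample = s, gene_a = ru$gene,
            gene_b = unname(.fusion_partners[ru$gene]),
            stringsAsFactors = FALSE)
        } else if (ru$kind == "codon") {
          alt <- if (!is.na(ru$alt_aa)) ru$alt_aa else sample(c("A", "S", "C"), 1)
          mut_rows[[length(mut_rows) + 1L]] <- data.frame(
            sample = s, gene = ru$gene,
            protein_change = sprintf("p.%s%d%s", ru$ref_aa, ru$position, alt),
            exon = ru$exon, variant_class = "missense",
            stringsAsFactors = FALSE)
        } else { # exon_class
          pc <- if (ru$variant_class == "inframe_del") {
            "p.E746_A750del"
          } else if (ru$gene == "EGFR") {
            "p.A767_V769dup"
          } else {
            "p.Y772_A775dup"
          }
          mut_rows[[length(mut_rows) + 1L]] <- data.frame(
            sample = s, gene = ru$gene, protein_change = pc, exon = ru$exon,
            variant_class = ru$variant_class, stringsAsFactors = FALSE)
        }
      }
    }
  })
  empty_mut <- data.frame(sample = character(0), gene = character(0),
                          protein_change = character(0), exon = integer(0),
                          variant_class = character(0),
                          stringsAsFactors = FALSE)
  empty_fus <- data.frame(sample = character(0), gene_a = character(0),
                          gene_b = character(0), stringsAsFactors = FALSE)
  mutations <- if (length(mut_rows) > 0) do.call(rbind, mut_rows) else empty_mut
  fusions <- if (length(fus_rows) > 0) do.call(rbind, fus_rows) else empty_fus

  cnv_events <- grep("_(amp|del)$", names(rates), value = TRUE)
  cnv_genes <- unique(sub("_(amp|del)$", "", cnv_events))
  cnv <- matrix(0L, length(cnv_genes), n,
                dimnames = list(cnv_genes, samples))
  for (ev in cnv_events) {
    gene <- sub("_(amp|del)$", "", ev)
    val <- if (grepl("_amp$", ev)) 2L else -2L
    cnv[gene, presence[ev, ] == 1] <- val
  }
  list(mutations = mutations, fusions = fusions, cnv = cnv,
       presence = presence,
       hotspot_truth = data.frame(sample = samples, planted = hot,
                                  stringsAsFactors = FALSE))
}

#' Simplified genome model (22 autosomes, hg38-like lengths)
#'
#' @return Data frame `chrom`, `length` (bp).
#' @export
default_genome <- function() {
  data.frame(
    chrom = paste0("chr", 1:22),
    length = c(248956422, 242193529, 198295559, 190214555, 181538259,
               170805979, 159345973, 145138636, 138394717, 133797422,
               135086622, 133275309, 114364328, 107043718, 101991189,
               90338345, 83257441, 80373285, 58617616, 64444167,
               46709983, 50818468),
    stringsAsFactors = FALSE
  )
}

#' Default planted SV signatures
#'
#' Three column-normalized 32-vectors: small non-clustered deletions /
#' duplications; large non-clustered inversions and translocations; and a
#' clustered mixed signature.
#'
#' @return 32 x 3 matrix, columns summing to 1.
#' @export
default_sv_signatures <- function() {
  nm <- sv_category_names()
  s <- matrix(0, 32, 3, dimnames = list(nm, paste0("TRUE", 1:3)))
  s[c("non-clustered:DEL:1-10Kb", "non-clustered:DEL:10-100Kb",
      "non-clustered:DUP:1-10Kb", "non-clustered:DUP:10-100Kb"), 1] <-
    c(0.4, 0.3, 0.2, 0.1)
  s[c("non-clustered:INV:1Mb-10Mb", "non-clustered:INV:>10Mb",
      "non-clustered:TRA", "non-clustered:DEL:100Kb-1Mb"), 2] <-
    c(0.3, 0.2, 0.35, 0.15)
  s[c("clustered:DEL:1-10Kb", "clustered:DUP:10-100Kb",
      "clustered:INV:100Kb-1Mb", "clustered:TRA"), 3] <-
    c(0.35, 0.25, 0.2, 0.2)
  s
}

# Size bounds per bin index (generation draws log-uniform within the bin;
# the top bin is capped for placement feasibility).
.sv_bin_bounds <- cbind(lo = c(1e3, 1e4, 1e5, 1e6, 1e7),
                        hi = c(1e4, 1e5, 1e6, 1e7, 5e7))

#' Generate SV events from planted signatures and exposures
#'
#' Per-sample category counts are Poisson with mean `signatures %*%
#' exposures`. Each event gets a size drawn log-uniformly inside its
#' category's bin, and breakpoint positions laid out to respect its
#' clustered / non-clustered status under the classifier's own adaptive
#' distance rule: non-clustered breakpoints are spread with stratified
#' spacing along chromosomes, clustered events are grouped into tight clumps
#' placed pairwise on chromosomes.
#'
#' @param sv_signatures 32 x r nonnegative matrix in canonical category
#'   order.
#' @param sv_exposures r x n nonnegative matrix; column names become sample
#'   ids.
#' @param genome Chromosome-length table (default [default_genome()]).
#' @param seed Integer seed.
#' @param cluster_factor The classifier's clustering divisor (shared rule).
#' @return SV record data frame: `sample`, `type`, `chrom1`, `pos1`,
#'   `chrom2`, `pos2`, `truth_category` (index into [sv_category_names()]).
#' @export
generate_sv_events <- function(sv_signatures, sv_exposures,
                               genome = default_genome(), seed = 1,
                               cluster_factor = 10) {
  stopifnot(is.matrix(sv_signatures), is.matrix(sv_exposures))
  if (nrow(sv_signatures) != 32) {
    stop("sv_signatures must have 32 rows in canonical category order",
         call. = FALSE)
  }
  if (any(sv_signatures < 0) || any(sv_exposures < 0)) {
    stop("signature and exposure matrices must be nonnegative", call. = FALSE)
  }
  if (ncol(sv_signatures) != nrow(sv_exposures)) {
    stop("signature / exposure dimension mismatch", call. = FALSE)
  }
  n <- ncol(sv_exposures)
  samples <- colnames(sv_exposures) %||% paste0("S", seq_len(n))
  M <- sv_signatures %*% sv_exposures
  cat_names <- sv_category_names()
  # decode category -> (clustered, type, bin)
  cat_clustered <- rep(c(FALSE, TRUE), each = 16)
  cat_type <- rep(c(rep(c("DEL", "DUP", "INV"), each = 5), "TRA"), 2)
  cat_bin <- rep(c(rep(1:5, 3), NA), 2)

  all_rows <- list()
  withr::with_seed(seed, {
    counts <- matrix(stats::rpois(32 * n, as.vector(M)), 32, n)
    for (j in seq_len(n)) {
      cj <- counts[, j]
      if (sum(cj) == 0) next
      ev <- data.frame(category = rep(seq_len(32), cj))
      ev$type <- cat_type[ev$category]
      ev$clustered <- cat_clustered[ev$category]
      ev$bin <- cat_bin[ev$category]
      ev$size <- NA_real_
      intra <- ev$type != "TRA"
      if (any(intra)) {
        b <- ev$bin[intra]
        ev$size[intra] <- 10^stats::runif(sum(intra),
                                          log10(.sv_bin_bounds[b, "lo"]),
                                          log10(.sv_bin_bounds[b, "hi"]))
      }
      rec <- place_sv_sample(ev, genome)
      rec$sample <- samples[j]
      all_rows[[length(all_rows) + 1L]] <- rec
    }
  })
  if (length(all_rows) == 0) {
    return(data.frame(sample = character(0), type = character(0),
                      chrom1 = character(0), pos1 = numeric(0),
                      chrom2 = character(0), pos2 = numeric(0),
                      truth_category = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, all_rows)
  rownames(out) <- NULL
  out[, c("sample", "type", "chrom1", "pos1", "chrom2", "pos2",
          "truth_category")]
}

# Lay out one sample's events on the genome. Non-clustered items (intra
# events and each TRA breakpoint) are spread along chromosomes with
# stratified spacing, which keeps every inter-record breakpoint distance
# well above the classifier's adaptive threshold. Clustered events are
# grouped into clumps of ~4 with all anchor breakpoints inside a window of
# length / 1000, two clumps per chromosome, which keeps within-clump
# distances well below it.
place_sv_sample <- function(ev, genome) {
  L <- stats::setNames(genome$length, genome$chrom)
  items <- list() # per chromosome: data.frame(event, side, footprint)
  for (ch in genome$chrom) items[[ch]] <- NULL
  ev$chrom1 <- NA_character_; ev$pos1 <- NA_real_
  ev$chrom2 <- NA_character_; ev$pos2 <- NA_real_

  add_item <- function(ch, event, side, footprint) {
    items[[ch]] <<- rbind(items[[ch]],
                          data.frame(event = event, side = side,
                                     footprint = footprint))
  }
  cap <- 0.6 * L
  used <- stats::setNames(rep(0, length(L)), names(L))
  pick_chrom <- function(footprint, min_len = 0) {
    ok <- which(L >= pmax(footprint / 0.4, min_len) &
                  (cap - used) >= footprint)
    if (length(ok) == 0) stop("genome too small for SV load", call. = FALSE)
    ch <- names(L)[sample(ok, 1, prob = L[ok])]
    used[ch] <<- used[ch] + footprint
    ch
  }

  nc <- which(!ev$clustered)
  for (i in sample(nc)) {
    if (ev$type[i] == "TRA") {
      ch1 <- pick_chrom(0)
      repeat {
        ch2 <- pick_chrom(0)
        if (ch2 != ch1) break
      }
      add_item(ch1, i, 1L, 0)
      add_item(ch2, i, 2L, 0)
    } else {
      ch <- pick_chrom(ev$size[i])
      add_item(ch, i, 0L, ev$size[i]) # side 0 = both breakpoints
    }
  }

  cl <- which(ev$clustered)
  if (length(cl) > 0) {
    cl <- sample(cl)
    n_clumps <- max(1L, ceiling(length(cl) / 4))
    clump_of <- rep(seq_len(n_clumps), length.out = length(cl))
    # merge singleton clumps so every clump has >= 2 events when possible
    if (length(cl) >= 2) {
      tb <- table(clump_of)
      for (cid in names(tb)[tb == 1]) {
        clump_of[clump_of == as.integer(cid)] <-
          as.integer(names(tb)[tb > 1][1]) %||% clump_of[1]
      }
    }
    clump_ids <- unique(clump_of)
    big <- vapply(clump_ids, function(cid) {
      sz <- ev$size[cl[clump_of == cid]]
      max(c(sz, 0), na.rm = TRUE)
    }, numeric(1))
    # two clumps per chromosome, large chromosomes for large events
    n_ch <- ceiling(length(clump_ids) / 2)
    ord <- order(-big)
    ch_pool <- names(sort(L, decreasing = TRUE))[seq_len(min(n_ch, length(L)))]
    centers <- c(0.3, 0.7)
    for (k in seq_along(ord)) {
      cid <- clump_ids[ord[k]]
      ch <- ch_pool[((k - 1) %% length(ch_pool)) + 1L]
      ctr <- centers[((k - 1) %/% length(ch_pool)) %% 2 + 1L] * L[ch]
      w <- L[ch] / 1000
      for (i in cl[clump_of == cid]) {
        anchor <- ctr + stats::runif(1, -w / 2, w / 2)
        if (ev$type[i] == "TRA") {
          ev$chrom1[i] <- ch
          ev$pos1[i] <- round(anchor)
          repeat {
            ch2 <- sample(names(L), 1, prob = L)
            if (ch2 != ch) break
          }
          ev$chrom2[i] <- ch2
          ev$pos2[i] <- round(stats::runif(1, 1, L[ch2]))
        } else {
          size <- min(ev$size[i], 0.25 * L[ch])
          if (anchor + size >= L[ch]) anchor <- L[ch] - size - 1
          ev$chrom1[i] <- ev$chrom2[i] <- ch
          ev$pos1[i] <- round(anchor)
          ev$pos2[i] <- round(anchor + size)
        }
      }
    }
  }

  for (ch in names(items)) {
    it <- items[[ch]]
    if (is.null(it) || nrow(it) == 0) next
    k <- nrow(it)
    free <- L[ch] - sum(it$footprint)
    g <- free / (k + 1)
    it <- it[sample.int(k), , drop = FALSE]
    cursor <- 0
    for (r in seq_len(k)) {
      cursor <- cursor + g * stats::runif(1, 0.5, 1)
      i <- it$event[r]
      if (it$side[r] == 1L) {
        ev$chrom1[i] <- ch; ev$pos1[i] <- round(cursor)
      } else if (it$side[r] == 2L) {
        ev$chrom2[i] <- ch; ev$pos2[i] <- round(cursor)
      } else {
        ev$chrom1[i] <- ev$chrom2[i] <- ch
        ev$pos1[i] <- round(cursor)
        ev$pos2[i] <- round(cursor + ev$size[i])
        cursor <- cursor + ev$size[i]
      }
    }
  }
  # guard against rounding-induced zero sizes
  intra <- ev$type != "TRA"
  zero <- intra & ev$pos2 == ev$pos1
  ev$pos2[zero] <- ev$pos1[zero] + 1
  data.frame(type = ev$type, chrom1 = ev$chrom1, pos1 = ev$pos1,
             chrom2 = ev$chrom2, pos2 = ev$pos2,
             truth_category = ev$category, stringsAsFactors = FALSE)
}

#' Generate a complete synthetic bulk cohort
#'
#' Samples subtype labels from the configured proportions, plants the
#' subtype score profiles into signature-member genes (mean = baseline +
#' `effect_size * profile$feature_means[f]`, Gaussian noise on the log2
#' scale), and generates matching clinical, alteration, and SV tables. All
#' tables share the sample identifiers and are deterministic given the
#' config seed.
#'
#' @param config A [generator_config()].
#' @param registry Signature registry defining the feature gene sets.
#' @param profiles Subtype profiles (default [subtype_profiles()]).
#' @param baseline Baseline log2 expression level (default 5).
#' @return Object of class `tcms_cohort`: `expression` (genes x samples),
#'   `truth_labels`, `clinical`, `mutations`, `fusions`, `cnv`, `svs`,
#'   `hotspot_truth`, `config`.
#' @export
generate_bulk_cohort <- function(config, registry,
                                 profiles = subtype_profiles(),
                                 baseline = 5) {
  stopifnot(inherits(config, "tcms_generator_config"),
            inherits(registry, "tcms_registry"))
  sets <- registry_gene_sets(registry)
  sig_genes <- unlist(sets, use.names = FALSE)
  if (anyDuplicated(sig_genes)) {
    stop("registry gene sets overlap; generator requires disjoint sets",
         call. = FALSE)
  }
  if (config$n_genes < length(sig_genes)) {
    stop("n_genes (", config$n_genes, ") below total signature genes (",
         length(sig_genes), ")", call. = FALSE)
  }
  n <- config$n_samples
  samples <- sprintf("S%04d", seq_len(n))
  prof_names <- vapply(profiles, `[[`, character(1), "name")
  names(profiles) <- prof_names

  labels <- withr::with_seed(config$seed + .seed_offsets[["labels"]], {
    idx <- sample.int(4, n, replace = TRUE,
                      prob = config$subtype_proportions)
    names(config$subtype_proportions)[idx]
  })
  names(labels) <- samples

  n_bg <- config$n_genes - length(sig_genes)
  genes <- c(sig_genes, if (n_bg > 0) sprintf("BG_%05d", seq_len(n_bg)))
  mu <- matrix(baseline, config$n_genes, n, dimnames = list(genes, samples))
  for (f in names(sets)) {
    shift <- vapply(labels, function(l) {
      fm <- profiles[[l]]$feature_means
      config$effect_size * (if (f %in% names(fm)) fm[[f]] else 0)
    }, numeric(1))
    mu[sets[[f]], ] <- rep(baseline + shift, each = length(sets[[f]]))
  }
  expression <- withr::with_seed(config$seed + .seed_offsets[["expression"]], {
    mu + matrix(stats::rnorm(length(mu), 0, config$noise_sd),
                nrow(mu), ncol(mu))
  })
  dimnames(expression) <- dimnames(mu)

  os <- generate_survival(labels, profiles, config$base_rate_os,
                          config$censor_rate,
                          config$seed + .seed_offsets[["os"]], "os")
  rfs <- generate_survival(labels, profiles, config$base_rate_rfs,
                           config$censor_rate,
                           config$seed + .seed_offsets[["rfs"]], "rfs")
  stage_info <- withr::with_seed(config$seed + .seed_offsets[["stage"]], {
    stage <- vapply(labels, function(l) {
      switch(l,
             LPI = sample(c("AIS", "MIA", "IA", "IB"), 1,
                          prob = c(0.25, 0.25, 0.3, 0.2)),
             IMD = sample(c("IA", "IB", "II", "III"), 1,
                          prob = c(0.3, 0.3, 0.25, 0.15)),
             IME = sample(c("IA", "IB", "II", "III"), 1,
                          prob = c(0.25, 0.25, 0.3, 0.2)),
             HPI = sample(c("IB", "II", "III", "IV"), 1,
                          prob = c(0.1, 0.3, 0.4, 0.2)))
    }, character(1))
    adj_p <- ifelse(stage %in% c("II", "III", "IV"), 0.7, 0.2)
    list(stage = stage, adjuvant = stats::rbinom(n, 1, adj_p))
  })
  clinical <- data.frame(
    sample = samples, subtype = unname(labels),
    os_time = os$time, os_event = os$event,
    rfs_time = rfs$time, rfs_event = rfs$event,
    stage = unname(stage_info$stage), relapse = rfs$event,
    adjuvant = stage_info$adjuvant, stringsAsFactors = FALSE
  )

  alt <- generate_alterations(config, labels,
                              seed = config$seed + .seed_offsets[["alterations"]])

  sig <- config$sv_signatures %||% default_sv_signatures()
  expo <- config$sv_exposures
  if (is.null(expo)) {
    expo <- withr::with_seed(config$seed + .seed_offsets[["sv"]] + 1L, {
      e <- matrix(stats::rgamma(ncol(sig) * n, shape = 2, rate = 0.2),
                  ncol(sig), n)
      colnames(e) <- samples
      e
    })
  }
  svs <- generate_sv_events(sig, expo, seed = config$seed +
                              .seed_offsets[["sv"]])

  structure(list(expression = expression, truth_labels = labels,
                 clinical = clinical, mutations = alt$mutations,
                 fusions = alt$fusions, cnv = alt$cnv, svs = svs,
                 presence = alt$presence,
                 hotspot_truth = alt$hotspot_truth, config = config),
            class = "tcms_cohort")
}

#' @export
print.tcms_cohort <- function(x, ...) {
  cat(sprintf("<tcms_cohort> %d samples, %d genes, %d SVs\n",
              ncol(x$expression), nrow(x$expression), nrow(x$svs)))
  print(table(x$truth_labels))
  invisible(x)
}

#' Generate a synthetic single-cell count matrix
#'
#' Negative-binomial counts with cell-type marker genes overexpressed in
#' their own type. Controllable fractions of low-quality cells (globally
#' depressed expression, hence few detected genes) and high-mitochondrial
#' cells support QC round-trip testing.
#'
#' @param n_cells,n_genes Matrix dimensions (genes include markers, mito
#'   genes, and background).
#' @param type_markers Named list: cell type -> marker genes (non-empty,
#'   disjoint from `mito_genes`).
#' @param mito_genes Mitochondrial gene names.
#' @param seed Integer seed.
#' @param base_mu Baseline NB mean per gene (default 1.5).
#' @param marker_fold Fold overexpression of markers in their type.
#' @param nb_size NB size (dispersion) parameter.
#' @param frac_low_quality Fraction of cells with expression scaled by 0.1.
#' @param frac_high_mito Fraction of cells with mitochondrial means
#'   inflated 12-fold (mito fraction ~ 20%).
#' @return List: `counts` (cells x genes integer matrix), `labels` (cell
#'   types), `mito_genes`, `flags` (data frame of planted low-quality /
#'   high-mito flags).
#' @export
generate_single_cell <- function(n_cells = 600, n_genes = 400,
                                 type_markers = default_cell_markers(),
                                 mito_genes = default_mito_genes(),
                                 seed = 1, base_mu = 1.5, marker_fold = 8,
                                 nb_size = 2, frac_low_quality = 0,
                                 frac_high_mito = 0) {
  if (length(type_markers) == 0) {
    stop("empty marker map", call. = FALSE)
  }
  markers <- unlist(type_markers, use.names = FALSE)
  if (length(intersect(markers, mito_genes)) > 0) {
    stop("marker sets must be disjoint from mitochondrial genes",
         call. = FALSE)
  }
  named_genes <- c(markers, mito_genes)
  if (n_genes < length(named_genes)) {
    stop("n_genes below the number of marker + mito genes", call. = FALSE)
  }
  genes <- c(named_genes,
             sprintf("BG_%04d", seq_len(n_genes - length(named_genes))))
  types <- names(type_markers)
  withr::with_seed(seed, {
    labels <- sample(types, n_cells, replace = TRUE)
    low_q <- stats::runif(n_cells) < frac_low_quality
    hi_m <- !low_q & stats::runif(n_cells) < frac_high_mito /
      max(1 - frac_low_quality, 1e-9)
    mu <- matrix(base_mu, n_cells, n_genes, dimnames = list(NULL, genes))
    for (ty in types) {
      mu[labels == ty, type_markers[[ty]]] <- base_mu * marker_fold
    }
    mu[, mito_genes] <- base_mu
    mu[hi_m, mito_genes] <- base_mu * 12
    mu[low_q, ] <- mu[low_q, ] * 0.1
    counts <- matrix(stats::rnbinom(n_cells * n_genes, mu = as.vector(mu),
                                    size = nb_size),
                     n_cells, n_genes)
  })
  dimnames(counts) <- list(sprintf("cell_%04d", seq_len(n_cells)), genes)
  list(counts = counts, labels = labels, mito_genes = mito_genes,
       flags = data.frame(cell = rownames(counts), low_quality = low_q,
                          high_mito = hi_m, stringsAsFactors = FALSE))
}

#' @rdname generate_single_cell
#' @export
default_cell_markers <- function() {
  list(
    CD8_T = c("CD8A", "CD8B", "CD3D", "CD2"),
    B = c("CD19", "CD79A", "MS4A1"),
    NK = c("NKG7", "KLRD1", "GNLY"),
    Macrophage = c("CD68", "AIF1", "LYZ"),
    Epithelial = c("SFTPC", "AGER", "EPCAM")
  )
}

#' @rdname generate_single_cell
#' @export
default_mito_genes <- function() {
  paste0("MT-", c("CO1", "CO2", "CO3", "ND1", "ND2", "ND3", "ND4", "CYB",
                  "ATP6", "ATP8"))
}

#' Write a synthetic cohort as plain-text tables
#'
#' Emits `expression.tsv`, `clinical.tsv`, `mutations.maf.tsv`,
#' `fusions.tsv`, `cnv.tsv`, `svs.bedpe.tsv`, and `truth.tsv` into a
#' directory.
#'
#' @param cohort A `tcms_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "tcms_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(x, f) {
    utils::write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  write_matrix_tsv(cohort$expression, file.path(dir, "expression.tsv"))
  wt(cohort$clinical, "clinical.tsv")
  wt(cohort$mutations, "mutations.maf.tsv")
  wt(cohort$fusions, "fusions.tsv")
  write_matrix_tsv(cohort$cnv, file.path(dir, "cnv.tsv"))
  write_bedpe(cohort$svs, file.path(dir, "svs.bedpe.tsv"))
  wt(data.frame(sample = names(cohort$truth_labels),
                subtype = unname(cohort$truth_labels)), "truth.tsv")
  invisible(dir)
}
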