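#' NCCN hotspot rule set
#'
#' A rule is one of three kinds:
#' \describe{
#'   \item{codon}{gene + protein position + reference amino acid, optionally
#'     restricted to a specific alternate amino acid and/or exon; matches
#'     missense records whose HGVS short protein change parses to that codon.}
#'   \item{exon_class}{gene + exon + variant class (e.g. exon 19 inframe
#'     deletions).}
#'   \item{fusion}{gene; matches a fusion record on either partner.}
#' }
#' `nccn_hotspot_rules()` returns the default actionable-driver list (NCCN
#' v5.2022): EGFR exon 18 G719, exon 19 deletions, exon 20 insertions, exon
#' 20 S768I, exon 21 L858R, L861Q; KRAS G12C; BRAF V600E; ERBB2 exon 20
#' insertions; and fusions of ALK, ROS1, MET, RET. MET exon-14 skipping is
#' deliberately not included.
#'
#' @return Data frame of class `tcms_hotspot_rules` with columns `rule_id`,
#'   `kind`, `gene`, `position`, `ref_aa`, `alt_aa`, `exon`, `variant_class`.
#' @export
nccn_hotspot_rules <- function() {
  r <- function(kind, gene, position = NA, ref_aa = NA, alt_aa = NA,
                exon = NA, variant_class = NA) {
    data.frame(kind = kind, gene = gene, position = as.integer(position),
               ref_aa = as.character(ref_aa), alt_aa = as.character(alt_aa),
               exon = as.integer(exon),
               variant_class = as.character(variant_class),
               stringsAsFactors = FALSE)
  }
  rules <- rbind(
    r("codon", "EGFR", 719, "G", NA, 18),
    r("exon_class", "EGFR", exon = 19, variant_class = "inframe_del"),
    r("exon_class", "EGFR", exon = 20, variant_class = "inframe_ins"),
    r("codon", "EGFR", 768, "S", "I", 20),
    r("codon", "EGFR", 858, "L", "R", 21),
    r("codon", "EGFR", 861, "L", "Q"),
    r("codon", "KRAS", 12, "G", "C"),
    r("codon", "BRAF", 600, "V", "E"),
    r("exon_class", "ERBB2", exon = 20, variant_class = "inframe_ins"),
    r("fusion", "ALK"),
    r("fusion", "ROS1"),
    r("fusion", "MET"),
    r("fusion", "RET")
  )
  rules$rule_id <- sprintf("R%02d", seq_len(nrow(rules)))
  class(rules) <- c("tcms_hotspot_rules", "data.frame")
  rules
}

#' Parse an HGVS short-form missense protein change
#'
#' Accepts only `p.`-prefixed single-letter forms like `p.L858R`. Anything
#' else (deletions, insertions, malformed strings) returns `NA` fields.
#'
#' @param p Character vector of protein changes.
#' @return Data frame with `ref_aa`, `position`, `alt_aa` (NA when
#'   unparseable as missense).
#' @export
parse_protein_change <- function(p) {
  m <- regmatches(p, regexec("^p\\.([A-Z])([0-9]+)([A-Z])$", as.character(p)))
  ref <- vapply(m, function(x) if (length(x) == 4) x[2] else NA_character_,
                character(1))
  pos <- vapply(m, function(x) if (length(x) == 4) as.integer(x[3]) else NA_integer_,
                integer(1))
  alt <- vapply(m, function(x) if (length(x) == 4) x[4] else NA_character_,
                character(1))
  data.frame(ref_aa = ref, position = pos, alt_aa = alt,
             stringsAsFactors = FALSE)
}

#' Call NCCN hotspot status for one sample
#'
#' A sample is hotspot-positive iff at least one rule matches one of its
#' alteration records. Missense records whose protein change cannot be parsed
#' are skipped with a warning, never silently matched. ERBB2 exon-20 events
#' that are not insertions are reported via message (they do not match).
#'
#' @param mutations Data frame of the sample's mutations with columns `gene`,
#'   `protein_change`, `exon`, `variant_class` (missense | inframe_del |
#'   inframe_ins | other).
#' @param fusions Data frame of the sample's fusions with columns `gene_a`,
#'   `gene_b`.
#' @param rules A `tcms_hotspot_rules` (default [nccn_hotspot_rules()]).
#' @return List with `status` (`"positive"` or `"negative"`) and `matches`
#'   (data frame of matched rule ids and the matching record index).
#' @export
call_hotspot_status <- function(mutations = NULL, fusions = NULL,
                                rules = nccn_hotspot_rules()) {
  matches <- data.frame(rule_id = character(0), record = integer(0),
                        source = character(0), stringsAsFactors = FALSE)
  if (!is.null(mutations) && nrow(mutations) > 0) {
    parsed <- parse_protein_change(mutations$protein_change)
    bad <- mutations$variant_class == "missense" & is.na(parsed$position)
    if (any(bad)) {
      warning(sum(bad), " missense record(s) with unparseable protein ",
              "change skipped", call. = FALSE)
    }
    odd_erbb2 <- mutations$gene == "ERBB2" &
      !is.na(mutations$exon) & mutations$exon == 20L &
      mutations$variant_class != "inframe_ins"
    if (any(odd_erbb2)) {
      message(sum(odd_erbb2), " ERBB2 exon-20 non-insertion event(s) ",
              "observed; not counted as hotspot")
    }
    for (i in seq_len(nrow(rules))) {
      ru <- rules[i, ]
      hit <- switch(
        ru$kind,
        codon = {
          ok <- mutations$gene == ru$gene &
            mutations$variant_class == "missense" &
            !is.na(parsed$position) &
            parsed$position == ru$position &
            parsed$ref_aa == ru$ref_aa
          if (!is.na(ru$alt_aa)) ok <- ok & parsed$alt_aa == ru$alt_aa
          if (!is.na(ru$exon)) {
            ok <- ok & !is.na(mutations$exon) & mutations$exon == ru$exon
          }
          ok
        },
        exon_class = {
          mutations$gene == ru$gene &
            !is.na(mutations$exon) & mutations$exon == ru$exon &
            mutations$variant_class == ru$variant_class
        },
        rep(FALSE, nrow(mutations))
      )
      hit[is.na(hit)] <- FALSE
      if (any(hit)) {
        matches <- rbind(matches, data.frame(
          rule_id = ru$rule_id, record = which(hit), source = "mutation",
          stringsAsFactors = FALSE))
      }
    }
  }
  if (!is.null(fusions) && nrow(fusions) > 0) {
    fr <- rules[rules$kind == "fusion", , drop = FALSE]
    for (i in seq_len(nrow(fr))) {
      hit <- fusions$gene_a == fr$gene[i] | fusions$gene_b == fr$gene[i]
      hit[is.na(hit)] <- FALSE
      if (any(hit)) {
        matches <- rbind(matches, data.frame(
          rule_id = fr$rule_id[i], record = which(hit), source = "fusion",
          stringsAsFactors = FALSE))
      }
    }
  }
  list(status = if (nrow(matches) > 0) "positive" else "negative",
       matches = matches)
}

#' Call hotspot status for every sample of a cohort
#'
#' @param samples Character vector of sample ids to call (samples with no
#'   records are negative).
#' @param mutations,fusions Cohort-level tables with a `sample` column (may
#'   be `NULL` or empty).
#' @inheritParams call_hotspot_status
#' @return Data frame with `sample`, `status`, `n_matches`.
#' @export
hotspot_status <- function(samples, mutations = NULL, fusions = NULL,
                           rules = nccn_hotspot_rules()) {
  res <- lapply(samples, function(s) {
    mu <- if (!is.null(mutations)) {
      mutations[mutations$sample == s, , drop = FALSE]
    }
    fu <- if (!is.null(fusions)) {
      fusions[fusions$sample == s, , drop = FALSE]
    }
    call_hotspot_status(mu, fu, rules)
  })
  data.frame(
    sample = samples,
    status = vapply(res, `[[`, character(1), "status"),
    n_matches = vapply(res, function(x) nrow(x$matches), integer(1)),
    stringsAsFactors = FALSE
  )
}
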