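#' Exact two-sided Fisher p-value for a 2x2 table
#'
#' Conditional on both margins, the count in the top-left cell follows a
#' hypergeometric law; the two-sided p-value is the sum of the probabilities
#' of all tables (with the same margins) no more likely than the observed
#' one, with a small relative tolerance on the comparison against the
#' observed probability (the convention of `stats::fisher.test`).
#'
#' @param a,b,c,d Cell counts: `a` = both events, `b` = A only, `c` = B
#'   only, `d` = neither.
#' @return The exact two-sided p-value.
#' @export
fisher_exact_p <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m_a <- a + b       # samples with event A
  m_b <- a + c       # samples with event B
  n <- a + b + c + d
  lo <- max(0L, m_a + m_b - n)
  hi <- min(m_a, m_b)
  support <- lo:hi
  dens <- stats::dhyper(support, m_b, n - m_b, m_a)
  p_obs <- stats::dhyper(a, m_b, n - m_b, m_a)
  sum(dens[dens <= p_obs * (1 + 1e-7)])
}

# Sample odds ratio with exact 0 / Inf handling (no Haldane correction).
sample_odds_ratio <- function(a, b, c, d) {
  num <- a * d
  den <- b * c
  if (den == 0) {
    if (num == 0) NaN else Inf
  } else {
    num / den
  }
}

#' Pairwise co-occurrence / mutual-exclusivity testing
#'
#' For every pair of events in a binary presence matrix, builds the 2x2
#' table over samples, computes the exact two-sided Fisher p, the sample
#' odds ratio (0 and Inf reported exactly), and the direction: co-occurrent
#' (OR > 1), exclusive (OR < 1), or none. BH adjustment is applied across
#' all testable pairs. Constant events (all present or all absent) are
#' untestable: such pairs are reported with direction `none`, `NA` p, and a
#' note.
#'
#' @param events Binary events x samples matrix with rownames.
#' @return Data frame with one row per event pair: `event_a`, `event_b`,
#'   `n_both`, `n_a_only`, `n_b_only`, `n_neither`, `odds_ratio`, `p`,
#'   `p_adj`, `direction`, `note`.
#' @export
pairwise_association <- function(events) {
  stopifnot(is.matrix(events), !is.null(rownames(events)), ncol(events) >= 1)
  if (!all(events %in% c(0, 1))) {
    stop("events matrix must be binary", call. = FALSE)
  }
  ev <- rownames(events)
  if (length(ev) < 2) stop("need at least 2 events", call. = FALSE)
  pairs <- utils::combn(length(ev), 2)
  n <- ncol(events)
  rs <- rowSums(events)
  out <- vector("list", ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    a <- sum(events[i1, ] == 1 & events[i2, ] == 1)
    b <- sum(events[i1, ] == 1 & events[i2, ] == 0)
    cc <- sum(events[i1, ] == 0 & events[i2, ] == 1)
    d <- n - a - b - cc
    constant <- rs[i1] %in% c(0, n) || rs[i2] %in% c(0, n)
    if (constant) {
      out[[j]] <- data.frame(
        event_a = ev[i1], event_b = ev[i2], n_both = a, n_a_only = b,
        n_b_only = cc, n_neither = d, odds_ratio = NA_real_, p = NA_real_,
        direction = "none", note = "constant event: association undefined",
        stringsAsFactors = FALSE)
    } else {
      or <- sample_odds_ratio(a, b, cc, d)
      dir <- if (is.nan(or) || or == 1) {
        "none"
      } else if (or > 1) "co-occurrent" else "exclusive"
      out[[j]] <- data.frame(
        event_a = ev[i1], event_b = ev[i2], n_both = a, n_a_only = b,
        n_b_only = cc, n_neither = d, odds_ratio = or,
        p = fisher_exact_p(a, b, cc, d), direction = dir, note = "",
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res[, c("event_a", "event_b", "n_both", "n_a_only", "n_b_only",
          "n_neither", "odds_ratio", "p", "p_adj", "direction", "note")]
}

#' Compare event frequencies between two sample groups
#'
#' Per event, an exact Fisher test on the 2x2 table (event present/absent x
#' group), as used for group-wise mutation-frequency comparisons between
#' subtypes.
#'
#' @param events Binary events x samples matrix with dimnames.
#' @param group_a,group_b Disjoint non-empty character vectors of sample ids
#'   (columns of `events`).
#' @return Data frame with `event`, `n_a`, `n_b`, `freq_a`, `freq_b`,
#'   `odds_ratio`, `p`, `p_adj`, `note`. Events absent (or fixed) in both
#'   groups get p = 1 and odds ratio 1 with a note.
#' @export
compare_event_frequencies <- function(events, group_a, group_b) {
  stopifnot(is.matrix(events), !is.null(colnames(events)))
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("empty group", call. = FALSE)
  }
  if (length(intersect(group_a, group_b)) > 0) {
    stop("groups must be disjoint", call. = FALSE)
  }
  miss <- setdiff(c(group_a, group_b), colnames(events))
  if (length(miss) > 0) {
    stop("samples not in event matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ea <- events[, group_a, drop = FALSE]
  eb <- events[, group_b, drop = FALSE]
  na <- length(group_a); nb <- length(group_b)
  res <- lapply(rownames(events), function(evn) {
    a <- sum(ea[evn, ] == 1)   # mutated in A
    b <- na - a                # wild in A
    cc <- sum(eb[evn, ] == 1)  # mutated in B
    d <- nb - cc
    if ((a + cc) == 0 || (b + d) == 0) {
      data.frame(event = evn, n_a = a, n_b = cc, freq_a = a / na,
                 freq_b = cc / nb, odds_ratio = 1, p = 1,
                 note = "event constant across both groups",
                 stringsAsFactors = FALSE)
    } else {
      # table: rows = group A / group B, cols = mutated / wild
      data.frame(event = evn, n_a = a, n_b = cc, freq_a = a / na,
                 freq_b = cc / nb,
                 odds_ratio = sample_odds_ratio(a, b, cc, d),
                 p = fisher_exact_p(a, b, cc, d), note = "",
                 stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, res)
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res[, c("event", "n_a", "n_b", "freq_a", "freq_b", "odds_ratio", "p",
          "p_adj", "note")]
}

#' Binary amplification / deletion events from a thresholded CNV matrix
#'
#' Consumes GISTIC-style gene-level integer calls in -2..2: amplification
#' events are value 2, deep deletions value -2 (values +/-1 are shallow and
#' do not count).
#'
#' @param cnv Integer genes x samples matrix with values in -2..2.
#' @param genes Genes of interest (default: all rows).
#' @param drop_empty Drop event rows with no occurrences (default TRUE).
#' @return Binary events x samples matrix with rownames `<gene>_amp` /
#'   `<gene>_del`.
#' @export
cnv_gene_events <- function(cnv, genes = rownames(cnv), drop_empty = TRUE) {
  stopifnot(is.matrix(cnv), !is.null(rownames(cnv)))
  if (!all(cnv %in% -2:2)) {
    stop("CNV values must be integers in -2..2", call. = FALSE)
  }
  miss <- setdiff(genes, rownames(cnv))
  if (length(miss) > 0) {
    stop("genes not in CNV matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x <- cnv[genes, , drop = FALSE]
  amp <- (x == 2) * 1L
  del <- (x == -2) * 1L
  rownames(amp) <- paste0(genes, "_amp")
  rownames(del) <- paste0(genes, "_del")
  ev <- rbind(amp, del)
  if (drop_empty) ev <- ev[rowSums(ev) > 0, , drop = FALSE]
  ev
}
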