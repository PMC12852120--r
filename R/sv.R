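#' The 32-category structural-variant taxonomy
#'
#' Deletions, tandem duplications, and inversions are binned by size into
#' five half-open ranges — [0, 10 Kb), [10 Kb, 100 Kb), [100 Kb, 1 Mb),
#' [1 Mb, 10 Mb), [10 Mb, Inf) (sub-1 Kb events fold into the smallest
#' bin) — while translocations carry no size. Each event is additionally
#' clustered or non-clustered, giving (3 x 5 + 1) x 2 = 32 categories.
#' Canonical order: all non-clustered categories (DEL x 5, DUP x 5, INV x 5,
#' TRA), then the clustered block in the same order.
#'
#' @return `sv_category_names()`: character vector of length 32.
#' @export
sv_category_names <- function() {
  bins <- sv_size_bin_labels()
  one <- c(paste("DEL", bins, sep = ":"),
           paste("DUP", bins, sep = ":"),
           paste("INV", bins, sep = ":"),
           "TRA")
  c(paste("non-clustered", one, sep = ":"),
    paste("clustered", one, sep = ":"))
}

#' @rdname sv_category_names
#' @return `sv_size_bin_labels()`: the five size-bin labels.
#' @export
sv_size_bin_labels <- function() {
  c("1-10Kb", "10-100Kb", "100Kb-1Mb", "1Mb-10Mb", ">10Mb")
}

sv_size_bin <- function(size) {
  findInterval(size, c(0, 1e4, 1e5, 1e6, 1e7), rightmost.closed = FALSE)
}

validate_sv_records <- function(records) {
  need <- c("type", "chrom1", "pos1", "chrom2", "pos2")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    stop("SV records lack columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- !records$type %in% c("DEL", "DUP", "INV", "TRA")
  if (any(bad)) {
    stop("unknown SV type(s): ",
         paste(unique(records$type[bad]), collapse = ", "), call. = FALSE)
  }
  intra <- records$type != "TRA"
  if (any(intra & records$chrom1 != records$chrom2)) {
    stop("non-TRA record with two chromosomes", call. = FALSE)
  }
  if (any(intra & records$pos2 == records$pos1)) {
    stop("non-TRA record with zero size", call. = FALSE)
  }
  if (any(!intra & records$chrom1 == records$chrom2)) {
    stop("TRA record must join two chromosomes", call. = FALSE)
  }
  invisible(records)
}

# Breakpoint table: one row per breakpoint with its record index.
sv_breakpoints <- function(records) {
  data.frame(
    record = rep(seq_len(nrow(records)), 2),
    chrom = c(records$chrom1, records$chrom2),
    pos = c(records$pos1, records$pos2),
    stringsAsFactors = FALSE
  )
}

#' Clustered / non-clustered status of SV records
#'
#' One sample's SVs are split by an adaptive distance rule: the sample's
#' same-chromosome inter-breakpoint distances (gaps between consecutive
#' breakpoints, pooled over chromosomes) define a threshold
#' `tau = mean(gap) / cluster_factor`; a record is clustered iff any of its
#' breakpoints lies within `tau` of a breakpoint belonging to a different
#' record on the same chromosome. An isolated record — or a sample with too
#' few breakpoints to define a gap — is non-clustered.
#'
#' @param records One sample's SV records (`type`, `chrom1`, `pos1`,
#'   `chrom2`, `pos2`).
#' @param cluster_factor Divisor applied to the mean gap (default 10).
#' @return Logical vector, one entry per record.
#' @export
sv_clustered_flags <- function(records, cluster_factor = 10) {
  n <- nrow(records)
  if (n == 0) return(logical(0))
  validate_sv_records(records)
  if (n == 1) return(FALSE)
  bp <- sv_breakpoints(records)
  gaps <- unlist(lapply(split(bp$pos, bp$chrom), function(p) {
    if (length(p) < 2) return(numeric(0))
    diff(sort(p))
  }), use.names = FALSE)
  if (length(gaps) == 0) return(rep(FALSE, n))
  tau <- mean(gaps) / cluster_factor
  clustered <- rep(FALSE, n)
  for (ch in unique(bp$chrom)) {
    sel <- bp$chrom == ch
    pos <- bp$pos[sel]
    rec <- bp$record[sel]
    if (length(pos) < 2) next
    for (i in seq_along(pos)) {
      other <- rec != rec[i]
      if (!any(other)) next
      if (min(abs(pos[other] - pos[i])) < tau) {
        clustered[rec[i]] <- TRUE
      }
    }
  }
  clustered
}

#' Classify one sample's SV records into the 32 categories
#'
#' @inheritParams sv_clustered_flags
#' @return Integer vector of category indices (1..32 into
#'   [sv_category_names()]), named with the category labels.
#' @export
classify_sv <- function(records, cluster_factor = 10) {
  if (nrow(records) == 0) {
    return(stats::setNames(integer(0), character(0)))
  }
  validate_sv_records(records)
  clustered <- sv_clustered_flags(records, cluster_factor)
  type_offset <- c(DEL = 0L, DUP = 5L, INV = 10L)
  idx <- integer(nrow(records))
  for (i in seq_len(nrow(records))) {
    within <- if (records$type[i] == "TRA") {
      16L
    } else {
      size <- abs(records$pos2[i] - records$pos1[i])
      type_offset[[records$type[i]]] + sv_size_bin(size)
    }
    idx[i] <- within + if (clustered[i]) 16L else 0L
  }
  stats::setNames(idx, sv_category_names()[idx])
}

#' Build per-sample 32-category SV catalogs
#'
#' @param records Cohort SV table with a `sample` column plus the record
#'   columns of [classify_sv()].
#' @param samples Sample ids to report (default: those present; samples with
#'   no records get a zero column).
#' @param cluster_factor Passed to [sv_clustered_flags()].
#' @return 32 x samples integer count matrix in canonical category order;
#'   each column sums to the sample's record count.
#' @export
build_sv_catalog <- function(records, samples = NULL, cluster_factor = 10) {
  if (is.null(samples)) {
    samples <- if (nrow(records) > 0) unique(records$sample) else character(0)
  }
  cat_names <- sv_category_names()
  out <- matrix(0L, 32L, length(samples),
                dimnames = list(cat_names, samples))
  for (s in samples) {
    rs <- records[records$sample == s, , drop = FALSE]
    if (nrow(rs) == 0) next
    idx <- classify_sv(rs, cluster_factor)
    tab <- tabulate(idx, nbins = 32L)
    out[, s] <- tab
  }
  out
}

#' Read a BEDPE-like SV table
#'
#' Tab-separated with columns `chrom1, start1, end1, chrom2, start2, end2,
#' sample, type`. BEDPE coordinates are 0-based half-open; breakpoints are
#' converted to the 1-based positions used internally (`pos = start + 1`).
#'
#' @param path File path.
#' @return SV record data frame (`sample`, `type`, `chrom1`, `pos1`,
#'   `chrom2`, `pos2`).
#' @export
read_bedpe <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("chrom1", "start1", "chrom2", "start2", "sample", "type")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop("BEDPE lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  rec <- data.frame(sample = x$sample, type = x$type,
                    chrom1 = as.character(x$chrom1), pos1 = x$start1 + 1,
                    chrom2 = as.character(x$chrom2), pos2 = x$start2 + 1,
                    stringsAsFactors = FALSE)
  validate_sv_records(rec)
  rec
}

#' Write SV records as BEDPE
#'
#' @param records SV record data frame.
#' @param path File path.
#' @export
write_bedpe <- function(records, path) {
  validate_sv_records(records)
  out <- data.frame(chrom1 = records$chrom1, start1 = records$pos1 - 1,
                    end1 = records$pos1, chrom2 = records$chrom2,
                    start2 = records$pos2 - 1, end2 = records$pos2,
                    sample = records$sample, type = records$type)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
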