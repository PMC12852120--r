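#' Resampled PAM consensus clustering
#'
#' For each of `reps` resamples, draws `floor(p_item * n)` samples (and
#' `floor(p_feature * p)` features) without replacement, clusters the
#' subsample with PAM (k-medoids, Euclidean distance on the z-scored
#' features) for every k in `k_range`, and accumulates, per pair of samples,
#' how often they co-cluster among the resamples in which they were co-drawn.
#' The per-k consensus matrix is co-cluster count / co-sample count. Final
#' per-k labels come from PAM run on `1 - consensus` as a dissimilarity.
#'
#' @param scores Samples x features numeric matrix, normally z-scored
#'   ([zscale_features()]).
#' @param k_range Integer vector of cluster numbers (default 2:10).
#' @param reps Number of resamples (default 1000; 200 is adequate for
#'   simulation work).
#' @param p_item Fraction of samples drawn per resample (default 0.8).
#' @param p_feature Fraction of features drawn per resample (default 1).
#' @param seed Integer seed; the run is a pure function of (inputs, seed).
#' @return An object of class `tcms_consensus`: list with `consensus` (named
#'   list of n x n matrices per k), `cosample` (co-draw count matrix),
#'   `labels` (named list of integer vectors per k), `params`, and
#'   `uncosampled_pairs` (count of pairs never co-drawn, flagged if > 0).
#' @export
consensus_cluster <- function(scores, k_range = 2:10, reps = 1000,
                              p_item = 0.8, p_feature = 1.0, seed = 1) {
  stopifnot(is.matrix(scores), length(k_range) >= 1, reps >= 1,
            p_item > 0, p_item <= 1, p_feature > 0, p_feature <= 1)
  k_range <- sort(unique(as.integer(k_range)))
  n <- nrow(scores)
  p <- ncol(scores)
  if (max(k_range) >= n) {
    stop("max of k_range must be below the number of samples", call. = FALSE)
  }
  if (n < 2 * max(k_range)) {
    stop("need at least 2 * max(k_range) samples", call. = FALSE)
  }
  ids <- rownames(scores)
  if (is.null(ids)) ids <- paste0("S", seq_len(n))
  n_sub <- max(max(k_range) + 1L, floor(p_item * n))
  p_sub <- max(1L, floor(p_feature * p))

  cosample <- matrix(0L, n, n)
  cocluster <- stats::setNames(
    lapply(k_range, function(k) matrix(0L, n, n)), as.character(k_range))

  withr::with_seed(seed, {
    for (r in seq_len(reps)) {
      idx <- sort(sample.int(n, n_sub))
      feats <- if (p_sub < p) sort(sample.int(p, p_sub)) else seq_len(p)
      cosample[idx, idx] <- cosample[idx, idx] + 1L
      d <- stats::dist(scores[idx, feats, drop = FALSE])
      for (kc in as.character(k_range)) {
        cl <- cluster::pam(d, as.integer(kc), diss = TRUE, pamonce = 6,
                           cluster.only = TRUE)
        for (g in unique(cl)) {
          member <- idx[cl == g]
          cocluster[[kc]][member, member] <-
            cocluster[[kc]][member, member] + 1L
        }
      }
    }
  })

  never <- cosample == 0
  diag(never) <- FALSE
  if (any(never)) {
    warning(sum(never) / 2, " sample pair(s) never co-sampled; ",
            "their consensus entries are set to 0", call. = FALSE)
  }
  denom <- pmax(cosample, 1L)
  consensus <- lapply(cocluster, function(m) {
    cm <- m / denom
    diag(cm) <- 1
    dimnames(cm) <- list(ids, ids)
    cm
  })
  labels <- stats::setNames(vector("list", length(k_range)),
                            as.character(k_range))
  for (kc in as.character(k_range)) {
    # classic SWAP here: the FasterPAM shortcuts can cycle on the heavily
    # tied consensus dissimilarities
    cl <- cluster::pam(stats::as.dist(1 - consensus[[kc]]),
                       as.integer(kc), diss = TRUE, cluster.only = TRUE)
    labels[[kc]] <- stats::setNames(cl, ids)
  }
  structure(
    list(consensus = consensus, cosample = cosample, labels = labels,
         params = list(k_range = k_range, reps = reps, p_item = p_item,
                       p_feature = p_feature, seed = seed),
         uncosampled_pairs = sum(never) / 2),
    class = "tcms_consensus"
  )
}

#' @export
print.tcms_consensus <- function(x, ...) {
  cat(sprintf("<tcms_consensus> n=%d, k=%s, reps=%d, pItem=%g, pFeature=%g\n",
              nrow(x$cosample),
              paste(range(x$params$k_range), collapse = "-"),
              x$params$reps, x$params$p_item, x$params$p_feature))
  invisible(x)
}

#' Select the number of clusters from consensus CDFs
#'
#' Computes, per k, three statistics of the off-diagonal consensus entries:
#' the area under their empirical CDF; the relative area increase
#' `delta_k = (A_k - A_{k-1}) / A_{k-1}` (for the smallest k, `delta = A_k`),
#' the classical elbow diagnostic; and the proportion of ambiguous
#' clustering, `PAC = F(0.9) - F(0.1)`, the mass of consensus entries that
#' are neither clearly together nor clearly apart. The chosen k minimizes
#' PAC; an exact PAC tie is broken toward the largest tied k whose
#' delta-area is at least `threshold`, else the smallest tied k. (The
#' delta-area elbow alone over-splits crisply separated data: splitting a
#' tight cluster still inflates the CDF area, while PAC correctly reads the
#' resulting ambiguity as over-clustering.) `override` pins k regardless —
#' the final k in practice also weighs biological and clinical
#' interpretability.
#'
#' @param run A `tcms_consensus`.
#' @param threshold Delta-area threshold used in tie-breaking (default 0.1).
#' @param override Optional integer k to force.
#' @return List of class `tcms_k_selection`: `k` (chosen), `area`,
#'   `delta_area`, `pac` (all named by k), `threshold`, `overridden`.
#' @export
select_k <- function(run, threshold = 0.1, override = NULL) {
  stopifnot(inherits(run, "tcms_consensus"))
  ks <- run$params$k_range
  if (length(ks) < 2 && is.null(override)) {
    stop("need at least 2 k values to select from", call. = FALSE)
  }
  entries <- lapply(as.character(ks), function(kc) {
    cm <- run$consensus[[kc]]
    cm[upper.tri(cm)]
  })
  area <- vapply(entries, function(x) 1 - mean(x), numeric(1))
  pac <- vapply(entries, function(x) mean(x > 0.1 & x < 0.9), numeric(1))
  delta <- numeric(length(ks))
  delta[1] <- area[1]
  if (length(ks) > 1) {
    delta[-1] <- diff(area) / area[-length(area)]
  }
  names(delta) <- names(area) <- names(pac) <- as.character(ks)
  if (!is.null(override)) {
    k <- as.integer(override)
  } else {
    tied <- which(pac <= min(pac) + 1e-12)
    good <- tied[delta[tied] >= threshold]
    k <- if (length(good) > 0) ks[max(good)] else ks[min(tied)]
  }
  structure(list(k = k, area = area, delta_area = delta, pac = pac,
                 threshold = threshold, overridden = !is.null(override)),
            class = "tcms_k_selection")
}

#' @export
print.tcms_k_selection <- function(x, ...) {
  cat(sprintf("<tcms_k_selection> chosen k = %d%s\n", x$k,
              if (x$overridden) " (override)" else ""))
  print(round(rbind(area = x$area, delta_area = x$delta_area, pac = x$pac),
              4))
  invisible(x)
}
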