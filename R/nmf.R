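# Cosine similarity between columns of two matrices.
cosine_sim <- function(a, b) {
  an <- sqrt(colSums(a^2)); bn <- sqrt(colSums(b^2))
  s <- crossprod(a, b) / (outer(an, bn))
  s[!is.finite(s)] <- 0
  s
}

# KL divergence D(V || WH), with 0 * log(0) = 0.
kl_divergence <- function(V, WH) {
  pos <- V > 0
  sum(V[pos] * log(V[pos] / WH[pos])) - sum(V) + sum(WH)
}

# One NMF fit by multiplicative updates on the KL objective. The objective
# is verified non-increasing at every iteration (up to numerical slack).
nmf_kl_fit <- function(V, r, maxit = 4000, tol = 1e-10) {
  m <- nrow(V); n <- ncol(V)
  eps <- .Machine$double.eps
  W <- matrix(stats::runif(m * r, 0.1, 1), m, r)
  H <- matrix(stats::runif(r * n, 0.1, 1), r, n)
  WH <- W %*% H + eps
  obj <- kl_divergence(V, WH)
  monotone <- TRUE
  for (it in seq_len(maxit)) {
    # H update
    H <- H * (crossprod(W, V / WH)) / pmax(colSums(W), eps)
    WH <- W %*% H + eps
    # W update
    W <- W * ((V / WH) %*% t(H)) / matrix(pmax(rowSums(H), eps), m, r,
                                          byrow = TRUE)
    WH <- W %*% H + eps
    new_obj <- kl_divergence(V, WH)
    if (new_obj > obj + 1e-8 * max(1, abs(obj))) monotone <- FALSE
    if (abs(obj - new_obj) < tol * max(1, abs(obj))) {
      obj <- new_obj
      break
    }
    obj <- new_obj
  }
  # column-normalize signatures, push scale into exposures
  cs <- pmax(colSums(W), eps)
  W <- sweep(W, 2, cs, "/")
  H <- sweep(H, 1, cs, "*")
  list(W = W, H = H, objective = obj, monotone = monotone)
}

# Stability of a rank-r factorization across random restarts: pool all
# replicate signature columns, partition them into r groups by PAM on
# cosine distance, and take the mean silhouette width. Rank 1 uses the mean
# cosine similarity of replicates to their average signature.
replicate_stability <- function(W_list, r) {
  allW <- do.call(cbind, W_list)
  if (r == 1) {
    ctr <- rowMeans(allW)
    return(mean(cosine_sim(allW, matrix(ctr, ncol = 1))))
  }
  d <- stats::as.dist(1 - cosine_sim(allW, allW))
  cl <- cluster::pam(d, r, diss = TRUE, pamonce = 6, cluster.only = TRUE)
  mean(cluster::silhouette(cl, d)[, "sil_width"])
}

#' Extract SV signatures by NMF with rank selection
#'
#' Factorizes a nonnegative catalog matrix (categories x samples) by NMF
#' with multiplicative updates on the Kullback-Leibler objective, run from
#' several random starts per candidate rank. For each rank the diagnostics
#' are the average stability (mean silhouette of the pooled replicate
#' signatures clustered at cosine distance) and the mean per-sample cosine
#' distance between the catalog and its reconstruction. Rank selection uses
#' both diagnostics: the selected rank is the largest one whose stability
#' reaches `stability_min` and whose mean cosine distance improves on the
#' previous rank by at least `min_improvement` (stability alone does not
#' penalize overfit ranks, whose surplus signatures are still moderately
#' reproducible; the reconstruction gain of a surplus rank is near zero).
#'
#' @param catalogs Nonnegative categories x samples matrix (e.g. from
#'   [build_sv_catalog()]).
#' @param rank_range Candidate ranks (default 1:8; the full search space is
#'   1-30 when the cohort supports it).
#' @param replicates Random restarts per rank (default 10).
#' @param stability_min Stability threshold for rank selection (default 0.8).
#' @param min_improvement Minimum decrease in mean cosine distance a rank
#'   must contribute over the previous rank to stay a candidate (default
#'   0.01).
#' @param seed Integer seed.
#' @param maxit Maximum multiplicative-update iterations per fit.
#' @return List of class `tcms_nmf`: `rank` (selected), `signatures`
#'   (categories x rank, columns sum to 1), `exposures` (rank x samples),
#'   `diagnostics` (per-rank stability, mean cosine distance, objective),
#'   `monotone` (TRUE iff every fit had a non-increasing objective).
#' @export
extract_signatures_nmf <- function(catalogs, rank_range = 1:8,
                                   replicates = 10, stability_min = 0.8,
                                   min_improvement = 0.01,
                                   seed = 1, maxit = 4000) {
  stopifnot(is.matrix(catalogs))
  if (any(catalogs < 0)) stop("catalog matrix must be nonnegative", call. = FALSE)
  if (sum(catalogs) == 0) stop("all-zero catalog matrix", call. = FALSE)
  if (ncol(catalogs) < 2) stop("need at least 2 samples", call. = FALSE)
  rank_range <- sort(unique(as.integer(rank_range)))
  rank_range <- rank_range[rank_range >= 1 &
                             rank_range <= min(dim(catalogs))]
  V <- catalogs
  diag_rows <- vector("list", length(rank_range))
  best_fits <- vector("list", length(rank_range))
  monotone_all <- TRUE
  withr::with_seed(seed, {
    for (ri in seq_along(rank_range)) {
      r <- rank_range[ri]
      fits <- lapply(seq_len(replicates), function(i) {
        nmf_kl_fit(V, r, maxit = maxit)
      })
      objs <- vapply(fits, `[[`, numeric(1), "objective")
      monotone_all <- monotone_all &&
        all(vapply(fits, `[[`, logical(1), "monotone"))
      best <- fits[[which.min(objs)]]
      stab <- replicate_stability(lapply(fits, `[[`, "W"), r)
      recon <- best$W %*% best$H
      cosd <- 1 - diag(cosine_sim(V, recon))
      diag_rows[[ri]] <- data.frame(rank = r, stability = stab,
                                    mean_cosine_dist = mean(cosd),
                                    objective = min(objs))
      best_fits[[ri]] <- best
    }
  })
  diagnostics <- do.call(rbind, diag_rows)
  improves <- c(TRUE, -diff(diagnostics$mean_cosine_dist) >= min_improvement)
  first_flat <- which(!improves)[1]
  eligible <- seq_len(if (is.na(first_flat)) nrow(diagnostics)
                      else first_flat - 1L)
  ok <- eligible[diagnostics$stability[eligible] >= stability_min]
  sel <- if (length(ok) > 0) max(ok) else 1L
  fit <- best_fits[[sel]]
  sig <- fit$W
  rownames(sig) <- rownames(catalogs)
  colnames(sig) <- paste0("SIG", seq_len(ncol(sig)))
  expo <- fit$H
  rownames(expo) <- colnames(sig)
  colnames(expo) <- colnames(catalogs)
  structure(list(rank = rank_range[sel], signatures = sig, exposures = expo,
                 diagnostics = diagnostics, monotone = monotone_all,
                 stability_min = stability_min),
            class = "tcms_nmf")
}

#' @export
print.tcms_nmf <- function(x, ...) {
  cat(sprintf("<tcms_nmf> selected rank %d (stability >= %.2f)\n",
              x$rank, x$stability_min))
  print(round(x$diagnostics, 4))
  invisible(x)
}

#' Refit known signatures to a catalog by nonnegative least squares
#'
#' Allocates a reference signature catalog (columns sum to 1) to one or more
#' observed catalogs by NNLS, the standard way of attributing known COSMIC
#' signatures to new samples without re-extracting.
#'
#' @param catalog Nonnegative numeric vector (one sample) or categories x
#'   samples matrix.
#' @param reference Categories x signatures matrix, columns summing to 1.
#' @return For a vector input: list with `exposures` (named, nonnegative)
#'   and `residual` (Euclidean norm). For a matrix: `exposures` is
#'   signatures x samples and `residual` a per-sample vector.
#' @export
refit_exposures <- function(catalog, reference) {
  stopifnot(is.matrix(reference))
  csum <- colSums(reference)
  if (any(abs(csum - 1) > 1e-9)) {
    stop("reference signature columns must sum to 1", call. = FALSE)
  }
  if (is.matrix(catalog)) {
    if (nrow(catalog) != nrow(reference)) {
      stop("catalog / reference dimension mismatch", call. = FALSE)
    }
    fits <- lapply(seq_len(ncol(catalog)), function(j) {
      refit_exposures(catalog[, j], reference)
    })
    expo <- vapply(fits, `[[`, numeric(ncol(reference)), "exposures")
    expo <- matrix(expo, ncol(reference), ncol(catalog),
                   dimnames = list(colnames(reference), colnames(catalog)))
    return(list(exposures = expo,
                residual = vapply(fits, `[[`, numeric(1), "residual")))
  }
  if (length(catalog) != nrow(reference)) {
    stop("catalog / reference dimension mismatch", call. = FALSE)
  }
  if (any(catalog < 0)) stop("negative catalog entries", call. = FALSE)
  if (all(catalog == 0)) {
    x <- stats::setNames(rep(0, ncol(reference)), colnames(reference))
    return(list(exposures = x, residual = 0))
  }
  fit <- pracma::lsqnonneg(reference, as.numeric(catalog))
  x <- stats::setNames(fit$x, colnames(reference))
  list(exposures = x,
       residual = sqrt(sum((catalog - reference %*% fit$x)^2)))
}

#' Match estimated signatures to a reference by cosine similarity
#'
#' Greedy one-to-one assignment on the cosine similarity matrix; useful for
#' comparing recovered NMF signatures with planted truth.
#'
#' @param estimated,truth Categories x signatures matrices with equal column
#'   counts.
#' @return Data frame with `estimated`, `truth` (column indices) and
#'   `cosine`.
#' @export
match_signatures <- function(estimated, truth) {
  stopifnot(ncol(estimated) == ncol(truth))
  s <- cosine_sim(estimated, truth)
  k <- ncol(estimated)
  out <- data.frame(estimated = integer(k), truth = integer(k),
                    cosine = numeric(k))
  for (i in seq_len(k)) {
    best <- which(s == max(s), arr.ind = TRUE)[1, ]
    out$estimated[i] <- best[1]
    out$truth[i] <- best[2]
    out$cosine[i] <- s[best[1], best[2]]
    s[best[1], ] <- -Inf
    s[, best[2]] <- -Inf
  }
  out
}
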