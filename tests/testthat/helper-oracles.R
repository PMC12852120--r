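# Independent oracles used by the unit and acceptance tests. These
# deliberately use literal loops / closed forms rather than the package's
# vectorized code paths.

# ssGSEA running-sum oracle: walk the ranked gene list position by
# position, accumulating the weighted in-set ECDF and the unweighted
# out-set ECDF.
ssgsea_oracle <- function(values, gene_set, alpha = 0.25) {
  n <- length(values)
  r <- rank(values, ties.method = "average")
  z <- r - (n + 1) / 2
  ord <- order(-r, names(values))
  in_set <- names(values) %in% gene_set
  m <- sum(in_set)
  w <- abs(z)^alpha
  w_in_total <- 0
  for (g in seq_len(n)) if (in_set[g]) w_in_total <- w_in_total + w[g]
  uniform <- w_in_total == 0
  score <- 0
  p_in <- 0
  p_out <- 0
  for (i in seq_len(n)) {
    g <- ord[i]
    if (in_set[g]) {
      p_in <- p_in + if (uniform) 1 / m else w[g] / w_in_total
    } else {
      p_out <- p_out + 1 / (n - m)
    }
    score <- score + (p_in - p_out)
  }
  unname(score)
}

# Two-sided Fisher p by direct hypergeometric enumeration with choose().
fisher_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  m1 <- a + b
  m2 <- a + c
  lo <- max(0, m1 + m2 - n)
  hi <- min(m1, m2)
  prob <- function(x) {
    choose(m2, x) * choose(n - m2, m1 - x) / choose(n, m1)
  }
  p_obs <- prob(a)
  total <- 0
  for (x in lo:hi) {
    px <- prob(x)
    if (px <= p_obs * (1 + 1e-7)) total <- total + px
  }
  total
}

# Two-group log-rank statistic by direct O-E/V tabulation.
logrank_oracle <- function(time, event, group) {
  lv <- sort(unique(group))
  stopifnot(length(lv) == 2)
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at <- time >= t
    n <- sum(at)
    n1 <- sum(at & group == lv[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == lv[1])
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Small registry for fast pipeline tests.
small_registry <- function(genes_per_signature = 8) {
  default_registry(genes_per_signature)
}

# Planted rank-3 SV signature truth for NMF tests.
planted_sv_signatures <- function() {
  W <- matrix(0, 32, 3)
  W[1:5, 1] <- c(5, 4, 3, 2, 1)
  W[c(6:10, 16), 2] <- c(1, 2, 3, 4, 5, 3)
  W[c(17:21, 32), 3] <- c(4, 1, 4, 1, 4, 4)
  sweep(W, 2, colSums(W), "/")
}
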