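# Independent oracle implementations used across the suite. These are kept
# deliberately naive (double loops, direct formulas) so they share no code
# path with the package.

# brute-force NMI from the joint contingency table
oracle_nmi <- function(x, y) {
  n <- length(x)
  ux <- unique(x)
  uy <- unique(y)
  hx <- 0
  for (a in ux) {
    p <- sum(x == a) / n
    hx <- hx - p * log(p)
  }
  hy <- 0
  for (b in uy) {
    p <- sum(y == b) / n
    hy <- hy - p * log(p)
  }
  if (hx == 0 && hy == 0) return(1)
  if (hx == 0 || hy == 0) return(0)
  mi <- 0
  for (a in ux) {
    for (b in uy) {
      pab <- sum(x == a & y == b) / n
      if (pab > 0) {
        mi <- mi + pab * log(pab / ((sum(x == a) / n) * (sum(y == b) / n)))
      }
    }
  }
  mi / ((hx + hy) / 2)
}

# rank-penalty embedding metrics evaluated by exhaustive enumeration
oracle_trust_cont <- function(high, low, k) {
  n <- ncol(high)
  dh <- as.matrix(dist(t(high)))
  dl <- as.matrix(dist(low))
  rank_of <- function(d, i, j) {
    # neighbor rank of j wrt i, ties by index
    others <- setdiff(seq_len(n), i)
    key <- order(d[i, others], others)
    match(j, others[key])
  }
  t_pen <- 0
  c_pen <- 0
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    knn_h <- others[order(dh[i, others], others)][seq_len(k)]
    knn_l <- others[order(dl[i, others], others)][seq_len(k)]
    for (j in setdiff(knn_l, knn_h)) t_pen <- t_pen + rank_of(dh, i, j) - k
    for (j in setdiff(knn_h, knn_l)) c_pen <- c_pen + rank_of(dl, i, j) - k
  }
  norm <- 2 / (n * k * (2 * n - 3 * k - 1))
  c(trust = 1 - norm * t_pen, cont = 1 - norm * c_pen)
}

# direct enumeration of the weighted KS-like enrichment walk for one sample
oracle_walk <- function(z_sample, gene_ids, set_genes, tau) {
  p <- length(z_sample)
  ord <- order(-z_sample, gene_ids, method = "radix")
  ranks <- integer(p)
  ranks[ord] <- seq_len(p)
  w <- abs(p / 2 - ranks)^tau
  in_set <- gene_ids %in% set_genes
  denom_in <- sum(w[in_set])
  denom_out <- p - sum(in_set)
  v <- 0
  best <- 0
  for (pos in seq_len(p)) {
    g <- ord[pos]
    if (in_set[g]) {
      v <- v + w[g] / denom_in
    } else {
      v <- v - 1 / denom_out
    }
    if (abs(v) > abs(best)) best <- v
  }
  best
}

# exact hypergeometric upper-tail by term summation
oracle_hyper_upper <- function(q, m, n_other, k) {
  total <- 0
  for (i in q:min(m, k)) {
    total <- total + choose(m, i) * choose(n_other, k - i)
  }
  total / choose(m + n_other, k)
}

# directory digest for byte-identity checks
dir_digest <- function(path) {
  files <- sort(list.files(path, recursive = TRUE, full.names = TRUE))
  lapply(files, function(f) readBin(f, "raw", file.info(f)$size))
}
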