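# Independent brute-force oracles used to validate the package's
# implementations. Each is written from the definition, not from the
# code path it checks.

# Upper hypergeometric tail by direct enumeration with choose().
oracle_hypergeom_tail <- function(n_expr_in, n_in, n_expr_out, n_out) {
  m <- n_expr_in + n_expr_out     # total expressing
  N <- n_in + n_out
  ks <- n_expr_in:min(m, n_in)
  sum(choose(m, ks) * choose(N - m, n_in - ks)) / choose(N, n_in)
}

# Two-sided rank-sum p-value by full enumeration of all assignments of
# the pooled values to the two groups (requires distinct values).
oracle_ranksum_enum <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  pooled <- c(x, y)
  r_obs <- sum(rank(pooled)[seq_len(n1)])
  combs <- utils::combn(n, n1)
  stats_all <- apply(combs, 2, function(ix) sum(rank(pooled)[ix]))
  mu <- n1 * (n + 1) / 2
  mean(abs(stats_all - mu) >= abs(r_obs - mu) - 1e-9)
}

# O(n^2) DBSCAN from the textbook definition (queue-based expansion,
# seeds visited in index order; labels 0.. and -1 for noise).
oracle_dbscan <- function(x, eps, min_pts) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  nbrs <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nbrs, length, 0L) >= min_pts
  labels <- rep(-1L, n)
  cl <- -1L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != -1L) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nbrs[[i]]
    while (length(queue) > 0) {
      j <- queue[1]; queue <- queue[-1]
      if (labels[j] == -1L) {
        labels[j] <- cl
        if (core[j]) queue <- c(queue, nbrs[[j]])
      }
    }
  }
  labels
}

# Exhaustive multi-Otsu over every threshold combination of a histogram
# (direct between-class variance, all bin cuts considered).
oracle_multiotsu <- function(channel, n_classes, n_bins = 256) {
  bin <- pmin(floor(channel * n_bins), n_bins - 1)
  h <- tabulate(as.vector(bin) + 1L, nbins = n_bins)
  total <- sum(h); mu_t <- sum(h * (seq_len(n_bins) - 1)) / total
  score <- function(cuts) {
    bounds <- c(-1, cuts, n_bins - 1)
    s <- 0
    for (c in seq_len(n_classes)) {
      sel <- (bounds[c] + 1):bounds[c + 1] + 1
      w <- sum(h[sel]) / total
      if (w == 0) next
      mu <- sum(h[sel] * (sel - 1)) / sum(h[sel])
      s <- s + w * (mu - mu_t)^2
    }
    s
  }
  combs <- utils::combn(0:(n_bins - 2), n_classes - 1)
  scores <- apply(combs, 2, score)
  list(best = max(scores),
       argmax = combs[, which(abs(scores - max(scores)) < 1e-12),
                      drop = FALSE],
       score = score)
}

# Minimum spanning tree weight by enumerating all n^(n-2) Prufer
# sequences (every labelled spanning tree of K_n exactly once).
oracle_mst_weight <- function(d) {
  n <- nrow(d)
  if (n == 2) return(d[1, 2])
  decode <- function(pr) {       # Prufer -> edge list
    n <- length(pr) + 2
    degree <- rep(1L, n)
    for (v in pr) degree[v] <- degree[v] + 1L
    w <- 0
    for (v in pr) {
      leaf <- which(degree == 1L)[1]
      w <- w + d[leaf, v]
      degree[leaf] <- 0L
      degree[v] <- degree[v] - 1L
    }
    ends <- which(degree == 1L)
    w + d[ends[1], ends[2]]
  }
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  min(apply(seqs, 1, decode))
}

# Straight-loop sparse-autoencoder loss (sigmoid net, paired
# reconstruction, weight decay on both matrices, KL sparsity).
oracle_ae_loss <- function(W1, b1, W2, b2, X, lambda, rho, beta) {
  n <- nrow(X); G <- ncol(X); H <- ncol(W1)
  sig <- function(z) 1 / (1 + exp(-z))
  Hm <- matrix(0, n, H); Ym <- matrix(0, n, G)
  for (i in seq_len(n)) {
    for (j in seq_len(H)) {
      acc <- b1[j]
      for (g in seq_len(G)) acc <- acc + X[i, g] * W1[g, j]
      Hm[i, j] <- sig(acc)
    }
    for (g in seq_len(G)) {
      acc <- b2[g]
      for (j in seq_len(H)) acc <- acc + Hm[i, j] * W2[j, g]
      Ym[i, g] <- sig(acc)
    }
  }
  recon <- 0
  for (i in seq_len(n)) recon <- recon + sum((X[i, ] - Ym[i, ])^2)
  recon <- recon / n
  weight <- lambda * (sum(W1^2) + sum(W2^2))
  sparsity <- 0
  for (j in seq_len(H)) {
    rh <- mean(Hm[, j])
    sparsity <- sparsity + rho * log(rho / rh) +
      (1 - rho) * log((1 - rho) / (1 - rh))
  }
  sparsity <- beta * sparsity
  list(total = recon + weight + sparsity, recon = recon,
       weight = weight, sparsity = sparsity)
}

# Adjusted Rand index (contingency-table formula).
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_ij <- si * sj / n2
  (sij - exp_ij) / ((si + sj) / 2 - exp_ij)
}

# Criterion for a successful end-to-end recovery of the planted
# five-cluster structure.
e2e_recovery_ok <- function(res, truth) {
  ann <- res$annotation
  ari <- oracle_ari(res$clusters$labels, truth$cluster)
  list(ok = res$clusters$n_clusters == 5 && ari >= 0.90 &&
         sum(ann$vessel_class == "VEC") == 3 &&
         sum(ann$vessel_class == "LEC") == 2 &&
         sum(ann$is_proliferating & ann$vessel_class == "VEC") == 1,
       ari = ari)
}
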