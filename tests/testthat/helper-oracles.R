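# Independent brute-force oracles the implementation is checked against.

# step-up BH from its definition: sort, scale by m/rank, cumulative minimum
# from the largest rank down, restore input order, cap at 1
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# hand meta-analysis: inverse-variance weights on precomputed ratios
ivw_oracle <- function(b, se) {
  w <- 1 / se^2
  est <- sum(w * b) / sum(w)
  list(estimate = est, se = sqrt(1 / sum(w)),
       p = 2 * pnorm(-abs(est) * sqrt(sum(w))))
}

# weighted 50th percentile by explicit cumulative-weight interpolation
# using approx() on the midpoint CDF
wm_oracle <- function(b, w) {
  o <- order(b)
  b <- b[o]; w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(b[1])
  if (0.5 >= s[length(s)]) return(b[length(b)])
  approx(s, b, xout = 0.5)$y
}

# closed-form weighted least squares via the normal equations,
# residual-variance scaling as in standard WLS
egger_oracle <- function(x, y, w) {
  flip <- ifelse(x < 0, -1, 1)
  x <- x * flip; y <- y * flip
  X <- cbind(1, x)
  W <- diag(w)
  xtw <- t(X) %*% W
  beta <- solve(xtw %*% X, xtw %*% y)
  res <- y - X %*% beta
  sigma2 <- sum(w * res^2) / (length(y) - 2)
  cov <- sigma2 * solve(xtw %*% X)
  int <- beta[1]; se <- sqrt(cov[1, 1])
  list(intercept = int, se = se,
       p = 2 * pt(-abs(int / se), df = length(y) - 2))
}

# exact hypergeometric upper tail by combinatorial enumeration
hyper_oracle <- function(N, K, n, k) {
  xs <- k:min(K, n)
  xs <- xs[n - xs <= N - K]
  if (length(xs) == 0) return(0)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# literal greedy clumping by sorted p-value; `near` marks SNP pairs inside
# the distance window (everything, when positions are omitted)
clump_oracle <- function(snps, p, r2, near = NULL) {
  if (is.null(near))
    near <- matrix(TRUE, length(snps), length(snps),
                   dimnames = list(snps, snps))
  kept <- character(0)
  ord <- order(p, snps)
  remaining <- snps[ord]
  while (length(remaining)) {
    top <- remaining[1]
    kept <- c(kept, top)
    remaining <- remaining[!(near[remaining, top] &
                               r2[remaining, top] > 0.001)]
  }
  kept
}

# naive O(n^3) agglomerative clustering; returns sorted merge heights
naive_hclust_heights <- function(m, linkage = "complete") {
  clusters <- lapply(seq_len(nrow(m)), identity)
  d <- as.matrix(dist(m))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dd <- d[clusters[[i]], clusters[[j]], drop = FALSE]
      cd <- switch(linkage, complete = max(dd), single = min(dd),
                   average = mean(dd))
      if (cd < bestd) { bestd <- cd; best <- c(i, j) }
    }
    heights <- c(heights, bestd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# BFS shells on the score-filtered graph via igraph
bfs_oracle <- function(seeds, edges, score_min, n_levels) {
  keep <- edges$score > score_min
  verts <- unique(c(edges$gene_a, edges$gene_b, seeds))
  g <- igraph::graph_from_data_frame(
    edges[keep, c("gene_a", "gene_b")], directed = FALSE,
    vertices = data.frame(name = verts))
  dmat <- igraph::distances(g, v = seeds)
  dmin <- apply(dmat, 2, min)
  out <- lapply(0:n_levels, function(k)
    sort(names(dmin)[is.finite(dmin) & dmin == k]))
  names(out) <- paste0("level", 0:n_levels)
  out
}
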