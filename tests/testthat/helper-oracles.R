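# Independent oracles and small fixture builders used across the suite.

# Union-find connected components, independent of the igraph-based
# implementation. Returns max component edge count and all component sizes.
uf_components <- function(edges) {
  if (nrow(edges) == 0) return(integer(0))
  nodes <- sort(unique(as.vector(edges)))
  parent <- stats::setNames(nodes, nodes)
  find <- function(v) {
    while (parent[[as.character(v)]] != v) v <- parent[[as.character(v)]]
    v
  }
  for (k in seq_len(nrow(edges))) {
    ra <- find(edges[k, 1]); rb <- find(edges[k, 2])
    if (ra != rb) parent[[as.character(ra)]] <- rb
  }
  roots <- vapply(edges[, 1], find, numeric(1))
  sort(as.integer(table(roots)), decreasing = TRUE)
}

# Pooled-variance two-sample t computed from the textbook formula.
pooled_t_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# Hand Benjamini-Hochberg step-up adjustment.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}

# Small behavior-linked cohort. The planted edges form a coherent network:
# they share a per-subject latent strength factor (as edges of a common
# functional circuit do), and behavior is their summed strength plus noise.
make_cpm_cohort <- function(n = 60, n_regions = 20, planted = 1:20,
                            noise = 0, seed = 1, edge_noise = 0.06) {
  withr::local_seed(seed)
  e <- n_edges(n_regions)
  x <- matrix(rnorm(n * e, 0.3, 0.2), n, e)
  g <- rnorm(n, 0, 0.2)
  x[, planted] <- 0.3 + g + matrix(rnorm(n * length(planted), 0, edge_noise),
                                   n, length(planted))
  y <- rowSums(x[, planted, drop = FALSE]) + rnorm(n, 0, noise)
  list(x = x, y = y, planted = planted, e = e)
}

# Small two-group edge-matrix cohort with an optional planted mean shift.
make_edge_cohort <- function(n1 = 12, n2 = 12, n_regions = 12, delta = 0,
                             shifted_edges = integer(0), seed = 1) {
  withr::local_seed(seed)
  e <- n_edges(n_regions)
  mu <- rnorm(e, 0.3, 0.1)
  z1 <- matrix(rnorm(n1 * e, 0, 0.15), n1, e) + rep(mu, each = n1)
  z1[, shifted_edges] <- z1[, shifted_edges, drop = FALSE] - delta
  z2 <- matrix(rnorm(n2 * e, 0, 0.15), n2, e) + rep(mu, each = n2)
  list(z = rbind(z1, z2),
       groups = factor(rep(c("patient", "control"), c(n1, n2)),
                       levels = c("patient", "control")),
       mu = mu, e = e)
}
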