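# Network-Based Statistics: edge-wise two-sample tests, suprathreshold
# connected components, and permutation family-wise error control over
# component size (edge count).

#' NBS configuration
#'
#' @param primary_alpha edge-level p-value threshold defining
#'   suprathreshold links (default `1e-4`).
#' @param tail `"lt"` (group 1 < group 2, the default, matching a
#'   connectivity-deficit hypothesis), `"gt"`, or `"two"`.
#' @param n_permutations permutations for the component-size null
#'   (default 10000).
#' @param prefilter_alpha family-wise alpha for the Bonferroni-corrected
#'   one-sample prefilter (default 0.05); `NULL` disables prefiltering.
#' @param var_equal pooled-variance Student t (default, classic NBS) or
#'   Welch when `FALSE`.
#' @param seed RNG seed for the permutations.
#' @return list of class `nbs_config`.
#' @export
nbs_config <- function(primary_alpha = 1e-4, tail = c("lt", "gt", "two"),
                       n_permutations = 10000L, prefilter_alpha = 0.05,
                       var_equal = TRUE, seed = NULL) {
  tail <- match.arg(tail)
  stopifnot(primary_alpha > 0, primary_alpha < 1, n_permutations >= 100)
  structure(list(primary_alpha = primary_alpha, tail = tail,
                 n_permutations = as.integer(n_permutations),
                 prefilter_alpha = prefilter_alpha, var_equal = var_equal,
                 seed = seed), class = "nbs_config")
}

#' Prefilter edges by significance against zero
#'
#' An edge is retained when a two-tailed one-sample t-test of its Fisher-z
#' values against zero, within at least one group, survives Bonferroni
#' correction over all E edges (`p < alpha / E`). Zero-variance edges are
#' treated as non-significant with a warning.
#'
#' @param z_group1,z_group2 subjects x E Fisher-z edge matrices.
#' @param alpha family-wise alpha before Bonferroni division (default 0.05).
#' @return logical mask of length E.
#' @export
prefilter_edges <- function(z_group1, z_group2, alpha = 0.05) {
  stopifnot(ncol(z_group1) == ncol(z_group2),
            nrow(z_group1) >= 2, nrow(z_group2) >= 2)
  e <- ncol(z_group1)
  one_sample_p <- function(z) {
    n <- nrow(z)
    mu <- colMeans(z)
    s <- col_sds(z)
    p <- rep(1, e)
    ok <- s > 0
    p[ok] <- 2 * stats::pt(-abs(mu[ok] / (s[ok] / sqrt(n))), df = n - 1)
    if (any(!ok)) {
      warning(sum(!ok), " zero-variance edge(s) treated as non-significant")
    }
    p
  }
  one_sample_p(z_group1) < alpha / e | one_sample_p(z_group2) < alpha / e
}

#' Edge-wise two-sample t statistics
#'
#' Pooled-variance (Student) t per edge for group 1 minus group 2, with
#' the configured one- or two-tailed p-value; Welch available via
#' `var_equal = FALSE`.
#'
#' @param z_group1,z_group2 subjects x E Fisher-z edge matrices.
#' @param tail `"lt"` (p small when group 1 < group 2), `"gt"`, `"two"`.
#' @param var_equal pooled (default) vs. Welch variance.
#' @return list with `t`, `p` (length E) and `df` (scalar for pooled,
#'   length E for Welch).
#' @export
edge_tstats <- function(z_group1, z_group2, tail = c("lt", "gt", "two"),
                        var_equal = TRUE) {
  tail <- match.arg(tail)
  n1 <- nrow(z_group1); n2 <- nrow(z_group2)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 subjects")
  m1 <- colMeans(z_group1); m2 <- colMeans(z_group2)
  v1 <- col_sds(z_group1)^2; v2 <- col_sds(z_group2)^2
  if (var_equal) {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- se^4 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  p <- switch(tail,
              lt = stats::pt(t, df),
              gt = stats::pt(t, df, lower.tail = FALSE),
              two = 2 * stats::pt(-abs(t), df))
  list(t = t, p = p, df = df)
}

#' Connected components of a suprathreshold edge set
#'
#' Component size is the number of edges (links), not nodes; isolated
#' nodes never form components.
#'
#' @param edges two-column matrix/data.frame of node indices (1-based),
#'   one row per edge.
#' @return list with `components` (list of integer row-index vectors into
#'   `edges`) and `sizes` (edge counts), ordered by decreasing size.
#' @export
connected_components <- function(edges) {
  edges <- as.matrix(edges)
  if (nrow(edges) == 0) return(list(components = list(), sizes = integer(0)))
  verts <- sort(unique(as.vector(edges)))
  g <- igraph::graph_from_edgelist(
    cbind(match(edges[, 1], verts), match(edges[, 2], verts)),
    directed = FALSE)
  memb <- igraph::components(g)$membership
  comp_of_edge <- memb[match(edges[, 1], verts)]
  split_idx <- split(seq_len(nrow(edges)), comp_of_edge)
  sizes <- lengths(split_idx)
  ord <- order(sizes, decreasing = TRUE)
  list(components = unname(split_idx[ord]), sizes = unname(sizes[ord]))
}

# Max component edge count of a suprathreshold edge list (internal fast path).
max_component_size <- function(edges) {
  if (nrow(edges) == 0) return(0L)
  if (nrow(edges) == 1) return(1L)
  max(connected_components(edges)$sizes)
}

#' Run the Network-Based Statistics group comparison
#'
#' Observed pipeline: Bonferroni prefilter (computed once on the observed
#' grouping), edge-wise two-sample t-tests, suprathreshold edges at
#' `primary_alpha`, connected components with edge-count sizes. The null
#' distribution of the maximal component size is built by permuting group
#' labels `n_permutations` times over the same retained edge set; the
#' corrected p-value of an observed component of size M is
#' `(1 + #\{null max >= M\}) / (n_permutations + 1)` (ties count as
#' exceedances).
#'
#' @param z subjects x E Fisher-z edge matrix.
#' @param groups factor with exactly two levels; the contrast is
#'   `levels[1] - levels[2]` (so `tail = "lt"` tests whether the first
#'   level's connectivity is reduced).
#' @param config an [nbs_config()].
#' @param n_regions number of regions (inferred from E when `NULL`).
#' @return object of class `nbs_result`: `components` (list of data.frames
#'   with columns `edge`, `i`, `j`, `t`), `sizes`, `corrected_p`,
#'   `null_max_sizes`, `tstats` (length E, `NA` for filtered edges),
#'   `retained_edges` mask, and the config.
#' @export
run_nbs <- function(z, groups, config = nbs_config(), n_regions = NULL) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  if (any(table(groups) < 2)) stop("each group needs at least 2 subjects")
  e <- ncol(z)
  if (is.null(n_regions)) {
    n_regions <- as.integer(round((1 + sqrt(1 + 8 * e)) / 2))
    if (n_edges(n_regions) != e) stop("cannot infer n_regions from ", e, " edges")
  }
  idx <- edge_index(n_regions)
  g1 <- which(groups == levels(groups)[1])
  g2 <- which(groups == levels(groups)[2])
  n1 <- length(g1); n2 <- length(g2); n <- n1 + n2

  retained <- if (is.null(config$prefilter_alpha)) rep(TRUE, e) else
    prefilter_edges(z[g1, , drop = FALSE], z[g2, , drop = FALSE],
                    config$prefilter_alpha)
  if (!any(retained)) {
    warning("prefilter removed every edge; no components to test")
    return(structure(list(components = list(), sizes = integer(0),
                          corrected_p = numeric(0),
                          null_max_sizes = integer(0),
                          tstats = rep(NA_real_, e), retained_edges = retained,
                          n_regions = n_regions, config = config),
                     class = "nbs_result"))
  }
  zr <- z[, retained, drop = FALSE]
  ridx <- which(retained)

  obs <- edge_tstats(z[g1, retained, drop = FALSE],
                     z[g2, retained, drop = FALSE],
                     tail = config$tail, var_equal = config$var_equal)
  supra <- which(obs$p < config$primary_alpha)
  comp <- connected_components(cbind(idx$i[ridx[supra]], idx$j[ridx[supra]]))

  # permutation null of the maximal component size, vectorized in chunks
  df <- n1 + n2 - 2
  crit <- switch(config$tail,
                 lt = stats::qt(config$primary_alpha, df),
                 gt = stats::qt(1 - config$primary_alpha, df),
                 two = stats::qt(1 - config$primary_alpha / 2, df))
  nperm <- config$n_permutations
  tot <- colSums(zr)
  tot2 <- colSums(zr * zr)
  null_max <- integer(nperm)
  ii <- idx$i[ridx]; jj <- idx$j[ridx]
  with_seed(config$seed, {
    done <- 0L
    chunk_size <- max(1L, min(nperm, as.integer(2e7 / max(ncol(zr), 1L))))
    while (done < nperm) {
      b <- min(chunk_size, nperm - done)
      sel <- matrix(0, n, b)
      for (k in seq_len(b)) sel[sample.int(n, n1), k] <- 1
      s1 <- crossprod(sel, zr)              # b x Er sums of permuted group 1
      ss1 <- crossprod(sel, zr * zr)
      m1 <- s1 / n1
      m2 <- sweep(-s1, 2, tot, `+`) / n2
      v1 <- (ss1 - n1 * m1 * m1) / (n1 - 1)
      v2 <- (sweep(-ss1, 2, tot2, `+`) - n2 * m2 * m2) / (n2 - 1)
      if (config$var_equal) {
        se <- sqrt((((n1 - 1) * v1 + (n2 - 1) * v2) / df) * (1 / n1 + 1 / n2))
        tmat <- (m1 - m2) / se
        hit <- switch(config$tail, lt = tmat < crit, gt = tmat > crit,
                      two = abs(tmat) > crit)
      } else {
        se <- sqrt(v1 / n1 + v2 / n2)
        tmat <- (m1 - m2) / se
        dfw <- se^4 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
        pmat <- switch(config$tail,
                       lt = stats::pt(tmat, dfw),
                       gt = stats::pt(tmat, dfw, lower.tail = FALSE),
                       two = 2 * stats::pt(-abs(tmat), dfw))
        hit <- pmat < config$primary_alpha
      }
      for (k in seq_len(b)) {
        h <- which(hit[k, ])
        null_max[done + k] <- if (length(h)) {
          max_component_size(cbind(ii[h], jj[h]))
        } else 0L
      }
      done <- done + b
    }
  })

  corrected_p <- vapply(comp$sizes, function(m) {
    (1 + sum(null_max >= m)) / (nperm + 1)
  }, numeric(1))

  tstats <- rep(NA_real_, e)
  tstats[ridx] <- obs$t
  components <- lapply(comp$components, function(rows) {
    eidx <- ridx[supra[rows]]
    data.frame(edge = eidx, i = idx$i[eidx], j = idx$j[eidx],
               t = tstats[eidx])
  })
  structure(list(components = components, sizes = comp$sizes,
                 corrected_p = corrected_p, null_max_sizes = null_max,
                 tstats = tstats, retained_edges = retained,
                 n_regions = n_regions, config = config),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat("NBS result:", length(x$sizes), "suprathreshold component(s)\n")
  if (length(x$sizes)) {
    for (k in seq_along(x$sizes)) {
      nodes <- length(unique(c(x$components[[k]]$i, x$components[[k]]$j)))
      cat(sprintf("  component %d: %d edges / %d nodes, corrected p = %.4g\n",
                  k, x$sizes[k], nodes, x$corrected_p[k]))
    }
  }
  invisible(x)
}

#' Write NBS outputs as flat files
#'
#' Component edge lists as TSV (with 0-based indices and t-values), the
#' null maximum-size vector as TSV, and a JSON summary.
#'
#' @param result an `nbs_result`.
#' @param dir output directory.
#' @param atlas optional atlas table for region names.
#' @return `dir`, invisibly.
#' @export
write_nbs_result <- function(result, dir, atlas = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nm <- if (!is.null(atlas)) atlas$name else
    as.character(seq_len(result$n_regions))
  rows <- do.call(rbind, lapply(seq_along(result$components), function(k) {
    d <- result$components[[k]]
    data.frame(component_id = k, i = d$i - 1L, j = d$j - 1L,
               region_i = nm[d$i], region_j = nm[d$j], t = d$t)
  }))
  if (is.null(rows)) {
    rows <- data.frame(component_id = integer(0), i = integer(0), j = integer(0),
                       region_i = character(0), region_j = character(0),
                       t = numeric(0))
  }
  utils::write.table(rows, file.path(dir, "nbs_components.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(max_component_size = result$null_max_sizes),
                     file.path(dir, "nbs_null_max_sizes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summary <- list(
    sizes = result$sizes,
    n_nodes = vapply(result$components,
                     function(d) length(unique(c(d$i, d$j))), integer(1)),
    corrected_p = result$corrected_p,
    n_retained_edges = sum(result$retained_edges),
    config = result$config[c("primary_alpha", "tail", "n_permutations",
                             "prefilter_alpha", "var_equal")],
    seed = result$config$seed)
  jsonlite::write_json(summary, file.path(dir, "nbs_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
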