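# Connectome-based Predictive Modeling: edge selection against behavior,
# network strength, cross-validated linear prediction, permutation
# significance, and network localization (degree tables, high-degree-node
# follow-up, group-wise evaluation).

#' CPM configuration
#'
#' @param select_alpha two-tailed p threshold on the edge-behavior Pearson
#'   correlation (default 0.005).
#' @param cv `"loocv"` (default) or `"kfold"`.
#' @param k folds for k-fold CV (default 10), stratified by group when
#'   group labels are supplied.
#' @param n_permutations permutations for significance (default 1000).
#' @param negative_r_to_zero report negative performance correlations as 0
#'   (default `TRUE`).
#' @param seed RNG seed (fold shuffling and permutations).
#' @return list of class `cpm_config`.
#' @export
cpm_config <- function(select_alpha = 0.005, cv = c("loocv", "kfold"), k = 10L,
                       n_permutations = 1000L, negative_r_to_zero = TRUE,
                       seed = NULL) {
  cv <- match.arg(cv)
  stopifnot(select_alpha > 0, select_alpha < 1, k >= 2, n_permutations >= 1)
  structure(list(select_alpha = select_alpha, cv = cv, k = as.integer(k),
                 n_permutations = as.integer(n_permutations),
                 negative_r_to_zero = negative_r_to_zero, seed = seed),
            class = "cpm_config")
}

#' Select behavior-correlated edges
#'
#' Pearson correlation of every edge with the behavioral score; p-values
#' from the exact t-transform (`t = r * sqrt((n-2)/(1-r^2))`, two-tailed).
#' Positive set: `r > 0 & p < alpha`; negative set: `r < 0 & p < alpha`.
#' Constant edge columns are excluded with a warning.
#'
#' @param x subjects x E edge matrix.
#' @param y behavioral score per subject.
#' @param alpha selection threshold (default 0.005).
#' @param warn warn on constant columns (default `TRUE`).
#' @return list with `positive`, `negative` (integer edge indices), `r`
#'   and `p` (length E; `NA` for constant edges).
#' @export
select_edges <- function(x, y, alpha = 0.005, warn = TRUE) {
  n <- length(y)
  stopifnot(nrow(x) == n, n >= 4)
  if (stats::sd(y) == 0) stop("behavior has zero variance")
  r <- edge_behavior_cor(colSums(x), colSums(x * x), crossprod(x, y)[, 1],
                         sum(y), sum(y * y), n)
  if (warn && anyNA(r)) {
    warning(sum(is.na(r)), " constant edge column(s) excluded from selection")
  }
  p <- cor_pvalue(r, n)
  list(positive = which(!is.na(r) & r > 0 & p < alpha),
       negative = which(!is.na(r) & r < 0 & p < alpha),
       r = r, p = p)
}

# Correlation of each column with y from sufficient statistics; returns NA
# for zero-variance columns. Shared by select_edges() and the leave-one-out
# fast path (where the statistics are downdated per fold).
edge_behavior_cor <- function(sx, sxx, sxy, sy, syy, n) {
  covxy <- sxy - sx * sy / n
  varx <- sxx - sx * sx / n
  vary <- syy - sy * sy / n
  r <- rep(NA_real_, length(sx))
  ok <- varx > 1e-12 & vary > 1e-12
  r[ok] <- pmin(1, pmax(-1, covxy[ok] / sqrt(varx[ok] * vary)))
  r
}

cor_pvalue <- function(r, n) {
  t <- r * sqrt((n - 2) / pmax(1 - r * r, 1e-300))
  2 * stats::pt(-abs(t), n - 2)
}

#' Network strength of a subject
#'
#' Sum of the subject's Fisher-z edge values over an edge set (a weighted
#' degree of the connectome restricted to that set). An empty set gives
#' strength 0.
#'
#' @param edge_vector length-E numeric vector (one subject), or a
#'   subjects x E matrix for per-subject strengths.
#' @param edge_set integer edge indices.
#' @return scalar (vector input) or per-subject vector (matrix input).
#' @export
network_strength <- function(edge_vector, edge_set) {
  if (is.matrix(edge_vector)) {
    if (!length(edge_set)) return(rep(0, nrow(edge_vector)))
    return(unname(rowSums(edge_vector[, edge_set, drop = FALSE])))
  }
  if (!length(edge_set)) return(0)
  sum(edge_vector[edge_set])
}

# Simple/combined linear fits on network strengths; returns closure-free
# coefficient lists. Empty edge sets degrade to the training mean.
fit_strength_models <- function(s_pos, s_neg, y) {
  fit1 <- function(s) {
    if (is.null(s) || stats::var(s) < 1e-12) {
      return(c(intercept = mean(y), slope = 0))
    }
    slope <- stats::cov(s, y) / stats::var(s)
    c(intercept = mean(y) - slope * mean(s), slope = slope)
  }
  has_pos <- !is.null(s_pos); has_neg <- !is.null(s_neg)
  combined <- if (has_pos && has_neg) {
    design <- cbind(1, s_pos, s_neg)
    qrd <- qr(design)
    if (qrd$rank < 3) NULL else {
      cf <- unname(qr.coef(qrd, y))
      c(intercept = cf[1], slope_pos = cf[2], slope_neg = cf[3])
    }
  } else NULL
  list(positive = if (has_pos) fit1(s_pos),
       negative = if (has_neg) fit1(s_neg),
       combined = combined)
}

#' Cross-validated CPM
#'
#' Per fold: edges are selected on the training subjects only; simple
#' linear models relate positive and negative network strength to
#' behavior, and a combined GLM uses both strengths; the models are
#' applied to the held-out subject(s). Out-of-fold predictions are
#' collected over all folds and model performance is the Pearson
#' correlation between predicted and observed scores (negative
#' correlations reported as 0 when configured). The consensus network is
#' the intersection of the selected sets across folds. A fold that
#' selects no edges predicts the training mean (warned unless `quiet`).
#'
#' @param x subjects x E edge matrix.
#' @param y behavioral score per subject.
#' @param config a [cpm_config()].
#' @param groups optional group labels for stratified k-fold assignment.
#' @param quiet suppress empty-selection warnings (used internally by the
#'   permutation test).
#' @return object of class `cpm_model`: `consensus_positive`,
#'   `consensus_negative`, `fold_positive`/`fold_negative` (per-fold edge
#'   sets), `predictions` (n x 3: positive, negative, combined),
#'   `performance` (raw and zeroed r per model), `folds`, and the config.
#' @export
cross_validate <- function(x, y, config = cpm_config(), groups = NULL,
                           quiet = FALSE) {
  n <- length(y)
  stopifnot(nrow(x) == n, n >= 10)
  folds <- make_folds(n, config, groups)
  use_fast <- config$cv == "loocv"

  x2 <- x * x
  sx <- colSums(x); sxx <- colSums(x2)
  sxy <- crossprod(x, y)[, 1]; sy <- sum(y); syy <- sum(y * y)

  preds <- matrix(NA_real_, n, 3,
                  dimnames = list(NULL, c("positive", "negative", "combined")))
  fold_pos <- vector("list", length(folds))
  fold_neg <- vector("list", length(folds))
  empty_folds <- 0L

  for (f in seq_along(folds)) {
    test <- folds[[f]]
    train <- setdiff(seq_len(n), test)
    nt <- length(train)
    if (use_fast) {
      i <- test
      r <- edge_behavior_cor(sx - x[i, ], sxx - x2[i, ], sxy - x[i, ] * y[i],
                             sy - y[i], syy - y[i]^2, nt)
      p <- cor_pvalue(r, nt)
      pos <- which(!is.na(r) & r > 0 & p < config$select_alpha)
      neg <- which(!is.na(r) & r < 0 & p < config$select_alpha)
    } else {
      sel <- select_edges(x[train, , drop = FALSE], y[train],
                          alpha = config$select_alpha, warn = FALSE)
      pos <- sel$positive; neg <- sel$negative
    }
    fold_pos[[f]] <- pos
    fold_neg[[f]] <- neg
    if (!length(pos) && !length(neg)) empty_folds <- empty_folds + 1L

    s_pos_tr <- if (length(pos)) network_strength(x[train, , drop = FALSE], pos)
    s_neg_tr <- if (length(neg)) network_strength(x[train, , drop = FALSE], neg)
    fits <- fit_strength_models(s_pos_tr, s_neg_tr, y[train])
    ytr_mean <- mean(y[train])

    s_pos_te <- network_strength(x[test, , drop = FALSE], pos)
    s_neg_te <- network_strength(x[test, , drop = FALSE], neg)
    preds[test, "positive"] <- if (!is.null(fits$positive)) {
      fits$positive["intercept"] + fits$positive["slope"] * s_pos_te
    } else ytr_mean
    preds[test, "negative"] <- if (!is.null(fits$negative)) {
      fits$negative["intercept"] + fits$negative["slope"] * s_neg_te
    } else ytr_mean
    preds[test, "combined"] <- if (!is.null(fits$combined)) {
      fits$combined["intercept"] + fits$combined["slope_pos"] * s_pos_te +
        fits$combined["slope_neg"] * s_neg_te
    } else if (!is.null(fits$positive) && length(pos)) {
      fits$positive["intercept"] + fits$positive["slope"] * s_pos_te
    } else if (!is.null(fits$negative) && length(neg)) {
      fits$negative["intercept"] + fits$negative["slope"] * s_neg_te
    } else ytr_mean
  }
  if (empty_folds > 0 && !quiet) {
    warning(empty_folds, " fold(s) selected no edges; training-mean prediction used")
  }

  r_raw <- apply(preds, 2, function(p) {
    if (stats::sd(p) < 1e-12) NA_real_ else stats::cor(p, y)
  })
  r_rep <- r_raw
  if (config$negative_r_to_zero) r_rep <- pmax(r_rep, 0, na.rm = FALSE)
  r_rep[is.na(r_raw)] <- 0

  structure(list(
    consensus_positive = Reduce(intersect, fold_pos),
    consensus_negative = Reduce(intersect, fold_neg),
    fold_positive = fold_pos, fold_negative = fold_neg,
    predictions = preds,
    performance = list(r = r_rep, r_raw = r_raw),
    folds = folds, n = n, config = config
  ), class = "cpm_model")
}

make_folds <- function(n, config, groups = NULL) {
  if (config$cv == "loocv") return(as.list(seq_len(n)))
  k <- config$k
  with_seed(config$seed, {
    assign_fold <- integer(n)
    if (is.null(groups)) {
      assign_fold <- sample(rep_len(seq_len(k), n))
    } else {
      for (g in unique(groups)) {
        idx <- sample(which(groups == g))
        assign_fold[idx] <- rep_len(seq_len(k), length(idx))
      }
    }
    unname(split(seq_len(n), assign_fold))
  })
}

#' Permutation significance of CPM performance
#'
#' Shuffles the correspondence between behavior and connectivity
#' `n_permutations` times, reruns the full cross-validated CPM on each
#' shuffle, and reports a one-tailed p-value per model:
#' `(1 + #\{null r >= observed r\}) / (n_permutations + 1)`. Raw
#' (un-zeroed) correlations are compared. An undefined observed r
#' (constant predictions) gives p = 1 with a warning.
#'
#' @param x subjects x E edge matrix.
#' @param y behavioral score.
#' @param config a [cpm_config()].
#' @param groups optional group labels (stratified k-fold).
#' @param model optional precomputed observed [cross_validate()] model.
#' @return list with `p` (per model), `observed` (raw r), `null`
#'   (n_permutations x 3 matrix) and the observed `model`.
#' @export
permutation_test <- function(x, y, config = cpm_config(), groups = NULL,
                             model = NULL) {
  if (is.null(model)) model <- cross_validate(x, y, config, groups)
  observed <- model$performance$r_raw
  seeds <- derive_seeds(config$seed, config$n_permutations + 1L)
  null <- matrix(NA_real_, config$n_permutations, 3,
                 dimnames = list(NULL, names(observed)))
  for (b in seq_len(config$n_permutations)) {
    yb <- with_seed(seeds[[b + 1L]], sample(y))
    mb <- cross_validate(x, yb, config, groups, quiet = TRUE)
    null[b, ] <- mb$performance$r_raw
  }
  p <- vapply(seq_len(3), function(m) {
    if (is.na(observed[m])) {
      warning("observed r undefined for the ", colnames(null)[m],
              " model; p set to 1")
      return(1)
    }
    (1 + sum(null[, m] >= observed[m], na.rm = TRUE)) /
      (config$n_permutations + 1)
  }, numeric(1))
  names(p) <- colnames(null)
  list(p = p, observed = observed, null = null, model = model)
}

#' Node degree table of an edge set
#'
#' Degree = number of edges of the set incident to each node, annotated
#' with atlas lobe/class/network columns when supplied; the handshake
#' identity (sum of degrees = 2 x edges) always holds.
#'
#' @param edges integer edge indices (1-based package convention).
#' @param n_regions number of regions.
#' @param atlas optional atlas table from [load_atlas()].
#' @param top_k optionally keep only the k highest-degree nodes.
#' @return data.frame sorted by decreasing degree with columns `region`,
#'   `degree` and any atlas annotations.
#' @export
degree_table <- function(edges, n_regions, atlas = NULL, top_k = NULL) {
  idx <- edge_index(n_regions)[edges, , drop = FALSE]
  deg <- tabulate(c(idx$i, idx$j), nbins = n_regions)
  out <- data.frame(region = seq_len(n_regions), degree = deg)
  if (!is.null(atlas)) {
    out <- cbind(out, atlas[match(out$region, atlas$region_id),
                            c("name", "lobe", "class", "canonical_network")])
    rownames(out) <- NULL
  }
  out <- out[order(-out$degree, out$region), , drop = FALSE]
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  rownames(out) <- NULL
  out
}

#' Partial correlation controlling for covariates
#'
#' Residualizes both variables on the covariates (OLS with intercept) and
#' correlates the residuals; p from the t-transform with
#' `df = n - 2 - n_covariates` (two-tailed). With `covariates = NULL`
#' this is the ordinary Pearson correlation test.
#'
#' @param a,b numeric vectors.
#' @param covariates optional numeric matrix/data.frame.
#' @return list with `r`, `p`, `df`.
#' @export
partial_cor <- function(a, b, covariates = NULL) {
  n <- length(a)
  stopifnot(length(b) == n)
  k <- 0L
  if (!is.null(covariates)) {
    cm <- as.matrix(covariates)
    stopifnot(nrow(cm) == n)
    k <- ncol(cm)
    design <- cbind(1, cm)
    qrd <- qr(design)
    a <- a - design %*% qr.coef(qrd, a)
    b <- b - design %*% qr.coef(qrd, b)
  }
  r <- stats::cor(as.vector(a), as.vector(b))
  df <- n - 2L - k
  t <- r * sqrt(df / max(1 - r * r, 1e-300))
  list(r = r, p = 2 * stats::pt(-abs(t), df), df = df)
}

#' High-degree-node follow-up
#'
#' For each of the `k` highest-degree nodes of the consensus positive
#' network: restrict the network to edges incident to that node,
#' recompute per-subject strength, correlate with behavior (partial
#' correlation given covariates), and Benjamini-Hochberg-adjust across
#' the k nodes. Nodes with zero incident edges are skipped with a
#' warning.
#'
#' @param x subjects x E edge matrix.
#' @param y behavioral score.
#' @param model a `cpm_model` with a consensus network.
#' @param n_regions number of regions.
#' @param k number of top nodes (default 4).
#' @param covariates optional covariate matrix/data.frame.
#' @param atlas optional atlas for names.
#' @param edge_set which consensus set to use (default positive).
#' @return data.frame with `region`, `degree`, `r`, `p`, `p_fdr` (and
#'   `name` when an atlas is given).
#' @export
high_degree_followup <- function(x, y, model, n_regions, k = 4L,
                                 covariates = NULL, atlas = NULL,
                                 edge_set = c("positive", "negative")) {
  edge_set <- match.arg(edge_set)
  edges <- if (edge_set == "positive") model$consensus_positive else
    model$consensus_negative
  if (!length(edges)) stop("consensus ", edge_set, " network is empty")
  top <- degree_table(edges, n_regions, atlas = atlas, top_k = k)
  top <- top[top$degree > 0, , drop = FALSE]
  if (nrow(top) < k) warning("only ", nrow(top), " node(s) have incident edges")
  idx <- edge_index(n_regions)
  res <- lapply(top$region, function(node) {
    inc <- incident_edges(edges, node, idx)
    s <- network_strength(x, inc)
    pc <- partial_cor(s, y, covariates)
    data.frame(region = node, degree = top$degree[top$region == node],
               n_edges = length(inc), r = pc$r, p = pc$p)
  })
  out <- do.call(rbind, res)
  out$p_fdr <- fdr_adjust(out$p)
  if (!is.null(atlas)) {
    out$name <- atlas$name[match(out$region, atlas$region_id)]
  }
  rownames(out) <- NULL
  out
}

#' Group-wise evaluation of network strength
#'
#' Within-group Pearson correlation between consensus-network strength
#' and behavior, to ask whether the predictive network is group-specific.
#' Groups with fewer than 4 subjects are excluded with a warning.
#'
#' @param strength per-subject network strength.
#' @param y behavioral score.
#' @param groups group labels.
#' @return data.frame with `group`, `n`, `r`, `p`.
#' @export
groupwise_evaluation <- function(strength, y, groups) {
  groups <- as.factor(groups)
  res <- lapply(levels(groups), function(g) {
    idx <- which(groups == g)
    if (length(idx) < 4) {
      warning("group ", g, " has fewer than 4 subjects; excluded")
      return(NULL)
    }
    ct <- stats::cor.test(strength[idx], y[idx])
    data.frame(group = g, n = length(idx), r = unname(ct$estimate),
               p = ct$p.value)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' @export
print.cpm_model <- function(x, ...) {
  cat("CPM model (", x$config$cv, "): consensus ",
      length(x$consensus_positive), " positive / ",
      length(x$consensus_negative), " negative edge(s)\n", sep = "")
  r <- x$performance$r
  cat(sprintf("  performance r: positive %.3f, negative %.3f, combined %.3f\n",
              r[1], r[2], r[3]))
  invisible(x)
}
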