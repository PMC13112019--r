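# Single-mediator mediation (exposure -> connectivity -> cognition) with
# covariate adjustment and bootstrap confidence intervals for the indirect
# effect.

#' Fit the mediation path regressions
#'
#' Three OLS regressions with a common covariate set:
#' `M ~ X + C` (path a), `Y ~ X + M + C` (paths c' and b) and
#' `Y ~ X + C` (total effect c). Continuous variables are mean-centered
#' before fitting. With identical covariate sets the OLS decomposition
#' `c = c' + a*b` holds exactly.
#'
#' @param x exposure (e.g. hemoglobin in g/L, or RDW).
#' @param m mediator (e.g. mean Fisher-z connectivity over a CPM network).
#' @param y outcome (e.g. a cognitive score).
#' @param covariates optional data.frame/matrix (e.g. age, sex, brain
#'   volume); binary columns are left uncentered.
#' @param standardize z-score x, m and y before fitting, so paths are in
#'   SD units (default `FALSE`).
#' @return data.frame with rows `a`, `b`, `c_prime`, `total_c`:
#'   `estimate`, `se`, `p`.
#' @export
fit_paths <- function(x, m, y, covariates = NULL, standardize = FALSE) {
  n <- length(x)
  stopifnot(length(m) == n, length(y) == n)
  if (anyNA(x) || anyNA(m) || anyNA(y)) {
    stop("missing values in x, m or y; apply listwise deletion first")
  }
  k <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n <= k + 3) stop("need n > n_covariates + 3 observations")
  prep <- function(v) {
    if (standardize) as.vector(scale(v)) else v - mean(v)
  }
  x <- prep(x); m <- prep(m); y <- prep(y)
  cmat <- NULL
  if (k > 0) {
    cmat <- as.matrix(covariates)
    if (is.null(colnames(cmat))) colnames(cmat) <- paste0("cov", seq_len(k))
    cont <- apply(cmat, 2, function(col) length(unique(col)) > 2)
    cmat[, cont] <- sweep(cmat[, cont, drop = FALSE], 2,
                          colMeans(cmat[, cont, drop = FALSE]))
  }
  check_rank <- function(design) {
    qrd <- qr(design)
    if (qrd$rank < ncol(design)) {
      bad <- colnames(design)[setdiff(seq_len(ncol(design)),
                                      qrd$pivot[seq_len(qrd$rank)])]
      stop("collinear design; offending column(s): ",
           paste(bad, collapse = ", "))
    }
  }
  design_a <- cbind(intercept = 1, x = x, cmat)
  design_b <- cbind(intercept = 1, x = x, m = m, cmat)
  check_rank(design_a); check_rank(design_b)

  ols <- function(design, yy) {
    fit <- stats::lm.fit(design, yy)
    res <- fit$residuals
    df <- length(yy) - ncol(design)
    sigma2 <- sum(res * res) / df
    xtx_inv <- chol2inv(qr.R(fit$qr))
    se <- numeric(ncol(design))
    se[fit$qr$pivot] <- sqrt(sigma2 * diag(xtx_inv))  # undo qr pivoting
    tval <- fit$coefficients / se
    list(coef = fit$coefficients, se = se, p = 2 * stats::pt(-abs(tval), df))
  }
  fa <- ols(design_a, m)
  fb <- ols(design_b, y)
  fc <- ols(design_a, y)
  out <- data.frame(
    path = c("a", "b", "c_prime", "total_c"),
    estimate = c(fa$coef["x"], fb$coef["m"], fb$coef["x"], fc$coef["x"]),
    se = c(fa$se[2], fb$se[3], fb$se[2], fc$se[2]),
    p = c(fa$p[2], fb$p[3], fb$p[2], fc$p[2]))
  rownames(out) <- out$path
  out
}

#' Bootstrap mediation analysis (single mediator, Model-4 style)
#'
#' Fits the path regressions, then resamples subjects with replacement
#' `n_boot` times to build a confidence interval for the indirect effect
#' `a*b` (percentile by default; bias-corrected-and-accelerated
#' optional). Degenerate resamples (constant exposure) are redrawn and
#' counted, with a warning if they exceed 1% of draws. The
#' `full_mediation` flag is `TRUE` when the indirect CI excludes 0 and
#' the direct path c' is non-significant at 0.05.
#'
#' @inheritParams fit_paths
#' @param n_boot bootstrap resamples (default 1000).
#' @param conf_level confidence level (default 0.95).
#' @param method `"percentile"` (default) or `"bca"`.
#' @param seed RNG seed for the bootstrap.
#' @return object of class `mediation_result`: `paths` (from
#'   [fit_paths()]), `indirect`, `ci`, `boot` (the draws),
#'   `full_mediation`, `n`, `n_redrawn`.
#' @export
mediate <- function(x, m, y, covariates = NULL, n_boot = 1000L,
                    conf_level = 0.95, method = c("percentile", "bca"),
                    seed = NULL, standardize = FALSE) {
  method <- match.arg(method)
  keep <- stats::complete.cases(x, m, y,
                                if (is.null(covariates)) rep(TRUE, length(x))
                                else as.matrix(covariates))
  x <- x[keep]; m <- m[keep]; y <- y[keep]
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)[keep, , drop = FALSE]
  }
  n <- length(x)
  paths <- fit_paths(x, m, y, covariates, standardize = standardize)
  indirect <- paths["a", "estimate"] * paths["b", "estimate"]

  ab_for <- function(idx) {
    px <- x[idx]; pm <- m[idx]; py <- y[idx]
    if (standardize) {
      px <- as.vector(scale(px)); pm <- as.vector(scale(pm))
      py <- as.vector(scale(py))
    }
    pc <- if (is.null(covariates)) NULL else covariates[idx, , drop = FALSE]
    da <- cbind(1, px, pc)
    db <- cbind(1, px, pm, pc)
    a <- stats::.lm.fit(da, pm)$coefficients[2]
    b <- stats::.lm.fit(db, py)$coefficients[3]
    a * b
  }

  n_redrawn <- 0L
  draws <- with_seed(seed, {
    vapply(seq_len(n_boot), function(bb) {
      for (try in 1:100) {
        idx <- sample.int(n, n, replace = TRUE)
        if (stats::sd(x[idx]) > 0 && stats::sd(m[idx]) > 0) break
        n_redrawn <<- n_redrawn + 1L
      }
      ab_for(idx)
    }, numeric(1))
  })
  if (n_redrawn > 0.01 * n_boot) {
    warning(n_redrawn, " degenerate bootstrap resample(s) redrawn")
  }
  alpha <- 1 - conf_level
  ci <- if (method == "percentile") {
    unname(stats::quantile(draws, c(alpha / 2, 1 - alpha / 2)))
  } else {
    bca_interval(draws, indirect, conf_level,
                 jack = vapply(seq_len(n), function(i) ab_for(setdiff(seq_len(n), i)),
                               numeric(1)))
  }
  structure(list(
    paths = paths, indirect = indirect, ci = ci, conf_level = conf_level,
    method = method, boot = draws, n = n, n_redrawn = n_redrawn,
    full_mediation = (ci[1] > 0 || ci[2] < 0) &&
      paths["c_prime", "p"] >= 0.05
  ), class = "mediation_result")
}

# Bias-corrected and accelerated interval from bootstrap draws + jackknife.
bca_interval <- function(draws, est, conf_level, jack) {
  alpha <- 1 - conf_level
  z0 <- stats::qnorm(mean(draws < est))
  jm <- mean(jack)
  num <- sum((jm - jack)^3)
  den <- 6 * sum((jm - jack)^2)^1.5
  acc <- if (den == 0) 0 else num / den
  adj <- function(a) {
    z <- z0 + stats::qnorm(a)
    stats::pnorm(z0 + z / (1 - acc * z))
  }
  unname(stats::quantile(draws, c(adj(alpha / 2), adj(1 - alpha / 2))))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone); a thin validated front-end to
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
fdr_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Mediation (n =", x$n, "):\n")
  print(round(x$paths[, c("estimate", "se", "p")], 4))
  cat(sprintf("indirect a*b = %.4f, %d%% %s CI [%.4f, %.4f]%s\n",
              x$indirect, round(100 * x$conf_level), x$method,
              x$ci[1], x$ci[2],
              if (isTRUE(x$full_mediation)) "  (full mediation)" else ""))
  invisible(x)
}

#' Write a mediation result as flat files
#'
#' @param result a `mediation_result`.
#' @param dir output directory.
#' @param label file-name stem (e.g. the exposure name).
#' @param write_draws also write the bootstrap draws TSV.
#' @return `dir`, invisibly.
#' @export
write_mediation_result <- function(result, dir, label = "mediation",
                                   write_draws = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- result$paths
  tab$ci_low <- NA_real_; tab$ci_high <- NA_real_
  utils::write.csv(tab, file.path(dir, paste0(label, "_paths.csv")),
                   row.names = FALSE)
  if (write_draws) {
    utils::write.table(data.frame(indirect = result$boot),
                       file.path(dir, paste0(label, "_boot.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(list(
    paths = as.list(stats::setNames(result$paths$estimate, result$paths$path)),
    p = as.list(stats::setNames(result$paths$p, result$paths$path)),
    indirect = result$indirect, ci = result$ci,
    conf_level = result$conf_level, method = result$method,
    full_mediation = result$full_mediation, n = result$n),
    file.path(dir, paste0(label, "_summary.json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
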