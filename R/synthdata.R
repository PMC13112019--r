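# Synthetic cohort generator with planted ground truth.
#
# Emulates a two-group connectome cohort (patients vs. controls) in which a
# connected set of edges is weakened in patients, a behavioral score is a
# linear readout of network strength over a planted edge set, and, in
# patients only, hematological exposures act on behavior purely through that
# network (full mediation by construction). Every stochastic operation takes
# an explicit seed; defaults derive deterministically from the spec seed.

#' Specification of a synthetic connectome cohort
#'
#' Captures every generative parameter: group sizes, parcellation size,
#' time-series length, the planted group-difference edge set and its
#' Fisher-z deficit in patients, the behavior-carrying edge set, the
#' behavior model, and the mediation path coefficients. Defaults mirror a
#' 116-region pediatric cohort of 25 patients and 35 controls with a
#' connected 72-edge disrupted component spanning 41 regions, of which 30
#' edges drive the behavioral score.
#'
#' @param n_patients,n_controls group sizes.
#' @param n_regions parcellation size (default 116).
#' @param n_timepoints usable volumes per subject (default 120: a
#'   130-volume acquisition minus 10 discarded equilibration volumes).
#' @param disrupted_edges integer edge indices (1-based, package edge
#'   convention) weakened in patients; `NULL` plants a connected 72-edge
#'   component over 41 regions drawn from the spec seed.
#' @param disruption_delta Fisher-z units subtracted from patient edge
#'   means on `disrupted_edges` (default 0.6).
#' @param behavior_edges edge indices whose summed strength drives the
#'   behavioral score; `NULL` takes 30 of the disrupted edges. May be
#'   `integer(0)` for a pure-noise behavior (null designs).
#' @param behavior_slope score units per unit summed Fisher-z strength
#'   (default 2).
#' @param noise_sd_behavior behavioral noise SD in score units (default 8).
#' @param mediation_strength list with unitless path coefficients on the
#'   standardized-exposure scale: `a` (exposure -> mediator), `b`
#'   (mediator -> outcome), `c_prime` (direct path; default 0, i.e. full
#'   mediation), `a_rdw` (magnitude of the negative RDW a-path), and the
#'   residual SDs `sigma_m`, `sigma_y` of the mediator and outcome
#'   models. The defaults (a = 0.43, b = 0.66, sigma_m = 0.59,
#'   sigma_y = 0.43) reproduce path standard errors of about 0.12 and
#'   0.15 at n = 25 patients.
#' @param subject_sd between-subject SD of true edge Fisher-z values
#'   (matrix route only; default 0.1).
#' @param ar_rho lag-1 temporal autocorrelation of the latent BOLD-like
#'   process (time-series route; default 0.3).
#' @param edge_z_mean,edge_z_sd population distribution of control edge
#'   Fisher-z targets (defaults 0.3 and 0.15).
#' @param seed master RNG seed for the cohort.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 25L, n_controls = 35L, n_regions = 116L,
                        n_timepoints = 120L,
                        disrupted_edges = NULL, disruption_delta = 0.6,
                        behavior_edges = NULL, behavior_slope = 2,
                        noise_sd_behavior = 8,
                        mediation_strength = list(a = 0.43, b = 0.66,
                                                  c_prime = 0, a_rdw = 0.48,
                                                  sigma_m = 0.59,
                                                  sigma_y = 0.43),
                        subject_sd = 0.1, ar_rho = 0.3,
                        edge_z_mean = 0.3, edge_z_sd = 0.15,
                        seed = 1L) {
  stopifnot(n_patients > 0, n_controls > 0, n_regions >= 3, n_timepoints >= 5,
            noise_sd_behavior >= 0, subject_sd >= 0,
            abs(ar_rho) < 1, edge_z_sd >= 0)
  e <- n_edges(n_regions)
  seeds <- derive_seeds(seed, 5L)
  if (is.null(disrupted_edges)) {
    if (disruption_delta != 0) {
      k_nodes <- min(41L, n_regions)
      k_edges <- min(72L, n_edges(k_nodes))
      nodes <- with_seed(seeds[[4]], sample.int(n_regions, k_nodes))
      disrupted_edges <- planted_component(nodes, k_edges, n_regions,
                                           seed = seeds[[4]])
    } else {
      disrupted_edges <- integer(0)
    }
  }
  disrupted_edges <- sort(unique(as.integer(disrupted_edges)))
  if (is.null(behavior_edges)) {
    k <- min(30L, length(disrupted_edges))
    behavior_edges <- if (k > 0) {
      with_seed(seeds[[5]], sort(sample(disrupted_edges, k)))
    } else integer(0)
  }
  behavior_edges <- sort(unique(as.integer(behavior_edges)))
  for (set in list(disrupted_edges, behavior_edges)) {
    if (length(set) && (min(set) < 1 || max(set) > e)) {
      stop("edge indices must lie in 1..", e, " for ", n_regions, " regions")
    }
  }
  ms <- utils::modifyList(list(a = 0.43, b = 0.66, c_prime = 0, a_rdw = 0.48,
                               sigma_m = 0.59, sigma_y = 0.43),
                          as.list(mediation_strength))
  structure(list(
    n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
    n_regions = as.integer(n_regions), n_timepoints = as.integer(n_timepoints),
    disrupted_edges = disrupted_edges, disruption_delta = disruption_delta,
    behavior_edges = behavior_edges, behavior_slope = behavior_slope,
    noise_sd_behavior = noise_sd_behavior, mediation_strength = ms,
    subject_sd = subject_sd, ar_rho = ar_rho,
    edge_z_mean = edge_z_mean, edge_z_sd = edge_z_sd,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Plant a connected edge component
#'
#' Builds a connected subgraph over `nodes` with exactly `size` edges: a
#' random spanning tree plus random extra within-set edges.
#'
#' @param nodes region indices (1-based) spanned by the component.
#' @param size number of edges (`length(nodes) - 1 <= size <= choose(k, 2)`).
#' @param n_regions total number of regions (for edge-index mapping).
#' @param seed RNG seed.
#' @return sorted integer vector of edge indices.
#' @export
planted_component <- function(nodes, size, n_regions, seed = NULL) {
  k <- length(nodes)
  stopifnot(k >= 2, size >= k - 1, size <= k * (k - 1) / 2)
  with_seed(seed, {
    nodes <- sample(nodes)     # random tree shape
    pairs <- matrix(0L, size, 2)
    for (v in 2:k) {           # spanning tree: attach each node to an earlier one
      pairs[v - 1, ] <- sort(c(nodes[v], nodes[sample.int(v - 1, 1)]))
    }
    all_pairs <- t(utils::combn(sort(nodes), 2))
    have <- paste(pairs[seq_len(k - 1), 1], pairs[seq_len(k - 1), 2])
    pool <- all_pairs[!(paste(all_pairs[, 1], all_pairs[, 2]) %in% have), ,
                      drop = FALSE]
    extra <- size - (k - 1)
    if (extra > 0) {
      pick <- pool[sample.int(nrow(pool), extra), , drop = FALSE]
      pairs[k:size, ] <- pick
    }
    sort(pair_to_edge(pairs[, 1], pairs[, 2], n_regions))
  })
}

# Edge index of a (i, j) pair (1-based, i < j, row-major upper triangle).
pair_to_edge <- function(i, j, n_regions) {
  swap <- i > j
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  as.integer((i - 1) * n_regions - i * (i - 1) / 2 + (j - i))
}

# Group-level edge Fisher-z targets: controls drawn once per cohort,
# patients = controls minus the planted deficit.
edge_targets <- function(spec, seed) {
  e <- n_edges(spec$n_regions)
  z_control <- with_seed(seed, stats::rnorm(e, spec$edge_z_mean, spec$edge_z_sd))
  z_patient <- z_control
  z_patient[spec$disrupted_edges] <-
    z_patient[spec$disrupted_edges] - spec$disruption_delta
  list(control = z_control, patient = z_patient)
}

new_cohort <- function(spec, z, manifest, timeseries = NULL, targets = NULL) {
  structure(list(z = z, manifest = manifest, timeseries = timeseries,
                 targets = targets, ground_truth = spec),
            class = "synthetic_cohort")
}

base_manifest <- function(spec, seed) {
  n <- spec$n_patients + spec$n_controls
  with_seed(seed, data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = rep(c("patient", "control"), c(spec$n_patients, spec$n_controls)),
    wis = NA_real_,
    age = round(stats::runif(n, 6.3, 15.1), 2),
    sex = stats::rbinom(n, 1, 0.5),
    brain_volume = round(stats::rnorm(n), 3),
    hemoglobin = NA_real_,
    rdw = NA_real_,
    stringsAsFactors = FALSE
  ))
}

#' Generate a cohort of connectivity matrices (direct z-matrix route)
#'
#' Draws each subject's edge vector around the group-level Fisher-z target:
#' target + between-subject deviation (`subject_sd`) + correlation-sampling
#' noise with SD `1/sqrt(T - 3)` (the asymptotic Fisher-z standard error
#' for `T` timepoints). Fast route used for large replicate simulations;
#' the implied matrices are exactly symmetric with zero diagonal.
#'
#' @param spec a [cohort_spec()].
#' @param seed RNG seed; `NULL` derives one from the spec seed.
#' @return object of class `synthetic_cohort` with fields `z` (subjects x E
#'   edge matrix), `manifest`, `targets` and `ground_truth`.
#' @export
generate_matrix_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  seeds <- derive_seeds(spec$seed, 5L)
  seed <- seed %||% seeds[[1]]
  e <- n_edges(spec$n_regions)
  n <- spec$n_patients + spec$n_controls
  sub <- derive_seeds(seed, 3L)
  targets <- edge_targets(spec, sub[[1]])
  sample_sd <- 1 / sqrt(spec$n_timepoints - 3)
  z <- with_seed(sub[[2]], {
    mu <- rbind(
      matrix(targets$patient, spec$n_patients, e, byrow = TRUE),
      matrix(targets$control, spec$n_controls, e, byrow = TRUE))
    mu + matrix(stats::rnorm(n * e, 0, sqrt(spec$subject_sd^2 + sample_sd^2)),
                n, e)
  })
  new_cohort(spec, z, base_manifest(spec, sub[[3]]), targets = targets)
}

#' Generate a cohort of ROI time series (BOLD-like route)
#'
#' For each group, edge correlation targets (`tanh` of the Fisher-z
#' targets) are assembled into a correlation matrix and projected to the
#' nearest positive semi-definite correlation matrix by eigenvalue
#' clipping. Each subject's T x N series is a stationary AR(1) process
#' (lag-1 autocorrelation `ar_rho`) given the group correlation structure
#' via a Cholesky factor, so detrending/bandpass operations act on
#' temporally autocorrelated input. Subject z-matrices are computed from
#' the raw series with [correlation_matrix()].
#'
#' The projection shrinks planted contrasts: with dense random targets
#' the patient and control matrices are both displaced, and part of the
#' requested group difference is absorbed. The realized population
#' Fisher-z contrast on each disrupted edge is checked after projection;
#' if the mean preserved contrast falls below `min_contrast_frac` of
#' `disruption_delta`, or any planted edge's contrast is lost entirely
#' (non-positive), the requested edits are infeasible and the function
#' stops, naming the worst-affected edges.
#'
#' @param spec a [cohort_spec()].
#' @param seed RNG seed; `NULL` derives one from the spec seed.
#' @param min_contrast_frac minimum fraction of the planted Fisher-z
#'   contrast that must survive the positive semi-definite projection
#'   (default 0.25).
#' @return `synthetic_cohort` with `timeseries` (list of T x N matrices),
#'   `z` (subjects x E edge matrix) and `manifest`.
#' @export
generate_timeseries_cohort <- function(spec, seed = NULL,
                                       min_contrast_frac = 0.25) {
  stopifnot(inherits(spec, "cohort_spec"))
  seeds <- derive_seeds(spec$seed, 5L)
  seed <- seed %||% seeds[[1]]
  sub <- derive_seeds(seed, 4L)
  n_reg <- spec$n_regions
  targets <- edge_targets(spec, sub[[1]])

  build_corr <- function(zvec) {
    r_target <- devectorize(tanh(zvec), n_reg)
    diag(r_target) <- 1
    nearest_psd(r_target)
  }
  r_control <- build_corr(targets$control)
  r_patient <- build_corr(targets$patient)
  de <- spec$disrupted_edges
  if (length(de) && spec$disruption_delta > 0) {
    clip <- function(v) pmin(pmax(v, -1 + 1e-7), 1 - 1e-7)
    contrast <- atanh(clip(vectorize(r_control, tol = Inf))) -
      atanh(clip(vectorize(r_patient, tol = Inf)))
    preserved <- contrast[de]
    if (mean(preserved) < min_contrast_frac * spec$disruption_delta ||
        any(preserved <= 0)) {
      bad <- de[order(preserved)][seq_len(min(5, length(de)))]
      idx <- edge_index(n_reg)[bad, ]
      stop("requested edge edits are infeasible: the positive semi-definite ",
           "projection erases the planted contrast; worst edges (i, j): ",
           paste(sprintf("(%d,%d)", idx$i, idx$j), collapse = ", "))
    }
  }

  chol_c <- chol(r_control + diag(1e-10, n_reg))
  chol_p <- chol(r_patient + diag(1e-10, n_reg))
  tt <- spec$n_timepoints
  burn <- 20L
  rho <- spec$ar_rho

  simulate_subject <- function(chol_r) {
    innov <- matrix(stats::rnorm((tt + burn) * n_reg, 0, sqrt(1 - rho^2)),
                    tt + burn, n_reg)
    lat <- stats::filter(innov, rho, method = "recursive")
    lat <- lat[(burn + 1):(burn + tt), , drop = FALSE]
    as.matrix(lat) %*% chol_r
  }

  n <- spec$n_patients + spec$n_controls
  series <- with_seed(sub[[2]], {
    lapply(seq_len(n), function(s) {
      simulate_subject(if (s <= spec$n_patients) chol_p else chol_c)
    })
  })
  z <- t(vapply(series, function(ts) vectorize(correlation_matrix(ts)),
                numeric(n_edges(n_reg))))
  new_cohort(spec, z, base_manifest(spec, sub[[3]]), timeseries = series,
             targets = targets)
}

#' Generate the behavioral score from network strength
#'
#' Sets each subject's behavior to
#' `intercept + behavior_slope * strength + noise`, where strength is the
#' sum of the subject's Fisher-z values over `behavior_edges`. The
#' intercept is chosen so that the control-group mean sits at the
#' reference control score (107.07); with an empty behavior edge set the
#' score is pure noise around that reference (a null design).
#'
#' @param spec the [cohort_spec()] used to generate `cohort`.
#' @param cohort a `synthetic_cohort`.
#' @param seed RNG seed; `NULL` derives one from the spec seed.
#' @return the cohort with `manifest$wis` filled in.
#' @export
generate_behavior <- function(spec, cohort, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(cohort, "synthetic_cohort"))
  seeds <- derive_seeds(spec$seed, 5L)
  seed <- seed %||% seeds[[2]]
  n <- nrow(cohort$z)
  ctrl <- cohort$manifest$group == "control"
  if (length(spec$behavior_edges)) {
    strength <- rowSums(cohort$z[, spec$behavior_edges, drop = FALSE])
    intercept <- 107.07 - spec$behavior_slope * mean(strength[ctrl])
    mu <- intercept + spec$behavior_slope * strength
  } else {
    mu <- rep(107.07, n)
  }
  cohort$manifest$wis <- with_seed(seed,
    mu + stats::rnorm(n, 0, spec$noise_sd_behavior))
  cohort
}

#' Generate patient hematology with a planted mediation structure
#'
#' For patients only (hematology is not measured in controls): draws
#' hemoglobin near the reference moments (mean 104.28, SD 13.31 g/L),
#' builds a latent mediator `m = a * x + sigma_m * noise` from the
#' standardized hemoglobin `x`, rewrites the patients' behavior-edge
#' values so that their standardized network strength tracks `m`, and
#' regenerates the patient behavioral score as
#' `b * m + c_prime * x + sigma_y * noise`, rescaled to the patient score
#' scale (mean 71.57, SD 16.25). RDW (mean 42.06, SD 9.21) is generated
#' as a negatively mediator-correlated exposure so its fitted a-path is
#' negative with magnitude `a_rdw`. With `c_prime = 0` this plants full
#' mediation.
#'
#' @param spec the [cohort_spec()]; paths come from
#'   `spec$mediation_strength`.
#' @param cohort a `synthetic_cohort` whose behavior has been generated.
#' @param group must be `"patient"`; requesting hematology for controls is
#'   unsupported and signals an error.
#' @param seed RNG seed; `NULL` derives one from the spec seed.
#' @return the cohort with patient `hemoglobin`, `rdw`, adjusted `z`
#'   values on the behavior edges, and regenerated patient `wis`.
#' @export
generate_hematology <- function(spec, cohort, group = "patient", seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(cohort, "synthetic_cohort"))
  if (!identical(group, "patient")) {
    stop("hematology generation is supported for patients only; ",
         "controls carry no hematological measurements")
  }
  if (all(is.na(cohort$manifest$wis))) {
    stop("generate behavior before hematology (generate_behavior())")
  }
  if (!length(spec$behavior_edges)) {
    stop("cannot plant a mediation structure with an empty behavior edge set")
  }
  seeds <- derive_seeds(spec$seed, 5L)
  seed <- seed %||% seeds[[3]]
  pat <- which(cohort$manifest$group == "patient")
  np <- length(pat)
  ms <- spec$mediation_strength
  with_seed(seed, {
    hgb <- stats::rnorm(np, 104.28, 13.31)
    x <- (hgb - 104.28) / 13.31
    m <- ms$a * x + ms$sigma_m * stats::rnorm(np)
    sd_m <- sqrt(ms$a^2 + ms$sigma_m^2)        # theoretical SD of m
    be <- spec$behavior_edges
    s <- rowSums(cohort$z[pat, be, drop = FALSE])
    s_sd <- stats::sd(s)
    if (!is.finite(s_sd) || s_sd == 0) s_sd <- 1
    target <- mean(s) + s_sd * (m / sd_m)      # strength tracks m, same scale
    shift <- (target - s) / length(be)
    cohort$z[pat, be] <- cohort$z[pat, be, drop = FALSE] + shift
    y_std <- ms$b * m + ms$c_prime * x + ms$sigma_y * stats::rnorm(np)
    sd_y <- sqrt(ms$b^2 * sd_m^2 + ms$c_prime^2 + ms$sigma_y^2 +
                   2 * ms$a * ms$b * ms$c_prime)
    cohort$manifest$wis[pat] <- 71.57 + 16.25 * y_std / sd_y
    rho_r <- min(0.95, ms$a_rdw / sd_m)        # fitted RDW a-path ~ -a_rdw
    x_rdw <- -rho_r * (m / sd_m) + sqrt(max(0, 1 - rho_r^2)) * stats::rnorm(np)
    cohort$manifest$hemoglobin[pat] <- round(hgb, 2)
    cohort$manifest$rdw[pat] <- round(42.06 + 9.21 * x_rdw, 2)
  })
  cohort
}

#' Subject connectivity matrix from a cohort
#'
#' @param cohort a `synthetic_cohort`.
#' @param subject subject row index.
#' @return symmetric N x N Fisher-z matrix.
#' @export
cohort_matrix <- function(cohort, subject) {
  devectorize(cohort$z[subject, ], cohort$ground_truth$n_regions)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort spec:", x$n_patients, "patients /", x$n_controls,
      "controls,", x$n_regions, "regions,", x$n_timepoints, "timepoints\n")
  cat("  disrupted edges:", length(x$disrupted_edges),
      "(delta =", x$disruption_delta, "z); behavior edges:",
      length(x$behavior_edges), "\n")
  cat("  mediation paths: a =", x$mediation_strength$a, "b =",
      x$mediation_strength$b, "c' =", x$mediation_strength$c_prime, "\n")
  invisible(x)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$z), "subjects x", ncol(x$z), "edges",
      if (!is.null(x$timeseries)) "(with time series)" else "", "\n")
  invisible(x)
}

# ---- serialization ---------------------------------------------------------

#' Serialize / restore a cohort spec as canonical JSON
#'
#' The serialization is canonical (fixed field order, full precision) so a
#' spec written, reloaded and rewritten is byte-identical.
#'
#' @param spec a [cohort_spec()].
#' @param path output file.
#' @return `write_cohort_spec` returns `path`; `read_cohort_spec` the spec.
#' @export
write_cohort_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- do.call(cohort_spec, raw[setdiff(names(raw),
                                           c("disrupted_edges", "behavior_edges"))])
  spec$disrupted_edges <- as.integer(raw$disrupted_edges %||% integer(0))
  spec$behavior_edges <- as.integer(raw$behavior_edges %||% integer(0))
  spec
}

#' Write a synthetic cohort to disk
#'
#' Writes the subjects x edges Fisher-z matrix as TSV, the manifest as CSV,
#' the ground-truth spec as canonical JSON, and (when present) per-subject
#' time-series TSVs under `timeseries/`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cohort$z, file.path(dir, "z_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  write_cohort_spec(cohort$ground_truth, file.path(dir, "ground_truth.json"))
  if (!is.null(cohort$timeseries)) {
    tsdir <- file.path(dir, "timeseries")
    dir.create(tsdir, showWarnings = FALSE)
    for (s in seq_along(cohort$timeseries)) {
      write_timeseries_tsv(cohort$timeseries[[s]],
                           file.path(tsdir, paste0(cohort$manifest$subject_id[s],
                                                   ".tsv")))
    }
  }
  invisible(dir)
}

#' Read a synthetic cohort written by [write_cohort()]
#' @param dir cohort directory.
#' @return a `synthetic_cohort` (time series are not reloaded).
#' @export
read_cohort <- function(dir) {
  z <- as.matrix(utils::read.table(file.path(dir, "z_edges.tsv"), sep = "\t"))
  dimnames(z) <- NULL
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  spec <- read_cohort_spec(file.path(dir, "ground_truth.json"))
  new_cohort(spec, z, manifest)
}
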