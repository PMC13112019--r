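test_that("cohort_spec validates invariants and plants a connected default", {
  spec <- cohort_spec(seed = 3)
  expect_identical(n_edges(spec$n_regions), 6670L)
  expect_length(spec$disrupted_edges, 72)
  expect_length(spec$behavior_edges, 30)
  expect_true(all(spec$behavior_edges %in% spec$disrupted_edges))
  # default planted component is connected and spans 41 regions
  idx <- edge_index(spec$n_regions)[spec$disrupted_edges, ]
  expect_identical(length(unique(c(idx$i, idx$j))), 41L)
  comp <- connected_components(cbind(idx$i, idx$j))
  expect_identical(comp$sizes, 72L)

  expect_error(cohort_spec(n_regions = 10, disrupted_edges = 100),
               "1..45")
  expect_error(cohort_spec(n_patients = 0))
  expect_error(cohort_spec(noise_sd_behavior = -1))
})

test_that("planted_component builds connected sets of the requested size", {
  withr::local_seed(7)
  for (r in 1:20) {
    k <- sample(3:10, 1)
    nodes <- sample.int(30, k)
    size <- sample(seq(k - 1, k * (k - 1) / 2), 1)
    edges <- planted_component(nodes, size, 30, seed = r)
    expect_length(edges, size)
    idx <- edge_index(30)[edges, ]
    expect_setequal(unique(c(idx$i, idx$j)), nodes)
    expect_identical(sum(connected_components(cbind(idx$i, idx$j))$sizes > 0), 1L)
  }
})

test_that("generated matrices are symmetric with zero diagonal", {
  spec <- cohort_spec(n_patients = 4, n_controls = 4, n_regions = 12, seed = 5)
  for (co in list(generate_matrix_cohort(spec),
                  generate_timeseries_cohort(spec))) {
    m <- cohort_matrix(co, 1)
    expect_identical(m, t(m))
    expect_identical(diag(m), rep(0, 12))
    expect_true(all(is.finite(co$z)))
    expect_identical(nrow(co$manifest), 8L)
  }
})

test_that("zero disruption yields groups identical in distribution", {
  spec <- cohort_spec(n_patients = 40, n_controls = 40, n_regions = 10,
                      disruption_delta = 0, behavior_edges = integer(0),
                      seed = 11)
  expect_length(spec$disrupted_edges, 0)
  co <- generate_matrix_cohort(spec)
  g <- co$manifest$group
  # no planted difference: edge-wise two-sample t-statistics look null
  ts <- edge_tstats(co$z[g == "patient", ], co$z[g == "control", ],
                    tail = "two")
  expect_gt(stats::ks.test(ts$p, "punif")$p.value, 0.01)
})

test_that("planted Fisher-z contrast survives the time-series route", {
  # one disrupted edge, delta = 0.6, large n: mean sample z-difference
  # across replicates recovers the planted contrast within 0.1
  diffs <- vapply(1:50, function(r) {
    spec <- cohort_spec(n_patients = 200, n_controls = 200, n_regions = 10,
                        disrupted_edges = 5L, disruption_delta = 0.6,
                        behavior_edges = integer(0), seed = 400 + r)
    co <- generate_timeseries_cohort(spec)
    g <- co$manifest$group
    mean(co$z[g == "control", 5]) - mean(co$z[g == "patient", 5])
  }, numeric(1))
  expect_lt(abs(mean(diffs) - 0.6), 0.1)
})

test_that("PSD projection at full scale preserves a usable planted contrast", {
  # with dense random targets over 116 regions the projection absorbs
  # roughly half of the 0.6-z planted deficit; what survives must stay
  # far above the per-edge sampling noise
  spec <- cohort_spec(seed = 42)
  co <- generate_timeseries_cohort(spec)
  g <- co$manifest$group
  d <- colMeans(co$z[g == "control", spec$disrupted_edges, drop = FALSE]) -
    colMeans(co$z[g == "patient", spec$disrupted_edges, drop = FALSE])
  expect_gt(mean(d), 0.2)
  expect_lt(mean(d), 0.45)
  expect_gt(min(d), 0.05)
})

test_that("noiseless behavior is exactly linear in network strength", {
  spec <- cohort_spec(n_patients = 10, n_controls = 10, n_regions = 12,
                      noise_sd_behavior = 0, seed = 13)
  co <- generate_behavior(spec, generate_matrix_cohort(spec))
  s <- network_strength(co$z, spec$behavior_edges)
  fit <- lm(co$manifest$wis ~ s)
  expect_equal(unname(coef(fit)[2]), spec$behavior_slope, tolerance = 1e-10)
  expect_lt(max(abs(residuals(fit))), 1e-8)
})

test_that("null behavior yields chance-level edge selection", {
  # behavior_edges empty: expected selected count ~ alpha * E
  spec <- cohort_spec(n_patients = 30, n_controls = 30, n_regions = 40,
                      disruption_delta = 0, behavior_edges = integer(0),
                      seed = 17)
  counts <- vapply(1:20, function(r) {
    s2 <- spec; s2$seed <- 17L + r
    co <- generate_behavior(s2, generate_matrix_cohort(s2))
    sel <- select_edges(co$z, co$manifest$wis, alpha = 0.05)
    length(sel$positive) + length(sel$negative)
  }, numeric(1))
  expected <- 0.05 * n_edges(40)
  expect_lt(abs(mean(counts) - expected) / expected, 0.35)
})

test_that("positive slope makes behavior-edge correlations positive", {
  spec <- cohort_spec(n_patients = 30, n_controls = 30, n_regions = 20,
                      disruption_delta = 0, seed = 19,
                      behavior_edges = 1:10, behavior_slope = 3,
                      noise_sd_behavior = 2)
  # each behavior edge carries only a slice of the summed signal, so the
  # sign is established per edge by averaging sample correlations over
  # replicate cohorts
  rbar <- Reduce(`+`, lapply(1:10, function(r) {
    s2 <- spec; s2$seed <- 100L + r
    co <- generate_behavior(s2, generate_matrix_cohort(s2))
    suppressWarnings(select_edges(co$z, co$manifest$wis)$r)
  })) / 10
  expect_true(all(rbar[spec$behavior_edges] > 0))
  expect_lt(mean(abs(rbar[-spec$behavior_edges])), 0.1)
})

test_that("hematology is patient-only with reference moments", {
  spec <- cohort_spec(n_patients = 25, n_controls = 10, n_regions = 16,
                      seed = 23)
  co <- generate_behavior(spec, generate_matrix_cohort(spec))
  expect_error(generate_hematology(spec, co, group = "control"),
               "patients only")
  co <- generate_hematology(spec, co)
  pat <- co$manifest$group == "patient"
  expect_true(all(is.na(co$manifest$hemoglobin[!pat])))
  expect_true(all(is.na(co$manifest$rdw[!pat])))
  # sample mean within 2 standard errors of the reference mean
  expect_lt(abs(mean(co$manifest$hemoglobin[pat]) - 104.28),
            2 * 13.31 / sqrt(25))
  # planted structure: strength over behavior edges tracks hemoglobin
  s <- network_strength(co$z, spec$behavior_edges)[pat]
  expect_gt(cor(s, co$manifest$hemoglobin[pat]), 0.2)
  expect_lt(cor(s, co$manifest$rdw[pat]), -0.2)
})

test_that("hematology requires behavior first", {
  spec <- cohort_spec(n_patients = 6, n_controls = 6, n_regions = 10, seed = 29)
  co <- generate_matrix_cohort(spec)
  expect_error(generate_hematology(spec, co), "behavior")
})

test_that("ground truth round-trips byte-identically", {
  dir <- withr::local_tempdir()
  spec <- cohort_spec(n_patients = 5, n_controls = 6, n_regions = 14, seed = 31)
  p1 <- file.path(dir, "gt1.json"); p2 <- file.path(dir, "gt2.json")
  write_cohort_spec(spec, p1)
  spec2 <- read_cohort_spec(p1)
  write_cohort_spec(spec2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  expect_equal(spec2$disrupted_edges, spec$disrupted_edges)
})

test_that("cohorts round-trip through the on-disk layout", {
  dir <- withr::local_tempdir()
  spec <- cohort_spec(n_patients = 4, n_controls = 5, n_regions = 10, seed = 37)
  co <- generate_behavior(spec, generate_matrix_cohort(spec))
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$z, co$z, tolerance = 1e-10)
  expect_identical(back$manifest$subject_id, co$manifest$subject_id)
  expect_equal(back$ground_truth$behavior_edges, spec$behavior_edges)
})

test_that("generation is reproducible from the spec seed", {
  spec <- cohort_spec(n_patients = 4, n_controls = 4, n_regions = 10, seed = 41)
  co1 <- generate_behavior(spec, generate_matrix_cohort(spec))
  co2 <- generate_behavior(spec, generate_matrix_cohort(spec))
  expect_identical(co1$z, co2$z)
  expect_identical(co1$manifest$wis, co2$manifest$wis)
})
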