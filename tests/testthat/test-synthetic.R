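# a desk-fast cohort configuration: 48^3 grid, default-size lesions (the
# cores must stay several voxels in radius or delta-V voxelizes too coarsely)
small_spec <- function(...) {
  cohort_spec(grid_shape = c(48L, 48L, 48L), ...)
}

test_that("a fixed seed reproduces the cohort exactly", {
  s <- small_spec(n_patients = 3L, seed = 101L)
  c1 <- generate_cohort(s)
  c2 <- generate_cohort(s)
  expect_identical(c1$table, c2$table)
  expect_identical(c1$patients[[2]]$volumes$W2$values,
                   c2$patients[[2]]$volumes$W2$values)
  c3 <- generate_cohort(small_spec(n_patients = 3L, seed = 102L))
  expect_false(identical(c1$table$pfs_months, c3$table$pfs_months))
})

test_that("zero drift and a zero-width stable band produce CP = 1", {
  s <- small_spec(n_patients = 1L, seed = 5L,
                  dynamics_mix = c(static_IH = 0, static_SH = 1,
                                   static_DH = 0, dynamic = 0, resolved = 0),
                  delta_v_bands = list(static_IH = c(20, 60),
                                       static_SH = c(0, 0),
                                       static_DH = c(-70, -25),
                                       dynamic = c(-70, -25)))
  p <- generate_cohort(s)$patients[[1]]
  bg <- estimate_background(p$volumes$W0, p$background_mask)
  h0 <- segment_hsv(p$volumes$W0, p$boost_mask, bg)
  h2 <- segment_hsv(p$volumes$W2, p$boost_mask, bg)
  st <- classification_parameter(overlap_metrics(h0, h2))
  expect_identical(st$size_class, "SH")
  expect_identical(st$cp, 1)
})

test_that("drift beyond the lesion diameter produces CP = 0", {
  s <- cohort_spec(grid_shape = c(48L, 48L, 48L), core_radius_mm = c(4, 5),
                   drift_mm = 24, n_patients = 1L, seed = 6L,
                   time_points = c("W0", "W2"),
                   dynamics_mix = c(static_IH = 0, static_SH = 0,
                                    static_DH = 0, dynamic = 1, resolved = 0))
  p <- generate_cohort(s)$patients[[1]]
  bg <- estimate_background(p$volumes$W0, p$background_mask)
  h0 <- segment_hsv(p$volumes$W0, p$boost_mask, bg)
  h2 <- segment_hsv(p$volumes$W2, p$boost_mask, bg)
  st <- classification_parameter(overlap_metrics(h0, h2))
  expect_identical(st$cp, 0)
})

test_that("the analysis recovers the planted size class and core", {
  set.seed(77)
  s <- small_spec(n_patients = 12L, seed = 77L)
  coh <- generate_cohort(s)
  n_checked <- 0; n_agree <- 0
  for (p in coh$patients) {
    bg <- estimate_background(p$volumes$W0, p$background_mask)
    h0 <- segment_hsv(p$volumes$W0, p$boost_mask, bg)
    # closure: segmentation recovers the planted core
    ov0 <- overlap_metrics(p$planted_cores$W0, h0)
    expect_gte(ov0$dice, 0.9)
    h2 <- segment_hsv(p$volumes$W2, p$boost_mask, bg)
    if (p$dynamics_class == "resolved") {
      st <- classification_parameter(overlap_metrics(h0, h2))
      expect_identical(st$size_class, "resolved")
      next
    }
    m <- overlap_metrics(h0, h2)
    planted_cls <- classify_size(p$planted_delta_v)
    n_checked <- n_checked + 1
    if (classify_size(m$delta_v) == planted_cls) n_agree <- n_agree + 1
  }
  expect_gte(n_agree / n_checked, 0.95)
})

test_that("the default mixture yields ~64% decreasing hypoxia at W2", {
  s <- small_spec(n_patients = 60L, seed = 303L, time_points = c("W0", "W2"))
  coh <- generate_cohort(s)
  cls <- vapply(coh$patients, function(p) {
    bg <- estimate_background(p$volumes$W0, p$background_mask)
    h0 <- segment_hsv(p$volumes$W0, p$boost_mask, bg)
    h2 <- segment_hsv(p$volumes$W2, p$boost_mask, bg)
    classification_parameter(overlap_metrics(h0, h2))$size_class
  }, character(1))
  dh_frac <- mean(cls == "DH")
  # binomial error around the planted 0.64 (static_DH + dynamic)
  expect_lt(abs(dh_frac - 0.64), 3 * sqrt(0.64 * 0.36 / 60))
})

test_that("more low-uptake zones raise the measured LGZE", {
  measure_lgze <- function(het, seed) {
    s <- small_spec(n_patients = 1L, seed = seed, heterogeneity = het,
                    time_points = "W0",
                    dynamics_mix = c(static_IH = 0, static_SH = 1,
                                     static_DH = 0, dynamic = 0,
                                     resolved = 0))
    p <- generate_cohort(s)$patients[[1]]
    bg <- estimate_background(p$volumes$W0, p$background_mask)
    hsv <- segment_hsv(p$volumes$W0, p$boost_mask, bg)
    d <- discretize_equal_probability(p$volumes$W0, hsv, 16L)
    lgze(build_matrices(d)$glszm)
  }
  lo <- vapply(1:12, function(i) measure_lgze(0.10, 400 + i), numeric(1))
  hi <- vapply(1:12, function(i) measure_lgze(0.60, 400 + i), numeric(1))
  expect_gt(mean(hi), mean(lo))
})

test_that("cohorts write NIfTI files and a readable manifest", {
  dir <- file.path(tempdir(), "synthcohort")
  s <- small_spec(n_patients = 4L, seed = 9L)
  coh <- generate_cohort(s, out_dir = dir)
  man <- read.csv(coh$manifest_path)
  expect_equal(nrow(man), 4)
  vol_files <- list.files(dir, pattern = "_W[025]\\.nii\\.gz$")
  expect_gte(length(vol_files), 12)  # 3 scans per patient
  studies <- read_manifest(coh$manifest_path)
  expect_length(studies, 4)
  expect_equal(studies[[1]]$volumes$W0$values,
               coh$patients[[1]]$volumes$W0$values, tolerance = 1e-6)
  expect_equal(studies[[3]]$outcome$pfs_months,
               coh$patients[[3]]$outcome$pfs_months, tolerance = 1e-6)
  unlink(dir, recursive = TRUE)
})

test_that("the logistic link calibration hits its AUC and prevalence", {
  lk <- calibrate_logistic_link(target_auc = 0.8, prevalence = 0.48)
  expect_equal(lk$auc, 0.8, tolerance = 1e-6)
  # Monte-Carlo confirmation with an independent simulation
  set.seed(83)
  z <- rnorm(2e5)
  y <- rbinom(2e5, 1, plogis(lk$intercept + lk$slope * z))
  expect_equal(mean(y), 0.48, tolerance = 0.01)
  r <- rank(z)
  auc_mc <- (sum(r[y == 1]) - sum(y) * (sum(y) + 1) / 2) /
    (sum(y) * sum(1 - y))
  expect_equal(auc_mc, 0.8, tolerance = 0.01)
})
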