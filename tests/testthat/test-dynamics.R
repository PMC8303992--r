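test_that("overlap metrics match hand computations", {
  p <- nested_masks(100, 100)
  m <- overlap_metrics(p$ref, p$ref)
  expect_equal(m$delta_v, 0)
  expect_equal(m$dice, 1); expect_equal(m$sens, 1); expect_equal(m$ppv, 1)

  # 8 vs 8 voxels with 4 shared
  ref <- box_mask(c(16, 16, 16), c(1, 1, 1), c(8, 1, 1))
  new <- box_mask(c(16, 16, 16), c(5, 1, 1), c(12, 1, 1))
  m2 <- overlap_metrics(ref, new)
  expect_equal(m2$delta_v, 0)
  expect_equal(m2$dice, 0.5)
  expect_equal(m2$sens, 0.5)
  expect_equal(m2$ppv, 0.5)

  p3 <- nested_masks(100, 120)
  m3 <- overlap_metrics(p3$ref, p3$new)
  expect_equal(m3$sens, 1)
  expect_equal(m3$ppv, 100 / 120)
  expect_equal(m3$delta_v, 20)
  expect_true(m3$intersection_ml <= min(m3$v_ref_ml, m3$v_new_ml))

  empty <- binary_mask(array(FALSE, c(24, 24, 24)))
  expect_error(overlap_metrics(empty, p$ref), "empty")
})

test_that("size classification bands and boundaries", {
  expect_identical(classify_size(0), "SH")
  expect_identical(classify_size(15), "IH")     # boundary included in IH
  expect_identical(classify_size(-20), "DH")
  expect_identical(classify_size(14.999), "SH")
  expect_identical(classify_size(-15), "DH")    # closing the partition
  expect_identical(classify_size(-14.999), "SH")
  # partition: exactly one label for any finite delta-V
  dv <- seq(-200, 200, by = 0.5)
  cls <- classify_size(dv)
  expect_true(all(cls %in% c("IH", "SH", "DH")))
  expect_error(classify_size(NaN), "finite")
})

test_that("CP selects DICE/Sens./PPV by size class and honors degeneracy", {
  p <- nested_masks(200, 200)
  st <- classification_parameter(overlap_metrics(p$ref, p$ref))
  expect_identical(st$size_class, "SH")
  expect_identical(st$cp, 1)

  grow <- nested_masks(200, 300)    # concentric growth, +50%
  st2 <- classification_parameter(overlap_metrics(grow$ref, grow$new))
  expect_identical(st2$size_class, "IH")
  expect_identical(st2$cp_source, "sens")
  expect_identical(st2$cp, 1)

  shrink <- nested_masks(60, 100)   # follow-up is a subset, -40%
  st3 <- classification_parameter(overlap_metrics(shrink$new, shrink$ref))
  expect_identical(st3$size_class, "DH")
  expect_identical(st3$cp_source, "ppv")
  expect_identical(st3$cp, 1)

  # disjoint equal-volume masks
  a <- box_mask(c(12, 12, 12), c(1, 1, 1), c(2, 2, 2))
  b <- box_mask(c(12, 12, 12), c(9, 9, 9), c(10, 10, 10))
  st4 <- classification_parameter(overlap_metrics(a, b))
  expect_identical(st4$size_class, "SH")
  expect_identical(st4$cp, 0)

  # resolved hypoxia: empty follow-up
  empty <- binary_mask(array(FALSE, c(12, 12, 12)))
  st5 <- classification_parameter(overlap_metrics(a, empty))
  expect_identical(st5$size_class, "resolved")
  expect_true(is.na(st5$cp))
})

test_that("CP is 1 for pairs covering the reference in their branch's sense,
          independently of the size change", {
  set.seed(5)
  for (i in 1:20) {
    n_ref <- sample(50:400, 1)
    # force the size class to match the nesting direction: growth >= +15%,
    # shrinkage <= -15%, or exact equality (the SH branch needs new == ref)
    n_new <- switch(sample(3, 1),
                    round(n_ref * runif(1, 1.15, 3)),
                    round(n_ref * runif(1, 0.2, 0.85)),
                    n_ref)
    p <- nested_masks(min(n_ref, n_new), max(n_ref, n_new))
    ref <- if (n_ref <= n_new) p$ref else p$new
    new <- if (n_ref <= n_new) p$new else p$ref
    st <- classification_parameter(overlap_metrics(ref, new))
    expect_true(st$cp >= 0 && st$cp <= 1)
    expect_identical(st$cp, 1)
  }
})

test_that("rigid translation of the follow-up mask never raises CP", {
  dims <- c(44, 44, 44)
  ref <- voxel_sphere(dims, c(16, 22, 22), 6)
  cps <- vapply(0:14, function(sh) {
    new <- voxel_sphere(dims, c(16 + sh, 22, 22), 6)
    classification_parameter(overlap_metrics(ref, new))$cp
  }, numeric(1))
  expect_true(all(diff(cps) <= 1e-12))
  expect_identical(cps[1], 1)
  expect_identical(cps[15], 0)  # shift beyond the diameter: disjoint
})

test_that("CP dichotomization: median split, ties high, exclusions", {
  mk <- function(cp, cls = "SH")
    structure(list(size_class = cls, cp = cp, pair = c("W0", "W2"),
                   cp_source = "dice"), class = "hypoxia_status")
  two <- list(mk(0.1), mk(0.9))
  expect_identical(dichotomize_cp(two), c("CP_low", "CP_high"))
  all_eq <- list(mk(0.5), mk(0.5), mk(0.5))
  expect_true(all(dichotomize_cp(all_eq) == "CP_high"))
  four <- list(mk(0.2), mk(0.4), mk(0.6), mk(0.8))
  expect_identical(dichotomize_cp(four),
                   c("CP_low", "CP_low", "CP_high", "CP_high"))
  with_res <- c(four, list(mk(NA_real_, "resolved")))
  expect_identical(dichotomize_cp(with_res)[5], "excluded")
  expect_identical(
    dichotomize_cp(with_res, resolved_as_high = TRUE)[5], "CP_high")
  expect_error(dichotomize_cp(list(mk(NA_real_, "resolved"))), ">= 2")
})
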