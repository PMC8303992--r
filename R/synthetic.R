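#' Specify a synthetic longitudinal hypoxia cohort
#'
#' The generator emulates the statistical structure the analysis assumes:
#' SUV-valued lesions on a Gaussian background of mean ~1 g/mL, a hypoxic
#' core whose voxels exceed 1.4 times the background, per-class volume
#' change and spatial drift between time-points, zone-structured core
#' heterogeneity (driving LGZE), and outcomes whose hazards depend on the
#' geographic hypoxia class.
#'
#' Class mixture defaults put 64% of patients in the decreasing-hypoxia
#' band at W2 (the static-DH and dynamic components together), mirroring
#' the predominance of shrinking hypoxia under chemo-radiotherapy.
#'
#' @param n_patients cohort size (default 25).
#' @param grid_shape voxel grid (default 64^3).
#' @param spacing voxel spacing in mm (default 2 mm isotropic).
#' @param time_points time-points to simulate (default W0/W2/W5).
#' @param background_mean,background_sd background SUV distribution
#'   (defaults 1.0 and 0.05 g/mL; the noise is additive Gaussian, no PSF
#'   blurring).
#' @param core_radius_mm baseline hypoxic-core radius range, mm.
#' @param low_tbr,high_tbr SUV of the low/high core zones as multiples of
#'   the background mean (both above the 1.4 threshold).
#' @param zone_block_voxels edge length of the cubic intensity zones the
#'   core is tiled with (default 2).
#' @param heterogeneity baseline probability that a core zone is a
#'   low-uptake zone (default 0.3); its on-treatment increase raises LGZE.
#' @param heterogeneity_gain per-time-point increase of the low-zone
#'   probability (default 0.25).
#' @param dynamics_mix named proportions over
#'   `static_IH`, `static_SH`, `static_DH`, `dynamic`, `resolved`
#'   (must sum to 1).
#' @param delta_v_bands per-class ranges (percent) the planted relative
#'   volume change is drawn from; the dynamic class shares the
#'   decreasing-hypoxia band.
#' @param drift_mm rigid displacement of the core for dynamic patients
#'   (default 12 mm).
#' @param pfs_median_months baseline (static-group) median PFS (default 20).
#' @param hazard_ratio_dynamic PFS hazard ratio of dynamic vs static
#'   patients (default 3).
#' @param censor_rate fraction of patients uniformly censored (default 0.2).
#' @param lr_auc target discrimination (AUC) of the planted
#'   delta-LGZE/local-recurrence logistic link (default 0.8).
#' @param lr_prevalence marginal local-recurrence probability (default 0.48).
#' @param dm_rate distant-metastasis probability (default 0.25).
#' @param fix_class_counts allocate dynamics classes in exact proportions
#'   (largest-remainder rounding, shuffled) instead of i.i.d. multinomial
#'   draws; used for fixed-arm power designs (default FALSE).
#' @param seed integer seed; a fixed seed reproduces the cohort exactly.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 25L,
                        grid_shape = c(64L, 64L, 64L),
                        spacing = c(2, 2, 2),
                        time_points = c("W0", "W2", "W5"),
                        background_mean = 1.0, background_sd = 0.05,
                        core_radius_mm = c(8, 12),
                        low_tbr = 1.7, high_tbr = 2.4,
                        zone_block_voxels = 2L,
                        heterogeneity = 0.3, heterogeneity_gain = 0.25,
                        dynamics_mix = c(static_IH = 0.08, static_SH = 0.16,
                                         static_DH = 0.28, dynamic = 0.36,
                                         resolved = 0.12),
                        delta_v_bands = list(static_IH = c(20, 60),
                                             static_SH = c(-10, 10),
                                             static_DH = c(-70, -25),
                                             dynamic = c(-70, -25)),
                        drift_mm = 12,
                        pfs_median_months = 20, hazard_ratio_dynamic = 3,
                        censor_rate = 0.2,
                        lr_auc = 0.8, lr_prevalence = 0.48,
                        dm_rate = 0.25,
                        fix_class_counts = FALSE,
                        seed = 1L) {
  stopifnot(abs(sum(dynamics_mix) - 1) < 1e-8, hazard_ratio_dynamic > 0,
            low_tbr > 1.4, high_tbr > low_tbr)
  spec <- as.list(environment())
  class(spec) <- "cohort_spec"
  spec
}

sphere_mask <- function(grid_shape, spacing, center_mm, radius_mm) {
  ax <- lapply(1:3, function(a) (seq_len(grid_shape[a]) - 1) * spacing[a])
  dx2 <- (ax[[1]] - center_mm[1])^2
  dy2 <- (ax[[2]] - center_mm[2])^2
  dz2 <- (ax[[3]] - center_mm[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= radius_mm^2
}

# analytic LGZE of a two-point zone mixture: zones sit at two SUV levels,
# whose fixed-bin gray levels (anchored at the low level) are 1 and
# 1 + (high-low)/W; used to plant the outcome link without running the
# imaging pipeline
planted_lgze <- function(p_low, low_suv, high_suv, bin_width = 0.01) {
  g_high <- floor((high_suv - low_suv) / bin_width) + 1
  p_low * 1 + (1 - p_low) / g_high^2
}

#' Calibrate a logistic feature-outcome link to a target AUC
#'
#' For a standard-normal feature `z` and outcome `y ~ Bernoulli(plogis(a +
#' b z))`, finds `(a, b)` so that the marginal prevalence and the
#' population AUC of `z` for `y` match the targets. Computed by numerical
#' integration over a fine grid (no simulation).
#'
#' @param target_auc population AUC in (0.5, 1).
#' @param prevalence marginal event probability.
#' @return list with `intercept`, `slope`, and the achieved `auc`.
#' @export
calibrate_logistic_link <- function(target_auc = 0.8, prevalence = 0.48) {
  stopifnot(target_auc > 0.5, target_auc < 1)
  zg <- seq(-6, 6, length.out = 4001)
  w <- dnorm(zg); w <- w / sum(w)
  auc_of <- function(a, b) {
    pi_ <- plogis(a + b * zg)
    w1 <- w * pi_; w0 <- w * (1 - pi_)
    # P(Z1 > Z0) + 0.5 P(=) with Z sorted ascending
    c0 <- cumsum(w0)
    (sum(w1 * (c0 - 0.5 * w0))) / (sum(w1) * sum(w0))
  }
  prev_of <- function(a, b) sum(w * plogis(a + b * zg))
  solve_a <- function(b) uniroot(function(a) prev_of(a, b) - prevalence,
                                 c(-20, 20), tol = 1e-10)$root
  b <- uniroot(function(b) auc_of(solve_a(b), b) - target_auc,
               c(1e-6, 20), tol = 1e-10)$root
  a <- solve_a(b)
  list(intercept = a, slope = b, auc = auc_of(a, b))
}

draw_delta_v <- function(class, bands) {
  if (class == "resolved") return(-100)
  b <- bands[[class]]
  runif(1, b[1], b[2])
}

#' Generate one synthetic patient study
#'
#' Builds the longitudinal SUV volumes (Gaussian background, spherical
#' boost volume, zone-structured hypoxic core), the boost and background
#' masks, the patient's planted dynamics class, and outcomes drawn from
#' the class-dependent hazard and the delta-LGZE logistic link. Random
#' draws come from the current RNG state; seed at the cohort level.
#'
#' @param spec a [cohort_spec()].
#' @param index patient index (used for the id).
#' @param class optional dynamics class override; drawn from
#'   `spec$dynamics_mix` when `NULL`.
#' @return a [patient_study()] with extra fields `dynamics_class`,
#'   `planted_delta_v`, `planted_delta_lgze`, and `planted_cores` (the
#'   ground-truth hypoxic-core masks per time-point).
#' @export
generate_patient <- function(spec, index = 1L, class = NULL) {
  gs <- spec$grid_shape; sp <- spec$spacing
  fov <- (gs - 1) * sp
  if (is.null(class))
    class <- sample(names(spec$dynamics_mix), 1L, prob = spec$dynamics_mix)
  r0 <- runif(1, spec$core_radius_mm[1], spec$core_radius_mm[2])
  delta_v <- draw_delta_v(class, spec$delta_v_bands)
  drift <- if (class == "dynamic") spec$drift_mm else 0
  center <- fov / 2
  r_boost <- r0 + drift + 6
  if (any(center - r_boost < 2 * sp) || any(center + r_boost > fov - 2 * sp))
    stop("lesion exceeds the grid; enlarge 'grid_shape' or shrink the lesion")
  boost <- binary_mask(sphere_mask(gs, sp, center, r_boost),
                       spacing = sp, role = "boost")
  bg_roi <- binary_mask(
    sphere_mask(gs, sp, c(6, 6, 6) * sp, 4 * min(sp)) & !boost$values,
    spacing = sp, role = "background")

  # cubic intensity zones: block ids are shared across time-points so the
  # same region keeps its identity while the low-zone probability evolves
  blk <- spec$zone_block_voxels
  co <- arrayInd(seq_len(prod(gs)), gs)
  block_id <- (co[, 1] - 1) %/% blk +
    ((co[, 2] - 1) %/% blk) * 1000 + ((co[, 3] - 1) %/% blk) * 1000000
  ub <- unique(block_id)
  low_suv <- spec$low_tbr * spec$background_mean
  high_suv <- spec$high_tbr * spec$background_mean

  tps <- spec$time_points
  # one latent severity score per patient drives both the heterogeneity
  # increase (hence the planted delta-LGZE, monotonically) and the local
  # recurrence probability; AUC is rank-based, so the monotone planted
  # feature carries the calibrated discrimination of the latent score
  z_latent <- rnorm(1)
  gain_i <- max(0.02, spec$heterogeneity_gain * (1 + 0.35 * z_latent))
  p_low <- pmin(0.95, pmax(0.02, spec$heterogeneity +
                             gain_i * (seq_along(tps) - 1)))
  names(p_low) <- tps
  volumes <- list()
  cores <- list()
  for (k in seq_along(tps)) {
    tp <- tps[k]
    if (tp == "W0") {
      core <- sphere_mask(gs, sp, center, r0)
      n0 <- sum(core)
    } else {
      # plant the relative volume change exactly in voxel counts: the
      # follow-up core is the n_target in-boost voxels closest to the
      # (possibly drifted) center, so voxelization cannot blur the class
      ctr_k <- center + c(drift, 0, 0) * (k - 1) / (length(tps) - 1)
      n_target <- if (class == "resolved") 0L else
        max(0L, round(n0 * (1 + delta_v / 100)))
      core <- array(FALSE, gs)
      if (n_target > 0L) {
        ax <- lapply(1:3, function(a) ((seq_len(gs[a]) - 1) * sp[a] -
                                         ctr_k[a])^2)
        d2 <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
        d2[!boost$values] <- Inf
        core[order(as.vector(d2))[seq_len(n_target)]] <- TRUE
      }
    }
    v <- rnorm(prod(gs), spec$background_mean, spec$background_sd)
    if (any(core)) {
      is_low <- runif(length(ub)) < p_low[tp]
      zl <- is_low[match(block_id, ub)]
      v[core] <- ifelse(zl[core], low_suv, high_suv)
      v[core] <- v[core] + rnorm(sum(core), 0, spec$background_sd)
    }
    v <- pmax(v, 0)
    volumes[[tp]] <- pet_volume(array(v, gs), spacing = sp, time_point = tp)
    cores[[tp]] <- binary_mask(core, spacing = sp, role = "HSV")
  }

  dl <- planted_lgze(p_low, low_suv, high_suv)
  planted_dlgze <- if (length(tps) > 1)
    (dl[2] - dl[1]) / abs(dl[1]) else NA_real_

  lam0 <- log(2) / spec$pfs_median_months
  lam <- lam0 * if (class == "dynamic") spec$hazard_ratio_dynamic else 1
  t_pfs <- rexp(1, lam)
  censored <- runif(1) < spec$censor_rate
  pfs_months <- if (censored) runif(1, 0, t_pfs) else t_pfs
  t_os <- t_pfs + rexp(1, lam0)
  os_censored <- runif(1) < spec$censor_rate
  os_months <- if (os_censored) runif(1, 0, t_os) else t_os

  lk <- calibrated_link_cached(spec$lr_auc, spec$lr_prevalence)
  # more heterogeneity increase (higher delta-LGZE) -> less recurrence
  lr <- rbinom(1, 1, plogis(lk$intercept - lk$slope * z_latent))
  dm <- rbinom(1, 1, spec$dm_rate)

  ps <- patient_study(sprintf("P%02d", index), volumes, boost, bg_roi,
                      outcome = outcome_record(pfs_months, as.integer(!censored),
                                               os_months, as.integer(!os_censored),
                                               lr, dm))
  ps$dynamics_class <- class
  ps$planted_delta_v <- delta_v
  ps$planted_delta_lgze <- planted_dlgze
  ps$planted_cores <- cores
  ps
}

# link calibration is deterministic; cache it per (auc, prevalence)
.link_cache <- new.env(parent = emptyenv())
calibrated_link_cached <- function(auc, prevalence) {
  key <- sprintf("%.6f_%.6f", auc, prevalence)
  if (is.null(.link_cache[[key]]))
    .link_cache[[key]] <- calibrate_logistic_link(auc, prevalence)
  .link_cache[[key]]
}

#' Generate a synthetic cohort
#'
#' Draws `n_patients` independent patient studies under one seed. With an
#' output directory, volumes and masks are written as NIfTI and a manifest
#' plus outcome table as CSV (the same format the pipeline consumes);
#' otherwise the studies are returned in memory.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir optional directory for NIfTI + manifest output.
#' @return list with `patients` (list of [generate_patient()] results) and
#'   `table` (per-patient class/outcome data.frame); with `out_dir`, also
#'   `manifest_path`.
#' @export
generate_cohort <- function(spec, out_dir = NULL) {
  set.seed(spec$seed)
  classes <- if (isTRUE(spec$fix_class_counts)) {
    counts <- diff(c(0, round(cumsum(spec$dynamics_mix) * spec$n_patients)))
    sample(rep(names(spec$dynamics_mix), counts))
  } else rep(list(NULL), spec$n_patients)
  patients <- lapply(seq_len(spec$n_patients),
                     function(i) generate_patient(spec, i, classes[[i]]))
  tab <- do.call(rbind, lapply(patients, function(p) {
    o <- p$outcome
    data.frame(patient_id = p$patient_id, dynamics_class = p$dynamics_class,
               planted_delta_v = p$planted_delta_v,
               planted_delta_lgze = p$planted_delta_lgze,
               pfs_months = o$pfs_months, pfs_event = o$pfs_event,
               os_months = o$os_months, os_event = o$os_event,
               local_recurrence = o$local_recurrence,
               distant_metastasis = o$distant_metastasis)
  }))
  out <- list(patients = patients, table = tab, spec = spec)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    rows <- lapply(patients, function(p) {
      paths <- vapply(names(p$volumes), function(tp) {
        f <- file.path(out_dir, sprintf("%s_%s.nii.gz", p$patient_id, tp))
        write_volume(p$volumes[[tp]], f)
        f
      }, character(1))
      bp <- file.path(out_dir, sprintf("%s_boost.nii.gz", p$patient_id))
      write_volume(p$boost_mask, bp)
      gp <- file.path(out_dir, sprintf("%s_bg.nii.gz", p$patient_id))
      write_volume(p$background_mask, gp)
      cbind(data.frame(patient_id = p$patient_id),
            as.data.frame(as.list(setNames(paths, paste0("volume_", names(paths))))),
            data.frame(boost_path = bp, background_path = gp))
    })
    manifest <- do.call(rbind, rows)
    manifest_path <- file.path(out_dir, "manifest.csv")
    write.csv(manifest, manifest_path, row.names = FALSE)
    write.csv(tab, file.path(out_dir, "outcomes.csv"), row.names = FALSE)
    out$manifest_path <- manifest_path
  }
  out
}

#' Reduced-form cohort: feature tables and outcomes without images
#'
#' For statistical calibration studies (type-I error, power, AUC bias) the
#' imaging stages are not in question; this generator draws per-patient
#' delta-feature tables at W2 and W5 directly, with outcomes either
#' independent of all features (`link_feature = NULL`, the null
#' configuration) or linked to one named feature through the calibrated
#' logistic model for local recurrence.
#'
#' @param n_patients cohort size.
#' @param n_features number of delta-features (default 130).
#' @param link_feature index of the feature carrying the signal, or `NULL`
#'   for a global null.
#' @param target_auc,prevalence link calibration (see
#'   [calibrate_logistic_link()]).
#' @param pfs_median_months,censor_rate survival simulation parameters.
#' @return list: `delta_w2`, `delta_w5` (data.frames), `outcomes`
#'   (data.frame).
#' @export
simulate_feature_cohort <- function(n_patients = 40L, n_features = 130L,
                                    link_feature = NULL, target_auc = 0.8,
                                    prevalence = 0.48,
                                    pfs_median_months = 20,
                                    censor_rate = 0.2) {
  nm <- sprintf("f%03d", seq_len(n_features))
  d2 <- matrix(rnorm(n_patients * n_features), n_patients,
               dimnames = list(NULL, nm))
  d5 <- matrix(rnorm(n_patients * n_features), n_patients,
               dimnames = list(NULL, nm))
  if (!is.null(link_feature)) {
    # the same latent signal appears (noisily) at both time-points
    z <- rnorm(n_patients)
    d2[, link_feature] <- z
    d5[, link_feature] <- (z + rnorm(n_patients, 0, 0.4)) / sqrt(1 + 0.16)
    lk <- calibrate_logistic_link(target_auc, prevalence)
    lr <- rbinom(n_patients, 1, plogis(lk$intercept + lk$slope * z))
  } else {
    lr <- rbinom(n_patients, 1, prevalence)
  }
  lam <- log(2) / pfs_median_months
  t_pfs <- rexp(n_patients, lam)
  cens <- runif(n_patients) < censor_rate
  outcomes <- data.frame(
    pfs_months = ifelse(cens, runif(n_patients) * t_pfs, t_pfs),
    pfs_event = as.integer(!cens),
    os_months = t_pfs + rexp(n_patients, lam),
    os_event = 1L,
    local_recurrence = lr,
    distant_metastasis = rbinom(n_patients, 1, 0.25))
  list(delta_w2 = as.data.frame(d2), delta_w5 = as.data.frame(d5),
       outcomes = outcomes)
}
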