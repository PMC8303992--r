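#' Pipeline run configuration
#'
#' Every tunable of the full study in one place. Defaults follow the
#' analysis conventions: TBR threshold 1.4, fixed bin width 0.01 SUV,
#' Spearman redundancy cutoff 0.8, significance level 0.05.
#'
#' @param tbr hypoxia segmentation threshold (default 1.4).
#' @param bin_width fixed discretization bin width, SUV (default 0.01).
#' @param q_levels equal-probability quantization levels (default 64).
#' @param wavelet wavelet basis (default `"coif1"`).
#' @param alpha significance level (default 0.05).
#' @param B bootstrap replicates (default 1000).
#' @param seed top-level seed propagated to all resampling.
#' @param cp_rule CP dichotomization rule, `"median"` or `"threshold"`.
#' @param cp_threshold fixed cut-point when `cp_rule = "threshold"`.
#' @param resolved_as_high map resolved hypoxia to the CP-high group.
#' @param r_cutoff Spearman redundancy cutoff (default 0.8).
#' @param endpoints outcome endpoints to analyze.
#' @param compute_auc compute bootstrap AUC for binary endpoints.
#' @return a `run_config` list.
#' @export
run_config <- function(tbr = 1.4, bin_width = 0.01, q_levels = 64L,
                       wavelet = "coif1", alpha = 0.05, B = 1000L,
                       seed = 1L, cp_rule = "median", cp_threshold = NULL,
                       resolved_as_high = FALSE, r_cutoff = 0.8,
                       endpoints = c("pfs", "os", "lr", "dm"),
                       compute_auc = TRUE) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Read a patient manifest
#'
#' The manifest is a CSV with columns `patient_id`, `volume_W0`
#' (mandatory), `volume_W2`/`volume_W5` (optional, empty = missing scan),
#' `boost_path`, `background_path`. Outcomes are read from a sibling
#' `outcomes.csv` (or `outcomes_path`) keyed by `patient_id`.
#'
#' @param manifest_path path to the manifest CSV.
#' @param outcomes_path optional path to the outcome table.
#' @return list of [patient_study()] objects.
#' @export
read_manifest <- function(manifest_path, outcomes_path = NULL) {
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  if (is.null(outcomes_path))
    outcomes_path <- file.path(dirname(manifest_path), "outcomes.csv")
  outc <- if (file.exists(outcomes_path))
    read.csv(outcomes_path, stringsAsFactors = FALSE) else NULL
  lapply(seq_len(nrow(man)), function(i) {
    row <- man[i, ]
    vols <- list()
    for (tp in TIME_POINTS) {
      col <- paste0("volume_", tp)
      if (col %in% names(row) && nzchar(row[[col]]) && !is.na(row[[col]]))
        vols[[tp]] <- read_volume(row[[col]], tp)
    }
    boost <- read_mask(row$boost_path, vols$W0, role = "boost")
    bg <- if ("background_path" %in% names(row) && nzchar(row$background_path))
      read_mask(row$background_path, vols$W0, role = "background") else NULL
    oc <- NULL
    if (!is.null(outc)) {
      r <- outc[outc$patient_id == row$patient_id, ]
      if (nrow(r) == 1L)
        oc <- outcome_record(r$pfs_months, r$pfs_event, r$os_months,
                             r$os_event, r$local_recurrence,
                             r$distant_metastasis)
    }
    patient_study(row$patient_id, vols, boost, bg, oc)
  })
}

segment_study <- function(study, config) {
  bg <- estimate_background(study$volumes$W0, study$background_mask)
  hsv <- lapply(study$volumes, function(v)
    segment_hsv(v, study$boost_mask, bg, tbr = config$tbr))
  list(background = bg, hsv = hsv)
}

#' Run the full longitudinal hypoxia study
#'
#' Orchestrates all stages on a cohort: background estimation and HSV
#' segmentation at each time-point, overlap metrics and classification
#' parameter for W0-W2 and W0-W5, the 130-feature vectors inside the
#' transferred baseline HSV and their relative deviations, and the
#' cohort-level statistics (CP survival grouping with log-rank,
#' per-feature endpoint prediction with BH adjustment, two-time-point
#' confirmation, Spearman redundancy filtering). A patient failing a stage
#' is excluded from that stage with a logged reason, never silently
#' dropped.
#'
#' @param cohort a [generate_cohort()] result, a list of
#'   [patient_study()] objects, or a manifest CSV path.
#' @param config a [run_config()].
#' @param out_dir optional directory; tables are written as CSV plus a
#'   `run_metadata.json` with the seed and a config hash.
#' @param features run the radiomics stage (default TRUE; disable for
#'   segmentation/dynamics-only studies).
#' @return list: `dynamics` (per patient-pair table), `cp_groups`,
#'   `cp_logrank` (per pair), `delta_w2`/`delta_w5` feature tables,
#'   `results_w2`/`results_w5`, `confirmed`, `selected_features`, `log`.
#' @export
run_study <- function(cohort, config = run_config(), out_dir = NULL,
                      features = TRUE) {
  if (is.character(cohort)) cohort <- read_manifest(cohort)
  patients <- if (!is.null(cohort$patients)) cohort$patients else cohort
  if (length(patients) < 2L) stop("need at least 2 patients")
  set.seed(config$seed)
  log <- list()
  note <- function(id, stage, msg)
    log[[length(log) + 1L]] <<- data.frame(patient_id = id, stage = stage,
                                           message = msg)

  seg <- list()
  for (p in patients) {
    seg[[p$patient_id]] <- tryCatch(segment_study(p, config),
                                    error = function(e) {
                                      note(p$patient_id, "segmentation",
                                           conditionMessage(e)); NULL })
  }

  pairs <- list(c("W0", "W2"), c("W0", "W5"))
  dyn_rows <- list(); statuses <- list()
  for (p in patients) {
    s <- seg[[p$patient_id]]
    if (is.null(s)) next
    for (pr in pairs) {
      tp <- pr[2]
      if (is.null(s$hsv[[tp]])) next
      ref <- s$hsv$W0; new <- s$hsv[[tp]]
      if (sum(ref$values) == 0L) {
        st <- hypoxia_status("absent", NA_real_, pr, NA_character_)
        note(p$patient_id, paste0("dynamics_", tp), "empty baseline HSV")
        m <- list(delta_v = NA_real_, dice = NA_real_, sens = NA_real_,
                  ppv = NA_real_)
      } else {
        m <- overlap_metrics(ref, new)
        st <- classification_parameter(m, pr)
      }
      key <- paste(pr, collapse = "_")
      statuses[[key]][[p$patient_id]] <- st
      dyn_rows[[length(dyn_rows) + 1L]] <- data.frame(
        patient_id = p$patient_id, pair = key, delta_v = m$delta_v,
        dice = m$dice, sens = m$sens, ppv = m$ppv,
        size_class = st$size_class, cp = st$cp)
    }
  }
  dynamics <- do.call(rbind, dyn_rows)

  outcomes <- do.call(rbind, lapply(patients, function(p) {
    o <- p$outcome
    if (is.null(o)) return(NULL)
    data.frame(patient_id = p$patient_id, pfs_months = o$pfs_months,
               pfs_event = o$pfs_event, os_months = o$os_months,
               os_event = o$os_event, local_recurrence = o$local_recurrence,
               distant_metastasis = o$distant_metastasis)
  }))

  cp_groups <- list(); cp_logrank <- list()
  for (key in names(statuses)) {
    st <- statuses[[key]]
    grp <- tryCatch(
      dichotomize_cp(st, rule = config$cp_rule,
                     threshold = config$cp_threshold,
                     resolved_as_high = config$resolved_as_high),
      error = function(e) NULL)
    if (is.null(grp)) next
    gtab <- data.frame(patient_id = names(st), group = grp)
    cp_groups[[key]] <- gtab
    if (!is.null(outcomes)) {
      d <- merge(gtab[gtab$group != "excluded", ], outcomes,
                 by = "patient_id")
      if (length(unique(d$group)) == 2L && sum(d$pfs_event) >= 1)
        cp_logrank[[key]] <- tryCatch(
          logrank_test(d$pfs_months, d$pfs_event, d$group),
          error = function(e) NULL)
    }
  }

  out <- list(dynamics = dynamics, cp_groups = cp_groups,
              cp_logrank = cp_logrank, outcomes = outcomes)

  if (features) {
    rcfg <- radiomics_config(bin_width = config$bin_width,
                             q_levels = config$q_levels,
                             wavelet = config$wavelet)
    deltas <- list(W2 = list(), W5 = list())
    for (p in patients) {
      s <- seg[[p$patient_id]]
      if (is.null(s) || sum(s$hsv$W0$values) == 0L) {
        if (!is.null(s)) note(p$patient_id, "features", "empty baseline HSV")
        next
      }
      fv <- tryCatch({
        f0 <- feature_vector(p$volumes$W0, s$hsv$W0, rcfg)
        lapply(c("W2", "W5"), function(tp) {
          if (is.null(p$volumes[[tp]])) return(NULL)
          mk <- transfer_contour(s$hsv$W0, p$volumes[[tp]])
          delta_features(f0, feature_vector(p$volumes[[tp]], mk, rcfg))
        })
      }, error = function(e) {
        note(p$patient_id, "features", conditionMessage(e)); NULL })
      if (is.null(fv)) next
      if (!is.null(fv[[1]])) deltas$W2[[p$patient_id]] <- as.numeric(fv[[1]])
      if (!is.null(fv[[2]])) deltas$W5[[p$patient_id]] <- as.numeric(fv[[2]])
    }
    to_table <- function(lst) {
      if (!length(lst)) return(NULL)
      m <- do.call(rbind, lst)
      colnames(m) <- radiomics_feature_names()
      df <- as.data.frame(m)
      df$patient_id <- names(lst)
      df
    }
    out$delta_w2 <- to_table(deltas$W2)
    out$delta_w5 <- to_table(deltas$W5)
    if (!is.null(out$delta_w2) && !is.null(out$delta_w5) &&
        !is.null(outcomes)) {
      run_ep <- function(dt) {
        d <- merge(dt, outcomes, by = "patient_id")
        predict_outcomes(d[, radiomics_feature_names(), drop = FALSE],
                         d, endpoints = config$endpoints,
                         alpha = config$alpha, B = config$B,
                         compute_auc = config$compute_auc)
      }
      out$results_w2 <- run_ep(out$delta_w2)
      out$results_w5 <- run_ep(out$delta_w5)
      out$confirmed <- two_timepoint_confirmation(out$results_w2,
                                                  out$results_w5,
                                                  alpha = config$alpha)
      conf <- out$confirmed[out$confirmed$confirmed_w5, ]
      out$selected_features <- lapply(split(conf, conf$endpoint), function(g) {
        pv <- setNames(g$p_raw, g$feature)
        spearman_redundancy_filter(out$delta_w2[, g$feature, drop = FALSE],
                                   pv, r_cutoff = config$r_cutoff)
      })
    }
  }

  out$log <- if (length(log)) do.call(rbind, log) else
    data.frame(patient_id = character(0), stage = character(0),
               message = character(0))
  out$config <- config

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, f) if (!is.null(x))
      write.csv(x, file.path(out_dir, f), row.names = FALSE)
    wr(out$dynamics, "dynamics.csv")
    wr(out$delta_w2, "delta_w2.csv")
    wr(out$delta_w5, "delta_w5.csv")
    wr(out$results_w2, "results_w2.csv")
    wr(out$results_w5, "results_w5.csv")
    wr(out$confirmed, "confirmed.csv")
    wr(out$log, "log.csv")
    meta <- list(seed = config$seed,
                 config_hash = config_hash(config),
                 config = config[setdiff(names(config), "cp_threshold")])
    jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
  }
  out
}

config_hash <- function(config) {
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(s, f)
  substr(unname(tools::md5sum(f)), 1, 12)
}
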