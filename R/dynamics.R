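#' Overlap metrics between a baseline and a follow-up hypoxia mask
#'
#' With the baseline (W0) hypoxic sub-volume as reference and a later scan's
#' HSV as comparison, computes the relative volume difference and three
#' spatial-overlap parameters:
#' \deqn{\Delta V = 100 (V_{new} - V_{ref}) / V_{ref}}
#' \deqn{DICE = 2 |ref \cap new| / (|ref| + |new|)}
#' \deqn{Sens. = |ref \cap new| / |ref|, \quad PPV = |ref \cap new| / |new|}
#'
#' @param ref baseline [binary_mask()] (nonempty).
#' @param new follow-up [binary_mask()] on the same grid (may be empty).
#' @return An `overlap_metrics` object: `delta_v` (percent), `dice`, `sens`,
#'   `ppv`, `v_ref_ml`, `v_new_ml`, `intersection_ml`.
#' @export
overlap_metrics <- function(ref, new) {
  stop_if_grid_mismatch(new, ref, "follow-up mask")
  n_ref <- sum(ref$values)
  n_new <- sum(new$values)
  if (n_ref == 0L) stop("reference mask is empty; delta-V undefined")
  n_int <- sum(ref$values & new$values)
  vv <- voxel_volume_ml(ref)
  structure(list(
    delta_v = 100 * (n_new - n_ref) / n_ref,
    dice = if (n_ref + n_new > 0) 2 * n_int / (n_ref + n_new) else NA_real_,
    sens = n_int / n_ref,
    ppv  = if (n_new > 0) n_int / n_new else NA_real_,
    v_ref_ml = n_ref * vv, v_new_ml = n_new * vv,
    intersection_ml = n_int * vv), class = "overlap_metrics")
}

#' Classify the hypoxia size change
#'
#' Three bands on the relative volume difference: increasing hypoxia
#' (IH, \eqn{\Delta V \ge 15\%}), stable hypoxia (SH, \eqn{-15\% < \Delta V
#' < 15\%}) and decreasing hypoxia (DH, \eqn{\Delta V \le -15\%}). The
#' printed bands leave exactly -15 unassigned; it is closed into DH so the
#' classifier partitions the line symmetrically to the IH boundary.
#'
#' @param delta_v relative volume difference in percent (finite scalar or
#'   vector).
#' @return character vector over `{"IH","SH","DH"}`.
#' @export
classify_size <- function(delta_v) {
  if (any(!is.finite(delta_v))) stop("'delta_v' must be finite")
  ifelse(delta_v >= 15, "IH", ifelse(delta_v <= -15, "DH", "SH"))
}

#' Classification parameter (CP) for geographic hypoxia dynamics
#'
#' The CP quantifies whether hypoxia stays in place or moves, independently
#' of its change in size: the size class selects which overlap parameter is
#' reported as CP — DICE for stable hypoxia, sensitivity for increasing
#' hypoxia, PPV for decreasing hypoxia. Full contour overlap in the branch's
#' sense gives CP = 1 (geographically static) regardless of the volume
#' change; disjoint masks give CP = 0 (geographically dynamic).
#'
#' Degenerate cases: an empty follow-up mask yields size class `"resolved"`
#' (hypoxia gone, CP undefined); an empty reference yields `"absent"`.
#'
#' @param metrics an [overlap_metrics()] result.
#' @param pair character length-2, e.g. `c("W0","W2")`.
#' @return A `hypoxia_status` object: `size_class` in
#'   `{"IH","SH","DH","resolved","absent"}`, `cp` in `[0,1]` or `NA`,
#'   `pair`, and the selected overlap parameter's name.
#' @export
classification_parameter <- function(metrics, pair = c("W0", "W2")) {
  stopifnot(inherits(metrics, "overlap_metrics"))
  if (metrics$v_ref_ml == 0) {
    return(hypoxia_status("absent", NA_real_, pair, NA_character_))
  }
  if (metrics$v_new_ml == 0) {
    return(hypoxia_status("resolved", NA_real_, pair, NA_character_))
  }
  cls <- classify_size(metrics$delta_v)
  cp <- switch(cls, SH = metrics$dice, IH = metrics$sens, DH = metrics$ppv)
  src <- switch(cls, SH = "dice", IH = "sens", DH = "ppv")
  hypoxia_status(cls, cp, pair, src)
}

hypoxia_status <- function(size_class, cp, pair, cp_source) {
  structure(list(size_class = size_class, cp = cp,
                 pair = as.character(pair), cp_source = cp_source),
            class = "hypoxia_status")
}

#' @export
print.hypoxia_status <- function(x, ...) {
  cat(sprintf("<hypoxia_status %s->%s> %s, CP = %s%s\n",
              x$pair[1], x$pair[2], x$size_class,
              if (is.na(x$cp)) "NA" else sprintf("%.3f", x$cp),
              if (is.na(x$cp_source)) "" else sprintf(" (%s)", x$cp_source)))
  invisible(x)
}

#' Dichotomize patients by classification parameter
#'
#' Splits classified patients into high-CP (geographically static) and
#' low-CP (geographically dynamic) groups for survival comparison. Default
#' rule: median split with ties assigned to the high group. Patients with
#' resolved or absent hypoxia have no CP and are excluded by default; an
#' option maps resolved hypoxia to the high group (hypoxia gone).
#'
#' @param statuses list of [classification_parameter()] results.
#' @param rule `"median"` (default) or `"threshold"`.
#' @param threshold fixed CP cut-point when `rule = "threshold"`; values
#'   `>= threshold` go to the high group.
#' @param resolved_as_high treat resolved-hypoxia patients as high CP
#'   (default FALSE, i.e. excluded).
#' @return character vector over `{"CP_high","CP_low","excluded"}`, one per
#'   status, in input order.
#' @export
dichotomize_cp <- function(statuses, rule = c("median", "threshold"),
                           threshold = NULL, resolved_as_high = FALSE) {
  rule <- match.arg(rule)
  cp <- vapply(statuses, function(s) s$cp, numeric(1))
  cls <- vapply(statuses, function(s) s$size_class, character(1))
  out <- rep("excluded", length(cp))
  usable <- !is.na(cp)
  if (rule == "median") {
    if (sum(usable) < 2L) stop("need >= 2 patients with a defined CP")
    cut <- median(cp[usable])
  } else {
    if (is.null(threshold)) stop("'threshold' required for rule = 'threshold'")
    cut <- threshold
  }
  out[usable] <- ifelse(cp[usable] >= cut, "CP_high", "CP_low")
  if (resolved_as_high) out[cls == "resolved"] <- "CP_high"
  out
}

#' Tabulate per-patient hypoxia dynamics
#'
#' Convenience wrapper: overlap metrics plus CP for one time-point pair per
#' patient, returned as a data frame ready for export.
#'
#' @param masks_ref,masks_new named lists of baseline / follow-up masks
#'   (names are patient ids).
#' @param pair time-point pair label, e.g. `c("W0","W2")`.
#' @return data.frame with one row per patient: overlap metrics, size class
#'   and CP. Patients with an empty reference mask get size class
#'   `"absent"` and NA metrics.
#' @export
dynamics_table <- function(masks_ref, masks_new, pair = c("W0", "W2")) {
  ids <- names(masks_ref)
  stopifnot(!is.null(ids), identical(ids, names(masks_new)))
  rows <- lapply(ids, function(id) {
    ref <- masks_ref[[id]]; new <- masks_new[[id]]
    if (sum(ref$values) == 0L) {
      return(data.frame(patient_id = id, pair = paste(pair, collapse = "_"),
                        delta_v = NA_real_, dice = NA_real_, sens = NA_real_,
                        ppv = NA_real_, v_ref_ml = 0,
                        v_new_ml = mask_volume_ml(new),
                        size_class = "absent", cp = NA_real_))
    }
    m <- overlap_metrics(ref, new)
    st <- classification_parameter(m, pair)
    data.frame(patient_id = id, pair = paste(pair, collapse = "_"),
               delta_v = m$delta_v, dice = m$dice, sens = m$sens,
               ppv = m$ppv, v_ref_ml = m$v_ref_ml, v_new_ml = m$v_new_ml,
               size_class = st$size_class, cp = st$cp)
  })
  do.call(rbind, rows)
}
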