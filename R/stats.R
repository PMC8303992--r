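#' Construct a per-patient outcome record
#'
#' Survival times are measured in months from the start of treatment;
#' events are 1 = observed, 0 = censored. Binary endpoints flag local
#' recurrence (LR) and distant metastasis (DM).
#'
#' @param pfs_months,os_months progression-free / overall survival times.
#' @param pfs_event,os_event event indicators (0/1).
#' @param local_recurrence,distant_metastasis binary endpoint flags (0/1).
#' @return An `outcome_record`.
#' @export
outcome_record <- function(pfs_months, pfs_event, os_months = NA_real_,
                           os_event = NA_integer_, local_recurrence = NA_integer_,
                           distant_metastasis = NA_integer_) {
  if (!is.na(pfs_months) && pfs_months < 0) stop("negative survival time")
  if (!is.na(os_months) && os_months < 0) stop("negative survival time")
  structure(list(pfs_months = pfs_months, pfs_event = pfs_event,
                 os_months = os_months, os_event = os_event,
                 local_recurrence = local_recurrence,
                 distant_metastasis = distant_metastasis),
            class = "outcome_record")
}

#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper around [survival::survfit()] returning the step-function
#' coordinates; the estimate is 1 before the first event.
#'
#' @param times survival times (>= 0).
#' @param events event indicators (1 = event, 0 = censored).
#' @return data.frame with columns `time`, `n_risk`, `n_event`, `surv`.
#' @export
kaplan_meier <- function(times, events) {
  if (any(times < 0)) stop("negative survival times")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv)
}

#' Two-group log-rank test
#'
#' @param times,events pooled survival data.
#' @param group two-level grouping vector.
#' @return list with `chisq` (1 df statistic) and `p`.
#' @export
logrank_test <- function(times, events, group) {
  g <- factor(group)
  if (nlevels(g) != 2L) stop("log-rank comparison needs exactly 2 groups")
  if (any(table(g) == 0L)) stop("a group is empty")
  if (sum(events) < 1) stop("need at least one event")
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ g)
  chisq <- sd_$chisq
  list(chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards hazard ratios
#'
#' Partial-likelihood estimates with Wald 95% confidence intervals, one row
#' per covariate; convergence problems are flagged, not silently returned.
#'
#' @param times,events survival data.
#' @param covariates data.frame (or vector) of covariates.
#' @return data.frame: `covariate`, `hr`, `ci_low`, `ci_high`, `p`,
#'   `converged`.
#' @export
cox_hr <- function(times, events, covariates) {
  x <- as.data.frame(covariates)
  if (sum(events) < ncol(x))
    stop("fewer events than covariates; fit would be unidentified")
  dat <- cbind(data.frame(.time = times, .event = events), x)
  fml <- as.formula(paste("survival::Surv(.time, .event) ~",
                          paste(names(x), collapse = " + ")))
  # Breslow tie handling keeps the score equation exactly invariant under
  # dataset replication
  fit <- tryCatch(survival::coxph(fml, data = dat, ties = "breslow"),
                  warning = function(w) {
                    f <- suppressWarnings(survival::coxph(fml, data = dat))
                    attr(f, "flagged") <- conditionMessage(w)
                    f
                  })
  sm <- summary(fit)
  data.frame(covariate = rownames(sm$coefficients),
             hr = sm$coefficients[, "exp(coef)"],
             ci_low = sm$conf.int[, "lower .95"],
             ci_high = sm$conf.int[, "upper .95"],
             p = sm$coefficients[, "Pr(>|z|)"],
             converged = is.null(attr(fit, "flagged")),
             row.names = NULL)
}

#' Mann-Whitney U test
#'
#' Exact two-sided p when the combined sample is small (<= 20 observations
#' and no ties), normal approximation with tie correction otherwise.
#'
#' @param values_a,values_b the two groups.
#' @return list with `u` (U statistic of group a) and `p`.
#' @export
mann_whitney <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b)) stop("both groups must be nonempty")
  n <- length(values_a) + length(values_b)
  if (length(unique(c(values_a, values_b))) == 1L)  # fully tied: no evidence
    return(list(u = length(values_a) * length(values_b) / 2, p = 1))
  wt <- suppressWarnings(
    wilcox.test(values_a, values_b, exact = n <= 20, correct = FALSE))
  list(u = unname(wt$statistic), p = wt$p.value)
}

# empirical AUC of score x for binary label y (1 = positive): the
# Mann-Whitney probability estimate with tie handling
empirical_auc <- function(x, y) {
  r <- rank(x)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Imbalance-adjusted bootstrap logistic prediction of a binary endpoint
#'
#' Single-feature logistic model. Prediction performance (AUC, specificity
#' at the operating point where sensitivity and specificity are closest)
#' and the model coefficients are estimated by class-stratified bootstrap
#' in which each class is resampled to equal effective size (half the
#' cohort each), so the minority class carries the same weight as the
#' majority class. The plain (unstratified) bootstrap is available via
#' `stratified = FALSE`.
#'
#' @param feature numeric feature values.
#' @param labels binary outcome (0/1), both classes present.
#' @param B bootstrap replicates (default 1000).
#' @param stratified class-balanced resampling (default TRUE).
#' @param seed optional integer seed applied locally.
#' @return list: `auc`, `specificity`, `auc_apparent`, `coef`
#'   (bootstrap-mean intercept and slope), `separation` flag, `B`.
#' @export
bootstrap_logistic_auc <- function(feature, labels, B = 1000L,
                                   stratified = TRUE, seed = NULL) {
  stopifnot(length(feature) == length(labels))
  ok <- !is.na(feature) & !is.na(labels)
  x <- feature[ok]; y <- as.integer(labels[ok])
  if (length(unique(y)) < 2L) stop("labels contain a single class")
  if (length(y) < 8L) stop("need at least 8 patients")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  fit_logistic <- function(xx, yy) {
    if (length(unique(xx)) < 2L)  # uninformative feature: flat model
      return(list(coef = c(qlogis(mean(yy)), 0), separated = FALSE))
    f <- suppressWarnings(glm.fit(cbind(1, xx), yy, family = binomial()))
    cf <- f$coefficients
    cf[is.na(cf)] <- 0
    list(coef = cf, separated = !f$converged || any(abs(cf) > 1e3))
  }
  full <- fit_logistic(x, y)
  auc_app <- empirical_auc(x * sign(full$coef[2] + 0), y)
  i1 <- which(y == 1); i0 <- which(y == 0)
  n <- length(y)
  m1 <- if (stratified) round(n / 2) else NA
  aucs <- specs <- numeric(B)
  coefs <- matrix(NA_real_, B, 2)
  for (b in seq_len(B)) {
    if (stratified) {
      sel <- c(sample(i1, m1, replace = TRUE),
               sample(i0, n - m1, replace = TRUE))
    } else {
      sel <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[sel])) < 2L) { aucs[b] <- NA; specs[b] <- NA; next }
    }
    xb <- x[sel]; yb <- y[sel]
    fb <- fit_logistic(xb, yb)
    coefs[b, ] <- fb$coef
    score <- plogis(fb$coef[1] + fb$coef[2] * xb)
    aucs[b] <- empirical_auc(score, yb)
    specs[b] <- balanced_specificity(score, yb)
  }
  list(auc = mean(aucs, na.rm = TRUE),
       specificity = mean(specs, na.rm = TRUE),
       auc_apparent = auc_app,
       coef = colMeans(coefs, na.rm = TRUE),
       separation = full$separated, B = B)
}

# specificity at the threshold where sensitivity and specificity are
# closest (the balanced operating point on the empirical ROC)
balanced_specificity <- function(score, y) {
  thr <- sort(unique(score))
  best <- NA_real_; gap <- Inf
  for (t in thr) {
    pred <- score >= t
    sens <- sum(pred & y == 1) / sum(y == 1)
    spec <- sum(!pred & y == 0) / sum(y == 0)
    if (abs(sens - spec) < gap) { gap <- abs(sens - spec); best <- spec }
  }
  best
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control; delegates to
#' [stats::p.adjust()][stats::p.adjust] (`method = "BH"`).
#'
#' @param p_values numeric vector in `[0, 1]` (`NA` allowed).
#' @return adjusted p-values, elementwise `>=` the raw ones, capped at 1.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Spearman redundancy filter
#'
#' Among features that predict well, strongly rank-correlated ones
#' (|rho| > `r_cutoff`) are redundant: features are visited in order of
#' ascending p-value and a feature is kept only if it is not correlated
#' beyond the cutoff with an already-kept feature.
#'
#' @param delta_table data.frame/matrix of per-patient feature values
#'   (columns = features).
#' @param p_values named p-values for the same features.
#' @param r_cutoff Spearman correlation cutoff (default 0.8).
#' @return character vector of retained feature names.
#' @export
spearman_redundancy_filter <- function(delta_table, p_values, r_cutoff = 0.8) {
  feats <- names(p_values)
  stopifnot(!is.null(feats), all(feats %in% colnames(delta_table)))
  if (length(feats) < 2L) return(feats)
  ord <- feats[order(p_values)]
  rho <- suppressWarnings(
    cor(as.matrix(delta_table[, ord, drop = FALSE]),
        method = "spearman", use = "pairwise.complete.obs"))
  kept <- character(0)
  for (f in ord) {
    if (!length(kept) ||
        all(abs(rho[f, kept]) <= r_cutoff, na.rm = TRUE))
      kept <- c(kept, f)
  }
  kept
}

#' Per-feature outcome prediction at one time-point
#'
#' For each delta-radiomics feature: binary endpoints (local recurrence,
#' distant metastasis) are tested with the Mann-Whitney U test and scored
#' with the imbalance-adjusted bootstrap logistic AUC/specificity;
#' survival endpoints (PFS, OS) are tested by median dichotomization of
#' the feature followed by the log-rank test. Raw p-values are
#' Benjamini-Hochberg adjusted per endpoint across the feature family.
#'
#' @param delta_table data.frame of per-patient feature deviations
#'   (rows = patients, columns = features).
#' @param outcomes data.frame with columns `pfs_months`, `pfs_event`,
#'   `os_months`, `os_event`, `local_recurrence`, `distant_metastasis`
#'   (any subset; missing endpoints are skipped).
#' @param endpoints endpoints to analyze.
#' @param alpha significance level used downstream (stored, default 0.05).
#' @param B bootstrap replicates for binary endpoints (default 1000).
#' @param compute_auc compute bootstrap AUC for binary endpoints (default
#'   TRUE; disable for speed in large scans).
#' @return data.frame: `feature`, `endpoint`, `p_raw`, `p_adjusted`,
#'   `auc`, `specificity`.
#' @export
predict_outcomes <- function(delta_table, outcomes,
                             endpoints = c("pfs", "os", "lr", "dm"),
                             alpha = 0.05, B = 1000L, compute_auc = TRUE) {
  endpoints <- match.arg(endpoints, several.ok = TRUE)
  feats <- colnames(delta_table)
  res <- list()
  for (ep in endpoints) {
    rows <- lapply(feats, function(f) {
      v <- delta_table[[f]]
      out <- data.frame(feature = f, endpoint = ep, p_raw = NA_real_,
                        auc = NA_real_, specificity = NA_real_)
      if (ep %in% c("lr", "dm")) {
        lab <- if (ep == "lr") outcomes$local_recurrence else
          outcomes$distant_metastasis
        ok <- !is.na(v) & !is.na(lab)
        if (sum(ok) >= 8 && length(unique(lab[ok])) == 2) {
          out$p_raw <- mann_whitney(v[ok][lab[ok] == 1],
                                    v[ok][lab[ok] == 0])$p
          if (compute_auc) {
            ba <- bootstrap_logistic_auc(v[ok], lab[ok], B = B)
            out$auc <- ba$auc; out$specificity <- ba$specificity
          }
        }
      } else {
        tm <- if (ep == "pfs") outcomes$pfs_months else outcomes$os_months
        ev <- if (ep == "pfs") outcomes$pfs_event else outcomes$os_event
        ok <- !is.na(v) & !is.na(tm) & !is.na(ev)
        if (sum(ok) >= 4) {
          grp <- ifelse(v[ok] >= median(v[ok]), "high", "low")
          if (length(unique(grp)) == 2 && sum(ev[ok]) >= 1)
            out$p_raw <- tryCatch(
              logrank_test(tm[ok], ev[ok], grp)$p, error = function(e) NA_real_)
        }
      }
      out
    })
    tab <- do.call(rbind, rows)
    tab$p_adjusted <- bh_adjust(tab$p_raw)
    res[[ep]] <- tab
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  out
}

#' Two-time-point confirmation rule
#'
#' A feature's predictive value is only considered relevant when the
#' BH-adjusted significance holds at both in-treatment time-points (W2 and
#' W5) for the same endpoint.
#'
#' @param results_w2,results_w5 [predict_outcomes()] tables for the two
#'   time-points (same features, same endpoints).
#' @param alpha significance level (default 0.05).
#' @return the W2 table with logical columns `significant_w2`,
#'   `significant_w5`, `confirmed_w5`.
#' @export
two_timepoint_confirmation <- function(results_w2, results_w5, alpha = 0.05) {
  key2 <- paste(results_w2$feature, results_w2$endpoint)
  key5 <- paste(results_w5$feature, results_w5$endpoint)
  if (!setequal(key2, key5))
    stop("feature/endpoint lists differ between time-points")
  m <- match(key2, key5)
  out <- results_w2
  out$significant_w2 <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  p5 <- results_w5$p_adjusted[m]
  out$significant_w5 <- !is.na(p5) & p5 < alpha
  out$confirmed_w5 <- out$significant_w2 & out$significant_w5
  out
}
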