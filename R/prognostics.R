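# Outcome statistics: cohort preparation under a fixed follow-up horizon,
# ROC/AUC with CI, sensitivity-anchored dichotomization, confusion
# arithmetic, univariate Cox regression, Kaplan-Meier with log-rank, and
# inter-rater agreement (Cohen / Light's kappa with interpretation bins).

#' Prepare an outcome cohort for analysis at a fixed horizon
#'
#' Applies the tumor-specific survival rules at `horizon_days` (default
#' 250): tumor-related deaths within the horizon are events; deaths of
#' unrelated cause within the horizon are censored at the death time; cases
#' lost to follow-up within the horizon are excluded; everyone surviving the
#' horizon is censored there. Binary labels for ROC analysis are derived
#' alongside: event within the horizon = positive, survived the horizon =
#' negative; censored-early cases (unrelated death, insufficient follow-up)
#' get no binary label.
#'
#' @param records Data frame with `case_id`, `time_days` (> 0), `event` in
#'   `c("tumor_death", "other_death", "lost", "alive")`, plus any score
#'   columns (carried through).
#' @param horizon_days Follow-up horizon in days.
#' @return List of class `prepared_cohort` with `survival` (case_id, time,
#'   status 0/1, scores), `binary` (case_id, label 0/1, scores), `excluded`
#'   (case ids with reasons) and `horizon_days`.
#' @export
prepare_cohort <- function(records, horizon_days = 250) {
  stopifnot(all(c("case_id", "time_days", "event") %in% names(records)),
            all(records$time_days > 0))
  ev <- as.character(records$event)
  bad <- setdiff(unique(ev), c("tumor_death", "other_death", "lost", "alive"))
  if (length(bad)) stop("unknown event type(s): ", paste(bad, collapse = ", "))
  t <- records$time_days
  h <- horizon_days
  score_cols <- setdiff(names(records), c("case_id", "time_days", "event"))

  surv_excluded <- ev == "lost" & t < h
  surv_time <- pmin(t, h)
  surv_status <- as.integer(ev == "tumor_death" & t <= h)
  # unrelated death / alive before horizon: censored at observed time
  # (already pmin'ed); survivors censored at horizon

  binary <- rep(NA_integer_, nrow(records))
  binary[ev == "tumor_death" & t <= h] <- 1L
  binary[t >= h & !(ev == "tumor_death" & t <= h)] <- 0L

  survival <- data.frame(case_id = records$case_id[!surv_excluded],
                         time = surv_time[!surv_excluded],
                         status = surv_status[!surv_excluded])
  survival[score_cols] <- records[!surv_excluded, score_cols, drop = FALSE]
  bin_keep <- !is.na(binary) & !surv_excluded
  binary_df <- data.frame(case_id = records$case_id[bin_keep],
                          label = binary[bin_keep])
  binary_df[score_cols] <- records[bin_keep, score_cols, drop = FALSE]
  excluded <- rbind(
    data.frame(case_id = records$case_id[surv_excluded],
               reason = rep("lost_within_horizon", sum(surv_excluded))),
    data.frame(case_id = records$case_id[is.na(binary) & !surv_excluded],
               reason = rep("no_binary_label",
                            sum(is.na(binary) & !surv_excluded))))
  structure(list(survival = survival, binary = binary_df,
                 excluded = excluded, horizon_days = h),
            class = "prepared_cohort")
}

#' ROC area under the curve with confidence interval
#'
#' Tie-corrected rank-sum AUC — the probability that a random positive case
#' scores higher than a random negative one, counting ties as 1/2 — with a
#' 95% CI by the asymptotic DeLong variance (default) or a stratified
#' bootstrap for very small samples. Larger scores are taken to indicate the
#' positive (poor-prognosis) class; set `direction = "smaller"` to flip.
#'
#' @param scores Numeric test values.
#' @param labels Binary 0/1 (or logical) outcome labels; both classes must
#'   be present.
#' @param ci_method `"delong"` or `"bootstrap"`.
#' @param direction `"larger"` (default) or `"smaller"`.
#' @param conf_level Confidence level.
#' @return List with `auc`, `ci` (length 2), `n_pos`, `n_neg`, `ci_method`.
#' @export
roc_auc <- function(scores, labels, ci_method = c("delong", "bootstrap"),
                    direction = c("larger", "smaller"), conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  direction <- match.arg(direction)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("both outcome classes must be present")
  if (direction == "smaller") scores <- -scores
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  muffle_degenerate <- function(expr)
    withCallingHandlers(expr, warning = function(w) {
      if (grepl("AUC == 1", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  ci <- muffle_degenerate(
    if (ci_method == "delong")
      pROC::ci.auc(r, conf.level = conf_level, method = "delong")
    else
      pROC::ci.auc(r, conf.level = conf_level, method = "bootstrap",
                   boot.n = 2000, progress = "none"))
  if (any(!is.finite(ci[c(1, 3)]))) {
    # asymptotic variance can degenerate with a single case in one class;
    # fall back to a stratified bootstrap
    ci <- suppressWarnings(
      pROC::ci.auc(r, conf.level = conf_level, method = "bootstrap",
                   boot.n = 2000, boot.stratified = TRUE, progress = "none"))
  }
  list(auc = as.numeric(pROC::auc(r)),
       ci = c(ci[1], ci[3]),
       n_pos = sum(labels == 1), n_neg = sum(labels == 0),
       ci_method = ci_method)
}

confusion_summary <- function(threshold, scores, labels) {
  pos <- scores >= threshold
  TP <- sum(pos & labels == 1); FP <- sum(pos & labels == 0)
  FN <- sum(!pos & labels == 1); TN <- sum(!pos & labels == 0)
  structure(list(threshold = threshold,
                 TP = TP, FP = FP, TN = TN, FN = FN,
                 sensitivity = TP / (TP + FN),
                 specificity = TN / (TN + FP),
                 precision = if (TP + FP > 0) TP / (TP + FP) else NA_real_),
            class = "confusion_summary")
}

#' Sensitivity-anchored threshold selection
#'
#' Dichotomizes a numeric test by choosing, among all candidate thresholds
#' (midpoints of adjacent distinct scores plus plus/minus infinity; a case is
#' called positive when `score >= threshold`), those reaching at least the
#' target sensitivity; among these, the ones with the smallest sensitivity;
#' and of those, the one with the highest specificity, breaking remaining
#' ties toward the larger threshold. This anchors all dichotomized tests at
#' a common sensitivity so their specificities are comparable.
#'
#' @param scores Numeric test values.
#' @param labels Binary 0/1 outcome labels, both classes present.
#' @param target_sensitivity Minimum sensitivity (default 0.70).
#' @return A `confusion_summary`: threshold, confusion cells, sensitivity,
#'   specificity, precision.
#' @export
select_threshold <- function(scores, labels, target_sensitivity = 0.70) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("both outcome classes must be present")
  stopifnot(target_sensitivity > 0, target_sensitivity <= 1)
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  summ <- lapply(cand, confusion_summary, scores = scores, labels = labels)
  sen <- vapply(summ, `[[`, numeric(1), "sensitivity")
  sp <- vapply(summ, `[[`, numeric(1), "specificity")
  ok <- sen >= target_sensitivity
  if (!any(ok)) stop("target sensitivity unreachable")  # defensive
  min_sen <- min(sen[ok])
  ok <- ok & sen == min_sen
  best_sp <- max(sp[ok])
  ok <- ok & sp == best_sp
  summ[[max(which(ok))]]  # ties -> larger threshold
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf(
    "<confusion_summary> threshold %.4g  Sen %.1f%%  Sp %.1f%%  Pre %.1f%%  (TP %d FP %d TN %d FN %d)\n",
    x$threshold, 100 * x$sensitivity, 100 * x$specificity,
    100 * x$precision, x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Precision from published sensitivity/specificity and class sizes
#'
#' Reconstructs the integer confusion cells behind rounded
#' sensitivity/specificity percentages — `TP = round(sen * n_pos)`,
#' `FP = round((1 - sp) * n_neg)` — and returns `TP / (TP + FP)`. The
#' products must be within 0.51 of an integer, which holds whenever the
#' rates are rounded versions of true integer-cell rates.
#'
#' @param sen,sp Sensitivity and specificity as fractions in \[0, 1\].
#' @param n_pos,n_neg Class sizes (e.g., 10 cases with tumor-specific
#'   mortality and 25 survivors).
#' @return Precision as a fraction in \[0, 1\].
#' @export
precision_from_rates <- function(sen, sp, n_pos, n_neg) {
  tp_f <- sen * n_pos
  fp_f <- (1 - sp) * n_neg
  if (abs(tp_f - round(tp_f)) > 0.51 || abs(fp_f - round(fp_f)) > 0.51)
    stop("rates inconsistent with integer confusion cells")
  TP <- round(tp_f); FP <- round(fp_f)
  if (TP + FP == 0) return(NA_real_)
  TP / (TP + FP)
}

#' Univariate Cox proportional-hazards regression
#'
#' Hazard ratio `exp(beta)` maximizing the partial likelihood (Efron tie
#' handling) with a Wald 95% confidence interval. A monotone partial
#' likelihood (complete separation) is reported as non-estimable with a
#' warning.
#'
#' @param x Numeric covariate or group indicator.
#' @param time_days Follow-up times.
#' @param status Event indicator (1 = event, 0 = censored).
#' @param conf_level Confidence level for the Wald interval.
#' @return List with `hr`, `ci`, `coef`, `se`, `p`, `n`, `n_events`,
#'   `estimable`.
#' @export
cox_univariate <- function(x, time_days, status, conf_level = 0.95) {
  stopifnot(length(x) == length(time_days), length(x) == length(status))
  if (sum(status) < 1) stop("at least one event is required")
  if (length(unique(x)) < 2) stop("covariate is constant")
  diverged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time_days, status) ~ x, ties = "efron"),
    warning = function(w) {
      # convergence failures signal a monotone likelihood; folded into the
      # non-estimable report below
      if (grepl("converge|infinite|out of iterations",
                conditionMessage(w))) {
        diverged <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  if (diverged || !is.finite(beta) || !is.finite(se) ||
      abs(beta) > 15 || se > 100) {
    warning("monotone partial likelihood; hazard ratio not estimable")
    return(list(hr = NA_real_, ci = c(NA_real_, NA_real_), coef = beta,
                se = se, p = NA_real_, n = length(x),
                n_events = sum(status), estimable = FALSE))
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(hr = exp(beta), ci = exp(beta + c(-z, z) * se), coef = beta, se = se,
       p = unname(summary(fit)$coefficients[1, "Pr(>|z|)"]),
       n = length(x), n_events = sum(status), estimable = TRUE)
}

#' Kaplan-Meier survival curves
#'
#' Product-limit estimates per group; censored subjects leave the risk set
#' without a drop in the curve.
#'
#' @param time_days,status Follow-up times and event indicators.
#' @param group Optional group labels (single curve if omitted).
#' @param conf_level Confidence level of the pointwise interval.
#' @return Data frame of step-curve points: `group`, `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`, `lower`, `upper`.
#' @export
kaplan_meier <- function(time_days, status, group = NULL, conf_level = 0.95) {
  if (is.null(group)) group <- rep("all", length(time_days))
  d <- data.frame(time = time_days, status = status, group = group)
  fit <- survival::survfit(survival::Surv(time, status) ~ group, data = d,
                           conf.int = conf_level)
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(s$strata)) rep(unique(group)[1], length(s$time))
         else sub("^group=", "", as.character(s$strata))
  data.frame(group = grp, time = s$time, n_risk = s$n.risk,
             n_event = s$n.event, n_censor = s$n.censor, surv = s$surv,
             lower = s$lower, upper = s$upper)
}

#' Log-rank test
#'
#' Standard observed-vs-expected chi-square comparison of survival between
#' groups (1 degree of freedom for two groups).
#'
#' @param time_days,status Follow-up times and event indicators.
#' @param group Group labels (>= 2 groups, >= 1 subject each).
#' @return List with `chisq`, `df`, `p`.
#' @export
log_rank <- function(time_days, status, group) {
  d <- data.frame(time = time_days, status = status,
                  group = as.factor(group))
  if (nlevels(d$group) < 2) stop("need at least two groups")
  sd_ <- survival::survdiff(survival::Surv(time, status) ~ group, data = d)
  df <- length(sd_$n) - 1
  list(chisq = sd_$chisq, df = df,
       p = stats::pchisq(sd_$chisq, df, lower.tail = FALSE))
}

#' Cohen's kappa for two raters
#'
#' Unweighted chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with
#' chance agreement from the raters' marginal category frequencies. If both
#' raters are constant (`p_e = 1`), kappa is 1 when they agree everywhere
#' and an error otherwise.
#'
#' @param a,b Category vectors of equal length (any common coding).
#' @return Kappa in \[-1, 1\].
#' @export
cohens_kappa <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 1)
  lev <- sort(unique(c(as.character(a), as.character(b))))
  a <- factor(as.character(a), levels = lev)
  b <- factor(as.character(b), levels = lev)
  tab <- table(a, b) / length(a)
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  if (pe >= 1 - 1e-12) {
    if (po >= 1 - 1e-12) return(1)
    stop("chance agreement is 1 with imperfect agreement; kappa undefined")
  }
  (po - pe) / (1 - pe)
}

#' Light's kappa for a multi-rater panel
#'
#' The mean of Cohen's kappa over all rater pairs, with the qualitative
#' interpretation label from [interpret_kappa()].
#'
#' @param panel Matrix or data frame, cases in rows and raters in columns
#'   (>= 2 raters).
#' @return Object of class `agreement_result`: `lights_kappa`, `pairwise`
#'   (symmetric matrix), `interpretation`.
#' @export
lights_kappa <- function(panel) {
  panel <- as.matrix(panel)
  k <- ncol(panel)
  if (k < 2) stop("need at least two raters")
  pw <- matrix(NA_real_, k, k, dimnames = list(colnames(panel),
                                               colnames(panel)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    pw[i, j] <- pw[j, i] <- cohens_kappa(panel[, i], panel[, j])
  lk <- mean(pw[upper.tri(pw)])
  structure(list(lights_kappa = lk, pairwise = pw,
                 interpretation = interpret_kappa(lk)),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> Light's kappa = %.3f (%s agreement)\n",
              x$lights_kappa, x$interpretation))
  invisible(x)
}

#' Qualitative interpretation of a kappa value
#'
#' The kappa is rounded to two decimals and then binned: <= 0 poor,
#' 0.01-0.20 slight, 0.21-0.40 fair, 0.41-0.60 moderate, 0.61-0.80
#' substantial, 0.81-1.00 almost perfect. Rounding first means e.g. 0.204 is
#' labeled "slight".
#'
#' @param k Kappa in \[-1, 1\].
#' @return Interpretation label (character).
#' @export
interpret_kappa <- function(k) {
  stopifnot(k >= -1, k <= 1)
  r <- round(k, 2)
  if (r <= 0) "poor"
  else if (r <= 0.20) "slight"
  else if (r <= 0.40) "fair"
  else if (r <= 0.60) "moderate"
  else if (r <= 0.80) "substantial"
  else "almost perfect"
}
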