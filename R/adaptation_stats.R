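# Paired-design statistics for dark/light adaptation under a glucose
# challenge: per-subject paired differences (hyperglycemia - control) in
# change-from-baseline, covariate-adjusted mean difference +/- SE with
# p-values, and within-condition paired change tests.

cq_parameters <- function() c("LV", "SV", "TCV", "CVI")

#' Validate a long-format measurement table
#'
#' The measurement table is the interface between quantification and
#' statistics: one row per (subject, condition, timepoint, ring, parameter)
#' with the measured `value` (volumes in mm^3, CVI in percent) and the
#' subject covariates.
#'
#' @param df Data frame with columns `subject_id`, `condition`, `timepoint`,
#'   `ring`, `parameter`, `value`, `axial_length_mm`, `age_years`.
#' @return The validated data frame, classed `measurement_table`.
#' @export
measurement_table <- function(df) {
  need <- c("subject_id", "condition", "timepoint", "ring", "parameter",
            "value", "axial_length_mm", "age_years")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("measurement_table: missing columns: ",
                         paste(miss, collapse = ", "))
  if (!all(df$condition %in% cq_conditions()))
    stop("measurement_table: unknown condition value")
  if (!all(df$timepoint %in% cq_timepoints()))
    stop("measurement_table: unknown timepoint value")
  if (!all(df$parameter %in% cq_parameters()))
    stop("measurement_table: unknown parameter value")
  key <- interaction(df$subject_id, df$condition, df$timepoint, df$ring,
                     df$parameter, drop = TRUE)
  if (anyDuplicated(key))
    stop("measurement_table: duplicate (subject, condition, timepoint, ring, parameter) records")
  class(df) <- unique(c("measurement_table", class(df)))
  df
}

# one value per subject for a given cell, NA for absent subjects
cell_values <- function(df, subjects, cond, tp, ring, parameter) {
  sel <- df$condition == cond & df$timepoint == tp & df$ring == ring &
    df$parameter == parameter
  out <- rep(NA_real_, length(subjects))
  idx <- match(df$subject_id[sel], subjects)
  out[idx] <- df$value[sel]
  out
}

#' Per-subject paired differences between conditions
#'
#' For the baseline timepoint, returns `value(hyperglycemia) -
#' value(control)` per subject. For post-baseline timepoints (dark and the
#' light-recovery points), values are first expressed as change from the
#' condition's own baseline, and the difference of changes is returned --
#' the quantity the adaptation analysis reports. Subjects missing any
#' required session are dropped with a warning.
#'
#' @param table A [measurement_table()].
#' @param timepoint,ring,parameter Cell selectors.
#' @return Data frame with columns `subject_id`, `diff`, `axial_length_mm`,
#'   `age_years`; at least 2 pairs or an error.
#' @export
paired_differences <- function(table, timepoint, ring, parameter) {
  stopifnot(inherits(table, "measurement_table"))
  timepoint <- match.arg(timepoint, cq_timepoints())
  parameter <- match.arg(parameter, cq_parameters())
  subjects <- unique(table$subject_id)
  v_g <- cell_values(table, subjects, "hyperglycemia", timepoint, ring, parameter)
  v_c <- cell_values(table, subjects, "control", timepoint, ring, parameter)
  if (timepoint != "baseline") {
    b_g <- cell_values(table, subjects, "hyperglycemia", "baseline", ring, parameter)
    b_c <- cell_values(table, subjects, "control", "baseline", ring, parameter)
    d <- (v_g - b_g) - (v_c - b_c)
  } else {
    d <- v_g - v_c
  }
  keep <- !is.na(d)
  if (any(!keep))
    warning("paired_differences: dropped ", sum(!keep),
            " subject(s) with incomplete sessions at ", timepoint)
  if (sum(keep) < 2L)
    stop("paired_differences: fewer than 2 complete pairs at ", timepoint)
  cov <- table[!duplicated(table$subject_id),
               c("subject_id", "axial_length_mm", "age_years")]
  idx <- match(subjects[keep], cov$subject_id)
  data.frame(subject_id = subjects[keep], diff = d[keep],
             axial_length_mm = cov$axial_length_mm[idx],
             age_years = cov$age_years[idx], row.names = NULL)
}

#' Covariate-adjusted mean of paired differences
#'
#' Regresses the per-subject differences on mean-centred covariates; the
#' intercept is the adjusted mean difference, with its standard error and a
#' two-sided p-value on `n - 1 - n_covariates` degrees of freedom. With no
#' covariates this reduces exactly to the paired t-test. Constant or
#' collinear covariates trigger a fall-back to the unadjusted analysis with
#' a warning. For a two-condition within-subject design this estimand is the
#' condition effect of a mixed model with subject random intercepts, which
#' the differencing absorbs exactly.
#'
#' @param differences Data frame from [paired_differences()] (or any frame
#'   with a `diff` column plus covariate columns).
#' @param covariates Character vector of covariate column names; use
#'   `character(0)` for the unadjusted paired t-test.
#' @return List of class `cq_meandiff`: `estimate`, `se`, `statistic`, `df`,
#'   `p_value`, `n`, `covariates`.
#' @export
adjusted_mean_difference <- function(differences,
                                     covariates = c("axial_length_mm", "age_years")) {
  d <- differences$diff
  n <- length(d)
  covariates <- intersect(covariates, names(differences))
  X <- NULL
  if (length(covariates)) {
    X <- as.matrix(differences[covariates])
    X <- sweep(X, 2L, colMeans(X))
    ok <- apply(X, 2L, function(x) stats::sd(x) > 0)
    X <- X[, ok, drop = FALSE]
    if (ncol(X) && qr(cbind(1, X))$rank < ncol(X) + 1L) ok[] <- FALSE
    if (!all(ok)) {
      warning("adjusted_mean_difference: constant/collinear covariates dropped; ",
              "falling back to unadjusted paired analysis")
      if (!any(ok)) X <- NULL else X <- X[, ok, drop = FALSE]
    }
    if (!is.null(X) && !ncol(X)) X <- NULL
  }
  p_cov <- if (is.null(X)) 0L else ncol(X)
  if (n < p_cov + 2L)
    stop("adjusted_mean_difference: need at least ", p_cov + 2L, " pairs")
  dfree <- n - 1L - p_cov
  if (is.null(X)) {
    est <- mean(d)
    se <- stats::sd(d) / sqrt(n)
  } else {
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), d)
    est <- unname(fit$coefficients[1L])
    sigma2 <- sum(fit$residuals^2) / dfree
    XtXinv <- chol2inv(qr.R(fit$qr))
    se <- sqrt(sigma2 * XtXinv[1L, 1L])
  }
  if (se == 0) {
    statistic <- if (est == 0) 0 else sign(est) * Inf
    p <- if (est == 0) 1 else 0
  } else {
    statistic <- est / se
    p <- 2 * stats::pt(-abs(statistic), dfree)
  }
  structure(list(estimate = est, se = se, statistic = statistic, df = dfree,
                 p_value = p, n = n,
                 covariates = if (is.null(X)) character(0) else colnames(X)),
            class = "cq_meandiff")
}

#' @export
print.cq_meandiff <- function(x, ...) {
  cat(sprintf("mean difference %.4f +/- %.4f (n = %d, t = %.3f, df = %d, p = %.4g)\n",
              x$estimate, x$se, x$n, x$statistic, x$df, x$p_value))
  if (length(x$covariates))
    cat("  adjusted for:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

#' Within-condition paired change test
#'
#' Paired t-test on per-subject changes `value(to) - value(from)` within one
#' condition (e.g. baseline to dark adaptation in the control arm).
#' Identical pairs (zero variance, zero mean change) return p = 1 by
#' convention.
#'
#' @param table A [measurement_table()].
#' @param condition,from_timepoint,to_timepoint,ring,parameter Selectors.
#' @return A `cq_meandiff` (unadjusted).
#' @export
within_condition_change <- function(table, condition, from_timepoint,
                                    to_timepoint, ring, parameter) {
  stopifnot(inherits(table, "measurement_table"))
  condition <- match.arg(condition, cq_conditions())
  subjects <- unique(table$subject_id)
  v_from <- cell_values(table, subjects, condition, from_timepoint, ring, parameter)
  v_to <- cell_values(table, subjects, condition, to_timepoint, ring, parameter)
  ch <- v_to - v_from
  keep <- !is.na(ch)
  if (any(!keep))
    warning("within_condition_change: dropped ", sum(!keep),
            " subject(s) with incomplete sessions")
  if (sum(keep) < 2L)
    stop("within_condition_change: fewer than 2 complete pairs")
  adjusted_mean_difference(data.frame(diff = ch[keep]), covariates = character(0))
}

#' Build the full adaptation difference report
#'
#' One cell per (ring, parameter, post-baseline timepoint): the
#' covariate-adjusted mean difference (glucose - control) in
#' change-from-baseline, its SE, the p-value and a significance star at the
#' chosen alpha. Mirrors the standard reporting grid of light-modulation
#' challenge studies (4 parameters x dark + 3 light-recovery timepoints).
#'
#' @param table A [measurement_table()]; an empty table yields an empty
#'   report.
#' @param covariates Covariates passed to [adjusted_mean_difference()].
#' @param alpha Significance level for starring (default 0.05).
#' @param p_adjust Multiple-testing correction across the report's cells
#'   (`"none"`, the default, or any [stats::p.adjust()] method such as
#'   `"holm"`).
#' @return Data frame of class `adaptation_report` with columns `ring`,
#'   `parameter`, `timepoint`, `n_pairs`, `mean_diff`, `se`, `p_value`,
#'   `significant`, `label` ("mean +/- SE" with star).
#' @export
build_report <- function(table, covariates = c("axial_length_mm", "age_years"),
                         alpha = 0.05, p_adjust = "none") {
  stopifnot(inherits(table, "measurement_table"))
  tps <- setdiff(cq_timepoints(), "baseline")
  rings <- unique(table$ring)
  grid <- expand.grid(ring = rings, parameter = cq_parameters(),
                      timepoint = tps, stringsAsFactors = FALSE)
  if (!nrow(table) || !nrow(grid)) {
    out <- data.frame(ring = character(0), parameter = character(0),
                      timepoint = character(0), n_pairs = integer(0),
                      mean_diff = numeric(0), se = numeric(0),
                      p_value = numeric(0), significant = logical(0),
                      label = character(0))
    class(out) <- c("adaptation_report", class(out))
    attr(out, "alpha") <- alpha
    return(out)
  }
  res <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    tryCatch({
      dd <- paired_differences(table, g$timepoint, g$ring, g$parameter)
      fit <- adjusted_mean_difference(dd, covariates)
      data.frame(g, n_pairs = fit$n, mean_diff = fit$estimate, se = fit$se,
                 p_value = fit$p_value)
    }, error = function(e)
      data.frame(g, n_pairs = NA_integer_, mean_diff = NA_real_,
                 se = NA_real_, p_value = NA_real_))
  })
  out <- do.call(rbind, res)
  out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  out$label <- ifelse(is.na(out$mean_diff), "-",
                      sprintf("%.2f ± %.2f%s", out$mean_diff, out$se,
                              ifelse(out$significant, "*", "")))
  row.names(out) <- NULL
  class(out) <- c("adaptation_report", class(out))
  attr(out, "alpha") <- alpha
  out
}

#' @export
print.adaptation_report <- function(x, ...) {
  need <- c("ring", "parameter", "timepoint", "label")
  if (!all(need %in% names(x))) return(NextMethod())  # subset lost structure
  cat("Adaptation difference report (glucose - control, change from baseline; * p < ",
      attr(x, "alpha") %||% 0.05, ")\n", sep = "")
  if (!nrow(x)) { cat("  <empty>\n"); return(invisible(x)) }
  for (rg in unique(x$ring)) {
    cat("ring ", rg, " mm:\n", sep = "")
    sub <- x[x$ring == rg, ]
    wide <- stats::reshape(sub[, c("parameter", "timepoint", "label")],
                           idvar = "parameter", timevar = "timepoint",
                           direction = "wide")
    names(wide) <- sub("^label\\.", "", names(wide))
    print.data.frame(wide, row.names = FALSE)
  }
  invisible(x)
}

#' Simulate a measurement-level cohort
#'
#' Parametric generator for calibration of the statistics layer: per-subject
#' baseline means, optional condition-by-timepoint effects, and independent
#' Gaussian session noise per parameter, at the scale of a healthy-adult
#' macular choroid (TCV ~26 mm^3, CVI ~58.8%). Effects are expressed on the
#' change-from-baseline difference scale (glucose - control), the scale the
#' report estimates. Parameters are simulated independently (no LV + SV =
#' TCV coherence): the target is the sampling model of the paired tests, for
#' which exact normality matters; the image-level phantom path provides
#' coherent values.
#'
#' @param n_subjects Number of subjects (default 24).
#' @param effects Named list, e.g. `list(CVI = c(dark = -0.36))`: additive
#'   shift of the hyperglycemia session at that timepoint, in the
#'   parameter's units (mm^3; CVI in percent).
#' @param noise_sd Per-parameter session measurement noise SD (defaults
#'   calibrated so paired-difference SEs sit at the reported study scale).
#' @param subject_sd Between-subject SD of baseline means.
#' @param baseline_mean Population baseline means.
#' @param al_slope Per-parameter dependence of the subject mean on axial
#'   length (per mm, centred at 25.47 mm), giving the covariate adjustment
#'   something real to absorb.
#' @param ring Ring label stamped on the records.
#' @param seed Integer RNG seed.
#' @return A [measurement_table()].
#' @export
simulate_cohort <- function(n_subjects = 24L,
                            effects = list(),
                            noise_sd = c(LV = 0.25, SV = 0.20, TCV = 0.40, CVI = 0.22),
                            subject_sd = c(LV = 3.5, SV = 2.5, TCV = 5.9, CVI = 1.3),
                            baseline_mean = c(LV = 15.34, SV = 10.74,
                                              TCV = 26.08, CVI = 58.77),
                            al_slope = c(LV = -0.6, SV = -0.4, TCV = -1.0, CVI = 0.3),
                            ring = "0-6", seed = 1L) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  pars <- cq_parameters()
  al <- stats::rnorm(n_subjects, 25.47, 1.16)
  age <- pmax(stats::rnorm(n_subjects, 25.29, 1.91), 18)
  mu <- sapply(pars, function(p)
    baseline_mean[[p]] + al_slope[[p]] * (al - 25.47) +
      stats::rnorm(n_subjects, 0, subject_sd[[p]]))
  rows <- list()
  for (cond in cq_conditions()) for (tp in cq_timepoints()) for (p in pars) {
    eff <- 0
    if (cond == "hyperglycemia" && tp != "baseline" &&
        !is.null(effects[[p]]) && !is.na(effects[[p]][tp]) &&
        tp %in% names(effects[[p]]))
      eff <- effects[[p]][[tp]]
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = sprintf("S%02d", seq_len(n_subjects)),
      condition = cond, timepoint = tp, ring = ring, parameter = p,
      value = mu[, p] + eff + stats::rnorm(n_subjects, 0, noise_sd[[p]]),
      axial_length_mm = al, age_years = age)
  }
  measurement_table(do.call(rbind, rows))
}
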