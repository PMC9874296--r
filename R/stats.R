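#' Endpoint statistics
#'
#' Temporal endpoint summarisation (trapezoidal AUC and group-peak
#' maxima), log-scale ANOVA with Tukey-adjusted pairwise contrasts,
#' beta regression of cell-type compositions with a logit link,
#' square-root / log transformed linear models for the spatial metrics,
#' and Pearson correlation matrices between endpoint families.
#'
#' All fitted comparisons are returned as a tidy data.frame (one row per
#' contrast) with columns `comparison, estimate, se, df, lower, upper,
#' p_value, transformation, adjustment`; estimates are on the transformed
#' (or link) scale.
#'
#' @name endpoint_stats
NULL

#' Trapezoidal area under a temporal curve
#'
#' Integrates the observed values over the observed timepoints by the
#' trapezoid rule: no baseline subtraction, no extrapolation beyond the
#' observed range, no imputation of missing timepoints (missing values are
#' dropped and the remaining points integrated).
#'
#' @param time_hr numeric timepoints in hours.
#' @param value endpoint values, same length.
#' @return AUC in endpoint.hr units.
#' @export
auc_trapezoid <- function(time_hr, value) {
  keep <- is.finite(time_hr) & is.finite(value)
  t <- time_hr[keep]; v <- value[keep]
  if (length(t) < 2L) stop("AUC needs at least 2 non-missing timepoints")
  o <- order(t)
  t <- t[o]; v <- v[o]
  sum(diff(t) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
}

#' Per-subject AUC of an endpoint table
#'
#' @param table long endpoint data.frame with columns
#'   `subject_id, group, cohort, time_hr, value`.
#' @return One row per subject: `subject_id, group, cohort, auc`.
#' @export
endpoint_auc <- function(table) {
  need <- c("subject_id", "group", "cohort", "time_hr", "value")
  if (!all(need %in% colnames(table))) {
    stop("endpoint table needs columns: ", paste(need, collapse = ", "))
  }
  subj <- unique(table[, c("subject_id", "group", "cohort")])
  subj$auc <- vapply(subj$subject_id, function(s) {
    sub <- table[table$subject_id == s, ]
    auc_trapezoid(sub$time_hr, sub$value)
  }, numeric(1))
  rownames(subj) <- NULL
  subj
}

#' Per-subject values at the group-peak timepoint
#'
#' For each (group, cohort) cell, the peak timepoint is the timepoint with
#' the highest group-mean response; every subject of that cell is then
#' read out at that shared timepoint. Ties in the group mean resolve to
#' the earliest tied timepoint (with a message).
#'
#' @param table long endpoint data.frame (see [endpoint_auc()]).
#' @return One row per subject: `subject_id, group, cohort, peak_time_hr,
#'   value`.
#' @export
group_max <- function(table) {
  need <- c("subject_id", "group", "cohort", "time_hr", "value")
  if (!all(need %in% colnames(table))) {
    stop("endpoint table needs columns: ", paste(need, collapse = ", "))
  }
  out <- list()
  for (co in unique(table$cohort)) for (g in unique(table$group)) {
    sub <- table[table$group == g & table$cohort == co, ]
    if (!nrow(sub)) next
    tp <- sort(unique(sub$time_hr))
    gm <- vapply(tp, function(t) mean(sub$value[sub$time_hr == t]),
                 numeric(1))
    peaks <- tp[gm == max(gm)]
    if (length(peaks) > 1L) {
      message("group ", g, " (", co, "): tied peak means at ",
              paste(peaks, collapse = ", "), " hr; using earliest")
    }
    pk <- min(peaks)
    at <- sub[sub$time_hr == pk, ]
    out[[length(out) + 1L]] <- data.frame(
      subject_id = at$subject_id, group = g, cohort = co,
      peak_time_hr = pk, value = at$value, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

tidy_emmeans_contrasts <- function(ctr, transformation, adjustment) {
  s <- as.data.frame(summary(ctr, infer = c(TRUE, TRUE)))
  # emmeans labels the CI columns asymp.* when the reference df is infinite
  if (is.null(s$lower.CL)) s$lower.CL <- s$asymp.LCL
  if (is.null(s$upper.CL)) s$upper.CL <- s$asymp.UCL
  # groups with literally identical values leave no residual variance;
  # the contrast is then 0/0 up to rounding -- no evidence of a difference
  exact0 <- abs(s$estimate) < 1e-8 & s$SE < 1e-8
  s$p.value[exact0] <- 1
  s$estimate[exact0] <- 0
  data.frame(comparison = as.character(s$contrast),
             estimate = s$estimate, se = s$SE, df = s$df,
             lower = s$lower.CL, upper = s$upper.CL,
             p_value = s$p.value,
             transformation = transformation, adjustment = adjustment,
             stringsAsFactors = FALSE)
}

#' Log-scale ANOVA with Tukey-adjusted pairwise contrasts
#'
#' Fits a linear model on log-transformed values with treatment as fixed
#' effect — optionally with cohort and the treatment-cohort interaction —
#' and returns all pairwise treatment contrasts with Tukey
#' studentized-range p-value adjustment.
#'
#' @param values positive endpoint summaries (e.g. per-subject AUC or peak
#'   values).
#' @param group treatment labels, one per value.
#' @param cohort optional cohort labels; when supplied the model includes
#'   cohort, and `interaction = TRUE` adds the treatment:cohort term, with
#'   contrasts over the crossed (group, cohort) cells.
#' @param interaction include the interaction term (requires `cohort`).
#' @return A tidy contrast data.frame (log-scale estimates).
#' @export
anova_log_tukey <- function(values, group, cohort = NULL,
                            interaction = FALSE) {
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("log-scale ANOVA requires strictly positive values; ",
         "decide an offset policy for non-positive endpoints upstream")
  }
  if (length(unique(group)) < 2L) stop("need at least 2 groups")
  df <- data.frame(y = log(values), group = factor(group))
  if (!is.null(cohort)) df$cohort <- factor(cohort)
  form <- if (is.null(cohort)) y ~ group
  else if (interaction) y ~ group * cohort else y ~ group + cohort
  fit <- stats::lm(form, data = df)
  spec <- if (!is.null(cohort) && interaction) ~ group * cohort else ~ group
  emm <- emmeans::emmeans(fit, spec)
  ctr <- emmeans::contrast(emm, method = "pairwise", adjust = "tukey")
  tidy_emmeans_contrasts(ctr, "log", "tukey")
}

#' Beta regression of cell-type ratios
#'
#' Models ratios in \[0, 1\] with a beta likelihood, the mean linked to the
#' treatment effect through a logit link and a single common precision
#' parameter, fitted by maximum likelihood (glmmTMB). Ratios equal to 0
#' are set to the pseudo count `pseudo` and ratios equal to 1 to
#' `1 - pseudo` before fitting. Pairwise treatment contrasts are Wald
#' tests, unadjusted (comparisons prespecified).
#'
#' @param ratios values in \[0, 1\].
#' @param group treatment labels.
#' @param pseudo pseudo count replacing exact zeros (default 1e-5).
#' @return A list with `contrasts` (tidy data.frame, logit-scale
#'   estimates), `model` (the glmmTMB fit), and `adjusted_ratios` (the
#'   values actually modelled).
#' @export
beta_regression <- function(ratios, group, pseudo = 1e-5) {
  if (any(ratios < 0 | ratios > 1)) stop("ratios must lie in [0, 1]")
  if (length(unique(group)) < 2L) stop("need at least 2 groups")
  y <- ratios
  y[y == 0] <- pseudo
  y[y == 1] <- 1 - pseudo
  df <- data.frame(y = y, group = factor(group))
  fit <- glmmTMB::glmmTMB(y ~ group, family = glmmTMB::beta_family("logit"),
                          data = df)
  if (!isTRUE(fit$sdr$pdHess) || !is.finite(stats::logLik(fit))) {
    grad <- tryCatch(fit$fit$objective, error = function(e) NA)
    stop("beta regression did not converge (non-PD Hessian); ",
         "objective = ", format(grad))
  }
  emm <- emmeans::emmeans(fit, ~group)
  ctr <- emmeans::contrast(emm, method = "pairwise", adjust = "none")
  list(contrasts = tidy_emmeans_contrasts(ctr, "logit", "none"),
       model = fit, adjusted_ratios = y)
}

#' Transformed linear model for spatial metrics
#'
#' OLS on a square-root (proximity counts) or log (nearest-neighbour
#' distances) transformed outcome with treatment as fixed effect;
#' pairwise contrasts unadjusted (comparisons prespecified).
#'
#' @param outcome non-negative (sqrt) or strictly positive (log) values.
#' @param group treatment labels.
#' @param transform `"sqrt"` or `"log"`.
#' @return A tidy contrast data.frame (transformed-scale estimates).
#' @export
transformed_lm <- function(outcome, group, transform = c("sqrt", "log")) {
  transform <- match.arg(transform)
  if (transform == "sqrt" && any(outcome < 0)) {
    stop("sqrt transform requires non-negative outcomes")
  }
  if (transform == "log" && any(outcome <= 0)) {
    stop("log transform requires strictly positive outcomes")
  }
  if (length(unique(group)) < 2L) stop("need at least 2 groups")
  df <- data.frame(y = if (transform == "sqrt") sqrt(outcome) else
    log(outcome), group = factor(group))
  fit <- stats::lm(y ~ group, data = df)
  if (stats::df.residual(fit) < 1L) {
    stop("no residual degrees of freedom (one observation per group)")
  }
  emm <- emmeans::emmeans(fit, ~group)
  ctr <- emmeans::contrast(emm, method = "pairwise", adjust = "none")
  tidy_emmeans_contrasts(ctr, transform, "none")
}

#' Pearson correlation matrix between two endpoint families
#'
#' Correlates every column of `X` with every column of `Y` (pairwise
#' complete observations), returning `r`, two-sided `p`, and the number of
#' complete pairs. Constant columns yield `NA` (undefined correlation),
#' never 0; pairs with fewer than 3 complete observations are `NA`.
#'
#' @param X numeric matrix or data.frame, samples x endpoints.
#' @param Y numeric matrix or data.frame, samples x endpoints; default
#'   `X`.
#' @return A list of matrices `r`, `p`, `n` (rows = columns of `X`,
#'   columns = columns of `Y`).
#' @export
pearson_matrix <- function(X, Y = X) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same rows (samples)")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  r <- p <- n <- matrix(NA_real_, ncol(X), ncol(Y),
                        dimnames = list(colnames(X), colnames(Y)))
  for (i in seq_len(ncol(X))) for (j in seq_len(ncol(Y))) {
    ok <- is.finite(X[, i]) & is.finite(Y[, j])
    n[i, j] <- sum(ok)
    if (n[i, j] < 3L) next
    if (stats::sd(X[ok, i]) == 0 || stats::sd(Y[ok, j]) == 0) next
    ct <- stats::cor.test(X[ok, i], Y[ok, j], method = "pearson")
    r[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
  }
  list(r = r, p = p, n = n)
}
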