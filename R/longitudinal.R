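#' Assemble the participant-wave table for longitudinal modelling
#'
#' Joins per-perceiver accuracy records with classroom transitivity on
#' (classroom, wave), drops rows whose classroom-wave transitivity is
#' undefined (counted in the `n_missing_transitivity` attribute), drops
#' participants observed on fewer than `min_waves` usable waves (counted in
#' `n_excluded_participants`), and disaggregates the time-varying transitivity
#' into a between-person baseline — the value at each participant's first
#' observed wave — and within-person deviations from it. Participants who
#' change classrooms between waves take each wave's transitivity from the
#' classroom they belong to at that wave.
#'
#' @param accuracy_records Data frame as returned by [accuracy_table()]
#'   (columns `perceiver`, `classroom_id`, `wave_id`, `accuracy` required).
#' @param transitivity_records Data frame as returned by
#'   [transitivity_table()] (columns `classroom_id`, `wave_id`,
#'   `transitivity` required); every classroom-wave referenced by
#'   `accuracy_records` must be present.
#' @param min_waves Minimum usable waves per participant; default 2.
#' @param verbose Report drop counts via `message()`?
#' @return A data frame of class `scm_long_table` with columns `participant`,
#'   `classroom_id`, `wave_id`, `time` (the integer wave index), `accuracy`,
#'   `transitivity`, `transitivity_t0` and `transitivity_change`
#'   (`transitivity - transitivity_t0`, zero at each participant's first
#'   observed wave).
#' @export
assemble_long_table <- function(accuracy_records, transitivity_records,
                                min_waves = 2L, verbose = TRUE) {
  need_acc <- c("perceiver", "classroom_id", "wave_id", "accuracy")
  need_tr <- c("classroom_id", "wave_id", "transitivity")
  stopifnot(all(need_acc %in% names(accuracy_records)),
            all(need_tr %in% names(transitivity_records)),
            is_count(min_waves, min = 1L))
  tkey <- paste(transitivity_records$classroom_id, transitivity_records$wave_id,
                sep = .EDGE_SEP)
  if (anyDuplicated(tkey)) {
    stop("transitivity_records has more than one row for some classroom-wave",
         call. = FALSE)
  }
  akey <- paste(accuracy_records$classroom_id, accuracy_records$wave_id,
                sep = .EDGE_SEP)
  idx <- match(akey, tkey)
  if (anyNA(idx)) {
    bad <- unique(sub(.EDGE_SEP, " wave ", akey[is.na(idx)], fixed = TRUE))
    stop("no transitivity record for classroom ", paste(bad, collapse = "; "),
         call. = FALSE)
  }
  df <- data.frame(
    participant = as.character(accuracy_records$perceiver),
    classroom_id = as.character(accuracy_records$classroom_id),
    wave_id = as.integer(accuracy_records$wave_id),
    accuracy = as.numeric(accuracy_records$accuracy),
    transitivity = transitivity_records$transitivity[idx],
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(paste(df$participant, df$wave_id, sep = .EDGE_SEP))) {
    stop("a participant has more than one accuracy record at the same wave",
         call. = FALSE)
  }
  miss <- is.na(df$transitivity)
  n_missing <- sum(miss)
  if (verbose && n_missing > 0L) {
    message(sprintf("dropping %d row(s) with undefined classroom transitivity", n_missing))
  }
  df <- df[!miss, , drop = FALSE]
  df <- df[order_c(df$participant, df$wave_id), , drop = FALSE]
  counts <- table(df$participant)
  keep_ids <- names(counts)[counts >= min_waves]
  n_excluded <- sum(counts < min_waves)
  if (verbose && n_excluded > 0L) {
    message(sprintf("dropping %d participant(s) observed on fewer than %d waves",
                    n_excluded, as.integer(min_waves)))
  }
  df <- df[df$participant %in% keep_ids, , drop = FALSE]
  if (nrow(df) > 0L) {
    first_wave <- !duplicated(df$participant)  # rows are participant/wave sorted
    t0 <- df$transitivity[first_wave]
    df$transitivity_t0 <- t0[match(df$participant, df$participant[first_wave])]
    df$transitivity_change <- df$transitivity - df$transitivity_t0
  } else {
    df$transitivity_t0 <- numeric()
    df$transitivity_change <- numeric()
  }
  df$time <- df$wave_id
  df <- df[, c("participant", "classroom_id", "wave_id", "time", "accuracy",
               "transitivity", "transitivity_t0", "transitivity_change")]
  rownames(df) <- NULL
  structure(df,
            class = c("scm_long_table", "data.frame"),
            n_missing_transitivity = n_missing,
            n_excluded_participants = n_excluded,
            min_waves = as.integer(min_waves))
}

#' Fitted random-intercept model or published coefficient set
#'
#' Container for the fixed effects (intercept, time, transitivity at the first
#' observation, transitivity change), their standard errors, degrees of
#' freedom and p-values, plus the participant-intercept and residual variance
#' components. Usually produced by [fit_random_intercept()]; can also be
#' constructed directly from published coefficients for effect-translation
#' calculations with [predicted_accuracy_difference()].
#'
#' @param estimates Named numeric vector with elements `intercept`, `time`,
#'   `transitivity_t0`, `transitivity_change`.
#' @param se,df,p_value Optional parallel named vectors.
#' @param sigma2_intercept,sigma2_residual Variance components (>= 0).
#' @param n_participants,n_observations Sample sizes.
#' @param df_method Label for the degrees-of-freedom approximation used for
#'   p-values (e.g. `"Satterthwaite"`).
#' @param model Optional underlying `merMod` fit.
#' @return An object of class `scm_model_fit` with a `fixed` data frame
#'   (term, estimate, se, df, p_value) and the remaining components as fields.
#' @export
scm_model_fit <- function(estimates, se = NULL, df = NULL, p_value = NULL,
                          sigma2_intercept = NA_real_, sigma2_residual = NA_real_,
                          n_participants = NA_integer_, n_observations = NA_integer_,
                          df_method = NA_character_, model = NULL) {
  terms <- c("intercept", "time", "transitivity_t0", "transitivity_change")
  if (!is.numeric(estimates) || !all(terms %in% names(estimates))) {
    stop("`estimates` must be a numeric vector named ",
         paste(terms, collapse = ", "), call. = FALSE)
  }
  pick <- function(v) if (is.null(v)) rep(NA_real_, 4L) else as.numeric(v[terms])
  fixed <- data.frame(
    term = terms,
    estimate = as.numeric(estimates[terms]),
    se = pick(se), df = pick(df), p_value = pick(p_value),
    stringsAsFactors = FALSE
  )
  for (v in c(sigma2_intercept, sigma2_residual)) {
    if (!is.na(v) && v < -1e-12) stop("variance components must be non-negative", call. = FALSE)
  }
  if (!is.na(n_participants) && !is.na(n_observations)) {
    if (n_participants < 2L || n_observations < n_participants) {
      stop("need n_observations >= n_participants >= 2", call. = FALSE)
    }
  }
  structure(
    list(fixed = fixed,
         sigma2_intercept = as.numeric(sigma2_intercept),
         sigma2_residual = as.numeric(sigma2_residual),
         n_participants = as.integer(n_participants),
         n_observations = as.integer(n_observations),
         df_method = df_method,
         model = model),
    class = "scm_model_fit"
  )
}

#' @export
print.scm_model_fit <- function(x, digits = 4L, ...) {
  cat("Random-intercept model of perception accuracy\n")
  cat(sprintf("  participants: %s, observations: %s, df method: %s\n",
              x$n_participants, x$n_observations, x$df_method))
  fx <- x$fixed
  fx$estimate <- round(fx$estimate, digits)
  fx$se <- round(fx$se, digits)
  fx$df <- round(fx$df, 1L)
  fx$p_value <- signif(fx$p_value, 3L)
  print(fx, row.names = FALSE)
  cat(sprintf("  sigma^2 intercept: %s  sigma^2 residual: %s\n",
              format(round(x$sigma2_intercept, digits)),
              format(round(x$sigma2_residual, digits))))
  invisible(x)
}

#' Fit the longitudinal random-intercept model of perception accuracy
#'
#' Fits `accuracy ~ time + transitivity_t0 + transitivity_change +
#' (1 | participant)` by restricted maximum likelihood, with Satterthwaite
#' degrees of freedom for the fixed-effect p-values. A positive
#' `transitivity_t0` coefficient means participants starting in
#' higher-transitivity classrooms are more accurate (between-person effect); a
#' positive `transitivity_change` coefficient means increases in classroom
#' transitivity go with increases in accuracy (within-person effect).
#'
#' A singular design — e.g. transitivity never changing, so
#' `transitivity_change` is identically zero — raises an error of class
#' `scmnet_singular_design` naming the offending predictor. Optimiser
#' non-convergence is an error, not a partial result; a boundary (zero)
#' estimate of the intercept variance is legitimate and returned as 0.
#'
#' @param table An [assemble_long_table()] result (or any data frame with the
#'   same columns).
#' @return An [scm_model_fit()].
#' @export
fit_random_intercept <- function(table) {
  need <- c("participant", "time", "accuracy", "transitivity_t0", "transitivity_change")
  stopifnot(all(need %in% names(table)))
  table <- as.data.frame(table)
  if (anyNA(table[need])) stop("missing values in model variables", call. = FALSE)
  if (length(unique(table$participant)) < 2L) {
    stop("need at least 2 participants to fit the random-intercept model", call. = FALSE)
  }
  for (pred in c("time", "transitivity_t0", "transitivity_change")) {
    if (stats::sd(table[[pred]]) == 0) {
      stop(errorCondition(
        sprintf("predictor '%s' is constant; the design is singular", pred),
        class = c("scmnet_singular_design", "error", "condition")
      ))
    }
  }
  if (stats::sd(table$accuracy) == 0) {
    stop(errorCondition(
      "response 'accuracy' is constant; the model cannot be fitted",
      class = c("scmnet_singular_design", "error", "condition")
    ))
  }
  x <- stats::model.matrix(~ time + transitivity_t0 + transitivity_change,
                           data = table)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    culprit <- colnames(x)[qx$pivot[(qx$rank + 1L):ncol(x)]]
    stop(errorCondition(
      sprintf("collinear predictor(s): %s; the design is singular",
              paste(culprit, collapse = ", ")),
      class = c("scmnet_singular_design", "error", "condition")
    ))
  }
  ctrl <- lme4::lmerControl(
    check.conv.singular = "ignore",
    optCtrl = list(xtol_abs = 1e-8, ftol_abs = 1e-8)
  )
  fit <- lmerTest::lmer(
    accuracy ~ time + transitivity_t0 + transitivity_change + (1 | participant),
    data = table, REML = TRUE, control = ctrl
  )
  opt <- fit@optinfo$conv
  msgs <- unlist(opt$lme4$messages)
  failed <- (!is.null(opt$opt) && opt$opt != 0) ||
    any(grepl("failed to converge", msgs, ignore.case = TRUE))
  if (failed) {
    stop("random-intercept model did not converge: ",
         paste(msgs, collapse = "; "), call. = FALSE)
  }
  cs <- stats::coef(summary(fit))
  rn <- rownames(cs)
  ord <- match(c("(Intercept)", "time", "transitivity_t0", "transitivity_change"), rn)
  terms <- c("intercept", "time", "transitivity_t0", "transitivity_change")
  vc <- as.data.frame(lme4::VarCorr(fit))
  scm_model_fit(
    estimates = stats::setNames(cs[ord, "Estimate"], terms),
    se = stats::setNames(cs[ord, "Std. Error"], terms),
    df = stats::setNames(cs[ord, "df"], terms),
    p_value = stats::setNames(cs[ord, "Pr(>|t|)"], terms),
    sigma2_intercept = vc$vcov[vc$grp == "participant"],
    sigma2_residual = vc$vcov[vc$grp == "Residual"],
    n_participants = length(unique(table$participant)),
    n_observations = nrow(table),
    df_method = "Satterthwaite",
    model = fit
  )
}

#' Translate a fitted coefficient into an expected accuracy difference
#'
#' For a linear model the expected accuracy difference associated with a
#' transitivity difference `delta` on one predictor is simply
#' `coefficient * delta`: e.g. a coefficient of 0.67 on baseline transitivity
#' means a 0.10 classroom difference in transitivity corresponds to an
#' expected 0.067 difference in accuracy.
#'
#' @param fit An [scm_model_fit()].
#' @param which `"transitivity_t0"` (between-person) or
#'   `"transitivity_change"` (within-person).
#' @param delta Transitivity difference on the proportion scale.
#' @return Expected accuracy difference (proportion scale).
#' @export
predicted_accuracy_difference <- function(fit,
                                          which = c("transitivity_t0",
                                                    "transitivity_change"),
                                          delta) {
  stopifnot(inherits(fit, "scm_model_fit"),
            is.numeric(delta), length(delta) == 1L, !is.na(delta))
  which <- match.arg(which)
  est <- fit$fixed$estimate[fit$fixed$term == which]
  unname(est * delta)
}
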