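# Fixed- and random-effects (DerSimonian-Laird) pooling of study-level
# hazard ratios on the log scale, with Cochran's Q, I-squared and the
# conventional chi-squared heterogeneity test.

# 95% normal quantile kept at full precision: rounding to 1.96 shifts
# back-transformed SEs in the 4th decimal.
.z_level <- function(level) stats::qnorm(1 - (1 - level) / 2)

#' Build a study effect from a hazard ratio and its confidence interval
#'
#' Back-transforms a reported HR with CI to the log scale:
#' `log_effect = ln(hr)` and `se = (ln ci_high - ln ci_low) / (2 z)`,
#' where `z` is the normal quantile for the stated level.
#'
#' @param hr Hazard ratio, positive.
#' @param ci_low,ci_high Confidence bounds, `0 < ci_low <= hr <= ci_high`.
#' @param level Confidence level of the interval (default 0.95).
#' @param study_id,outcome Optional identifiers carried along.
#' @return One-row data frame of class `study_effects` with columns
#'   `study_id`, `outcome`, `hr`, `ci_low`, `ci_high`, `log_effect`, `se`.
#' @export
effect_from_ci <- function(hr, ci_low, ci_high, level = 0.95,
                           study_id = NA_character_, outcome = NA_character_) {
  if (!is.numeric(hr) || !is.numeric(ci_low) || !is.numeric(ci_high) ||
      anyNA(c(hr, ci_low, ci_high)) || any(c(hr, ci_low, ci_high) <= 0)) {
    stop("hr, ci_low and ci_high must be positive numbers", call. = FALSE)
  }
  if (length(level) != 1 || level <= 0 || level >= 1) {
    stop("level must lie in (0, 1)", call. = FALSE)
  }
  n <- max(length(hr), length(ci_low), length(ci_high))
  hr <- rep_len(hr, n); ci_low <- rep_len(ci_low, n); ci_high <- rep_len(ci_high, n)
  if (any(ci_low > hr) || any(hr > ci_high)) {
    stop("confidence interval must bracket the hazard ratio (ci_low <= hr <= ci_high)",
         call. = FALSE)
  }
  out <- data.frame(study_id = rep_len(as.character(study_id), n),
                    outcome = rep_len(as.character(outcome), n),
                    hr = hr, ci_low = ci_low, ci_high = ci_high,
                    log_effect = log(hr),
                    se = (log(ci_high) - log(ci_low)) / (2 * .z_level(level)))
  class(out) <- c("study_effects", "data.frame")
  out
}

.check_effects <- function(effects) {
  need <- c("log_effect", "se")
  if (!is.data.frame(effects) || !all(need %in% names(effects))) {
    stop("effects must be a study_effects data frame (see effect_from_ci)",
         call. = FALSE)
  }
  k <- nrow(effects)
  if (k < 1) stop("at least one study is required", call. = FALSE)
  if ("outcome" %in% names(effects)) {
    oc <- unique(effects$outcome[!is.na(effects$outcome)])
    if (length(oc) > 1) {
      stop(sprintf("effects mix outcomes (%s); pool one outcome at a time",
                   paste(oc, collapse = ", ")), call. = FALSE)
    }
  }
  if (k > 1 && any(effects$se <= 0)) {
    stop("all standard errors must be positive when pooling k > 1 studies",
         call. = FALSE)
  }
  effects
}

.pooled <- function(effects, model, tau2, level) {
  k <- nrow(effects)
  y <- effects$log_effect
  se <- effects$se
  if (k == 1 && se[1] <= 0) {
    # degenerate single study with zero-width CI: return it unchanged
    w <- 1
    yb <- y
    se_pool <- 0
    q <- 0
  } else {
    w_fixed <- 1 / se^2
    yb_fixed <- sum(w_fixed * y) / sum(w_fixed)
    q <- sum(w_fixed * (y - yb_fixed)^2)
    w <- 1 / (se^2 + tau2)
    yb <- sum(w * y) / sum(w)
    se_pool <- sqrt(1 / sum(w))
  }
  z <- .z_level(level)
  i2 <- if (q > 0) max(0, (q - (k - 1)) / q) else 0
  het_p <- if (k > 1) stats::pchisq(q, df = k - 1, lower.tail = FALSE) else NA_real_
  ci <- c(exp(yb - z * se_pool), exp(yb + z * se_pool))
  if (k == 1 && all(c("ci_low", "ci_high") %in% names(effects))) {
    # a single study is returned unchanged, keeping its reported
    # (possibly log-asymmetric) interval
    ci <- c(effects$ci_low, effects$ci_high)
  }
  structure(list(model = model, k = k,
                 hr = exp(yb),
                 ci_low = ci[1],
                 ci_high = ci[2],
                 log_effect = yb, se = se_pool,
                 tau2 = tau2, q_stat = q, i2 = i2, het_p = het_p,
                 outcome = if ("outcome" %in% names(effects))
                   effects$outcome[1] else NA_character_),
            class = "pooled_effect")
}

#' Fixed-effects (inverse-variance) pooling
#'
#' @param effects A `study_effects` data frame, all on one outcome.
#' @param level Confidence level for the pooled interval.
#' @return A `pooled_effect` list: pooled `hr`, `ci_low`/`ci_high`,
#'   Cochran's `q_stat`, `i2`, heterogeneity p-value, `tau2 = 0`.
#' @export
pool_fixed <- function(effects, level = 0.95) {
  effects <- .check_effects(effects)
  .pooled(effects, "fixed", tau2 = 0, level = level)
}

#' DerSimonian-Laird random-effects pooling
#'
#' Method-of-moments between-study variance
#' `tau2 = max(0, (Q - (k - 1)) / (sum(w) - sum(w^2)/sum(w)))` with
#' fixed-effects weights `w = 1/se^2`, then inverse-variance pooling with
#' weights `1/(se^2 + tau2)`.
#'
#' @inheritParams pool_fixed
#' @return A `pooled_effect` list (see [pool_fixed()]), with `tau2`
#'   estimated and `model = "random"`.
#' @export
pool_random <- function(effects, level = 0.95) {
  effects <- .check_effects(effects)
  k <- nrow(effects)
  tau2 <- 0
  if (k > 1) {
    w <- 1 / effects$se^2
    yb <- sum(w * effects$log_effect) / sum(w)
    q <- sum(w * (effects$log_effect - yb)^2)
    denom <- sum(w) - sum(w^2) / sum(w)
    if (denom > 0) tau2 <- max(0, (q - (k - 1)) / denom)
  }
  .pooled(effects, "random", tau2 = tau2, level = level)
}

#' @export
print.pooled_effect <- function(x, ...) {
  cat(sprintf("%s-effects pooled HR%s (k = %d): %.3f (95%% CI %.3f-%.3f)\n",
              if (x$model == "random") "Random" else "Fixed",
              if (!is.na(x$outcome)) paste0(" [", x$outcome, "]") else "",
              x$k, x$hr, x$ci_low, x$ci_high))
  cat(sprintf("  tau2 = %.4f, Q = %.2f, I2 = %.1f %%, het. p = %s\n",
              x$tau2, x$q_stat, 100 * x$i2,
              if (is.na(x$het_p)) "NA" else format.pval(x$het_p, digits = 3)))
  invisible(x)
}

#' Forest table of per-study and pooled effects
#'
#' @param effects A `study_effects` data frame (one outcome).
#' @param pooled Optional `pooled_effect` to append; defaults to
#'   [pool_random()] of `effects`.
#' @return Data frame with one row per study plus a pooled row.
#' @export
forest_table <- function(effects, pooled = pool_random(effects)) {
  effects <- .check_effects(effects)
  rbind(data.frame(study_id = effects$study_id, outcome = effects$outcome,
                   hr = effects$hr, ci_low = effects$ci_low,
                   ci_high = effects$ci_high,
                   weight = (1 / (effects$se^2 + pooled$tau2)) /
                     sum(1 / (effects$se^2 + pooled$tau2))),
        data.frame(study_id = sprintf("pooled (%s)", pooled$model),
                   outcome = pooled$outcome, hr = pooled$hr,
                   ci_low = pooled$ci_low, ci_high = pooled$ci_high,
                   weight = 1))
}
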