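# Synthetic screening cohorts, synthetic meta-analysis study sets, and
# a patient-level micro-simulator of the screening Markov model. All
# generators are pure functions of (parameters, seed): the global RNG
# state is saved and restored around each call.

.with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# default semi-quantitative confusion matrix: row-normalized
# development-subgroup concordance counts
.default_confusion <- function() {
  cnt <- development_subgroup_table()$counts
  sweep(cnt, 1, rowSums(cnt), "/")
}

#' Generate a synthetic screening cohort
#'
#' Draws each patient's true albuminuria category from `category_prior`,
#' the observed semi-quantitative category from the matching row of the
#' `confusion` matrix, and a cosmetic quantitative uACR value
#' log-uniformly within the true category's bin (upper bin capped at
#' 3000 mg/g). eGFR and dipstick flags are independent Bernoulli draws
#' carried for realism only.
#'
#' Default prior `(0.826, 0.168, 0.006)` mirrors the development
#' subgroup's category distribution; the default confusion matrix is the
#' row-normalized development-subgroup concordance table.
#'
#' @param n Number of patients, `>= 1`.
#' @param category_prior Length-3 probability vector over
#'   [uacr_categories()].
#' @param confusion 3x3 row-stochastic matrix: `confusion[i, j]` is the
#'   probability the semi-quantitative test reports category `j` when
#'   the true category is `i`.
#' @param seed Integer seed; identical inputs reproduce the cohort
#'   bit-for-bit.
#' @param p_egfr_ge60,p_dipstick_negative Marginal probabilities of the
#'   cosmetic subgroup flags.
#' @return Data frame (one row per patient) with columns `id`,
#'   `true_category`, `quantitative_uacr_mg_g`, `semiquant_category`,
#'   `egfr_ge60`, `dipstick_negative`; generator parameters are attached
#'   as attributes.
#' @export
generate_cohort <- function(n, category_prior = c(0.826, 0.168, 0.006),
                            confusion = .default_confusion(), seed = 1L,
                            p_egfr_ge60 = 0.73, p_dipstick_negative = 0.81) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    stop("n must be an integer >= 1", call. = FALSE)
  }
  if (length(category_prior) != 3 || any(category_prior < 0) ||
      abs(sum(category_prior) - 1) > 1e-8) {
    stop("category_prior must be 3 non-negative proportions summing to 1",
         call. = FALSE)
  }
  confusion <- as.matrix(confusion)
  if (!all(dim(confusion) == c(3L, 3L)) || any(confusion < 0) ||
      any(abs(rowSums(confusion) - 1) > 1e-8)) {
    stop("confusion must be a 3x3 row-stochastic matrix", call. = FALSE)
  }
  .with_seed(seed, {
    true_cat <- sample.int(3L, n, replace = TRUE, prob = category_prior)
    semiq <- integer(n)
    for (i in 1:3) {
      idx <- which(true_cat == i)
      if (length(idx)) {
        semiq[idx] <- sample.int(3L, length(idx), replace = TRUE,
                                 prob = confusion[i, ])
      }
    }
    # log-uniform within-bin values; bins [1,30), [30,300), [300,3000]
    lo <- c(1, 30, 300)[true_cat]
    hi <- c(30, 300, 3000)[true_cat]
    uacr <- exp(stats::runif(n, log(lo), log(hi)))
    out <- data.frame(id = seq_len(n),
                      true_category = uacr_categories()[true_cat],
                      quantitative_uacr_mg_g = uacr,
                      semiquant_category = uacr_categories()[semiq],
                      egfr_ge60 = stats::runif(n) < p_egfr_ge60,
                      dipstick_negative = stats::runif(n) < p_dipstick_negative)
    attr(out, "seed") <- as.integer(seed)
    attr(out, "category_prior") <- category_prior
    attr(out, "confusion") <- confusion
    out
  })
}

#' Generate a synthetic meta-analysis study set
#'
#' Study log hazard ratios are drawn as
#' `y_i ~ Normal(true_log_hr, tau^2 + se_i^2)` with within-study
#' standard errors `se_i` uniform over `se_range`; 95% confidence
#' intervals are back-computed from `se_i`.
#'
#' @param k Number of studies, `>= 1`.
#' @param true_log_hr True pooled effect on the log-HR scale.
#' @param tau Between-study standard deviation (log scale), `>= 0`.
#' @param se_range Length-2 positive interval for within-study SEs.
#' @param seed Integer seed.
#' @param outcome Outcome label attached to every study.
#' @return A `study_effects` data frame (see [effect_from_ci()]).
#' @export
generate_meta_studies <- function(k, true_log_hr, tau = 0,
                                  se_range = c(0.05, 0.3), seed = 1L,
                                  outcome = "death") {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k)) {
    stop("k must be an integer >= 1", call. = FALSE)
  }
  if (tau < 0) stop("tau must be >= 0", call. = FALSE)
  if (length(se_range) != 2 || any(se_range <= 0) || se_range[1] > se_range[2]) {
    stop("se_range must be a positive interval c(low, high)", call. = FALSE)
  }
  .with_seed(seed, {
    se <- stats::runif(k, se_range[1], se_range[2])
    y <- stats::rnorm(k, true_log_hr, sqrt(tau^2 + se^2))
    z <- .z_level(0.95)
    effect_from_ci(hr = exp(y), ci_low = exp(y - z * se),
                   ci_high = exp(y + z * se),
                   study_id = sprintf("synthetic_%02d", seq_len(k)),
                   outcome = outcome)
  })
}

#' Micro-simulate individual patients through the screening model
#'
#' Individual-level stochastic realization of the same decision tree as
#' [run_strategy()]: each patient walks the annual cycle with Bernoulli
#' draws at every chance node, using the same screening proportions and
#' event probabilities as the cohort engine, and identical cost
#' accounting (confirmed false positives who experience an event exit
#' but accrue no outcome cost).
#'
#' @param strategy `"quantitative"` or `"semi-quantitative"`.
#' @param config A [model_config()].
#' @param n Number of patients.
#' @param seed Integer seed.
#' @return Data frame with one row per patient: `id`, `exit_cycle` (`NA`
#'   if still screening at the horizon), `exit_reason` (`screen_positive`,
#'   `confirmed_positive`, `ESRD`, `CVD`, `death`, or `completed`),
#'   `screens`, `confirmatory`, crude cost components
#'   (`cost_screening_test`, `cost_screening_transport`,
#'   `cost_confirmatory_test`, `cost_confirmatory_transport`,
#'   `cost_outcome`), `total_crude`, `total_discounted`.
#' @export
microsimulate <- function(strategy = c("quantitative", "semi-quantitative"),
                          config = model_config(), n = 1000L, seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(config, "model_config"))
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    stop("n must be an integer >= 1", call. = FALSE)
  }
  p <- .event_probs(config)
  s <- config$screening
  h <- config$horizon
  df <- (1 + config$discount_rate)^(-(seq_len(h) - 1))
  quant <- strategy == "quantitative"
  screen_cost <- if (quant) config$cost_quant_test else config$cost_semiq_test
  screen_transport <- (if (quant) config$transport_trips_quant
                       else config$transport_trips_semiq) * config$cost_transport
  confirm_transport <- config$transport_trips_confirm * config$cost_transport
  unit_cost <- config$outcomes[.outcome_names, "unit_cost"]

  .with_seed(seed, {
    active <- rep(TRUE, n)
    exit_cycle <- rep(NA_integer_, n)
    exit_reason <- rep(NA_character_, n)
    screens <- confirms <- integer(n)
    c_screen_test <- c_screen_tr <- c_conf_test <- c_conf_tr <-
      c_outcome <- disc_total <- numeric(n)

    event_of <- function(u, probs) {
      # u uniform; returns 0 for no event else the outcome index;
      # events are mutually exclusive with probabilities probs
      e <- integer(length(u))
      edges <- cumsum(probs)
      e[u < edges[3]] <- 3L
      e[u < edges[2]] <- 2L
      e[u < edges[1]] <- 1L
      e
    }

    for (t in seq_len(h)) {
      idx <- which(active)
      if (!length(idx)) break
      m <- length(idx)
      screens[idx] <- screens[idx] + 1L
      c_screen_test[idx] <- c_screen_test[idx] + screen_cost
      c_screen_tr[idx] <- c_screen_tr[idx] + screen_transport
      disc_total[idx] <- disc_total[idx] + (screen_cost + screen_transport) * df[t]

      if (quant) {
        pos <- stats::runif(m) >= s$q_negative
        if (any(pos)) {
          pid <- idx[pos]
          active[pid] <- FALSE
          exit_cycle[pid] <- t
          exit_reason[pid] <- "screen_positive"
        }
        stay <- idx[!pos]
        if (length(stay)) {
          ev <- event_of(stats::runif(length(stay)), p$normo)
          hit <- ev > 0
          if (any(hit)) {
            eid <- stay[hit]
            active[eid] <- FALSE
            exit_cycle[eid] <- t
            exit_reason[eid] <- .outcome_names[ev[hit]]
            c_outcome[eid] <- c_outcome[eid] + unit_cost[ev[hit]]
            disc_total[eid] <- disc_total[eid] + unit_cost[ev[hit]] * df[t]
          }
        }
      } else {
        semiq_pos <- stats::runif(m) >= s$semiq_negative
        pos_id <- idx[semiq_pos]
        neg_id <- idx[!semiq_pos]
        if (length(pos_id)) {
          confirms[pos_id] <- confirms[pos_id] + 1L
          conf_cash <- config$cost_quant_test + confirm_transport
          c_conf_test[pos_id] <- c_conf_test[pos_id] + config$cost_quant_test
          c_conf_tr[pos_id] <- c_conf_tr[pos_id] + confirm_transport
          disc_total[pos_id] <- disc_total[pos_id] + conf_cash * df[t]
          confirmed <- stats::runif(length(pos_id)) < s$tp_given_semiq_positive
          tid <- pos_id[confirmed]
          if (length(tid)) {
            active[tid] <- FALSE
            exit_cycle[tid] <- t
            exit_reason[tid] <- "confirmed_positive"
          }
          # confirmed false positives: normo events, exit, NOT costed
          fid <- pos_id[!confirmed]
          if (length(fid)) {
            ev <- event_of(stats::runif(length(fid)), p$normo)
            hit <- ev > 0
            if (any(hit)) {
              eid <- fid[hit]
              active[eid] <- FALSE
              exit_cycle[eid] <- t
              exit_reason[eid] <- .outcome_names[ev[hit]]
            }
          }
        }
        if (length(neg_id)) {
          fn <- stats::runif(length(neg_id)) < s$fn_given_semiq_negative
          for (grp in list(list(id = neg_id[!fn], probs = p$normo),
                           list(id = neg_id[fn], probs = p$albuminuric))) {
            gid <- grp$id
            if (!length(gid)) next
            ev <- event_of(stats::runif(length(gid)), grp$probs)
            hit <- ev > 0
            if (any(hit)) {
              eid <- gid[hit]
              active[eid] <- FALSE
              exit_cycle[eid] <- t
              exit_reason[eid] <- .outcome_names[ev[hit]]
              c_outcome[eid] <- c_outcome[eid] + unit_cost[ev[hit]]
              disc_total[eid] <- disc_total[eid] + unit_cost[ev[hit]] * df[t]
            }
          }
        }
      }
    }
    exit_reason[is.na(exit_reason)] <- "completed"
    total <- c_screen_test + c_screen_tr + c_conf_test + c_conf_tr + c_outcome
    out <- data.frame(id = seq_len(n), exit_cycle = exit_cycle,
                      exit_reason = exit_reason,
                      screens = screens, confirmatory = confirms,
                      cost_screening_test = c_screen_test,
                      cost_screening_transport = c_screen_tr,
                      cost_confirmatory_test = c_conf_test,
                      cost_confirmatory_transport = c_conf_tr,
                      cost_outcome = c_outcome,
                      total_crude = total,
                      total_discounted = disc_total)
    attr(out, "strategy") <- strategy
    attr(out, "seed") <- as.integer(seed)
    out
  })
}
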