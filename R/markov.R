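# Deterministic annual-cycle Markov cohort model of two albuminuria
# screening strategies in diabetic patients with normal renal function:
#
#   quantitative      — everyone gets the laboratory uACR each year;
#                       positives leave screening for medical care.
#   semi-quantitative — everyone gets the point-of-care strip each year;
#                       strip-positives get a confirmatory quantitative
#                       test, confirmed positives leave, false positives
#                       stay in the pool.
#
# Remaining occupants face annual probabilities of ESRD, CVD and death,
# converted from incidence rates by 1 - exp(-rate * time); the
# false-negative stratum faces albuminuric rates (rate * hazard ratio).
# Screening results are re-drawn each cycle (memoryless re-entry).

.outcome_names <- c("ESRD", "CVD", "death")

#' Per-outcome model inputs
#'
#' Annual incidence among normo-albuminuric diabetic patients, the
#' albuminuria-versus-normo hazard ratio (with its 95% CI bounds, used by
#' the sensitivity analysis), and the unit cost per event.
#'
#' Defaults pair the incidence rates 0.0095 / 0.0154 / 0.0006 per year
#' and unit costs 25,634.48 / 13,149.62 / 6,810.38 USD with death, CVD
#' and ESRD respectively, and the pooled hazard ratios 3.432 (ESRD),
#' 1.315 (CVD) and 1.480 (death).
#'
#' @param esrd,cvd,death Named lists with elements `rate`, `hr`,
#'   `hr_low`, `hr_high`, `unit_cost`.
#' @return Data frame with rows `ESRD`, `CVD`, `death`.
#' @export
outcome_params <- function(
    esrd = list(rate = 0.0006, hr = 3.432, hr_low = 2.757, hr_high = 4.271,
                unit_cost = 6810.38),
    cvd = list(rate = 0.0154, hr = 1.315, hr_low = 1.250, hr_high = 1.384,
               unit_cost = 13149.62),
    death = list(rate = 0.0095, hr = 1.480, hr_low = 1.408, hr_high = 1.556,
                 unit_cost = 25634.48)) {
  rows <- list(ESRD = esrd, CVD = cvd, death = death)
  out <- do.call(rbind, lapply(names(rows), function(nm) {
    r <- rows[[nm]]
    for (f in c("rate", "hr", "unit_cost")) {
      if (is.null(r[[f]]) || !is.numeric(r[[f]]) || is.na(r[[f]])) {
        stop(sprintf("outcome %s: field %s must be a number", nm, f), call. = FALSE)
      }
    }
    if (r$rate < 0) stop(sprintf("outcome %s: rate must be >= 0", nm), call. = FALSE)
    if (r$hr <= 0) stop(sprintf("outcome %s: hazard ratio must be > 0", nm), call. = FALSE)
    if (r$unit_cost < 0) stop(sprintf("outcome %s: unit cost must be >= 0", nm), call. = FALSE)
    data.frame(outcome = nm, rate_normo = r$rate, hr = r$hr,
               hr_low = if (is.null(r$hr_low)) NA_real_ else r$hr_low,
               hr_high = if (is.null(r$hr_high)) NA_real_ else r$hr_high,
               unit_cost = r$unit_cost)
  }))
  rownames(out) <- out$outcome
  out
}

#' Full model configuration
#'
#' Bundles the screening-result proportions, the three outcome parameter
#' rows, unit costs, transport trip multiplicities, the annual discount
#' rate and the time horizon. Defaults reproduce the development-cohort
#' baseline: quantitative test 17.76 USD, semi-quantitative test 0.86
#' USD, transport 9.265 USD per trip (two trips per quantitative screen,
#' one per semi-quantitative screen, one per confirmatory test), 3%/year
#' discounting, ten 1-year cycles.
#'
#' @param screening A [screening_params()] object.
#' @param outcomes An [outcome_params()] data frame.
#' @param cost_quant_test,cost_semiq_test,cost_transport Unit costs (USD).
#' @param transport_trips_quant,transport_trips_semiq,transport_trips_confirm
#'   Trips per quantitative screen / semi-quantitative screen /
#'   confirmatory test.
#' @param discount_rate Annual discount rate (proportion).
#' @param horizon Number of annual cycles.
#' @param cycle_length Cycle length in years.
#' @param currency Currency label carried into reports.
#' @return An object of class `model_config`.
#' @export
model_config <- function(screening = screening_params(),
                         outcomes = outcome_params(),
                         cost_quant_test = 17.76,
                         cost_semiq_test = 0.86,
                         cost_transport = 9.265,
                         transport_trips_quant = 2L,
                         transport_trips_semiq = 1L,
                         transport_trips_confirm = 1L,
                         discount_rate = 0.03,
                         horizon = 10L,
                         cycle_length = 1,
                         currency = "USD, 2016 prices (1 USD = 1,160 KRW)") {
  stopifnot(inherits(screening, "screening_params"))
  if (!identical(rownames(outcomes), .outcome_names)) {
    stop("outcomes must be an outcome_params() data frame with rows ESRD, CVD, death",
         call. = FALSE)
  }
  costs <- c(cost_quant_test = cost_quant_test, cost_semiq_test = cost_semiq_test,
             cost_transport = cost_transport)
  if (any(!is.finite(costs)) || any(costs < 0)) {
    stop("unit costs must be non-negative numbers", call. = FALSE)
  }
  trips <- c(transport_trips_quant, transport_trips_semiq, transport_trips_confirm)
  if (any(trips < 1) || any(trips != round(trips))) {
    stop("transport trip multiplicities must be integers >= 1", call. = FALSE)
  }
  if (!is.finite(discount_rate) || discount_rate < 0) {
    stop("discount_rate must be >= 0", call. = FALSE)
  }
  if (!is.finite(horizon) || horizon < 1 || horizon != round(horizon)) {
    stop("horizon must be an integer >= 1", call. = FALSE)
  }
  if (!is.finite(cycle_length) || cycle_length <= 0) {
    stop("cycle_length must be > 0", call. = FALSE)
  }
  structure(list(screening = screening, outcomes = outcomes,
                 cost_quant_test = cost_quant_test,
                 cost_semiq_test = cost_semiq_test,
                 cost_transport = cost_transport,
                 transport_trips_quant = as.integer(transport_trips_quant),
                 transport_trips_semiq = as.integer(transport_trips_semiq),
                 transport_trips_confirm = as.integer(transport_trips_confirm),
                 discount_rate = discount_rate,
                 horizon = as.integer(horizon),
                 cycle_length = cycle_length,
                 currency = currency),
            class = "model_config")
}

#' Development-cohort baseline configuration
#'
#' Screening proportions from the development subgroup (diabetics with
#' eGFR >= 60 ml/min/1.73m2 and negative dipstick, n = 1110): beta
#' counts (917, 193), (615, 495), (36, 579), (157, 338).
#'
#' @param ... Overrides passed to [model_config()].
#' @return A `model_config`.
#' @export
development_config <- function(...) model_config(...)

#' Validation-cohort configuration
#'
#' Screening proportions rebuilt from the external validation subgroup
#' (n = 301: TP 38, FN 8, FP 68, TN 187); all other inputs at baseline.
#'
#' @param ... Overrides passed to [model_config()].
#' @return A `model_config`.
#' @export
validation_config <- function(...) {
  model_config(screening = strategy_probabilities(validation_subgroup_table()), ...)
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("Screening cost model: horizon %d x %g y, discount %.1f %%/y\n",
              x$horizon, x$cycle_length, 100 * x$discount_rate))
  cat(sprintf("  tests: quantitative %.2f, semi-quantitative %.2f, transport %.3f x (%d/%d/%d trips)\n",
              x$cost_quant_test, x$cost_semiq_test, x$cost_transport,
              x$transport_trips_quant, x$transport_trips_semiq,
              x$transport_trips_confirm))
  print(x$screening)
  print(x$outcomes, row.names = FALSE)
  invisible(x)
}

#' Convert an incidence rate to a per-period probability
#'
#' `probability = 1 - exp(-rate * time)`, the standard constant-hazard
#' conversion used for decision-model cycles.
#'
#' @param rate Events per person-year, `>= 0`.
#' @param time Period length in years, `>= 0`.
#' @return Probability in `[0, 1)`.
#' @export
rate_to_probability <- function(rate, time = 1) {
  if (!is.numeric(rate) || !is.numeric(time) || anyNA(rate) || anyNA(time) ||
      any(rate < 0) || any(time < 0)) {
    stop("rate and time must be non-negative", call. = FALSE)
  }
  1 - exp(-rate * time)
}

#' Annual event probability under albuminuria
#'
#' Scales the normo-albuminuric incidence rate by the hazard ratio before
#' the rate-to-probability conversion: `1 - exp(-rate * hr * time)`.
#'
#' @param rate_normo Annual incidence among normo-albuminuric patients.
#' @param hr Hazard ratio (albuminuria vs normo), `> 0`.
#' @param time Period length in years.
#' @return Probability in `[0, 1)`.
#' @export
albuminuric_probability <- function(rate_normo, hr, time = 1) {
  if (!is.numeric(hr) || anyNA(hr) || any(hr <= 0)) {
    stop("hazard ratio must be positive", call. = FALSE)
  }
  rate_to_probability(rate_normo * hr, time)
}

# per-cycle event probabilities by stratum; events are mutually
# exclusive within a cycle (independent conversion, summed removal)
.event_probs <- function(config) {
  p_normo <- rate_to_probability(config$outcomes$rate_normo, config$cycle_length)
  p_albu <- albuminuric_probability(config$outcomes$rate_normo,
                                    config$outcomes$hr, config$cycle_length)
  names(p_normo) <- names(p_albu) <- .outcome_names
  if (sum(p_normo) > 1 || sum(p_albu) > 1) {
    stop("combined annual event probabilities exceed 1; rates/HRs too large for a 1-cycle step",
         call. = FALSE)
  }
  list(normo = p_normo, albuminuric = p_albu)
}

.strata_for <- function(strategy) {
  switch(strategy,
         quantitative = "q_negative",
         `semi-quantitative` = c("true_negative", "false_negative", "false_positive"))
}

#' Run one screening strategy through the cohort model
#'
#' Tracks the expected fraction of an initial cohort of size 1 through
#' `horizon` annual cycles. Each cycle, in order: everyone occupying the
#' screening state is screened; screen-positives exit to medical care
#' (in the semi-quantitative arm via a confirmatory quantitative test,
#' with false positives remaining in the pool); the remaining strata
#' experience mutually exclusive ESRD/CVD/death events at
#' normo-albuminuric probabilities (albuminuric probabilities for the
#' semi-quantitative false-negative stratum) and event-takers leave;
#' survivors re-enter the screening state memorylessly.
#'
#' @param strategy `"quantitative"` or `"semi-quantitative"`.
#' @param config A [model_config()].
#' @return An object of class `cycle_trace`: a list with `strategy`,
#'   `cycles` (data frame: cycle, occupancy, screens, confirmatory,
#'   exits, events, survivors), `events` (cycles x outcome x stratum
#'   array) and the `config`.
#' @export
run_strategy <- function(strategy = c("quantitative", "semi-quantitative"),
                         config = model_config()) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(config, "model_config"))
  p <- .event_probs(config)
  s <- config$screening
  h <- config$horizon
  strata <- .strata_for(strategy)

  events <- array(0, dim = c(h, 3L, length(strata)),
                  dimnames = list(cycle = NULL, outcome = .outcome_names,
                                  stratum = strata))
  occupancy <- screens <- confirms <- exits <- survivors <- numeric(h)

  occ <- 1
  for (t in seq_len(h)) {
    occupancy[t] <- occ
    screens[t] <- occ
    if (strategy == "quantitative") {
      exits[t] <- occ * (1 - s$q_negative)
      staying <- c(q_negative = occ * s$q_negative)
      probs <- list(q_negative = p$normo)
    } else {
      pos <- occ * (1 - s$semiq_negative)
      confirms[t] <- pos
      exits[t] <- pos * s$tp_given_semiq_positive
      neg <- occ * s$semiq_negative
      staying <- c(true_negative = neg * (1 - s$fn_given_semiq_negative),
                   false_negative = neg * s$fn_given_semiq_negative,
                   false_positive = pos * (1 - s$tp_given_semiq_positive))
      probs <- list(true_negative = p$normo,
                    false_negative = p$albuminuric,
                    false_positive = p$normo)
    }
    for (st in strata) {
      events[t, , st] <- staying[[st]] * probs[[st]]
    }
    survivors[t] <- sum(staying) - sum(events[t, , ])
    occ <- survivors[t]
  }

  structure(list(strategy = strategy,
                 cycles = data.frame(cycle = seq_len(h),
                                     occupancy = occupancy,
                                     screens = screens,
                                     confirmatory = confirms,
                                     exits = exits,
                                     events = apply(events, 1, sum),
                                     survivors = survivors),
                 events = events,
                 config = config),
            class = "cycle_trace")
}

#' @export
print.cycle_trace <- function(x, digits = 4, ...) {
  cat(sprintf("Cycle trace: %s strategy, %d cycles\n", x$strategy,
              nrow(x$cycles)))
  print(round(x$cycles, digits), row.names = FALSE)
  cat(sprintf("totals: screens %.4f, confirmatory %.4f, exits %.4f, events %.4f\n",
              sum(x$cycles$screens), sum(x$cycles$confirmatory),
              sum(x$cycles$exits), sum(x$cycles$events)))
  invisible(x)
}

#' Modify one scalar model parameter
#'
#' Recognized names: `cost_quant_test`, `cost_semiq_test`,
#' `cost_transport`, `cost_esrd`, `cost_cvd`, `cost_death`, `rate_esrd`,
#' `rate_cvd`, `rate_death`, `hr_esrd`, `hr_cvd`, `hr_death`.
#'
#' @param config A [model_config()].
#' @param parameter Parameter name (see above).
#' @param value New value.
#' @return The modified `model_config`.
#' @export
set_parameter <- function(config, parameter, value) {
  stopifnot(inherits(config, "model_config"))
  valid <- c("cost_quant_test", "cost_semiq_test", "cost_transport",
             paste0("cost_", tolower(.outcome_names)),
             paste0("rate_", tolower(.outcome_names)),
             paste0("hr_", tolower(.outcome_names)))
  if (!is.character(parameter) || length(parameter) != 1 ||
      !parameter %in% valid) {
    stop(sprintf("unknown parameter %s; valid names: %s",
                 dQuote(as.character(parameter)[1]),
                 paste(valid, collapse = ", ")), call. = FALSE)
  }
  if (!is.numeric(value) || length(value) != 1 || !is.finite(value)) {
    stop("value must be a single finite number", call. = FALSE)
  }
  if (parameter %in% c("cost_quant_test", "cost_semiq_test", "cost_transport")) {
    config[[parameter]] <- value
    return(model_config(screening = config$screening, outcomes = config$outcomes,
                        cost_quant_test = config$cost_quant_test,
                        cost_semiq_test = config$cost_semiq_test,
                        cost_transport = config$cost_transport,
                        transport_trips_quant = config$transport_trips_quant,
                        transport_trips_semiq = config$transport_trips_semiq,
                        transport_trips_confirm = config$transport_trips_confirm,
                        discount_rate = config$discount_rate,
                        horizon = config$horizon,
                        cycle_length = config$cycle_length,
                        currency = config$currency))
  }
  parts <- strsplit(parameter, "_", fixed = TRUE)[[1]]
  field <- switch(parts[1], cost = "unit_cost", rate = "rate_normo", hr = "hr")
  row <- .outcome_names[tolower(.outcome_names) == parts[2]]
  config$outcomes[row, field] <- value
  model_config(screening = config$screening, outcomes = config$outcomes,
               cost_quant_test = config$cost_quant_test,
               cost_semiq_test = config$cost_semiq_test,
               cost_transport = config$cost_transport,
               transport_trips_quant = config$transport_trips_quant,
               transport_trips_semiq = config$transport_trips_semiq,
               transport_trips_confirm = config$transport_trips_confirm,
               discount_rate = config$discount_rate,
               horizon = config$horizon,
               cycle_length = config$cycle_length,
               currency = config$currency)
}
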