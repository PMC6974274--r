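# Cost accounting over a cycle trace: per-component crude and
# discounted totals, strategy comparison, and one-way (tornado)
# sensitivity analysis.
#
# Conventions: screening and confirmatory testing costs accrue at cycle
# start; event costs are one-off at the annual unit cost; cycle 1 is
# undiscounted and cycle t is discounted by (1 + d)^-(t - 1). Only
# screen-negative strata contribute outcome ("under-detected") costs:
# confirmed false positives in the semi-quantitative arm experience
# events, which the engine records, but their costs are not tallied
# unless cost_false_positive_events = TRUE.

.component_names <- c("screening_test", "screening_transport",
                      "confirmatory_test", "confirmatory_transport",
                      "outcome_ESRD", "outcome_CVD", "outcome_death")

#' Cost breakdown of a strategy run
#'
#' Turns a [run_strategy()] trace into per-component crude and
#' discounted per-person costs over the horizon.
#'
#' @param trace A `cycle_trace`.
#' @param config The [model_config()] the trace was produced under;
#'   defaults to the one stored in the trace.
#' @param cost_false_positive_events If `TRUE`, events in the
#'   confirmed-false-positive stratum also accrue outcome costs
#'   (default `FALSE`: only screen-negative strata are costed).
#' @return An object of class `cost_breakdown`: `components` (data frame
#'   with `crude` and `discounted` columns), `total_crude`,
#'   `total_discounted`, plus the strategy label.
#' @export
cost_breakdown <- function(trace, config = trace$config,
                           cost_false_positive_events = FALSE) {
  stopifnot(inherits(trace, "cycle_trace"), inherits(config, "model_config"))
  if (!identical(trace$strategy, .trace_strategy_check(trace, config))) {
    stop("trace and config disagree on the strategy structure", call. = FALSE)
  }
  h <- config$horizon
  df <- (1 + config$discount_rate)^(-(seq_len(h) - 1))
  quant <- trace$strategy == "quantitative"

  screen_cost <- if (quant) config$cost_quant_test else config$cost_semiq_test
  screen_trips <- if (quant) config$transport_trips_quant else config$transport_trips_semiq

  # per-cycle cash flows, one column per component
  flows <- matrix(0, nrow = h, ncol = length(.component_names),
                  dimnames = list(NULL, .component_names))
  flows[, "screening_test"] <- trace$cycles$screens * screen_cost
  flows[, "screening_transport"] <- trace$cycles$screens * screen_trips *
    config$cost_transport
  flows[, "confirmatory_test"] <- trace$cycles$confirmatory * config$cost_quant_test
  flows[, "confirmatory_transport"] <- trace$cycles$confirmatory *
    config$transport_trips_confirm * config$cost_transport

  costed <- .strata_for(trace$strategy)
  if (!cost_false_positive_events) costed <- setdiff(costed, "false_positive")
  for (k in .outcome_names) {
    ev <- trace$events[, k, costed, drop = FALSE]
    flows[, paste0("outcome_", k)] <- apply(ev, 1, sum) *
      config$outcomes[k, "unit_cost"]
  }

  components <- data.frame(component = .component_names,
                           crude = colSums(flows),
                           discounted = colSums(flows * df))
  rownames(components) <- .component_names
  structure(list(strategy = trace$strategy,
                 components = components,
                 total_crude = sum(components$crude),
                 total_discounted = sum(components$discounted),
                 currency = config$currency),
            class = "cost_breakdown")
}

# a semi-quantitative trace has the 3-stratum event array
.trace_strategy_check <- function(trace, config) {
  st <- dimnames(trace$events)$stratum
  if (identical(st, "q_negative")) "quantitative" else "semi-quantitative"
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat(sprintf("Per-person 10-year costs, %s strategy (%s)\n", x$strategy,
              x$currency))
  print(round(x$components[, c("crude", "discounted")], 2))
  cat(sprintf("totals: crude %.2f, discounted %.2f\n",
              x$total_crude, x$total_discounted))
  invisible(x)
}

#' Cost saving of the semi-quantitative versus the quantitative strategy
#'
#' @param q,semiq `cost_breakdown` objects for the quantitative and
#'   semi-quantitative strategies under the same configuration.
#' @return List with `crude_saving`, `crude_fraction` (of the
#'   quantitative total), and the discounted analogues.
#' @export
saved_cost <- function(q, semiq) {
  stopifnot(inherits(q, "cost_breakdown"), inherits(semiq, "cost_breakdown"))
  if (q$strategy != "quantitative" || semiq$strategy != "semi-quantitative") {
    stop("saved_cost expects (quantitative, semi-quantitative) breakdowns in that order",
         call. = FALSE)
  }
  crude <- q$total_crude - semiq$total_crude
  disc <- q$total_discounted - semiq$total_discounted
  list(crude_saving = crude,
       crude_fraction = crude / q$total_crude,
       discounted_saving = disc,
       discounted_fraction = disc / q$total_discounted)
}

#' Run both strategies and compare costs
#'
#' @param config A [model_config()].
#' @return List with the two `cost_breakdown`s (`quantitative`,
#'   `semi_quantitative`) and the [saved_cost()] summary (`saving`).
#' @export
compare_strategies <- function(config = model_config()) {
  q <- cost_breakdown(run_strategy("quantitative", config))
  s <- cost_breakdown(run_strategy("semi-quantitative", config))
  list(quantitative = q, semi_quantitative = s, saving = saved_cost(q, s))
}

#' One-way sensitivity analysis of the cost saving
#'
#' Re-runs both strategies with one parameter set to its low and high
#' bound, all else at baseline, and records the saving at each bound.
#'
#' @param config Baseline [model_config()].
#' @param parameter Scalar parameter name (see [set_parameter()]).
#' @param low,high Bounds for the parameter.
#' @param basis `"discounted"` (default) or `"crude"` saving.
#' @return One-row data frame: parameter, bounds, saving at each bound,
#'   and the absolute span.
#' @export
one_way_sensitivity <- function(config, parameter, low, high,
                                basis = c("discounted", "crude")) {
  basis <- match.arg(basis)
  pick <- function(sv) if (basis == "discounted") sv$discounted_saving else sv$crude_saving
  at <- function(v) pick(compare_strategies(set_parameter(config, parameter, v))$saving)
  s_lo <- at(low)
  s_hi <- at(high)
  data.frame(parameter = parameter, low_input = low, high_input = high,
             saving_at_low = s_lo, saving_at_high = s_hi,
             span = abs(s_hi - s_lo), basis = basis)
}

#' Default one-way sensitivity ranges
#'
#' Unit costs (both tests, transport, three outcome costs) and the three
#' incidence rates are varied by +/- 20% around baseline; hazard ratios
#' are varied over their 95% confidence intervals.
#'
#' @param config A [model_config()].
#' @param rel Relative variation for costs and rates (default 0.2).
#' @return Data frame with columns `parameter`, `low`, `high`.
#' @export
default_sensitivity_ranges <- function(config = model_config(), rel = 0.2) {
  base <- c(cost_quant_test = config$cost_quant_test,
            cost_semiq_test = config$cost_semiq_test,
            cost_transport = config$cost_transport,
            cost_esrd = config$outcomes["ESRD", "unit_cost"],
            cost_cvd = config$outcomes["CVD", "unit_cost"],
            cost_death = config$outcomes["death", "unit_cost"],
            rate_esrd = config$outcomes["ESRD", "rate_normo"],
            rate_cvd = config$outcomes["CVD", "rate_normo"],
            rate_death = config$outcomes["death", "rate_normo"])
  rel_df <- data.frame(parameter = names(base),
                       low = unname(base) * (1 - rel),
                       high = unname(base) * (1 + rel))
  hr_df <- data.frame(parameter = paste0("hr_", tolower(.outcome_names)),
                      low = config$outcomes[.outcome_names, "hr_low"],
                      high = config$outcomes[.outcome_names, "hr_high"])
  out <- rbind(rel_df, hr_df)
  rownames(out) <- NULL
  out
}

#' Tornado analysis
#'
#' Runs [one_way_sensitivity()] for every row of `ranges` and returns
#' the entries sorted by span, widest first, with the baseline saving
#' attached as an attribute.
#'
#' @param config Baseline [model_config()].
#' @param ranges Data frame with columns `parameter`, `low`, `high`;
#'   defaults to [default_sensitivity_ranges()].
#' @param basis `"discounted"` (default) or `"crude"`.
#' @return Data frame of class `tornado` ordered by decreasing span,
#'   with attribute `baseline_saving`.
#' @export
tornado <- function(config = model_config(),
                    ranges = default_sensitivity_ranges(config),
                    basis = c("discounted", "crude")) {
  basis <- match.arg(basis)
  if (!is.data.frame(ranges) || nrow(ranges) == 0 ||
      !all(c("parameter", "low", "high") %in% names(ranges))) {
    stop("ranges must be a non-empty data frame with columns parameter, low, high",
         call. = FALSE)
  }
  entries <- do.call(rbind, lapply(seq_len(nrow(ranges)), function(i) {
    one_way_sensitivity(config, ranges$parameter[i], ranges$low[i],
                        ranges$high[i], basis = basis)
  }))
  entries <- entries[order(-entries$span), ]
  rownames(entries) <- NULL
  sv <- compare_strategies(config)$saving
  attr(entries, "baseline_saving") <-
    if (basis == "discounted") sv$discounted_saving else sv$crude_saving
  class(entries) <- c("tornado", "data.frame")
  entries
}

#' @export
print.tornado <- function(x, digits = 1, ...) {
  cat(sprintf("One-way sensitivity of the %s saving (baseline %.1f)\n",
              x$basis[1], attr(x, "baseline_saving")))
  print(within(as.data.frame(x), {
    saving_at_low <- round(saving_at_low, digits)
    saving_at_high <- round(saving_at_high, digits)
    span <- round(span, digits)
  }), row.names = FALSE)
  invisible(x)
}
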