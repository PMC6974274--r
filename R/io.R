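# Delimited-text readers and writers, YAML model configuration, and a
# small run manifest. All machine-readable output is tab-separated at
# full precision; display rounding (two decimals for currency, one for
# percentages) happens only in the formatted report columns.

#' Read a pre-tabulated 3x3 concordance table
#'
#' Expects tab-separated text: a header naming the three
#' semi-quantitative categories, then three rows (quantitative category
#' label followed by three counts).
#'
#' @param path File path.
#' @param label Cohort label; defaults to the file name.
#' @return A [concordance_table()].
#' @export
read_concordance <- function(path, label = basename(path)) {
  raw <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  if (!all(dim(raw) == c(3L, 3L))) {
    stop(sprintf("%s: expected a 3x3 count table, got %dx%d",
                 path, nrow(raw), ncol(raw)), call. = FALSE)
  }
  concordance_table(as.matrix(raw), label = label)
}

#' Write a concordance table as tab-separated text
#'
#' @param table A [concordance_table()].
#' @param path File path.
#' @export
write_concordance <- function(table, path) {
  stopifnot(inherits(table, "concordance_table"))
  df <- as.data.frame(table$counts)
  utils::write.table(cbind(quantitative = rownames(df), df), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-patient uACR records
#'
#' Tab- or comma-separated text with columns `id`,
#' `quantitative_uacr_mg_g`, `semiquant_category`.
#'
#' @param path File path.
#' @param sep Field separator (default tab).
#' @return Data frame of records ready for [build_concordance()].
#' @export
read_uacr_records <- function(path, sep = "\t") {
  rec <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("id", "quantitative_uacr_mg_g", "semiquant_category")
  miss <- setdiff(need, names(rec))
  if (length(miss)) {
    stop(sprintf("%s: missing column(s) %s", path, paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  rec
}

#' Read a study table for meta-analysis
#'
#' Tab-separated columns `study_id`, `outcome`, `hr`, `ci_low`,
#' `ci_high`; log effects and SEs are derived via [effect_from_ci()].
#'
#' @param path File path.
#' @param level Confidence level of the reported intervals.
#' @return A `study_effects` data frame.
#' @export
read_study_table <- function(path, level = 0.95) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("study_id", "outcome", "hr", "ci_low", "ci_high")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop(sprintf("%s: missing column(s) %s", path, paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  effect_from_ci(tab$hr, tab$ci_low, tab$ci_high, level = level,
                 study_id = tab$study_id, outcome = tab$outcome)
}

#' Accuracy report in the published-table layout
#'
#' One row per cohort: n, sensitivity, specificity, over-/under-detected
#' fractions (all %, one decimal) and NNS, plus full-precision columns.
#'
#' @param metrics_list List of [accuracy_metrics()] results.
#' @param path Optional file to write (tab-separated).
#' @return The report data frame, invisibly if written.
#' @export
accuracy_report <- function(metrics_list, path = NULL) {
  if (inherits(metrics_list, "accuracy_metrics")) metrics_list <- list(metrics_list)
  rep <- do.call(rbind, lapply(metrics_list, function(m) {
    data.frame(cohort = m$label, n = m$n,
               sensitivity_pct = round(100 * m$sensitivity, 1),
               specificity_pct = round(100 * m$specificity, 1),
               over_detected_pct = round(100 * m$over_detected, 1),
               under_detected_pct = round(100 * m$under_detected, 1),
               nns = round(m$nns, 1),
               sensitivity = m$sensitivity, specificity = m$specificity,
               over_detected = m$over_detected,
               under_detected = m$under_detected)
  }))
  if (!is.null(path)) {
    utils::write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(rep))
  }
  rep
}

#' Cost report in the published-table layout
#'
#' Two strategy columns, component rows, crude and discounted totals,
#' and the saved-cost lines.
#'
#' @param comparison Result of [compare_strategies()].
#' @param path Optional file to write (tab-separated).
#' @return The report data frame, invisibly if written.
#' @export
cost_report <- function(comparison, path = NULL) {
  q <- comparison$quantitative$components
  s <- comparison$semi_quantitative$components
  sv <- comparison$saving
  rows <- c("screening_test", "screening_transport", "confirmatory_test",
            "confirmatory_transport", "outcome_ESRD", "outcome_CVD",
            "outcome_death")
  rep <- data.frame(component = c(rows, "summed_crude", "summed_discounted",
                                  "saved_crude", "saved_crude_pct",
                                  "saved_discounted"),
                    quantitative = c(q[rows, "crude"],
                                     comparison$quantitative$total_crude,
                                     comparison$quantitative$total_discounted,
                                     NA, NA, NA),
                    semi_quantitative = c(s[rows, "crude"],
                                          comparison$semi_quantitative$total_crude,
                                          comparison$semi_quantitative$total_discounted,
                                          sv$crude_saving,
                                          100 * sv$crude_fraction,
                                          sv$discounted_saving))
  if (!is.null(path)) {
    utils::write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(rep))
  }
  rep
}

#' Export a cycle trace as delimited text
#'
#' One row per cycle x quantity: the per-cycle occupancy, screens,
#' confirmatory tests, exits and survivors, followed by the
#' outcome-by-stratum event fractions.
#'
#' @param trace A `cycle_trace`.
#' @param path File path.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "cycle_trace"))
  core <- utils::stack(trace$cycles[-1])
  core <- data.frame(cycle = trace$cycles$cycle, quantity = core$ind,
                     value = core$values)
  ev <- as.data.frame.table(trace$events, responseName = "value")
  ev$cycle <- as.integer(ev$cycle)
  ev$quantity <- paste("events", ev$outcome, ev$stratum, sep = "_")
  out <- rbind(core, ev[, c("cycle", "quantity", "value")])
  out <- out[order(out$cycle), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a tornado table
#'
#' @param entries A [tornado()] result.
#' @param path File path.
#' @export
write_tornado <- function(entries, path) {
  out <- as.data.frame(entries)
  out$baseline_saving <- attr(entries, "baseline_saving")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- YAML model configuration -------------------------------------------

#' Load a model configuration from YAML
#'
#' Flat keys mirror the [model_config()] arguments; the `screening`
#' block carries beta-count pairs and the `outcomes` block one map per
#' outcome (`rate`, `hr`, `hr_low`, `hr_high`, `unit_cost`). Missing
#' keys fall back to the development-cohort baseline defaults.
#'
#' @param path YAML file path; `NULL` returns the full default
#'   configuration.
#' @return A [model_config()].
#' @export
read_model_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (!is.list(raw)) stop(sprintf("%s: not a YAML mapping", path), call. = FALSE)
  known <- c("screening", "outcomes", "cost_quant_test", "cost_semiq_test",
             "cost_transport", "transport_trips_quant", "transport_trips_semiq",
             "transport_trips_confirm", "discount_rate", "horizon",
             "cycle_length", "currency")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  args <- raw[setdiff(names(raw), c("screening", "outcomes"))]
  if (!is.null(raw$screening)) {
    sp <- formals(screening_params)
    keys <- intersect(names(raw$screening), names(sp))
    bad <- setdiff(names(raw$screening), names(sp))
    if (length(bad)) {
      stop(sprintf("screening: unknown key(s) %s", paste(bad, collapse = ", ")),
           call. = FALSE)
    }
    args$screening <- do.call(screening_params,
                              lapply(raw$screening[keys], unlist))
  }
  if (!is.null(raw$outcomes)) {
    oc <- raw$outcomes
    bad <- setdiff(names(oc), c("ESRD", "CVD", "death"))
    if (length(bad)) {
      stop(sprintf("outcomes: unknown outcome(s) %s", paste(bad, collapse = ", ")),
           call. = FALSE)
    }
    defaults <- outcome_params()
    merged <- lapply(c(ESRD = "ESRD", CVD = "CVD", death = "death"), function(nm) {
      d <- as.list(defaults[nm, c("rate_normo", "hr", "hr_low", "hr_high", "unit_cost")])
      names(d)[1] <- "rate"
      for (f in names(oc[[nm]])) {
        if (!f %in% names(d)) {
          stop(sprintf("outcomes.%s: unknown field %s", nm, f), call. = FALSE)
        }
        d[[f]] <- oc[[nm]][[f]]
      }
      d
    })
    args$outcomes <- outcome_params(esrd = merged$ESRD, cvd = merged$CVD,
                                    death = merged$death)
  }
  do.call(model_config, args)
}

#' Write a model configuration to YAML
#'
#' @param config A [model_config()].
#' @param path File path.
#' @export
write_model_config <- function(config, path) {
  stopifnot(inherits(config, "model_config"))
  oc <- config$outcomes
  out <- list(
    screening = lapply(config$screening$beta, as.numeric),
    outcomes = stats::setNames(lapply(rownames(oc), function(nm) {
      list(rate = oc[nm, "rate_normo"], hr = oc[nm, "hr"],
           hr_low = oc[nm, "hr_low"], hr_high = oc[nm, "hr_high"],
           unit_cost = oc[nm, "unit_cost"])
    }), rownames(oc)),
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
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records what produced a set of outputs: a free-text command label,
#' the seed(s), the package version, an MD5 digest of the configuration,
#' a timestamp and the output file list, as JSON.
#'
#' @param path Manifest file path (JSON).
#' @param command Free-text label of the run.
#' @param seed Seed(s) used, if any.
#' @param config Optional [model_config()] to digest.
#' @param outputs Character vector of output files.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, command, seed = NULL, config = NULL,
                           outputs = character()) {
  digest <- NA_character_
  if (!is.null(config)) {
    tmp <- tempfile(fileext = ".yaml")
    on.exit(unlink(tmp))
    write_model_config(config, tmp)
    digest <- unname(tools::md5sum(tmp))
  }
  manifest <- list(command = command,
                   seed = seed,
                   package = "uacrscreen",
                   version = as.character(utils::packageVersion("uacrscreen")),
                   config_md5 = digest,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   outputs = outputs)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
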