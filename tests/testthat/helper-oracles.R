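# Independent oracles used against the package implementation.
#
# The cycle model has no memory across cycles (screening results are
# re-drawn every year and every stratum's survival leads back to the
# same screening state), so every per-cycle expectation is proportional
# to the occupancy and all horizon totals are geometric series. The
# oracle below evaluates those closed forms directly and never touches
# the package's cycle loop.

oracle_totals <- function(config, strategy) {
  p <- 1 - exp(-config$outcomes$rate_normo * config$cycle_length)
  q <- 1 - exp(-config$outcomes$rate_normo * config$outcomes$hr * config$cycle_length)
  names(p) <- names(q) <- config$outcomes$outcome
  s <- config$screening
  h <- config$horizon
  geom <- function(r, n) if (abs(1 - r) < 1e-15) n else (1 - r^n) / (1 - r)

  if (strategy == "quantitative") {
    stay <- s$q_negative
    ratio <- stay * (1 - sum(p))
    events_per_occ <- stay * p           # costed stratum: q-negatives
    confirms_per_occ <- 0
    cash <- config$cost_quant_test +
      config$transport_trips_quant * config$cost_transport +
      sum(events_per_occ * config$outcomes$unit_cost)
  } else {
    tn <- s$semiq_negative * (1 - s$fn_given_semiq_negative)
    fn <- s$semiq_negative * s$fn_given_semiq_negative
    fp <- (1 - s$semiq_negative) * (1 - s$tp_given_semiq_positive)
    ratio <- (tn + fp) * (1 - sum(p)) + fn * (1 - sum(q))
    events_per_occ <- tn * p + fn * q    # costed strata exclude false positives
    confirms_per_occ <- 1 - s$semiq_negative
    cash <- config$cost_semiq_test +
      config$transport_trips_semiq * config$cost_transport +
      confirms_per_occ * (config$cost_quant_test +
                            config$transport_trips_confirm * config$cost_transport) +
      sum(events_per_occ * config$outcomes$unit_cost)
  }
  screens <- geom(ratio, h)
  disc_screens <- geom(ratio / (1 + config$discount_rate), h)
  list(screens = screens,
       confirms = screens * confirms_per_occ,
       events = screens * events_per_occ,
       total_crude = screens * cash,
       total_discounted = disc_screens * cash)
}

oracle_saving <- function(config, basis = "crude") {
  q <- oracle_totals(config, "quantitative")
  s <- oracle_totals(config, "semi-quantitative")
  if (basis == "crude") q$total_crude - s$total_crude
  else q$total_discounted - s$total_discounted
}

# Hand-computed inverse-variance pooling for very small k, written as
# bare arithmetic (no loops shared with the implementation).
oracle_pool_fixed <- function(y, se) {
  w <- 1 / se^2
  yb <- sum(w * y) / sum(w)
  list(log_effect = yb, se = sqrt(1 / sum(w)),
       q = sum(w * (y - yb)^2))
}

oracle_pool_dl <- function(y, se) {
  f <- oracle_pool_fixed(y, se)
  k <- length(y)
  w <- 1 / se^2
  tau2 <- max(0, (f$q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (se^2 + tau2)
  list(log_effect = sum(wr * y) / sum(wr), se = sqrt(1 / sum(wr)), tau2 = tau2)
}

# random concordance table for property checks
random_table <- function(n = 500) {
  concordance_table(matrix(stats::rmultinom(1, n, prob = runif(9, 0.02, 1)),
                           nrow = 3),
                    label = "random")
}
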