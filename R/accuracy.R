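# Concordance tables and diagnostic accuracy of the semi-quantitative
# uACR test against the quantitative standard. Categories follow the
# clinical albuminuria bins: <30 (normo), 30-300 (micro), >=300 mg/g
# (overt); a positive screen is uACR >= 30 mg/g.

#' Albuminuria category labels
#'
#' Canonical order of the three uACR categories used throughout the
#' package: `"<30"`, `"30-300"`, `">=300"` (mg albumin / g creatinine).
#' The dichotomization for screening is negative (`<30`) versus positive
#' (`>=30`, i.e. the upper two categories).
#'
#' @return Character vector of length 3.
#' @export
uacr_categories <- function() c("<30", "30-300", ">=300")

#' Bin quantitative uACR values into albuminuria categories
#'
#' Bin edges are 30 and 300 mg/g with both edges belonging to the upper
#' bin: `[0, 30)`, `[30, 300)`, `[300, Inf)`.
#'
#' @param x Numeric vector of uACR values (mg/g), all `>= 0`.
#' @return Factor with levels [uacr_categories()].
#' @export
bin_uacr <- function(x) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0)) {
    stop("quantitative uACR values must be non-negative numbers", call. = FALSE)
  }
  cut(x, breaks = c(0, 30, 300, Inf), labels = uacr_categories(),
      right = FALSE, include.lowest = TRUE)
}

#' Construct a concordance table
#'
#' A `concordance_table` is a 3x3 matrix of counts with rows indexing the
#' quantitative (reference) category and columns the semi-quantitative
#' (index) category, both in the order `<30`, `30-300`, `>=300` mg/g.
#'
#' @param counts 3x3 matrix (or coercible) of non-negative integer counts.
#' @param label Free-text cohort or subgroup name.
#' @return An object of class `concordance_table`.
#' @seealso [build_concordance()], [accuracy_metrics()],
#'   [strategy_probabilities()]
#' @export
concordance_table <- function(counts, label = "") {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(3L, 3L))) {
    stop("counts must be a 3x3 matrix (quantitative rows x semi-quantitative columns)",
         call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  n <- sum(counts)
  if (n < 1) stop("a concordance table needs at least one record (n >= 1)", call. = FALSE)
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(quantitative = uacr_categories(),
                           semiquantitative = uacr_categories())
  structure(list(counts = counts, label = as.character(label)[1], n = n),
            class = "concordance_table")
}

#' Tabulate per-patient records into a concordance table
#'
#' @param quantitative Numeric vector of quantitative uACR values (mg/g).
#' @param semiquant Character or factor vector of semi-quantitative
#'   categories; each must be one of [uacr_categories()].
#' @param label Cohort label passed to [concordance_table()].
#' @return A `concordance_table`.
#' @export
build_concordance <- function(quantitative, semiquant, label = "") {
  if (length(quantitative) != length(semiquant)) {
    stop("quantitative and semiquant must have the same length", call. = FALSE)
  }
  if (length(quantitative) == 0) {
    stop("no records supplied: a concordance table needs at least one record",
         call. = FALSE)
  }
  semiquant <- as.character(semiquant)
  bad <- which(!semiquant %in% uacr_categories())
  if (length(bad)) {
    stop(sprintf("unknown semi-quantitative category %s in record %d (expected one of %s)",
                 dQuote(semiquant[bad[1]]), bad[1],
                 paste(dQuote(uacr_categories()), collapse = ", ")),
         call. = FALSE)
  }
  qcat <- bin_uacr(quantitative)
  scat <- factor(semiquant, levels = uacr_categories())
  concordance_table(table(qcat, scat), label = label)
}

#' Build a concordance table from dichotomized screening counts
#'
#' Convenience constructor for cohorts reported only as 2x2 screening
#' results (e.g. dipstick comparisons or validation summaries): the
#' positive mass is placed in the `30-300` row/column so the dichotomized
#' margins are exact and the overt-albuminuria cells are zero.
#'
#' @param tp,fn,fp,tn Counts: true positive (both methods >= 30 mg/g),
#'   false negative (quantitative >= 30, index < 30), false positive
#'   (quantitative < 30, index >= 30), true negative.
#' @param label Cohort label.
#' @return A `concordance_table`.
#' @export
dichotomous_concordance <- function(tp, fn, fp, tn, label = "") {
  concordance_table(matrix(c(tn, fp, 0,
                             fn, tp, 0,
                             0,  0,  0), nrow = 3, byrow = TRUE),
                    label = label)
}

#' @export
print.concordance_table <- function(x, ...) {
  cat(sprintf("Concordance table%s (n = %d)\n",
              if (nzchar(x$label)) paste0(": ", x$label) else "", x$n))
  print(x$counts)
  invisible(x)
}

# dichotomized margins: quantitative-positive row mass etc.
.dichotomize <- function(table) {
  cnt <- table$counts
  list(tp = sum(cnt[2:3, 2:3]),   # both methods >= 30
       fn = sum(cnt[2:3, 1]),     # quantitative >= 30, index < 30
       fp = sum(cnt[1, 2:3]),     # quantitative < 30, index >= 30
       tn = cnt[1, 1],
       q_pos = sum(cnt[2:3, ]), q_neg = sum(cnt[1, ]),
       s_pos = sum(cnt[, 2:3]), s_neg = sum(cnt[, 1]),
       n = table$n)
}

#' Diagnostic accuracy of the semi-quantitative test
#'
#' Dichotomizes the table at 30 mg/g and returns sensitivity,
#' specificity, the over- and under-detected fractions (false positives
#' and false negatives as proportions of everyone screened), the number
#' needed to screen (1/sensitivity), and per-category row concordance
#' (diagonal cell over row total).
#'
#' @param table A [concordance_table()].
#' @return An object of class `accuracy_metrics` (a list).
#' @export
accuracy_metrics <- function(table) {
  stopifnot(inherits(table, "concordance_table"))
  d <- .dichotomize(table)
  if (d$q_pos == 0) {
    stop("no quantitative-positive subjects: sensitivity is undefined for this table",
         call. = FALSE)
  }
  if (d$q_neg == 0) {
    stop("no quantitative-negative subjects: specificity is undefined for this table",
         call. = FALSE)
  }
  sens <- d$tp / d$q_pos
  spec <- d$tn / d$q_neg
  row_tot <- rowSums(table$counts)
  row_conc <- ifelse(row_tot > 0, diag(table$counts) / row_tot, NA_real_)
  names(row_conc) <- uacr_categories()
  structure(list(label = table$label,
                 n = d$n,
                 sensitivity = sens,
                 specificity = spec,
                 over_detected = d$fp / d$n,
                 under_detected = d$fn / d$n,
                 nns = number_needed_to_screen(sens),
                 row_concordance = row_conc),
            class = "accuracy_metrics")
}

#' @export
print.accuracy_metrics <- function(x, ...) {
  cat(sprintf("Diagnostic accuracy%s (n = %d)\n",
              if (nzchar(x$label)) paste0(": ", x$label) else "", x$n))
  cat(sprintf("  sensitivity    %5.1f %%\n", 100 * x$sensitivity))
  cat(sprintf("  specificity    %5.1f %%\n", 100 * x$specificity))
  cat(sprintf("  over-detected  %5.1f %%\n", 100 * x$over_detected))
  cat(sprintf("  under-detected %5.1f %%\n", 100 * x$under_detected))
  cat(sprintf("  NNS            %5.1f\n", x$nns))
  invisible(x)
}

#' Number needed to screen
#'
#' Expected number of screening applications per true case detected,
#' computed as the reciprocal of sensitivity.
#'
#' @param sensitivity Proportion in (0, 1].
#' @return Positive real `>= 1`.
#' @export
number_needed_to_screen <- function(sensitivity) {
  if (!is.numeric(sensitivity) || anyNA(sensitivity) ||
      any(sensitivity <= 0) || any(sensitivity > 1)) {
    stop("sensitivity must lie in (0, 1]; NNS is undefined at sensitivity 0",
         call. = FALSE)
  }
  1 / sensitivity
}

#' Screening-result proportions for the Markov model
#'
#' Bundle of the four per-cycle result proportions that drive the
#' screening decision tree, each carried as beta counts `(a, b)` with
#' proportion `a / (a + b)`:
#' \describe{
#'   \item{q_negative}{negative at quantitative screening}
#'   \item{semiq_negative}{negative at semi-quantitative screening}
#'   \item{fn_given_semiq_negative}{quantitative-positive fraction among
#'     semi-quantitative negatives (false negatives)}
#'   \item{tp_given_semiq_positive}{confirmed quantitative-positive
#'     fraction among semi-quantitative positives}
#' }
#'
#' Defaults are the development-subgroup counts (diabetics with eGFR >=
#' 60 ml/min/1.73m2 and a negative dipstick, n = 1110).
#'
#' @param q_negative,semiq_negative,fn_given_semiq_negative,tp_given_semiq_positive
#'   Length-2 non-negative count vectors `c(a, b)`.
#' @return An object of class `screening_params`.
#' @export
screening_params <- function(q_negative = c(917, 193),
                             semiq_negative = c(615, 495),
                             fn_given_semiq_negative = c(36, 579),
                             tp_given_semiq_positive = c(157, 338)) {
  beta <- list(q_negative = q_negative,
               semiq_negative = semiq_negative,
               fn_given_semiq_negative = fn_given_semiq_negative,
               tp_given_semiq_positive = tp_given_semiq_positive)
  for (nm in names(beta)) {
    ab <- beta[[nm]]
    if (length(ab) != 2 || anyNA(ab) || any(ab < 0) || sum(ab) <= 0) {
      stop(sprintf("beta counts for %s must be two non-negative numbers with a + b > 0", nm),
           call. = FALSE)
    }
  }
  p <- vapply(beta, function(ab) ab[1] / sum(ab), numeric(1))
  structure(c(as.list(p), list(beta = beta)), class = "screening_params")
}

#' @export
print.screening_params <- function(x, ...) {
  cat("Screening-result proportions (beta counts):\n")
  for (nm in names(x$beta)) {
    ab <- x$beta[[nm]]
    cat(sprintf("  %-26s %.4f  Beta(%g, %g)\n", nm, x[[nm]], ab[1], ab[2]))
  }
  invisible(x)
}

#' Derive screening-strategy proportions from a concordance table
#'
#' Dichotomizes the table at 30 mg/g and expresses the four decision-tree
#' proportions as beta counts: `q_negative = Beta(q-neg, q-pos)`,
#' `semiq_negative = Beta(s-neg, s-pos)`,
#' `fn_given_semiq_negative = Beta(FN, TN)`,
#' `tp_given_semiq_positive = Beta(TP, FP)`.
#'
#' @param table A [concordance_table()].
#' @return A [screening_params()] object.
#' @export
strategy_probabilities <- function(table) {
  stopifnot(inherits(table, "concordance_table"))
  d <- .dichotomize(table)
  if (d$s_neg == 0) {
    stop("no semi-quantitative negatives: the false-negative proportion is undefined",
         call. = FALSE)
  }
  if (d$s_pos == 0) {
    stop("no semi-quantitative positives: the confirmed-positive proportion is undefined",
         call. = FALSE)
  }
  screening_params(q_negative = c(d$q_neg, d$q_pos),
                   semiq_negative = c(d$s_neg, d$s_pos),
                   fn_given_semiq_negative = c(d$fn, d$tn),
                   tp_given_semiq_positive = c(d$tp, d$fp))
}
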