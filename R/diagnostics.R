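# Diagnostic accuracy: pooled confusion table, exact binomial confidence
# intervals, prevalence-adjusted predictive values, and the published
# per-set positive/tested counts of the assay.

#' Published per-set counts of the triple DNA FISH study
#'
#' The per-set case, FISH-tested and positive counts of the three study
#' sets (training on frozen tissue, validation on touch preparations,
#' feasibility on archived FNAC smears), as printed in the source study's
#' summary table. `marker_positive` counts carcinoma patients carrying at
#' least one of the three markers by any assay (aCGH or FISH);
#' `fish_tested`/`fish_positive` feed the pooled 2x2 confusion table.
#'
#' @return data.frame: set, class, cases, fish_tested, fish_positive,
#'   marker_positive.
#' @export
study_set_counts <- function() {
  data.frame(
    set = rep(c("training", "validation", "feasibility"), each = 2),
    class = rep(c("cFA", "cFTC"), 3),
    cases = c(33L, 33L, 26L, 34L, 13L, 14L),
    fish_tested = c(20L, 24L, 26L, 34L, 13L, 14L),
    fish_positive = c(1L, 18L, 0L, 16L, 0L, 6L),
    marker_positive = c(NA, 18L, NA, 16L, NA, 6L),
    stringsAsFactors = FALSE)
}

#' Pool per-set calls into a confusion table
#'
#' Positive = marker-positive call; disease = cFTC by histology. Cases
#' with an "insufficient" call are excluded (with their count recorded),
#' not counted as negative.
#'
#' Accepts either a data.frame of per-case calls (columns case_id, label,
#' case_call; optionally set) or a data.frame of per-set counts in the
#' [study_set_counts()] layout.
#'
#' @param calls per-case calls or per-set counts (see above).
#' @return list of class `confusion_table`: TP, FP, TN, FN, n_excluded.
#' @export
pool_confusion <- function(calls) {
  if (all(c("fish_tested", "fish_positive", "class") %in% names(calls))) {
    cftc <- calls$class == "cFTC"
    tp <- sum(calls$fish_positive[cftc])
    fn <- sum(calls$fish_tested[cftc] - calls$fish_positive[cftc])
    fp <- sum(calls$fish_positive[!cftc])
    tn <- sum(calls$fish_tested[!cftc] - calls$fish_positive[!cftc])
    return(structure(list(TP = tp, FP = fp, TN = tn, FN = fn,
                          n_excluded = 0L), class = "confusion_table"))
  }
  stopifnot(all(c("case_id", "label", "case_call") %in% names(calls)))
  if (anyDuplicated(calls$case_id))
    stop("duplicate case id across sets: ",
         calls$case_id[which(duplicated(calls$case_id))[1]])
  stopifnot(all(calls$label %in% c("cFA", "cFTC")),
            all(calls$case_call %in% c("positive", "negative",
                                       "insufficient")))
  excl <- calls$case_call == "insufficient"
  kept <- calls[!excl, , drop = FALSE]
  structure(list(
    TP = sum(kept$label == "cFTC" & kept$case_call == "positive"),
    FP = sum(kept$label == "cFA" & kept$case_call == "positive"),
    TN = sum(kept$label == "cFA" & kept$case_call == "negative"),
    FN = sum(kept$label == "cFTC" & kept$case_call == "negative"),
    n_excluded = sum(excl)), class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("confusion table: TP=%d FP=%d TN=%d FN=%d (%d excluded)\n",
              x$TP, x$FP, x$TN, x$FN, x$n_excluded))
  invisible(x)
}

# Exact (Clopper-Pearson) binomial interval on x successes of n.
clopper_pearson <- function(x, n, conf = 0.95) {
  a <- (1 - conf) / 2
  lo <- if (x == 0) 0 else qbeta(a, x, n - x + 1)
  hi <- if (x == n) 1 else qbeta(1 - a, x + 1, n - x)
  c(lo, hi)
}

#' Accuracy statistics with exact confidence intervals
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), PPV TP/(TP+FP), NPV
#' TN/(TN+FN), accuracy (TP+TN)/total and prevalence (TP+FN)/total, each
#' with an exact Clopper-Pearson binomial 95% CI on its numerator /
#' denominator pair. Integer-percent renderings round half up ("56",
#' "43-67"). A statistic with a zero denominator is reported as NA
#' (undefined), never as 0.
#'
#' @param ct a `confusion_table` from [pool_confusion()].
#' @param conf confidence level (default 0.95).
#' @return data.frame with one row per statistic: statistic, x, n,
#'   estimate, ci_lo, ci_hi, percent, ci_render.
#' @export
accuracy_stats <- function(ct, conf = 0.95) {
  stopifnot(inherits(ct, "confusion_table"))
  total <- ct$TP + ct$FP + ct$TN + ct$FN
  if (total <= 0) stop("empty confusion table")
  pairs <- list(
    sensitivity = c(ct$TP, ct$TP + ct$FN),
    specificity = c(ct$TN, ct$TN + ct$FP),
    ppv = c(ct$TP, ct$TP + ct$FP),
    npv = c(ct$TN, ct$TN + ct$FN),
    accuracy = c(ct$TP + ct$TN, total),
    prevalence = c(ct$TP + ct$FN, total))
  rows <- lapply(names(pairs), function(s) {
    x <- pairs[[s]][1]
    n <- pairs[[s]][2]
    if (n == 0) {
      return(data.frame(statistic = s, x = x, n = n, estimate = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_,
                        percent = NA_real_, ci_render = NA_character_,
                        stringsAsFactors = FALSE))
    }
    ci <- clopper_pearson(x, n, conf)
    data.frame(statistic = s, x = x, n = n, estimate = x / n,
               ci_lo = ci[1], ci_hi = ci[2],
               percent = percent_render(x / n),
               ci_render = paste0(percent_render(ci[1]), "–",
                                  percent_render(ci[2])),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Prevalence-adjusted predictive values
#'
#' Bayes' rule at an assumed disease prevalence `pi` (clinical settings
#' see far fewer carcinomas than a surgical case series):
#' `PPV = sens*pi / (sens*pi + (1-spec)*(1-pi))`,
#' `NPV = spec*(1-pi) / ((1-sens)*pi + spec*(1-pi))`.
#'
#' @param sensitivity,specificity fractions in \[0, 1\].
#' @param pi assumed disease prevalence, strictly inside (0, 1).
#' @return list with `ppv` and `npv`.
#' @export
adjust_prevalence <- function(sensitivity, specificity, pi) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  if (!(pi > 0 && pi < 1))
    stop("prevalence must be strictly between 0 and 1")
  list(ppv = sensitivity * pi /
         (sensitivity * pi + (1 - specificity) * (1 - pi)),
       npv = specificity * (1 - pi) /
         ((1 - sensitivity) * pi + specificity * (1 - pi)))
}

#' Per-set marker positivity rates
#'
#' Fraction of carcinoma patients carrying at least one marker in each
#' set, plus the pooled rate over all carcinomas, computed by one
#' aggregation.
#'
#' @param counts per-set counts in the [study_set_counts()] layout.
#' @return data.frame: set, positive, cases, rate, percent (pooled row
#'   rendered at one decimal as published).
#' @export
positivity_rates <- function(counts = study_set_counts()) {
  cftc <- counts[counts$class == "cFTC", , drop = FALSE]
  pos <- c(cftc$marker_positive, sum(cftc$marker_positive))
  n <- c(cftc$cases, sum(cftc$cases))
  data.frame(set = c(cftc$set, "pooled"),
             positive = pos, cases = n, rate = pos / n,
             percent = c(percent_render(cftc$marker_positive / cftc$cases),
                         percent_render(sum(cftc$marker_positive) /
                                          sum(cftc$cases), digits = 1)),
             stringsAsFactors = FALSE)
}
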