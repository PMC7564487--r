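# Triple DNA FISH scoring: per-nucleus signal patterns, case-level marker
# calls. Panels: P1 = 1p36.31 target / 1q25.3 control, P22 = 22q13.3 target /
# 22q11.2 control, PXY = CEP X (target) / CEP Y (control).

FISH_PANELS <- c("P1", "P22", "PXY")
PANEL_MARKER <- c(P1 = "loss", P22 = "loss", PXY = "gain")

#' Classify one nucleus's FISH signal pattern
#'
#' Locus panels (P1, P22) are read as a target:control ratio so that
#' polyploid nuclei score correctly (3 target vs 6 control signals is a
#' loss): with at least two control signals, fewer target than control
#' signals is a loss, more is a gain, equality is normal. Fewer than two
#' control signals leaves the target dosage unanchored (this includes the
#' ambiguous 1:1 whole-chromosome/monosomy pattern) and the nucleus is
#' uninformative.
#'
#' The sex-chromosome panel counts CEP X signals against the expected
#' dosage: females are normal at X=2, a gain at X>=3, a loss below 2;
#' males are normal at X=1 with the Y control present, a gain at X>=2
#' regardless of Y (the 2X/1Y male pattern reads as trisomic), a loss at
#' X=0, and uninformative when X=1 with no Y signal (monosomy-like,
#' tallied separately) or when no signal is seen at all.
#'
#' @param panel "P1", "P22" or "PXY" (vectorized).
#' @param target,control signal counts (0-10).
#' @param sex "female" or "male".
#' @return character vector of patterns: "normal", "loss", "gain" or
#'   "uninformative".
#' @export
classify_nucleus <- function(panel, target, control, sex) {
  n <- max(length(panel), length(target), length(control), length(sex))
  panel <- rep_len(as.character(panel), n)
  target <- rep_len(as.integer(target), n)
  control <- rep_len(as.integer(control), n)
  sex <- rep_len(as.character(sex), n)
  if (!all(panel %in% FISH_PANELS))
    stop("unknown FISH panel: ", paste(setdiff(panel, FISH_PANELS),
                                       collapse = ", "))
  stopifnot(all(sex %in% c("female", "male")),
            all(target >= 0L), all(control >= 0L),
            all(target <= 10L), all(control <= 10L))
  out <- character(n)
  locus <- panel %in% c("P1", "P22")
  # locus panels: ratio rule anchored on >= 2 control signals
  li <- which(locus)
  out[li] <- "uninformative"
  anchored <- locus & control >= 2L
  out[anchored & target < control] <- "loss"
  out[anchored & target > control] <- "gain"
  out[anchored & target == control] <- "normal"
  # sex-chromosome panel: target = X count, control = Y count
  xi <- which(!locus)
  for (i in xi) {
    x <- target[i]; y <- control[i]
    if (x == 0L && y == 0L) { out[i] <- "uninformative"; next }
    if (sex[i] == "female") {
      out[i] <- if (x >= 3L) "gain" else if (x == 2L) "normal" else "loss"
    } else {
      out[i] <- if (x >= 2L) "gain"
        else if (x == 1L && y >= 1L) "normal"
        else if (x == 1L) "uninformative"   # 1X/0Y monosomy-like
        else "loss"                          # x == 0, some Y signal
    }
  }
  out
}

#' Score a FISH case from its nucleus counts
#'
#' Nuclei are classified with [classify_nucleus()]; uninformative nuclei
#' are excluded from numerator and denominator. A panel with fewer than
#' `min_nuclei` informative nuclei is "insufficient"; otherwise the
#' panel's marker (P1 loss, P22 loss, PXY gain) is "positive" when the
#' aberrant-pattern fraction reaches `positivity_fraction`. The case is
#' positive iff at least one marker is positive.
#'
#' The positivity cutoff is a design constant of this implementation, not
#' a published value; it defaults to 0.20 of informative nuclei and is
#' reported alongside every call.
#'
#' @param counts data.frame of one case's nuclei: panel, target_count,
#'   control_count (and optionally sex/case_id columns).
#' @param sex "female" or "male".
#' @param min_nuclei minimum informative nuclei per panel (default 100).
#' @param positivity_fraction aberrant-nucleus fraction required for a
#'   positive marker call (default 0.20).
#' @return list of class `fish_case_result`: per-panel data.frame
#'   (`panels`: panel, n_informative, n_aberrant, fraction, call) and
#'   `case_call` ("positive"/"negative"/"insufficient").
#' @export
score_case <- function(counts, sex, min_nuclei = 100L,
                       positivity_fraction = 0.20) {
  stopifnot(all(c("panel", "target_count", "control_count") %in%
                  names(counts)))
  res <- data.frame(panel = FISH_PANELS, n_informative = 0L,
                    n_aberrant = 0L, fraction = NA_real_,
                    call = "insufficient", stringsAsFactors = FALSE)
  for (k in seq_along(FISH_PANELS)) {
    pn <- FISH_PANELS[k]
    cc <- counts[counts$panel == pn, , drop = FALSE]
    if (nrow(cc) == 0L) {
      warning("case has no nuclei for panel ", pn, "; marker insufficient")
      next
    }
    pat <- classify_nucleus(pn, cc$target_count, cc$control_count, sex)
    inf <- pat != "uninformative"
    res$n_informative[k] <- sum(inf)
    res$n_aberrant[k] <- sum(pat[inf] == PANEL_MARKER[pn])
    if (res$n_informative[k] >= min_nuclei) {
      res$fraction[k] <- res$n_aberrant[k] / res$n_informative[k]
      res$call[k] <- if (res$fraction[k] >= positivity_fraction)
        "positive" else "negative"
    }
  }
  case_call <- if (any(res$call == "positive")) "positive"
    else if (all(res$call == "insufficient")) "insufficient"
    else "negative"
  structure(list(panels = res, case_call = case_call,
                 positivity_fraction = positivity_fraction,
                 min_nuclei = as.integer(min_nuclei)),
            class = "fish_case_result")
}

#' Score every case of a FISH count table
#'
#' @param counts data.frame as from [read_fish_counts()] (case_id, sex,
#'   panel, target_count, control_count).
#' @inheritParams score_case
#' @return data.frame with one row per case: case_id, sex, per-marker
#'   calls (call_1p_loss, call_22q_loss, call_x_gain), aberrant fractions
#'   and the overall case_call.
#' @export
score_fish <- function(counts, min_nuclei = 100L,
                       positivity_fraction = 0.20) {
  ids <- unique(counts$case_id)
  rows <- lapply(ids, function(id) {
    cc <- counts[counts$case_id == id, , drop = FALSE]
    sex <- unique(cc$sex)
    stopifnot(length(sex) == 1L)
    r <- score_case(cc, sex, min_nuclei, positivity_fraction)
    data.frame(case_id = id, sex = sex,
               call_1p_loss = r$panels$call[1],
               call_22q_loss = r$panels$call[2],
               call_x_gain = r$panels$call[3],
               frac_1p = r$panels$fraction[1],
               frac_22q = r$panels$fraction[2],
               frac_x = r$panels$fraction[3],
               case_call = r$case_call, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
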