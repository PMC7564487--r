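# Synthetic FISH nucleus counts and DNA indices.

#' FISH simulation configuration
#'
#' @param n_nuclei nuclei scored per case and panel (default 200; the
#'   assay scores at least 100 informative nuclei, and dropout plus
#'   uninformative patterns must still leave that many).
#' @param aberrant_fraction fraction of tumor nuclei carrying the aberrant
#'   pattern in a positive case (default 0.6).
#' @param failure_rate probability that a true signal is not seen
#'   (hybridization failure, default 0.05).
#' @param contamination fraction of normal (non-tumor) cells on the slide
#'   (default 0.1).
#' @return list of class `fish_sim_config`.
#' @export
fish_sim_config <- function(n_nuclei = 200L, aberrant_fraction = 0.6,
                            failure_rate = 0.05, contamination = 0.1) {
  stopifnot(n_nuclei >= 1,
            aberrant_fraction >= 0, aberrant_fraction <= 1,
            failure_rate >= 0, failure_rate <= 1,
            contamination >= 0, contamination <= 1)
  structure(list(n_nuclei = as.integer(n_nuclei),
                 aberrant_fraction = aberrant_fraction,
                 failure_rate = failure_rate,
                 contamination = contamination),
            class = "fish_sim_config")
}

# True (pre-dropout) signal-count patterns per panel and state.
fish_pattern <- function(panel, state, sex) {
  if (panel == "P1" || panel == "P22") {
    if (state == "normal") c(2L, 2L) else c(1L, 2L)   # loss: 1 target, 2 ctrl
  } else {
    if (sex == "female") {
      if (state == "normal") c(2L, 0L) else c(3L, 0L)
    } else {
      if (state == "normal") c(1L, 1L) else c(2L, 1L)
    }
  }
}

#' Simulate the nucleus counts of one FISH case
#'
#' Per nucleus: with probability `aberrant_fraction * (1 - contamination)`
#' the panel's aberrant pattern (when the case truly carries it),
#' otherwise the sex-appropriate normal pattern; each expected signal is
#' then independently lost with probability `failure_rate`.
#'
#' @param true_state named logical/character: which panels are aberrant.
#'   Accepts `c(P1 = TRUE/FALSE, P22 = ..., PXY = ...)` or a character
#'   subset of `c("1p-loss", "22q-loss", "X-gain")`.
#' @param config a [fish_sim_config()].
#' @param sex "female" or "male".
#' @param seed RNG seed (NULL uses the ambient stream).
#' @return data.frame: panel, target_count, control_count, one row per
#'   nucleus and panel.
#' @export
simulate_fish_case <- function(true_state, config = fish_sim_config(), sex,
                               seed = NULL) {
  if (is.character(true_state)) {
    stopifnot(all(true_state %in% c("1p-loss", "22q-loss", "X-gain")))
    true_state <- c(P1 = "1p-loss" %in% true_state,
                    P22 = "22q-loss" %in% true_state,
                    PXY = "X-gain" %in% true_state)
  }
  stopifnot(all(FISH_PANELS %in% names(true_state)),
            sex %in% c("female", "male"))
  with_seed(seed, {
    out <- lapply(FISH_PANELS, function(pn) {
      n <- config$n_nuclei
      p_ab <- if (isTRUE(true_state[[pn]]))
        config$aberrant_fraction * (1 - config$contamination) else 0
      aberrant <- runif(n) < p_ab
      nrm <- fish_pattern(pn, "normal", sex)
      abn <- fish_pattern(pn, "aberrant", sex)
      tgt_true <- ifelse(aberrant, abn[1], nrm[1])
      ctl_true <- ifelse(aberrant, abn[2], nrm[2])
      keep <- 1 - config$failure_rate
      data.frame(panel = pn,
                 target_count = rbinom(n, tgt_true, keep),
                 control_count = rbinom(n, ctl_true, keep),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Simulate FISH counts for every FISH-available case of a design
#'
#' @param design data.frame as from [study_design()] (or a subset).
#' @param config a [fish_sim_config()].
#' @param seed integer seed; per-case streams are derived from it so the
#'   table is reproducible.
#' @return FISH count data.frame (set, case_id, sex, panel, target_count,
#'   control_count).
#' @export
simulate_study_fish <- function(design, config = fish_sim_config(),
                                seed = 1L) {
  design <- design[design$fish_available, , drop = FALSE]
  rows <- lapply(seq_len(nrow(design)), function(i) {
    d <- design[i, ]
    counts <- simulate_fish_case(
      c(P1 = d$m1p, P22 = d$m22q, PXY = d$mx), config, d$sex,
      seed = derive_seed(seed, i))
    cbind(set = d$set, case_id = d$case_id, sex = d$sex, counts,
          stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate DNA indices for a ploidy class
#'
#' Draws uniformly from the class's DI interval(s): diploid \[0.9, 1.1\],
#' haploid \[0.5, 0.6), tetraploid \[1.8, 2.2\], aneuploid from one of its
#' two sub-intervals, multiploid two draws from two distinct intervals
#' (e.g. 0.7 and 1.35). [classify_ploidy()] recovers the class from the
#' output by construction.
#'
#' @param class one of "diploid", "aneuploid", "haploid", "tetraploid",
#'   "multiploid".
#' @param seed RNG seed (NULL uses the ambient stream).
#' @return numeric vector of DNA indices (length 1, or 2 for multiploid).
#' @export
simulate_di <- function(class = c("diploid", "aneuploid", "haploid",
                                  "tetraploid", "multiploid"),
                        seed = NULL) {
  class <- match.arg(class)
  draw <- function(iv) runif(1, iv[1], iv[2])
  with_seed(seed, switch(class,
    diploid = draw(DI_INTERVALS$diploid),
    haploid = draw(DI_INTERVALS$haploid),
    tetraploid = draw(DI_INTERVALS$tetraploid),
    aneuploid = if (runif(1) < 0.5) draw(DI_INTERVALS$aneuploid_low)
      else draw(DI_INTERVALS$aneuploid_high),
    multiploid = c(draw(DI_INTERVALS$aneuploid_low),
                   draw(DI_INTERVALS$aneuploid_high))))
}
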