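# The study-faithful cohort configuration: three sets (training on frozen
# tissue with aCGH + FISH, validation on touch preparations with FISH,
# feasibility on archived FNAC smears with FISH), with the per-set marker
# alteration counts of the source study wired in as fixed case assignments.

#' Case-level design of the three study-faithful synthetic sets
#'
#' Returns one row per case with its set, class label, sex, FISH
#' availability and ground-truth marker status. The assignment is fixed,
#' not sampled:
#' * training: 33 cFA + 33 cFTC; among cFTC, 5 carry the 1p36.33-p35.1
#'   loss, 8 the 22q13.2-q13.31 loss and 8 the whole-X gain, with one case
#'   carrying 1p+22q and one carrying all three (18 distinct positive
#'   cases, 21 alterations). 24 cFTC and 20 cFA have FISH (44 touch
#'   preparations); one cFA is FISH-positive for the 22q loss without an
#'   aCGH correlate (sub-clonal fraction below array sensitivity).
#' * validation: 26 cFA + 34 cFTC, FISH only; 16 positive cFTC (three
#'   1p+22q, nine 22q only, four X only; 19 alterations).
#' * feasibility: 13 cFA + 14 cFTC, FISH only; 6 positive cFTC (two per
#'   marker, no co-occurrence).
#'
#' Sex ratios follow the study's per-set tallies where published.
#' Columns `m1p`, `m22q`, `mx` are the FISH-level truth; `acgh_m1p`,
#' `acgh_m22q`, `acgh_mx` the array-level truth (they differ only for the
#' heterogeneous cFA case).
#'
#' @return data.frame, one row per case.
#' @export
study_design <- function() {
  sex_vec <- function(n_f, n_m) rep(c("female", "male"), c(n_f, n_m))
  mk <- function(set, label, n, prefix, sexes) {
    data.frame(set = set, case_id = sprintf("%s%02d", prefix, seq_len(n)),
               label = label, sex = sexes, fish_available = TRUE,
               m1p = FALSE, m22q = FALSE, mx = FALSE,
               stringsAsFactors = FALSE)
  }
  tr_a <- mk("training", "cFA", 33, "TR_A", sex_vec(21, 12))
  tr_c <- mk("training", "cFTC", 33, "TR_C", sex_vec(16, 17))
  # marker carriers: one double (1p+22q), one triple, then singles
  tr_c$m1p[1:5] <- TRUE
  tr_c$m22q[c(1, 2, 6:11)] <- TRUE
  tr_c$mx[c(2, 12:18)] <- TRUE
  tr_c$fish_available[25:33] <- FALSE
  tr_a$fish_available[21:33] <- FALSE
  va_a <- mk("validation", "cFA", 26, "VA_A", sex_vec(20, 6))
  va_c <- mk("validation", "cFTC", 34, "VA_C", sex_vec(20, 14))
  va_c$m1p[1:3] <- TRUE
  va_c$m22q[1:12] <- TRUE      # 1p loss always associated with 22q loss
  va_c$mx[13:16] <- TRUE       # X gain always the only abnormality
  fe_a <- mk("feasibility", "cFA", 13, "FE_A", sex_vec(8, 5))
  fe_c <- mk("feasibility", "cFTC", 14, "FE_C", sex_vec(8, 6))
  fe_c$m1p[1:2] <- TRUE
  fe_c$m22q[3:4] <- TRUE
  fe_c$mx[5:6] <- TRUE
  design <- rbind(tr_a, tr_c, va_a, va_c, fe_a, fe_c)
  design$acgh_m1p <- design$m1p
  design$acgh_m22q <- design$m22q
  design$acgh_mx <- design$mx
  # the heterogeneous training cFA: FISH-positive for 22q, array-negative
  design$m22q[design$case_id == "TR_A01"] <- TRUE
  # aCGH truth only exists for the training set
  design$acgh_m1p[design$set != "training"] <- NA
  design$acgh_m22q[design$set != "training"] <- NA
  design$acgh_mx[design$set != "training"] <- NA
  design
}

# Marker regions on a genome map.
marker_regions <- function(genome) {
  r1 <- resolve_band_range(genome, "1p36.33-1p35.1")
  r22 <- resolve_band_range(genome, "22q13.2-22q13.31")
  list(m1p = data.frame(chrom = r1$chrom, start = r1$start, end = r1$end),
       m22q = data.frame(chrom = r22$chrom, start = r22$start,
                         end = r22$end),
       mx = data.frame(chrom = "X", start = 0,
                       end = unname(genome$lengths[["X"]])))
}

#' Simulate the training cohort's aCGH profiles
#'
#' Generates 66 profiles (33 cFA, 33 cFTC) on the given probe grid with
#' the fixed marker assignment of [study_design()]: marker losses are
#' single-copy (CN 1), the whole-X gain adds one copy (CN 3 female / CN 2
#' male against the sex-matched reference). Shared whole-chromosome
#' background events (gains of 5, 7, 9, 12, 14, 16, 17, 20; losses of 3,
#' 4, 8, 11, 21) are drawn per class at the configured frequencies and
#' recorded in the ground truth; they sit on chromosomes outside the
#' default probe grid, so they do not perturb marker discovery unless the
#' grid is configured to include them.
#'
#' @param probes probe grid from [make_probe_grid()].
#' @param genome the `genome_map` the grid was built on.
#' @param config a [sim_config()].
#' @param seed integer seed; identical config + seed give bit-identical
#'   cohorts.
#' @return list of class `acgh_cohort`: `probes`, `ratio` (probes x 66
#'   matrix), `pheno` (sample_id, label, sex, purity) and `truth` (ground
#'   truth events: sample_id, chrom, start, end, cn, event).
#' @export
simulate_training_cohort <- function(probes, genome,
                                     config = sim_config(), seed = 1L) {
  design <- study_design()
  design <- design[design$set == "training", , drop = FALSE]
  mreg <- marker_regions(genome)
  with_seed(seed, {
    ratio <- matrix(NA_real_, nrow(probes), nrow(design),
                    dimnames = list(NULL, design$case_id))
    truth <- NULL
    for (i in seq_len(nrow(design))) {
      d <- design[i, ]
      ev <- NULL
      add <- function(ev, region, cn, what)
        rbind(ev, data.frame(chrom = region$chrom, start = region$start,
                             end = region$end, cn = cn, event = what,
                             stringsAsFactors = FALSE))
      if (isTRUE(d$acgh_m1p)) ev <- add(ev, mreg$m1p, 1L, "1p_loss")
      if (isTRUE(d$acgh_m22q)) ev <- add(ev, mreg$m22q, 1L, "22q_loss")
      if (isTRUE(d$acgh_mx))
        ev <- add(ev, mreg$mx,
                  baseline_cn("X", d$sex) + 1L, "x_gain")
      bg_p <- if (d$label == "cFA") config$bg_freq_cfa else
        config$bg_freq_cftc
      for (ch in BG_GAIN_CHROMS) if (runif(1) < bg_p)
        ev <- add(ev, data.frame(chrom = ch, start = 0,
                                 end = unname(genome$lengths[[ch]])),
                  3L, "background_gain")
      for (ch in BG_LOSS_CHROMS) if (runif(1) < bg_p)
        ev <- add(ev, data.frame(chrom = ch, start = 0,
                                 end = unname(genome$lengths[[ch]])),
                  1L, "background_loss")
      if (is.null(ev))
        ev <- data.frame(chrom = character(0), start = numeric(0),
                         end = numeric(0), cn = integer(0),
                         event = character(0))
      ratio[, i] <- simulate_profile(probes, ev, config, d$sex,
                                     seed = NULL)
      if (nrow(ev) > 0)
        truth <- rbind(truth, cbind(sample_id = d$case_id, ev))
    }
    structure(list(probes = probes,
                   ratio = ratio,
                   pheno = data.frame(sample_id = design$case_id,
                                      label = design$label,
                                      sex = design$sex,
                                      purity = config$purity,
                                      stringsAsFactors = FALSE),
                   truth = truth),
              class = "acgh_cohort")
  })
}
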