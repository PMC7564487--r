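# End-to-end study-faithful reproduction: simulate the three cohorts, run
# normalization -> segmentation -> calling -> marker discovery (training
# aCGH), score the FISH sets, pool the confusion table and compute the
# accuracy statistics. All randomness fans out from one global seed.

fnv_hash <- function(s) {
  h <- 5381
  for (b in as.integer(charToRaw(s))) h <- (h * 33 + b) %% 2147483629
  sprintf("%08x", as.integer(h))
}

#' Run the full study-faithful pipeline on synthetic cohorts
#'
#' Simulates the training set's aCGH profiles and all three sets' FISH
#' counts with the fixed case assignment of [study_design()], then runs
#' the complete analysis chain. Two runs with the same configuration and
#' seed produce bit-identical outputs.
#'
#' @param seed global integer seed (default 1); per-stage seeds are
#'   derived from it via [derive_seed()].
#' @param out_dir optional output directory; when given, writes
#'   `calls.seg`, `markers.bed`, `fish_results.csv`, `accuracy.json` and
#'   `run.log`.
#' @param sim a [sim_config()].
#' @param call a [call_config()].
#' @param fish a [fish_sim_config()].
#' @param prevalence assumed clinical prevalence for the adjusted
#'   predictive values (default 0.10).
#' @param skip_fish when TRUE, stop after aCGH marker discovery and
#'   report only array-level marker recovery.
#' @param quiet suppress progress messages.
#' @return list with elements `cohort`, `calls`, `noise`, `markers`,
#'   `fish_results` (unless skipped), `confusion`, `stats`,
#'   `adjusted`, `positivity`, `log`.
#' @export
run_reproduce <- function(seed = 1L, out_dir = NULL, sim = sim_config(),
                          call = call_config(), fish = fish_sim_config(),
                          prevalence = 0.10, skip_fish = FALSE,
                          quiet = FALSE) {
  t0 <- Sys.time()
  logline <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    logline <<- c(logline, msg)
    if (!quiet) message(msg)
  }
  cfg_hash <- fnv_hash(paste(deparse(sim), deparse(call), deparse(fish),
                             collapse = " "))
  say("run_reproduce: seed=%d config_hash=%s", as.integer(seed), cfg_hash)

  genome <- read_cytobands(system.file("extdata",
                                       "cytoband_hg19_synthetic.txt",
                                       package = "thyrofish"))
  probes <- make_probe_grid(genome, sim$spacing, sim$chromosomes,
                            seed = derive_seed(seed, 0))
  say("probe grid: %d probes on %s (spacing %g bp)", nrow(probes),
      paste(sim$chromosomes, collapse = ","), sim$spacing)

  cohort <- simulate_training_cohort(probes, genome, sim,
                                     seed = derive_seed(seed, 1))
  say("training cohort: %d samples, %d ground-truth events",
      ncol(cohort$ratio), nrow(cohort$truth))

  calls <- vector("list", ncol(cohort$ratio))
  names(calls) <- colnames(cohort$ratio)
  noise <- numeric(ncol(cohort$ratio))
  autosomal <- which(probes$chrom %in% as.character(1:22))
  for (i in seq_along(calls)) {
    v <- normalize_profile(cohort$ratio[, i], probes$gc,
                           center_idx = autosomal)
    tau <- profile_noise(v, probes$chrom)
    segs <- segment_profile(v, probes, call,
                            seed = derive_seed(seed, 100 + i))
    calls[[i]] <- call_aberrations(segs, tau, call)
    noise[i] <- tau
  }
  say("aCGH calls: %d segments, %d aberrant",
      sum(vapply(calls, nrow, integer(1))),
      sum(vapply(calls, function(s) sum(s$state != "normal"), integer(1))))

  labels <- setNames(cohort$pheno$label, cohort$pheno$sample_id)
  rm_ <- build_region_matrix(calls, probes)
  ranked <- rank_regions(rm_, labels)
  markers <- select_minimal_markers(ranked)
  for (i in seq_len(nrow(markers))) {
    mcr <- refine_marker_mcr(calls, markers[i, ])
    markers$start[i] <- mcr$start
    markers$end[i] <- mcr$end
  }
  markers$name <- vapply(seq_len(nrow(markers)), function(i)
    band_range_name(genome, markers$chrom[i], markers$start[i],
                    markers$end[i]), character(1))
  say("marker discovery: %d candidate regions, %d markers selected (%s)",
      nrow(ranked), nrow(markers), paste(markers$name, collapse = "; "))

  out <- list(cohort = cohort, calls = calls, noise = noise,
              ranked = ranked, markers = markers, config_hash = cfg_hash,
              seed = as.integer(seed))

  if (!skip_fish) {
    design <- study_design()
    counts <- simulate_study_fish(design, fish,
                                  seed = derive_seed(seed, 2))
    scored <- score_fish(counts)
    scored <- merge(scored,
                    design[, c("case_id", "set", "label")], by = "case_id",
                    sort = FALSE)
    say("FISH: %d cases scored (%d nuclei/panel)",
        nrow(scored), fish$n_nuclei)
    ct <- pool_confusion(scored)
    stats <- accuracy_stats(ct)
    sens <- stats$estimate[stats$statistic == "sensitivity"]
    spc <- stats$estimate[stats$statistic == "specificity"]
    adjusted <- adjust_prevalence(sens, spc, prevalence)
    pos_counts <- do.call(rbind, lapply(split(scored, scored$set),
      function(d) {
        data.frame(set = d$set[1],
                   class = c("cFA", "cFTC"),
                   cases = c(sum(design$set == d$set[1] &
                                   design$label == "cFA"),
                             sum(design$set == d$set[1] &
                                   design$label == "cFTC")),
                   fish_tested = c(sum(d$label == "cFA"),
                                   sum(d$label == "cFTC")),
                   fish_positive = c(
                     sum(d$label == "cFA" & d$case_call == "positive"),
                     sum(d$label == "cFTC" & d$case_call == "positive")),
                   stringsAsFactors = FALSE)
      }))
    # array-level positives complete the training patient tally
    pos_counts$marker_positive <-
      ifelse(pos_counts$class == "cFTC", pos_counts$fish_positive, NA)
    tr <- pos_counts$set == "training" & pos_counts$class == "cFTC"
    acgh_pos <- sum(design$acgh_m1p | design$acgh_m22q | design$acgh_mx,
                    na.rm = TRUE)
    pos_counts$marker_positive[tr] <- acgh_pos
    say("pooled confusion: TP=%d FP=%d TN=%d FN=%d", ct$TP, ct$FP, ct$TN,
        ct$FN)
    out$fish_counts <- counts
    out$fish_results <- scored
    out$confusion <- ct
    out$stats <- stats
    out$adjusted <- adjusted
    out$set_counts <- pos_counts
    out$positivity <- positivity_rates(pos_counts)
  }

  say("elapsed: %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  out$log <- logline

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    seg_all <- do.call(rbind, lapply(names(calls), function(s)
      cbind(sample_id = s, calls[[s]])))
    write_seg(seg_all, file.path(out_dir, "calls.seg"))
    write_bed(markers[, c("chrom", "start", "end", "name", "p", "n_cov")],
              file.path(out_dir, "markers.bed"))
    if (!skip_fish) {
      write.csv(out$fish_results, file.path(out_dir, "fish_results.csv"),
                row.names = FALSE, quote = FALSE)
      report <- list(
        seed = as.integer(seed), config_hash = cfg_hash,
        confusion = out$confusion[c("TP", "FP", "TN", "FN")],
        stats = out$stats[, c("statistic", "x", "n", "estimate", "ci_lo",
                              "ci_hi", "percent", "ci_render")],
        adjusted_prevalence = prevalence,
        adjusted = out$adjusted,
        positivity = out$positivity)
      jsonlite::write_json(report, file.path(out_dir, "accuracy.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    writeLines(logline, file.path(out_dir, "run.log"))
  }
  invisible(out)
}
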