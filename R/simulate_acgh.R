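# Synthetic aCGH cohorts with the statistical structure the analysis
# assumes: purity-attenuated copy-number amplitudes on a uniform probe
# grid, GC/dye bias, Gaussian probe noise, and the study's two-class event
# configuration (marker losses of 1p36.33-p35.1 and 22q13.2-q13.31, whole-X
# gain, plus whole-chromosome background events shared by both classes).

#' Expected log2 ratio under the purity-mixture model
#'
#' A specimen with tumor-cell fraction `purity` carrying `tumor_cn` copies
#' against a (sex-matched) reference of `baseline_cn` copies yields an
#' expected ratio of
#' `log2((purity * tumor_cn + (1 - purity) * baseline_cn) / baseline_cn)`.
#'
#' @param tumor_cn integer tumor copy number (>= 0).
#' @param baseline_cn integer reference copy number (>= 1).
#' @param purity tumor-cell fraction in (0, 1\].
#' @return expected log2 ratio (vectorized).
#' @export
expected_log2 <- function(tumor_cn, baseline_cn, purity) {
  if (any(baseline_cn < 1)) stop("baseline copy number must be >= 1")
  stopifnot(all(purity > 0), all(purity <= 1), all(tumor_cn >= 0))
  log2((purity * tumor_cn + (1 - purity) * baseline_cn) / baseline_cn)
}

#' Simulation configuration for aCGH cohorts
#'
#' @param spacing probe spacing in bp (default 1e5, one probe per 100 kb).
#' @param noise_sd per-probe Gaussian noise sd in log2 units (default
#'   0.12; arrays of this class show no published noise figure, so this is
#'   a free parameter of the generator).
#' @param purity tumor-cell fraction (default 0.8, the study's floor).
#' @param gc_bias linear GC bias coefficient: `gc_bias * (gc - mean(gc))`
#'   is added to every probe (default 0.2).
#' @param dye_offset constant dye (Cy5/Cy3) offset in log2 units (default
#'   0.05).
#' @param chromosomes chromosomes carrying probes (default "1", "22",
#'   "X"; chromosome Y is left off the grid because the tumor/reference
#'   ratio is undefined for female samples there).
#' @param bg_freq_cfa,bg_freq_cftc per-event probabilities of the shared
#'   whole-chromosome background events (gains of 5, 7, 9, 12, 14, 16, 17,
#'   20; losses of 3, 4, 8, 11, 21) in each class.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(spacing = 1e5, noise_sd = 0.12, purity = 0.8,
                       gc_bias = 0.2, dye_offset = 0.05,
                       chromosomes = c("1", "22", "X"),
                       bg_freq_cfa = 0.06, bg_freq_cftc = 0.15) {
  stopifnot(noise_sd >= 0, purity > 0, purity <= 1, spacing > 0,
            bg_freq_cfa >= 0, bg_freq_cfa <= 1,
            bg_freq_cftc >= 0, bg_freq_cftc <= 1)
  structure(list(spacing = spacing, noise_sd = noise_sd, purity = purity,
                 gc_bias = gc_bias, dye_offset = dye_offset,
                 chromosomes = norm_chrom(chromosomes),
                 bg_freq_cfa = bg_freq_cfa, bg_freq_cftc = bg_freq_cftc),
            class = "sim_config")
}

BG_GAIN_CHROMS <- c("5", "7", "9", "12", "14", "16", "17", "20")
BG_LOSS_CHROMS <- c("3", "4", "8", "11", "21")

#' Build a uniform probe grid over a genome map
#'
#' Probes tile each requested chromosome at the configured spacing
#' (0-based half-open). GC fractions are drawn once, uniformly in
#' \[0.35, 0.65\], from the given seed, so a grid is reproducible.
#'
#' @param genome a `genome_map`.
#' @param spacing probe spacing in bp.
#' @param chromosomes chromosomes to tile.
#' @param seed RNG seed for the GC fractions.
#' @return probe data.frame (probe_id, chrom, start, end, gc).
#' @export
make_probe_grid <- function(genome, spacing = 1e5,
                            chromosomes = c("1", "22", "X"), seed = 1L) {
  chromosomes <- norm_chrom(chromosomes)
  stopifnot(all(chromosomes %in% genome$chromosomes))
  chromosomes <- chromosomes[order(chrom_rank(chromosomes))]
  rows <- lapply(chromosomes, function(ch) {
    len <- genome$lengths[[ch]]
    start <- seq(0, len - spacing, by = spacing)
    data.frame(chrom = ch, start = start,
               end = pmin(start + spacing, len), stringsAsFactors = FALSE)
  })
  probes <- do.call(rbind, rows)
  probes$probe_id <- sprintf("P_%s_%07d", probes$chrom,
                             seq_len(nrow(probes)))
  probes$gc <- with_seed(seed, runif(nrow(probes), 0.35, 0.65))
  probes[, c("probe_id", "chrom", "start", "end", "gc")]
}

# Baseline copy number per chromosome for a given sex (sex-matched
# reference): autosomes 2; X 2/1 for female/male; Y 0/1.
baseline_cn <- function(chrom, sex) {
  ifelse(chrom == "X", ifelse(sex == "female", 2L, 1L),
         ifelse(chrom == "Y", ifelse(sex == "female", 0L, 1L), 2L))
}

#' Simulate one aCGH profile
#'
#' Per-probe value = purity-mixture expected log2 ratio of the covering
#' event (baseline elsewhere) + `gc_bias * (gc - mean(gc))` + `dye_offset`
#' + Gaussian(0, `noise_sd`) noise. A probe is covered by an event iff its
#' midpoint falls inside the event's region.
#'
#' @param probes probe data.frame.
#' @param events data.frame of copy-number events (chrom, start, end, cn),
#'   non-overlapping within each chromosome; zero rows for a flat profile.
#' @param config a [sim_config()].
#' @param sex "female" or "male".
#' @param seed RNG seed (NULL uses the ambient stream).
#' @return numeric vector of simulated log2 ratios.
#' @export
simulate_profile <- function(probes, events, config = sim_config(), sex,
                             seed = NULL) {
  stopifnot(sex %in% c("female", "male"))
  if (nrow(events) > 0) {
    ev <- events[order(chrom_rank(events$chrom), events$start), ,
                 drop = FALSE]
    for (ch in unique(ev$chrom)) {
      e <- ev[ev$chrom == ch, , drop = FALSE]
      if (nrow(e) > 1L && any(e$start[-1] < e$end[-nrow(e)]))
        stop("overlapping events on chromosome ", ch)
    }
  }
  base <- baseline_cn(probes$chrom, sex)
  cn <- base
  if (nrow(events) > 0) {
    mid <- (probes$start + probes$end) / 2
    for (r in seq_len(nrow(events))) {
      hit <- probes$chrom == events$chrom[r] & mid >= events$start[r] &
        mid < events$end[r]
      cn[hit] <- events$cn[r]
    }
  }
  if (any(base < 1L & cn != base))
    stop("event on a chromosome with zero baseline copies for this sex")
  mu <- numeric(nrow(probes))
  ok <- base >= 1L
  mu[ok] <- expected_log2(cn[ok], base[ok], config$purity)
  with_seed(seed,
    mu + config$gc_bias * (probes$gc - mean(probes$gc)) +
      config$dye_offset + rnorm(nrow(probes), 0, config$noise_sd))
}
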