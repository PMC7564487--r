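# Small fixtures built in code.

bundled_cytoband_path <- function() {
  system.file("extdata", "cytoband_hg19_synthetic.txt",
              package = "thyrofish")
}

bundled_genome <- function() read_cytobands(bundled_cytoband_path())

# Two-band toy cytoband file on chr1.
toy_cytoband_file <- function(lines = c(
  "chr1\t0\t50\tp36.33\tgneg",
  "chr1\t50\t100\tp36.32\tgneg")) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}

# Uniform single-chromosome probe grid for segmentation tests.
toy_probes <- function(n, chrom = "1", spacing = 1e5, gc = NULL,
                       gc_seed = 42L) {
  if (is.null(gc)) {
    gc <- withr::with_seed(gc_seed, runif(n, 0.35, 0.65))
  }
  data.frame(probe_id = sprintf("tp_%s_%04d", chrom, seq_len(n)),
             chrom = chrom,
             start = (seq_len(n) - 1) * spacing,
             end = seq_len(n) * spacing,
             gc = gc,
             stringsAsFactors = FALSE)
}

# Hand-built called-segment table (the shape call_aberrations() returns).
toy_calls <- function(chrom, bounds, states, means = NULL, probes = NULL) {
  k <- length(bounds) - 1L
  if (is.null(means)) means <- ifelse(states == "gain", 1,
                                      ifelse(states == "loss", -1, 0))
  istart <- bounds[-length(bounds)] + 1L
  iend <- bounds[-1L]
  if (is.null(probes)) {
    start <- (istart - 1) * 1e5
    end <- iend * 1e5
  } else {
    start <- probes$start[istart]
    end <- probes$end[iend]
  }
  data.frame(chrom = chrom, start = start, end = end,
             num_probes = iend - istart + 1L, seg_mean = means,
             istart = istart, iend = iend, state = states,
             threshold = 0.05, stringsAsFactors = FALSE)
}

# Run one profile through normalize -> noise -> segment -> call.
pipeline_one <- function(value, probes, cfg = call_config(), seed = 1L,
                         center_idx = NULL) {
  v <- normalize_profile(value, probes$gc, center_idx = center_idx)
  tau <- profile_noise(v, probes$chrom)
  segs <- segment_profile(v, probes, cfg, seed = seed)
  call_aberrations(segs, tau, cfg)
}
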