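# Circular binary segmentation (CBS) of log2-ratio profiles.
#
# Per chromosome the probe values are arranged on a circle; among all arc
# pairs the binary split maximizing a two-sample mean-shift statistic is
# located (compiled scan, see src/cbs.cpp) and accepted when its seeded
# permutation p-value falls below alpha; accepted splits are recursed into.
# Permutations stop early once exact or Clopper-Pearson bounds on the
# exceedance probability settle the comparison with alpha; the decision is
# deterministic for a fixed seed.

#' Aberration-calling configuration
#'
#' @param min_probes minimum consecutive probes for a gain/loss call
#'   (default 3).
#' @param floor minimal absolute log2 amplitude threshold; the effective
#'   calling threshold is `max(tau, floor)` with `tau` the per-profile
#'   noise estimate (default 0.05).
#' @param alpha significance level of the permutation test for accepting a
#'   split (default 0.01).
#' @param nperm maximum number of permutations per split test
#'   (default 10000).
#' @param min_width minimum arc width in probes considered by the split
#'   scan (default 2).
#' @param stop_delta error budget of the sequential early-stopping rule:
#'   permutations stop as soon as a Clopper-Pearson bound at level
#'   `1 - stop_delta` places the exceedance probability entirely on one
#'   side of `alpha` (default 1e-3).
#' @return list of class `call_config`.
#' @export
call_config <- function(min_probes = 3L, floor = 0.05, alpha = 0.01,
                        nperm = 10000L, min_width = 2L, stop_delta = 1e-3) {
  stopifnot(min_probes >= 1, alpha > 0, alpha < 1, nperm >= 100,
            min_width >= 1, floor >= 0, stop_delta > 0, stop_delta < 0.5)
  structure(list(min_probes = as.integer(min_probes), floor = floor,
                 alpha = alpha, nperm = as.integer(nperm),
                 min_width = as.integer(min_width), stop_delta = stop_delta),
            class = "call_config")
}

# Sequential permutation test of an observed max arc statistic.
# Returns list(significant, p, m, e) with p = (1 + e) / (1 + m) over the m
# permutations actually drawn. Consumes one sample.int() draw per
# permutation from the ambient RNG stream.
perm_split_test <- function(x, stat2_obs, cfg) {
  n <- length(x)
  e <- 0L
  m <- 0L
  e_stop <- ceiling(cfg$alpha * (1 + cfg$nperm) - 1)
  repeat {
    perm <- sample.int(n)
    m <- m + 1L
    if (.max_arc_exceeds(x[perm], cfg$min_width, stat2_obs)) e <- e + 1L
    if (e >= e_stop)
      return(list(significant = FALSE, p = (1 + e) / (1 + m), m = m, e = e))
    if (e > 0 && qbeta(cfg$stop_delta, e, m - e + 1) > cfg$alpha)
      return(list(significant = FALSE, p = (1 + e) / (1 + m), m = m, e = e))
    if (e < m && qbeta(1 - cfg$stop_delta, e + 1, m - e) < cfg$alpha)
      return(list(significant = TRUE, p = (1 + e) / (1 + m), m = m, e = e))
    if (m >= cfg$nperm) {
      p <- (1 + e) / (1 + m)
      return(list(significant = p < cfg$alpha, p = p, m = m, e = e))
    }
  }
}

# Change-point indices (cut after these 1-based positions) for one
# chromosome's values. Recursion is depth-first, sub-segments visited in
# genome order, so the RNG stream is fully determined by the data.
cbs_changepoints <- function(x, cfg) {
  cps <- integer(0)
  recurse <- function(lo, hi) {
    n <- hi - lo + 1L
    if (n < 2L * cfg$min_width) return(invisible(NULL))
    res <- .max_arc_stat(x[lo:hi], cfg$min_width)
    if (res$i < 0) return(invisible(NULL))
    dec <- perm_split_test(x[lo:hi], res$stat2, cfg)
    if (!dec$significant) return(invisible(NULL))
    local <- setdiff(c(res$i, res$j), c(0L, n))
    if (length(local) == 0L) return(invisible(NULL))
    abs_cp <- lo - 1L + as.integer(local)
    cps <<- c(cps, abs_cp)
    bounds <- c(lo - 1L, sort(abs_cp), hi)
    for (t in seq_len(length(bounds) - 1L))
      recurse(bounds[t] + 1L, bounds[t + 1L])
    invisible(NULL)
  }
  recurse(1L, length(x))
  sort(unique(cps))
}

#' Segment a log2-ratio profile by circular binary segmentation
#'
#' @param value numeric vector of (normalized) log2 ratios aligned to
#'   `probes`.
#' @param probes probe data.frame (probe_id, chrom, start, end, gc) in
#'   genome order.
#' @param config a [call_config()].
#' @param seed integer seed driving the permutation stream (NULL uses the
#'   ambient RNG state). Identical input and seed give identical segments.
#' @return data.frame of segments: chrom, start, end, num_probes, seg_mean,
#'   istart, iend (1-based probe index range). Segments partition the probe
#'   grid exactly; each `seg_mean` is the arithmetic mean of its member
#'   probes. Chromosomes with fewer than `2 * min_width` probes yield one
#'   segment with a warning.
#' @export
segment_profile <- function(value, probes, config = call_config(),
                            seed = NULL) {
  stopifnot(length(value) == nrow(probes), all(is.finite(value)))
  chroms <- unique(probes$chrom)
  with_seed(seed, {
    out <- vector("list", length(chroms))
    for (ci in seq_along(chroms)) {
      idx <- which(probes$chrom == chroms[ci])
      x <- value[idx]
      n <- length(x)
      if (n < 2L * config$min_width) {
        warning("chromosome ", chroms[ci], " has only ", n,
                " probes; kept as a single segment")
        cps <- integer(0)
      } else {
        cps <- cbs_changepoints(x, config)
      }
      bounds <- c(0L, cps, n)
      k <- length(bounds) - 1L
      istart <- idx[bounds[-length(bounds)] + 1L]
      iend <- idx[bounds[-1L]]
      out[[ci]] <- data.frame(
        chrom = chroms[ci],
        start = probes$start[istart],
        end = probes$end[iend],
        num_probes = diff(bounds),
        seg_mean = vapply(seq_len(k), function(t)
          mean(x[(bounds[t] + 1L):bounds[t + 1L]]), numeric(1)),
        istart = istart,
        iend = iend,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}
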