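# Noise-adaptive aberration calling, class frequency summaries and sample
# clustering on segmented profiles.

#' Per-profile internal noise estimate
#'
#' The internal noise tau of a profile is one fourth of the median absolute
#' log2-ratio difference across consecutive probes in genome order.
#' Differences never cross chromosome boundaries (crossing would inject
#' spurious large distances between unlinked loci).
#'
#' @param value numeric log2 ratios (normalized).
#' @param chrom chromosome of each probe, genome-ordered.
#' @return tau (log2 units, >= 0).
#' @export
profile_noise <- function(value, chrom) {
  stopifnot(length(value) == length(chrom))
  if (length(value) < 2L) stop("need at least 2 probes to estimate noise")
  same <- chrom[-1] == chrom[-length(chrom)]
  d <- abs(diff(value))[same]
  if (length(d) == 0L) stop("no consecutive probe pairs within a chromosome")
  median(d) / 4
}

#' Call copy-number gains and losses on segments
#'
#' A segment is called a gain when its mean is at or above the effective
#' threshold `max(tau, floor)` and a loss when at or below its negative,
#' provided it spans at least `min_probes` consecutive probes. All other
#' segments are "normal".
#'
#' @param segments data.frame from [segment_profile()].
#' @param tau per-profile noise estimate from [profile_noise()].
#' @param config a [call_config()] (supplies `floor` and `min_probes`).
#' @return the segment data.frame with added columns `state`
#'   ("gain"/"loss"/"normal") and `threshold` (the effective threshold
#'   used). Rows with `state != "normal"` are the aberration calls.
#' @export
call_aberrations <- function(segments, tau, config = call_config()) {
  stopifnot(tau >= 0)
  thr <- max(tau, config$floor)
  state <- rep("normal", nrow(segments))
  eligible <- segments$num_probes >= config$min_probes
  state[eligible & segments$seg_mean >= thr] <- "gain"
  state[eligible & segments$seg_mean <= -thr] <- "loss"
  segments$state <- state
  segments$threshold <- thr
  segments
}

#' Per-probe gain/loss frequency by class
#'
#' For every probe and class label, the fraction of samples whose calls
#' cover the probe as a gain (resp. loss). Gain and loss fractions sum to
#' at most 1 per probe and class.
#'
#' @param calls named list of called segment data.frames (one per sample,
#'   from [call_aberrations()]); all samples must share the probe grid.
#' @param probes the shared probe data.frame.
#' @param labels named character vector (sample id -> class).
#' @return data.frame: probe_id, chrom, start, end, then
#'   `gain_<class>`/`loss_<class>` fraction columns per class.
#' @export
frequency_table <- function(calls, probes, labels) {
  stopifnot(!is.null(names(calls)), all(names(calls) %in% names(labels)))
  np <- nrow(probes)
  classes <- unique(labels[names(calls)])
  out <- probes[, c("probe_id", "chrom", "start", "end")]
  for (cl in classes) {
    ids <- names(calls)[labels[names(calls)] == cl]
    if (length(ids) == 0L) {
      warning("class ", cl, " has no samples; zero frequencies")
      out[[paste0("gain_", cl)]] <- numeric(np)
      out[[paste0("loss_", cl)]] <- numeric(np)
      next
    }
    g <- numeric(np)
    l <- numeric(np)
    for (id in ids) {
      sg <- calls[[id]]
      for (r in which(sg$state != "normal")) {
        span <- sg$istart[r]:sg$iend[r]
        if (sg$state[r] == "gain") g[span] <- g[span] + 1
        else l[span] <- l[span] + 1
      }
    }
    out[[paste0("gain_", cl)]] <- g / length(ids)
    out[[paste0("loss_", cl)]] <- l / length(ids)
  }
  out
}

#' Hierarchical clustering of samples on segmented profiles
#'
#' Agglomerative clustering with Ward's method on either the Pearson
#' distance (1 - correlation; used for whole-genome profiles) or the
#' Euclidean distance (used for selected genomic regions). A sample vector
#' with zero variance has undefined correlation; its Pearson distance to
#' every other sample is set to the maximum 2.0 with a warning.
#'
#' @param mat numeric matrix, samples x features (per-probe segment means).
#' @param distance "pearson" or "euclidean".
#' @param k number of clusters for the dendrogram cut (default 2).
#' @return list with `hclust` (the tree) and `cluster` (named integer
#'   k-cut labels).
#' @export
cluster_samples <- function(mat, distance = c("pearson", "euclidean"),
                            k = 2L) {
  distance <- match.arg(distance)
  stopifnot(is.matrix(mat), nrow(mat) >= 2L)
  if (distance == "euclidean") {
    d <- dist(mat)
  } else {
    v <- apply(mat, 1, sd)
    if (any(v == 0)) {
      warning("zero-variance sample vector(s) under pearson distance; ",
              "distance to all other samples set to 2.0")
      dm <- matrix(2, nrow(mat), nrow(mat))
      ok <- v > 0
      if (sum(ok) >= 2L)
        dm[ok, ok] <- 1 - cor(t(mat[ok, , drop = FALSE]))
      diag(dm) <- 0
      rownames(dm) <- colnames(dm) <- rownames(mat)
      d <- as.dist(dm)
    } else {
      d <- as.dist(1 - cor(t(mat)))
    }
  }
  hc <- hclust(d, method = "ward.D2")
  list(hclust = hc, cluster = cutree(hc, k = k))
}
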