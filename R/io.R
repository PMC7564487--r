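# Readers/writers for the plain-text formats the pipeline touches.
#
# Conventions: 0-based half-open coordinates internally; written SEG/BED use
# 1-based inclusive coordinates and "chr"-prefixed names. Probe-table ratios
# are printed at 6 decimals and round-trip exactly at that precision.

#' Read a probe table (probe grid + log2-ratio profiles)
#'
#' Tab-delimited with header `ProbeID Chrom Start End GC` followed by one
#' column of log2 ratios per sample. Probes are returned sorted in genome
#' order (with a warning if the file was unsorted); a non-numeric ratio cell
#' is an error identifying the offending row and column.
#'
#' @param path path to the TSV file.
#' @return list with `probes` (data.frame: probe_id, chrom, start, end, gc)
#'   and `ratio` (numeric matrix, probes x samples, sample ids as colnames).
#' @export
read_probe_table <- function(path) {
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character")
  need <- c("ProbeID", "Chrom", "Start", "End", "GC")
  if (!identical(colnames(tab)[1:5], need))
    stop("probe table must start with columns ", paste(need, collapse = ", "))
  probes <- data.frame(probe_id = tab$ProbeID,
                       chrom = norm_chrom(tab$Chrom),
                       start = as.numeric(tab$Start),
                       end = as.numeric(tab$End),
                       gc = as.numeric(tab$GC),
                       stringsAsFactors = FALSE)
  samples <- colnames(tab)[-(1:5)]
  if (length(samples) == 0L) stop("probe table has no sample columns")
  ratio <- matrix(NA_real_, nrow(tab), length(samples),
                  dimnames = list(NULL, samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(tab[[samples[j]]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("non-numeric log2 ratio at row ", bad[1], ", column '",
           samples[j], "' (value '", tab[[samples[j]]][bad[1]], "')")
    ratio[, j] <- v
  }
  validate_probes(probes)
  ord <- order(chrom_rank(probes$chrom), probes$start)
  if (any(ord != seq_len(nrow(probes)))) {
    warning("probe table was not in genome order; sorting")
    probes <- probes[ord, , drop = FALSE]
    ratio <- ratio[ord, , drop = FALSE]
    rownames(probes) <- NULL
  }
  list(probes = probes, ratio = ratio)
}

validate_probes <- function(probes) {
  stopifnot(all(c("probe_id", "chrom", "start", "end", "gc") %in%
                  names(probes)))
  if (any(probes$start >= probes$end)) stop("probe with start >= end")
  if (anyDuplicated(probes$probe_id)) stop("duplicate probe ids")
  if (any(probes$gc < 0 | probes$gc > 1)) stop("GC fraction outside [0,1]")
  n_per <- table(probes$chrom)
  if (any(n_per < 3L))
    stop("chromosome(s) with fewer than 3 probes: ",
         paste(names(n_per)[n_per < 3L], collapse = ", "))
  invisible(TRUE)
}

#' Write a probe table
#'
#' @param probes probe data.frame (probe_id, chrom, start, end, gc).
#' @param ratio numeric matrix probes x samples with sample ids as colnames.
#' @param path output path.
#' @export
write_probe_table <- function(probes, ratio, path) {
  stopifnot(nrow(probes) == nrow(ratio), !is.null(colnames(ratio)))
  out <- data.frame(ProbeID = probes$probe_id,
                    Chrom = ucsc_chrom(probes$chrom),
                    Start = format(probes$start, scientific = FALSE,
                                   trim = TRUE),
                    End = format(probes$end, scientific = FALSE, trim = TRUE),
                    GC = sprintf("%.4f", probes$gc),
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (s in colnames(ratio)) out[[s]] <- sprintf("%.6f", ratio[, s])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write the phenotype table
#'
#' CSV with columns sample_id, label (cFA/cFTC/unknown), sex (female/male)
#' and purity (tumor-cell fraction in (0, 1\]).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_phenotype <- function(path) {
  ph <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "label", "sex", "purity")
  if (!all(need %in% names(ph)))
    stop("phenotype file must have columns ", paste(need, collapse = ", "))
  stopifnot(all(ph$label %in% c("cFA", "cFTC", "unknown")),
            all(ph$sex %in% c("female", "male")),
            all(ph$purity > 0 & ph$purity <= 1))
  ph
}

#' @rdname read_phenotype
#' @param pheno phenotype data.frame.
#' @export
write_phenotype <- function(pheno, path) {
  write.csv(pheno, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write segments in SEG format
#'
#' Standard SEG: header `Sample Chromosome Start End Num_Probes Segment_Mean`
#' (tab-separated). Internal 0-based half-open coordinates are written
#' 1-based inclusive, so an internal segment (0, 100) becomes Start=1,
#' End=100.
#'
#' @param segments data.frame with columns sample_id, chrom, start, end,
#'   num_probes, seg_mean (several samples may be stacked).
#' @param path output path.
#' @export
write_seg <- function(segments, path) {
  stopifnot(all(c("sample_id", "chrom", "start", "end", "num_probes",
                  "seg_mean") %in% names(segments)))
  ord <- order(match(segments$sample_id, unique(segments$sample_id)),
               chrom_rank(segments$chrom), segments$start)
  segments <- segments[ord, , drop = FALSE]
  out <- data.frame(Sample = segments$sample_id,
                    Chromosome = ucsc_chrom(segments$chrom),
                    Start = format(segments$start + 1, scientific = FALSE,
                                   trim = TRUE),
                    End = format(segments$end, scientific = FALSE,
                                 trim = TRUE),
                    Num_Probes = segments$num_probes,
                    Segment_Mean = sprintf("%.6f", segments$seg_mean),
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_seg
#' @return `read_seg` returns the data.frame with internal 0-based
#'   half-open coordinates.
#' @export
read_seg <- function(path) {
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  data.frame(sample_id = tab$Sample,
             chrom = norm_chrom(tab$Chromosome),
             start = as.numeric(tab$Start) - 1,
             end = as.numeric(tab$End),
             num_probes = as.integer(tab$Num_Probes),
             seg_mean = as.numeric(tab$Segment_Mean),
             stringsAsFactors = FALSE)
}

#' Write genomic regions as a BED-like table
#'
#' Columns chrom, start, end, name (plus any extra columns supplied),
#' written 1-based inclusive to match the SEG convention used throughout.
#'
#' @param regions data.frame with chrom, start, end, name (internal
#'   coordinates).
#' @param path output path.
#' @export
write_bed <- function(regions, path) {
  out <- regions
  out$chrom <- ucsc_chrom(out$chrom)
  out$start <- format(out$start + 1, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read/write FISH nucleus count tables
#'
#' CSV with one row per scored nucleus: case_id, sex, panel (P1/P22/PXY),
#' target_count, control_count. Counts above 10 are rejected as scoring
#' artifacts.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_fish_counts <- function(path) {
  fc <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "sex", "panel", "target_count", "control_count")
  if (!all(need %in% names(fc)))
    stop("FISH counts file must have columns ", paste(need, collapse = ", "))
  stopifnot(all(fc$panel %in% c("P1", "P22", "PXY")),
            all(fc$sex %in% c("female", "male")))
  if (any(fc$target_count < 0 | fc$control_count < 0))
    stop("negative signal count")
  if (any(fc$target_count > 10 | fc$control_count > 10))
    stop("signal count above 10 (rejected as a scoring artifact)")
  fc
}

#' @rdname read_fish_counts
#' @param counts FISH count data.frame.
#' @export
write_fish_counts <- function(counts, path) {
  write.csv(counts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
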