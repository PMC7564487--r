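# Genome coordinate model: cytobands, band-range resolution, region naming.
# Internal coordinates are 0-based half-open; UCSC cytoBand input already is.

#' Read a UCSC-style cytoBand file into a genome map
#'
#' Parses the 5-column tab-separated cytoBand dialect (chrom, start, end,
#' band, stain; 0-based half-open). Bands of each chromosome must be sorted,
#' non-overlapping and tile \[0, length); the chromosome length is taken as
#' the largest band end.
#'
#' The package bundles a reduced, synthetic hg19-like fixture
#' (`system.file("extdata", "cytoband_hg19_synthetic.txt", package =
#' "thyrofish")`) with standard band names on chromosome 1p, 22q, X and Y
#' and coarse bands elsewhere; a full UCSC `cytoBand.txt` is accepted when
#' available.
#'
#' @param path path to a cytoBand file.
#' @return A `genome_map`: list with `chromosomes` (ordered bare names),
#'   `lengths` (named numeric, base pairs) and `bands` (data.frame with
#'   columns chrom, start, end, band, arm, stain).
#' @export
read_cytobands <- function(path) {
  raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chrom", "start", "end", "band", "stain"),
                    colClasses = c("character", "numeric", "numeric",
                                   "character", "character"))
  if (nrow(raw) == 0L) stop("cytoband file is empty: ", path)
  raw$chrom <- norm_chrom(raw$chrom)
  raw$arm <- substr(raw$band, 1, 1)
  if (!all(raw$arm %in% c("p", "q"))) {
    bad <- which(!raw$arm %in% c("p", "q"))[1]
    stop("cytoband line ", bad, ": band name '", raw$band[bad],
         "' does not start with p or q")
  }
  keep <- raw$chrom %in% chrom_levels()
  raw <- raw[keep, , drop = FALSE]
  ord <- order(chrom_rank(raw$chrom), raw$start)
  if (any(ord != seq_len(nrow(raw)))) raw <- raw[ord, , drop = FALSE]
  # per-chromosome invariant checks
  for (ch in unique(raw$chrom)) {
    b <- raw[raw$chrom == ch, , drop = FALSE]
    if (b$start[1] != 0)
      stop("cytoband chromosome ", ch, ": first band does not start at 0")
    if (nrow(b) > 1L) {
      gap <- b$start[-1] != b$end[-nrow(b)]
      if (any(gap)) {
        i <- which(gap)[1]
        stop("cytoband chromosome ", ch, ": bands '", b$band[i], "' and '",
             b$band[i + 1], "' overlap or leave a gap (end ", b$end[i],
             " vs start ", b$start[i + 1], ")")
      }
    }
    if (any(b$start >= b$end))
      stop("cytoband chromosome ", ch, ": band with start >= end")
    if (anyDuplicated(b$band))
      stop("cytoband chromosome ", ch, ": duplicate band name '",
           b$band[which(duplicated(b$band))[1]], "'")
    if (is.unsorted(match(b$arm, c("p", "q"))))
      stop("cytoband chromosome ", ch, ": q band precedes a p band")
  }
  chroms <- unique(raw$chrom)
  lens <- vapply(chroms, function(ch) max(raw$end[raw$chrom == ch]),
                 numeric(1))
  structure(list(chromosomes = chroms,
                 lengths = setNames(lens, chroms),
                 bands = raw[, c("chrom", "start", "end", "band", "arm",
                                 "stain")]),
            class = "genome_map")
}

#' @export
print.genome_map <- function(x, ...) {
  cat("genome_map:", length(x$chromosomes), "chromosomes,",
      nrow(x$bands), "bands\n")
  invisible(x)
}

# Split "1p36.33" into chrom = "1", band = "p36.33"; NULL if malformed.
parse_band_name <- function(name) {
  m <- regmatches(name, regexec("^(chr)?([0-9]{1,2}|X|Y)([pq][0-9.]*)$", name))[[1]]
  if (length(m) == 0L) return(NULL)
  list(chrom = m[3], band = m[4])
}

lookup_band <- function(map, chrom, band) {
  hit <- map$bands[map$bands$chrom == chrom & map$bands$band == band, ,
                   drop = FALSE]
  if (nrow(hit) != 1L)
    stop("unknown cytoband '", chrom, band, "'")
  hit
}

#' Resolve a band-range name to genomic coordinates
#'
#' Accepts a single band ("1p36.33") or a range "1p36.33-1p35.1" (the second
#' chromosome prefix may be omitted: "1p36.33-p35.1"). The region spans from
#' the smaller band start to the larger band end, so the operation is
#' symmetric in its endpoints.
#'
#' @param map a `genome_map`.
#' @param name band or band-range string.
#' @return list with `chrom`, `start`, `end` (0-based half-open) and `name`.
#' @export
resolve_band_range <- function(map, name) {
  stopifnot(inherits(map, "genome_map"), is.character(name),
            length(name) == 1L)
  parts <- strsplit(name, "-", fixed = TRUE)[[1]]
  if (!length(parts) %in% 1:2) stop("malformed band range '", name, "'")
  a <- parse_band_name(parts[1])
  if (is.null(a)) stop("malformed band name '", parts[1], "'")
  if (length(parts) == 2L) {
    b <- parse_band_name(parts[2])
    if (is.null(b)) {
      # allow bare "p35.1" second endpoint, inheriting the chromosome
      if (grepl("^[pq]", parts[2])) b <- list(chrom = a$chrom, band = parts[2])
      else stop("malformed band name '", parts[2], "'")
    }
  } else b <- a
  if (a$chrom != b$chrom)
    stop("band range '", name, "' spans two chromosomes (", a$chrom,
         " and ", b$chrom, ")")
  ba <- lookup_band(map, a$chrom, a$band)
  bb <- lookup_band(map, b$chrom, b$band)
  list(chrom = a$chrom,
       start = min(ba$start, bb$start),
       end = max(ba$end, bb$end),
       name = name)
}

#' Name a genomic region by the cytobands it touches
#'
#' Inverse of [resolve_band_range()]: returns "1p36.33-1p35.1"-style names
#' from the first to the last band overlapping the region (a single band
#' name when only one is touched).
#'
#' @param map a `genome_map`.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open region coordinates.
#' @return band-range string.
#' @export
band_range_name <- function(map, chrom, start, end) {
  chrom <- norm_chrom(chrom)
  b <- map$bands[map$bands$chrom == chrom & map$bands$end > start &
                   map$bands$start < end, , drop = FALSE]
  if (nrow(b) == 0L) stop("no cytobands overlap ", chrom, ":", start, "-", end)
  first <- paste0(chrom, b$band[1])
  if (nrow(b) == 1L) return(first)
  paste0(first, "-", chrom, b$band[nrow(b)])
}
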