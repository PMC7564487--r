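# DNA-index (DI) ploidy classification. DI = 1.0 is DNA diploid.

# Interval endpoints follow the flow-cytometric convention used in the
# source assay, with boundaries assigned to the more benign class: diploid
# is the closed interval [0.9, 1.1], aneuploid is open at 1.1 and 1.8.
DI_INTERVALS <- list(
  diploid = c(0.9, 1.1),
  haploid = c(0.5, 0.6),
  tetraploid = c(1.8, 2.2),
  aneuploid_low = c(0.6, 0.9),
  aneuploid_high = c(1.1, 1.8))

classify_single_di <- function(d) {
  if (d >= 0.9 && d <= 1.1) "diploid"
  else if ((d >= 0.6 && d < 0.9) || (d > 1.1 && d < 1.8)) "aneuploid"
  else if (d >= 0.5 && d < 0.6) "haploid"
  else if (d >= 1.8 && d <= 2.2) "tetraploid"
  else "unclassifiable"
}

#' Classify DNA-index ploidy
#'
#' A case with two or more distinct DNA indices is DNA multiploid; a
#' single DI classifies by interval: \[0.9, 1.1\] diploid, \[0.6, 0.9) or
#' (1.1, 1.8) aneuploid, \[0.5, 0.6) haploid, \[1.8, 2.2\] tetraploid,
#' outside \[0.5, 2.2\] unclassifiable. "Distinct" means separated by more
#' than `distinct_gap` (flow-cytometric CV scale; exact floating-point
#' equality would be meaningless).
#'
#' @param dis numeric vector of DNA indices (> 0), at least one.
#' @param distinct_gap minimum separation for two DIs to count as distinct
#'   (default 0.05).
#' @return one of "diploid", "aneuploid", "haploid", "tetraploid",
#'   "multiploid", "unclassifiable".
#' @export
classify_ploidy <- function(dis, distinct_gap = 0.05) {
  if (length(dis) == 0L) stop("empty DNA index list")
  stopifnot(all(dis > 0))
  ds <- sort(dis)
  # cluster DIs closer than the gap; >= 2 clusters is multiploidy
  if (length(ds) > 1L && any(diff(ds) > distinct_gap)) return("multiploid")
  classify_single_di(mean(ds))
}
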