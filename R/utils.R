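# Shared helpers: chromosome ordering, seeding, rounding.

#' Canonical chromosome order
#'
#' Human chromosomes in genome order: "1".."22", "X", "Y". Chromosome names
#' are handled bare internally; "chr" prefixes are accepted on input and
#' added back on output.
#'
#' @return Character vector of the 24 chromosome names.
#' @export
chrom_levels <- function() c(as.character(1:22), "X", "Y")

#' Strip/add "chr" prefixes
#' @param x character vector of chromosome names.
#' @return normalized bare names ("1", "X", ...).
#' @keywords internal
norm_chrom <- function(x) sub("^chr", "", as.character(x))

#' @keywords internal
ucsc_chrom <- function(x) paste0("chr", norm_chrom(x))

#' @keywords internal
chrom_rank <- function(x) match(norm_chrom(x), chrom_levels())

#' Derive a stage seed from a global seed
#'
#' A single run seed fans out to per-stage seeds through a fixed integer
#' recurrence so stages can be re-run independently yet reproducibly. All
#' derived seeds stay below 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param stage integer stage counter (>= 0).
#' @return integer seed for the stage.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stage))
  m <- 2147483647
  s <- (abs(as.numeric(seed)) %% m)
  as.integer((s * 48271 + 12345 + as.numeric(stage) * 65537) %% m)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. seed = NULL runs in the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Round-half-up percent rendering
#'
#' Renders a fraction as an integer percent with ties rounded away from
#' zero (so 54.5% renders as 55, not 54 as banker's rounding would give).
#'
#' @param p fraction in \[0, 1\] (may be NA).
#' @param digits decimal digits to keep (default 0).
#' @return numeric percent value.
#' @export
percent_render <- function(p, digits = 0) {
  scale <- 10^digits
  ifelse(is.na(p), NA_real_, floor(p * 100 * scale + 0.5) / scale)
}
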