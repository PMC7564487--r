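test_that("region matrix slices chromosomes at the union of breakpoints", {
  probes <- toy_probes(100)
  # sample A breaks after probe 50, sample B after probe 70
  calls <- list(
    A = toy_calls("1", c(0L, 50L, 100L), c("loss", "normal"),
                  means = c(-0.7, 0)),
    B = toy_calls("1", c(0L, 70L, 100L), c("normal", "gain"),
                  means = c(0, 0.5)))
  rm_ <- build_region_matrix(calls, probes)
  expect_equal(nrow(rm_$regions), 3L)
  expect_equal(rm_$regions$istart, c(1L, 51L, 71L))
  expect_equal(rm_$regions$iend, c(50L, 70L, 100L))
  expect_identical(rm_$state["A", ], c("loss", "normal", "normal"))
  expect_identical(rm_$state["B", ], c("normal", "normal", "gain"))
  expect_equal(rm_$value["A", ], c(-0.7, 0, 0))
  # identical single breakpoints: two regions
  calls2 <- list(
    A = toy_calls("1", c(0L, 50L, 100L), c("loss", "normal")),
    B = toy_calls("1", c(0L, 50L, 100L), c("normal", "normal")))
  expect_equal(nrow(build_region_matrix(calls2, probes)$regions), 2L)
  # no calls anywhere: single all-normal region per chromosome
  calls3 <- list(A = toy_calls("1", c(0L, 100L), "normal"))
  rm3 <- build_region_matrix(calls3, probes)
  expect_true(all(rm3$state == "normal"))
})

test_that("rank-sum p-values match exact small-sample arithmetic", {
  # one extreme assignment out of C(6,3) = 20, doubled
  expect_equal(rank_sum_p(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(rank_sum_p(c(1, 1), c(1, 1)), 1)
})

test_that("rank-sum p equals full enumeration for all small groups", {
  set.seed(404)
  for (rep in 1:20) {
    n1 <- sample(2:8, 1)
    n2 <- sample(2:8, 1)
    x <- round(rnorm(n1), 6)
    y <- round(rnorm(n2, sample(c(0, 1), 1)), 6)
    expect_equal(rank_sum_p(x, y), oracle_wilcoxon_p(x, y),
                 tolerance = 1e-12,
                 info = sprintf("rep %d (n1=%d n2=%d)", rep, n1, n2))
  }
})

test_that("rank-sum p is invariant under monotone transforms", {
  set.seed(77)
  x <- rnorm(12)
  y <- rnorm(15, 0.5)
  for (f in list(function(v) exp(v), function(v) v^3,
                 function(v) 5 * v - 2)) {
    expect_equal(rank_sum_p(x, y), rank_sum_p(f(x), f(y)))
  }
})

test_that("region ranking separates an implanted discriminating region", {
  probes <- toy_probes(100)
  mk <- function(state, mean_ab) {
    if (state == "none")
      toy_calls("1", c(0L, 100L), "normal", means = 0)
    else
      toy_calls("1", c(0L, 40L, 60L, 100L), c("normal", "loss", "normal"),
                means = c(0, mean_ab, 0))
  }
  set.seed(9)
  calls <- c(
    setNames(lapply(1:6, function(i) mk("none", 0)), paste0("fa", 1:6)),
    setNames(lapply(1:6, function(i)
      if (i <= 4) mk("loss", -0.7 + rnorm(1, 0, 0.01))
      else mk("none", 0)), paste0("tc", 1:6)))
  # add tiny jitter so values are tie-free
  for (s in names(calls)) calls[[s]]$seg_mean <-
    calls[[s]]$seg_mean + rnorm(nrow(calls[[s]]), 0, 1e-4)
  labels <- setNames(rep(c("cFA", "cFTC"), each = 6), names(calls))
  rm_ <- build_region_matrix(calls, probes)
  ranked <- rank_regions(rm_, labels)
  top <- ranked[1, ]
  expect_equal(c(top$istart, top$iend), c(41L, 60L))
  expect_identical(top$direction, "loss")
  expect_setequal(top$coverage[[1]], paste0("tc", 1:4))
  expect_true(top$cfa_all_normal)
  expect_lt(top$p, ranked$p[2])
})

test_that("greedy selection solves the covering example and the filters", {
  mk_row <- function(id, start, p, cov, cfa_ok = TRUE) {
    data.frame(chrom = "1", start = start, end = start + 10,
               istart = 1L, iend = 2L, p = p, direction = "loss",
               n_cov = length(cov), cfa_all_normal = cfa_ok,
               coverage = I(list(cov)), stringsAsFactors = FALSE)
  }
  ranked <- rbind(
    mk_row("A", 0, 0.001, c("t1", "t2", "t3")),
    mk_row("B", 100, 0.002, c("t3", "t4")),
    mk_row("C", 200, 0.003, c("t4")))
  sel <- select_minimal_markers(ranked, min_coverage = 1)
  expect_equal(sel$start, c(0, 100))           # A then B, never C
  expect_equal(sel$cum_cov, c(3L, 4L))
  expect_equal(oracle_min_cover_size(list(c("t1", "t2", "t3"),
                                          c("t3", "t4"), "t4")), 2L)
  # a region aberrant in any cFA can never be selected
  ranked2 <- rbind(mk_row("A", 0, 1e-6, c("t1", "t2", "t3", "t4"),
                          cfa_ok = FALSE),
                   mk_row("B", 100, 0.5, c("t1", "t2")))
  sel2 <- select_minimal_markers(ranked2, min_coverage = 1)
  expect_equal(sel2$start, 100)
  expect_true(all(sel2$cfa_all_normal))
  # nothing passes: empty result with a warning
  expect_warning(
    sel3 <- select_minimal_markers(ranked2[1, , drop = FALSE],
                                   min_coverage = 1),
    "no candidate")
  expect_equal(nrow(sel3), 0L)
  # single candidate covering everything: selected alone
  sel4 <- select_minimal_markers(ranked[1, , drop = FALSE],
                                 min_coverage = 1)
  expect_equal(nrow(sel4), 1L)
})

test_that("the optional raw-p gate is honored when requested", {
  mk_row <- function(start, p, cov) {
    data.frame(chrom = "1", start = start, end = start + 10,
               istart = 1L, iend = 2L, p = p, direction = "loss",
               n_cov = length(cov), cfa_all_normal = TRUE,
               coverage = I(list(cov)), stringsAsFactors = FALSE)
  }
  ranked <- rbind(mk_row(0, 0.2, c("t1", "t2")),
                  mk_row(100, 0.01, c("t3", "t4")))
  sel <- select_minimal_markers(ranked, p_threshold = 0.05)
  expect_equal(sel$start, 100)
})

test_that("minimal common regions intersect carrier intervals", {
  one <- data.frame(chrom = "1", start = 10, end = 100)
  expect_equal(minimal_common_region(one),
               list(chrom = "1", start = 10, end = 100))
  two <- data.frame(chrom = "1", start = c(0, 50), end = c(100, 150))
  expect_equal(minimal_common_region(two)[c("start", "end")],
               list(start = 50, end = 100))
  disjoint <- data.frame(sample_id = c("s1", "s2"), chrom = "1",
                         start = c(0, 120), end = c(100, 150))
  expect_error(minimal_common_region(disjoint), "s2")
})

test_that("jittered carrier breakpoints still contain the common region", {
  probes <- toy_probes(200)
  set.seed(31)
  calls <- list()
  truth_lo <- 50L
  truth_hi <- 120L
  for (i in 1:5) {
    lo <- truth_lo - sample(0:5, 1)
    hi <- truth_hi + sample(0:5, 1)
    calls[[paste0("s", i)]] <-
      toy_calls("1", c(0L, lo, hi, 200L), c("normal", "loss", "normal"),
                means = c(0, -0.7, 0))
  }
  ivs <- do.call(rbind, lapply(names(calls), function(s) {
    sg <- calls[[s]]
    ab <- sg[sg$state == "loss", ]
    data.frame(sample_id = s, chrom = "1", start = ab$start, end = ab$end)
  }))
  mcr <- minimal_common_region(ivs)
  # the intersection is contained in every carrier's call
  for (s in names(calls)) {
    ab <- calls[[s]][calls[[s]]$state == "loss", ]
    expect_true(mcr$start >= ab$start && mcr$end <= ab$end)
  }
  expect_equal(mcr$start, max(ivs$start))
  expect_equal(mcr$end, min(ivs$end))
})

test_that("selected markers refine to the carriers' common region", {
  probes <- toy_probes(100)
  # three carriers share a loss of probes 31..70; one unrelated sample
  # contributes a breakpoint at probe 50 that slices the region grid
  calls <- list(
    t1 = toy_calls("1", c(0L, 30L, 70L, 100L), c("normal", "loss",
                                                 "normal"),
                   means = c(0.001, -0.71, 0.002)),
    t2 = toy_calls("1", c(0L, 30L, 70L, 100L), c("normal", "loss",
                                                 "normal"),
                   means = c(-0.001, -0.72, 0.001)),
    t3 = toy_calls("1", c(0L, 30L, 70L, 100L), c("normal", "loss",
                                                 "normal"),
                   means = c(0.002, -0.69, -0.002)),
    fa1 = toy_calls("1", c(0L, 50L, 100L), c("normal", "normal"),
                    means = c(0.0005, -0.0005)),
    fa2 = toy_calls("1", c(0L, 100L), "normal", means = 0.0001))
  labels <- c(t1 = "cFTC", t2 = "cFTC", t3 = "cFTC",
              fa1 = "cFA", fa2 = "cFA")
  rm_ <- build_region_matrix(calls, probes)
  ranked <- rank_regions(rm_, labels)
  sel <- select_minimal_markers(ranked, min_coverage = 2)
  expect_gte(nrow(sel), 1L)
  mcr <- refine_marker_mcr(calls, sel[1, ])
  expect_equal(mcr$start, probes$start[31])
  expect_equal(mcr$end, probes$end[70])
})
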