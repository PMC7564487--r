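test_that("normalization centers and is stable on GC-flat input", {
  # constant GC: the GC step is skipped, centering is exact
  expect_warning(v <- normalize_profile(rep(0.3, 20), rep(0.5, 20)),
                 "constant")
  expect_equal(v, rep(0, 20))
  # an already-centered, GC-independent profile passes through unchanged
  x <- rep(c(-0.1, 0.1), 10)
  expect_warning(v2 <- normalize_profile(x, rep(0.45, 20)))
  expect_equal(v2, x, tolerance = 1e-9)
})

test_that("an implanted GC trend and dye offset are removed", {
  probes <- toy_probes(800, gc_seed = 7L)
  base <- withr::with_seed(11L, rnorm(800, 0, 0.1))
  raw <- base + 0.5 * (probes$gc - mean(probes$gc)) + 0.3
  v <- normalize_profile(raw, probes$gc)
  expect_lt(abs(cor(v, probes$gc)), 0.05)
  expect_lt(abs(median(v)), 1e-9)
})

test_that("centering can be anchored on a probe subset", {
  probes <- toy_probes(100)
  raw <- c(rep(0.5, 60), rep(0, 40))  # large aberration in the first block
  idx <- 61:100
  suppressWarnings(v <- normalize_profile(raw, rep(0.5, 100),
                                          center_idx = idx))
  expect_equal(median(v[idx]), 0)
  expect_equal(unique(v[1:60]), 0.5)
})

test_that("profile noise is the quartered median consecutive distance", {
  # |diffs| = 0.1, 0.3, 0.2 -> tau = median 0.2 / 4
  x <- c(0, 0.1, 0.4, 0.2)
  expect_equal(profile_noise(x, rep("1", 4)), 0.05)
  # constant profile: tau 0, floor takes over downstream
  expect_equal(profile_noise(rep(1, 10), rep("1", 10)), 0)
  # alternating +-d: all diffs 2d, tau = d/2
  d <- 0.3
  expect_equal(profile_noise(rep(c(d, -d), 8), rep("1", 16)), d / 2)
  expect_error(profile_noise(1, "1"), "at least 2")
})

test_that("noise never crosses chromosome boundaries", {
  # big inter-chromosome jump must not enter the median
  x <- c(0, 0.1, 0.2, 5, 5.1, 5.2)
  chrom <- rep(c("1", "2"), each = 3)
  expect_equal(profile_noise(x, chrom), 0.1 / 4)
})

test_that("aberration calls honor amplitude threshold and probe minimum", {
  segs <- data.frame(chrom = "1", start = c(0, 2e5, 7e5),
                     end = c(2e5, 7e5, 10e5),
                     num_probes = c(2L, 5L, 3L),
                     seg_mean = c(1.0, 0.4, -0.1),
                     istart = c(1L, 3L, 8L), iend = c(2L, 7L, 10L))
  out <- call_aberrations(segs, tau = 0.2, call_config(floor = 0.05))
  # 2-probe segment at +1.0 is never called; 5-probe +0.4 is a gain;
  # -0.1 sits inside the +-0.2 noise band
  expect_identical(out$state, c("normal", "gain", "normal"))
  expect_equal(unique(out$threshold), 0.2)
  # flat profile: no calls at all
  flat <- data.frame(chrom = "1", start = 0, end = 1e6, num_probes = 10L,
                     seg_mean = 0, istart = 1L, iend = 10L)
  expect_identical(call_aberrations(flat, 0, call_config())$state,
                   "normal")
})

test_that("raising the threshold floor never creates a call", {
  segs <- withr::with_seed(5L, data.frame(
    chrom = "1", start = (0:19) * 1e6, end = (1:20) * 1e6,
    num_probes = sample(1:8, 20, TRUE),
    seg_mean = rnorm(20, 0, 0.3),
    istart = 1:20, iend = 1:20))
  floors <- c(0.01, 0.05, 0.1, 0.2, 0.5)
  called_sets <- lapply(floors, function(fl) {
    out <- call_aberrations(segs, tau = 0.02, call_config(floor = fl))
    which(out$state != "normal")
  })
  for (i in seq_along(floors)[-1])
    expect_true(all(called_sets[[i]] %in% called_sets[[i - 1]]))
})

test_that("a constant chromosome yields exactly one segment", {
  probes <- toy_probes(100)
  segs <- segment_profile(rep(0.25, 100), probes, call_config(),
                          seed = 1)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$seg_mean, 0.25)
  expect_equal(segs$num_probes, 100L)
})

test_that("a two-change-point shift is recovered near the truth", {
  probes <- toy_probes(300)
  x <- withr::with_seed(23L, rnorm(300, 0, 0.1))
  x[101:200] <- x[101:200] - 1
  segs <- segment_profile(x, probes, call_config(), seed = 11)
  expect_equal(nrow(segs), 3L)
  cps <- segs$iend[1:2]
  expect_true(all(abs(cps - c(100, 200)) <= 2))
  # and the exhaustive least-squares oracle agrees
  ls <- oracle_two_changepoints(x)
  expect_equal(cps, ls)
})

test_that("segments partition every profile with exact means", {
  probes <- toy_probes(60)
  for (s in 1:5) {
    x <- withr::with_seed(100L + s, {
      x0 <- rnorm(60, 0, 0.15)
      if (s %% 2 == 0) x0[20:40] <- x0[20:40] + 0.8
      x0
    })
    segs <- segment_profile(x, probes, call_config(), seed = s)
    expect_equal(segs$istart[1], 1L)
    expect_equal(segs$iend[nrow(segs)], 60L)
    if (nrow(segs) > 1)
      expect_equal(segs$istart[-1], segs$iend[-nrow(segs)] + 1L)
    for (r in seq_len(nrow(segs)))
      expect_equal(segs$seg_mean[r], mean(x[segs$istart[r]:segs$iend[r]]),
                   tolerance = 1e-12)
  }
})

test_that("segmentation is deterministic for a fixed seed", {
  probes <- toy_probes(150)
  x <- withr::with_seed(3L, rnorm(150, 0, 0.1))
  x[50:90] <- x[50:90] + 0.7
  s1 <- segment_profile(x, probes, call_config(), seed = 42)
  s2 <- segment_profile(x, probes, call_config(), seed = 42)
  expect_identical(s1, s2)
})

test_that("undersized chromosomes fall back to one segment with warning", {
  probes <- rbind(toy_probes(3, chrom = "1"), toy_probes(3, chrom = "2"))
  probes$probe_id <- paste0(probes$probe_id, "_", probes$chrom)
  w <- capture_warnings(
    segs <- segment_profile(rep(0, 6), probes,
                            call_config(min_width = 2), seed = 1))
  expect_length(w, 2L)  # both 3-probe chromosomes fall back
  expect_match(w, "single segment", all = TRUE)
  expect_equal(nrow(segs), 2L)
})

test_that("per-probe class frequencies count covering calls", {
  probes <- toy_probes(30)
  calls <- list(
    a = toy_calls("1", c(0L, 9L, 20L, 30L), c("normal", "gain", "normal")),
    b = toy_calls("1", c(0L, 9L, 20L, 30L), c("normal", "gain", "normal")),
    c = toy_calls("1", c(0L, 15L, 30L), c("loss", "normal")),
    d = toy_calls("1", c(0L, 30L), "normal"))
  labels <- c(a = "cFTC", b = "cFTC", c = "cFTC", d = "cFA")
  ft <- frequency_table(calls, probes, labels)
  expect_equal(ft$gain_cFTC[10], 2 / 3)
  expect_equal(ft$gain_cFTC[25], 0)
  expect_equal(ft$loss_cFTC[1], 1 / 3)
  expect_true(all(ft$gain_cFTC + ft$loss_cFTC <= 1))
  expect_true(all(ft$gain_cFA == 0 & ft$loss_cFA == 0))
  # single sample, single gain: fraction 1 on its probes, 0 elsewhere
  ft1 <- frequency_table(calls["a"], probes, labels)
  expect_equal(unique(ft1$gain_cFTC[10:20]), 1)
  expect_equal(unique(ft1$gain_cFTC[c(1:9, 21:30)]), 0)
})

test_that("ward clustering separates clean groups and orders merges", {
  mat <- rbind(g1a = c(0, 0, 0), g1b = c(0, 0, 0.01),
               g2a = c(1, 1, 1), g2b = c(1, 1, 0.99))
  cl <- cluster_samples(mat, "euclidean", k = 2)
  expect_equal(unname(cl$cluster["g1a"]), unname(cl$cluster["g1b"]))
  expect_equal(unname(cl$cluster["g2a"]), unname(cl$cluster["g2b"]))
  expect_false(cl$cluster[["g1a"]] == cl$cluster[["g2a"]])
  # hand-computed Ward merge order on 1-d points 0, 0.1, 10, 10.2:
  # (1,2) first (d = .1), then (3,4) (d = .2), then the two pairs
  m <- cluster_samples(cbind(c(0, 0.1, 10, 10.2)), "euclidean", k = 2)
  expect_equal(m$hclust$merge[1, ], c(-1, -2))
  expect_equal(m$hclust$merge[2, ], c(-3, -4))
  expect_equal(m$hclust$merge[3, ], c(1, 2))
})

test_that("pearson distance handles zero-variance samples explicitly", {
  mat <- rbind(a = c(0, 0, 0), b = c(1, 2, 3), c = c(1.1, 2, 2.9))
  expect_warning(cl <- cluster_samples(mat, "pearson", k = 2),
                 "zero-variance")
  # the two correlated profiles merge first; the flat sample sits at the
  # maximal distance 2 from both
  expect_equal(sort(cl$hclust$merge[1, ]), c(-3, -2))
  expect_equal(unname(cl$cluster["b"]), unname(cl$cluster["c"]))
  expect_false(cl$cluster[["a"]] == cl$cluster[["b"]])
})
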