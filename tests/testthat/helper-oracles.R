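# Independent reference implementations ("oracles") used to cross-check the
# package's algorithms on small inputs. Everything here is written naively
# (explicit loops, exhaustive enumeration) and stays independent of the code
# paths it checks; the CBS oracle shares only the definition of the scan
# order and sequential decision rule so that the seeded permutation streams
# coincide.

# ---- circular binary segmentation ----------------------------------------

# Plain-double prefix sums (R's cumsum accumulates in extended precision;
# the arithmetic here must match ordinary double accumulation bit for bit).
plain_prefix <- function(x) {
  n <- length(x)
  S <- numeric(n + 1)
  for (t in seq_len(n)) S[t + 1] <- S[t] + x[t]
  S
}

# Naive max arc statistic: scan arcs in (k ascending, i ascending) order,
# strict > comparison, exactly as the compiled kernel defines.
oracle_max_arc <- function(x, min_width) {
  n <- length(x)
  S <- plain_prefix(x)
  xbar <- S[n + 1] / n
  best <- -1
  bi <- -1L
  bj <- -1L
  if (min_width < 1) min_width <- 1L
  if (n >= 2 * min_width) {
    for (k in min_width:(n - min_width)) {
      w <- n / (k * (n - k))
      kc <- k * xbar
      for (i in 0:(n - k)) {
        if (i == 0 && k == n) next
        num <- (S[i + k + 1] - S[i + 1]) - kc
        t2 <- num * num * w
        if (t2 > best) {
          best <- t2
          bi <- i
          bj <- i + k
        }
      }
    }
  }
  list(stat2 = best, i = bi, j = bj)
}

# Does any arc of x reach the reference statistic? Same arithmetic as the
# compiled early-exit scan (limit in the |num| domain).
oracle_exceeds <- function(x, min_width, ref) {
  n <- length(x)
  S <- plain_prefix(x)
  xbar <- S[n + 1] / n
  if (min_width < 1) min_width <- 1L
  for (k in min_width:(n - min_width)) {
    w <- n / (k * (n - k))
    kc <- k * xbar
    lim <- sqrt(ref / w)
    for (i in 0:(n - k)) {
      if (i == 0 && k == n) next
      num <- (S[i + k + 1] - S[i + 1]) - kc
      if (num >= lim || -num >= lim) return(TRUE)
    }
  }
  FALSE
}

# Sequential permutation decision, replicated from its documented
# definition: draw sample.int(n) permutations one at a time; stop-reject
# once the final p is guaranteed >= alpha or the Clopper-Pearson lower
# bound on the exceedance probability passes alpha; stop-accept once the
# upper bound falls below alpha; cap at nperm.
oracle_perm_decide <- function(x, stat2, cfg) {
  n <- length(x)
  e <- 0L
  m <- 0L
  e_stop <- ceiling(cfg$alpha * (1 + cfg$nperm) - 1)
  repeat {
    perm <- sample.int(n)
    m <- m + 1L
    if (oracle_exceeds(x[perm], cfg$min_width, stat2)) e <- e + 1L
    if (e >= e_stop) return(FALSE)
    if (e > 0 && qbeta(cfg$stop_delta, e, m - e + 1) > cfg$alpha)
      return(FALSE)
    if (e < m && qbeta(1 - cfg$stop_delta, e + 1, m - e) < cfg$alpha)
      return(TRUE)
    if (m >= cfg$nperm) return((1 + e) / (1 + m) < cfg$alpha)
  }
}

# Full recursive CBS by brute force: every split located by the naive scan,
# every decision by the naive sequential rule, recursion depth-first into
# sub-segments in genome order. Returns sorted change-point indices (cut
# after these positions).
oracle_cbs <- function(x, cfg) {
  cps <- integer(0)
  recurse <- function(lo, hi) {
    n <- hi - lo + 1L
    if (n < 2L * cfg$min_width) return(invisible(NULL))
    res <- oracle_max_arc(x[lo:hi], cfg$min_width)
    if (res$i < 0) return(invisible(NULL))
    if (!oracle_perm_decide(x[lo:hi], res$stat2, cfg))
      return(invisible(NULL))
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

# Exhaustive two-change-point least-squares fit: minimize the residual sum
# of squares over all 3-piece partitions of x.
oracle_two_changepoints <- function(x) {
  n <- length(x)
  S <- c(0, cumsum(x))
  Q <- c(0, cumsum(x^2))
  sse <- function(a, b) {
    (Q[b + 1] - Q[a + 1]) - (S[b + 1] - S[a + 1])^2 / (b - a)
  }
  best <- Inf
  arg <- c(NA, NA)
  for (a in 1:(n - 2)) {
    for (b in (a + 1):(n - 1)) {
      v <- sse(0, a) + sse(a, b) + sse(b, n)
      if (v < best) {
        best <- v
        arg <- c(a, b)
      }
    }
  }
  arg
}

# ---- Wilcoxon rank-sum ---------------------------------------------------

# Exact two-sided rank-sum p by full enumeration of all C(n1+n2, n1) label
# assignments (no ties), using the same two-sided convention as the
# standard exact test: double the smaller tail at the observed U, capped
# at 1.
oracle_wilcoxon_p <- function(x, y) {
  ux <- function(xx, yy) sum(outer(xx, yy, ">"))
  u_obs <- ux(x, y)
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  us <- apply(idx, 2, function(ii) ux(pooled[ii], pooled[-ii]))
  mu <- n1 * length(y) / 2
  p <- if (u_obs > mu) 2 * mean(us >= u_obs) else 2 * mean(us <= u_obs)
  min(1, p)
}

# ---- minimum set cover ---------------------------------------------------

# Smallest family of candidate sets covering the union of all candidates,
# by exhaustive subset search. Returns the minimum cardinality.
oracle_min_cover_size <- function(sets) {
  universe <- sort(unique(unlist(sets)))
  if (length(universe) == 0L) return(0L)
  for (size in seq_along(sets)) {
    for (pick in utils::combn(length(sets), size, simplify = FALSE)) {
      if (setequal(intersect(unique(unlist(sets[pick])), universe),
                   universe))
        return(size)
    }
  }
  length(sets)
}

# ---- Clopper-Pearson -----------------------------------------------------

# Exact binomial interval by direct tail inversion (uniroot on the
# binomial tail probabilities), independent of the beta-quantile form.
oracle_clopper_pearson <- function(x, n, conf = 0.95) {
  a <- (1 - conf) / 2
  lo <- if (x == 0) 0 else
    uniroot(function(p) pbinom(x - 1, n, p, lower.tail = FALSE) - a,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  hi <- if (x == n) 1 else
    uniroot(function(p) pbinom(x, n, p) - a,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(lo, hi)
}
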