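test_that("gc_correct removes an exact linear GC wave", {
  gc <- seq(0.3, 0.7, length.out = 50)
  lrr <- 0.8 * gc
  p <- array_profile("s", "chr1", 1:50, lrr, gc_fraction = gc)
  out <- gc_correct(p)
  expect_equal(out$lrr, rep(median(lrr), 50), tolerance = 1e-12)
})

test_that("gc_correct is a no-op (with warning) at zero GC variance", {
  lrr <- rnorm(20)
  p <- array_profile("s", "chr1", 1:20, lrr, gc_fraction = rep(0.4, 20))
  expect_warning(out <- gc_correct(p), "zero variance")
  expect_equal(out$lrr, lrr)
})

test_that("gc_correct leaves GC-independent profiles essentially unchanged", {
  set.seed(32)
  n <- 1000
  gc <- runif(n, 0.3, 0.7)
  lrr <- rnorm(n, 0, 0.2)
  p <- array_profile("s", "chr1", 1:n, lrr, gc_fraction = gc)
  fit <- lm(lrr ~ gc)
  expect_lt(abs(coef(fit)[2]), 0.05)
  out <- gc_correct(p)
  expect_lt(max(abs(out$lrr - lrr)), 0.06)
  expect_error(gc_correct(array_profile("s", "chr1", 1:20, rnorm(20))),
               "gc_fraction")
})

test_that("arc_statistic matches the two-sample t statistic", {
  x <- c(1, 2, 4, 2, 1, 5, 2, 3)
  o <- abs(t.test(x[3:5], x[-(3:5)], var.equal = TRUE)$statistic)
  expect_equal(arc_statistic(x, 2, 5), unname(o), tolerance = 1e-12)
  # zero pooled variance conventions
  expect_equal(arc_statistic(rep(1, 6), 2, 4), 0)
  expect_equal(arc_statistic(c(0, 0, 0, 1, 1, 1), 3, 6), Inf)
  expect_error(arc_statistic(x, 0, 8), "proper subset")
})

test_that("arc_statistic agrees with an exhaustive t-test oracle at n=20", {
  set.seed(5)
  y <- rnorm(20)
  for (i in 0:19) {
    for (j in (i + 1):20) {
      if (j - i >= 20) next
      o <- abs(t.test(y[(i + 1):j], y[-((i + 1):j)],
                      var.equal = TRUE)$statistic)
      expect_equal(arc_statistic(y, i, j), unname(o), tolerance = 1e-12)
    }
  }
})

test_that("max_arc finds the step boundaries and equals the R oracle", {
  x <- c(rep(0, 10), rep(-0.5, 10))
  m <- max_arc(x)
  o <- oracle_max_arc(x)
  expect_equal(m$i, o$i)
  expect_equal(m$j, o$j)
  expect_true(10 %in% c(m$i, m$j))  # the split lands on the step
  expect_equal(max_arc(rep(2, 15))$t_max, 0)
  set.seed(17)
  for (k in 1:5) {
    y <- rnorm(12)
    m <- max_arc(y)
    o <- oracle_max_arc(y)
    expect_equal(m$t_max, o$t, tolerance = 1e-12)
    expect_equal(c(m$i, m$j), c(o$i, o$j))
  }
})

test_that("max_arc breaks ties toward the lexicographically smallest arc", {
  # integer-valued data where several partitions tie exactly in floating
  # point (all group sums are exact integers)
  x <- c(1, 2, 0, 2, 0)
  n <- length(x)
  scores <- list()
  for (i in 0:(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      scores[[length(scores) + 1L]] <- c(i, j, arc_statistic(x, i, j))
    }
  }
  sc <- do.call(rbind, scores)
  top <- sc[sc[, 3] == max(sc[, 3]), , drop = FALSE]
  expect_gte(nrow(top), 2L)  # a genuine tie exists
  m <- max_arc(x)
  expect_equal(m$t_max, max(sc[, 3]))
  expect_equal(c(m$i, m$j), unname(top[1L, 1:2]))
})

test_that("permutation_pvalue degenerate cases and determinism", {
  expect_equal(permutation_pvalue(rep(1, 10), 0, nperm = 200), 1)
  x <- rnorm(12)
  t_obs <- max_arc(x)$t_max
  p1 <- permutation_pvalue(x, t_obs, nperm = 500, seed = 9)
  p2 <- permutation_pvalue(x, t_obs, nperm = 500, seed = 9)
  expect_identical(p1, p2)
  expect_gt(p1, 0)
  expect_lte(p1, 1)
})

test_that("permutation_pvalue matches the exhaustive permutation null at n=6", {
  x <- c(0.3, -0.2, 1.1, 0.9, 1.4, 0.1)
  t_obs <- max_arc(x)$t_max
  perms <- enumerate_permutations(seq_along(x))
  tm <- vapply(perms, function(p) max_arc(x[p])$t_max, 0)
  exact <- mean(tm >= t_obs)
  nperm <- 4000
  est <- permutation_pvalue(x, t_obs, nperm = nperm, seed = 99)
  se <- sqrt(exact * (1 - exact) / nperm)
  expect_lt(abs(est - exact), 3 * se + 1 / (nperm + 1))
})

test_that("cbs_segment handles constant, step, and sub-threshold profiles", {
  params <- segmentation_params(nperm = 500, seed = 3)
  p <- array_profile("s", "chr1", 1:100, rep(0.3, 100))
  s <- cbs_segment(p, params)
  expect_equal(nrow(s), 1L)
  expect_equal(s$n_markers, 100L)
  expect_equal(s$mean_lrr, 0.3)

  x <- c(rep(0, 50), rep(-1, 50))
  s <- cbs_segment(array_profile("s", "chr1", 1:100, x), params)
  expect_equal(nrow(s), 2L)
  expect_equal(s$mean_lrr, c(0, -1))
  expect_equal(s$copy_value, c(2, 1))
  expect_equal(s$start_idx, c(0L, 50L))

  # a 3-probe dip stays below the 5-marker detection cut-off
  x2 <- rep(0, 100)
  x2[40:42] <- -1
  s <- cbs_segment(array_profile("s", "chr1", 1:100, x2), params)
  expect_equal(nrow(s), 1L)
  expect_error(cbs_segment(array_profile("s", "chr1", numeric(0),
                                         numeric(0)), params), "empty")
})

test_that("segments partition the probe range and are idempotent", {
  params <- segmentation_params(nperm = 500, seed = 11)
  set.seed(23)
  for (k in 1:5) {
    n <- 120
    x <- rnorm(n, 0, 0.15)
    cut <- sort(sample(20:100, 2))
    x[cut[1]:cut[2]] <- x[cut[1]:cut[2]] - 1
    s <- cbs_segment(array_profile("s", "chr1", 1:n, x), params)
    expect_equal(s$start_idx[1], 0L)
    expect_equal(s$end_idx[nrow(s)], n)
    if (nrow(s) > 1) {
      expect_equal(s$start_idx[-1], s$end_idx[-nrow(s)])
    }
    expect_equal(sum(s$n_markers), n)
    # idempotence on the piecewise-constant reconstruction
    recon <- rep(s$mean_lrr, s$n_markers)
    s2 <- cbs_segment(array_profile("s", "chr1", 1:n, recon), params)
    expect_equal(s2$start_idx, s$start_idx)
    expect_equal(s2$end_idx, s$end_idx)
  }
})
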