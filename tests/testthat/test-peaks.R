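test_that("peak calling finds threshold runs and drops singletons", {
  pk <- as.data.frame(call_peaks(ratio_track(c(1, 6, 7, 1))))
  expect_equal(nrow(pk), 1)
  expect_equal(pk$direction, "increased")
  expect_equal(c(pk$first_probe, pk$last_probe), c(2, 3))

  ## an isolated above-cutoff probe is background noise
  expect_equal(nrow(as.data.frame(call_peaks(ratio_track(c(1, 9, 1))))), 0)

  dn <- as.data.frame(call_peaks(ratio_track(c(0.1, 0.1, 0.1))))
  expect_equal(dn$direction, "decreased")
  expect_equal(dn$n_probes, 3)

  ## inclusive thresholds
  at <- as.data.frame(call_peaks(ratio_track(c(5, 5, 1, 0.2, 0.2))))
  expect_equal(at$direction, c("increased", "decreased"))
})

test_that("max_gap bridges short sub-threshold stretches", {
  v <- c(6, 6, 1, 6, 6)
  expect_equal(nrow(as.data.frame(call_peaks(ratio_track(v)))), 2)
  gap1 <- as.data.frame(call_peaks(ratio_track(v), max_gap = 1))
  expect_equal(nrow(gap1), 1)
  expect_equal(gap1$n_probes, 5)
})

test_that("runs crossing the origin of a circular genome merge", {
  v <- c(7, 6, 1, 1, 1, 1, 1, 1, 6, 7)
  pk <- as.data.frame(call_peaks(ratio_track(v, circular = TRUE)))
  expect_equal(nrow(pk), 1)
  expect_true(pk$wraps)
  expect_equal(pk$n_probes, 4)
  expect_equal(c(pk$first_probe, pk$last_probe), c(9, 2))
  ## the same values on a linear axis give two separate peaks
  expect_equal(nrow(as.data.frame(call_peaks(ratio_track(v)))), 2)
})

test_that("peak calling matches exhaustive run enumeration", {
  set.seed(42)
  for (rep in 1:200) {
    m <- sample(5:50, 1)
    v <- exp(rnorm(m, 0, 1.6))
    pk <- as.data.frame(call_peaks(ratio_track(v)))
    up <- oracle_runs(v >= 5, 2)
    dn <- oracle_runs(v <= 0.2, 2)
    expect_equal(nrow(pk), length(up) + length(dn))
    for (dir in c("increased", "decreased")) {
      want <- if (dir == "increased") up else dn
      got <- pk[pk$direction == dir, c("first_probe", "last_probe")]
      got <- got[order(got$first_probe), ]
      expect_equal(unlist(Map(c, got$first_probe, got$last_probe)),
                   unlist(want), ignore_attr = TRUE)
    }
  }
})

test_that("peak counts are monotone in the cutoffs", {
  set.seed(11)
  v <- exp(rnorm(200, 0, 1.5))
  tr <- ratio_track(v)
  n_up <- vapply(c(2, 3, 5, 8, 12), function(cu) {
    sum(as.data.frame(call_peaks(tr, cutoff_up = cu))$direction ==
          "increased")
  }, numeric(1))
  expect_true(all(diff(n_up) <= 0))
  n_dn <- vapply(c(0.05, 0.1, 0.2, 0.4), function(cd) {
    sum(as.data.frame(call_peaks(tr, cutoff_down = cd))$direction ==
          "decreased")
  }, numeric(1))
  expect_true(all(diff(n_dn) >= 0))
})

test_that("same-direction peaks never overlap and cover every run", {
  set.seed(3)
  for (rep in 1:50) {
    v <- exp(rnorm(80, 0, 1.6))
    pk <- as.data.frame(call_peaks(ratio_track(v)))
    for (dir in c("increased", "decreased")) {
      p <- pk[pk$direction == dir, ]
      if (nrow(p) > 1) {
        p <- p[order(p$first_probe), ]
        expect_true(all(p$first_probe[-1] > p$last_probe[-nrow(p)]))
      }
    }
  }
})

test_that("combined levels follow the documented quantification formulas", {
  g <- linear_grid(4)
  mk <- function(v) occupancy_track(c(1, v, 1), g)
  pk <- call_peaks(occupancy_track(c(1, 9, 9, 1), g, "ratio"))

  lv <- function(wt, mut, method) {
    as.data.frame(quantify_peaks(pk, mk(wt), mk(mut), method))$level
  }
  expect_equal(lv(c(10, 10), c(50, 50), "ratio-of-sums"), 5)
  expect_equal(lv(c(10, 10), c(10, 10), "ratio-of-sums"), 1)
  expect_equal(lv(c(10, 10), c(10, 10), "sum-ratio"), 1)
  ## the two methods agree on flat wild-type signal and diverge otherwise
  expect_equal(lv(c(10, 10), c(30, 90), "ratio-of-sums"), 6)
  expect_equal(lv(c(10, 10), c(30, 90), "sum-ratio"), 6)
  expect_equal(lv(c(10, 30), c(30, 90), "ratio-of-sums"), 3)
  expect_equal(lv(c(10, 30), c(30, 90), "sum-ratio"), 3)
  expect_equal(lv(c(30, 10), c(30, 90), "ratio-of-sums"), 3)
  expect_equal(lv(c(30, 10), c(30, 90), "sum-ratio"), 5)

  expect_error(quantify_peaks(pk, mk(c(0, 0)), mk(c(1, 1))), "zero")
})

test_that("ranking orders tables the way occupancy lists are printed", {
  pk <- data.frame(level = c(5.1, 82.5, 11.0), start = c(10, 20, 30),
                   direction = "increased")
  expect_equal(rank_peaks(pk, "increased")$level, c(82.5, 11.0, 5.1))
  dn <- data.frame(level = c(0.10, 0.012, 0.02), start = c(5, 10, 15),
                   direction = "decreased")
  expect_equal(rank_peaks(dn, "decreased")$level, c(0.012, 0.02, 0.10))
  tie <- data.frame(level = c(7, 7), start = c(500, 100),
                    direction = "increased")
  expect_equal(rank_peaks(tie, "increased")$start, c(100, 500))
  expect_error(rank_peaks(data.frame(level = NA_real_, start = 1,
                                     direction = "increased"),
                          "increased"), "quantified")
})
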