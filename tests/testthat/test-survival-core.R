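test_that("event tables count deaths and at-risk subjects correctly", {
  et <- buildEventTable(c(2, 4, 4, 6), c(1, 1, 0, 1))
  expect_equal(eventTimes(et), c(2, 4, 6))
  expect_equal(nDeaths(et), c(1L, 1L, 1L))
  expect_equal(nAtRisk(et), c(4L, 3L, 1L))

  expect_length(eventTimes(buildEventTable(c(5, 9), c(0, 0))), 0)

  et1 <- buildEventTable(5, 1)
  expect_equal(eventTimes(et1), 5)
  expect_equal(nDeaths(et1), 1L)
  expect_equal(nAtRisk(et1), 1L)

  expect_error(buildEventTable(c(-1, 2), c(1, 1)), ">= 0")
  expect_error(buildEventTable(c(1, 2), 1), "equal length")
})

test_that("Kaplan-Meier estimate is the running product over event times", {
  km <- kmEstimate(buildEventTable(c(2, 4, 4, 6), c(1, 1, 0, 1)))
  expect_equal(curveAt(km, c(1, 2, 4, 6, 10)), c(1, 0.75, 0.5, 0, 0))

  expect_equal(curveAt(kmEstimate(buildEventTable(c(3, 4), c(0, 0))), 5), 1)

  # single death among n at risk: S drops to (n-1)/n
  km1 <- kmEstimate(buildEventTable(c(5, 7, 9, 11), c(1, 0, 0, 0)))
  expect_equal(curveAt(km1, 5), 3 / 4)
})

test_that("KM on fully uncensored samples equals the empirical survival function", {
  set.seed(11)
  for (rep in 1:40) {
    n <- sample(2:8, 1)
    dur <- sample(1:5, n, replace = TRUE)  # ties likely
    km <- kmEstimate(buildEventTable(dur, rep(1, n)))
    for (t in 0:6)
      expect_equal(curveAt(km, t), mean(dur > t))
  }
})

test_that("Nelson-Aalen is the running sum and is bounded by -log KM", {
  na <- naEstimate(buildEventTable(c(2, 4, 4, 6), c(1, 1, 0, 1)))
  expect_equal(curveAt(na, c(2, 4, 6)), c(1/4, 1/4 + 1/3, 1/4 + 1/3 + 1))

  expect_equal(curveAt(naEstimate(buildEventTable(3, 0)), 9), 0)

  set.seed(7)
  for (rep in 1:20) {
    arm <- simArm(30, 1 / 500)
    et <- buildEventTable(arm$durations, arm$events)
    km <- kmEstimate(et); na <- naEstimate(et)
    s <- km@estimate; h <- na@estimate
    ok <- s > 0
    expect_true(all(-log(s[ok]) >= h[ok] - 1e-12))
  }
})

test_that("log-rank test matches the hand-evaluated example and its symmetries", {
  lr <- logrankTest(c(1, 2), c(1, 1), c(3, 4), c(1, 1))
  expect_equal(lr@observed[["A"]] - lr@expected[["A"]], 7 / 6)
  expect_equal(lr@variance, 17 / 36)
  expect_equal(lr@z, 7 / sqrt(17))
  expect_equal(lr@p.value, pchisq(49 / 17, 1, lower.tail = FALSE))

  # identical groups: Z = 0, p = 1
  same <- logrankTest(c(1, 2, 3), c(1, 0, 1), c(1, 2, 3), c(1, 0, 1))
  expect_equal(same@z, 0)
  expect_equal(same@p.value, 1)

  # antisymmetry under swapping
  a <- simArm(20, 1 / 300); b <- simArm(20, 1 / 600)
  f <- logrankTest(a$durations, a$events, b$durations, b$events)
  r <- logrankTest(b$durations, b$events, a$durations, a$events)
  expect_equal(f@z, -r@z)
  expect_equal(f@p.value, r@p.value)

  # no events at all: degenerate
  d <- logrankTest(c(1, 2), c(0, 0), c(3, 4), c(0, 0))
  expect_true(d@degenerate)
  expect_equal(c(d@z, d@p.value), c(0, 1))
})

test_that("log-rank agrees with survival::survdiff across random datasets", {
  skip_if_not_installed("survival")
  set.seed(21)
  for (rep in 1:10) {
    a <- simArm(25, 1 / 300); b <- simArm(30, 1 / 500)
    dur <- c(a$durations, b$durations)
    ev <- as.integer(c(a$events, b$events))
    g <- rep(1:2, c(25, 30))
    sd <- survival::survdiff(survival::Surv(dur, ev) ~ g)
    lr <- logrankTest(a$durations, a$events, b$durations, b$events)
    expect_equal(lr@z^2, sd$chisq, tolerance = 1e-10)
    expect_equal(unname(lr@observed), unname(sd$obs), tolerance = 1e-10)
    expect_equal(unname(lr@expected), unname(sd$exp), tolerance = 1e-10)
  }
})

test_that("O/E hazard ratio reproduces hand-summed expected counts", {
  expect_equal(hazardRatio(c(1, 2), c(1, 1), c(3, 4), c(1, 1)), 19 / 5)

  # identical event experience gives HR = 1
  expect_equal(hazardRatio(c(1, 2, 3), c(1, 1, 0), c(1, 2, 3), c(1, 1, 0)), 1)

  # swapping gives the reciprocal
  a <- simArm(30, 1 / 200); b <- simArm(30, 1 / 500)
  h1 <- hazardRatio(a$durations, a$events, b$durations, b$events)
  h2 <- hazardRatio(b$durations, b$events, a$durations, a$events)
  expect_equal(h1, 1 / h2)

  # group A leaves risk before any event: zero expected events
  expect_warning(r <- hazardRatio(0.5, 0, c(1, 2), c(1, 1)),
                 "undefined")
  expect_true(is.na(r))
  expect_error(hazardRatio(numeric(0), logical(0), 1, 1), "at least one")
})

test_that("median split sends ties low and flags degenerate markers", {
  s <- medianSplit(c(s1 = 1, s2 = 2, s3 = 3, s4 = 4))
  expect_equal(s$low, c("s1", "s2"))
  expect_equal(s$high, c("s3", "s4"))

  s3 <- medianSplit(c(s1 = 1, s2 = 2, s3 = 3))
  expect_equal(s3$low, c("s1", "s2"))
  expect_equal(s3$high, "s3")

  d <- medianSplit(c(5, 5, 5, 5))
  expect_true(d$degenerate)
  expect_length(d$high, 0)

  expect_error(medianSplit(3), "at least 2")

  # always a partition; imbalance bounded by the number of median ties
  set.seed(5)
  for (rep in 1:30) {
    v <- sample(1:6, sample(2:12, 1), replace = TRUE)
    names(v) <- paste0("x", seq_along(v))
    sp <- medianSplit(v)
    expect_setequal(c(sp$low, sp$high), names(v))
    expect_lte(abs(length(sp$low) - length(sp$high)),
               sum(v == stats::median(v)) + 1)
  }
})

test_that("prevalence filter keeps the 60% boundary inclusive", {
  m <- rbind(keep6 = c(rep(1, 6), rep(0, 4)),
             drop5 = c(rep(1, 5), rep(0, 5)),
             zero = rep(0, 10))
  colnames(m) <- paste0("s", 1:10)
  kept <- filterMirnas(m, 0.6)
  expect_equal(rownames(kept), "keep6")
  expect_error(filterMirnas(m, 0), "in \\(0, 1\\]")
  expect_error(filterMirnas(m, 1.2), "in \\(0, 1\\]")
})

test_that("null log-rank rejection rate is nominal", {
  set.seed(99)
  rej <- 0; nSim <- 300
  for (i in seq_len(nSim)) {
    a <- simArm(50, 1 / 800); b <- simArm(50, 1 / 800)
    lr <- logrankTest(a$durations, a$events, b$durations, b$events)
    rej <- rej + (lr@p.value < 0.05)
  }
  expect_lt(abs(rej / nSim - 0.05), 0.03)
})
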