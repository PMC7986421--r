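test_that("competence threshold is the reference's day-0 fitted total", {
  panel <- generate_panel(default_archetypes(),
                          noise_spec(sigma_log = 0, detection_floor = 0),
                          seed = 1)
  fits <- fit_panel(panel)
  # the threshold is exactly the reference total fit's day-0 value ...
  thr <- competence_threshold(fits, "Westar_like")
  ref_fit <- fits$fits[["Westar_like:total"]]
  expect_identical(thr, ref_fit$a + ref_fit$c)
  # ... and close to the generating day-0 total of 75 (a single
  # exponential approximates the 9-paralogue sum, not exactly)
  expect_equal(thr, 75, tolerance = 0.02)
  expect_equal(competence_threshold(override = 100), 100)
  expect_error(competence_threshold(fits, "nonesuch"), "reference")
})

test_that("single-trajectory crossing matches the closed form", {
  expect_equal(crossing_time(c(a = 75, b = -0.1, c = 0), 75), 0)
  expect_equal(crossing_time(c(a = 300, b = -0.1, c = 100), 75), Inf)
  expect_equal(crossing_time(c(a = 300, b = 0.01, c = 0), 75), Inf)
  expect_equal(crossing_time(c(a = 300, b = -0.05, c = 0), 75),
               log(4) / 0.05, tolerance = 1e-10)
  expect_equal(crossing_time(c(a = 300, b = -0.05, c = 0), 75), 27.726,
               tolerance = 1e-3)
  expect_error(crossing_time(c(a = NaN, b = -1, c = 0), 75), "finite")
})

test_that("summed crossing reduces to the single case and censors correctly", {
  # one paralogue carrying everything equals the closed form
  t1 <- crossing_time_total(c(p = 300), c(p = -0.05), threshold = 75)
  expect_equal(t1, log(4) / 0.05, tolerance = 1e-5)

  # no decay above threshold: unbounded
  expect_equal(crossing_time_total(c(p = 100, q = 50), c(p = 0, q = 0),
                                   threshold = 75), Inf)

  # two-term sum agrees with a fine-grid scan oracle
  total <- function(t) 200 * exp(-0.1 * t) + 100 * exp(-0.01 * t)
  tt <- crossing_time_total(c(p = 200, q = 100), c(p = -0.1, q = -0.01),
                            threshold = 75)
  grid <- seq(0, 365, by = 1e-4)
  oracle <- grid[which(total(grid) <= 75)[1]]
  expect_equal(tt, oracle, tolerance = 1e-3)

  expect_error(crossing_time_total(c(p = -1), c(p = -0.1), threshold = 75),
               "non-negative")
  expect_error(crossing_time_total(c(p = 10), c(q = -0.1), threshold = 75),
               "no rate")
})

test_that("scenario rates pool fitted rates as specified", {
  tab <- data.frame(
    accession = rep(c("s1", "w1"), each = 2),
    target = rep(c("pA", "pB"), 2),
    model = "M1",
    a = 100, b = c(-0.10, -0.02, -0.06, -0.04), c = 0, sse = 1,
    n_obs = 24, flags = "", stringsAsFactors = FALSE)
  fits <- structure(list(fits = list(), table = tab), class = "decay_fit_panel")
  ct <- c(acc1 = "spring", acc2 = "winter")

  common <- build_scenario_rates(fits, "common", crop_type_map = ct)
  expect_true(all(common == mean(tab$b)))

  per <- build_scenario_rates(fits, "paralogue", crop_type_map = ct)
  expect_equal(unname(per["acc1", "pA"]), mean(c(-0.10, -0.06)))
  expect_equal(unname(per["acc1", "pB"]), mean(c(-0.02, -0.04)))
  expect_equal(per["acc1", ], per["acc2", ])

  ext <- build_scenario_rates(fits, "extreme", crop_type_map = ct)
  # low-requirement accession gets the fastest (min) rate per paralogue
  expect_equal(unname(ext["acc1", "pA"]), -0.10)
  expect_equal(unname(ext["acc2", "pA"]), -0.06)
  expect_equal(unname(ext["acc1", "pB"]), -0.04)
  expect_equal(unname(ext["acc2", "pB"]), -0.02)

  # degenerate fits are excluded; an all-degenerate paralogue falls back
  tab2 <- tab
  tab2$flags[tab2$target == "pB"] <- "degenerate"
  fits2 <- structure(list(fits = list(), table = tab2),
                     class = "decay_fit_panel")
  per2 <- build_scenario_rates(fits2, "paralogue", crop_type_map = ct)
  expect_equal(unname(per2["acc1", "pB"]), mean(c(-0.10, -0.06)))
  expect_identical(attr(per2, "fallback"), "pB")

  expect_error(build_scenario_rates(fits, "extreme"), "crop_type_map")
})

test_that("requirement predictions follow the threshold and rates", {
  rates <- matrix(-0.05, 3, 2,
                  dimnames = list(c("low", "same1", "same2"), c("pA", "pB")))
  attr(rates, "scenario") <- "common"
  prevern <- rbind(low = c(pA = 30, pB = 30),
                   same1 = c(pA = 100, pB = 100),
                   same2 = c(pA = 100, pB = 100))
  pred <- predict_requirements(prevern, rates, threshold = 75)
  expect_equal(pred$crossing_day[pred$accession == "low"], 0)
  # identical accessions get identical predictions
  expect_equal(pred$crossing_day[pred$accession == "same1"],
               pred$crossing_day[pred$accession == "same2"])

  # planted fast/slow rank order is preserved
  set.seed(4)
  n <- 10
  prev2 <- matrix(200, 2 * n, 1,
                  dimnames = list(paste0("a", 1:(2 * n)), "pA"))
  rates2 <- matrix(rep(c(-0.2, -0.02), each = n), 2 * n, 1,
                   dimnames = dimnames(prev2))
  pred2 <- predict_requirements(prev2, rates2, threshold = 75)
  fast <- pred2$crossing_day[1:n]; slow <- pred2$crossing_day[(n + 1):(2 * n)]
  expect_true(max(fast) < min(slow))

  expect_error(predict_requirements(prevern[, , drop = FALSE],
                                    rates[1:2, , drop = FALSE], 75),
               "no rates")
})

test_that("separation report counts overlap and censoring", {
  mk <- function(days, accs) {
    structure(data.frame(accession = accs, crossing_day = days,
                         censored = !is.finite(days), threshold = 75,
                         scenario = "common", stringsAsFactors = FALSE),
              class = c("vernalization_prediction", "data.frame"))
  }
  ct <- c(s1 = "spring", s2 = "spring", w1 = "winter", w2 = "winter")

  rep1 <- separation_report(mk(c(10, 20, 30, 40), names(ct)), ct)
  expect_equal(rep1$overlap, 0)
  rep2 <- separation_report(mk(c(10, 50, 30, 40), names(ct)), ct)
  expect_equal(rep2$overlap, 2)
  rep3 <- separation_report(mk(c(10, 20, Inf, Inf), names(ct)), ct)
  expect_equal(rep3$overlap, 0)
  expect_equal(rep3$n_censored, 2)
  expect_error(separation_report(mk(1:4, names(ct)),
                                 c(ct[1:3], w2 = "alpine")), "unknown")
})

test_that("crossing times are monotone in rates and threshold", {
  set.seed(77)
  for (i in 1:25) {
    prev <- setNames(runif(3, 50, 200), c("p1", "p2", "p3"))
    b <- setNames(runif(3, -0.2, 0.02), names(prev))
    thr <- runif(1, 40, 120)
    t0 <- crossing_time_total(prev, b, threshold = thr)
    # more negative rate never delays crossing
    b2 <- b; b2[1] <- b2[1] - runif(1, 0, 0.1)
    t_faster <- crossing_time_total(prev, b2, threshold = thr)
    expect_lte(t_faster, t0 + 1e-5)
    # higher threshold never delays crossing
    t_easier <- crossing_time_total(prev, b, threshold = thr + 20)
    expect_lte(t_easier, t0 + 1e-5)
  }
})
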