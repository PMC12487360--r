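test_that("model evaluation matches the closed forms", {
  # logistic3 at its inflection returns half the asymptote
  expect_equal(eval_growth_model("logistic3", c(48.5, 0.0566, 113), 113),
               24.25)
  # Gompertz approaches its asymptote
  expect_equal(eval_growth_model("gompertz", c(5, 3, 0.1), 1e6), 5)
  # logistic4 midpoint is (A - B)/2 + B
  expect_equal(eval_growth_model("logistic4", c(10, 2, 1, 0), 0), 6)
  expect_equal(eval_growth_model("linear", c(2, 1), c(0, 3)), c(1, 7))
  expect_equal(eval_growth_model("quadratic", c(1, 0, 1), 2), 5)
  expect_error(eval_growth_model("logistic3", c(1, 2), 0), "parameters")
  expect_error(eval_growth_model("logistic3", c(1, 2, NA), 0), "finite")
})

test_that("noiseless generate-then-fit round trips recover the truth", {
  y3 <- eval_growth_model("logistic3", c(40, 0.05, 110), ages_7)
  f3 <- fit_growth_curve("logistic3", ages_7, y3)
  expect_true(f3$converged)
  expect_equal(unname(f3$params), c(40, 0.05, 110), tolerance = 1e-4)

  yg <- eval_growth_model("gompertz", c(5, 3, 0.05), ages_7)
  fg <- fit_growth_curve("gompertz", ages_7, yg)
  expect_true(fg$converged)
  expect_equal(unname(fg$params), c(5, 3, 0.05), tolerance = 1e-4)

  y4 <- eval_growth_model("logistic4", c(14.3, 1.5, 0.109, 108), ages_7)
  f4 <- fit_growth_curve("logistic4", ages_7, y4)
  expect_equal(unname(f4$params), c(14.3, 1.5, 0.109, 108),
               tolerance = 1e-3)
})

test_that("two points determine a line exactly", {
  f <- fit_growth_curve("linear", c(0, 10), c(0, 5))
  expect_equal(unname(f$params), c(0.5, 0))
})

test_that("pinning a parameter at its true value leaves the others", {
  yg <- eval_growth_model("gompertz", c(5, 3, 0.05), ages_7)
  free <- fit_growth_curve("gompertz", ages_7, yg)
  pinned <- fit_growth_curve("gompertz", ages_7, yg, fixed = list(a = 5))
  expect_equal(pinned$params[c("b", "c")], free$params[c("b", "c")],
               tolerance = 1e-6)
  expect_equal(unname(pinned$params["a"]), 5)
})

test_that("degenerate inputs yield converged = FALSE, not an error", {
  flat <- fit_growth_curve("logistic3", ages_7, rep(3, 7))
  expect_false(flat$converged)
  expect_true(is.infinite(flat$bic))
  one_age <- fit_percent_of_adult(rep(100, 5), rep(50, 5))
  expect_false(one_age$converged)
  expect_error(fit_growth_curve("logistic3", 1:2, 1:2), "at least")
})

test_that("bounded LS matches a dense grid search on a small instance", {
  truth <- c(A = 20, Rg = 0.08, tmid = 115)
  set.seed(11)
  y <- eval_growth_model("logistic3", truth, ages_7) + rnorm(7, 0, 0.2)
  fit <- fit_growth_curve("logistic3", ages_7, y)
  grid <- expand.grid(A = seq(15, 25, by = 0.25),
                      Rg = seq(0.04, 0.12, by = 0.002),
                      tmid = seq(105, 125, by = 0.5))
  rss <- vapply(seq_len(nrow(grid)), function(i) {
    sum((y - eval_growth_model("logistic3", as.numeric(grid[i, ]),
                               ages_7))^2)
  }, numeric(1))
  best <- grid[which.min(rss), ]
  expect_lte(fit$rss, min(rss) + 1e-10)
  expect_equal(unname(fit$params["A"]), best$A, tolerance = 0.25 / 15)
  expect_equal(unname(fit$params["Rg"]), best$Rg, tolerance = 0.002 / 0.04)
  expect_equal(unname(fit$params["tmid"]), best$tmid, tolerance = 0.5 / 105)
})

test_that("BIC selects the generating family", {
  ages <- seq(85, 155, length.out = 40)
  set.seed(2)
  y_lin <- eval_growth_model("linear", c(0.5, 2), ages) +
    rnorm(40, 0, 1e-3 * 35)
  expect_identical(select_growth_model(ages, y_lin)$winner, "linear")
  # U-shaped (ventricle-like) series picks the quadratic
  y_quad <- eval_growth_model("quadratic", c(4.35, -0.0604, 2.6e-4), ages) +
    rnorm(40, 0, 1e-3)
  expect_identical(select_growth_model(ages, y_quad)$winner, "quadratic")
  expect_error(select_growth_model(1:5, 1:5), "at least 6")
})

test_that("selection rate is monotone as noise shrinks", {
  ages <- seq(85, 155, length.out = 60)
  y0 <- eval_growth_model("logistic3", c(48, 0.055, 115), ages)
  rng <- diff(range(y0))
  rate <- vapply(c(0.10, 0.01, 0.001), function(frac) {
    hits <- vapply(1:40, function(s) {
      set.seed(s)
      sel <- select_growth_model(ages, y0 + rnorm(60, 0, frac * rng))
      sel$winner == "logistic3"
    }, logical(1))
    mean(hits)
  }, numeric(1))
  expect_true(all(diff(rate) >= 0))
  expect_gte(rate[3], 0.95)
})

test_that("derived descriptors match their closed forms and invert", {
  g <- fit_growth_curve("gompertz", ages_7,
                        eval_growth_model("gompertz", c(exp(1), exp(1), 1),
                                          c(0.2, 0.5, 1, 1.5, 2, 3, 4)))
  # direct construction (fit not needed for the formula check)
  gfit <- structure(list(family = "gompertz",
                         params = c(a = exp(1), b = exp(1), c = 1),
                         converged = TRUE), class = "growth_fit")
  d <- derived_descriptors(gfit)
  expect_equal(d$t_mid, 1)
  expect_equal(d$r_max, 1)

  # printed brainstem descriptors invert to (b, c) and back
  p <- gompertz_from_descriptors(3.19, 0.0166, 135)
  expect_equal(unname(p["c"]), 0.014145, tolerance = 1e-4)
  expect_equal(unname(p["b"]), 6.751, tolerance = 1e-3)
  bfit <- structure(list(family = "gompertz", params = p, converged = TRUE),
                    class = "growth_fit")
  db <- derived_descriptors(bfit)
  expect_equal(db$r_max, 0.0166, tolerance = 1e-10)
  expect_equal(db$t_mid, 135, tolerance = 1e-10)

  # whole-brain female logistic3 row: r_max = A Rg / 4
  lfit <- structure(list(family = "logistic3",
                         params = c(A = 48.0, Rg = 0.0533, tmid = 116),
                         converged = TRUE), class = "growth_fit")
  dl <- derived_descriptors(lfit)
  expect_equal(dl$r_max, 0.6396, tolerance = 1e-6)
  expect_equal(dl$t_mid, 116)

  expect_error(derived_descriptors(
    fit_growth_curve("linear", c(0, 10), c(0, 5))), "sigmoid")
})

test_that("descriptor inversion round-trips on random valid triples", {
  set.seed(5)
  for (i in 1:20) {
    a <- runif(1, 1, 50); r_max <- runif(1, 0.01, 1); tm <- runif(1, 50, 200)
    p <- gompertz_from_descriptors(a, r_max, tm)
    fit <- structure(list(family = "gompertz", params = p, converged = TRUE),
                     class = "growth_fit")
    d <- derived_descriptors(fit)
    expect_equal(d$asymptote, a, tolerance = 1e-10)
    expect_equal(d$r_max, r_max, tolerance = 1e-10)
    expect_equal(d$t_mid, tm, tolerance = 1e-8)
  }
})

test_that("percent-of-adult fits pin the asymptote at 100", {
  y <- eval_growth_model("logistic3", c(100, 0.1484, 135), ages_7)
  f <- fit_percent_of_adult(ages_7, y)
  expect_equal(unname(f$params["A"]), 100)
  expect_equal(unname(f$params["Rg"]), 0.1484, tolerance = 1e-4)
  expect_equal(f$r_max_percent_per_day, 3.71, tolerance = 1e-3)
})

test_that("an inflection beyond the sampled range is still recovered", {
  truth <- c(100, 0.05, 175)  # cerebellum-like: maximal growth after birth
  y0 <- eval_growth_model("logistic3", truth, ages_7)
  errs <- vapply(1:20, function(s) {
    set.seed(s)
    f <- fit_percent_of_adult(ages_7, y0 * (1 + rnorm(7, 0, 0.01)))
    abs(f$params[["tmid"]] - 175)
  }, numeric(1))
  expect_lt(median(errs), 5)
})

test_that("overshooting percent values trigger the warning", {
  expect_warning(fit_percent_of_adult(ages_7, c(40, 55, 70, 85, 95, 105, 115)),
                 "exceeds 110")
})
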