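make_tables <- function() {
  cases <- data.frame(
    site_id = rep(c("a", "b"), each = 3),
    year = rep(2001:2003, 2),
    cases = c(0, 2, 1, 5, 0, 7))
  py <- data.frame(
    site_id = rep(c("a", "b"), each = 3),
    year = rep(2001:2003, 2),
    person_years = c(4000, 4100, 3900, 9000, 9100, 8900))
  list(cases = cases, py = py)
}

test_that("pooled rate sums over years before dividing", {
  tb <- make_tables()
  out <- pooledRate(tb$cases, tb$py)
  # loop oracle: explicit per-year accumulation
  for (id in c("a", "b")) {
    sc <- 0; sp <- 0
    for (yr in 2001:2003) {
      sc <- sc + tb$cases$cases[tb$cases$site_id == id & tb$cases$year == yr]
      sp <- sp + tb$py$person_years[tb$py$site_id == id & tb$py$year == yr]
    }
    expect_equal(out$rate[out$site_id == id], 1000 * sc / sp)
  }
  expect_equal(pooledRate(data.frame(site_id = "a", cases = 0),
                          data.frame(site_id = "a", person_years = 1e4))$rate, 0)
  expect_equal(pooledRate(data.frame(site_id = "a", cases = 50),
                          data.frame(site_id = "a", person_years = 1e4))$rate, 5)
})

test_that("pooled rate is invariant to re-binning years and linear in scale", {
  tb <- make_tables()
  out1 <- pooledRate(tb$cases, tb$py)
  split_cases <- rbind(tb$cases,
                       data.frame(site_id = "a", year = 2004, cases = 0))
  split_cases$cases[2] <- 1   # split year 2002's 2 cases into 1 + 1
  split_cases <- rbind(split_cases,
                       data.frame(site_id = "a", year = 2005, cases = 1))
  split_py <- rbind(tb$py,
                    data.frame(site_id = "a", year = 2004:2005,
                               person_years = c(1, 1)))
  split_py$person_years[2] <- 4098   # move 2 person-years into the new rows
  out2 <- pooledRate(split_cases, split_py)
  expect_equal(out2$rate[out2$site_id == "a"],
               out1$rate[out1$site_id == "a"])
  out5 <- pooledRate(tb$cases, tb$py, scale = 100000)
  expect_equal(out5$rate, out1$rate * 100)
})

test_that("pooled rate names the offending site on missing or bad denominators", {
  tb <- make_tables()
  expect_error(pooledRate(tb$cases, tb$py[tb$py$site_id == "a", ]),
               "site\\(s\\): b")
  expect_error(pooledRate(data.frame(site_id = "a", cases = -1),
                          data.frame(site_id = "a", person_years = 10)),
               "nonnegative")
})

test_that("sex-specific responses demand sex-specific denominators", {
  cases <- data.frame(site_id = c("a", "a"), sex = c("male", "female"),
                      cases = c(3, 4))
  py <- data.frame(site_id = c("a", "a"), sex = c("male", "female"),
                   person_years = c(1000, 1100))
  out <- pooledRate(cases, py, sex_filter = "male")
  expect_equal(out$rate, 3)
  py_all <- data.frame(site_id = "a", person_years = 2100)
  expect_error(pooledRate(cases, py_all, sex_filter = "male"),
               "no sex column")
  # 'all' rows must not double-count alongside sex-specific rows
  py_mix <- rbind(py, data.frame(site_id = "a", sex = "all",
                                 person_years = 2100))
  expect_error(pooledRate(cases, py_mix, sex_filter = "all"), "mixes")
})

test_that("KS normality gate holds its level and has power", {
  reject_null <- logical(100); reject_exp <- logical(100)
  for (r in 1:100) {
    set.seed(5000 + r)
    reject_null[r] <- ksNormality(rnorm(500))$reject
    reject_exp[r] <- ksNormality(rexp(500))$reject
  }
  expect_gte(mean(!reject_null), 0.90)
  expect_gte(mean(reject_exp), 0.99)
  expect_error(ksNormality(rep(1, 10)), "constant")
  expect_error(ksNormality(1:4), "at least 5")
  # plain variant runs and returns the same shape
  set.seed(1)
  out <- ksNormality(rnorm(100), method = "plain")
  expect_named(out, c("p", "statistic", "reject", "method"))
})

test_that("response preparation applies the log10 gate as specified", {
  set.seed(42)
  normal_rates <- abs(rnorm(200, 10, 1))
  r1 <- prepareResponse(normal_rates)
  expect_equal(r1$transform, "none")
  expect_equal(r1$value, normal_rates)

  r2 <- prepareResponse(c(1, 10, 100, 2, 20, 50), transform = "always")
  expect_equal(r2$value[1:3], c(0, 1, 2))
  expect_equal(r2$transform, "log10")

  # strongly right-skewed rates: transformed, and more often normal after
  improved <- 0
  for (r in 1:30) {
    set.seed(6000 + r)
    skewed <- rlnorm(200, 1, 0.8)
    resp <- prepareResponse(skewed)
    expect_equal(resp$transform, "log10")
    improved <- improved +
      (ksNormality(resp$value)$p > ksNormality(skewed)$p)
  }
  expect_gt(improved / 30, 0.5)
})

test_that("zero rates under log10 error by default, offset on request", {
  rates <- c(0, 2, 3, 0.5, 8, 1, 4, 9, 0.2, 6)
  expect_error(prepareResponse(rates, transform = "always"), "zero pooled rate")
  expect_message(
    resp <- prepareResponse(rates, transform = "always",
                            zero_policy = "offset"),
    "offset")
  expect_equal(resp$offset, 0.1)
  expect_equal(resp$value[1], log10(0.1))
})
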