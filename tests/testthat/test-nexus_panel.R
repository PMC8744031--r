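make_panel <- function(...) {
  syn <- generate_transition_panel(years = 25, populations = 2, seed = 4,
                                   start_year = 1976)
  list(panel = build_panel(syn$tables, ...), syn = syn)
}

test_that("panel rows carry every index and follow the omega policy", {
  res <- make_panel()
  p <- res$panel
  expect_equal(nrow(p), 50)  # 2 populations x 25 years
  expect_true(all(c("e0", "AID", "G", "sigma", "CV", "edagger", "H",
                    "Gstar") %in% names(p)))
  expect_true(all(p$omega == 122))
  # fixed-omega normalized Gini is the row-wise correcting factor
  expect_equal(p$Gstar, p$G * 122 / (122 - p$e0), tolerance = 1e-12)
  # record-series policy: omega looked up per year (series must clear the
  # table's top age, so shift the synthetic record series upward)
  series <- transform(res$syn$record_series, omega = omega + 16)
  ps <- build_panel(res$syn$tables, omega_series = series)
  expect_equal(ps$omega, series$omega[match(ps$year, series$year)])
  expect_equal(ps$Gstar, ps$G * ps$omega / (ps$omega - ps$e0),
               tolerance = 1e-12)
  # an omega below the table's top age is rejected
  expect_error(build_panel(res$syn$tables, omega = 100), "omega policy")
})

test_that("every panel point lies on or below the maximal-inequality curve", {
  p <- make_panel()$panel
  for (idx in c("AID", "G", "sigma", "CV"))
    expect_true(all(p[[idx]] <= vapply(p$e0, function(e)
      max_index(idx, e, 122), numeric(1)) + 1e-9))
})

test_that("the ratio series divides e0 by the record lifespan", {
  res <- make_panel()
  r <- ratio_series(res$panel, res$syn$record_series)
  expect_equal(r$ratio, r$e0 / r$omega_record)
  # a modern life expectancy against the final record value
  one <- data.frame(population = "X", sex = "f", year = 2019, e0 = 84.7)
  expect_equal(ratio_series(one, data.frame(year = 2019,
                                            omega = 122.45))$ratio,
               0.6917, tolerance = 1e-4)
  expect_error(ratio_series(transform(res$panel, year = year + 1000),
                            res$syn$record_series), "missing year")
})

test_that("maximal-inequality curves have the documented shapes", {
  grid <- seq(1, 121, by = 0.5)
  a <- max_inequality_curve("AID", 122, grid)
  expect_equal(grid[which.max(a)], 61)
  g <- max_inequality_curve("G", 122, grid)
  expect_true(all(diff(g) < 0))  # straight line falling to 0 at omega
  expect_equal(max_inequality_curve("G", 122, 1e-12), 1, tolerance = 1e-9)
  expect_lt(max_inequality_curve("G", 122, 122 - 1e-9), 1e-10)
})

test_that("rolling correlations pool the window and flag degenerate ones", {
  # collinear index: r = -1 in every window
  years <- 2000:2009
  p <- data.frame(population = "X", sex = "f", year = years,
                  e0 = 60 + seq_along(years),
                  G = 0.5 - 0.01 * seq_along(years))
  rc <- rolling_correlation(p, "G", window = 5)
  expect_true(all(abs(rc$r + 1) < 1e-12))
  expect_equal(rc$n[rc$year == 2004], 5)
  # constant index: zero variance is reported, not computed
  p$G <- 0.3
  rc2 <- rolling_correlation(p, "G", window = 5)
  expect_true(all(is.na(rc2$r)))
  expect_match(rc2$diagnostic[1], "zero variance")
  # an index independent of e0 has correlation near zero
  set.seed(99)
  big <- data.frame(population = "X", sex = "f",
                    year = rep(2000:2004, each = 400),
                    e0 = stats::runif(2000, 50, 80),
                    G = stats::runif(2000, 0.1, 0.3))
  r0 <- rolling_correlation(big, "G", window = 5)
  expect_lt(max(abs(r0$r)), 0.1)
})

test_that("joint-change quadrants classify consecutive-year changes", {
  years <- 1980:1990
  p <- data.frame(population = "X", sex = "f", year = years,
                  e0 = 60 + seq_along(years),
                  G = 0.5 - 0.01 * seq_along(years))
  q <- joint_change_quadrants(p, "G", from_year = 1980)
  expect_equal(unname(q$shares["e0_up_index_down"]), 1)
  expect_equal(sum(q$shares), 1)
  expect_equal(q$ties, 0)
  # exact zero changes go to the tie margin, not a quadrant
  p2 <- p
  p2$G[2] <- p2$G[1]
  q2 <- joint_change_quadrants(p2, "G", from_year = 1980)
  expect_equal(q2$ties, 1)
  expect_equal(sum(q2$counts), q2$n_pairs - q2$ties)
  # log-change option
  ql <- joint_change_quadrants(p, "G", from_year = 1980, change = "log")
  expect_equal(unname(ql$shares["e0_up_index_down"]), 1)
  expect_error(joint_change_quadrants(p, "G", from_year = 2050), "no consec")
})

test_that("on the synthetic transition the longevity-inequality link is negative", {
  p <- make_panel()$panel
  expect_lt(stats::cor(p$e0, p$G), -0.9)
  q <- joint_change_quadrants(p, "G", from_year = 1976)
  expect_gt(unname(q$shares["e0_up_index_down"]), 0.9)
})
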