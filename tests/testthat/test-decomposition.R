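siler_pair <- function(seed = 1, jitter = 0.3) {
  set.seed(seed)
  tweak <- function(p, f) siler_params(p$a1 * f[1], p$b1, p$a2 * f[2],
                                       p$a3 * f[3], p$b3)
  p1 <- tweak(siler_preset("modern"), exp(stats::rnorm(3, 0, jitter)))
  p2 <- tweak(siler_preset("modern"), exp(stats::rnorm(3, 0, jitter)))
  list(siler_lifetable(p1), siler_lifetable(p2))
}

test_that("the integration hot path matches the public index functions", {
  set.seed(77)
  lt0 <- siler_lifetable(siler_preset("modern"))
  for (i in 1:20) {
    mx <- lt0$mx * exp(stats::rnorm(length(lt0$mx), 0, 0.3))
    lt <- build_lifetable_from_mx(mx, ax = lt0$ax, radix = lt0$radix)
    for (idx in c("AID", "G", "sigma", "CV", "edagger", "H", "Gstar"))
      expect_equal(lifeineq:::.index_from_mx(mx, lt0$ax, idx, 122),
                   lifespan_index(lt, idx, 122), tolerance = 1e-10)
  }
})

test_that("identical inputs decompose to zero everywhere", {
  lt <- siler_lifetable(siler_preset("modern"))
  res <- horiuchi_decompose(lt, lt, "G")
  expect_equal(res$contributions, rep(0, length(lt$ages)))
  expect_equal(res$total_change, 0)
  expect_equal(res$residual, 0)
})

test_that("a single perturbed rate receives the whole index change", {
  lt1 <- siler_lifetable(siler_preset("modern"))
  mx2 <- lt1$mx
  mx2[41] <- mx2[41] * 2.5  # age 40
  lt2 <- build_lifetable_from_mx(mx2, ax = lt1$ax, radix = lt1$radix)
  for (idx in c("G", "Gstar")) {
    res <- horiuchi_decompose(lt1, lt2, idx, n_steps = 40)
    direct <- lifespan_index(lt2, idx, 122) - lifespan_index(lt1, idx, 122)
    expect_equal(sum(res$contributions != 0), 1)
    expect_equal(res$contributions[41], direct, tolerance = 1e-6)
  }
})

test_that("contributions add up to the index change and flip with the order", {
  pair <- siler_pair(seed = 21)
  for (idx in c("G", "Gstar", "AID", "sigma")) {
    res <- horiuchi_decompose(pair[[1]], pair[[2]], idx)
    expect_lt(abs(res$residual), 1e-4 * max(1, abs(res$total_change)))
    back <- horiuchi_decompose(pair[[2]], pair[[1]], idx)
    expect_equal(back$contributions, -res$contributions, tolerance = 1e-6)
  }
})

test_that("refining the path integration barely moves the contributions", {
  pair <- siler_pair(seed = 5)
  a <- horiuchi_decompose(pair[[1]], pair[[2]], "G", n_steps = 20)
  b <- horiuchi_decompose(pair[[1]], pair[[2]], "G", n_steps = 200)
  expect_lt(max(abs(a$contributions - b$contributions)), 1e-4)
})

test_that("old-age mortality decline raises inequality above the threshold age", {
  lt1 <- siler_lifetable(siler_preset("modern"))  # e0 near 79
  improve <- function(cut, fac = 0.6) {
    m <- lt1$mx
    m[lt1$ages >= cut] <- m[lt1$ages >= cut] * fac
    build_lifetable_from_mx(m, ax = lt1$ax, radix = lt1$radix)
  }
  # improvements confined to ages above the threshold age raise both
  # indices, age by age
  lt85 <- improve(85)
  very_old <- lt1$ages >= 85
  for (idx in c("G", "Gstar")) {
    res <- horiuchi_decompose(lt1, lt85, idx)
    expect_true(all(res$contributions[!very_old] == 0))
    expect_true(all(res$contributions[very_old] >= 0))
    expect_gt(res$total_change, 0)
  }
  # improvements from 65 up straddle the threshold age: reductions just
  # below it, increases above it, with the switch in between
  lt65 <- improve(65)
  res_g <- horiuchi_decompose(lt1, lt65, "G")
  res_gs <- horiuchi_decompose(lt1, lt65, "Gstar")
  for (res in list(res_g, res_gs)) {
    th <- threshold_age(res)
    expect_gt(th$age, 65)
    expect_lt(th$age, 90)
  }
  # the normalized index reacts more strongly above e0
  above_e0 <- lt1$ages >= 80
  expect_true(all(abs(res_gs$contributions[above_e0]) >=
                    abs(res_g$contributions[above_e0]) - 1e-12))
})

test_that("threshold age reports the final negative-to-positive switch", {
  res <- structure(list(ages = 0:3, contributions = c(-1, -1, 1, 1),
                        total_change = 0, residual = 0, n_steps = 2,
                        index = "G", omega = 122,
                        additive_ages = integer(0)),
                   class = "decomposition_result")
  th <- threshold_age(res)
  expect_equal(th$age, 2)
  expect_equal(th$sign_pattern, c(-1, -1, 1, 1))
  res$contributions <- c(-1, -2, -3, -1)
  expect_true(is.na(threshold_age(res)$age))
  expect_match(threshold_age(res)$diagnostic, "no negative-to-positive")
  # zeros are skipped when locating the switch
  res$contributions <- c(-1, 0, 0, 2)
  expect_equal(threshold_age(res)$age, 3)
  # a realistic mortality-decline pair has a mid-life threshold
  lt1 <- siler_lifetable(siler_preset("pretransition"))
  lt2 <- siler_lifetable(siler_preset("modern"))
  resG <- horiuchi_decompose(lt1, lt2, "G")
  thG <- threshold_age(resG)
  expect_false(is.na(thG$age))
  expect_gt(thG$age, 30)
  expect_lt(thG$age, 100)
})

test_that("grids must match and rate zeros fall back to the additive path", {
  lt1 <- siler_lifetable(siler_preset("modern"))
  lt3 <- build_lifetable_from_mx(lt1$mx[1:80], ax = lt1$ax[1:80])
  expect_error(horiuchi_decompose(lt1, lt3, "G"), "same age grid")
  mx0 <- lt1$mx; mx0[11] <- 0
  lt0 <- build_lifetable_from_mx(mx0, ax = lt1$ax)
  res <- horiuchi_decompose(lt0, lt1, "G")
  expect_equal(res$additive_ages, 10L)
  expect_lt(abs(res$residual), 1e-4 * max(1, abs(res$total_change)))
})
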