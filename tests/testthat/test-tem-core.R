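test_that("paired-difference TEM matches hand-computed values", {
  # identical pairs: no error, perfect reliability
  res <- intra_pair_tem(c(5, 7), c(5, 7))
  expect_equal(res$tem, 0)
  expect_equal(res$r, 1)

  # sum of squared differences 4 + 1 + 0 = 5 over 2N = 6
  res <- intra_pair_tem(c(10, 20, 30), c(12, 19, 30))
  expect_equal(res$tem, sqrt(5 / 6), tolerance = 1e-12)
  expect_equal(res$mean, mean(c(10, 20, 30, 12, 19, 30)))
  expect_equal(res$sd, sd(c(11, 19.5, 30)))
  expect_equal(res$percent_tem, 100 * res$tem / res$mean)
  expect_equal(res$k_observers, 1L)

  expect_error(intra_pair_tem(1, 2), "at least 2")
  expect_error(intra_pair_tem(c(1, NA), c(1, 2)), "finite")
  expect_error(intra_pair_tem(c(1, 2, 3), c(1, 2)), "same length")
})

test_that("multi-observer TEM matches hand-computed values and rejects bad input", {
  # one subject, values (1,2,3): sum M^2 = 14, (sum M)^2 / K = 12
  res <- multi_observer_tem(rbind(c(1, 2, 3)))
  expect_equal(res$tem, 1)
  expect_equal(res$k_observers, 3L)

  # rows of identical values carry no within-subject variance
  res <- multi_observer_tem(rbind(c(5, 5, 5), c(9, 9, 9)))
  expect_equal(res$tem, 0)
  expect_equal(res$r, 1)

  expect_error(multi_observer_tem(list(c(1, 2), c(1, 2, 3))), "ragged")
  expect_error(multi_observer_tem(cbind(1:3)), "at least 2 observers")
})

test_that("multi-observer TEM equals the root mean within-subject variance", {
  # independent oracle: within-subject sample variance via stats::var
  set.seed(7)
  for (i in 1:25) {
    n <- sample(1:6, 1)
    k <- sample(2:5, 1)
    m <- matrix(rnorm(n * k, 100, 10), n, k)
    oracle <- sqrt(mean(apply(m, 1, var)))
    expect_equal(multi_observer_tem(m)$tem, oracle, tolerance = 1e-12)
  }
})

test_that("two-observer TEM coincides with the paired-difference TEM", {
  set.seed(1)
  for (i in 1:30) {
    n <- sample(2:8, 1)
    a <- rnorm(n, 170, 8)
    b <- a + rnorm(n, 0, 0.7)
    pair <- intra_pair_tem(a, b)
    multi <- multi_observer_tem(cbind(a, b))
    expect_equal(multi$tem, pair$tem, tolerance = 1e-9)
    expect_equal(multi$percent_tem, pair$percent_tem, tolerance = 1e-9)
    expect_equal(multi$r_raw, pair$r_raw, tolerance = 1e-9)
  }
})

test_that("TEM is scale-equivariant; relative quantities are scale-free", {
  set.seed(2)
  a <- rnorm(6, 80, 9); b <- a + rnorm(6, 0, 1.2)
  for (c_mult in c(0.1, 3.7)) {
    r1 <- intra_pair_tem(a, b)
    r2 <- intra_pair_tem(c_mult * a, c_mult * b)
    expect_equal(r2$tem, c_mult * r1$tem, tolerance = 1e-12)
    expect_equal(r2$sd, c_mult * r1$sd, tolerance = 1e-12)
    expect_equal(r2$percent_tem, r1$percent_tem, tolerance = 1e-12)
    expect_equal(r2$cv, r1$cv, tolerance = 1e-12)
    expect_equal(r2$r_raw, r1$r_raw, tolerance = 1e-12)
  }
})

test_that("relative TEM and the 95% half-width evaluate correctly", {
  expect_equal(percent_tem(0, 50), 0)
  expect_equal(percent_tem(0.9, 170), 100 * 0.9 / 170)
  expect_equal(percent_tem(2, 80), 2.5)
  expect_error(percent_tem(1, 0), "> 0")
  expect_error(percent_tem(-1, 10), ">= 0")

  expect_equal(ci95_halfwidth(0), 0)
  expect_equal(ci95_halfwidth(0.51), 1.96 * sqrt(2) * 0.51)
  expect_equal(ci95_halfwidth(0.51), 1.4136, tolerance = 1e-4)
  expect_equal(ci95_halfwidth(3, 4), 9.8)
  expect_error(ci95_halfwidth(-1), ">= 0")
})

test_that("reliability coefficient works from both absolute and relative forms", {
  expect_equal(reliability_coefficient(tem = 0, sd = 2)$r, 1)
  # the mean cancels: (tem, sd) and (%TEM, CV) routes agree
  abs_form <- reliability_coefficient(tem = 1.5, sd = 4)
  rel_form <- reliability_coefficient(percent_tem = 100 * 1.5 / 80,
                                      cv = 4 / 80)
  expect_equal(abs_form$r_raw, rel_form$r_raw, tolerance = 1e-12)

  # heavily error-dominated skinfold: raw R negative, clamped to 0
  res <- reliability_coefficient(percent_tem = 83.7, cv = 0.64)
  expect_lt(res$r_raw, 0)
  expect_equal(res$r, 0)
  res <- reliability_coefficient(percent_tem = 18.8, cv = 0.62)
  expect_equal(res$r, 0.908, tolerance = 1e-3)

  expect_error(reliability_coefficient(tem = 1, sd = 0), "> 0")
  expect_error(reliability_coefficient(tem = 1), "supply either")
})

test_that("total TEM pools intra and inter components", {
  expect_equal(total_tem(c(0, 0, 0), 0)$total, 0)
  t <- 1.3
  expect_equal(total_tem(c(t, t, t), t)$total, t * sqrt(2), tolerance = 1e-12)
  expect_equal(total_tem(c(0.62, 0.90, 2.07), 0.90)$total, 1.623709,
               tolerance = 1e-6)
  expect_error(total_tem(numeric(0), 1), "at least one")
  expect_error(total_tem(c(1, -1), 1), ">= 0")

  # monotone, and never below either component class
  tt <- total_tem(c(0.5, 0.7), 0.6)
  expect_gte(tt$total, 0.6)
  expect_gte(tt$total, sqrt(mean(c(0.5, 0.7)^2)))
  expect_gt(total_tem(c(0.5, 0.9), 0.6)$total, tt$total)
  expect_gt(total_tem(c(0.5, 0.7), 0.8)$total, tt$total)
})
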