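test_that("the TEF table carries the standard potency groups", {
  tef <- tef_nisbet_lagoy()
  expect_equal(sort(names(tef)), sort(pah_congeners()))
  expect_equal(unname(tef[c("NAP", "ACP", "ACY", "FLU", "PHE", "PYR")]),
               rep(0.001, 6))
  expect_equal(unname(tef[c("ANT", "BgP", "CYR")]), rep(0.01, 3))
  expect_equal(unname(tef[c("BaA", "BbF", "BkF", "IcP")]), rep(0.1, 4))
  expect_equal(unname(tef[c("BaP", "DbA")]), c(1, 1))
  expect_equal(unname(tef["FLA"]), 0.001)
  expect_equal(unname(tef_nisbet_lagoy(fla = 0.05)["FLA"]), 0.05)
})

test_that("TEQ reproduces hand-summed weighted totals exactly", {
  expect_equal(teq(make_profile(BaP = 1)), 1.0, tolerance = 1e-12)
  expect_equal(teq(make_profile(DbA = 2)), 2.0, tolerance = 1e-12)
  expect_equal(teq(make_profile(NAP = 100, BaA = 10, BaP = 1)), 2.1,
               tolerance = 1e-12)
})

test_that("TEQ is linear and monotone in every congener", {
  base <- random_profiles(1, seed = 31)
  t0 <- teq(base)
  for (cg in pah_congeners()) {
    bumped <- base
    bumped[[cg]] <- bumped[[cg]] + 1
    expect_equal(teq(bumped) - t0, unname(tef_nisbet_lagoy()[cg]),
                 tolerance = 1e-12)
    expect_gt(teq(bumped), t0)
  }
  # scaling the profile scales the TEQ
  doubled <- base
  doubled[pah_congeners()] <- 2 * doubled[pah_congeners()]
  expect_equal(teq(doubled), 2 * t0, tolerance = 1e-12)
})

test_that("TEQ contributions sum to 100% and honour the weights", {
  expect_equal(unname(teq_contributions(make_profile(BaP = 3))[1, "BaP"]), 100)
  both <- teq_contributions(make_profile(BaP = 1, DbA = 1))
  expect_equal(unname(both[1, c("BaP", "DbA")]), c(50, 50))
  flat <- make_profile()
  flat[pah_congeners()] <- 1
  contrib <- teq_contributions(flat)
  expect_equal(sum(contrib[1, ]), 100, tolerance = 1e-10)
  expect_equal(unname(contrib[1, "BaP"]),
               100 / sum(tef_nisbet_lagoy()), tolerance = 1e-10)
  expect_error(teq_contributions(make_profile()), "zero")
})

test_that("point ILCR matches the closed-form reference case", {
  expect_equal(ilcr_point(0, 70), 0)
  ref <- 1e-6 * 3.85 * 12 * 6 * 250 / (70 * 25550)
  expect_equal(ilcr_point(1, 70), ref, tolerance = 1e-12)
  expect_equal(ilcr_point(1, 70), 3.875e-8, tolerance = 1e-3)
})

test_that("ILCR increases with TEQ and decreases with body weight", {
  teqs <- seq(0.5, 30, length.out = 20)
  risks <- ilcr_point(teqs, 32)
  expect_true(all(diff(risks) > 0))
  bws <- seq(10, 120, length.out = 50)
  risks_bw <- ilcr_point(10, bws)
  expect_true(all(diff(risks_bw) < 0))
  expect_error(ilcr_point(1, 0), "positive")
  expect_error(ilcr_point(1, -5), "positive")
  expect_warning(ilcr_point(1, 5), "10-120")
})

test_that("body-weight calibration inverts the risk model", {
  for (target in c(1.13e-6, 1.6e-7)) {
    bw <- suppressWarnings(calibrate_body_weight(target, 17.35))
    expect_equal(suppressWarnings(ilcr_point(17.35, bw)), target,
                 tolerance = 1e-12)
  }
  expect_error(calibrate_body_weight(-1, 10), "positive")
})

test_that("log-normal moment inversion round-trips", {
  expect_equal(lognormal_from_arithmetic(1, 0), list(mu = 0, sigma = 0))
  ln <- lognormal_from_arithmetic(2.21, 2.51)
  expect_equal(ln$mu, 0.3787, tolerance = 1e-4)
  expect_equal(ln$sigma, 0.9102, tolerance = 1e-4)
  for (s in 1:5) {
    set.seed(s)
    m <- stats::runif(1, 0.5, 20)
    sd <- stats::runif(1, 0, 10)
    ln <- lognormal_from_arithmetic(m, sd)
    expect_equal(exp(ln$mu + ln$sigma^2 / 2), m, tolerance = 1e-12)
    expect_equal((exp(ln$sigma^2) - 1) * exp(2 * ln$mu + ln$sigma^2), sd^2,
                 tolerance = 1e-9)
  }
  expect_error(lognormal_from_arithmetic(-1, 1), "positive")
})

test_that("distribution sampling matches the requested families", {
  expect_equal(sample_dist(dist_spec("constant", value = 12), 5), rep(12, 5))

  set.seed(77)
  m <- 17.35; s <- 1.74
  draws <- sample_dist(dist_spec("logistic", mean = m, scale = s), 1e5)
  se <- s * pi / sqrt(3) / sqrt(1e5)
  expect_lt(abs(mean(draws) - m), 4 * se)

  set.seed(78)
  draws <- sample_dist(dist_spec("lognormal_arithmetic", mean = 2.21,
                                 sd = 2.51), 1e5)
  expect_lt(abs(mean(draws) - 2.21), 4 * 2.51 / sqrt(1e5))

  set.seed(79)
  nb <- dist_spec("negative_binomial", p = 0.206, r = 8.33)
  draws <- sample_dist(nb, 1e5)
  expect_true(all(draws >= 0 & draws == round(draws)))
  expect_lt(abs(mean(draws) - 8.33 * (1 - 0.206) / 0.206), 0.3)

  expect_error(dist_spec("triangular", a = 1), "arg")
  expect_error(dist_spec("logistic", mean = 1), "scale")
  expect_error(dist_spec("negative_binomial", p = 1.2, r = 3), "\\(0, 1\\)")
})

test_that("degenerate Monte Carlo equals the deterministic model", {
  mc <- monte_carlo_ilcr(dist_spec("constant", value = 1),
                         dist_spec("constant", value = 70),
                         n_iter = 200, seed = 1)
  expect_equal(unique(mc$draws), ilcr_point(1, 70))
  expect_equal(unname(quantile(mc, 0.95)), mc$mean)
  expect_equal(mc$mean, mean(mc$draws))
})

test_that("Monte Carlo runs are reproducible under a fixed seed", {
  cfg <- generate_risk_inputs("exposed")
  a <- monte_carlo_ilcr(cfg$teq_spec, cfg$bw_spec, n_iter = 500, seed = 42)
  b <- monte_carlo_ilcr(cfg$teq_spec, cfg$bw_spec, n_iter = 500, seed = 42)
  expect_identical(a$draws, b$draws)
  expect_true(all(a$draws >= 0))
  c <- monte_carlo_ilcr(cfg$teq_spec, cfg$bw_spec, n_iter = 500, seed = 43)
  expect_false(identical(a$draws, c$draws))
})

test_that("MC mean converges to the analytic expectation as O(1/sqrt(n))", {
  teq_spec <- dist_spec("logistic", mean = 17.35, scale = 1.74)
  bw_spec <- dist_spec("constant", value = 32)
  analytic <- ilcr_point(17.35, 32)  # E[ILCR] linear in TEQ at constant BW
  err <- sapply(c(1e3, 1e5), function(n) {
    mc <- monte_carlo_ilcr(teq_spec, bw_spec, n_iter = n, seed = 7)
    abs(mc$mean - analytic)
  })
  expect_lt(err[2], err[1])
  se5 <- 1.74 * pi / sqrt(3) / sqrt(1e5) * analytic / 17.35
  expect_lt(err[2], 4 * se5)
})

test_that("percentile conventions are the documented linear interpolation", {
  mc <- monte_carlo_ilcr(dist_spec("constant", value = 2),
                         dist_spec("constant", value = 70),
                         n_iter = 50, seed = 1)
  q <- quantile(mc, c(0.05, 0.5, 0.95))
  expect_true(all(q == ilcr_point(2, 70)))

  fake <- structure(list(draws = as.numeric(1:100)), class = "ilcr_mc")
  p95 <- unname(quantile(fake, 0.95))
  expect_gte(p95, 95); expect_lte(p95, 96)

  # logistic closed form: the 95th percentile is mean + scale * log(19)
  set.seed(5)
  draws <- sample_dist(dist_spec("logistic", mean = 17.35, scale = 1.74), 1e6)
  expect_equal(unname(stats::quantile(draws, 0.95, type = 7)),
               17.35 + 1.74 * log(19), tolerance = 0.01)
})

test_that("sensitivity analysis attributes variance by rank correlation", {
  # single varying input takes the whole contribution
  mc <- monte_carlo_ilcr(dist_spec("logistic", mean = 17.35, scale = 1.74),
                         dist_spec("constant", value = 32),
                         n_iter = 2000, seed = 3)
  expect_warning(sens <- sensitivity_analysis(mc), "one varying")
  expect_equal(sens$variable, "teq")
  expect_equal(sens$contribution, 1)
  expect_gt(sens$rank_correlation, 0.99)

  # all-constant inputs are an error
  mc0 <- monte_carlo_ilcr(dist_spec("constant", value = 1),
                          dist_spec("constant", value = 70),
                          n_iter = 100, seed = 1)
  expect_error(sensitivity_analysis(mc0), "constant")

  # symmetric pseudo-inputs split the contribution evenly
  set.seed(13)
  u <- stats::rnorm(20000); v <- stats::rnorm(20000)
  fake <- structure(list(draws = u + v,
                         inputs = data.frame(teq = u, bw = v)),
                    class = "ilcr_mc")
  sens2 <- sensitivity_analysis(fake)
  expect_equal(sum(sens2$contribution), 1, tolerance = 1e-12)
  expect_equal(sens2$contribution, c(0.5, 0.5), tolerance = 0.03)

  # body weight correlates negatively when it varies
  cfg <- generate_risk_inputs("exposed")
  mc2 <- monte_carlo_ilcr(cfg$teq_spec, cfg$bw_spec, n_iter = 4000, seed = 8)
  sens3 <- sensitivity_analysis(mc2)
  expect_lt(sens3$rank_correlation[sens3$variable == "bw"], 0)
  expect_equal(sum(sens3$contribution), 1, tolerance = 0.02)
})

test_that("risk configuration YAML round-trips", {
  cfg <- list(
    params = list(IR = 12, EF = 250, ED = 6, AT = 25550, CSF = 3.85),
    teq_spec = list(family = "logistic", mean = 17.35, scale = 1.74),
    bw_spec = list(family = "negative_binomial", p = 0.206, r = 8.3),
    n_iter = 2000, seed = 11
  )
  f <- tempfile(fileext = ".yaml")
  write_risk_config(cfg, f)
  back <- read_risk_config(f)
  expect_s3_class(back$teq_spec, "dist_spec")
  expect_equal(back$teq_spec$params$mean, 17.35)
  expect_equal(back$bw_spec$params$p, 0.206)
  expect_equal(back$params$CSF, 3.85)
  expect_equal(back$n_iter, 2000)
  mc <- monte_carlo_ilcr(back$teq_spec, back$bw_spec, back$params,
                         n_iter = back$n_iter, seed = back$seed)
  expect_length(mc$draws, 2000)
})

test_that("risk and sensitivity CSV writers emit the documented schemas", {
  cfg <- generate_risk_inputs("comparative")
  mc <- monte_carlo_ilcr(cfg$teq_spec, cfg$bw_spec, n_iter = 500, seed = 2)
  f <- tempfile(fileext = ".csv")
  write_risk_csv(list(comparative = mc), f)
  out <- utils::read.csv(f)
  expect_named(out, c("scenario", "mean", "p5", "p50", "p95"))
  f2 <- tempfile(fileext = ".csv")
  write_sensitivity_csv(sensitivity_analysis(mc), f2)
  expect_named(utils::read.csv(f2),
               c("variable", "rank_correlation", "contribution"))
  f3 <- tempfile(fileext = ".csv")
  write_draws_csv(mc, f3)
  expect_named(utils::read.csv(f3), c("teq", "bw", "ilcr"))
})
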