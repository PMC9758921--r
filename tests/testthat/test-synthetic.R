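test_that("Gompertz-Makeham rates follow the closed form", {
  m <- mortality_model(a = 1e-4, b = 0.1, c = 5e-4)
  sched <- generate_mortality(m, 15:100)
  expect_equal(sched$mx[sched$age == 50], 5e-4 + 1e-4 * exp(0.1 * 50))
  expect_true(all(diff(sched$mx) > 0))
  # slope ~ 0 collapses to a constant baseline-plus-level hazard
  flat <- generate_mortality(mortality_model(a = 0.02, b = 1e-12), 15:100)
  expect_equal(flat$mx, rep(0.02, 86), tolerance = 1e-9)
  expect_error(mortality_model(a = -1, b = 0.1), "a > 0")
})

test_that("response models validate their parameters", {
  kap <- matrix(rep(c(0, 1, 2, 3), each = 5), nrow = 5)
  expect_s3_class(response_model(kap), "response_model")
  bad <- kap; bad[2, ] <- c(1, 1, 2, 3)
  expect_error(response_model(bad), class = "qale_model_error")
  expect_error(response_model(kap, rho = 1), class = "qale_model_error")
  expect_error(response_model(kap[1:4, ]), class = "qale_model_error")
})

test_that("degenerate cutpoints produce universal perfect health", {
  kap <- matrix(rep(c(20, 21, 22, 23), each = 5), nrow = 5)
  model <- response_model(kap, beta_age = 0, rho = 0.5)
  rec <- generate_survey(model, 200, data.frame(gender = "men"), seed = 1)
  expect_true(all(rec$mo == 1 & rec$sc == 1 & rec$ua == 1 &
                    rec$pd == 1 & rec$ad == 1))
  tn <- true_norms(model, toy_value_set())
  expect_equal(tn$pi, rep(1, nrow(tn)))
})

test_that("marginal level frequencies match the ordered-probit probabilities", {
  kap <- rbind(c(0.8, 1.4, 1.9, 2.4), c(1.2, 1.8, 2.2, 2.6),
               c(0.5, 1.2, 1.8, 2.3), c(0.1, 0.9, 1.5, 2.1),
               c(0.6, 1.3, 1.9, 2.5))
  model <- response_model(kap, beta_age = 0.01, rho = 0.4)
  n <- 50000
  strata <- data.frame(year = 2018, gender = "men", region = "BE")
  rec <- generate_survey(model, n, strata, seed = 5,
                         age_dist = c(1, rep(0, 85))) # all age 15
  s <- 0 # shift at age 15 with no offsets
  for (d in 1:5) {
    cc <- c("mo", "sc", "ua", "pd", "ad")[d]
    pk <- diff(c(0, pnorm(kap[d, ] - s), 1)) # analytic level probabilities
    obs <- tabulate(rec[[cc]], nbins = 5) / n
    mc_se <- sqrt(pk * (1 - pk) / n)
    expect_true(all(abs(obs - pk) <= 3 * mc_se + 1e-8))
  }
})

test_that("zero copula correlation yields independent dimensions", {
  kap <- matrix(rep(c(0, 0.8, 1.5, 2.2), each = 5), nrow = 5)
  model <- response_model(kap, rho = 0)
  rec <- generate_survey(model, 50000, data.frame(gender = "men"), seed = 9)
  lv <- as.matrix(rec[c("mo", "sc", "ua", "pd", "ad")])
  cors <- cor(lv)
  expect_true(all(abs(cors[upper.tri(cors)]) < 0.025))
  # positive rho induces positive cross-dimension correlation
  rec2 <- generate_survey(response_model(kap, rho = 0.6), 50000,
                          data.frame(gender = "men"), seed = 9)
  cors2 <- cor(as.matrix(rec2[c("mo", "sc", "ua", "pd", "ad")]))
  expect_true(all(cors2[upper.tri(cors2)] > 0.2))
})

test_that("identical seeds reproduce the survey byte for byte", {
  scn <- scenario_belgium_like()
  strata <- data.frame(year = c(2013, 2018), gender = "women")
  models <- function(year, gender, region) scn$response(year, gender)
  r1 <- generate_survey(models, 500, strata, seed = 123)
  r2 <- generate_survey(models, 500, strata, seed = 123)
  expect_identical(r1, r2)
  r3 <- generate_survey(models, 500, strata, seed = 124)
  expect_false(identical(r1, r3))
  # file round trip preserves the records
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_survey_csv(r1, tmp)
  expect_equal(read_survey_csv(tmp)$weight, r1$weight, tolerance = 1e-12)
})

test_that("exact norms match an independent product-form summation", {
  kap <- rbind(c(0.9, 1.5, 2.0, 2.5), c(1.3, 1.9, 2.3, 2.7),
               c(0.6, 1.3, 1.9, 2.4), c(0.2, 1.0, 1.6, 2.2),
               c(0.7, 1.4, 2.0, 2.6))
  model <- response_model(kap, beta_age = 0.012, rho = 0)
  vs <- toy_value_set()
  ages <- c(15, 40, 80)
  got <- true_pi_by_age(model, vs, ages)
  states <- as.matrix(enumerate_states())
  for (j in seq_along(ages)) {
    s <- 0.012 * (ages[j] - 15)
    pmat <- t(vapply(1:5, function(d) diff(c(0, pnorm(kap[d, ] - s), 1)),
                     numeric(5)))
    # independent oracle: explicit loop over all 3125 states
    expect_pi <- 0
    for (r in seq_len(nrow(states))) {
      pr <- prod(pmat[cbind(1:5, states[r, ])])
      expect_pi <- expect_pi + pr * vs$table$utility[r]
    }
    expect_equal(got[j], expect_pi, tolerance = 1e-10)
  }
})

test_that("correlated-copula norms agree with a large simulated sample", {
  scn <- scenario_belgium_like()
  model <- scn$response(2018, "women")
  vs <- synthetic_belgian_value_set()
  n <- 200000
  rec <- generate_survey(model, n, data.frame(year = 2018, gender = "women"),
                         seed = 77, age_dist = c(1, rep(0, 85)))
  u <- index_value(stats::setNames(rec[c("mo", "sc", "ua", "pd", "ad")],
                                   eq5d_dimensions()), vs)
  truth <- true_pi_by_age(model, vs, 15)
  expect_lt(abs(mean(u) - truth), 4 * sd(u) / sqrt(n))
  # the utility norm is insensitive to rho for additive value sets, but the
  # state distribution is not: verify rho only reshuffles the joint
  model0 <- scn$response(2018, "women")
  model0$rho <- 0
  expect_equal(true_pi_by_age(model0, vs, 15), truth, tolerance = 1e-6)
})

test_that("estimated norms converge to the exact norms", {
  scn <- scenario_belgium_like()
  model <- scn$response(2018, "men")
  vs <- synthetic_belgian_value_set()
  strata <- data.frame(year = 2018, gender = "men", region = "BE")
  rec <- generate_survey(model, 100000, strata, seed = 31)
  est <- estimate_norms(rec, vs, by = character())
  tn <- true_norms(model, vs)
  expect_equal(nrow(est), nrow(tn))
  expect_true(all(abs(est$pi - tn$pi) < 4 * sqrt(est$var_pi)))
  for (cc in c("mo", "sc", "ua", "pd", "ad")) {
    expect_true(all(abs(est[[paste0("prev_", cc)]] -
                          tn[[paste0("prev_", cc)]]) <
                      4 * sqrt(est[[paste0("var_prev_", cc)]]) + 1e-3))
  }
})
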