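# Synthetic mortality schedules and EQ-5D-5L survey microdata with known
# ground truth, for end-to-end validation of the pipeline.

#' Gompertz-Makeham mortality model
#'
#' Central death rates follow \eqn{m_x = c + k\, a\, e^{b x}} with a
#' Makeham baseline `c`, Gompertz level `a` and slope `b`, and a
#' multiplicative modifier `k` (gender/region/period factor on the
#' senescent component).
#'
#' @param a Gompertz level (> 0, per year).
#' @param b Gompertz slope (> 0, per year of age).
#' @param c Makeham baseline hazard (>= 0, per year).
#' @param modifier Multiplicative factor on `a` (default 1).
#' @return Object of class `mortality_model`.
#' @export
mortality_model <- function(a, b, c = 0, modifier = 1) {
  stopifnot(a > 0, b > 0, c >= 0, modifier > 0)
  structure(list(a = a, b = b, c = c, modifier = modifier),
            class = "mortality_model")
}

#' Generate a deterministic mortality schedule from a model
#'
#' @param model A `mortality_model`.
#' @param ages Single years of age; the last age is the open group
#'   (default `15:100`).
#' @param year,gender,region Labels attached to the schedule.
#' @return Data frame with columns `year, gender, region, age, mx`.
#' @export
generate_mortality <- function(model, ages = 15:100,
                               year = NA, gender = NA, region = NA) {
  stopifnot(inherits(model, "mortality_model"))
  mx <- model$c + model$modifier * model$a * exp(model$b * ages)
  if (any(mx <= 0)) qale_error("mortality model yields non-positive rates",
                               "qale_rate_error")
  data.frame(year = year, gender = gender, region = region,
             age = as.integer(ages), mx = mx)
}

#' Ordered-probit EQ-5D-5L response model
#'
#' Each respondent has a shared standard-normal factor \eqn{Z_0} and five
#' dimension-specific factors; the latent severity for dimension \eqn{d} is
#' \eqn{\sqrt{\rho} Z_0 + \sqrt{1-\rho}\,\varepsilon_d + s}, a Gaussian
#' copula with common correlation \eqn{\rho} across dimensions. The shift
#' \eqn{s = \mathrm{offset} + \beta_{age}(age - 15) + \beta_{gender}
#' \mathbf{1}[women] + \beta_{year} \mathbf{1}[late\ year]} moves mass
#' towards worse levels. The reported level is 1 plus the number of
#' cutpoints below the latent, so marginally
#' \eqn{P(level \le k) = \Phi(\kappa_k - s)}.
#'
#' @param cutpoints 5 x 4 numeric matrix (rows in the order of
#'   [eq5d_dimensions()]), strictly increasing within each row.
#' @param beta_age Latent shift per year of age above 15 (default 0).
#' @param beta_gender Latent shift applied to women (default 0).
#' @param beta_year Latent shift applied to the later survey year
#'   (default 0).
#' @param rho Cross-dimension correlation in [0, 1) (default 0).
#' @param offset Baseline latent shift (default 0).
#' @return Object of class `response_model`.
#' @export
response_model <- function(cutpoints, beta_age = 0, beta_gender = 0,
                           beta_year = 0, rho = 0, offset = 0) {
  cutpoints <- as.matrix(cutpoints)
  if (!identical(dim(cutpoints), c(5L, 4L))) {
    qale_error("cutpoints must be a 5 x 4 matrix", "qale_model_error")
  }
  if (any(apply(cutpoints, 1, function(r) any(diff(r) <= 0)))) {
    qale_error("cutpoints must be strictly increasing within each dimension",
               "qale_model_error")
  }
  if (!(rho >= 0 && rho < 1)) {
    qale_error("rho must lie in [0, 1)", "qale_model_error")
  }
  rownames(cutpoints) <- eq5d_dimensions()
  structure(list(cutpoints = cutpoints, beta_age = beta_age,
                 beta_gender = beta_gender, beta_year = beta_year,
                 rho = rho, offset = offset),
            class = "response_model")
}

model_shift <- function(model, age, women = FALSE, late_year = FALSE) {
  model$offset + model$beta_age * (age - 15) +
    model$beta_gender * as.numeric(women) +
    model$beta_year * as.numeric(late_year)
}

#' Generate synthetic EQ-5D-5L survey microdata
#'
#' Draws respondents stratum by stratum under an ordered-probit response
#' model with Gaussian-copula dependence across dimensions. Survey weights
#' are log-normal, rescaled to mean 1 within each stratum. Fully
#' reproducible from `seed`.
#'
#' @param models A single `response_model` applied to every stratum, or a
#'   function `(year, gender, region) -> response_model`. With a single
#'   shared model, the model's `beta_gender` applies to records with
#'   `gender == "women"` and `beta_year` to records of the latest year in
#'   `strata`; per-stratum model functions should bake such contrasts into
#'   `offset` instead.
#' @param n Respondents per stratum: a scalar or a vector along the rows of
#'   `strata`.
#' @param strata Data frame with one row per stratum and columns among
#'   `year`, `gender`, `region` (missing columns are filled with a single
#'   label).
#' @param seed Integer seed; the whole draw is a single deterministic RNG
#'   stream.
#' @param age_dist Age distribution over single years 15-100: `NULL`
#'   (uniform), a length-86 probability vector, or a function
#'   `(year, gender, region) ->` such a vector.
#' @param weight_sdlog Log-scale standard deviation of the raw log-normal
#'   weights (default 0.5).
#' @return Data frame of survey records: `year, age, gender, region,
#'   weight, mo, sc, ua, pd, ad`.
#' @export
generate_survey <- function(models, n, strata, seed, age_dist = NULL,
                            weight_sdlog = 0.5) {
  stopifnot(is.data.frame(strata), nrow(strata) >= 1, all(n >= 1))
  for (k in c("year", "gender", "region")) {
    if (!k %in% names(strata)) strata[[k]] <- "all"
  }
  n <- rep_len(as.integer(n), nrow(strata))
  late <- suppressWarnings(max(as.numeric(strata$year)))
  codes <- unname(eq5d_dim_codes())
  set.seed(as.integer(seed))
  out <- vector("list", nrow(strata))
  for (s in seq_len(nrow(strata))) {
    st <- strata[s, ]
    model <- if (inherits(models, "response_model")) models else
      models(st$year, st$gender, st$region)
    stopifnot(inherits(model, "response_model"))
    prob <- if (is.null(age_dist)) rep(1, 86) else if (is.function(age_dist))
      age_dist(st$year, st$gender, st$region) else age_dist
    stopifnot(length(prob) == 86L)
    ns <- n[s]
    age <- sample(15:100, ns, replace = TRUE, prob = prob)
    shift <- model_shift(model, age,
                         women = identical(st$gender, "women"),
                         late_year = isTRUE(suppressWarnings(
                           as.numeric(st$year)) == late))
    z0 <- stats::rnorm(ns)
    rec <- data.frame(year = st$year, age = age, gender = st$gender,
                      region = st$region, weight = NA_real_)
    for (d in seq_along(codes)) {
      lat <- sqrt(model$rho) * z0 +
        sqrt(1 - model$rho) * stats::rnorm(ns) + shift
      rec[[codes[d]]] <- 1L + findInterval(lat, model$cutpoints[d, ])
    }
    w <- stats::rlnorm(ns, meanlog = 0, sdlog = weight_sdlog)
    rec$weight <- w / mean(w)
    out[[s]] <- rec
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Marginal level probabilities (5-vector) for one dimension at shift s.
marginal_level_probs <- function(kappa, s) {
  cdf <- c(stats::pnorm(kappa - s), 1)
  c(cdf[1], diff(cdf))
}

#' Exact per-age mean utility under a response model
#'
#' Computes the population value of the utility norm \eqn{\pi(x)} at each
#' age by exact summation over all 3125 health states, with state
#' probabilities obtained from the Gaussian copula by numerical integration
#' over the shared factor (fine Gauss-weighted grid on the factor axis; for
#' \eqn{\rho = 0} this reduces to the product of the five closed-form
#' ordered-probit marginals).
#'
#' @param model A `response_model`.
#' @param vs An `eq5d_value_set`.
#' @param ages Single years of age (default `15:100`).
#' @param women,late_year Indicator contrasts passed to the model's
#'   `beta_gender` / `beta_year` terms.
#' @param grid_n Number of grid nodes for the shared-factor integral
#'   (default 101).
#' @return Numeric vector of \eqn{\pi(x)} along `ages`.
#' @export
true_pi_by_age <- function(model, vs, ages = 15:100, women = FALSE,
                           late_year = FALSE, grid_n = 101) {
  stopifnot(inherits(model, "response_model"), inherits(vs, "eq5d_value_set"))
  u <- vs$table$utility
  kap <- model$cutpoints
  shift <- model_shift(model, ages, women, late_year)
  rho <- model$rho
  if (rho == 0) {
    vapply(shift, function(s) {
      p <- lapply(seq_len(5), function(d) marginal_level_probs(kap[d, ], s))
      joint <- Reduce(kronecker, p)
      sum(joint * u)
    }, numeric(1))
  } else {
    z <- seq(-8, 8, length.out = grid_n)
    wz <- stats::dnorm(z)
    wz <- wz / sum(wz)
    sr <- sqrt(rho)
    s1 <- sqrt(1 - rho)
    vapply(shift, function(s) {
      acc <- 0
      for (j in seq_along(z)) {
        p <- lapply(seq_len(5), function(d) {
          cdf <- c(stats::pnorm((kap[d, ] - s - sr * z[j]) / s1), 1)
          c(cdf[1], diff(cdf))
        })
        acc <- acc + wz[j] * sum(Reduce(kronecker, p) * u)
      }
      acc
    }, numeric(1))
  }
}

#' Exact population norms under a response model
#'
#' The ground-truth counterpart of [estimate_norms()]: per age band, the
#' population mean utility and per-dimension no-problem prevalences implied
#' by the response model, averaged over ages within the band with the given
#' age distribution. Sampling variances are zero (these are population
#' values) and `n_eff` is infinite.
#'
#' @inheritParams true_pi_by_age
#' @param age_bands Bands partitioning 15-100 (default
#'   [default_age_bands()]).
#' @param age_dist Probability weights over ages 15-100 used to average
#'   within bands (default uniform); must match the age distribution used
#'   when generating survey records for the comparison to be exact.
#' @param labels Named list of stratum labels (`year`, `gender`, `region`)
#'   attached as columns.
#' @return A `qale_norms` data frame with `var_pi = 0`.
#' @export
true_norms <- function(model, vs, age_bands = default_age_bands(),
                       ages = 15:100, age_dist = NULL, women = FALSE,
                       late_year = FALSE, labels = list(), grid_n = 101) {
  bands <- check_age_bands(age_bands)
  ages <- as.integer(ages)
  w <- if (is.null(age_dist)) rep(1, length(ages)) else as.numeric(age_dist)
  stopifnot(length(w) == length(ages))
  pi_age <- true_pi_by_age(model, vs, ages, women, late_year, grid_n)
  shift <- model_shift(model, ages, women, late_year)
  # marginal no-problem probability is closed-form: level 1 iff latent < k1
  prev_age <- vapply(seq_len(5), function(d) {
    stats::pnorm(model$cutpoints[d, 1] - shift)
  }, numeric(length(ages)))
  i <- band_of_age(ages, bands)
  out <- bands
  for (k in names(labels)) out[[k]] <- labels[[k]]
  agg <- function(v) {
    vapply(seq_len(nrow(bands)),
           function(b) sum((w * v)[i == b]) / sum(w[i == b]), numeric(1))
  }
  out$n <- Inf
  out$n_eff <- Inf
  out$pi <- agg(pi_age)
  out$var_pi <- 0
  codes <- eq5d_dim_codes()
  for (d in seq_along(codes)) {
    out[[paste0("prev_", codes[[d]])]] <- agg(prev_age[, d])
    out[[paste0("var_prev_", codes[[d]])]] <- 0
  }
  attr(out, "by") <- names(labels)
  attr(out, "age_bands") <- bands
  class(out) <- c("qale_norms", "data.frame")
  out
}

#' Belgium-like synthetic scenario
#'
#' A self-contained scenario emulating the structure of the study data: two
#' survey years (2013, 2018), two genders, three regions plus a national
#' aggregate, Gompertz-Makeham mortality improving over time, and
#' ordered-probit EQ-5D-5L responses whose health-related quality of life
#' worsens with age, is lower for women, and declines between the two years
#' at younger ages while improving at older ages for women. Response-model
#' offsets are calibrated so the utility norm at age 15 in the later year
#' is near 0.92 for men and 0.89 for women. Ages are drawn from the
#' stationary population of each stratum's life table.
#'
#' @param rho Cross-dimension latent correlation (default 0.35).
#' @return Object of class `qale_scenario`: a list with `years`, `genders`,
#'   `regions`, `region_share`, `national_region`, and functions
#'   `mortality(year, gender, region)` and `response(year, gender)`.
#' @export
scenario_belgium_like <- function(rho = 0.35) {
  years <- c(2013L, 2018L)
  genders <- c("men", "women")
  regions <- c("FLA", "BRU", "WAL")
  region_share <- c(FLA = 0.58, BRU = 0.10, WAL = 0.32)
  region_mod <- c(FLA = 0.93, BRU = 1.05, WAL = 1.12)
  base <- list(men = list(a = 2.6e-5, b = 0.096, c = 3.0e-4),
               women = list(a = 1.05e-5, b = 0.102, c = 2.0e-4))
  year_mod <- list(men = c("2013" = 1.12, "2018" = 1.00),
                   women = c("2013" = 1.06, "2018" = 1.00))
  cutpoints <- rbind(
    mobility = stats::qnorm(c(0.930, 0.970, 0.985, 0.995)),
    self_care = stats::qnorm(c(0.970, 0.990, 0.995, 0.998)),
    usual_activities = stats::qnorm(c(0.900, 0.960, 0.985, 0.995)),
    pain_discomfort = stats::qnorm(c(0.600, 0.850, 0.950, 0.990)),
    anxiety_depression = stats::qnorm(c(0.780, 0.920, 0.970, 0.995)))
  offsets <- list(men = c("2013" = -0.025, "2018" = 0.045),
                  women = c("2013" = 0.130, "2018" = 0.260))
  slopes <- list(men = c("2013" = 0.0130, "2018" = 0.0130),
                 women = c("2013" = 0.0150, "2018" = 0.0118))
  mortality <- function(year, gender, region) {
    p <- base[[gender]]
    k <- year_mod[[gender]][as.character(year)]
    mod <- if (region %in% names(region_mod)) {
      unname(region_mod[region])
    } else {
      sum(region_share * region_mod) # national aggregate
    }
    mortality_model(a = p$a, b = p$b, c = p$c, modifier = unname(k) * mod)
  }
  response <- function(year, gender) {
    response_model(cutpoints,
                   beta_age = unname(slopes[[gender]][as.character(year)]),
                   rho = rho,
                   offset = unname(offsets[[gender]][as.character(year)]))
  }
  structure(list(years = years, genders = genders, regions = regions,
                 region_share = region_share, national_region = "BE",
                 mortality = mortality, response = response,
                 n_year = c("2013" = 10829L, "2018" = 11611L)),
            class = "qale_scenario")
}

#' Simulate a full scenario: mortality schedules and survey microdata
#'
#' Generates the deterministic mortality table (regions plus the national
#' aggregate) and the seeded survey microdata for every year-gender-region
#' stratum of a scenario. Stratum sample sizes split the per-year totals
#' evenly by gender and proportionally to region shares.
#'
#' @param scn A `qale_scenario`.
#' @param seed Integer seed for the survey draw.
#' @param n_year Named vector of total respondents per year (default: the
#'   scenario's, emulating the study's survey sizes).
#' @return List with `mortality` (data frame) and `survey` (data frame).
#' @export
simulate_scenario <- function(scn, seed, n_year = scn$n_year) {
  stopifnot(inherits(scn, "qale_scenario"))
  mort <- list()
  for (y in scn$years) for (g in scn$genders) {
    for (r in c(scn$regions, scn$national_region)) {
      mort[[length(mort) + 1L]] <-
        generate_mortality(scn$mortality(y, g, r), 15:100,
                           year = y, gender = g, region = r)
    }
  }
  mortality <- do.call(rbind, mort)
  strata <- expand.grid(year = scn$years, gender = scn$genders,
                        region = scn$regions, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  n <- round(n_year[as.character(strata$year)] / length(scn$genders) *
               scn$region_share[strata$region])
  age_dist <- function(year, gender, region) {
    lt <- build_lifetable(
      generate_mortality(scn$mortality(year, gender, region), 15:100))
    lt$L / sum(lt$L)
  }
  models <- function(year, gender, region) scn$response(year, gender)
  survey <- generate_survey(models, n, strata, seed, age_dist = age_dist)
  list(mortality = mortality, survey = survey)
}
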