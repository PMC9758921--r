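# Shared fixtures: hand-built life tables, random generators, and
# independent brute-force oracles. Everything is generated in code.

# Hand-constructed 3-age toy life table: l = (100000, 60000, 20000),
# a = 0.5, open-age L = 10000 (so the open-age rate is l/L = 2).
toy_lifetable3 <- function(ages = 15:17) {
  l <- c(1e5, 6e4, 2e4)
  d <- c(l[-3] - l[-1], l[3])
  L <- c(l[2] + 0.5 * d[1], l[3] + 0.5 * d[2], 1e4)
  Tx <- rev(cumsum(rev(L)))
  out <- data.frame(age = as.integer(ages), m = d / L, a = c(0.5, 0.5, L[3] / l[3]),
                    q = d / l, l = l, d = d, L = L, T = Tx, e = Tx / l)
  attr(out, "radix") <- 1e5
  class(out) <- c("lifetable", "data.frame")
  out
}

# Hand-constructed life table with prescribed l and L columns; only the
# fields used by the Sullivan and decomposition code are meaningful.
fake_lifetable <- function(ages, l, L) {
  out <- data.frame(age = as.integer(ages), m = NA_real_, a = NA_real_,
                    q = NA_real_, l = l, d = NA_real_, L = L,
                    T = rev(cumsum(rev(L))), e = rev(cumsum(rev(L))) / l)
  attr(out, "radix") <- l[1]
  class(out) <- c("lifetable", "data.frame")
  out
}

# Random single-year mortality schedule and life table (uses the current
# RNG stream; callers set the seed).
random_lifetable <- function(n_ages = sample(3:30, 1), start = 15L,
                             radix = 1e5) {
  ages <- seq(start, start + n_ages - 1L)
  mx <- stats::rlnorm(n_ages, meanlog = -4, sdlog = 1.2)
  mx[n_ages] <- mx[n_ages] + 0.05 # open-age rate comfortably positive
  build_lifetable(data.frame(age = ages, mx = mx), radix = radix)
}

random_measure <- function(lt, with_var = FALSE) {
  n <- nrow(lt)
  age_measure(lt$age, stats::runif(n),
              var = if (with_var) stats::runif(n, 0, 1e-3) else NA_real_,
              n_eff = if (with_var) stats::runif(n, 50, 500) else NA_real_)
}

# Independent oracle: double loop over ages, no vectorised shortcuts.
brute_force_he <- function(lt, values, x) {
  acc <- 0
  for (i in seq_len(nrow(lt))) {
    y <- lt$age[i]
    if (y >= x) acc <- acc + values[i] * lt$L[i]
  }
  acc / lt$l[match(x, lt$age)]
}

# Monte-Carlo cohort oracle: remaining lifetime from `start` under the
# piecewise-constant hazard mx (last rate applies beyond the open age),
# by inversion of the piecewise-linear cumulative hazard.
simulate_cohort_e <- function(ages, mx, n) {
  k <- length(ages)
  cumhaz <- c(0, cumsum(mx[-k])) # at interval starts
  E <- stats::rexp(n)
  idx <- findInterval(E, cumhaz)
  t_within <- (E - cumhaz[idx]) / mx[idx]
  life <- (ages[idx] - ages[1]) + t_within
  # draws beyond the last closed interval fall into the open group, where
  # the hazard stays at mx[k]; findInterval already maps them to idx = k
  list(mean = mean(life), se = stats::sd(life) / sqrt(n))
}

# Survey records holding a fixed health state for every respondent.
records_of_state <- function(state, n, weight = 1, age = 40,
                             year = 2018, gender = "men", region = "BE") {
  codes <- c("mo", "sc", "ua", "pd", "ad")
  rec <- data.frame(year = year, age = age, gender = gender,
                    region = region, weight = weight)
  for (i in seq_along(codes)) rec[[codes[i]]] <- state[i]
  rec[rep(1, n), , drop = FALSE]
}

one_band <- data.frame(age_lo = 15, age_hi = 100)
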