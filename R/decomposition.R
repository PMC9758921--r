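# Decomposition of a change in QALE into mortality and disutility effects
# (Nusselder-Looman additive decomposition).

#' Decompose a change in QALE into mortality and disutility effects
#'
#' Splits the change in quality-adjusted life expectancy at index age `a`
#' between two periods into age-specific mortality and disutility effects.
#' Person-years are first conditioned on survival to the index age within
#' each period, \eqn{\lambda_x = L_x / l_a}, so that
#' \eqn{QALE_a = \sum_{x \ge a} \pi_x \lambda_x}. The effects are
#' \deqn{MOR_x = \frac{\pi_x(t) + \pi_x(t+n)}{2}\,
#'   (\lambda_x(t+n) - \lambda_x(t)),}
#' \deqn{DIS_x = \frac{\lambda_x(t) + \lambda_x(t+n)}{2}\,
#'   (\pi_x(t+n) - \pi_x(t)).}
#' The half-sum averaging allocates the mortality-health interaction
#' symmetrically, so the effects are exactly additive:
#' \eqn{\sum_x MOR_x + \sum_x DIS_x = QALE_a(t+n) - QALE_a(t)} up to
#' floating-point accumulation.
#'
#' @param lt_t,lt_tn Life tables for the first (`t`) and second (`t+n`)
#'   period; they must share the same age range.
#' @param pi_t,pi_tn `qale_measure` objects giving the per-age health
#'   measure (utility norm or prevalence) in each period, covering all ages
#'   from `a` to the end of the tables.
#' @param a Index age.
#' @param periods Character vector of two period labels (e.g.
#'   `c("2013", "2018")`).
#' @return Object of class `qale_decomposition`: list with `index_age`,
#'   `per_age` (data frame `age, pi_t, pi_tn, lambda_t, lambda_tn, mor,
#'   dis`), `mor_total`, `dis_total`, `delta_qale`, and `periods`.
#' @export
decompose_qale <- function(lt_t, pi_t, lt_tn, pi_tn, a,
                           periods = c("t", "t+n")) {
  stopifnot(inherits(lt_t, "lifetable"), inherits(lt_tn, "lifetable"))
  if (!identical(lt_t$age, lt_tn$age)) {
    qale_error("life tables cover different age ranges",
               "qale_alignment_error")
  }
  i <- match(a, lt_t$age)
  if (is.na(i)) qale_error(sprintf("index age %s outside life tables", a),
                           "qale_range_error")
  keep <- lt_t$age >= a
  ages <- lt_t$age[keep]
  m_t <- measure_for_ages(pi_t, ages)
  m_tn <- measure_for_ages(pi_tn, ages)
  lam_t <- lt_t$L[keep] / lt_t$l[i]
  lam_tn <- lt_tn$L[keep] / lt_tn$l[i]
  mor <- (m_t$value + m_tn$value) / 2 * (lam_tn - lam_t)
  dis <- (lam_t + lam_tn) / 2 * (m_tn$value - m_t$value)
  per_age <- data.frame(age = ages, pi_t = m_t$value, pi_tn = m_tn$value,
                        lambda_t = lam_t, lambda_tn = lam_tn,
                        mor = mor, dis = dis)
  structure(list(index_age = a, per_age = per_age,
                 mor_total = sum(mor), dis_total = sum(dis),
                 delta_qale = sum(m_tn$value * lam_tn) -
                   sum(m_t$value * lam_t),
                 periods = periods),
            class = "qale_decomposition")
}

#' @export
print.qale_decomposition <- function(x, ...) {
  cat(sprintf(
    "QALE change at age %d (%s -> %s): %+.3f years\n  mortality effect %+.3f, disutility effect %+.3f\n",
    x$index_age, x$periods[1], x$periods[2], x$delta_qale,
    x$mor_total, x$dis_total))
  invisible(x)
}

#' Decomposition totals across index ages
#'
#' Runs [decompose_qale()] at each requested index age and collects the
#' effect totals, the shape used for stacked-bar-plus-line displays of the
#' decomposition across ages.
#'
#' @inheritParams decompose_qale
#' @param index_ages Integer vector of index ages.
#' @return Data frame with columns `index_age, mor_total, dis_total,
#'   delta_qale`.
#' @export
decomposition_profile <- function(lt_t, pi_t, lt_tn, pi_tn,
                                  index_ages, periods = c("t", "t+n")) {
  rows <- lapply(index_ages, function(a) {
    d <- decompose_qale(lt_t, pi_t, lt_tn, pi_tn, a, periods)
    data.frame(index_age = a, mor_total = d$mor_total,
               dis_total = d$dis_total, delta_qale = d$delta_qale)
  })
  do.call(rbind, rows)
}

#' Aggregate per-age decomposition effects to display bands
#'
#' Bins the age-specific mortality and disutility effects of one
#' decomposition into age bands (presentation only; the computation stays
#' at single-year resolution).
#'
#' @param dec A `qale_decomposition`.
#' @param bands Data frame with columns `age_lo`, `age_hi` covering the
#'   decomposition's age range.
#' @return Data frame with columns `age_lo, age_hi, mor, dis`.
#' @export
aggregate_decomposition <- function(dec, bands) {
  stopifnot(inherits(dec, "qale_decomposition"))
  b <- as.data.frame(bands)[order(bands$age_lo), , drop = FALSE]
  i <- band_of_age(dec$per_age$age, b)
  if (anyNA(i)) {
    qale_error("decomposition ages not covered by the display bands",
               "qale_band_error")
  }
  data.frame(
    age_lo = b$age_lo, age_hi = b$age_hi,
    mor = vapply(seq_len(nrow(b)),
                 function(k) sum(dec$per_age$mor[i == k]), numeric(1)),
    dis = vapply(seq_len(nrow(b)),
                 function(k) sum(dec$per_age$dis[i == k]), numeric(1)))
}
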