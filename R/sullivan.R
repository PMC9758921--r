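# Sullivan health expectancies: QALE and dimension-specific no-problem
# life expectancies, with EURO-REVES style standard errors.

#' Expand banded population norms to single years of age
#'
#' Step-function expansion: every single age receives the health measure,
#' variance, and effective sample size of the band containing it. Band
#' intervals are closed, so with bands 15-49 and 50-100 age 49 takes the
#' first band's value and age 50 the second's.
#'
#' @param norms A `qale_norms` data frame restricted to a single stratum
#'   (at most one row per age band), as produced by [estimate_norms()] or
#'   [true_norms()].
#' @param ages Integer vector of single years of age to cover (e.g.
#'   `15:100`). Every age must fall inside some band, otherwise a coverage
#'   error is raised.
#' @param measure `"pi"` for the mean utility norm, or one of the dimension
#'   codes `mo, sc, ua, pd, ad` for that dimension's no-problem prevalence.
#' @return Data frame of class `qale_measure` with one row per age and
#'   columns `age`, `value`, `var` (sampling variance of the band mean),
#'   `n_eff`, and `band` (band id; ages sharing a band share one estimate,
#'   which the variance formula in [sullivan_se()] accounts for).
#' @export
expand_norms <- function(norms, ages, measure = "pi") {
  stopifnot(is.data.frame(norms))
  ages <- as.integer(ages)
  codes <- unname(eq5d_dim_codes())
  measure <- match.arg(measure, c("pi", codes))
  vcol <- if (measure == "pi") "pi" else paste0("prev_", measure)
  varcol <- if (measure == "pi") "var_pi" else paste0("var_prev_", measure)
  need <- c("age_lo", "age_hi", vcol)
  if (!all(need %in% names(norms))) {
    qale_error(paste0("norms lack column(s): ",
                      paste(setdiff(need, names(norms)), collapse = ", ")),
               "qale_band_error")
  }
  by <- attr(norms, "by")
  if (!is.null(by)) {
    for (k in by) {
      if (k %in% names(norms) && length(unique(norms[[k]])) > 1L) {
        qale_error(sprintf(
          "norms span several strata (key '%s'); filter to one stratum first",
          k), "qale_band_error")
      }
    }
  }
  b <- norms[order(norms$age_lo), , drop = FALSE]
  if (any(b$age_hi < b$age_lo) ||
      (nrow(b) > 1 && any(b$age_lo[-1] <= b$age_hi[-nrow(b)]))) {
    qale_error("age bands overlap or are inverted", "qale_band_error")
  }
  i <- findInterval(ages, b$age_lo)
  bad <- i < 1L | ages > b$age_hi[pmax(i, 1L)]
  if (any(bad)) {
    qale_error(paste0("age(s) not covered by any norm band: ",
                      paste(ages[bad], collapse = ", ")),
               "qale_coverage_error")
  }
  out <- data.frame(
    age = ages,
    value = b[[vcol]][i],
    var = if (varcol %in% names(b)) b[[varcol]][i] else NA_real_,
    n_eff = if ("n_eff" %in% names(b)) b$n_eff[i] else NA_real_,
    band = sprintf("%d-%d", b$age_lo[i], b$age_hi[i]),
    stringsAsFactors = FALSE)
  class(out) <- c("qale_measure", "data.frame")
  out
}

#' Construct a per-age health measure directly
#'
#' Convenience constructor for a `qale_measure` when per-age values are
#' already in hand (each age is its own band, i.e. estimates are treated as
#' independent across ages).
#'
#' @param ages Integer vector of ages.
#' @param value Health measure per age (utility or prevalence).
#' @param var Sampling variance of each age's estimate (default `NA`).
#' @param n_eff Effective sample size per age (default `NA`).
#' @return A `qale_measure` data frame.
#' @export
age_measure <- function(ages, value, var = NA_real_, n_eff = NA_real_) {
  out <- data.frame(age = as.integer(ages),
                    value = rep_len(as.numeric(value), length(ages)),
                    var = rep_len(as.numeric(var), length(ages)),
                    n_eff = rep_len(as.numeric(n_eff), length(ages)),
                    band = as.character(ages), stringsAsFactors = FALSE)
  class(out) <- c("qale_measure", "data.frame")
  out
}

measure_for_ages <- function(measure, ages) {
  i <- match(ages, measure$age)
  if (anyNA(i)) {
    qale_error(paste0("health measure missing for age(s): ",
                      paste(ages[is.na(i)], collapse = ", ")),
               "qale_coverage_error")
  }
  measure[i, , drop = FALSE]
}

#' Sullivan health expectancy
#'
#' Deflates life-table person-years by an age-specific health measure and
#' sums from the index age:
#' \deqn{HE_x = \frac{1}{l_x} \sum_{y \ge x} \pi_y L_y.}
#' With a utility measure this is quality-adjusted life expectancy (QALE);
#' with a no-problem prevalence it is the life expectancy without problems
#' on that dimension (a disability-free life expectancy, DFLE). A measure
#' identically 1 recovers ordinary life expectancy \eqn{e_x}.
#'
#' @param lt A `lifetable`.
#' @param measure A `qale_measure` covering every age of `lt` from `x` up.
#' @param x Index age (must be an age of the life table).
#' @param kind Label for the result, e.g. `"QALE"`, `"LE"`, or
#'   `"noprob_pd"`; purely descriptive.
#' @param labels Optional named list of stratum labels (year, gender,
#'   region) carried through to outputs.
#' @return Object of class `health_expectancy`: list with `index_age`,
#'   `value` (years), `se` (years; `NA` when the measure carries no
#'   variance), `kind`, and `labels`.
#' @export
sullivan_he <- function(lt, measure, x, kind = "QALE", labels = list()) {
  stopifnot(inherits(lt, "lifetable"))
  i <- match(x, lt$age)
  if (is.na(i)) qale_error(sprintf("index age %s outside life table", x),
                           "qale_range_error")
  ages <- lt$age[lt$age >= x]
  mm <- measure_for_ages(measure, ages)
  value <- sum(mm$value * lt$L[lt$age >= x]) / lt$l[i]
  se <- if (all(!is.na(mm$var))) sullivan_se(lt, measure, x) else NA_real_
  structure(list(index_age = x, value = value, se = se, kind = kind,
                 labels = labels),
            class = "health_expectancy")
}

#' @export
print.health_expectancy <- function(x, ...) {
  lab <- if (length(x$labels)) {
    paste0(" [", paste(unlist(x$labels), collapse = ", "), "]")
  } else ""
  cat(sprintf("%s at age %d%s: %.2f years (se %.3f)\n",
              x$kind, x$index_age, lab, x$value, x$se))
  invisible(x)
}

#' Standard error of a Sullivan health expectancy
#'
#' Variance of the Sullivan estimator treating mortality as fixed
#' (register-based) and the health measure as the only sampled quantity.
#' Ages that share one banded estimate are perfectly correlated, so
#' person-years are summed within bands before squaring:
#' \deqn{se_x^2 = \frac{1}{l_x^2} \sum_{b}
#'   \Big(\sum_{y \in b,\, y \ge x} L_y\Big)^2 v_b,}
#' where \eqn{v_b} is the sampling variance of band \eqn{b}'s estimate
#' (\eqn{s^2/N_{eff}} for utilities, \eqn{p(1-p)/N_{eff}} for prevalences).
#' Only ages at or above the index age contribute to a band's
#' person-year sum.
#'
#' @inheritParams sullivan_he
#' @return Standard error in years (radix-free).
#' @export
sullivan_se <- function(lt, measure, x) {
  stopifnot(inherits(lt, "lifetable"))
  i <- match(x, lt$age)
  if (is.na(i)) qale_error(sprintf("index age %s outside life table", x),
                           "qale_range_error")
  ages <- lt$age[lt$age >= x]
  mm <- measure_for_ages(measure, ages)
  if (anyNA(mm$var) || any(!is.na(mm$n_eff) & mm$n_eff == 0)) {
    qale_error("health-measure variance missing for some ages",
               "qale_missing_variance")
  }
  L <- lt$L[lt$age >= x]
  Lb <- rowsum(L, mm$band)
  vb <- mm$var[!duplicated(mm$band)]
  names(vb) <- mm$band[!duplicated(mm$band)]
  if (any(abs(mm$var - vb[mm$band]) > 1e-12)) {
    qale_error("variance differs within a band", "qale_missing_variance")
  }
  sqrt(sum(Lb[, 1]^2 * vb[rownames(Lb)]) / lt$l[i]^2)
}

#' Compare two health expectancies by Z-score
#'
#' Conservative two-sample comparison: the difference divided by the root
#' sum of squared standard errors, referred to the standard normal
#' distribution, two-sided.
#'
#' @param a,b `health_expectancy` objects of the same kind and index age.
#' @return Object of class `he_comparison`: list with `delta = a - b`
#'   (years), `z`, and two-sided `p`.
#' @export
compare_he <- function(a, b) {
  stopifnot(inherits(a, "health_expectancy"), inherits(b, "health_expectancy"))
  if (a$index_age != b$index_age || !identical(a$kind, b$kind)) {
    qale_error("health expectancies differ in index age or kind",
               "qale_alignment_error")
  }
  delta <- a$value - b$value
  s <- sqrt(a$se^2 + b$se^2)
  if (is.na(s)) qale_error("standard errors unavailable for comparison",
                           "qale_missing_variance")
  if (s == 0) {
    if (delta != 0) {
      qale_error("zero standard errors with a non-zero difference",
                 "qale_degenerate_comparison")
    }
    z <- 0
  } else {
    z <- delta / s
  }
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(delta = delta, z = z, p = p), class = "he_comparison")
}

#' @export
print.he_comparison <- function(x, ...) {
  cat(sprintf("difference %.3f years, z = %.3f, two-sided p = %.4g\n",
              x$delta, x$z, x$p))
  invisible(x)
}

#' Ratio of a health expectancy to life expectancy across ages
#'
#' Computes, for every age of the life table at or above `from`, the
#' Sullivan health expectancy and its ratio to the remaining life
#' expectancy \eqn{e_x} (the share of remaining life spent in the healthy
#' or quality-weighted state).
#'
#' @param lt A `lifetable`.
#' @param measure A `qale_measure` covering the table's ages.
#' @param from First index age (default: first age of the table).
#' @return Data frame with columns `age`, `value` (health expectancy),
#'   `le` (\eqn{e_x}), and `ratio`.
#' @export
he_le_ratio <- function(lt, measure, from = min(lt$age)) {
  stopifnot(inherits(lt, "lifetable"))
  ages <- lt$age[lt$age >= from]
  if (!length(ages)) qale_error("no ages at or above 'from'",
                                "qale_range_error")
  mm <- measure_for_ages(measure, ages)
  keep <- lt$age >= from
  piL <- mm$value * lt$L[keep]
  value <- rev(cumsum(rev(piL))) / lt$l[keep]
  le <- lt$e[keep]
  if (any(le == 0)) qale_error("life expectancy of zero; ratio undefined",
                               "qale_undefined_ratio")
  data.frame(age = ages, value = value, le = le, ratio = value / le)
}
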