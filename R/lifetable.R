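# Non-abridged period life tables with an open last age group.

#' Read age-specific mortality rates from CSV
#'
#' Expects columns `year, gender, region, age, mx` with one row per single
#' year of age per (year, gender, region) group. Within each group ages must
#' be consecutive integers ending at the open age; all rates must be
#' strictly positive.
#'
#' @param path Path to the CSV file.
#' @return Data frame of validated mortality rates (all groups stacked).
#' @export
read_mortality_csv <- function(path) {
  if (!file.exists(path)) qale_error(paste0("no such file: ", path),
                                     "qale_io_error")
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "gender", "region", "age", "mx")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    qale_error(paste0("mortality file lacks column(s): ",
                      paste(missing, collapse = ", ")), "qale_parse_error")
  }
  grp <- interaction(x$year, x$gender, x$region, drop = TRUE)
  for (g in levels(grp)) {
    rows <- which(grp == g)
    a <- x$age[rows]
    if (anyDuplicated(a)) {
      qale_error(sprintf("duplicate age %d in group %s",
                         a[duplicated(a)][1], g), "qale_schedule_error")
    }
    a <- sort(a)
    if (length(a) > 1 && any(diff(a) != 1L)) {
      gap <- a[which(diff(a) != 1L)[1]] + 1L
      qale_error(sprintf("gap in ages (missing age %d) in group %s", gap, g),
                 "qale_schedule_error")
    }
    if (any(x$mx[rows] <= 0 | is.na(x$mx[rows]))) {
      qale_error(sprintf("non-positive mortality rate in group %s", g),
                 "qale_rate_error")
    }
  }
  x[order(x$year, x$gender, x$region, x$age), , drop = FALSE]
}

#' Build a non-abridged period life table
#'
#' Constructs the standard single-year life table columns (m, a, q, l, d, L,
#' T, e) from central death rates, with an open last age group closed by the
#' constant-hazard rule \eqn{L_\omega = l_\omega / m_\omega}. For closed
#' intervals \eqn{q_x = m_x / (1 + (1 - a_x) m_x)} and
#' \eqn{L_x = l_{x+1} + a_x d_x}.
#'
#' @param ms Mortality schedule for a single stratum: data frame with
#'   columns `age` (consecutive single years; the last age is the open
#'   group) and `mx` (central death rate, > 0).
#' @param radix Starting cohort size \eqn{l} at the first age
#'   (default 100000).
#' @param a_default Average fraction of the year lived by those dying within
#'   a closed interval (default 0.5).
#' @return Data frame of class `lifetable` with columns
#'   `age, m, a, q, l, d, L, T, e` and attribute `radix`. A closed-interval
#'   q exceeding 1 is clamped to 1 with a warning.
#' @export
build_lifetable <- function(ms, radix = 1e5, a_default = 0.5) {
  stopifnot(is.data.frame(ms), all(c("age", "mx") %in% names(ms)))
  if (!(a_default > 0 && a_default < 1)) {
    qale_error("a_default must lie strictly between 0 and 1",
               "qale_schedule_error")
  }
  ms <- ms[order(ms$age), , drop = FALSE]
  age <- as.integer(ms$age)
  m <- as.numeric(ms$mx)
  n <- length(age)
  if (n < 2L) qale_error("schedule needs at least two ages",
                         "qale_schedule_error")
  if (any(diff(age) != 1L)) {
    qale_error("ages must be consecutive single years", "qale_schedule_error")
  }
  if (any(m <= 0 | is.na(m))) {
    qale_error("all death rates must be strictly positive", "qale_rate_error")
  }
  a <- rep(a_default, n)
  q <- m / (1 + (1 - a) * m)
  if (any(q[-n] > 1)) {
    warning("closed-interval death probability exceeded 1; clamped")
    q[-n][q[-n] > 1] <- 1
  }
  q[n] <- 1
  l <- radix * cumprod(c(1, 1 - q[-n]))
  d <- l * q
  L <- c(l[-1] + a[-n] * d[-n], l[n] / m[n])
  Tx <- rev(cumsum(rev(L)))
  e <- Tx / l
  out <- data.frame(age = age, m = m, a = a, q = q, l = l, d = d,
                    L = L, T = Tx, e = e)
  attr(out, "radix") <- radix
  class(out) <- c("lifetable", "data.frame")
  out
}

#' Write a life table to CSV at full precision
#' @param lt A `lifetable`.
#' @param path Output path.
#' @export
write_lifetable_csv <- function(lt, path) {
  stopifnot(inherits(lt, "lifetable"))
  df <- as.data.frame(lt)
  for (cc in c("m", "a", "q", "l", "d", "L", "T", "e")) {
    df[[cc]] <- format(df[[cc]], digits = 17, trim = TRUE, scientific = FALSE)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Remaining life expectancy at an index age
#' @param lt A `lifetable`.
#' @param x Index age (must be in the table).
#' @return `e_x` in years.
#' @export
life_expectancy <- function(lt, x) {
  i <- match(x, lt$age)
  if (is.na(i)) qale_error(sprintf("age %s outside life table", x),
                           "qale_range_error")
  lt$e[i]
}
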