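# EQ-5D-5L health states, value sets, and survey-weighted population norms.

#' EQ-5D-5L dimension names
#'
#' The five dimensions of the EQ-5D-5L descriptive system, in the canonical
#' order used throughout the package: mobility, self-care, usual activities,
#' pain/discomfort, anxiety/depression.
#'
#' @return Character vector of length 5.
#' @export
eq5d_dimensions <- function() {
  c("mobility", "self_care", "usual_activities",
    "pain_discomfort", "anxiety_depression")
}

# short column codes used in survey files (mo, sc, ua, pd, ad)
eq5d_dim_codes <- function() {
  c(mobility = "mo", self_care = "sc", usual_activities = "ua",
    pain_discomfort = "pd", anxiety_depression = "ad")
}

qale_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "qale_error")))
}

# Coerce a health-state input (length-5 vector, matrix, or data frame with
# the five dimension columns) to an integer matrix with canonical columns.
as_state_matrix <- function(state) {
  dims <- eq5d_dimensions()
  if (is.data.frame(state)) {
    missing <- setdiff(dims, names(state))
    if (length(missing)) {
      qale_error(paste0("health-state data frame lacks column(s): ",
                        paste(missing, collapse = ", ")),
                 "qale_invalid_state")
    }
    m <- as.matrix(state[dims])
  } else if (is.matrix(state)) {
    if (ncol(state) != 5L) {
      qale_error("health-state matrix must have 5 columns", "qale_invalid_state")
    }
    m <- state
    colnames(m) <- dims
  } else {
    if (length(state) != 5L) {
      qale_error("a health state has exactly 5 severity levels",
                 "qale_invalid_state")
    }
    m <- matrix(as.numeric(state), nrow = 1L, dimnames = list(NULL, dims))
  }
  storage.mode(m) <- "numeric"
  bad <- !is.na(m) & (m != round(m) | m < 1 | m > 5)
  if (any(bad)) {
    qale_error("severity levels must be integers in 1..5", "qale_invalid_state")
  }
  storage.mode(m) <- "integer"
  m
}

state_key <- function(m) {
  apply(m, 1L, paste0, collapse = "")
}

#' Enumerate all EQ-5D-5L health states
#'
#' Returns all 5^5 = 3125 health states exactly once, in lexicographic order
#' of (mobility, self_care, usual_activities, pain_discomfort,
#' anxiety_depression), so the first state is 11111 (perfect health) and the
#' last is 55555.
#'
#' @return A data frame with 3125 rows and one integer column per dimension.
#' @export
enumerate_states <- function() {
  g <- expand.grid(anxiety_depression = 1:5, pain_discomfort = 1:5,
                   usual_activities = 1:5, self_care = 1:5, mobility = 1:5,
                   KEEP.OUT.ATTRS = FALSE)
  out <- g[, rev(seq_along(g))]
  rownames(out) <- NULL
  out
}

#' Construct an EQ-5D-5L value set
#'
#' A value set maps every one of the 3125 health states to a utility (index
#' value) anchored at 1 for perfect health (state 11111). Value sets are
#' stored as explicit full tables; additive decrement systems are expanded to
#' the full table before construction (see [expand_additive_value_set()]).
#'
#' @param table Data frame with the five dimension columns (levels 1-5) and a
#'   numeric `utility` column; must contain every state exactly once.
#' @param name Identifier for the value set.
#' @return An object of class `eq5d_value_set` with elements `name`, `table`
#'   (ordered as [enumerate_states()]), `floor` (minimum utility), and an
#'   internal lookup vector.
#' @export
value_set <- function(table, name = "unnamed") {
  if (!is.data.frame(table) || !"utility" %in% names(table)) {
    qale_error("value-set table needs dimension columns and 'utility'",
               "qale_incomplete_value_set")
  }
  m <- as_state_matrix(table[eq5d_dimensions()])
  key <- state_key(m)
  if (anyDuplicated(key)) {
    qale_error("value-set table contains duplicated health states",
               "qale_incomplete_value_set")
  }
  if (nrow(table) != 3125L) {
    qale_error(sprintf(
      "value set must cover all 3125 health states (got %d)", nrow(table)),
      "qale_incomplete_value_set")
  }
  u <- as.numeric(table$utility)
  if (anyNA(u)) {
    qale_error("value set contains missing utilities",
               "qale_incomplete_value_set")
  }
  lookup <- stats::setNames(u, key)
  if (abs(lookup[["11111"]] - 1) > 1e-12) {
    qale_error("value set must anchor perfect health (11111) at utility 1",
               "qale_incomplete_value_set")
  }
  if (any(u > 1 + 1e-12)) {
    qale_error("utilities cannot exceed 1", "qale_incomplete_value_set")
  }
  full <- enumerate_states()
  full$utility <- unname(lookup[state_key(as.matrix(full))])
  structure(list(name = name, table = full, floor = min(u), lookup = lookup),
            class = "eq5d_value_set")
}

#' @export
print.eq5d_value_set <- function(x, ...) {
  cat(sprintf("EQ-5D-5L value set '%s': 3125 states, floor %.3f, anchor 1\n",
              x$name, x$floor))
  invisible(x)
}

#' Expand an additive decrement system to a full value-set table
#'
#' Many published EQ-5D-5L value sets are additive: the utility of a state is
#' 1 minus the sum of one decrement per dimension-level. This expands such a
#' decrement table to the explicit 3125-row table used by [value_set()].
#'
#' @param decrements Data frame with columns `dimension` (one of
#'   [eq5d_dimensions()]), `level` (2-5; level 1 implicitly has decrement 0),
#'   and `decrement` (non-negative).
#' @param name Identifier passed to [value_set()].
#' @return An `eq5d_value_set`.
#' @export
expand_additive_value_set <- function(decrements, name = "additive") {
  dims <- eq5d_dimensions()
  need <- c("dimension", "level", "decrement")
  if (!all(need %in% names(decrements))) {
    qale_error("decrement table needs columns dimension, level, decrement",
               "qale_incomplete_value_set")
  }
  dec <- matrix(0, nrow = 5L, ncol = 5L, dimnames = list(NULL, dims))
  for (i in seq_len(nrow(decrements))) {
    d <- as.character(decrements$dimension[i])
    l <- as.integer(decrements$level[i])
    if (!d %in% dims || is.na(l) || l < 2L || l > 5L) {
      qale_error(sprintf("invalid decrement row %d (%s level %s)", i, d, l),
                 "qale_incomplete_value_set")
    }
    dec[l, d] <- as.numeric(decrements$decrement[i])
  }
  states <- enumerate_states()
  u <- 1
  for (d in dims) u <- u - dec[cbind(states[[d]], match(d, dims))]
  states$utility <- u
  value_set(states, name = name)
}

#' Look up EQ-5D-5L index values
#'
#' Pure table lookup of the utility (index value) of one or more health
#' states in a value set. No arithmetic is performed beyond the value set's
#' own structure.
#'
#' @param state A length-5 level vector, a matrix, or a data frame with the
#'   five dimension columns.
#' @param vs An `eq5d_value_set`.
#' @return Numeric vector of utilities; `NA` for rows with missing levels.
#' @export
index_value <- function(state, vs) {
  stopifnot(inherits(vs, "eq5d_value_set"))
  m <- as_state_matrix(state)
  out <- rep(NA_real_, nrow(m))
  ok <- stats::complete.cases(m)
  if (any(ok)) {
    u <- vs$lookup[state_key(m[ok, , drop = FALSE])]
    if (anyNA(u)) {
      qale_error("state(s) missing from value set (incomplete value set)",
                 "qale_incomplete_value_set")
    }
    out[ok] <- unname(u)
  }
  out
}

#' Dichotomise EQ-5D-5L dimensions into no-problem flags
#'
#' Each dimension is dichotomised into "no problem" (level 1) versus "any
#' problems" (levels 2-5).
#'
#' @inheritParams index_value
#' @return Logical data frame with one column per dimension; `TRUE` means no
#'   problem (level 1).
#' @export
dichotomize <- function(state) {
  m <- as_state_matrix(state)
  as.data.frame(m == 1L)
}

#' Default age banding for population norms
#'
#' Ten-year bands 15-24, 25-34, ..., 75-84 and a top band 85-100, partitioning
#' the analysis range 15-100.
#'
#' @return Data frame with columns `age_lo`, `age_hi` (closed intervals).
#' @export
default_age_bands <- function() {
  lo <- c(seq(15, 75, by = 10), 85)
  data.frame(age_lo = lo, age_hi = c(lo[-1] - 1, 100))
}

check_age_bands <- function(age_bands, lo = 15L, hi = 100L) {
  b <- as.data.frame(age_bands)
  if (!all(c("age_lo", "age_hi") %in% names(b))) {
    qale_error("age bands need columns age_lo, age_hi", "qale_band_error")
  }
  b <- b[order(b$age_lo), , drop = FALSE]
  if (b$age_lo[1] != lo || b$age_hi[nrow(b)] != hi ||
      any(b$age_hi < b$age_lo) ||
      (nrow(b) > 1 && any(b$age_lo[-1] != b$age_hi[-nrow(b)] + 1))) {
    qale_error(sprintf("age bands must partition [%d, %d] without overlap",
                       lo, hi), "qale_band_error")
  }
  rownames(b) <- NULL
  b
}

band_of_age <- function(age, bands) {
  i <- findInterval(age, bands$age_lo)
  i[age > bands$age_hi[pmax(i, 1L)] | i < 1L] <- NA_integer_
  i
}

#' Read EQ-5D-5L survey microdata from CSV
#'
#' Expects columns `year, age, gender, region, weight, mo, sc, ua, pd, ad`
#' where the last five are severity levels 1-5 (empty = missing response).
#'
#' @param path Path to the CSV file.
#' @return Data frame of survey records.
#' @export
read_survey_csv <- function(path) {
  if (!file.exists(path)) qale_error(paste0("no such file: ", path),
                                     "qale_io_error")
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "age", "gender", "region", "weight",
            unname(eq5d_dim_codes()))
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    qale_error(paste0("survey file lacks column(s): ",
                      paste(missing, collapse = ", ")), "qale_parse_error")
  }
  if (any(!is.na(x$weight) & x$weight <= 0) || anyNA(x$weight)) {
    qale_error("survey weights must be positive", "qale_parse_error")
  }
  if (any(x$age < 15)) {
    qale_error("survey records must have age >= 15", "qale_parse_error")
  }
  for (cc in unname(eq5d_dim_codes())) {
    v <- x[[cc]]
    if (any(!is.na(v) & (v != round(v) | v < 1 | v > 5))) {
      qale_error(sprintf("column %s has levels outside 1..5", cc),
                 "qale_parse_error")
    }
  }
  x
}

#' Write survey microdata to CSV
#' @param records Survey record data frame.
#' @param path Output path.
#' @export
write_survey_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Estimate stratified EQ-5D-5L population norms
#'
#' Computes, per stratum (age band crossed with the `by` keys), the
#' survey-weighted mean index value (the population norm), its sampling
#' variance, the Kish effective sample size, and the weighted prevalence of
#' "no problem" (level 1) per dimension with its binomial variance.
#' Records with any missing dimension are excluded (complete-case) before
#' weighting.
#'
#' @param records Data frame of survey records as from [read_survey_csv()]:
#'   columns `age`, `weight`, the level columns `mo, sc, ua, pd, ad`, and any
#'   stratification keys in `by`.
#' @param vs An `eq5d_value_set` used to score the responses.
#' @param age_bands Closed-interval bands partitioning 15-100;
#'   default [default_age_bands()].
#' @param by Character vector of stratification columns
#'   (default `c("year", "gender", "region")`); keys absent from `records`
#'   are dropped with a warning.
#' @return A data frame of class `qale_norms`: one row per stratum with
#'   columns `age_lo`, `age_hi`, the `by` keys, `n`, `n_eff`, `pi`, `var_pi`,
#'   and `prev_*` / `var_prev_*` per dimension code. The effective sample
#'   size is Kish's \eqn{(\sum w)^2 / \sum w^2}; `var_pi` is the weighted
#'   sample variance divided by `n_eff`.
#' @export
estimate_norms <- function(records, vs,
                           age_bands = default_age_bands(),
                           by = c("year", "gender", "region")) {
  stopifnot(inherits(vs, "eq5d_value_set"))
  bands <- check_age_bands(age_bands)
  drop <- setdiff(by, names(records))
  if (length(drop)) {
    warning("dropping absent stratification key(s): ",
            paste(drop, collapse = ", "))
    by <- setdiff(by, drop)
  }
  codes <- eq5d_dim_codes()
  lv <- as.matrix(records[unname(codes)])
  if (any(records$weight <= 0)) {
    qale_error("survey weights must be positive", "qale_parse_error")
  }
  complete <- stats::complete.cases(lv)
  strat_lab <- function(df) {
    lab <- sprintf("[%d,%d]", df$age_lo, df$age_hi)
    for (k in by) lab <- paste(lab, df[[k]], sep = "/")
    lab
  }
  # every stratum present in the data must have at least one scored record
  # in every band
  all_keys <- if (length(by)) unique(records[by]) else
    data.frame(row.names = "1")[, 0, drop = FALSE]
  rec <- records[complete, , drop = FALSE]
  lv <- lv[complete, , drop = FALSE]
  band <- band_of_age(rec$age, bands)
  if (anyNA(band)) {
    qale_error("survey record age outside the banded range 15-100",
               "qale_band_error")
  }
  u <- index_value(as_state_matrix(stats::setNames(
    as.data.frame(lv), names(codes))), vs)
  grid <- merge(bands, all_keys, by = NULL)
  key_of <- function(df) {
    k <- sprintf("%d_%d", df$age_lo, df$age_hi)
    for (kk in by) k <- paste(k, df[[kk]], sep = "\r")
    k
  }
  rec_key <- key_of(cbind(bands[band, , drop = FALSE],
                          rec[, by, drop = FALSE]))
  grid_key <- key_of(grid)
  g <- match(rec_key, grid_key)
  counts <- tabulate(g, nbins = nrow(grid))
  if (any(counts == 0L)) {
    miss <- strat_lab(grid[counts == 0L, , drop = FALSE])
    qale_error(paste0("stratum with no scored EQ-5D responses: ",
                      paste(miss, collapse = "; ")), "qale_missing_stratum")
  }
  w <- rec$weight
  sw <- as.numeric(rowsum(w, g))
  sw2 <- as.numeric(rowsum(w^2, g))
  n_eff <- sw^2 / sw2
  pi_hat <- as.numeric(rowsum(w * u, g)) / sw
  s2 <- as.numeric(rowsum(w * (u - pi_hat[g])^2, g)) / sw
  # Bessel-type small-sample correction on the effective sample size
  s2 <- ifelse(n_eff > 1, s2 * n_eff / (n_eff - 1), NA_real_)
  out <- grid
  out$n <- counts
  out$n_eff <- n_eff
  out$pi <- pi_hat
  out$var_pi <- s2 / n_eff
  for (d in names(codes)) {
    cc <- codes[[d]]
    p <- as.numeric(rowsum(w * (lv[, cc] == 1L), g)) / sw
    out[[paste0("prev_", cc)]] <- p
    out[[paste0("var_prev_", cc)]] <- p * (1 - p) / n_eff
  }
  out <- out[do.call(order, unname(out[c(by, "age_lo")])), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "by") <- by
  attr(out, "age_bands") <- bands
  class(out) <- c("qale_norms", "data.frame")
  out
}
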