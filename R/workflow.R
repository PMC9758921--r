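# End-to-end analysis workflow: norms -> life tables -> health
# expectancies -> comparisons -> decomposition, with tabular outputs.

#' Build an analysis configuration
#'
#' @param mortality_csv,survey_csv Paths to the input CSV files (see
#'   [read_mortality_csv()] and [read_survey_csv()]).
#' @param value_set_csv Path to a value-set CSV, or `NULL` to use the
#'   packaged [synthetic_belgian_value_set()].
#' @param years The two survey years compared, earlier first.
#' @param genders Gender labels analysed (default `c("men", "women")`).
#' @param regions Region labels for the per-region supplements; empty to
#'   skip them.
#' @param national_region Region label of the national mortality rows.
#' @param age_bands Norm age bands (default [default_age_bands()]).
#' @param index_ages Index ages for the headline table (default 15 and 65).
#' @param profile_ages Index ages for the decomposition profile
#'   (default `15:99`).
#' @param output_dir Directory for output files.
#' @param small_stratum_n Threshold below which a stratum count triggers a
#'   small-sample warning in validation (default 30).
#' @return Object of class `qale_config` (a named list).
#' @export
analysis_config <- function(mortality_csv, survey_csv, value_set_csv = NULL,
                            years = c(2013, 2018),
                            genders = c("men", "women"),
                            regions = character(),
                            national_region = "BE",
                            age_bands = default_age_bands(),
                            index_ages = c(15, 65),
                            profile_ages = 15:99,
                            output_dir = ".",
                            small_stratum_n = 30) {
  if (length(years) != 2 || years[1] == years[2]) {
    qale_error("exactly two distinct years must be compared",
               "qale_config_error")
  }
  if (any(index_ages < 15 | index_ages > 100)) {
    qale_error("index ages must lie in [15, 100]", "qale_config_error")
  }
  structure(list(mortality_csv = mortality_csv, survey_csv = survey_csv,
                 value_set_csv = value_set_csv, years = years,
                 genders = genders, regions = regions,
                 national_region = national_region,
                 age_bands = check_age_bands(age_bands),
                 index_ages = index_ages, profile_ages = profile_ages,
                 output_dir = output_dir,
                 small_stratum_n = small_stratum_n),
            class = "qale_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Paths in the file are resolved relative to the file's directory.
#' Recognised keys mirror the arguments of [analysis_config()]; `age_bands`
#' is a list of two-element `[lo, hi]` pairs.
#'
#' @param path Path to the YAML configuration.
#' @return A `qale_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) qale_error(paste0("no such file: ", path),
                                     "qale_io_error")
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) if (is.null(p)) NULL else
    if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  bands <- if (is.null(y$age_bands)) default_age_bands() else
    do.call(rbind, lapply(y$age_bands, function(b)
      data.frame(age_lo = b[[1]], age_hi = b[[2]])))
  analysis_config(
    mortality_csv = rel(y$mortality_csv),
    survey_csv = rel(y$survey_csv),
    value_set_csv = rel(y$value_set_csv),
    years = if (is.null(y$years)) c(2013, 2018) else unlist(y$years),
    genders = if (is.null(y$genders)) c("men", "women") else
      unlist(y$genders),
    regions = if (is.null(y$regions)) character() else unlist(y$regions),
    national_region = if (is.null(y$national_region)) "BE" else
      y$national_region,
    age_bands = bands,
    index_ages = if (is.null(y$index_ages)) c(15, 65) else
      unlist(y$index_ages),
    profile_ages = if (is.null(y$profile_ages)) 15:99 else
      do.call(seq, as.list(unlist(y$profile_ages))),
    output_dir = if (is.null(y$output_dir)) base else rel(y$output_dir),
    small_stratum_n = if (is.null(y$small_stratum_n)) 30 else
      y$small_stratum_n)
}

#' Validate analysis inputs
#'
#' Checks file existence, schemas, value-set totality, mortality age
#' coverage for every required stratum, and survey stratum sizes. Schema
#' violations are fatal findings; small strata are warnings.
#'
#' @param cfg A `qale_config`.
#' @return Object of class `qale_validation`: data frame with columns
#'   `level` (`"fatal"` or `"warning"`) and `message`; zero rows when all
#'   checks pass.
#' @export
validate_inputs <- function(cfg) {
  stopifnot(inherits(cfg, "qale_config"))
  finding <- function(level, msg) data.frame(level = level, message = msg)
  out <- list()
  add_err <- function(e) out[[length(out) + 1L]] <<-
    finding("fatal", conditionMessage(e))
  vs <- NULL
  tryCatch({
    vs <- if (is.null(cfg$value_set_csv)) synthetic_belgian_value_set()
          else read_value_set(cfg$value_set_csv)
  }, error = add_err)
  survey <- NULL
  tryCatch(survey <- read_survey_csv(cfg$survey_csv), error = add_err)
  mort <- NULL
  tryCatch(mort <- read_mortality_csv(cfg$mortality_csv), error = add_err)
  if (!is.null(mort)) {
    for (y in cfg$years) for (g in cfg$genders) {
      for (r in c(cfg$national_region, cfg$regions)) {
        rows <- mort$year == y & mort$gender == g & mort$region == r
        if (!any(rows)) {
          out[[length(out) + 1L]] <- finding("fatal", sprintf(
            "no mortality rates for year %s, gender %s, region %s", y, g, r))
        } else if (min(mort$age[rows]) > 15 || max(mort$age[rows]) < 100) {
          out[[length(out) + 1L]] <- finding("fatal", sprintf(
            "mortality ages for %s/%s/%s do not cover 15-100", y, g, r))
        }
      }
    }
  }
  if (!is.null(survey)) {
    bands <- cfg$age_bands
    for (y in cfg$years) for (g in cfg$genders) {
      rows <- survey$year == y & survey$gender == g
      if (!any(rows)) {
        out[[length(out) + 1L]] <- finding("fatal", sprintf(
          "no survey records for year %s, gender %s", y, g))
        next
      }
      cnt <- table(factor(band_of_age(survey$age[rows], bands),
                          levels = seq_len(nrow(bands))))
      small <- which(cnt < cfg$small_stratum_n)
      for (b in small) {
        out[[length(out) + 1L]] <- finding("warning", sprintf(
          "small stratum (n = %d < %d): ages %d-%d, year %s, gender %s",
          cnt[b], cfg$small_stratum_n, bands$age_lo[b], bands$age_hi[b],
          y, g))
      }
    }
  }
  rep <- if (length(out)) do.call(rbind, out) else
    data.frame(level = character(), message = character())
  class(rep) <- c("qale_validation", "data.frame")
  rep
}

#' @export
print.qale_validation <- function(x, ...) {
  if (!nrow(x)) {
    cat("validation: no findings\n")
  } else {
    for (i in seq_len(nrow(x))) {
      cat(sprintf("[%s] %s\n", x$level[i], x$message[i]))
    }
  }
  invisible(x)
}

he_kinds <- function() {
  c("le", "qale", paste0("noprob_", unname(eq5d_dim_codes())))
}

# Health expectancies (value + se) for one stratum's life table and norms
# slice, at one index age, for all seven kinds.
stratum_hes <- function(lt, norms_slice, x) {
  out <- list(le = list(value = life_expectancy(lt, x), se = 0))
  mm <- expand_norms(norms_slice, lt$age, "pi")
  he <- sullivan_he(lt, mm, x, kind = "QALE")
  out$qale <- list(value = he$value, se = he$se)
  for (cc in unname(eq5d_dim_codes())) {
    mm <- expand_norms(norms_slice, lt$age, cc)
    he <- sullivan_he(lt, mm, x, kind = paste0("noprob_", cc))
    out[[paste0("noprob_", cc)]] <- list(value = he$value, se = he$se)
  }
  out
}

#' Run the full QALE analysis
#'
#' Orchestrates the pipeline: value-set scoring, population norms, life
#' tables, Sullivan health expectancies with standard errors, Z-score
#' change tests, the mortality/disutility decomposition, health-expectancy
#' to life-expectancy ratio curves, and per-region supplements. Writes CSV
#' outputs plus a run log to the configured output directory; on any stage
#' error the partial outputs of this run are removed.
#'
#' Output files: `table1.csv` (full precision) and `table1_report.csv`
#' (years rounded to one decimal), `decomposition_totals.csv`,
#' `decomposition_ages.csv`, `ratios.csv`, `supplement_<year>.csv` (when
#' regions are configured), and `run_log.txt`.
#'
#' @param cfg A `qale_config`.
#' @param log Whether to write `run_log.txt` (default `TRUE`).
#' @return Invisibly, a list with elements `table1`, `table1_report`,
#'   `decomposition_totals`, `decomposition_ages`, `ratios`, `supplements`,
#'   `norms`, and `validation`.
#' @export
run_analysis <- function(cfg, log = TRUE) {
  stopifnot(inherits(cfg, "qale_config"))
  rep <- validate_inputs(cfg)
  if (any(rep$level == "fatal")) {
    qale_error(paste0("fatal validation finding(s):\n",
                      paste(rep$message[rep$level == "fatal"],
                            collapse = "\n")), "qale_validation_error")
  }
  if (!dir.exists(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE)
  }
  written <- character()
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)
  warn_log <- character()
  emit <- function(df, name) {
    p <- file.path(cfg$output_dir, name)
    utils::write.csv(df, p, row.names = FALSE, na = "")
    written <<- c(written, p)
    p
  }
  withCallingHandlers({
    vs <- if (is.null(cfg$value_set_csv)) synthetic_belgian_value_set()
          else read_value_set(cfg$value_set_csv)
    survey <- read_survey_csv(cfg$survey_csv)
    survey <- survey[survey$year %in% cfg$years &
                       survey$gender %in% cfg$genders, , drop = FALSE]
    mort <- read_mortality_csv(cfg$mortality_csv)

    norms_nat <- estimate_norms(survey, vs, cfg$age_bands,
                                by = c("year", "gender"))
    lt_of <- function(y, g, r) {
      rows <- mort$year == y & mort$gender == g & mort$region == r &
        mort$age >= 15 & mort$age <= 100
      build_lifetable(mort[rows, c("age", "mx")])
    }
    slice_nat <- function(y, g) {
      norms_nat[norms_nat$year == y & norms_nat$gender == g, , drop = FALSE]
    }

    # -- headline table (Table-1 shape) --------------------------------
    kinds <- he_kinds()
    t1 <- list()
    for (x in cfg$index_ages) for (g in cfg$genders) {
      hes <- lapply(cfg$years, function(y) {
        stratum_hes(lt_of(y, g, cfg$national_region), slice_nat(y, g), x)
      })
      row <- function(vals, label) {
        cbind(data.frame(index_age = x, gender = g, row = label),
              as.data.frame(vals))
      }
      v1 <- lapply(hes[[1]], `[[`, "value")
      v2 <- lapply(hes[[2]], `[[`, "value")
      pv <- lapply(kinds, function(k) {
        if (k == "le") return(NA_real_)
        a <- structure(list(index_age = x, value = hes[[2]][[k]]$value,
                            se = hes[[2]][[k]]$se, kind = k,
                            labels = list()), class = "health_expectancy")
        b <- structure(list(index_age = x, value = hes[[1]][[k]]$value,
                            se = hes[[1]][[k]]$se, kind = k,
                            labels = list()), class = "health_expectancy")
        compare_he(a, b)$p
      })
      names(pv) <- kinds
      t1[[length(t1) + 1L]] <- rbind(
        row(v1, as.character(cfg$years[1])),
        row(v2, as.character(cfg$years[2])),
        row(mapply(function(a, b) b - a, v1, v2, SIMPLIFY = FALSE),
            "change"),
        row(pv, "p_value"))
    }
    table1 <- do.call(rbind, t1)
    rownames(table1) <- NULL
    table1_report <- table1
    num <- setdiff(names(table1), c("index_age", "gender", "row"))
    for (cc in num) {
      yr <- table1_report$row != "p_value"
      table1_report[[cc]][yr] <- round(table1_report[[cc]][yr], 1)
      table1_report[[cc]][!yr] <- round(table1_report[[cc]][!yr], 3)
    }

    # -- decomposition --------------------------------------------------
    dec_tot <- list()
    dec_ages <- list()
    for (g in cfg$genders) {
      lt1 <- lt_of(cfg$years[1], g, cfg$national_region)
      lt2 <- lt_of(cfg$years[2], g, cfg$national_region)
      m1 <- expand_norms(slice_nat(cfg$years[1], g), lt1$age, "pi")
      m2 <- expand_norms(slice_nat(cfg$years[2], g), lt2$age, "pi")
      prof <- decomposition_profile(lt1, m1, lt2, m2, cfg$profile_ages,
                                    periods = as.character(cfg$years))
      prof <- cbind(data.frame(gender = g), prof)
      dec_tot[[g]] <- prof
      for (x in cfg$index_ages) {
        d <- decompose_qale(lt1, m1, lt2, m2, x,
                            periods = as.character(cfg$years))
        dec_ages[[paste(g, x)]] <-
          cbind(data.frame(gender = g, index_age = x),
                d$per_age[c("age", "mor", "dis")])
      }
    }
    decomposition_totals <- do.call(rbind, dec_tot)
    decomposition_ages <- do.call(rbind, dec_ages)
    rownames(decomposition_totals) <- rownames(decomposition_ages) <- NULL

    # -- HE/LE ratio curves --------------------------------------------
    rat <- list()
    for (y in cfg$years) for (g in cfg$genders) {
      lt <- lt_of(y, g, cfg$national_region)
      sl <- slice_nat(y, g)
      for (k in setdiff(kinds, "le")) {
        meas <- if (k == "qale") "pi" else sub("noprob_", "", k)
        r <- he_le_ratio(lt, expand_norms(sl, lt$age, meas))
        rat[[length(rat) + 1L]] <-
          cbind(data.frame(year = y, gender = g, kind = k), r)
      }
    }
    ratios <- do.call(rbind, rat)
    rownames(ratios) <- NULL

    # -- per-region supplements ----------------------------------------
    supplements <- list()
    if (length(cfg$regions)) {
      norms_reg <- estimate_norms(survey, vs, cfg$age_bands,
                                  by = c("year", "gender", "region"))
      for (y in cfg$years) {
        sup <- list()
        for (g in cfg$genders) for (r in cfg$regions) {
          lt <- lt_of(y, g, r)
          sl <- norms_reg[norms_reg$year == y & norms_reg$gender == g &
                            norms_reg$region == r, , drop = FALSE]
          for (k in setdiff(kinds, "le")) {
            meas <- if (k == "qale") "pi" else sub("noprob_", "", k)
            mm <- expand_norms(sl, lt$age, meas)
            vals <- he_le_ratio(lt, mm)
            ses <- vapply(lt$age, function(x) sullivan_se(lt, mm, x),
                          numeric(1))
            sup[[length(sup) + 1L]] <- data.frame(
              year = y, gender = g, region = r, kind = k,
              age = vals$age, value = vals$value, se = ses, le = vals$le)
          }
        }
        supplements[[as.character(y)]] <- do.call(rbind, sup)
      }
    }

    emit(table1, "table1.csv")
    emit(table1_report, "table1_report.csv")
    emit(decomposition_totals, "decomposition_totals.csv")
    emit(decomposition_ages, "decomposition_ages.csv")
    emit(ratios, "ratios.csv")
    for (y in names(supplements)) {
      emit(supplements[[y]], sprintf("supplement_%s.csv", y))
    }
    if (log) {
      lines <- c(sprintf("run_analysis at %s", format(Sys.time())),
                 "config:",
                 utils::capture.output(utils::str(unclass(cfg))),
                 sprintf("validation findings: %d", nrow(rep)),
                 if (nrow(rep)) paste0("  [", rep$level, "] ", rep$message),
                 sprintf("warnings: %d", length(warn_log)),
                 warn_log)
      writeLines(lines, file.path(cfg$output_dir, "run_log.txt"))
      written <- c(written, file.path(cfg$output_dir, "run_log.txt"))
    }
    ok <- TRUE
    invisible(list(table1 = table1, table1_report = table1_report,
                   decomposition_totals = decomposition_totals,
                   decomposition_ages = decomposition_ages,
                   ratios = ratios, supplements = supplements,
                   norms = norms_nat, validation = rep))
  }, warning = function(w) {
    warn_log <<- c(warn_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
}

#' Write scenario inputs and a ready-to-run configuration
#'
#' Materialises a synthetic scenario as the CSV inputs consumed by
#' [run_analysis()] (mortality, survey, value set) plus a YAML
#' configuration pointing at them.
#'
#' @param scn A `qale_scenario`.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed for the survey draw.
#' @param n_year Total respondents per year (default: the scenario's).
#' @param vs Value set to write (default [synthetic_belgian_value_set()]).
#' @return Path to the written `config.yaml`, invisibly.
#' @export
write_scenario_inputs <- function(scn, dir, seed, n_year = scn$n_year,
                                  vs = synthetic_belgian_value_set()) {
  stopifnot(inherits(scn, "qale_scenario"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- simulate_scenario(scn, seed, n_year)
  utils::write.csv(sim$mortality, file.path(dir, "mortality.csv"),
                   row.names = FALSE, quote = FALSE)
  write_survey_csv(sim$survey, file.path(dir, "survey.csv"))
  write_value_set(vs, file.path(dir, "valueset.csv"))
  cfg <- list(mortality_csv = "mortality.csv", survey_csv = "survey.csv",
              value_set_csv = "valueset.csv",
              years = as.numeric(scn$years), genders = scn$genders,
              regions = scn$regions,
              national_region = scn$national_region,
              output_dir = "results")
  path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Recompute the headline QALE at 15 from external inputs
#'
#' Convenience helper for replicating published national results from
#' user-supplied files: a mortality CSV (Statbel-style rates by single year
#' of age) and a norms CSV with columns `gender, age_lo, age_hi, pi` (and
#' optionally `var_pi`, `n_eff`). Neither file ships with the package;
#' both must be downloaded and converted by the user.
#'
#' @param mortality_csv Path to mortality rates (`year, gender, region,
#'   age, mx`).
#' @param norms_csv Path to published utility norms per age band.
#' @param year,region Mortality rows to use.
#' @param index_age Index age (default 15).
#' @return Data frame with columns `gender`, `le`, `qale`.
#' @export
replicate_headline <- function(mortality_csv, norms_csv, year = 2018,
                               region = "BE", index_age = 15) {
  if (!file.exists(mortality_csv) || !file.exists(norms_csv)) {
    qale_error(paste0(
      "external inputs not found (downloaded mortality and norms files ",
      "are required): ", mortality_csv, ", ", norms_csv),
      "qale_external_data_error")
  }
  mort <- read_mortality_csv(mortality_csv)
  norms <- utils::read.csv(norms_csv, stringsAsFactors = FALSE)
  need <- c("gender", "age_lo", "age_hi", "pi")
  if (!all(need %in% names(norms))) {
    qale_error("norms file needs columns gender, age_lo, age_hi, pi",
               "qale_external_data_error")
  }
  out <- list()
  for (g in unique(norms$gender)) {
    rows <- mort$year == year & mort$gender == g & mort$region == region
    if (!any(rows)) {
      qale_error(sprintf("no mortality rates for gender %s in %s/%s",
                         g, year, region), "qale_external_data_error")
    }
    lt <- build_lifetable(mort[rows, c("age", "mx")])
    mm <- expand_norms(norms[norms$gender == g, , drop = FALSE], lt$age,
                       "pi")
    he <- sullivan_he(lt, mm, index_age, kind = "QALE")
    out[[g]] <- data.frame(gender = g,
                           le = life_expectancy(lt, index_age),
                           qale = he$value)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
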