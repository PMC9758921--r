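make_scenario_dir <- function(seed = 7, n_year = c("2013" = 4000,
                                                   "2018" = 4000)) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  scn <- scenario_belgium_like()
  write_scenario_inputs(scn, dir, seed = seed, n_year = n_year)
}

test_that("the full analysis produces the expected output structure", {
  cfgp <- make_scenario_dir()
  cfg <- read_config(cfgp)
  res <- run_analysis(cfg)
  # headline table: 2 index ages x 2 genders x 4 rows (two years, change,
  # p-value), 7 expectancy kinds as value columns
  expect_equal(nrow(res$table1), 2 * 2 * 4)
  kinds <- c("le", "qale", "noprob_mo", "noprob_sc", "noprob_ua",
             "noprob_pd", "noprob_ad")
  expect_true(all(kinds %in% names(res$table1)))
  yr_rows <- res$table1$row %in% c("2013", "2018")
  expect_equal(sum(yr_rows), 2 * 2 * 2)
  # QALE never exceeds LE; both positive
  expect_true(all(res$table1$qale[yr_rows] < res$table1$le[yr_rows]))
  expect_true(all(res$table1$qale[yr_rows] > 0))
  # decomposition profile covers both genders over the index-age grid
  expect_equal(nrow(res$decomposition_totals), 2 * length(15:99))
  # ratio curves: 2 years x 2 genders x 6 measures x 86 ages
  expect_equal(nrow(res$ratios), 2 * 2 * 6 * 86)
  expect_true(all(res$ratios$ratio > 0 & res$ratios$ratio <= 1 + 1e-12))
  # regional supplements: one file per year, 2 genders x 3 regions x 6
  # measures x 86 ages each
  expect_equal(length(res$supplements), 2)
  expect_equal(nrow(res$supplements[["2013"]]), 2 * 3 * 6 * 86)
  files <- list.files(cfg$output_dir)
  expect_true(all(c("table1.csv", "table1_report.csv",
                    "decomposition_totals.csv", "decomposition_ages.csv",
                    "ratios.csv", "supplement_2013.csv",
                    "supplement_2018.csv", "run_log.txt") %in% files))
})

test_that("change rows equal later-year minus earlier-year values", {
  cfgp <- make_scenario_dir(seed = 11, n_year = c("2013" = 2500,
                                                  "2018" = 2500))
  res <- run_analysis(read_config(cfgp))
  t1 <- res$table1
  kinds <- c("le", "qale", "noprob_mo", "noprob_sc", "noprob_ua",
             "noprob_pd", "noprob_ad")
  for (x in unique(t1$index_age)) for (g in unique(t1$gender)) {
    blk <- t1[t1$index_age == x & t1$gender == g, ]
    for (k in kinds) {
      expect_equal(blk[[k]][blk$row == "change"],
                   blk[[k]][blk$row == "2018"] - blk[[k]][blk$row == "2013"])
    }
    # decomposition totals reproduce the QALE change row
    dt <- res$decomposition_totals
    drow <- dt[dt$gender == g & dt$index_age == x, ]
    expect_equal(drow$mor_total + drow$dis_total,
                 blk$qale[blk$row == "change"], tolerance = 1e-10)
    expect_equal(drow$delta_qale, blk$qale[blk$row == "change"],
                 tolerance = 1e-10)
  }
})

test_that("reruns on the same inputs are byte-identical", {
  cfgp <- make_scenario_dir(seed = 19, n_year = c("2013" = 1500,
                                                  "2018" = 1500))
  cfg <- read_config(cfgp)
  out1 <- file.path(dirname(cfgp), "r1")
  out2 <- file.path(dirname(cfgp), "r2")
  cfg1 <- cfg; cfg1$output_dir <- out1
  cfg2 <- cfg; cfg2$output_dir <- out2
  run_analysis(cfg1)
  run_analysis(cfg2)
  files <- setdiff(list.files(out1), "run_log.txt")
  expect_true(length(files) >= 6)
  for (f in files) {
    expect_identical(readBin(file.path(out1, f), "raw", 1e7),
                     readBin(file.path(out2, f), "raw", 1e7),
                     info = f)
  }
  # and the simulated inputs themselves are seed-reproducible
  dirB <- withr::local_tempdir()
  write_scenario_inputs(scenario_belgium_like(), dirB, seed = 19,
                        n_year = c("2013" = 1500, "2018" = 1500))
  for (f in c("survey.csv", "mortality.csv", "valueset.csv")) {
    expect_identical(readBin(file.path(dirname(cfgp), f), "raw", 1e8),
                     readBin(file.path(dirB, f), "raw", 1e8), info = f)
  }
})

test_that("identical periods yield zero changes and zero decompositions", {
  dir <- withr::local_tempdir()
  scn <- scenario_belgium_like()
  # one survey draw, duplicated under both year labels; identical mortality
  strata <- expand.grid(year = 2013, gender = c("men", "women"),
                        stringsAsFactors = FALSE)
  rec <- generate_survey(function(y, g, r) scn$response(2013, g),
                         1500, strata, seed = 3)
  rec2 <- rec
  rec2$year <- 2018
  write_survey_csv(rbind(rec, rec2), file.path(dir, "survey.csv"))
  mort <- rbind(
    generate_mortality(scn$mortality(2013, "men", "BE"), 15:100,
                       year = 2013, gender = "men", region = "BE"),
    generate_mortality(scn$mortality(2013, "women", "BE"), 15:100,
                       year = 2013, gender = "women", region = "BE"))
  mort2 <- mort
  mort2$year <- 2018
  write.csv(rbind(mort, mort2), file.path(dir, "mortality.csv"),
            row.names = FALSE)
  cfg <- analysis_config(
    mortality_csv = file.path(dir, "mortality.csv"),
    survey_csv = file.path(dir, "survey.csv"),
    output_dir = file.path(dir, "out"))
  res <- run_analysis(cfg)
  ch <- res$table1[res$table1$row == "change", ]
  for (k in c("le", "qale", "noprob_pd")) {
    expect_equal(ch[[k]], rep(0, nrow(ch)))
  }
  expect_equal(res$table1$qale[res$table1$row == "p_value"],
               rep(1, 4))
  expect_equal(res$decomposition_totals$mor_total,
               rep(0, nrow(res$decomposition_totals)))
  expect_equal(res$decomposition_totals$dis_total,
               rep(0, nrow(res$decomposition_totals)))
})

test_that("validation flags schema violations and small strata", {
  cfgp <- make_scenario_dir(seed = 23, n_year = c("2013" = 3000,
                                                  "2018" = 3000))
  cfg <- read_config(cfgp)
  expect_equal(sum(validate_inputs(cfg)$level == "fatal"), 0)
  # truncate the value set to 3124 rows: fatal totality finding
  vs_path <- file.path(dirname(cfgp), "valueset.csv")
  vtab <- read.csv(vs_path)
  write.csv(vtab[-100, ], vs_path, row.names = FALSE)
  rep <- validate_inputs(cfg)
  expect_true(any(rep$level == "fatal" & grepl("3125", rep$message)))
  expect_error(run_analysis(cfg), class = "qale_validation_error")
  # tiny survey: small-stratum warnings surface, analysis still runs
  cfgp2 <- make_scenario_dir(seed = 29, n_year = c("2013" = 260,
                                                   "2018" = 260))
  rep2 <- validate_inputs(read_config(cfgp2))
  expect_true(any(rep2$level == "warning" &
                    grepl("small stratum", rep2$message)))
  expect_false(any(rep2$level == "fatal"))
})

test_that("the command-line interface drives simulate, validate and run", {
  dir <- withr::local_tempdir()
  expect_invisible(qale_cli(c("simulate", "--out", dir, "--seed", "5",
                              "--n-year", "3000")))
  expect_true(file.exists(file.path(dir, "config.yaml")))
  expect_output(qale_cli(c("validate", "--config",
                           file.path(dir, "config.yaml"))))
  qale_cli(c("run", "--config", file.path(dir, "config.yaml")))
  expect_true(file.exists(file.path(dir, "results", "table1.csv")))
  expect_error(qale_cli(c("run")), class = "qale_cli_error")
})
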