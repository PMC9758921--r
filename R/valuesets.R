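# Packaged value sets and value-set file I/O.

#' Read a value set from a CSV file
#'
#' The file must have columns `mobility, self_care, usual_activities,
#' pain_discomfort, anxiety_depression, utility` and exactly 3125 data rows
#' covering every health state once. Validation is strict.
#'
#' @param path Path to the CSV file.
#' @param name Identifier; defaults to the file name.
#' @return An `eq5d_value_set`.
#' @export
read_value_set <- function(path, name = basename(path)) {
  if (!file.exists(path)) qale_error(paste0("no such file: ", path),
                                     "qale_io_error")
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c(eq5d_dimensions(), "utility")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    qale_error(paste0("value-set file lacks column(s): ",
                      paste(missing, collapse = ", ")),
               "qale_incomplete_value_set")
  }
  value_set(x, name = name)
}

#' Write a value set to CSV
#' @param vs An `eq5d_value_set`.
#' @param path Output path.
#' @export
write_value_set <- function(vs, path) {
  stopifnot(inherits(vs, "eq5d_value_set"))
  utils::write.csv(vs$table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Synthetic Belgian-anchored EQ-5D-5L value set
#'
#' An additive value set expanded to the full 3125-state table and anchored
#' to published Belgian index values: utility 1 for perfect health (11111),
#' 0.849 for state 11113 (moderate anxiety/depression only), 0.678 for state
#' 11333, and a floor of -0.532 for the worst state (55555). All remaining
#' dimension-level decrements are synthetic: plausible, monotone-in-severity
#' values chosen to respect those anchors. This is a stand-in for the real
#' Belgian value set (distributed separately in the EQ5D.be package), not a
#' reproduction of it; only the anchored utilities coincide with published
#' Belgian values.
#'
#' @return An `eq5d_value_set` named `"belgium-synthetic"`.
#' @export
synthetic_belgian_value_set <- function() {
  path <- system.file("extdata", "valueset_belgium_synthetic_decrements.csv",
                      package = "qale", mustWork = TRUE)
  dec <- utils::read.csv(path, stringsAsFactors = FALSE)
  expand_additive_value_set(dec, name = "belgium-synthetic")
}

#' Toy EQ-5D-5L value set for examples and tests
#'
#' A self-contained linear value set: each level above 1 subtracts 0.05 per
#' severity step, so utility = 1 - 0.05 * sum(level - 1), with floor 0 for
#' the worst state. Useful wherever a total, easily hand-checked value set
#' is needed.
#'
#' @return An `eq5d_value_set` named `"toy-linear"`.
#' @export
toy_value_set <- function() {
  states <- enumerate_states()
  states$utility <- 1 - 0.05 * rowSums(states - 1L)
  value_set(states, name = "toy-linear")
}
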