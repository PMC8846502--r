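#' Write a cohort to delimited text tables
#'
#' Writes `hospitalizations.csv`, `xrays.csv` and `index_scores.csv` into a
#' directory, comma-separated with a header row, times in decimal hours and
#' absent values empty.
#'
#' @param cohort a `cohort` list.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(cohort$hospitalizations,
                   file.path(dir, "hospitalizations.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(cohort$xrays, file.path(dir, "xrays.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(cohort$index_scores, file.path(dir, "index_scores.csv"),
                   row.names = FALSE, na = "")
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' Validates the schema of the three tables and basic invariants (scores in
#' `[0,1]`, radiograph times sorted per hospitalization).
#'
#' @param dir directory containing the three csv tables.
#' @return A `cohort` list.
#' @export
read_cohort <- function(dir) {
  read_one <- function(name, cols) {
    path <- file.path(dir, name)
    if (!file.exists(path)) stop("missing table: ", path, call. = FALSE)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    missing <- setdiff(cols, names(df))
    if (length(missing) > 0) {
      stop(sprintf("%s: missing column(s) %s", name,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    df[, cols, drop = FALSE]
  }
  h <- read_one("hospitalizations.csv",
                c("patient_id", "hosp_id", "admit_time", "exit_time",
                  "deterioration_time", "deterioration_type", "on_oxygen"))
  h$deterioration_time <- as.numeric(h$deterioration_time)
  h$deterioration_type <- ifelse(h$deterioration_type %in% "",
                                 NA_character_, h$deterioration_type)
  h$on_oxygen <- as.logical(h$on_oxygen)
  xr <- read_one("xrays.csv", c("hosp_id", "time", "image_score"))
  idx <- read_one("index_scores.csv", c("hosp_id", "time", "score"))
  for (chk in list(list(xr$image_score, "xrays.csv image_score"),
                   list(idx$score, "index_scores.csv score"))) {
    if (any(chk[[1]] < 0 | chk[[1]] > 1, na.rm = TRUE)) {
      stop(chk[[2]], ": scores must lie in [0,1]", call. = FALSE)
    }
  }
  structure(list(hospitalizations = h, xrays = xr, index_scores = idx),
            class = "cohort")
}

#' Write prediction instances to csv
#' @param instances instance data frame from [build_instances()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_instances <- function(instances, path) {
  utils::write.csv(instances, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read prediction instances written by [write_instances()]
#' @param path instances csv file.
#' @return Instance data frame.
#' @export
read_instances <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("hosp_id", "window_start", FUSION_FEATURES)
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("instances file missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}
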