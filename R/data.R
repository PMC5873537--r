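# Long-format data handling.
#
# The canonical data shape is one row per observation with columns
# patient_id, group, marker, time_months, value. `group` may be NA for
# patients of unknown prognosis.

LONG_COLUMNS <- c("patient_id", "group", "marker", "time_months", "value")

#' Validate a long-format marker table
#'
#' Checks column presence, value domains against the marker families,
#' strictly increasing observation times within patient and marker, and
#' returns the table in canonical order (patient, marker, time).
#'
#' @param data Data frame with columns `patient_id`, `group`, `marker`,
#'   `time_months`, `value`.
#' @param specs Marker specifications; markers present in the data must all
#'   be declared.
#' @return The validated tibble, canonically ordered.
#' @export
validate_long_table <- function(data, specs) {
  specs <- as_marker_specs(specs)
  data <- as_tibble(data)
  missing_cols <- setdiff(LONG_COLUMNS, names(data))
  if (length(missing_cols)) {
    abort_structure(paste0("missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  unknown <- setdiff(unique(data$marker), names(specs))
  if (length(unknown)) {
    abort_structure(paste0("markers not declared in specs: ",
                           paste(unknown, collapse = ", ")))
  }
  if (any(!is.finite(data$time_months)) || any(data$time_months < 0)) {
    abort_structure("observation times must be nonnegative and finite")
  }
  for (nm in unique(data$marker)) {
    fam <- specs[[nm]]$family
    vals <- data$value[data$marker == nm]
    bad <- which(!value_domain_ok(fam, vals))
    if (length(bad)) {
      abort_structure(sprintf(
        "marker '%s' has %d value(s) outside the %s domain (first offending value: %g)",
        nm, length(bad), fam, vals[bad[1L]]))
    }
  }
  data <- dplyr::arrange(data, .data$patient_id, .data$marker, .data$time_months)
  dup <- dplyr::summarise(
    dplyr::group_by(data, .data$patient_id, .data$marker),
    dup = anyDuplicated(.data$time_months) > 0, .groups = "drop")
  if (any(dup$dup)) {
    off <- dup[dup$dup, ]
    abort_structure(sprintf(
      "duplicate observation times for patient '%s', marker '%s'",
      off$patient_id[1L], off$marker[1L]))
  }
  grp <- dplyr::distinct(data, .data$patient_id, .data$group)
  if (anyDuplicated(grp$patient_id)) {
    abort_structure("a patient is labelled with more than one group")
  }
  data
}

# Internal flattened representation consumed by the samplers and predictors:
# patient ids/groups plus, per marker, stacked y/X/Z and 1-based patient row
# indices.
build_model_data <- function(data, specs) {
  specs <- as_marker_specs(specs)
  data <- validate_long_table(data, specs)
  ids <- unique(data$patient_id)
  pid_of <- setNames(seq_along(ids), ids)
  grp <- dplyr::distinct(data, .data$patient_id, .data$group)
  groups <- setNames(grp$group, grp$patient_id)[ids]
  lay <- re_layout(specs)
  markers <- lapply(specs, function(s) {
    rows <- data[data$marker == s$name, ]
    des <- marker_design(s, rows$time_months)
    list(
      name = s$name,
      family = match(s$family, c("gaussian", "poisson", "bernoulli")) - 1L,
      y = as.numeric(rows$value),
      t = as.numeric(rows$time_months),
      X = des$X,
      Z = des$Z,
      pid = unname(pid_of[rows$patient_id]),
      zidx = lay$index[[s$name]]
    )
  })
  list(ids = ids, groups = unname(groups), n = length(ids),
       q = lay$q, markers = unname(markers), layout = lay, specs = specs)
}

# Restrict a long table to one patient and check it is indeed one patient.
one_patient <- function(data) {
  if (length(unique(data$patient_id)) != 1L) {
    abort_argument("expected data for exactly one patient")
  }
  data
}

#' Read / write long-format marker tables
#'
#' Comma-separated UTF-8 with the fixed header
#' `patient_id,group,marker,time_months,value`; times are stored in months
#' to six decimals. `read_long_table()` returns the table in canonical
#' order (patient, marker, time) so that write-then-read round-trips.
#'
#' @param path File path.
#' @param specs Optional marker specifications; when supplied the table is
#'   validated against them.
#' @return A tibble in canonical column order.
#' @export
read_long_table <- function(path, specs = NULL) {
  if (!file.exists(path)) abort_argument(sprintf("file not found: %s", path))
  data <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      group = readr::col_integer(),
      marker = readr::col_character(),
      time_months = readr::col_double(),
      value = readr::col_double()
    )
  )
  prob <- readr::problems(data)
  if (nrow(prob)) {
    abort_structure(sprintf("malformed value at row %d of %s", prob$row[1L], path))
  }
  if (!is.null(specs)) data <- validate_long_table(data, specs)
  else data <- dplyr::arrange(data, .data$patient_id, .data$marker, .data$time_months)
  data
}

#' @param data Long-format table to write.
#' @rdname read_long_table
#' @export
write_long_table <- function(data, path) {
  data <- as_tibble(data)[LONG_COLUMNS]
  data$time_months <- round(data$time_months, 6)
  data <- dplyr::arrange(data, .data$patient_id, .data$marker, .data$time_months)
  readr::write_csv(data, path)
  invisible(path)
}
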