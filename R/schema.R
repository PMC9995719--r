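# Registry data model: column schema, enum vocabularies, reading/writing
# and row-level validation of the flat per-transplant table.

.tx_types <- c("allogeneic", "autologous")
.diagnoses <- c("AML", "MDS", "ALL", "lymphoma", "myeloma", "solid_tumor",
                "bone_marrow_failure", "inherited_disorder", "autoimmune",
                "histiocytic", "hemoglobinopathy", "other_haem", "non_haem")
.stages <- c("early", "intermediate", "advanced")
.mds_substages <- c("RAEB1", "RAEB2", "transformed_AML", "other")
.cyto_status <- c("normal", "abnormal_classified", "abnormal_no_detail", "not_done")
.cyto_risk <- c("favorable", "intermediate", "adverse")
.donor_types <- c("MSD", "MUD", "MMUD", "haplo", "cord", "auto")
.graft_sources <- c("BM", "PB", "CB")
.conditioning <- c("MAC", "RIC")
.sexes <- c("M", "F")
.vital <- c("alive", "dead")
.yesno <- c("yes", "no")

.patient_fields <- c("patient_id", "center_code", "transplant_type",
                     "transplant_number", "transplant_date", "diagnosis",
                     "disease_stage", "mds_substage", "cytogenetics_status",
                     "cytogenetics_risk", "age_years", "sex",
                     "performance_score", "donor_type", "graft_source",
                     "conditioning_intensity", "comorbidity_any",
                     "comorbidities", "n_molecular_markers",
                     "last_contact_days", "vital_status", "death_days")
.mandatory_fields <- c("patient_id", "center_code", "transplant_type",
                       "transplant_date")
.enum_fields <- list(transplant_type = .tx_types, diagnosis = .diagnoses,
                     disease_stage = .stages, mds_substage = .mds_substages,
                     cytogenetics_status = .cyto_status,
                     cytogenetics_risk = .cyto_risk, sex = .sexes,
                     donor_type = .donor_types, graft_source = .graft_sources,
                     conditioning_intensity = .conditioning,
                     comorbidity_any = .yesno, vital_status = .vital)
.numeric_fields <- c("transplant_number", "age_years", "performance_score",
                     "n_molecular_markers", "last_contact_days", "death_days")

#' Registry column schema
#'
#' Describes how a patient-level CSV maps onto the internal record fields:
#' column names, date formats and enum "dialects" (alternate spellings used
#' by a source registry, mapped in configuration rather than code).
#'
#' @param columns Named character vector mapping internal field names to
#'   CSV column names. Defaults to the identity mapping.
#' @param date_format Date format string for `transplant_date`
#'   (default ISO-8601, `"%Y-%m-%d"`).
#' @param dialects Named list; one entry per enum field, each a named
#'   character vector mapping source spellings to canonical levels, e.g.
#'   `list(transplant_type = c(allo = "allogeneic", auto = "autologous"))`.
#'
#' @return An object of class `"registry_schema"`.
#' @export
registry_schema <- function(columns = NULL, date_format = "%Y-%m-%d",
                            dialects = list()) {
  cols <- stats::setNames(.patient_fields, .patient_fields)
  if (!is.null(columns)) cols[names(columns)] <- columns
  bad <- setdiff(names(dialects), names(.enum_fields))
  if (length(bad))
    stop("dialects given for non-enum fields: ", paste(bad, collapse = ", "))
  structure(list(columns = cols, date_format = date_format,
                 dialects = dialects),
            class = "registry_schema")
}

# Map one raw character column onto canonical enum levels; values outside
# the dialect/vocabulary become NA with a warning (they are treated as the
# field's missing level downstream).
.map_enum <- function(x, field, schema) {
  x[!nzchar(x)] <- NA_character_
  dia <- schema$dialects[[field]]
  if (!is.null(dia)) {
    hit <- match(x, names(dia))
    x[!is.na(hit)] <- unname(dia[hit[!is.na(hit)]])
  }
  levels <- .enum_fields[[field]]
  bad <- !is.na(x) & !(x %in% levels)
  if (any(bad)) {
    warning(sprintf("%d value(s) of '%s' outside the dialect (e.g. '%s'); set to missing",
                    sum(bad), field, x[bad][1]), call. = FALSE)
    x[bad] <- NA_character_
  }
  x
}

.parse_num <- function(x, field) {
  x[!nzchar(x)] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    warning(sprintf("%d non-numeric value(s) in '%s'; set to missing",
                    sum(bad), field), call. = FALSE)
  }
  out
}

#' Validate patient records
#'
#' Applies the row-level invariants of the data model. Rows violating an
#' invariant are rejected with a machine-readable reason; accepted plus
#' rejected rows always partition the input.
#'
#' @param patients Patient data frame with the fields of
#'   [registry_schema()].
#' @param vocabulary Character vector of allowed comorbidity labels.
#'
#' @return A list with elements `patients` (accepted rows) and
#'   `rejections` (data frame of `row`, `patient_id`, `reason`).
#' @export
validate_patients <- function(patients, vocabulary = names(hctci_weights())) {
  n <- nrow(patients)
  reasons <- character(n)
  add <- function(bad, msg) {
    bad[is.na(bad)] <- FALSE
    m <- if (length(msg) > 1) msg[bad] else msg
    reasons[bad] <<- ifelse(nzchar(reasons[bad]),
                            paste(reasons[bad], m, sep = "; "), m)
  }
  add(is.na(patients$patient_id) | !nzchar(patients$patient_id),
      "patient_id required")
  add(is.na(patients$center_code) | !nzchar(patients$center_code),
      "center_code required")
  add(is.na(patients$transplant_type), "transplant_type required")
  add(is.na(patients$transplant_date), "transplant_date required")
  add(!is.na(patients$transplant_number) & patients$transplant_number < 1,
      "transplant_number must be >= 1")
  dead <- !is.na(patients$vital_status) & patients$vital_status == "dead"
  add(dead & is.na(patients$death_days), "death date required")
  add(!dead & !is.na(patients$death_days),
      "death day present without death status")
  add(dead & !is.na(patients$death_days) & !is.na(patients$last_contact_days) &
        patients$last_contact_days != patients$death_days,
      "last contact must equal day of death")
  # a dead patient's last contact is the death day
  fix <- dead & !is.na(patients$death_days) & is.na(patients$last_contact_days)
  patients$last_contact_days[fix] <- patients$death_days[fix]
  for (f in c("age_years", "last_contact_days", "death_days")) {
    add(!is.na(patients[[f]]) & patients[[f]] < 0,
        paste(f, "must be non-negative"))
  }
  labels <- .split_comorbidities(patients$comorbidities)
  bad_lab <- vapply(labels, function(l) {
    u <- setdiff(l, vocabulary)
    if (length(u)) u[1] else NA_character_
  }, character(1))
  add(!is.na(bad_lab), paste0("unknown comorbidity '", bad_lab, "'"))

  keep <- !nzchar(reasons)
  rejections <- data.frame(row = which(!keep),
                           patient_id = patients$patient_id[!keep],
                           reason = reasons[!keep],
                           stringsAsFactors = FALSE)
  list(patients = patients[keep, , drop = FALSE], rejections = rejections)
}

.split_comorbidities <- function(x) {
  x[is.na(x)] <- ""
  strsplit(x, ";", fixed = TRUE)
}

#' Read a patient registry CSV
#'
#' Reads a flat one-row-per-transplant CSV, maps columns and enum values
#' through a [registry_schema()], coerces types, and validates the row
#' invariants. Rows that violate an invariant are returned as structured
#' rejections; enum values outside the dialect become missing with a
#' warning.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema A [registry_schema()].
#'
#' @return A data frame of accepted patient records with an attribute
#'   `"rejections"` (data frame of `row`, `patient_id`, `reason`).
#' @export
read_registry <- function(path, schema = registry_schema()) {
  if (!file.exists(path)) stop("cannot read registry file: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  need <- unname(schema$columns[.mandatory_fields])
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("mandatory column(s) missing: ", paste(miss, collapse = ", "))
  out <- list()
  n <- nrow(raw)
  for (f in .patient_fields) {
    col <- schema$columns[[f]]
    x <- if (col %in% names(raw)) raw[[col]] else rep("", n)
    if (f %in% names(.enum_fields)) {
      x <- .map_enum(x, f, schema)
    } else if (f %in% .numeric_fields) {
      x <- .parse_num(x, f)
      if (f != "age_years") x <- as.integer(round(x))
    } else if (f == "transplant_date") {
      x[!nzchar(x)] <- NA_character_
      x <- as.Date(x, format = schema$date_format)
    } else {
      x[!nzchar(x)] <- NA_character_
      if (f == "comorbidities") x[is.na(x)] <- ""
    }
    out[[f]] <- x
  }
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  v <- validate_patients(out)
  structure(v$patients, rejections = v$rejections)
}

#' Write a patient registry CSV
#'
#' Emits exactly the schema's columns; missing values are written as empty
#' strings and dates in the schema's date format. Writing is deterministic:
#' repeated writes of the same records are byte-identical.
#'
#' @param patients Patient data frame (validated).
#' @param path Output path.
#' @param schema A [registry_schema()].
#' @return `path`, invisibly.
#' @export
write_registry <- function(patients, path, schema = registry_schema()) {
  out <- patients[, .patient_fields, drop = FALSE]
  out$transplant_date <- format(out$transplant_date, schema$date_format)
  for (f in names(out)) {
    x <- as.character(out[[f]])
    x[is.na(x)] <- ""
    out[[f]] <- x
  }
  names(out) <- unname(schema$columns[.patient_fields])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read / write a centre activity table
#'
#' The activity table holds, per centre, year and transplant type, the
#' number of transplants reported to the annual Activity Survey, plus the
#' full-membership flag used by centre selection.
#'
#' @param path CSV path.
#' @return `read_activity()`: a data frame with columns `center_code`,
#'   `year`, `transplant_type`, `transplants_survey`, `full_member`.
#' @export
read_activity <- function(path) {
  if (!file.exists(path)) stop("cannot read activity file: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("center_code", "year", "transplant_type", "transplants_survey")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("mandatory column(s) missing: ", paste(miss, collapse = ", "))
  data.frame(center_code = raw$center_code,
             year = as.integer(raw$year),
             transplant_type = .map_enum(raw$transplant_type,
                                         "transplant_type", registry_schema()),
             transplants_survey = as.integer(raw$transplants_survey),
             full_member = if ("full_member" %in% names(raw))
               raw$full_member %in% c("TRUE", "true", "1", "yes") else TRUE,
             stringsAsFactors = FALSE)
}

#' @rdname read_activity
#' @param activity Activity data frame.
#' @export
write_activity <- function(activity, path) {
  utils::write.csv(activity, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Analysis window
#'
#' Fixes the observation interval, the extraction date and the outcome
#' horizon. One year is taken as 365 days throughout.
#'
#' @param start,end First and last transplant dates covered (inclusive).
#' @param extraction Data extraction date; should leave at least
#'   `horizon_days` of potential follow-up after `end` (a warning is
#'   issued otherwise).
#' @param horizon_days Outcome horizon in days (default 365).
#'
#' @return An object of class `"analysis_window"`.
#' @export
analysis_window <- function(start, end, extraction, horizon_days = 365L) {
  start <- as.Date(start); end <- as.Date(end); extraction <- as.Date(extraction)
  if (!(start <= end && end < extraction))
    stop("analysis window requires start <= end < extraction")
  if (as.numeric(extraction - end) < horizon_days)
    warning("extraction date allows less than the full outcome horizon after the window end")
  structure(list(start = start, end = end, extraction = extraction,
                 horizon_days = as.integer(horizon_days)),
            class = "analysis_window")
}

#' @export
print.analysis_window <- function(x, ...) {
  cat(sprintf("Analysis window: %s .. %s, extraction %s, horizon %d days\n",
              x$start, x$end, x$extraction, x$horizon_days))
  invisible(x)
}

.window_years <- function(window) {
  seq(as.integer(format(window$start, "%Y")),
      as.integer(format(window$end, "%Y")))
}

.tx_year <- function(patients) as.integer(format(patients$transplant_date, "%Y"))
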