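# Patient-record data model and cohort container.
#
# A cohort is a plain data.frame (class "cohort") with one row per child and
# a fixed set of canonical columns; extra columns (e.g. temperature) are
# carried through untouched but never scored.

.cohort_fields <- c(
  "id", "age_months", "heart_rate", "respiratory_rate", "crt_seconds",
  "crt_prolonged", "bcs", "pallor", "dehydration", "poor_nutrition",
  "outcome"
)

.numeric_fields  <- c("age_months", "heart_rate", "respiratory_rate",
                      "crt_seconds", "bcs")
.yes_no_fields   <- c("crt_prolonged", "poor_nutrition")
.severity_fields <- c("pallor", "dehydration")

.levels_for <- function(field) {
  switch(field,
    crt_prolonged  = c("no", "yes"),
    poor_nutrition = c("no", "yes"),
    pallor         = c("none", "moderate-or-severe"),
    dehydration    = c("none", "moderate-or-severe"),
    outcome        = c("survived", "died"),
    stop("no enumerated levels for field '", field, "'")
  )
}

#' Construct a cohort of patient records
#'
#' Builds the canonical cohort container used throughout the package: one row
#' per child, with age in months, vital signs (heart rate in beats/min,
#' respiratory rate in breaths/min, capillary refill time in seconds or as a
#' pre-coded prolonged flag), Blantyre Coma Score (0--5), bedside signs
#' (pallor, dehydration, poor nutrition) and in-hospital outcome. Missing
#' values are plain \code{NA}. Columns not supplied are filled with \code{NA};
#' extra columns are preserved as passthrough.
#'
#' @param data A data.frame with any subset of the canonical columns
#'   \code{id}, \code{age_months}, \code{heart_rate}, \code{respiratory_rate},
#'   \code{crt_seconds}, \code{crt_prolonged}, \code{bcs}, \code{pallor},
#'   \code{dehydration}, \code{poor_nutrition}, \code{outcome}.
#' @param name Cohort label.
#' @param validate If \code{TRUE} (default), stop when
#'   \code{\link{validate_cohort}} reports any violation.
#' @return A data.frame of class \code{"cohort"}.
#' @seealso \code{\link{read_cohort_csv}}, \code{\link{validate_cohort}}
#' @export
#' @examples
#' cohort(data.frame(id = c("a", "b"), age_months = c(10, 48),
#'                   bcs = c(5, 3), outcome = c("survived", "died")))
cohort <- function(data, name = "cohort", validate = TRUE) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (is.null(data$id)) {
    data$id <- if (nrow(data)) as.character(seq_len(nrow(data))) else character()
  }
  data$id <- as.character(data$id)
  for (f in setdiff(.cohort_fields, names(data))) {
    data[[f]] <- rep(if (f %in% .numeric_fields) NA_real_ else NA_character_,
                     nrow(data))
  }
  for (f in .numeric_fields) data[[f]] <- as.numeric(data[[f]])
  for (f in c(.yes_no_fields, .severity_fields, "outcome")) {
    data[[f]] <- as.character(data[[f]])
  }
  extra <- setdiff(names(data), .cohort_fields)
  data <- data[, c(.cohort_fields, extra), drop = FALSE]
  rownames(data) <- NULL
  out <- structure(data, class = c("cohort", "data.frame"), cohort_name = name)
  if (validate) {
    viol <- validate_cohort(out)
    if (nrow(viol)) {
      stop("invalid cohort:\n", paste(
        sprintf("  record %s, field %s: %s", viol$id, viol$field, viol$rule),
        collapse = "\n"))
    }
  }
  out
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort '%s': %d records>\n",
              attr(x, "cohort_name") %||% "cohort", nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... and %d more rows\n", nrow(x) - 10))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.normalise_missing <- function(x, na_strings) {
  x <- trimws(x)
  x[x == "" | tolower(x) %in% tolower(na_strings)] <- NA_character_
  x
}

#' Read a cohort from CSV
#'
#' Reads a comma-separated, UTF-8 file with a header row into a
#' \code{\link{cohort}}. Empty cells and the \code{na} sentinel
#' (case-insensitive, default \code{"NA"}) become missing values. A schema
#' mapping adapts arbitrary source headers to the canonical field names.
#' Out-of-range values (negative age, BCS outside 0--5, unknown outcome
#' level, ...) raise a validation error naming the offending row and column;
#' the reader never coerces them silently.
#'
#' @param path Path to a CSV file.
#' @param schema Optional named character vector mapping canonical field
#'   names to source column headers, e.g. \code{c(bcs = "coma_score")}.
#'   Unmapped canonical fields are taken from identically named columns when
#'   present.
#' @param na Character vector of missing-value sentinels (matched
#'   case-insensitively, in addition to the empty cell).
#' @param name Cohort label; defaults to the file name.
#' @return A \code{\link{cohort}}.
#' @export
read_cohort_csv <- function(path, schema = NULL, na = "NA",
                            name = basename(path)) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(schema)) {
    schema <- unlist(schema)
    bad <- setdiff(unname(schema), names(raw))
    if (length(bad)) {
      stop("schema maps to columns absent from the file: ",
           paste(bad, collapse = ", "))
    }
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (src != canon) {
        raw[[canon]] <- raw[[src]]
        raw[[src]] <- NULL
      }
    }
  }
  for (col in names(raw)) raw[[col]] <- .normalise_missing(raw[[col]], na)

  # validate convertible fields cell-by-cell so errors cite row and column
  for (f in intersect(.numeric_fields, names(raw))) {
    val <- suppressWarnings(as.numeric(raw[[f]]))
    bad <- which(!is.na(raw[[f]]) & is.na(val))
    if (length(bad)) {
      stop(sprintf("row %d, column %s: not a number ('%s')",
                   bad[1], f, raw[[f]][bad[1]]))
    }
    raw[[f]] <- val
  }
  coh <- cohort(raw, name = name, validate = FALSE)
  viol <- validate_cohort(coh)
  if (nrow(viol)) {
    rows <- match(viol$id, coh$id)
    stop("invalid cohort file:\n", paste(
      sprintf("  row %d, column %s: %s", rows, viol$field, viol$rule),
      collapse = "\n"))
  }
  coh
}

#' Write a cohort to CSV
#'
#' Inverse of \code{\link{read_cohort_csv}}: missing values are written as
#' the sentinel string so that re-reading reproduces the cohort
#' field-for-field.
#'
#' @param cohort A \code{\link{cohort}}.
#' @param path Destination path.
#' @param na Sentinel written for missing cells.
#' @return \code{path}, invisibly.
#' @export
write_cohort_csv <- function(cohort, path, na = "NA") {
  stopifnot(inherits(cohort, "cohort"))
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = na,
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' Validate a cohort against the record invariants
#'
#' Checks every record: non-negative age, strictly positive vitals when
#' present, integer BCS in 0--5, enumerated levels for categorical fields,
#' and unique record ids. Reports violations instead of throwing, so a dirty
#' cohort can be inspected wholesale.
#'
#' @param cohort A \code{\link{cohort}}.
#' @return A data.frame with columns \code{id}, \code{field}, \code{rule};
#'   zero rows iff the cohort is valid.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  v <- list()
  add <- function(ids, field, rule) {
    if (length(ids)) {
      v[[length(v) + 1]] <<- data.frame(id = ids, field = field, rule = rule,
                                        stringsAsFactors = FALSE)
    }
  }
  dup <- unique(cohort$id[duplicated(cohort$id)])
  add(dup, "id", "duplicate record id")
  add(cohort$id[!is.na(cohort$age_months) & cohort$age_months < 0],
      "age_months", "age_months must be >= 0")
  for (f in c("heart_rate", "respiratory_rate", "crt_seconds")) {
    add(cohort$id[!is.na(cohort[[f]]) & cohort[[f]] <= 0], f,
        paste(f, "must be strictly positive"))
  }
  bad_bcs <- !is.na(cohort$bcs) &
    (cohort$bcs < 0 | cohort$bcs > 5 | cohort$bcs != round(cohort$bcs))
  add(cohort$id[bad_bcs], "bcs", "bcs must be an integer in 0..5")
  for (f in c(.yes_no_fields, .severity_fields, "outcome")) {
    lv <- .levels_for(f)
    bad <- !is.na(cohort[[f]]) & !(cohort[[f]] %in% lv)
    add(cohort$id[bad], f,
        sprintf("%s must be one of {%s}", f, paste(lv, collapse = ", ")))
  }
  if (!length(v)) {
    return(data.frame(id = character(), field = character(),
                      rule = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, v)
}
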