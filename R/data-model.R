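#' Verbal autopsy symptom dataset
#'
#' A `va_data` object holds the dichotomous symptom responses for a set of
#' deaths, together with an optional cause-of-death label (hospital/training
#' data) and an optional stratum label (e.g. age group) used by the
#' stratified estimator.
#'
#' @param symptoms n-by-K matrix (or data frame) of 0/1 symptom indicators.
#' @param cause optional length-n vector of cause-of-death labels.  Kept as
#'   labels internally; the integer coding 1..J follows `cause_names`.
#' @param stratum optional length-n vector of stratum labels.
#' @param symptom_names optional length-K character vector; defaults to the
#'   column names of `symptoms`.
#' @param cause_names optional character vector fixing the cause order.
#'   Defaults to first-appearance order of `cause`, which gives stable
#'   output ordering across runs.
#'
#' @return An object of class `va_data` with elements `symptoms` (integer
#'   matrix), `cause` (integer vector in 1..J or `NULL`), `stratum` (factor
#'   or `NULL`), `symptom_names`, `cause_names`.
#' @export
va_data <- function(symptoms, cause = NULL, stratum = NULL,
                    symptom_names = NULL, cause_names = NULL) {
  symptoms <- as.matrix(symptoms)
  if (nrow(symptoms) < 1L || ncol(symptoms) < 1L)
    stop_va("symptom matrix must have at least one row and one column")
  if (!all(symptoms %in% c(0, 1)))
    stop_va("symptom values must be exactly 0 or 1")
  storage.mode(symptoms) <- "integer"
  symptom_names <- symptom_names %||% colnames(symptoms) %||%
    paste0("s", seq_len(ncol(symptoms)))
  if (length(symptom_names) != ncol(symptoms))
    stop_va("symptom_names length does not match number of symptom columns")
  colnames(symptoms) <- symptom_names

  cause_idx <- NULL
  if (!is.null(cause)) {
    if (length(cause) != nrow(symptoms))
      stop_va("cause labels must have one entry per record")
    cause <- as.character(cause)
    cause_names <- cause_names %||% unique(cause)
    if (!all(cause %in% cause_names))
      stop_va("cause labels outside the supplied cause list: ",
              paste(setdiff(cause, cause_names), collapse = ", "))
    cause_idx <- match(cause, cause_names)
  }
  if (!is.null(stratum)) {
    if (length(stratum) != nrow(symptoms))
      stop_va("stratum labels must have one entry per record")
    stratum <- factor(stratum)
  }
  structure(
    list(symptoms = symptoms, cause = cause_idx, stratum = stratum,
         symptom_names = symptom_names, cause_names = cause_names),
    class = "va_data"
  )
}

#' @export
print.va_data <- function(x, ...) {
  cat("<va_data> ", nrow(x$symptoms), " deaths, ",
      ncol(x$symptoms), " symptoms",
      if (!is.null(x$cause)) paste0(", ", length(x$cause_names),
                                    " causes (labelled)") else " (unlabelled)",
      if (!is.null(x$stratum)) paste0(", strata: ",
                                      paste(levels(x$stratum), collapse = "/")),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.va_data <- function(x) dim(x$symptoms)

n_records <- function(x) nrow(x$symptoms)
n_symptoms <- function(x) ncol(x$symptoms)
n_causes <- function(x) length(x$cause_names)

# Subset records of a va_data (used by the bootstrap and stratified paths).
va_data_rows <- function(x, idx) {
  va_data(x$symptoms[idx, , drop = FALSE],
          cause = if (!is.null(x$cause)) x$cause_names[x$cause[idx]],
          stratum = if (!is.null(x$stratum)) x$stratum[idx],
          symptom_names = x$symptom_names,
          cause_names = x$cause_names)
}

#' Cause-specific mortality fraction vector
#'
#' Constructs a CSMF: a nonnegative vector over causes summing to one, the
#' population quantity of interest P(D).
#'
#' @param fractions numeric vector of cause proportions.
#' @param cause_names optional cause identifiers (defaults to names of
#'   `fractions` or `cause1..causeJ`).
#' @return A named numeric vector of class `csmf`.
#' @export
csmf <- function(fractions, cause_names = NULL) {
  fractions <- as.numeric(fractions)
  cause_names <- cause_names %||% names(fractions) %||%
    paste0("cause", seq_along(fractions))
  if (any(fractions < -1e-12))
    stop_va("CSMF fractions must be nonnegative")
  fractions[fractions < 0] <- 0
  if (abs(sum(fractions) - 1) > 1e-8)
    stop_va("CSMF fractions must sum to 1 (got ", format(sum(fractions)), ")")
  structure(setNames(fractions, cause_names), class = "csmf")
}

#' @export
print.csmf <- function(x, digits = 4, ...) {
  cat("<csmf over", length(x), "causes>\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Validate a verbal autopsy dataset
#'
#' Checks the structural invariants of a `va_data` object (binary symptoms,
#' consistent labels) and returns a machine-readable report rather than
#' stopping, so loaders can surface every problem at once.
#'
#' @param x a `va_data` object or a raw list with the same fields.
#' @return A list of class `va_validation` with `errors` (data frame of
#'   record/field/message), `warnings` (character), and `is_valid`
#'   (`TRUE` iff no errors).
#' @export
validate_va_data <- function(x) {
  errors <- list()
  warnings <- character()
  add_err <- function(record, field, message)
    errors[[length(errors) + 1L]] <<- data.frame(
      record = record, field = field, message = message,
      stringsAsFactors = FALSE)

  sm <- as.matrix(x$symptoms)
  bad <- which(!(sm %in% c(0L, 1L)))
  for (b in bad) {
    rc <- arrayInd(b, dim(sm))
    add_err(rc[1], colnames(sm)[rc[2]] %||% paste0("s", rc[2]),
            paste0("non-binary symptom value ", sm[b]))
  }
  if (!is.null(x$cause)) {
    J <- length(x$cause_names)
    out <- which(is.na(x$cause) | x$cause < 1L | x$cause > J)
    for (i in out) add_err(i, "cause", "cause label outside 1..J")
  }
  if (!is.null(x$stratum) && anyNA(x$stratum))
    warnings <- c(warnings, "missing stratum labels present")

  errors <- if (length(errors)) do.call(rbind, errors) else
    data.frame(record = integer(), field = character(), message = character())
  structure(list(errors = errors, warnings = warnings,
                 is_valid = nrow(errors) == 0L),
            class = "va_validation")
}

#' @export
print.va_validation <- function(x, ...) {
  cat("<va_validation>", if (x$is_valid) "valid" else
    paste(nrow(x$errors), "error(s)"), "\n")
  if (nrow(x$errors)) print(head(x$errors, 10))
  invisible(x)
}

#' Write a validation report as JSON
#'
#' @param report a `va_validation` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  jsonlite::write_json(
    list(is_valid = report$is_valid, errors = report$errors,
         warnings = report$warnings),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a verbal autopsy dataset from a delimited text file
#'
#' Reads a CSV or TSV export of a verbal autopsy questionnaire (delimiter
#' chosen by file extension, `.tsv`/`.txt` = tab) and maps its columns onto
#' a [va_data] object using a schema.
#'
#' @param path file path to a delimited text file with a header row.
#' @param role `"hospital"` (cause column required) or `"community"`
#'   (cause column ignored even if present in the schema).
#' @param schema a list with elements `cause_col` (required for hospital),
#'   and optionally `id_col`, `stratum_col`, and `symptom_cols` (character
#'   vector of column names, or `"auto"` to use every remaining column).
#'   See [read_va_schema] to load one from YAML/JSON.
#' @param missing how to treat missing (NA) symptom responses:
#'   `"strict"` (default) treats them as validation errors; `"zero"`
#'   recodes missing/don't-know as 0 (symptom absent) and reports how many
#'   cells were recoded via a message.
#' @param cause_names optional fixed cause ordering passed to [va_data].
#' @return A validated `va_data` object.
#' @export
read_va_data <- function(path, role = c("hospital", "community"),
                         schema = list(symptom_cols = "auto"),
                         missing = c("strict", "zero"),
                         cause_names = NULL) {
  role <- match.arg(role)
  missing <- match.arg(missing)
  if (!file.exists(path)) stop_va("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  df <- if (ext %in% c("tsv", "txt")) read.delim(path, check.names = FALSE)
        else read.csv(path, check.names = FALSE)

  reserved <- c(schema$id_col, schema$cause_col, schema$stratum_col)
  if (role == "hospital") {
    if (is.null(schema$cause_col))
      stop_va("schema must name a cause_col for hospital data")
    if (!schema$cause_col %in% names(df))
      stop_va("cause column '", schema$cause_col, "' not found in ", path)
  }
  for (col in c(schema$id_col, schema$stratum_col))
    if (!is.null(col) && !col %in% names(df))
      stop_va("schema column '", col, "' not found in ", path)

  sym_cols <- schema$symptom_cols %||% "auto"
  if (identical(sym_cols, "auto")) {
    sym_cols <- setdiff(names(df), reserved)
  } else if (!all(sym_cols %in% names(df))) {
    stop_va("symptom columns missing from ", path, ": ",
            paste(setdiff(sym_cols, names(df)), collapse = ", "))
  }
  if (length(sym_cols) == 0L) stop_va("no symptom columns identified")

  sm <- as.matrix(df[, sym_cols, drop = FALSE])
  suppressWarnings(storage.mode(sm) <- "double")
  if (anyNA(sm)) {
    if (missing == "zero") {
      n_fill <- sum(is.na(sm))
      sm[is.na(sm)] <- 0
      message("recoded ", n_fill, " missing symptom responses to 0")
    } else {
      bad <- which(is.na(sm), arr.ind = TRUE)
      stop_va("missing/non-numeric symptom values under strict policy, ",
              "first at record ", bad[1, 1], ", column '",
              sym_cols[bad[1, 2]], "'")
    }
  }
  nb <- which(!(sm %in% c(0, 1)))
  if (length(nb)) {
    rc <- arrayInd(nb[1], dim(sm))
    stop_va("non-binary symptom value ", sm[nb[1]], " at record ", rc[1],
            ", column '", sym_cols[rc[2]], "'")
  }

  cause <- if (role == "hospital") as.character(df[[schema$cause_col]])
  stratum <- if (!is.null(schema$stratum_col)) df[[schema$stratum_col]]
  va_data(sm, cause = cause, stratum = stratum, symptom_names = sym_cols,
          cause_names = cause_names)
}

#' Read a column-mapping schema from a YAML or JSON file
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file with fields
#'   `id_col`, `cause_col`, `stratum_col`, `symptom_cols`.
#' @return A schema list usable by [read_va_data].
#' @export
read_va_schema <- function(path) {
  if (!file.exists(path)) stop_va("schema file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

#' Write a verbal autopsy dataset to CSV
#'
#' @param x a `va_data` object.
#' @param path output path (`.csv`).
#' @param cause_col,stratum_col column names to use for the labels, when
#'   present.
#' @return `path`, invisibly.
#' @export
write_va_data <- function(x, path, cause_col = "cause",
                          stratum_col = "stratum") {
  df <- as.data.frame(x$symptoms)
  if (!is.null(x$cause)) df[[cause_col]] <- x$cause_names[x$cause]
  if (!is.null(x$stratum)) df[[stratum_col]] <- as.character(x$stratum)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
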