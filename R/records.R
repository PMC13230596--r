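# Tabular experiment records: the interchange types every other module
# consumes. A record set is a data.frame in a fixed canonical schema, one
# row per experiment, carrying provenance (paper, figure, subfigure).
#
# The six target experimental conditions are protein name, protein
# concentration, RNA concentration, pH, temperature and phase status;
# sequence region and modification state are auxiliary annotations kept
# for protein identification but not scored. Concentrations are stored on
# the canonical micromolar scale; a non-NA *_unit column marks a
# non-convertible quantity (e.g. "mg/ml") whose value is on that unit's
# own scale. Missing values are NA, deliberately distinct from the empty
# string: "not extracted" is not the same datum as "extracted as empty".

RECORD_COLUMNS <- c(
  "paper_id", "figure_id", "subfigure_id",
  "protein_name", "sequence_region", "modification_state",
  "protein_conc_um", "protein_conc_unit",
  "rna_conc_um", "rna_conc_unit",
  "ph", "temperature_c", "phase_status"
)

RECORD_COL_TYPES <- c(
  paper_id = "character", figure_id = "character",
  subfigure_id = "character",
  protein_name = "character", sequence_region = "character",
  modification_state = "character",
  protein_conc_um = "numeric", protein_conc_unit = "character",
  rna_conc_um = "numeric", rna_conc_unit = "character",
  ph = "numeric", temperature_c = "numeric", phase_status = "integer"
)

# the six scored fields, in reporting order
TARGET_FIELDS <- c("protein_name", "protein_conc", "rna_conc",
                   "ph", "temperature", "phase_status")

# map scored field -> record column holding its value
FIELD_VALUE_COLUMN <- c(
  protein_name = "protein_name",
  protein_conc = "protein_conc_um",
  rna_conc     = "rna_conc_um",
  ph           = "ph",
  temperature  = "temperature_c",
  phase_status = "phase_status"
)

#' Construct a record set
#'
#' A record set is a `data.frame` in the package's canonical column
#' schema with class `record_set` and an `origin` attribute marking it as
#' curated label data or model-extracted data.
#'
#' @param df A data.frame. Missing canonical columns are added as `NA`;
#'   unknown columns are an error. Column order is normalized.
#' @param origin `"label"` or `"extracted"`.
#' @param validate Check row invariants (default `TRUE`).
#' @return A `record_set` data.frame.
#' @export
record_set <- function(df = NULL, origin = c("extracted", "label"),
                       validate = TRUE) {
  origin <- match.arg(origin)
  if (is.null(df)) df <- data.frame()
  if (!is.data.frame(df)) {
    llps_validation_error("`df` must be a data.frame")
  }
  unknown <- setdiff(names(df), RECORD_COLUMNS)
  if (length(unknown) > 0) {
    llps_validation_error(sprintf(
      "unknown column(s): %s; accepted columns are: %s",
      paste(unknown, collapse = ", "),
      paste(RECORD_COLUMNS, collapse = ", ")
    ))
  }
  n <- nrow(df)
  out <- data.frame(row.names = seq_len(max(n, 0L)))
  for (col in RECORD_COLUMNS) {
    if (col %in% names(df)) {
      v <- df[[col]]
      v <- coerce_column(v, col)
    } else {
      v <- vector(RECORD_COL_TYPES[[col]], n)
      is.na(v) <- seq_len(n)
    }
    out[[col]] <- v
  }
  rownames(out) <- NULL
  class(out) <- c("record_set", "data.frame")
  attr(out, "origin") <- origin
  if (validate) validate_record_set(out)
  out
}

coerce_column <- function(v, col) {
  type <- RECORD_COL_TYPES[[col]]
  if (type == "character") {
    v <- as.character(v)
    v[!is.na(v) & v == ""] <- NA_character_
    return(v)
  }
  if (is.character(v)) v[!is.na(v) & trimws(v) == ""] <- NA
  if (type == "integer") {
    vi <- suppressWarnings(as.integer(v))
    bad <- which(!is.na(v) & (is.na(vi) | suppressWarnings(as.numeric(v)) != vi))
    if (length(bad) > 0) {
      llps_validation_error(sprintf(
        "row %d: field '%s' is not an integer code: %s",
        bad[1], col, v[bad[1]]), row = bad[1], field = col)
    }
    return(vi)
  }
  vn <- suppressWarnings(as.numeric(v))
  bad <- which(!is.na(v) & is.na(vn))
  if (length(bad) > 0) {
    llps_validation_error(sprintf(
      "row %d: field '%s' is not numeric: %s",
      bad[1], col, v[bad[1]]), row = bad[1], field = col)
  }
  vn
}

#' Validate record-set invariants
#'
#' Checks, per row: at least one of the six target fields present; pH in
#' \[0, 14\]; phase status strictly binary (0/1); finite numeric values;
#' a unit column never set without its value.
#'
#' @param rs A `record_set`.
#' @return `rs`, invisibly; signals a validation error otherwise.
#' @export
validate_record_set <- function(rs) {
  if (nrow(rs) == 0) return(invisible(rs))
  if (anyNA(rs$paper_id)) {
    llps_validation_error(sprintf(
      "row %d: field 'paper_id' is missing", which(is.na(rs$paper_id))[1]),
      row = which(is.na(rs$paper_id))[1], field = "paper_id")
  }
  for (col in c("protein_conc_um", "rna_conc_um", "ph", "temperature_c")) {
    bad <- which(!is.na(rs[[col]]) & !is.finite(rs[[col]]))
    if (length(bad) > 0) {
      llps_validation_error(sprintf(
        "row %d: field '%s' is not finite", bad[1], col),
        row = bad[1], field = col)
    }
  }
  bad <- which(!is.na(rs$ph) & (rs$ph < 0 | rs$ph > 14))
  if (length(bad) > 0) {
    llps_validation_error(sprintf(
      "row %d: field 'ph' outside [0, 14]: %s", bad[1], rs$ph[bad[1]]),
      row = bad[1], field = "ph")
  }
  bad <- which(!is.na(rs$phase_status) & !(rs$phase_status %in% c(0L, 1L)))
  if (length(bad) > 0) {
    llps_validation_error(sprintf(
      "row %d: field 'phase_status' must be 0 or 1, got %s",
      bad[1], rs$phase_status[bad[1]]), row = bad[1], field = "phase_status")
  }
  for (pre in c("protein_conc", "rna_conc")) {
    val <- rs[[paste0(pre, "_um")]]
    unit <- rs[[paste0(pre, "_unit")]]
    bad <- which(!is.na(unit) & is.na(val))
    if (length(bad) > 0) {
      llps_validation_error(sprintf(
        "row %d: field '%s_unit' set without a value", bad[1], pre),
        row = bad[1], field = paste0(pre, "_unit"))
    }
  }
  present <- field_presence(rs)
  bad <- which(rowSums(present) == 0)
  if (length(bad) > 0) {
    llps_validation_error(sprintf(
      "row %d: none of the six target fields is present", bad[1]),
      row = bad[1], field = NA_character_)
  }
  invisible(rs)
}

# logical matrix rows x TARGET_FIELDS: is the scored field present?
field_presence <- function(rs) {
  m <- sapply(TARGET_FIELDS, function(f) !is.na(rs[[FIELD_VALUE_COLUMN[[f]]]]))
  if (nrow(rs) == 1L) m <- matrix(m, nrow = 1, dimnames = list(NULL, TARGET_FIELDS))
  m
}

#' @export
print.record_set <- function(x, ...) {
  cat(sprintf("<record_set> %d record(s), origin: %s\n",
              nrow(x), attr(x, "origin") %||% "?"))
  if (nrow(x) > 0) {
    print.data.frame(utils::head(as.data.frame(x), 10))
    if (nrow(x) > 10) cat(sprintf("... and %d more rows\n", nrow(x) - 10))
  }
  invisible(x)
}

## Readers / writers -----------------------------------------------------

table_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "json") "json" else if (ext == "csv") "csv"
  else llps_validation_error(sprintf(
    "cannot infer table format from '%s' (use .csv or .json)", path))
}

#' Read a record table
#'
#' Reads a CSV (RFC 4180, UTF-8, header required) or JSON (array of flat
#' objects) file in the canonical record schema. Empty cells / nulls
#' become missing markers; row order is preserved.
#'
#' @param path File path ending in `.csv` or `.json`.
#' @param origin `"label"` or `"extracted"`.
#' @return A [record_set].
#' @export
read_record_table <- function(path, origin = c("extracted", "label")) {
  origin <- match.arg(origin)
  if (!file.exists(path)) {
    llps_validation_error(sprintf("file not found: %s", path))
  }
  fmt <- table_format(path)
  if (fmt == "csv") {
    df <- utils::read.csv(path, colClasses = "character",
                          check.names = FALSE, fileEncoding = "UTF-8")
  } else {
    obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                              simplifyDataFrame = TRUE)
    if (length(obj) == 0) obj <- data.frame()
    if (!is.data.frame(obj)) {
      llps_validation_error(sprintf(
        "%s: expected a JSON array of flat objects", path))
    }
    df <- obj
  }
  record_set(df, origin = origin)
}

#' Write a record table
#'
#' Writes a record set as CSV or JSON (by extension) with a fixed column
#' order and shortest-round-trip number formatting, so that re-reading
#' yields an equal set and write-read-write is byte-identical.
#'
#' @param rs A [record_set].
#' @param path Destination path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_record_table <- function(rs, path) {
  validate_record_set(rs)
  fmt <- table_format(path)
  df <- as.data.frame(rs)[, RECORD_COLUMNS, drop = FALSE]
  if (fmt == "csv") {
    lines <- c(paste(RECORD_COLUMNS, collapse = ","))
    if (nrow(df) > 0) {
      cells <- sapply(RECORD_COLUMNS, function(col) {
        v <- df[[col]]
        s <- if (is.numeric(v) && !is.integer(v)) fmt_num(v) else as.character(v)
        s[is.na(s)] <- ""
        csv_escape(s)
      })
      if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1)
      lines <- c(lines, apply(cells, 1, paste, collapse = ","))
    }
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
  } else {
    rows <- lapply(seq_len(nrow(df)), function(i) {
      row <- lapply(RECORD_COLUMNS, function(col) df[[col]][i])
      names(row) <- RECORD_COLUMNS
      row[!vapply(row, is.na, logical(1))]
    })
    txt <- jsonlite::toJSON(rows, auto_unbox = TRUE, digits = I(17),
                            pretty = TRUE)
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(txt, con, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}

csv_escape <- function(s) {
  needs <- grepl('[",\n]', s)
  s[needs] <- paste0('"', gsub('"', '""', s[needs]), '"')
  s
}

# scope key used to pair extracted and label data
scope_key <- function(rs, scope = c("figure", "paper")) {
  scope <- match.arg(scope)
  if (nrow(rs) == 0) return(character(0))
  if (scope == "paper") rs$paper_id
  else paste(rs$paper_id, ifelse(is.na(rs$figure_id), "<paper>", rs$figure_id),
             sep = "::")
}
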