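# Rule-based standardization of extracted values before evaluation.
#
# Temperatures are reported on the Celsius scale with textual aliases
# ("RT", "room temperature") collapsed to 25 degrees C; molar
# concentrations are rescaled to micromolar; mass-per-volume units such
# as mg/mL cannot be converted without a molecular weight and are passed
# through unchanged, flagged non-convertible; protein names are
# casefolded, whitespace-collapsed and mapped through a user-supplied
# synonym table; phase status is mapped from a free-text vocabulary to a
# strict binary outcome.

#' Normalization rule set
#'
#' Bundles the lookup tables driving value standardization. All alias
#' lookups are case-insensitive (keys are folded on construction);
#' canonical names must be fixed points of the synonym map.
#'
#' @param temperature_aliases Named numeric: folded text alias -> Celsius
#'   value. Must cover the room-temperature aliases.
#' @param molar_unit_factors Named numeric: folded molar unit symbol ->
#'   multiplier to micromolar.
#' @param non_convertible_units Character: folded unit symbols passed
#'   through unchanged (value kept on its own scale).
#' @param protein_synonyms Named character: folded alias -> canonical
#'   name. Ships empty; protein dictionaries are corpus-specific
#'   configuration.
#' @param phase_vocab Named integer (0/1): folded token -> binary phase
#'   status.
#' @return A `normalization_rules` object.
#' @export
normalization_rules <- function(
    temperature_aliases = c(
      "rt" = 25, "r.t." = 25, "rt." = 25, "room temperature" = 25,
      "room temp" = 25, "ambient" = 25, "ambient temperature" = 25),
    molar_unit_factors = c(
      "m" = 1e6, "mm" = 1e3, "um" = 1, "nm" = 1e-3, "pm" = 1e-6),
    non_convertible_units = c(
      "mg/ml", "ug/ml", "ng/ul", "ng/ml", "g/l", "%", "%w/v", "wt%"),
    protein_synonyms = character(0),
    phase_vocab = c(
      "droplet" = 1L, "droplets" = 1L, "llps" = 1L, "condensate" = 1L,
      "condensates" = 1L, "phase separation" = 1L, "phase separated" = 1L,
      "phase-separated" = 1L, "two-phase" = 1L, "two phase" = 1L,
      "two phases" = 1L, "demixed" = 1L, "ps" = 1L, "yes" = 1L, "1" = 1L,
      "soluble" = 0L, "one phase" = 0L, "one-phase" = 0L,
      "single phase" = 0L, "no llps" = 0L, "no phase separation" = 0L,
      "homogeneous" = 0L, "mixed" = 0L, "dilute" = 0L, "no" = 0L,
      "0" = 0L)) {
  names(temperature_aliases) <- fold_text(names(temperature_aliases))
  names(molar_unit_factors) <- fold_unit(names(molar_unit_factors))
  non_convertible_units <- fold_unit(non_convertible_units)
  if (length(protein_synonyms) > 0) {
    names(protein_synonyms) <- fold_text(names(protein_synonyms))
    canon <- unname(protein_synonyms)
    fp <- fold_text(canon)
    not_fixed <- canon[fp %in% names(protein_synonyms) &
                         protein_synonyms[fp] != canon]
    if (length(not_fixed) > 0) {
      llps_config_error(sprintf(
        "canonical name(s) not fixed points of the synonym map: %s",
        paste(unique(not_fixed), collapse = ", ")))
    }
  }
  names(phase_vocab) <- fold_text(names(phase_vocab))
  if (any(molar_unit_factors <= 0)) {
    llps_config_error("molar unit factors must be positive")
  }
  structure(
    list(temperature_aliases = temperature_aliases,
         molar_unit_factors = molar_unit_factors,
         non_convertible_units = non_convertible_units,
         protein_synonyms = protein_synonyms,
         phase_vocab = phase_vocab),
    class = "normalization_rules")
}

#' Load normalization rules from a YAML or JSON file
#'
#' Any omitted section falls back to the package defaults. A default
#' rules file ships under `inst/extdata/default_rules.yaml`.
#'
#' @param path YAML or JSON file.
#' @return A [normalization_rules] object.
#' @export
read_normalization_rules <- function(path) {
  if (!file.exists(path)) {
    llps_config_error(sprintf("rules file not found: %s", path))
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- list()
  if (!is.null(raw$temperature_aliases)) {
    args$temperature_aliases <- unlist(raw$temperature_aliases)
  }
  if (!is.null(raw$molar_unit_factors)) {
    args$molar_unit_factors <- unlist(raw$molar_unit_factors)
  }
  if (!is.null(raw$non_convertible_units)) {
    args$non_convertible_units <- as.character(unlist(raw$non_convertible_units))
  }
  if (!is.null(raw$protein_synonyms)) {
    syn <- unlist(raw$protein_synonyms)
    args$protein_synonyms <- stats::setNames(as.character(syn), names(syn))
  }
  if (!is.null(raw$phase_vocab)) {
    pv <- unlist(raw$phase_vocab)
    args$phase_vocab <- stats::setNames(as.integer(pv), names(pv))
  }
  do.call(normalization_rules, args)
}

#' Default normalization rules
#' @return A [normalization_rules] object with package defaults.
#' @export
default_rules <- function() normalization_rules()

quantity <- function(value, unit, convertible = TRUE) {
  if (!is.na(value) && !is.finite(value)) {
    llps_normalization_error("quantity value must be finite")
  }
  structure(list(value = value, unit = unit, convertible = convertible),
            class = "quantity")
}

## Temperature -----------------------------------------------------------

#' Normalize a temperature to Celsius
#'
#' Resolves textual aliases (e.g. `"RT"` -> 25), parses numeric strings
#' with Celsius, Kelvin or Fahrenheit units, and accepts bare numbers as
#' Celsius. Numeric input is taken as already canonical.
#'
#' @param raw Number or non-empty string.
#' @param rules A [normalization_rules] object.
#' @return A `quantity` with unit `"°C"`.
#' @export
normalize_temperature <- function(raw, rules = default_rules()) {
  if (is.numeric(raw)) return(quantity(raw, "°C"))
  txt <- fold_text(raw)
  if (txt == "") llps_normalization_error("empty temperature", raw = raw)
  alias <- rules$temperature_aliases[txt]
  if (!is.na(alias)) return(quantity(unname(alias), "°C"))
  m <- regmatches(txt, regexec(
    "^([+-]?[0-9]*\\.?[0-9]+(?:e[+-]?[0-9]+)?)\\s*(°?\\s*c|celsius|deg\\.?\\s*c|k|kelvin|°?\\s*f|fahrenheit|)$",
    txt))[[1]]
  if (length(m) == 0) {
    llps_normalization_error(
      sprintf("cannot parse temperature: '%s'", raw), raw = raw)
  }
  value <- as.numeric(m[2])
  unit <- gsub("[°. ]", "", m[3])
  value <- switch(unit,
    "k" = , "kelvin" = value - 273.15,
    "f" = , "fahrenheit" = (value - 32) * 5 / 9,
    value)
  quantity(value, "°C")
}

## Concentration ---------------------------------------------------------

#' Normalize a concentration to micromolar
#'
#' Molar units are rescaled to the canonical micromolar scale
#' (`convertible = TRUE`). Units listed as non-convertible (mg/mL and
#' kin) keep their value and unit unchanged with `convertible = FALSE`:
#' converting them to molar would require a molecular weight. Numeric
#' input is taken as micromolar.
#'
#' @param raw Number, or string containing a number and a unit token.
#' @param rules A [normalization_rules] object.
#' @return A `quantity`.
#' @export
normalize_concentration <- function(raw, rules = default_rules()) {
  if (is.numeric(raw)) return(quantity(raw, "uM"))
  txt <- trimws(raw)
  m <- regmatches(txt, regexec(
    "^([+-]?[0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?)\\s*(.*)$", txt))[[1]]
  if (length(m) == 0 || m[2] == "") {
    llps_normalization_error(
      sprintf("no parseable number in concentration: '%s'", raw), raw = raw)
  }
  value <- as.numeric(m[2])
  unit <- fold_unit(m[3])
  if (unit == "") {
    llps_normalization_error(
      sprintf("concentration without a unit: '%s'", raw), raw = raw)
  }
  factor <- rules$molar_unit_factors[unit]
  if (!is.na(factor)) {
    return(quantity(value * unname(factor), "uM"))
  }
  if (unit %in% rules$non_convertible_units) {
    return(quantity(value, unit, convertible = FALSE))
  }
  llps_normalization_error(
    sprintf("unknown concentration unit: '%s'", m[3]), raw = raw)
}

## Protein names ---------------------------------------------------------

#' Canonicalize a protein name
#'
#' Casefolds, collapses whitespace and maps through the synonym table;
#' names absent from the table pass through folded. Total on non-empty
#' text.
#'
#' @param raw Non-empty string.
#' @param rules A [normalization_rules] object.
#' @return Canonical name string.
#' @export
canonicalize_protein_name <- function(raw, rules = default_rules()) {
  key <- fold_text(raw)
  canon <- rules$protein_synonyms[key]
  if (!is.na(canon)) unname(canon) else key
}

## Phase status ----------------------------------------------------------

#' Normalize a phase-status token to binary
#'
#' Maps free-text outcome tokens ("droplets", "soluble", ...) through the
#' phase vocabulary to 0/1. Numeric and logical inputs are accepted
#' directly; unmapped tokens are a normalization error, since phase
#' status is strictly binary.
#'
#' @param raw Token, number or logical.
#' @param rules A [normalization_rules] object.
#' @return Integer 0 or 1.
#' @export
normalize_phase <- function(raw, rules = default_rules()) {
  if (is.logical(raw)) return(as.integer(raw))
  if (is.numeric(raw)) {
    if (!raw %in% c(0, 1)) {
      llps_normalization_error(
        sprintf("phase status must be binary, got %s", raw), raw = raw)
    }
    return(as.integer(raw))
  }
  key <- fold_text(raw)
  val <- rules$phase_vocab[key]
  if (is.na(val)) {
    llps_normalization_error(
      sprintf("phase-status token not in vocabulary: '%s'", raw), raw = raw)
  }
  unname(val)
}

## Whole records ---------------------------------------------------------

#' Normalize one raw record
#'
#' Applies the field normalizers to a named list as produced by
#' [parse_model_output()]: `protein_name`, `protein_conc`, `rna_conc`,
#' `ph`, `temperature`, `phase_status`, plus auxiliary
#' `sequence_region` / `modification_state` and provenance. Missing
#' fields are untouched; per-field normalization failures are collected
#' (attribute `"errors"`), never fatal — the failing field is kept raw
#' and flagged non-convertible where the schema allows, or dropped to
#' missing otherwise. Idempotent: canonical values pass through.
#'
#' A leading "pH" token on the pH field is stripped before parsing.
#'
#' @param rec Named list of raw field values.
#' @param rules A [normalization_rules] object.
#' @return Named list in canonical columns (subset of [RECORD_COLUMNS]).
#' @export
normalize_record <- function(rec, rules = default_rules()) {
  out <- list()
  errs <- character(0)
  if (!is.null(rec[["paper_id"]])) out$paper_id <- as.character(rec[["paper_id"]])
  if (!is.null(rec[["figure_id"]])) out$figure_id <- as.character(rec[["figure_id"]])
  if (!is.null(rec[["subfigure_id"]])) out$subfigure_id <- as.character(rec[["subfigure_id"]])

  if (has_value(rec[["protein_name"]])) {
    out$protein_name <- canonicalize_protein_name(rec[["protein_name"]], rules)
  }
  for (aux in c("sequence_region", "modification_state")) {
    if (has_value(rec[[aux]])) out[[aux]] <- fold_text(rec[[aux]])
  }
  for (spec in list(c("protein_conc", "protein_conc_um", "protein_conc_unit"),
                    c("rna_conc", "rna_conc_um", "rna_conc_unit"))) {
    raw <- rec[[spec[1]]] %||% rec[[spec[2]]]
    unit <- rec[[spec[3]]]
    if (has_value(raw)) {
      if (is.numeric(raw) && has_value(unit)) {
        # already canonical non-convertible pair: pass through
        out[[spec[2]]] <- raw
        out[[spec[3]]] <- fold_unit(unit)
      } else {
        q <- tryCatch(normalize_concentration(raw, rules),
                      llps_normalization_error = function(e) e)
        if (inherits(q, "condition")) {
          errs <- c(errs, conditionMessage(q))
          out[[spec[2]]] <- suppressWarnings(as.numeric(gsub("[^0-9.eE+-]", "", as.character(raw))))
          if (is.na(out[[spec[2]]])) out[[spec[2]]] <- NULL
          else out[[spec[3]]] <- fold_unit(as.character(raw))
        } else {
          out[[spec[2]]] <- q$value
          if (!q$convertible) out[[spec[3]]] <- q$unit
        }
      }
    }
  }
  if (has_value(rec[["ph"]])) {
    raw <- rec[["ph"]]
    if (is.character(raw)) raw <- sub("^\\s*ph\\s*", "", raw, ignore.case = TRUE)
    v <- suppressWarnings(as.numeric(raw))
    if (is.na(v)) errs <- c(errs, sprintf("cannot parse pH: '%s'", rec[["ph"]]))
    else out$ph <- v
  }
  if (has_value(rec[["temperature"]]) || has_value(rec[["temperature_c"]])) {
    raw <- rec[["temperature"]] %||% rec[["temperature_c"]]
    q <- tryCatch(normalize_temperature(raw, rules),
                  llps_normalization_error = function(e) e)
    if (inherits(q, "condition")) errs <- c(errs, conditionMessage(q))
    else out$temperature_c <- q$value
  }
  if (has_value(rec[["phase_status"]])) {
    v <- tryCatch(normalize_phase(rec[["phase_status"]], rules),
                  llps_normalization_error = function(e) e)
    if (inherits(v, "condition")) errs <- c(errs, conditionMessage(v))
    else out$phase_status <- v
  }
  if (length(errs) > 0) attr(out, "errors") <- errs
  out
}

has_value <- function(x) {
  !is.null(x) && length(x) == 1 && !is.na(x) &&
    !(is.character(x) && trimws(x) == "")
}

#' Normalize a list of raw records into a record set
#'
#' @param recs List of named lists (raw records).
#' @param rules A [normalization_rules] object.
#' @param paper_id,figure_id,subfigure_id Provenance applied to records
#'   that do not carry their own.
#' @param origin Origin tag for the resulting set.
#' @return A [record_set]; rows violating record invariants are dropped
#'   with a diagnostic in attribute `"diagnostics"`.
#' @export
normalize_records <- function(recs, rules = default_rules(),
                              paper_id = NULL, figure_id = NULL,
                              subfigure_id = NULL, origin = "extracted") {
  diags <- character(0)
  rows <- list()
  for (i in seq_along(recs)) {
    nr <- normalize_record(recs[[i]], rules)
    if (!is.null(attr(nr, "errors"))) {
      diags <- c(diags, sprintf("record %d: %s", i,
                                paste(attr(nr, "errors"), collapse = "; ")))
    }
    nr$paper_id <- nr$paper_id %||% paper_id
    nr$figure_id <- nr$figure_id %||% figure_id
    nr$subfigure_id <- nr$subfigure_id %||% subfigure_id
    if (!any(names(nr) %in% FIELD_VALUE_COLUMN)) {
      diags <- c(diags, sprintf(
        "record %d: no target field present after normalization; dropped", i))
      next
    }
    row <- stats::setNames(rep(list(NA), length(RECORD_COLUMNS)), RECORD_COLUMNS)
    for (nm in intersect(names(nr), RECORD_COLUMNS)) row[[nm]] <- nr[[nm]]
    rows[[length(rows) + 1L]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  df <- if (length(rows) > 0) do.call(rbind, rows) else data.frame()
  rs <- record_set(df, origin = origin)
  if (length(diags) > 0) attr(rs, "diagnostics") <- diags
  rs
}
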