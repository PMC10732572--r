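# Tabular IO with unit-tagged column names, and machine-readable result
# reports.  Columns carry their unit as a suffix (e.g. conc_uM, time_s,
# temp_C); reading normalises everything to molar / seconds / degC
# internally, writing re-applies the tags.

# recognised unit suffixes and the factor converting to the internal unit
.UNIT_TAGS <- list(
  M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9,     # -> molar
  L = 1, ml = 1e-3, ul = 1e-6,                  # -> liters
  s = 1, min = 60,                              # -> seconds
  C = 1,                                        # degC at the boundary
  nm = 1,                                       # wavelength shift
  kcal_per_mol = 1
)

.split_unit <- function(colname) {
  # longest matching suffix wins (so `_kcal_per_mol` beats a bare `_mol`)
  tags <- names(.UNIT_TAGS)[order(-nchar(names(.UNIT_TAGS)))]
  for (tag in tags) {
    suffix <- paste0("_", tag)
    if (endsWith(colname, suffix) && nchar(colname) > nchar(suffix))
      return(list(base = substr(colname, 1L, nchar(colname) - nchar(suffix)),
                  unit = tag, factor = .UNIT_TAGS[[tag]]))
  }
  list(base = colname, unit = NA_character_, factor = 1)
}

#' Read a unit-tagged CSV table
#'
#' Numeric columns whose names end in a recognised unit tag (`_M`, `_mM`,
#' `_uM`, `_nM`, `_s`, `_min`, `_C`, `_nm`, `_kcal_per_mol`) are converted
#' to internal units (molar, seconds, degC) and the tag is stripped from
#' the column name.  Untagged numeric columns are an error when
#' `require_units = TRUE` unless listed in `unitless`.
#'
#' @param path CSV file path.
#' @param require_units Insist every numeric column is tagged or whitelisted
#'   (default TRUE).
#' @param unitless Column names allowed without a tag (default
#'   `c("injection", "replicate", "y", "F", "ratio", "phase", "condition",
#'   "sample", "molar_ratio")`).
#' @return Data frame in internal units; the original units are kept in
#'   `attr(, "units")`.
#' @export
read_table <- function(path, require_units = TRUE,
                       unitless = c("injection", "replicate", "y", "F",
                                    "ratio", "phase", "condition", "sample",
                                    "molar_ratio")) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  units <- character(0)
  out <- df
  names_out <- names(df)
  for (i in seq_along(df)) {
    nm <- names(df)[i]
    info <- .split_unit(nm)
    if (!is.na(info$unit)) {
      out[[i]] <- df[[i]] * info$factor
      names_out[i] <- info$base
      units[info$base] <- info$unit
    } else if (require_units && is.numeric(df[[i]]) && !nm %in% unitless) {
      stop(sprintf(
        "column '%s' has no unit tag; accepted tags: %s (or list it in `unitless`)",
        nm, paste(names(.UNIT_TAGS), collapse = ", ")), call. = FALSE)
    }
  }
  names(out) <- names_out
  attr(out, "units") <- units
  out
}

#' Write a table with unit-tagged column names
#'
#' Inverse of [read_table()]: columns named in `units` are converted from
#' internal units back to the stated unit and the tag is appended.
#'
#' @param df Data frame in internal units.
#' @param path Output CSV path.
#' @param units Named character vector, e.g. `c(conc = "uM", time = "s")`.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, units = attr(df, "units")) {
  out <- df
  if (length(units)) {
    for (base in names(units)) {
      if (!base %in% names(out)) next
      u <- units[[base]]
      if (!u %in% names(.UNIT_TAGS))
        stop("unknown unit tag '", u, "'", call. = FALSE)
      out[[base]] <- out[[base]] / .UNIT_TAGS[[u]]
      names(out)[names(out) == base] <- paste0(base, "_", u)
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble a machine-readable result report
#'
#' Standard container for a fit result: parameters with units and standard
#' errors, diagnostics, and provenance (input hash, seed, package version).
#' Serialises losslessly to JSON via [write_report()].
#'
#' @param assay Assay kind (e.g. "itc", "bli", "activation").
#' @param parameters Named list; each element a list with `value`, `unit`
#'   and optionally `se`.
#' @param diagnostics Named list (rss, convergence, warnings, ...).
#' @param seed Seed used, if any.
#' @param input Optional path or object the fit consumed; hashed into
#'   provenance.
#' @return Object of class `result_report`.
#' @export
result_report <- function(assay, parameters, diagnostics = list(),
                          seed = NA_integer_, input = NULL) {
  hash <- if (is.null(input)) NA_character_ else {
    x <- if (is.character(input) && length(input) == 1L && file.exists(input))
      readLines(input, warn = FALSE) else utils::capture.output(utils::str(input))
    sprintf("%08x", sum(utf8ToInt(paste(x, collapse = "\n")) *
                          (seq_along(utf8ToInt(paste(x, collapse = "\n"))) %% 997)))
  }
  structure(
    list(schema_version = "1.0", assay = assay, parameters = parameters,
         diagnostics = diagnostics,
         provenance = list(seed = seed, input_hash = hash,
                           package_version = as.character(
                             utils::packageVersion("bindassay")))),
    class = "result_report"
  )
}

#' Write a result report to JSON
#'
#' @param report A [result_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "result_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Read a result report from JSON
#'
#' @param path JSON path written by [write_report()].
#' @return A `result_report`.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  structure(x, class = "result_report")
}
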