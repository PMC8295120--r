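#' Read a conformer free-energy table from CSV
#'
#' One row per conformer: \code{compound_id, conformer_id, gas_energy_kcal,
#' thermal_water_kcal, thermal_octanol_kcal, dgsolv_water_kcal,
#' dgsolv_octanol_kcal}. The octanol columns may be absent or empty for
#' aqueous-only data sets. Malformed numbers, missing mandatory columns and
#' duplicate (compound, conformer) rows are reported with the offending
#' line number.
#'
#' @param path Path to the CSV file.
#' @return A \code{\link{conformer_table}}, row order preserved.
#' @export
read_conformer_table <- function(path) {
  raw <- .read_csv_chr(path)
  need <- c("compound_id", "conformer_id", "gas_energy_kcal",
            "thermal_water_kcal", "dgsolv_water_kcal")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  key <- paste(raw$compound_id, raw$conformer_id, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    stop(sprintf("%s: duplicate (compound_id, conformer_id) row at line %d: %s/%s",
                 path, i + 1L, raw$compound_id[i], raw$conformer_id[i]))
  }
  for (col in setdiff(names(raw), c("compound_id", "conformer_id")))
    raw[[col]] <- .num_col(raw[[col]], col, path,
                           allow_na = grepl("octanol", col))
  conformer_table(raw)
}

.read_csv_chr <- function(path, skip = 0L) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, colClasses = "character", check.names = FALSE,
                  skip = skip, comment.char = "#",
                  stringsAsFactors = FALSE)
}

.num_col <- function(x, col, path, allow_na = FALSE) {
  blank <- is.na(x) | !nzchar(trimws(x))
  v <- suppressWarnings(as.numeric(x))
  bad <- !blank & !is.finite(v)
  if (any(bad))
    stop(sprintf("%s: malformed number '%s' in column %s at line %d",
                 path, x[bad][1L], col, which(bad)[1L] + 1L))
  if (any(blank) && !allow_na)
    stop(sprintf("%s: missing value in mandatory column %s at line %d",
                 path, col, which(blank)[1L] + 1L))
  v
}

#' Read a microstate free-energy table from CSV
#'
#' Long format, one row per (microstate, conformer):
#' \code{compound_id, microstate_id, formal_charge, conformer_id,
#' free_energy_kcal}. The file must declare its free-energy dialect in a
#' leading comment line, e.g. \code{# dialect: absolute_aqueous} or
#' \code{# dialect: relative_transition} (the latter additionally
#' \code{# reference: <microstate_id>}); an undeclared dialect is an error,
#' never guessed.
#'
#' @param path Path to the CSV file.
#' @return data.frame with attributes \code{dialect} and (when relative)
#'   \code{reference}; feed to \code{\link{as_microstate_sets}} or
#'   \code{\link{pka_table}}.
#' @export
read_microstate_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  head_lines <- grep("^#", readLines(path, n = 10L), value = TRUE)
  meta <- function(key) {
    hit <- grep(paste0("^#\\s*", key, "\\s*:"), head_lines, value = TRUE)
    if (!length(hit)) return(NULL)
    trimws(sub(paste0("^#\\s*", key, "\\s*:"), "", hit[1L]))
  }
  dialect <- meta("dialect")
  if (is.null(dialect))
    stop(path, ": missing '# dialect:' declaration ",
         "(absolute_aqueous or relative_transition)")
  if (!dialect %in% c("absolute_aqueous", "relative_transition"))
    stop(path, ": unknown dialect '", dialect, "'")
  raw <- .read_csv_chr(path)
  need <- c("compound_id", "microstate_id", "formal_charge",
            "conformer_id", "free_energy_kcal")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  key <- paste(raw$compound_id, raw$microstate_id, raw$conformer_id, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    stop(sprintf("%s: duplicate (microstate, conformer) row at line %d: %s/%s",
                 path, i + 1L, raw$microstate_id[i], raw$conformer_id[i]))
  }
  raw$formal_charge <- as.integer(.num_col(raw$formal_charge, "formal_charge", path))
  raw$free_energy_kcal <- .num_col(raw$free_energy_kcal, "free_energy_kcal", path)
  attr(raw, "dialect") <- dialect
  if (dialect == "relative_transition") {
    ref <- meta("reference")
    if (is.null(ref) || !ref %in% raw$microstate_id)
      stop(path, ": relative_transition dialect requires a '# reference:' ",
           "line naming a microstate in the table")
    attr(raw, "reference") <- ref
  }
  raw
}

#' Write a conformer or microstate table to CSV
#'
#' Writers matching \code{\link{read_conformer_table}} and
#' \code{\link{read_microstate_table}}; the microstate writer emits the
#' dialect (and reference) metadata lines from the table's attributes.
#'
#' @param x The table to write.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_conformer_table <- function(x, path) {
  x <- conformer_table(x)
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_conformer_table
#' @export
write_microstate_table <- function(x, path) {
  dialect <- attr(x, "dialect")
  if (is.null(dialect)) stop("microstate table has no 'dialect' attribute")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("# dialect: ", dialect), con)
  if (identical(dialect, "relative_transition"))
    writeLines(paste0("# reference: ", attr(x, "reference")), con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write predictions to disk
#'
#' \code{format = "csv"} writes \code{compound_id, property, value} rows at
#' 4 decimal places, sorted by compound then property, plus a full-precision
#' machine-readable sidecar \code{<path>.full.csv}; \code{format = "sampl"}
#' writes a simplified challenge-submission dialect (versioned header; one
#' \code{compound_id,value,uncertainty} line per prediction, placeholder
#' uncertainty).
#'
#' @param results data.frame with columns \code{compound_id},
#'   \code{property} and \code{value} (e.g. stacked \code{\link{logp_table}}
#'   / \code{\link{pka_table}} output).
#' @param path Output path.
#' @param format \code{"csv"} or \code{"sampl"}.
#' @return \code{path}, invisibly.
#' @export
write_predictions <- function(results, path, format = c("csv", "sampl")) {
  format <- match.arg(format)
  results <- as.data.frame(results)
  stopifnot(all(c("compound_id", "property", "value") %in% names(results)),
            nrow(results) > 0L)
  results <- results[order(results$compound_id, results$property,
                           method = "radix"), , drop = FALSE]
  if (format == "csv") {
    disp <- results
    disp$value <- sprintf("%.4f", disp$value)
    utils::write.csv(disp, path, row.names = FALSE, quote = FALSE)
    full <- results
    full$value <- sprintf("%.17g", full$value)
    utils::write.csv(full, paste0(path, ".full.csv"),
                     row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("# logpka-sampl-predictions v1",
                 "# compound_id,property,value,uncertainty"), con)
    writeLines(sprintf("%s,%s,%.4f,NA", results$compound_id,
                       results$property, results$value), con)
  }
  invisible(path)
}

#' Read back written predictions
#'
#' Reads the full-precision sidecar when present, otherwise the 4-decimal
#' display file.
#'
#' @param path Path given to \code{\link{write_predictions}}.
#' @return data.frame \code{compound_id, property, value}.
#' @export
read_predictions <- function(path) {
  full <- paste0(path, ".full.csv")
  raw <- .read_csv_chr(if (file.exists(full)) full else path)
  raw$value <- .num_col(raw$value, "value", path)
  raw
}
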