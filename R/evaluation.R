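#' Paired calculated/experimental prediction records
#'
#' Builds the record table on which all prediction-versus-experiment
#' statistics operate. Experimental entries may be numeric or censored
#' bounds written as strings (\code{"> 12.00"}, \code{"<2"}); censored
#' records keep their operator and bound but are excluded from every
#' statistic and flag.
#'
#' @param compound_id Character vector of compound identifiers.
#' @param calculated Numeric vector of predicted property values (log P or
#'   pKa units); must be finite.
#' @param experimental Numeric vector, or character vector mixing numbers
#'   with censored bounds.
#' @return data.frame of class \code{prediction_records} with columns
#'   \code{compound_id}, \code{calculated}, \code{experimental} (NA when
#'   censored), \code{censor_op}, \code{censor_bound}, \code{excluded},
#'   \code{exclude_reason}.
#' @examples
#' prediction_records(c("A", "B"), c(1.2, 15.8), c("0.9", "> 12.00"))
#' @export
prediction_records <- function(compound_id, calculated, experimental) {
  if (anyDuplicated(compound_id))
    stop("duplicate compound_id in prediction records: ",
         compound_id[duplicated(compound_id)][1L])
  .check_finite(calculated, "calculated")
  stopifnot(length(compound_id) == length(calculated),
            length(calculated) == length(experimental))
  cens <- .parse_experimental(experimental)
  out <- data.frame(compound_id = as.character(compound_id),
                    calculated = as.numeric(calculated),
                    experimental = cens$value,
                    censor_op = cens$op,
                    censor_bound = cens$bound,
                    excluded = cens$censored,
                    exclude_reason = ifelse(cens$censored,
                                            "censored experimental value",
                                            NA_character_),
                    stringsAsFactors = FALSE)
  class(out) <- unique(c("prediction_records", class(out)))
  out
}

.parse_experimental <- function(x) {
  x <- trimws(as.character(x))
  m <- regmatches(x, regexec("^([<>])\\s*([-0-9.eE+]+)$", x))
  op <- vapply(m, function(g) if (length(g)) g[2L] else NA_character_, character(1))
  bound <- vapply(m, function(g) if (length(g)) as.numeric(g[3L]) else NA_real_,
                  numeric(1))
  censored <- !is.na(op)
  value <- suppressWarnings(as.numeric(x))
  value[censored] <- NA_real_
  bad <- !censored & !is.finite(value)
  if (any(bad))
    stop("unparseable experimental value: '", x[bad][1L],
         "' (expected a number or '> x' / '< x')")
  list(value = value, op = op, bound = bound, censored = censored)
}

.active <- function(records) {
  stopifnot(inherits(records, "prediction_records"))
  records[!records$excluded, , drop = FALSE]
}

#' Error statistics of predictions against experiment
#'
#' Over the non-excluded records, with delta = calculated - experimental:
#' rmsd = sqrt(mean(delta^2)), mse = mean(delta) (signed), mue =
#' mean(|delta|), and the sample Pearson correlation r of calculated versus
#' experimental values. Censored/excluded records never contribute.
#'
#' @param records A \code{\link{prediction_records}} table.
#' @return Object of class \code{prediction_stats}: list with \code{n},
#'   \code{rmsd}, \code{mse}, \code{mue}, \code{pearson_r}.
#' @export
summarize_predictions <- function(records) {
  act <- .active(records)
  if (nrow(act) == 0L)
    stop("no non-excluded records: cannot compute statistics")
  delta <- act$calculated - act$experimental
  r <- if (nrow(act) >= 2L && stats::sd(act$experimental) > 0 &&
           stats::sd(act$calculated) > 0)
    stats::cor(act$calculated, act$experimental) else NA_real_
  structure(list(n = nrow(act),
                 rmsd = sqrt(mean(delta^2)),
                 mse = mean(delta),
                 mue = mean(abs(delta)),
                 pearson_r = r),
            class = "prediction_stats")
}

#' @export
print.prediction_stats <- function(x, ...) {
  cat(sprintf("n = %d  rmsd = %.2f  mse = %.2f  mue = %.2f  r = %.2f\n",
              x$n, x$rmsd, x$mse, x$mue, x$pearson_r))
  invisible(x)
}

#' Flag large-deviation compounds
#'
#' @param records A \code{\link{prediction_records}} table.
#' @param threshold Positive deviation threshold in property units
#'   (default 1.50); compounds with |calculated - experimental| strictly
#'   greater are flagged. Censored records are never flagged.
#' @return Character vector of flagged compound ids (sorted).
#' @export
flag_outliers <- function(records, threshold = 1.50) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold <= 0)
    stop("'threshold' must be a single positive number")
  act <- .active(records)
  sort(act$compound_id[abs(act$calculated - act$experimental) > threshold])
}

#' Statistics after excluding named compounds
#'
#' @param records A \code{\link{prediction_records}} table.
#' @param exclude_ids Character vector of compound ids to drop (in addition
#'   to censored records); may be empty.
#' @return \code{prediction_stats} as \code{\link{summarize_predictions}},
#'   with the applied exclusions attached as attribute \code{"excluded"}.
#' @export
summarize_excluding <- function(records, exclude_ids = character(0)) {
  stopifnot(inherits(records, "prediction_records"))
  hit <- records$compound_id %in% exclude_ids
  records$excluded[hit] <- TRUE
  records$exclude_reason[hit] <- "excluded by request"
  out <- summarize_predictions(records)
  attr(out, "excluded") <- sort(unique(records$compound_id[records$excluded]))
  out
}

#' Matched-pair experimental substituent shifts
#'
#' For each (base, substituted) compound pair, the experimental shift
#' delta = experimental(substituted) - experimental(base), plus their mean.
#' Used e.g. to quantify the lipophilicity gain of a methyl-to-phenyl
#' replacement across a congeneric series.
#'
#' @param records A \code{\link{prediction_records}} table.
#' @param pairs List of length-2 character vectors \code{c(base_id,
#'   substituted_id)}, or a 2-column data.frame/matrix.
#' @return List with \code{shifts} (data.frame base_id, substituted_id,
#'   delta) and \code{mean_delta}.
#' @export
pair_shifts <- function(records, pairs) {
  stopifnot(inherits(records, "prediction_records"))
  if (is.data.frame(pairs) || is.matrix(pairs))
    pairs <- lapply(seq_len(nrow(pairs)), function(i) as.character(pairs[i, 1:2]))
  exp_of <- function(id, pair) {
    i <- match(id, records$compound_id)
    if (is.na(i))
      stop(sprintf("pair (%s, %s): compound %s not found", pair[1L], pair[2L], id))
    if (records$excluded[i])
      stop(sprintf("pair (%s, %s): compound %s has no usable experimental value (%s)",
                   pair[1L], pair[2L], id, records$exclude_reason[i]))
    records$experimental[i]
  }
  shifts <- do.call(rbind, lapply(pairs, function(p) {
    data.frame(base_id = p[1L], substituted_id = p[2L],
               delta = exp_of(p[2L], p) - exp_of(p[1L], p),
               stringsAsFactors = FALSE)
  }))
  list(shifts = shifts, mean_delta = mean(shifts$delta))
}
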