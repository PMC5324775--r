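#' Construct a strike dataset
#'
#' A strike dataset holds paired collision counts for a set of spatial units:
#' for each unit, the number of predator ("fox") strikes and the number of
#' prey ("lagomorph") strikes recorded over a common study period. One unit
#' may be flagged as held out, meaning its predator count is treated as
#' missing during model fitting and predicted afterwards.
#'
#' @param unit character vector of unit labels (e.g. state or territory
#'   names); must be non-empty and unique after trimming and case-folding.
#' @param fox_strikes non-negative integer vector of predator strike counts.
#' @param lagomorph_strikes non-negative integer vector of prey strike
#'   counts.
#' @param held_out optional label of the held-out unit, matched
#'   case-insensitively after trimming whitespace.
#' @return An object of class `strike_dataset`: a list with elements
#'   `records` (a data.frame with columns `unit`, `fox_strikes`,
#'   `lagomorph_strikes`) and `held_out` (a unit label or `NULL`).
#' @examples
#' ds <- strike_dataset(c("A", "B", "C"), c(5, 2, 0), c(30, 10, 4))
#' @export
strike_dataset <- function(unit, fox_strikes, lagomorph_strikes,
                           held_out = NULL) {
  unit <- as.character(unit)
  if (length(unit) == 0L) {
    stop("a strike dataset needs at least one record", call. = FALSE)
  }
  if (length(fox_strikes) != length(unit) ||
      length(lagomorph_strikes) != length(unit)) {
    stop("unit, fox_strikes and lagomorph_strikes must have equal length",
         call. = FALSE)
  }
  if (any(!nzchar(trimws(unit)))) {
    stop("unit labels must be non-empty", call. = FALSE)
  }
  key <- .unit_key(unit)
  if (anyDuplicated(key)) {
    stop("unit labels must be unique (case-insensitive): ",
         paste(unique(unit[duplicated(key)]), collapse = ", "),
         call. = FALSE)
  }
  fox_strikes <- .check_count(fox_strikes, "fox_strikes")
  lagomorph_strikes <- .check_count(lagomorph_strikes, "lagomorph_strikes")
  ds <- structure(
    list(records = data.frame(unit = unit,
                              fox_strikes = fox_strikes,
                              lagomorph_strikes = lagomorph_strikes,
                              stringsAsFactors = FALSE),
         held_out = NULL),
    class = "strike_dataset")
  if (!is.null(held_out)) ds <- set_held_out(ds, held_out)
  ds
}

.unit_key <- function(x) tolower(trimws(x))

.check_count <- function(x, name) {
  if (!is.numeric(x)) {
    stop(name, " must be numeric counts", call. = FALSE)
  }
  bad <- which(!is.finite(x) | x < 0 | x != round(x))
  if (length(bad)) {
    stop(name, " must be non-negative integers; offending row ", bad[1],
         " has value ", x[bad[1]], call. = FALSE)
  }
  as.integer(x)
}

#' Flag the held-out unit of a strike dataset
#'
#' @param ds a `strike_dataset`.
#' @param label unit label to hold out (case-insensitive, whitespace
#'   trimmed), or `NULL` to clear the flag.
#' @return The dataset with `held_out` updated.
#' @export
set_held_out <- function(ds, label) {
  stopifnot(inherits(ds, "strike_dataset"))
  if (is.null(label)) {
    ds$held_out <- NULL
    return(ds)
  }
  hit <- which(.unit_key(ds$records$unit) == .unit_key(label))
  if (length(hit) != 1L) {
    stop("held-out label ", sQuote(label), " matches ", length(hit),
         " records; it must match exactly one", call. = FALSE)
  }
  ds$held_out <- ds$records$unit[hit]
  ds
}

#' Read a strike dataset from CSV
#'
#' Expects a comma-separated UTF-8 file with a header row containing the
#' columns `unit`, `fox_strikes` and `lagomorph_strikes`. Row order is
#' preserved and counts are validated as non-negative integers.
#'
#' @param path path to the CSV file.
#' @param held_out optional held-out unit label (see [set_held_out()]).
#' @return A [strike_dataset()].
#' @examples
#' path <- system.file("extdata", "runway_strikes.csv",
#'                     package = "strikeinfer")
#' ds <- read_strike_csv(path, held_out = "Tasmania")
#' @export
read_strike_csv <- function(path, held_out = NULL) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  need <- c("unit", "fox_strikes", "lagomorph_strikes")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  strike_dataset(raw$unit, raw$fox_strikes, raw$lagomorph_strikes,
                 held_out = held_out)
}

#' Write a strike dataset to CSV
#'
#' Inverse of [read_strike_csv()]; writes the canonical three-column schema.
#' The held-out flag is not stored in the file.
#'
#' @param ds a `strike_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_strike_csv <- function(ds, path) {
  stopifnot(inherits(ds, "strike_dataset"))
  utils::write.csv(ds$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The packaged fox and lagomorph runway-strike dataset
#'
#' Loads the case-study table: runway strikes of red foxes and lagomorphs
#' (European hares and rabbits) recorded per Australian state and territory
#' over 2002--2014, as reported to the Australian Transport Safety Bureau.
#' Tasmania (0 fox strikes, 15 lagomorph strikes) is the natural held-out
#' unit for absence inference.
#'
#' @param held_out unit label to hold out; defaults to `"Tasmania"`. Use
#'   `NULL` for no held-out unit.
#' @return A [strike_dataset()] with 8 records.
#' @examples
#' fox_lagomorph_strikes()
#' @export
fox_lagomorph_strikes <- function(held_out = "Tasmania") {
  path <- system.file("extdata", "runway_strikes.csv",
                      package = "strikeinfer", mustWork = TRUE)
  read_strike_csv(path, held_out = held_out)
}

#' Drop the held-out unit from a dataset
#'
#' Returns the fitting subset: every record except the held-out one, with
#' the held-out flag cleared. The model is fitted to this subset; the
#' held-out unit is predicted from its prey count afterwards.
#'
#' @param ds a `strike_dataset` with `held_out` set.
#' @return A `strike_dataset` with one fewer record and no held-out flag.
#' @examples
#' mainland_subset(fox_lagomorph_strikes())
#' @export
mainland_subset <- function(ds) {
  stopifnot(inherits(ds, "strike_dataset"))
  if (is.null(ds$held_out)) {
    stop("mainland_subset() requires a dataset with a held-out unit; ",
         "use set_held_out() first", call. = FALSE)
  }
  keep <- .unit_key(ds$records$unit) != .unit_key(ds$held_out)
  out <- ds
  out$records <- ds$records[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  out$held_out <- NULL
  out
}

#' Extract the held-out record of a dataset
#'
#' @param ds a `strike_dataset` with `held_out` set.
#' @return A one-row data.frame with the held-out record.
#' @export
held_out_record <- function(ds) {
  stopifnot(inherits(ds, "strike_dataset"))
  if (is.null(ds$held_out)) {
    stop("dataset has no held-out unit", call. = FALSE)
  }
  hit <- .unit_key(ds$records$unit) == .unit_key(ds$held_out)
  out <- ds$records[hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.strike_dataset <- function(x, ...) {
  cat("strike_dataset:", nrow(x$records), "units",
      if (!is.null(x$held_out)) paste0("(held out: ", x$held_out, ")"),
      "\n")
  print(x$records, row.names = FALSE)
  invisible(x)
}

# internal: validate a dataset for fitting (no held-out unit, identifiable)
.check_fit_data <- function(ds) {
  stopifnot(inherits(ds, "strike_dataset"))
  if (!is.null(ds$held_out)) {
    stop("remove the held-out unit with mainland_subset() before fitting",
         call. = FALSE)
  }
  if (sum(ds$records$lagomorph_strikes > 0) < 2) {
    stop("model unidentifiable: need at least 2 records with positive ",
         "prey strike counts", call. = FALSE)
  }
  invisible(ds)
}
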