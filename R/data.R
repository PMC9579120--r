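#' Read a long-format trial table
#'
#' Reads a delimited text file (CSV or TSV, detected from the file extension)
#' of continuous-report trial data, one row per trial, converts all angular
#' columns to canonical radians in (-pi, pi], and validates the structure.
#' Column names are configurable so existing data sets need not be renamed;
#' non-target columns are discovered by a shared name prefix (e.g.
#' `non_target_1`, `non_target_2`, ...). Missing non-targets may be empty
#' cells or the literal `NA`.
#'
#' @param path Path to a `.csv` or `.tsv`/`.txt` file with a header row.
#' @param unit Angular unit of the response/target/non-target columns:
#'   `"degrees"` (1-360), `"degrees_180"` (axial, 1-180) or `"radians"`.
#' @param id_var,response_var,target_var Column names for participant id,
#'   response and target value.
#' @param non_target_var Common prefix of the non-target columns; set to
#'   `NULL` if the design has no non-targets.
#' @param set_size_var,condition_var Optional column names for set size and an
#'   additional experimental condition; `NULL` if absent.
#' @return A `data.frame` with standardised columns `id`, `set_size`,
#'   (`condition`,) `response`, `target`, `non_target_1` ... `non_target_k`,
#'   all angles in radians. When no set-size column is supplied, set size is
#'   inferred per trial as 1 + the number of non-missing non-targets.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write.csv(data.frame(id = 1, response = 0.5, target = 0.4,
#'                      non_target_1 = 2, non_target_2 = -2),
#'           tf, row.names = FALSE)
#' read_trial_data(tf, unit = "radians")
#' @export
read_trial_data <- function(path, unit = c("degrees", "degrees_180", "radians"),
                            id_var = "id", response_var = "response",
                            target_var = "target", non_target_var = "non_target",
                            set_size_var = NULL, condition_var = NULL) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  na.strings = c("NA", ""))
  standardise_trial_data(raw, unit = unit, id_var = id_var,
                         response_var = response_var, target_var = target_var,
                         non_target_var = non_target_var,
                         set_size_var = set_size_var,
                         condition_var = condition_var)
}

#' Write a trial table to disk
#'
#' Writes a (standardised) trial table as CSV or TSV, chosen from the file
#' extension. Angles are written as-is (radians for tables produced by this
#' package); missing non-targets become `NA` cells.
#'
#' @param data A trial `data.frame`.
#' @param path Output path ending in `.csv` or `.tsv`.
#' @return `path`, invisibly.
#' @export
write_trial_data <- function(data, path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  write.table(data, path, sep = sep, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Validate and standardise an in-memory trial table
#'
#' The in-memory counterpart of [read_trial_data()]: validates a raw
#' `data.frame` of trials, maps the declared column names onto the package's
#' standard ones, converts all angles to canonical radians and infers per-trial
#' set size when no set-size column is supplied. Every analysis entry point
#' calls this internally, so passing a raw `data.frame` to e.g.
#' [fit_mixture_model()] gets the same checks as reading from disk. Tables
#' already standardised (e.g. output of [simulate_responses()]) pass through
#' unchanged.
#'
#' @inheritParams read_trial_data
#' @param data A `data.frame`, one row per trial.
#' @return A standardised trial `data.frame` (see [read_trial_data()]).
#' @export
standardise_trial_data <- function(data, unit = "radians",
                                   id_var = "id", response_var = "response",
                                   target_var = "target",
                                   non_target_var = "non_target",
                                   set_size_var = NULL, condition_var = NULL) {
  if (!is.data.frame(data)) stop("`data` must be a data.frame", call. = FALSE)
  if (isTRUE(attr(data, "circmix_standardised"))) {
    # already canonical (e.g. simulator output); still honour explicit column
    # requests so typos surface instead of being silently ignored
    for (v in c(id_var, response_var, target_var, set_size_var, condition_var)) {
      if (!v %in% names(data))
        stop("column '", v, "' not found in the data", call. = FALSE)
    }
    return(data)
  }
  mapped <- c(id_var, response_var, target_var, set_size_var, condition_var)
  if (anyDuplicated(mapped)) stop("mapped column names must be distinct", call. = FALSE)
  for (v in mapped) {
    if (!v %in% names(data))
      stop("column '", v, "' not found in the data", call. = FALSE)
  }
  nt_cols <- character(0)
  if (!is.null(non_target_var)) {
    nt_cols <- grep(paste0("^", non_target_var), names(data), value = TRUE)
    nt_cols <- setdiff(nt_cols, mapped)
  }

  num_angle <- function(col, name) {
    v <- data[[col]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(ifelse(v == "", NA, v)))
    bad <- which(is.na(v) & !is.na(data[[col]]) & data[[col]] != "")
    if (length(bad) > 0)
      stop("non-numeric value in column '", name, "' at row(s): ",
           paste(head(bad, 5), collapse = ", "), call. = FALSE)
    v
  }

  out <- data.frame(id = data[[id_var]],
                    response = convert_to_radians(num_angle(response_var, response_var), unit),
                    target = convert_to_radians(num_angle(target_var, target_var), unit))
  if (anyNA(out$response) || anyNA(out$target)) {
    bad <- which(is.na(out$response) | is.na(out$target))
    stop("missing response/target value at row(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  k <- length(nt_cols)
  if (k > 0) {
    for (j in seq_len(k)) {
      v <- num_angle(nt_cols[j], nt_cols[j])
      out[[paste0("non_target_", j)]] <-
        ifelse(is.na(v), NA_real_, convert_to_radians(v, unit))
    }
  }
  n_nt <- if (k > 0) {
    rowSums(!is.na(as.matrix(out[paste0("non_target_", seq_len(k))])))
  } else rep(0L, nrow(out))

  if (!is.null(set_size_var)) {
    ss <- data[[set_size_var]]
    if (any(!is.finite(ss)) || any(ss < 1))
      stop("set_size must be a positive integer", call. = FALSE)
    # the count can only be verified when non-target columns are present
    if (k > 0) {
      mism <- which(n_nt != ss - 1)
      if (length(mism) > 0)
        stop("non-target count does not equal set_size - 1 at row(s): ",
             paste(head(mism, 5), collapse = ", "), call. = FALSE)
    }
    out$set_size <- as.integer(ss)
  } else {
    out$set_size <- as.integer(1L + n_nt)
  }
  if (!is.null(condition_var)) out$condition <- data[[condition_var]]
  ord <- c("id", "set_size", if (!is.null(condition_var)) "condition",
           "response", "target",
           if (k > 0) paste0("non_target_", seq_len(k)))
  out <- out[ord]
  attr(out, "circmix_standardised") <- TRUE
  attr(out, "unit") <- unit
  out
}
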