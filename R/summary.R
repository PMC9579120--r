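#' Wrapped response error
#'
#' Angular deviation between a response and the true target value, wrapped
#' onto (-pi, pi]. Zero means a perfect report; the sign carries the
#' direction of the deviation.
#'
#' @param response,target Numeric vectors of angles (radians).
#' @return Numeric vector of wrapped errors in (-pi, pi].
#' @examples
#' response_error(-3, 3)   # 0.283..., the short way round the circle
#' @export
response_error <- function(response, target) {
  wrap_angle(response - target)
}

#' Chance level of the precision statistic
#'
#' Expected value of the reciprocal circular standard deviation for `n_trials`
#' responses drawn uniformly on the circle, estimated by seeded Monte Carlo
#' (default 10,000 replicates) and cached per trial count. Subtracted from
#' observed 1/SD so that the precision statistic is zero, on average, for a
#' participant who only guesses.
#'
#' @param n_trials Number of trials in the cell (`>= 2`).
#' @param n_reps Monte Carlo replicates.
#' @param seed Seed for the internal Monte Carlo stream (fixed by default so
#'   repeated calls agree; the caller's RNG state is untouched).
#' @return The expected chance value of 1/SD (a single number).
#' @export
chance_precision <- function(n_trials, n_reps = 10000, seed = 104729) {
  if (length(n_trials) != 1L || !is.finite(n_trials) || n_trials < 2)
    stop("n_trials must be a single value >= 2", call. = FALSE)
  n_trials <- as.integer(n_trials)
  key <- paste0("chance_", n_trials, "_", n_reps, "_", seed)
  if (!is.null(.circmix_cache[[key]])) return(.circmix_cache[[key]])
  val <- with_seed(seed, {
    mean(vapply(seq_len(n_reps), function(i) {
      1 / circular_moments(runif(n_trials, -pi, pi))$sd
    }, numeric(1)))
  })
  .circmix_cache[[key]] <- val
  val
}

#' Model-free summary statistics of response error
#'
#' Computes, per participant and optionally per set size and/or condition,
#' four model-free descriptions of the response-error distribution:
#' \describe{
#'   \item{mean_absolute_error}{mean absolute wrapped deviation between
#'     response and target (0 = perfectly accurate; at most pi).}
#'   \item{resultant_vector_length}{length of the mean resultant vector of the
#'     errors: 1 = all responses on a single value, 0 = spread over the circle.}
#'   \item{precision}{reciprocal of the circular standard deviation of the
#'     errors minus the value expected by chance for the same number of
#'     trials (see [chance_precision()]).}
#'   \item{bias}{circular mean of the signed errors; 0 = no systematic
#'     clockwise/anticlockwise shift.}
#' }
#'
#' @inheritParams read_trial_data
#' @param data A trial `data.frame` (raw, with the declared column names, or
#'   one already produced by [read_trial_data()] / [simulate_responses()]).
#' @return A `data.frame` with one row per participant x grouping cell and
#'   columns `id`, (`set_size`, `condition`,) `mean_absolute_error`,
#'   `resultant_vector_length`, `precision`, `bias`. Angular statistics are in
#'   radians; for `degrees_180` data the error-based columns
#'   (`mean_absolute_error`, `bias`) are halved back to the native axial scale.
#' @export
get_summary_statistics <- function(data, unit = c("degrees", "degrees_180", "radians"),
                                   id_var = "id", response_var = "response",
                                   target_var = "target",
                                   non_target_var = "non_target",
                                   set_size_var = NULL, condition_var = NULL) {
  unit <- match.arg(unit)
  std <- standardise_trial_data(data, unit = unit, id_var = id_var,
                                response_var = response_var,
                                target_var = target_var,
                                non_target_var = non_target_var,
                                set_size_var = set_size_var,
                                condition_var = condition_var)
  group_cols <- c("id",
                  if (!is.null(set_size_var)) "set_size",
                  if (!is.null(condition_var)) "condition")
  err <- response_error(std$response, std$target)
  cells <- split(seq_len(nrow(std)), std[group_cols], drop = TRUE)
  # halve error-scale outputs for axial data that were doubled on input
  scale_back <- if (identical(attr(std, "unit"), "degrees_180")) 0.5 else 1

  rows <- lapply(cells, function(idx) {
    e <- err[idx]
    if (length(e) < 2) {
      warning("cell with fewer than 2 trials omitted", call. = FALSE)
      return(NULL)
    }
    mom <- circular_moments(e)
    prec <- if (is.infinite(mom$sd)) 0 else 1 / mom$sd
    stats <- data.frame(
      mean_absolute_error = mean(abs(e)) * scale_back,
      resultant_vector_length = mom$R,
      precision = prec - chance_precision(length(e)),
      bias = mom$mean * scale_back
    )
    cbind(std[idx[1], group_cols, drop = FALSE], stats)
  })
  out <- do.call(rbind, rows)
  out <- out[do.call(order, out[group_cols]), , drop = FALSE]
  rownames(out) <- NULL
  out
}
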