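#' Binned response-error density, averaged over participants
#'
#' Histograms each participant's wrapped response errors on (-pi, pi] into
#' `n_bins` equal bins normalised to a probability density (per participant,
#' densities times the bin width sum to 1), then averages across participants
#' within each grouping cell and reports +-1 standard error of that average.
#'
#' @inheritParams get_summary_statistics
#' @param n_bins Number of bins over (-pi, pi] (`>= 3`); the default 18 gives
#'   20-degree bins.
#' @return A `data.frame` with columns (`set_size`, `condition`,) `bin_centre`
#'   (radians), `density` (participant-averaged) and `se`.
#' @export
error_density <- function(data, n_bins = 18,
                          unit = c("degrees", "degrees_180", "radians"),
                          id_var = "id", response_var = "response",
                          target_var = "target", non_target_var = "non_target",
                          set_size_var = NULL, condition_var = NULL) {
  if (n_bins < 3) stop("n_bins must be >= 3", call. = FALSE)
  unit <- match.arg(unit)
  std <- standardise_trial_data(data, unit = unit, id_var = id_var,
                                response_var = response_var,
                                target_var = target_var,
                                non_target_var = non_target_var,
                                set_size_var = set_size_var,
                                condition_var = condition_var)
  group_cols <- c(if (!is.null(set_size_var)) "set_size",
                  if (!is.null(condition_var)) "condition")
  breaks <- seq(-pi, pi, length.out = n_bins + 1)
  centres <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  width <- 2 * pi / n_bins
  err <- response_error(std$response, std$target)

  cell_index <- if (length(group_cols) > 0) std[group_cols] else
    data.frame(all = rep(1L, nrow(std)))
  cells <- split(seq_len(nrow(std)), cell_index, drop = TRUE)
  out <- lapply(cells, function(idx) {
    per_part <- lapply(split(idx, std$id[idx]), function(pi_idx) {
      h <- hist(err[pi_idx], breaks = breaks, plot = FALSE)
      h$counts / (length(pi_idx) * width)
    })
    dens <- do.call(rbind, per_part)
    keys <- if (length(group_cols) > 0)
      std[idx[1], group_cols, drop = FALSE] else NULL
    res <- data.frame(bin_centre = centres,
                      density = colMeans(dens),
                      se = if (nrow(dens) > 1) apply(dens, 2, sd) / sqrt(nrow(dens))
                           else 0)
    if (!is.null(keys)) cbind(keys[rep(1, n_bins), , drop = FALSE], res) else res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Empirical vs model-predicted response-error densities
#'
#' Computes the participant-averaged empirical error density (see
#' [error_density()]) alongside the density predicted by a fitted model,
#' evaluated at each bin centre for every trial's actual non-target
#' configuration, averaged over trials and then participants. Used to judge
#' goodness of fit visually via [plot_model_fit()].
#'
#' @inheritParams error_density
#' @param fits A fit table from [fit_mixture_model()] covering every plotted
#'   cell (same grouping).
#' @param model The model the fits came from.
#' @return A list with `empirical` and `predicted` density tables (each a
#'   `data.frame` of grouping keys, `bin_centre` and `density`).
#' @export
model_fit_overlay <- function(data, fits,
                              model = c("2_component", "3_component",
                                        "slots", "slots_averaging"),
                              n_bins = 18,
                              unit = c("degrees", "degrees_180", "radians"),
                              id_var = "id", response_var = "response",
                              target_var = "target",
                              non_target_var = "non_target",
                              set_size_var = NULL, condition_var = NULL) {
  model <- match.arg(model)
  unit <- match.arg(unit)
  std <- standardise_trial_data(data, unit = unit, id_var = id_var,
                                response_var = response_var,
                                target_var = target_var,
                                non_target_var = non_target_var,
                                set_size_var = set_size_var,
                                condition_var = condition_var)
  emp <- error_density(std, n_bins = n_bins, set_size_var = set_size_var,
                       condition_var = condition_var)
  breaks <- seq(-pi, pi, length.out = n_bins + 1)
  centres <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  fit_keys <- intersect(c("id", "set_size", "condition"), names(fits))
  group_cols <- setdiff(fit_keys, "id")
  nt_cols <- grep("^non_target_", names(std), value = TRUE)

  pred_one_trial <- function(row, pars) {
    nts <- as.numeric(row[nt_cols])
    nts <- nts[!is.na(nts)]
    vapply(centres, function(b) {
      # b is the error bin centre: response = target + b
      if (model == "2_component") {
        density_two_component(b, pars$kappa, pars$p_u)
      } else if (model == "3_component") {
        nte <- wrap_angle(row[["target"]] + b - nts)
        density_three_component(b, pars$kappa, pars$p_u,
                                if (length(nts) > 0) pars$p_n else 0, nte)
      } else if (model == "slots") {
        slots_density(b, pars$K, pars$kappa, row[["set_size"]])
      } else {
        spa_density(b, pars$K, pars$kappa, row[["set_size"]])
      }
    }, numeric(1))
  }

  std_cells <- split(seq_len(nrow(std)),
                     std[c("id", group_cols)], drop = TRUE)
  pred_rows <- lapply(std_cells, function(idx) {
    keys <- std[idx[1], c("id", group_cols), drop = FALSE]
    frow <- fits
    for (k in names(keys)) frow <- frow[frow[[k]] == keys[[k]], , drop = FALSE]
    if (nrow(frow) == 0)
      stop("no fit provided for cell: ",
           paste(names(keys), unlist(keys), sep = "=", collapse = ", "),
           call. = FALSE)
    pars <- as.list(frow[1, ])
    dens <- rowMeans(vapply(idx, function(i)
      pred_one_trial(std[i, , drop = FALSE], pars), numeric(length(centres))))
    cbind(keys[rep(1, length(centres)), , drop = FALSE],
          data.frame(bin_centre = centres, density = dens))
  })
  pred <- do.call(rbind, pred_rows)
  # average the per-participant predicted curves within each cell
  by <- c(if (length(group_cols) > 0) pred[group_cols], pred["bin_centre"])
  pred <- stats::aggregate(pred["density"], by = by, FUN = mean)
  pred <- pred[do.call(order, pred[c(group_cols, "bin_centre")]), , drop = FALSE]
  rownames(pred) <- NULL
  list(empirical = emp, predicted = pred)
}

#' Plot participant-averaged response error
#'
#' Density histogram of wrapped response error averaged over participants,
#' with error bars of +-1 SE, optionally split by set size and/or condition.
#' Every plotting function returns its underlying table through the
#' `return_data` argument.
#'
#' @inheritParams error_density
#' @param return_data Return `list(plot, data)` instead of just the plot?
#' @return A ggplot object, or `list(plot, data)` when `return_data = TRUE`.
#' @export
plot_response_error <- function(data, n_bins = 18,
                                unit = c("degrees", "degrees_180", "radians"),
                                id_var = "id", response_var = "response",
                                target_var = "target",
                                non_target_var = "non_target",
                                set_size_var = NULL, condition_var = NULL,
                                return_data = FALSE) {
  tab <- error_density(data, n_bins = n_bins, unit = unit, id_var = id_var,
                       response_var = response_var, target_var = target_var,
                       non_target_var = non_target_var,
                       set_size_var = set_size_var,
                       condition_var = condition_var)
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$bin_centre, y = .data$density)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$density - .data$se,
                                        ymax = .data$density + .data$se),
                           width = 0) +
    ggplot2::labs(x = "Response error (radians)", y = "Probability density") +
    ggplot2::theme_minimal()
  if ("condition" %in% names(tab))
    p <- p + ggplot2::aes(colour = factor(.data$condition)) +
      ggplot2::labs(colour = "Condition") +
      ggplot2::scale_colour_viridis_d()
  if ("set_size" %in% names(tab))
    p <- p + ggplot2::facet_wrap(~set_size)
  if (return_data) list(plot = p, data = tab) else p
}

#' Plot a model-free summary statistic
#'
#' Participant-averaged mean of one summary statistic (see
#' [get_summary_statistics()]) with +-1 SE error bars, by set size and/or
#' condition.
#'
#' @inheritParams get_summary_statistics
#' @param statistic One of `"mean_absolute_error"`,
#'   `"resultant_vector_length"`, `"precision"`, `"bias"`.
#' @param return_data Return `list(plot, data)` instead of just the plot?
#' @return A ggplot object, or `list(plot, data)` when `return_data = TRUE`.
#' @export
plot_summary_statistic <- function(data, statistic = "precision",
                                   unit = c("degrees", "degrees_180", "radians"),
                                   id_var = "id", response_var = "response",
                                   target_var = "target",
                                   non_target_var = "non_target",
                                   set_size_var = NULL, condition_var = NULL,
                                   return_data = FALSE) {
  stats_tab <- get_summary_statistics(data, unit = unit, id_var = id_var,
                                      response_var = response_var,
                                      target_var = target_var,
                                      non_target_var = non_target_var,
                                      set_size_var = set_size_var,
                                      condition_var = condition_var)
  if (!statistic %in% names(stats_tab))
    stop("unknown statistic '", statistic, "'", call. = FALSE)
  group_cols <- intersect(c("set_size", "condition"), names(stats_tab))
  if (length(group_cols) == 0) {
    agg <- data.frame(mean = mean(stats_tab[[statistic]]),
                      se = sd(stats_tab[[statistic]]) / sqrt(nrow(stats_tab)))
    agg$x <- "all"
  } else {
    agg <- stats::aggregate(stats_tab[statistic],
                            by = stats_tab[group_cols],
                            FUN = function(v) c(mean = mean(v),
                                                se = sd(v) / sqrt(length(v))))
    agg <- cbind(agg[group_cols], as.data.frame(agg[[statistic]]))
    names(agg)[names(agg) == "mean"] <- "mean"
    agg$x <- agg[[group_cols[1]]]
  }
  p <- ggplot2::ggplot(agg, ggplot2::aes(x = factor(.data$x), y = .data$mean)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.1) +
    ggplot2::labs(x = group_cols[1] %||% "", y = statistic) +
    ggplot2::theme_minimal()
  if ("condition" %in% group_cols && group_cols[1] != "condition")
    p <- p + ggplot2::aes(colour = factor(.data$condition)) +
      ggplot2::labs(colour = "Condition") +
      ggplot2::scale_colour_viridis_d()
  if (return_data) list(plot = p, data = agg) else p
}

#' Plot participant-averaged best-fitting parameters
#'
#' Means (+-1 SE across participants) of the fitted parameters from
#' [fit_mixture_model()], by set size and/or condition.
#'
#' @param fits A fit table from [fit_mixture_model()].
#' @param return_data Return `list(plot, data)` instead of just the plot?
#' @return A ggplot object, or `list(plot, data)` when `return_data = TRUE`.
#' @export
plot_model_parameters <- function(fits, return_data = FALSE) {
  par_cols <- intersect(c("kappa", "p_t", "p_u", "p_n", "K"), names(fits))
  group_cols <- intersect(c("set_size", "condition"), names(fits))
  long <- do.call(rbind, lapply(par_cols, function(pc) {
    cbind(fits[c("id", group_cols)],
          data.frame(parameter = pc, value = fits[[pc]]))
  }))
  by_cols <- c("parameter", group_cols)
  agg <- stats::aggregate(long["value"], by = long[by_cols],
                          FUN = function(v) c(mean = mean(v),
                                              se = sd(v) / sqrt(length(v))))
  agg <- cbind(agg[by_cols], as.data.frame(agg$value))
  agg$x <- if (length(group_cols) > 0) agg[[group_cols[1]]] else "all"
  p <- ggplot2::ggplot(agg, ggplot2::aes(x = factor(.data$x), y = .data$mean)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.1) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = if (length(group_cols) > 0) group_cols[1] else "",
                  y = "Parameter estimate") +
    ggplot2::theme_minimal()
  if (return_data) list(plot = p, data = agg) else p
}

#' Plot model fit against participant-averaged data
#'
#' Overlays the model-predicted response-error density (line) on the
#' participant-averaged empirical density (points with +-1 SE), by set size
#' and/or condition. See [model_fit_overlay()] for how the prediction is
#' computed.
#'
#' @inheritParams model_fit_overlay
#' @param return_data Return `list(plot, data)` instead of just the plot?
#' @return A ggplot object, or `list(plot, data)` when `return_data = TRUE`.
#' @export
plot_model_fit <- function(data, fits,
                           model = c("2_component", "3_component",
                                     "slots", "slots_averaging"),
                           n_bins = 18,
                           unit = c("degrees", "degrees_180", "radians"),
                           id_var = "id", response_var = "response",
                           target_var = "target",
                           non_target_var = "non_target",
                           set_size_var = NULL, condition_var = NULL,
                           return_data = FALSE) {
  ov <- model_fit_overlay(data, fits, model = model, n_bins = n_bins,
                          unit = unit, id_var = id_var,
                          response_var = response_var, target_var = target_var,
                          non_target_var = non_target_var,
                          set_size_var = set_size_var,
                          condition_var = condition_var)
  p <- ggplot2::ggplot(ov$empirical,
                       ggplot2::aes(x = .data$bin_centre, y = .data$density)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$density - .data$se,
                                        ymax = .data$density + .data$se),
                           width = 0) +
    ggplot2::geom_line(data = ov$predicted) +
    ggplot2::labs(x = "Response error (radians)", y = "Probability density") +
    ggplot2::theme_minimal()
  if ("set_size" %in% names(ov$empirical))
    p <- p + ggplot2::facet_wrap(~set_size)
  if (return_data) list(plot = p, data = ov) else p
}
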