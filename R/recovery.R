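#' Label the quality of a recovery correlation
#'
#' Classifies a product-moment correlation between generating and recovered
#' parameter values: poor below .5, fair from .5 to .75, good from .75 to .9,
#' excellent from .9. Boundary values take the higher label.
#'
#' @param r Correlation(s) in `[-1, 1]`.
#' @return Character vector of labels.
#' @examples
#' classify_recovery(c(0.3, 0.82, 0.95))
#' @export
classify_recovery <- function(r) {
  if (any(!is.finite(r))) stop("r must be finite", call. = FALSE)
  cut(r, breaks = c(-Inf, 0.5, 0.75, 0.9, Inf), right = FALSE,
      labels = c("poor", "fair", "good", "excellent")) |> as.character()
}

# Generating-parameter ranges used throughout the recovery studies:
# kappa 1-16 and p_u 0-0.4 for both models, p_n 0-0.14 for the
# three-component model.
default_param_ranges <- function(model) {
  r <- list(kappa = c(1, 16), p_u = c(0, 0.4))
  if (model == "3_component") r$p_n <- c(0, 0.14)
  r
}

draw_params <- function(ranges) {
  lapply(ranges, function(rg) runif(1, rg[1], rg[2]))
}

#' Parameter-recovery study
#'
#' Simulates synthetic participants with known parameters, fits the same
#' model back to each, and quantifies recovery by the product-moment
#' correlation between generating and recovered values of every parameter.
#' Each participant's generating parameters are drawn uniformly from
#' `param_ranges` (defaults: `kappa` 1-16, `p_u` 0-0.4 and, for the
#' three-component model, `p_n` 0-0.14).
#'
#' @param model `"2_component"` or `"3_component"`.
#' @param n_participants Number of synthetic participants.
#' @param n_trials Trials per participant.
#' @param set_size Set size of the simulated displays.
#' @param separation_policy,separation Stimulus spacing, see
#'   [generate_stimuli()].
#' @param param_ranges Named list of `c(lower, upper)` ranges for the
#'   generating parameters; `NULL` for the defaults above.
#' @param seed Master seed; per-participant substream seeds are derived from
#'   it so the run is reproducible.
#' @return A list with `params` (a `data.frame` of generating and recovered
#'   values per participant), `correlations` (named vector of r per
#'   parameter) and `labels` (recovery quality per parameter, see
#'   [classify_recovery()]).
#' @examples
#' \donttest{
#' rec <- run_parameter_recovery("2_component", n_participants = 20,
#'                               n_trials = 50, seed = 1)
#' rec$correlations
#' }
#' @export
run_parameter_recovery <- function(model = c("2_component", "3_component"),
                                   n_participants = 500, n_trials = 500,
                                   set_size = 4,
                                   separation_policy = c("unconstrained",
                                                         "fixed_separation",
                                                         "min_separation"),
                                   separation = NULL, param_ranges = NULL,
                                   seed = NULL) {
  model <- match.arg(model)
  separation_policy <- match.arg(separation_policy)
  if (is.null(param_ranges)) param_ranges <- default_param_ranges(model)
  par_names <- names(param_ranges)
  seeds <- spawn_seeds(seed, n_participants)
  rows <- lapply(seq_len(n_participants), function(i) {
    gen <- with_seed(seeds[i], draw_params(param_ranges))
    sim <- simulate_responses(model, kappa = gen$kappa,
                              p_u = gen$p_u %||% 0, p_n = gen$p_n %||% 0,
                              n_trials = n_trials, set_size = set_size,
                              separation_policy = separation_policy,
                              separation = separation, seed = seeds[i] + 1)
    fit <- fit_mixture_model(sim, model = model, unit = "radians")
    row <- data.frame(participant = i)
    for (p in par_names) {
      row[[paste0("gen_", p)]] <- gen[[p]]
      row[[paste0("rec_", p)]] <- fit[[p]][1]
    }
    row
  })
  params <- do.call(rbind, rows)
  correlations <- vapply(par_names, function(p) {
    cor(params[[paste0("gen_", p)]], params[[paste0("rec_", p)]])
  }, numeric(1))
  list(params = params,
       correlations = correlations,
       labels = setNames(classify_recovery(correlations), par_names))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parameter trade-off study
#'
#' Varies one generating parameter over an equally spaced sweep while holding
#' the others at default values (`kappa = 8`, `p_u = 0.10` and, for the
#' three-component model, `p_n = 0.15`), simulating and refitting `reps`
#' data sets per sweep point, and summarises every recovered parameter at
#' every point by its mean and a 95% interval. Selective recovery — only the
#' varied parameter moves — indicates the absence of trade-offs. Sweep
#' ranges follow the study design: `kappa` 4-12, `p_u` 0.05-0.80,
#' `p_n` 0.05-0.80.
#'
#' @param model `"2_component"` or `"3_component"`.
#' @param varied Which parameter to sweep (`"kappa"`, `"p_u"` or `"p_n"`).
#' @param n_values Number of sweep points.
#' @param reps Simulated data sets per sweep point.
#' @param n_trials Trials per data set.
#' @param set_size Set size of the simulated displays.
#' @param seed Master seed.
#' @return A `data.frame` with one row per sweep point x recovered parameter:
#'   the generating value of the varied parameter, the recovered parameter's
#'   name, and the mean, 2.5% and 97.5% quantiles of its recovered values.
#' @export
run_tradeoff_study <- function(model = c("2_component", "3_component"),
                               varied = c("kappa", "p_u", "p_n"),
                               n_values = 50, reps = 500, n_trials = 500,
                               set_size = 4, seed = NULL) {
  model <- match.arg(model)
  varied <- match.arg(varied)
  if (varied == "p_n" && model == "2_component")
    stop("the two-component model has no p_n", call. = FALSE)
  defaults <- list(kappa = 8, p_u = 0.10, p_n = 0.15)
  sweep_range <- switch(varied, kappa = c(4, 12), p_u = c(0.05, 0.80),
                        p_n = c(0.05, 0.80))
  values <- seq(sweep_range[1], sweep_range[2], length.out = n_values)
  par_names <- c("kappa", "p_u", if (model == "3_component") "p_n")
  seeds <- spawn_seeds(seed, n_values)
  out <- lapply(seq_along(values), function(v) {
    gen <- defaults[par_names]
    gen[[varied]] <- values[v]
    rep_seeds <- spawn_seeds(seeds[v], reps)
    rec <- vapply(seq_len(reps), function(r) {
      sim <- simulate_responses(model, kappa = gen$kappa, p_u = gen$p_u,
                                p_n = gen$p_n %||% 0, n_trials = n_trials,
                                set_size = set_size, seed = rep_seeds[r])
      fit <- fit_mixture_model(sim, model = model, unit = "radians")
      vapply(par_names, function(p) fit[[p]][1], numeric(1))
    }, numeric(length(par_names)))
    rec <- matrix(rec, nrow = length(par_names))
    do.call(rbind, lapply(seq_along(par_names), function(j) {
      data.frame(varied = varied, generating_value = values[v],
                 parameter = par_names[j],
                 mean_recovered = mean(rec[j, ]),
                 lower = quantile(rec[j, ], 0.025, names = FALSE),
                 upper = quantile(rec[j, ], 0.975, names = FALSE))
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Model-recovery study
#'
#' Simulates data sets from a known generating model (parameters drawn
#' uniformly from the recovery-study ranges), fits both the two- and
#' three-component models to each, and scores per data set the AIC and BIC
#' differences (two-component minus three-component; positive favours the
#' three-component model). Aggregates the percentage of data sets in which
#' each criterion selects the true generating model. Because the models are
#' nested, the AIC difference is bounded below by -2.
#'
#' @param generating_model The true model data are simulated from.
#' @param n_datasets Number of simulated data sets.
#' @param n_trials Trials per data set.
#' @param set_size Set size of the simulated displays.
#' @param seed Master seed.
#' @return A list with `datasets` (per-data-set generating parameters and
#'   AIC/BIC differences) and `percent_correct` (named vector, per
#'   criterion).
#' @export
run_model_recovery <- function(generating_model = c("2_component", "3_component"),
                               n_datasets = 1000, n_trials = 500,
                               set_size = 4, seed = NULL) {
  generating_model <- match.arg(generating_model)
  ranges <- default_param_ranges(generating_model)
  seeds <- spawn_seeds(seed, n_datasets)
  rows <- lapply(seq_len(n_datasets), function(i) {
    gen <- with_seed(seeds[i], draw_params(ranges))
    sim <- simulate_responses(generating_model, kappa = gen$kappa,
                              p_u = gen$p_u, p_n = gen$p_n %||% 0,
                              n_trials = n_trials, set_size = set_size,
                              seed = seeds[i] + 1)
    f2 <- fit_mixture_model(sim, "2_component", unit = "radians", return_fit = TRUE)
    f3 <- fit_mixture_model(sim, "3_component", unit = "radians", return_fit = TRUE)
    cmp <- suppressWarnings(compare_models(f2, f3))
    data.frame(dataset = i, gen_kappa = gen$kappa, gen_p_u = gen$p_u,
               gen_p_n = gen$p_n %||% NA_real_,
               AIC_difference = cmp$AIC_difference[1],
               BIC_difference = cmp$BIC_difference[1])
  })
  datasets <- do.call(rbind, rows)
  correct_sign <- if (generating_model == "2_component") -1 else 1
  percent_correct <- c(
    AIC = 100 * mean(sign(datasets$AIC_difference) == correct_sign),
    BIC = 100 * mean(sign(datasets$BIC_difference) == correct_sign)
  )
  list(datasets = datasets, percent_correct = percent_correct)
}
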