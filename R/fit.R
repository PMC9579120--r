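#' Multi-start grid of optimiser starting values
#'
#' The fit routine launches Nelder-Mead from every permutation of a fixed
#' grid of starting values to avoid local minima: concentration
#' `kappa` in {1, 10, 100} crossed with mixture probabilities
#' `p_u` (and `p_n` for the three-component model) in {0.01, 0.1, 0.4},
#' giving 9 starts for the two-component model and 27 for the
#' three-component model. The slots models use `K` in {1, 2, 4} crossed with
#' the same `kappa` values.
#'
#' @param model One of `"2_component"`, `"3_component"`, `"slots"`,
#'   `"slots_averaging"`.
#' @return A `data.frame` of starting parameter vectors, one row per start.
#' @export
start_grid <- function(model = c("2_component", "3_component",
                                 "slots", "slots_averaging")) {
  model <- match.arg(model)
  kappas <- c(1, 10, 100)
  ps <- c(0.01, 0.1, 0.4)
  switch(model,
    "2_component" = expand.grid(kappa = kappas, p_u = ps,
                                KEEP.OUT.ATTRS = FALSE),
    "3_component" = expand.grid(kappa = kappas, p_u = ps, p_n = ps,
                                KEEP.OUT.ATTRS = FALSE),
    expand.grid(K = c(1, 2, 4), kappa = kappas, KEEP.OUT.ATTRS = FALSE)
  )
}

# ---- parameter transforms ----------------------------------------------------
# Nelder-Mead runs unconstrained: log(kappa) (bounded to (1e-3, 1e4)), and an
# additive-log-ratio transform of the probability simplex (p_t, p_u, p_n).
KAPPA_MIN <- 1e-3
KAPPA_MAX <- 1e4

to_unconstrained <- function(par, model) {
  if (model %in% c("slots", "slots_averaging")) {
    c(log(par[["K"]]), log(par[["kappa"]]))
  } else if (model == "2_component") {
    p_u <- par[["p_u"]]
    c(log(par[["kappa"]]), log(p_u / (1 - p_u)))
  } else {
    p_u <- par[["p_u"]]; p_n <- par[["p_n"]]; p_t <- 1 - p_u - p_n
    c(log(par[["kappa"]]), log(p_u / p_t), log(p_n / p_t))
  }
}

from_unconstrained <- function(theta, model) {
  if (model %in% c("slots", "slots_averaging")) {
    list(K = exp(theta[1]), kappa = exp(theta[2]))
  } else if (model == "2_component") {
    list(kappa = exp(theta[1]), p_u = stats::plogis(theta[2]), p_n = 0)
  } else {
    eu <- exp(theta[2]); en <- exp(theta[3])
    s <- 1 + eu + en
    list(kappa = exp(theta[1]), p_u = eu / s, p_n = en / s)
  }
}

# Fit one cell of trials (already prepared cosines) by multi-start Nelder-Mead.
fit_cell <- function(prep, model) {
  grid <- start_grid(model)
  slots <- model %in% c("slots", "slots_averaging")
  objective <- function(theta) {
    if (!all(is.finite(theta))) return(.Machine$double.xmax)
    if (slots) {
      K <- exp(theta[1]); kappa <- exp(theta[2])
      if (kappa < KAPPA_MIN || kappa > KAPPA_MAX || K > 64) return(.Machine$double.xmax)
      v <- nll_slots_cpp(K, kappa, model == "slots_averaging",
                         prep$cos_t, as.numeric(prep$set_size))
    } else {
      p <- from_unconstrained(theta, model)
      if (p$kappa < KAPPA_MIN || p$kappa > KAPPA_MAX) return(.Machine$double.xmax)
      v <- nll_mixture_cpp(p$kappa, p$p_u, p$p_n, prep$cos_t, prep$cos_nt)
    }
    if (!is.finite(v)) .Machine$double.xmax else v
  }
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    theta0 <- to_unconstrained(grid[i, , drop = FALSE], model)
    opt <- tryCatch(
      optim(theta0, objective, method = "Nelder-Mead",
            control = list(reltol = 1e-8, maxit = 2000)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best) || best$value >= .Machine$double.xmax)
    stop("all optimiser starts failed to converge for model '", model, "'",
         call. = FALSE)
  # final polish from the winning start at a tighter tolerance, so nested
  # models respect their analytic likelihood ordering to well below 1e-6
  pol <- tryCatch(
    optim(best$par, objective, method = "Nelder-Mead",
          control = list(reltol = 1e-12, maxit = 2000)),
    error = function(e) NULL)
  if (!is.null(pol) && pol$value < best$value) best <- pol
  par <- from_unconstrained(best$par, model)
  c(par, list(nll = best$value))
}

#' Information criteria from a log-likelihood
#'
#' Computes the penalised model-comparison criteria
#' `AIC = -2 * LL + 2 * p`,
#' `AICc = -2 * LL + 2 * p * (n / (n - p - 1))` and
#' `BIC = -2 * LL + p * log(n)`,
#' where `LL` is the maximised log-likelihood, `p` the number of free
#' parameters and `n` the number of trials. `AICc` is reported as `NA` when
#' `n <= p + 1` (the correction is undefined there).
#'
#' @param log_likelihood Maximised log-likelihood.
#' @param n_params Number of free parameters (2 for the two-component and
#'   slots models, 3 for the three-component model).
#' @param n_trials Number of trials used in the fit.
#' @return A list with `AIC`, `AICc`, `BIC`.
#' @examples
#' information_criteria(-100, n_params = 2, n_trials = 100)
#' @export
information_criteria <- function(log_likelihood, n_params, n_trials) {
  if (n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  aic <- -2 * log_likelihood + 2 * n_params
  aicc <- if (n_trials > n_params + 1) {
    -2 * log_likelihood + 2 * n_params * (n_trials / (n_trials - n_params - 1))
  } else NA_real_
  bic <- -2 * log_likelihood + n_params * log(n_trials)
  list(AIC = aic, AICc = aicc, BIC = bic)
}

#' Fit mixture models to trial data by maximum likelihood
#'
#' Fits one of the four response models to each cell of the data (participant
#' crossed with set size and/or condition, when those columns are declared) by
#' maximum likelihood: Nelder-Mead minimisation of the negative
#' log-likelihood, started from every point of the [start_grid()] to avoid
#' local minima, with `kappa` optimised on the log scale and the mixture
#' probabilities through a simplex transform. The best converged start wins;
#' ties go to the earliest start in grid order.
#'
#' Cells whose trials all have set size 1 carry no non-targets, so the
#' three-component model is fitted there with `p_n` fixed at 0. Cells with
#' fewer than 2 trials are skipped with a warning.
#'
#' @inheritParams get_summary_statistics
#' @param model `"2_component"`, `"3_component"`, `"slots"` or
#'   `"slots_averaging"`.
#' @param return_fit Also return the log-likelihood, trial count and
#'   information criteria per cell?
#' @return A `data.frame` with one row per fitted cell: grouping keys, the
#'   best-fitting parameters (`kappa`, `p_t`, `p_u` and, for the
#'   three-component model, `p_n`; `K` and `kappa` for the slots models) and,
#'   when `return_fit = TRUE`, `log_likelihood`, `n_trials`, `AIC`, `AICc`,
#'   `BIC`.
#' @examples
#' sim <- simulate_responses("2_component", kappa = 8, p_u = 0.1,
#'                           n_trials = 200, set_size = 4, seed = 1)
#' fit_mixture_model(sim, model = "2_component", unit = "radians")
#' @export
fit_mixture_model <- function(data, model = c("2_component", "3_component",
                                              "slots", "slots_averaging"),
                              unit = c("degrees", "degrees_180", "radians"),
                              id_var = "id", response_var = "response",
                              target_var = "target",
                              non_target_var = "non_target",
                              set_size_var = NULL, condition_var = NULL,
                              return_fit = FALSE) {
  model <- match.arg(model)
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
  # Every standardised table carries set_size. The three-component likelihood
  # cannot pool trials with and without non-targets (set size 1 fixes p_n = 0),
  # so split such data by set size even when no set-size column was declared.
  nt_cols_all <- grep("^non_target_", names(std), value = TRUE)
  n_nt_all <- if (length(nt_cols_all) > 0) {
    rowSums(!is.na(as.matrix(std[nt_cols_all])))
  } else rep(0L, nrow(std))
  if (is.null(set_size_var) && model == "3_component" &&
      any(n_nt_all == 0) && !all(n_nt_all == 0)) {
    group_cols <- union(group_cols, "set_size")
  }
  cells <- split(seq_len(nrow(std)), std[group_cols], drop = TRUE)
  slots <- model %in% c("slots", "slots_averaging")

  rows <- lapply(cells, function(idx) {
    if (length(idx) < 2) {
      warning("cell with fewer than 2 trials skipped", call. = FALSE)
      return(NULL)
    }
    cell <- std[idx, , drop = FALSE]
    prep <- prepare_trial_errors(cell)
    eff_model <- model
    if (model == "3_component" && all(prep$n_nt == 0)) eff_model <- "2_component"
    if (model == "3_component" && any(prep$n_nt == 0) && !all(prep$n_nt == 0))
      stop("a cell mixes trials with and without non-targets; group by set size",
           call. = FALSE)
    fit <- fit_cell(prep, eff_model)
    keys <- std[idx[1], group_cols, drop = FALSE]
    pars <- if (slots) {
      data.frame(K = fit$K, kappa = fit$kappa)
    } else if (model == "3_component") {
      data.frame(kappa = fit$kappa, p_t = 1 - fit$p_u - fit$p_n,
                 p_n = fit$p_n, p_u = fit$p_u)
    } else {
      data.frame(kappa = fit$kappa, p_t = 1 - fit$p_u, p_u = fit$p_u)
    }
    out <- cbind(keys, pars)
    if (return_fit) {
      n_params <- if (model == "3_component") 3 else 2
      # a 3-component fit collapsed to p_n = 0 at set size 1 still estimates
      # only kappa and p_u there, but is reported with its own p for
      # comparability across cells
      ll <- -fit$nll
      ic <- information_criteria(ll, n_params, length(idx))
      out <- cbind(out, data.frame(log_likelihood = ll, n_trials = length(idx),
                                   AIC = ic$AIC, AICc = ic$AICc, BIC = ic$BIC))
    }
    out
  })
  out <- do.call(rbind, rows)
  out <- out[do.call(order, out[group_cols]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare two fitted models by information criteria
#'
#' Computes the AIC and BIC differences between a two-component and a
#' three-component fit of the same cells, oriented as
#' `difference = criterion(two-component) - criterion(three-component)`:
#' values above zero favour the three-component model, values below zero the
#' two-component model. Because the three-component model nests the
#' two-component model (it reduces to it at `p_n = 0`), the AIC difference
#' can never legitimately fall below -2 (identical fit, one extra parameter
#' penalised by 2); differences below `-2 - tol` are flagged as optimiser
#' failures.
#'
#' @param fit2,fit3 Fits from [fit_mixture_model()] with `return_fit = TRUE`
#'   for the two- and three-component model on the same data and grouping.
#' @param tol Numerical slack on the -2 bound.
#' @return A `data.frame` per cell with `AIC_difference`, `BIC_difference`,
#'   the winning model per criterion, and a `bound_violated` flag.
#' @export
compare_models <- function(fit2, fit3, tol = 1e-6) {
  keys <- intersect(c("id", "set_size", "condition"), names(fit2))
  if (!all(keys %in% names(fit3)))
    stop("fits carry different grouping columns", call. = FALSE)
  if (!all(c("AIC", "BIC") %in% names(fit2)) ||
      !all(c("AIC", "BIC") %in% names(fit3)))
    stop("fits must be produced with return_fit = TRUE", call. = FALSE)
  m <- merge(fit2[c(keys, "AIC", "BIC", "n_trials")],
             fit3[c(keys, "AIC", "BIC", "n_trials")],
             by = keys, suffixes = c("_2", "_3"))
  if (nrow(m) == 0) stop("no matching cells between the two fits", call. = FALSE)
  if (any(m$n_trials_2 != m$n_trials_3))
    stop("fits cover different trials in at least one cell", call. = FALSE)
  out <- m[keys]
  out$AIC_difference <- m$AIC_2 - m$AIC_3
  out$BIC_difference <- m$BIC_2 - m$BIC_3
  out$AIC_winner <- ifelse(out$AIC_difference > 0, "3_component", "2_component")
  out$BIC_winner <- ifelse(out$BIC_difference > 0, "3_component", "2_component")
  out$bound_violated <- out$AIC_difference < -2 - tol
  if (any(out$bound_violated))
    warning("AIC difference below the -2 nesting bound in ",
            sum(out$bound_violated), " cell(s); check optimiser convergence",
            call. = FALSE)
  out
}
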