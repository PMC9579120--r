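#' Trial-level mixture-model densities
#'
#' Response densities of the four models of continuous-report data, evaluated
#' for a single trial. These are the plain-R reference definitions; the fit
#' routine evaluates the same quantities through a compiled kernel, and the
#' two are checked against each other in the test suite.
#'
#' The two-component model mixes a von Mises distribution centred on the
#' target (weight `1 - p_u`) with a uniform guessing component (weight `p_u`):
#' `(1 - p_u) * dvonmises(e; 0, kappa) + p_u / (2 * pi)` where `e` is the
#' wrapped response error.
#'
#' The three-component model adds swap (binding) errors: with probability
#' `p_n` the response is centred on one of the `n` non-target values, each
#' equally likely, stored with the same concentration `kappa` as the target:
#' `(1 - p_u - p_n) * dvonmises(e) + p_u / (2 * pi) +
#'  (p_n / n) * sum_i dvonmises(e_i)` with `e_i` the wrapped deviations from
#' each non-target. With `p_n = 0` it reduces exactly to the two-component
#' model.
#'
#' @param target_error Wrapped deviation of the response from the target
#'   (radians).
#' @param kappa von Mises concentration shared by target and non-target
#'   components (`> 0`).
#' @param p_u Probability of a uniform guess, in `[0, 1]`.
#' @param p_n Probability of a non-target (swap) response, in `[0, 1]`,
#'   `p_u + p_n <= 1`.
#' @param nontarget_errors Numeric vector of wrapped deviations of the
#'   response from each non-target value (may be empty when `p_n = 0`).
#' @return Density of the response (single number).
#' @seealso [slots_density()], [fit_mixture_model()]
#' @examples
#' density_two_component(0, kappa = 8, p_u = 0.2)
#' density_three_component(1.2, kappa = 8, p_u = 0.1, p_n = 0.3,
#'                         nontarget_errors = c(0.1, -2.0, 1.4))
#' @export
density_two_component <- function(target_error, kappa, p_u) {
  check_mixture_params(kappa, p_u, 0)
  (1 - p_u) * dvonmises(target_error, 0, kappa) + p_u / (2 * pi)
}

#' @rdname density_two_component
#' @export
density_three_component <- function(target_error, kappa, p_u, p_n,
                                    nontarget_errors = numeric(0)) {
  check_mixture_params(kappa, p_u, p_n)
  nontarget_errors <- nontarget_errors[!is.na(nontarget_errors)]
  n <- length(nontarget_errors)
  if (p_n > 0 && n == 0)
    stop("p_n > 0 requires at least one non-target value", call. = FALSE)
  nt <- if (n > 0) (p_n / n) * sum(dvonmises(nontarget_errors, 0, kappa)) else 0
  (1 - p_u - p_n) * dvonmises(target_error, 0, kappa) + p_u / (2 * pi) + nt
}

check_mixture_params <- function(kappa, p_u, p_n) {
  if (!is.finite(kappa) || kappa < 0) stop("kappa must be finite and >= 0", call. = FALSE)
  if (p_u < 0 || p_n < 0 || p_u + p_n > 1 + 1e-12)
    stop("mixture probabilities must lie in [0, 1] with p_u + p_n <= 1", call. = FALSE)
  invisible(TRUE)
}

# Continuous slot allocation shared by the slots and slots-plus-averaging
# densities: with capacity K and set size N, items carry floor(K/N) or
# floor(K/N) + 1 slots, the fraction frac(K/N) of items carrying the extra
# slot. m = 0 slots means the item is unstored (uniform guess at test).
slot_allocation <- function(K, set_size) {
  q <- K / set_size
  m_low <- floor(q)
  list(m_low = m_low, m_high = m_low + 1, f_high = q - m_low)
}

#' Slots and slots-plus-averaging densities
#'
#' Capacity-model response densities. The slots model stores up to `K` of the
#' `set_size` items, each in one high-precision slot (concentration `kappa`);
#' a probed unstored item produces a uniform guess, so it is the
#' two-component density with guess rate `p_u = max(0, 1 - K / set_size)`.
#'
#' The slots-plus-averaging model lets spare slots hold duplicate copies: an
#' item stored in `m` slots is reported as the average of its copies, with
#' circular standard deviation divided by `sqrt(m)` (re-expressed as a
#' concentration through [sd_to_kappa()]). With capacity `K` and `set_size`
#' items, items carry `floor(K / set_size)` or one more slot, a fraction
#' `frac(K / set_size)` of them carrying the extra; zero slots yields a
#' guess. For `K <= set_size` this reduces exactly to the slots model. `K` is
#' continuous, so the same rule serves fitting without an integer constraint.
#'
#' @param target_error Wrapped deviation of the response from the target
#'   (radians).
#' @param K Slot capacity (`>= 0`, continuous).
#' @param kappa Concentration of a single-slot representation (`> 0`).
#' @param set_size Number of items on the trial (`>= 1`).
#' @return Density of the response (single number).
#' @examples
#' slots_density(0, K = 2, kappa = 8, set_size = 4)  # implied p_u = 0.5
#' spa_density(0, K = 8, kappa = 8, set_size = 4)    # every item in 2 slots
#' @export
slots_density <- function(target_error, K, kappa, set_size) {
  check_slots_params(K, kappa, set_size)
  p_u <- max(0, 1 - K / set_size)
  (1 - p_u) * dvonmises(target_error, 0, kappa) + p_u / (2 * pi)
}

#' @rdname slots_density
#' @export
spa_density <- function(target_error, K, kappa, set_size) {
  check_slots_params(K, kappa, set_size)
  al <- slot_allocation(K, set_size)
  comp <- function(m) {
    if (m == 0) return(1 / (2 * pi))
    k_m <- if (m == 1) kappa else sd_to_kappa(kappa_to_sd(kappa) / sqrt(m))
    dvonmises(target_error, 0, k_m)
  }
  (1 - al$f_high) * comp(al$m_low) + al$f_high * comp(al$m_high)
}

check_slots_params <- function(K, kappa, set_size) {
  if (!is.finite(K) || K < 0) stop("K must be finite and >= 0", call. = FALSE)
  if (!is.finite(kappa) || kappa <= 0) stop("kappa must be finite and > 0", call. = FALSE)
  if (!is.finite(set_size) || set_size < 1) stop("set_size must be >= 1", call. = FALSE)
  invisible(TRUE)
}

# ---- prepared trial errors ---------------------------------------------------
# Precompute, once per fitted cell, the cosines the likelihood kernels need:
# cos of the target error per trial and an n x k matrix of cos non-target
# errors (NA where a trial has fewer non-targets).
prepare_trial_errors <- function(std) {
  te <- response_error(std$response, std$target)
  nt_cols <- grep("^non_target_", names(std), value = TRUE)
  k <- length(nt_cols)
  if (k > 0) {
    nte <- wrap_angle(std$response - as.matrix(std[nt_cols]))
    cos_nt <- cos(nte)
  } else {
    cos_nt <- matrix(numeric(0), nrow = nrow(std), ncol = 0)
  }
  list(cos_t = cos(te), cos_nt = cos_nt,
       n_nt = if (k > 0) rowSums(!is.na(cos_nt)) else rep(0, nrow(std)),
       set_size = std$set_size, n = nrow(std))
}

#' Negative log-likelihood of a mixture model
#'
#' Evaluates `-sum(log density)` of a model over a set of trials. Out-of-bound
#' parameter values return `+Inf` (used by the optimiser to reject proposals).
#'
#' @param data A trial `data.frame` in canonical radians (e.g. from
#'   [simulate_responses()] or [read_trial_data()]).
#' @param model One of `"2_component"`, `"3_component"`, `"slots"`,
#'   `"slots_averaging"`.
#' @param kappa,p_u,p_n,K Model parameters (see [density_two_component()] and
#'   [slots_density()]; `p_n` only for the three-component model, `K` only
#'   for the slots models).
#' @return The negative log-likelihood (single number; `+Inf` when the
#'   parameters are outside their domain).
#' @export
negative_log_likelihood <- function(data, model = c("2_component", "3_component",
                                                    "slots", "slots_averaging"),
                                    kappa, p_u = 0, p_n = 0, K = NULL) {
  model <- match.arg(model)
  std <- standardise_trial_data(data)
  if (nrow(std) == 0) stop("at least one trial is required", call. = FALSE)
  prep <- prepare_trial_errors(std)
  if (model %in% c("slots", "slots_averaging")) {
    if (is.null(K)) stop("slots models require K", call. = FALSE)
    if (!is.finite(K) || K < 0 || !is.finite(kappa) || kappa <= 0) return(Inf)
    nll_slots_cpp(K, kappa, model == "slots_averaging",
                  prep$cos_t, as.numeric(prep$set_size))
  } else {
    if (model == "2_component") p_n <- 0
    if (!is.finite(kappa) || kappa <= 0 || p_u < 0 || p_n < 0 || p_u + p_n > 1)
      return(Inf)
    if (p_n > 0 && any(prep$n_nt == 0))
      stop("p_n > 0 requires every trial to carry at least one non-target",
           call. = FALSE)
    nll_mixture_cpp(kappa, p_u, p_n, prep$cos_t, prep$cos_nt)
  }
}
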