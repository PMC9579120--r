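#' Generate stimulus displays
#'
#' Draws per-trial target and non-target feature values on the integer-degree
#' colour-wheel grid (1-360), converted to radians. Three spacing policies are
#' supported, mirroring common experimental constraints:
#' \describe{
#'   \item{unconstrained}{values sampled uniformly without replacement
#'     (the default; no minimum spacing).}
#'   \item{`fixed_separation`}{consecutive values at exactly `separation`
#'     degrees from a uniformly random integer start (e.g. 5 degrees from
#'     start 17 gives 17, 22, 27, 32); the probed target is chosen uniformly
#'     among the items.}
#'   \item{`min_separation`}{rejection sampling until every pairwise circular
#'     distance is at least `separation` degrees.}
#' }
#'
#' @param n_trials Number of displays to draw.
#' @param set_size Items per display (`>= 1`).
#' @param separation_policy `"unconstrained"`, `"fixed_separation"` or
#'   `"min_separation"`.
#' @param separation Spacing in degrees (required for the two constrained
#'   policies; `separation * set_size` must not exceed 360).
#' @param seed Optional seed (the caller's RNG state is preserved).
#' @return A `data.frame` with columns `target` and `non_target_1` ...
#'   `non_target_(set_size - 1)`, all in radians in (-pi, pi].
#' @export
generate_stimuli <- function(n_trials, set_size = 4,
                             separation_policy = c("unconstrained",
                                                   "fixed_separation",
                                                   "min_separation"),
                             separation = NULL, seed = NULL) {
  separation_policy <- match.arg(separation_policy)
  if (set_size < 1) stop("set_size must be >= 1", call. = FALSE)
  if (separation_policy != "unconstrained") {
    if (is.null(separation)) stop("a separation (degrees) is required", call. = FALSE)
    if (separation * set_size > 360)
      stop("separation * set_size exceeds 360 degrees; infeasible", call. = FALSE)
    if (separation_policy == "min_separation" && separation != round(separation))
      stop("min_separation requires a whole number of degrees", call. = FALSE)
  }
  with_seed(seed, {
    vals <- matrix(NA_real_, nrow = n_trials, ncol = set_size)
    for (i in seq_len(n_trials)) {
      deg <- switch(separation_policy,
        unconstrained = sample.int(360, set_size, replace = FALSE),
        fixed_separation = {
          start <- sample.int(360, 1)
          items <- (start + separation * (seq_len(set_size) - 1)) %% 360
          # probed target uniform among the equally spaced items
          sample(items, set_size, replace = FALSE)
        },
        min_separation = {
          # exact sampler: draw the circular gaps directly (uniform over
          # integer-degree configurations with all pairwise distances >= d),
          # which stays fast even when d * set_size approaches 360 where
          # naive rejection sampling becomes astronomically slow
          if (set_size == 1) sample.int(360, 1) else {
            s <- 360 - set_size * separation
            cuts <- sort(sample.int(s + set_size - 1, set_size - 1))
            parts <- diff(c(0, cuts, s + set_size)) - 1
            gaps <- separation + parts
            start <- sample.int(360, 1)
            pos <- (start + cumsum(c(0, gaps[seq_len(set_size - 1)]))) %% 360
            sample(pos, set_size, replace = FALSE)
          }
        })
      vals[i, ] <- deg
    }
    out <- as.data.frame(convert_to_radians(vals, "degrees"))
    names(out) <- c("target",
                    if (set_size > 1) paste0("non_target_", seq_len(set_size - 1)))
    out
  })
}

#' Simulate responses from a mixture or slots model
#'
#' Generates a long-format trial table from one of the four response models.
#' Per trial, a latent response mode is drawn — target (probability `p_t`),
#' a specific non-target (probability `p_n`, the non-target chosen uniformly),
#' or a uniform guess (probability `p_u`) — and the response is a von Mises
#' draw around the chosen item's value (or uniform on the circle for a
#' guess). For the two-component model, non-target values are still emitted
#' in the output but never influence responses. For the slots models the
#' guess rate and effective concentration are derived from capacity `K` and
#' the trial's set size (see [slots_density()] and [spa_density()]).
#'
#' A vector of set sizes simulates an interleaved design: trials are
#' allocated equally across set sizes (remainder to the earliest) and
#' shuffled, and each parameter may then be either a scalar (shared) or a
#' vector of matching length (one value per set size).
#'
#' @param model `"2_component"`, `"3_component"`, `"slots"` or
#'   `"slots_averaging"`.
#' @param kappa von Mises concentration (scalar or one per set size).
#' @param p_u Guess probability (mixture models).
#' @param p_n Non-target probability (three-component model only).
#' @param K Slot capacity (slots models only).
#' @param n_trials Total number of trials.
#' @param set_size Set size(s) of the simulated displays.
#' @param separation_policy,separation Stimulus spacing policy, see
#'   [generate_stimuli()].
#' @param id Value of the `id` column of the output (a single simulated
#'   participant by default).
#' @param seed Optional seed; identical seed and configuration give an
#'   identical table, and the caller's RNG state is preserved.
#' @return A `data.frame` with columns `id`, `set_size`, `target`,
#'   `response`, `non_target_1` ... (radians in (-pi, pi]; `NA` non-target
#'   cells for trials with fewer items than the widest display).
#' @examples
#' sim <- simulate_responses("3_component", kappa = 8, p_u = 0.1, p_n = 0.15,
#'                           n_trials = 100, set_size = 4, seed = 42)
#' head(sim)
#' @export
simulate_responses <- function(model = c("2_component", "3_component",
                                         "slots", "slots_averaging"),
                               kappa, p_u = 0, p_n = 0, K = NULL,
                               n_trials = 1000, set_size = 4,
                               separation_policy = c("unconstrained",
                                                     "fixed_separation",
                                                     "min_separation"),
                               separation = NULL, id = 1, seed = NULL) {
  model <- match.arg(model)
  separation_policy <- match.arg(separation_policy)
  slots <- model %in% c("slots", "slots_averaging")
  n_ss <- length(set_size)
  check_len <- function(x, name) {
    if (!length(x) %in% c(1L, n_ss))
      stop("`", name, "` must be a scalar or match the length of `set_size`",
           call. = FALSE)
    rep_len(x, n_ss)
  }
  kappa <- check_len(kappa, "kappa")
  if (slots) {
    if (is.null(K)) stop("slots models require K", call. = FALSE)
    K <- check_len(K, "K")
  } else {
    p_u <- check_len(p_u, "p_u")
    p_n <- check_len(p_n, "p_n")
    if (model == "2_component" && any(p_n != 0))
      stop("the two-component model has no p_n", call. = FALSE)
    if (any(p_u < 0) || any(p_n < 0) || any(p_u + p_n > 1))
      stop("mixture probabilities must lie in [0, 1] with p_u + p_n <= 1",
           call. = FALSE)
    if (model == "3_component" && any(p_n > 0 & set_size == 1))
      stop("p_n > 0 requires set sizes above 1", call. = FALSE)
  }

  with_seed(seed, {
    # equal allocation across set sizes, remainder to the earliest
    n_per <- rep(n_trials %/% n_ss, n_ss)
    extra <- n_trials %% n_ss
    if (extra > 0) n_per[seq_len(extra)] <- n_per[seq_len(extra)] + 1
    blocks <- lapply(seq_len(n_ss), function(s) {
      ss <- set_size[s]
      stim <- generate_stimuli(n_per[s], ss, separation_policy, separation)
      resp <- simulate_block(model, stim, ss, kappa[s],
                             if (!slots) p_u[s] else NULL,
                             if (!slots) p_n[s] else NULL,
                             if (slots) K[s] else NULL)
      cbind(data.frame(id = id, set_size = ss), response = resp, stim)
    })
    k_max <- max(set_size) - 1
    blocks <- lapply(blocks, function(b) {
      have <- sum(grepl("^non_target_", names(b)))
      if (k_max > have) for (j in seq(have + 1, k_max)) b[[paste0("non_target_", j)]] <- NA_real_
      b[c("id", "set_size", "target", "response",
          if (k_max > 0) paste0("non_target_", seq_len(k_max)))]
    })
    out <- do.call(rbind, blocks)
    if (n_ss > 1) out <- out[sample.int(nrow(out)), , drop = FALSE]  # interleave
    rownames(out) <- NULL
    attr(out, "circmix_standardised") <- TRUE
    attr(out, "unit") <- "radians"
    out
  })
}

# Draw responses for one block of trials sharing a set size.
simulate_block <- function(model, stim, set_size, kappa, p_u, p_n, K) {
  n <- nrow(stim)
  items <- as.matrix(stim)  # column 1 = target, then non-targets
  if (model %in% c("2_component", "3_component")) {
    p_t <- 1 - p_u - p_n
    mode <- sample(c("t", "n", "u"), n, replace = TRUE, prob = c(p_t, p_n, p_u))
    centre <- items[, 1]
    if (any(mode == "n")) {
      pick <- sample.int(set_size - 1, sum(mode == "n"), replace = TRUE)
      centre[mode == "n"] <- items[cbind(which(mode == "n"), 1 + pick)]
    }
    resp <- numeric(n)
    vm <- mode != "u"
    if (any(vm)) resp[vm] <- wrap_angle(centre[vm] + rvonmises(sum(vm), 0, kappa))
    if (any(!vm)) resp[!vm] <- wrap_angle(runif(sum(!vm), -pi, pi))
    return(resp)
  }
  # slots / slots-plus-averaging: per-item slot counts from the continuous
  # allocation; the probed item is the target (column 1)
  al <- slot_allocation(K, set_size)
  if (model == "slots") {
    p_store <- min(1, K / set_size)
    stored <- runif(n) < p_store
    k_eff <- rep(kappa, n)
  } else {
    extra <- runif(n) < al$f_high
    m <- ifelse(extra, al$m_high, al$m_low)
    stored <- m >= 1
    sd1 <- kappa_to_sd(kappa)
    k_eff <- ifelse(m <= 1, kappa, NA_real_)
    for (mm in unique(m[m > 1])) k_eff[m == mm] <- sd_to_kappa(sd1 / sqrt(mm))
  }
  resp <- wrap_angle(runif(n, -pi, pi))
  if (any(stored)) {
    idx <- which(stored)
    for (kk in unique(k_eff[idx])) {
      sel <- idx[k_eff[idx] == kk]
      resp[sel] <- wrap_angle(items[sel, 1] + rvonmises(length(sel), 0, kk))
    }
  }
  resp
}
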