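#' System state constructor
#'
#' A snapshot of all stocks at one instant: per-species pest populations
#' `N` and per-guild parasitoid populations `P`, both in individuals/ha.
#'
#' @param t Months since simulation start.
#' @param N Named numeric vector of pest stocks (names are species codes).
#' @param P Named numeric vector of parasitoid stocks, same names as `N`.
#' @return A list of class `system_state`.
#' @export
system_state <- function(t, N, P) {
  stopifnot(t >= 0, length(N) == length(P), identical(names(N), names(P)),
            all(N >= 0), all(P >= 0))
  structure(list(t = t, N = N, P = P, carryover_applied_at = NA_real_),
            class = "system_state")
}

## ---- parasitism functional forms ---------------------------------------
## The guild-level parasitism loss flow L_i is a pluggable strategy; each
## form maps (N, P, phi, K, parasitoid parameters) to a loss rate in
## individuals/ha/month. "saturating" is the default: per-capita parasitism
## rises with parasitoid density but saturates at the recorded fraction
## phi_i, so the printed parasitism fractions are the high-parasitoid
## limit. "mass_action" is a bilinear alternative normalized by the
## current capacity; its per-capita parasitism equals phi_i * p_meet when
## P = K, which keeps parasitoid recruitment below the guild decrease rate
## at any feasible stock and therefore cannot sustain a guild (documented
## in the methods vignette).
.parasitism_forms <- list(
  saturating = function(N, P, phi, K, parasitoid) {
    phi * N * (1 - exp(-parasitoid$meeting_probability * P))
  },
  mass_action = function(N, P, phi, K, parasitoid) {
    phi * parasitoid$meeting_probability * N * P / K
  }
)

#' Registered parasitism functional forms
#'
#' @return Named list of the available forms; each is a function of
#'   `(N, P, phi, K, parasitoid)` returning the loss flow in
#'   individuals/ha/month.
#' @export
parasitism_forms <- function() .parasitism_forms

resolve_parasitism_form <- function(config) {
  f <- config$parasitism_form
  if (is.function(f)) f else .parasitism_forms[[f]]
}

## ---- flows -------------------------------------------------------------

## per-species active parasitism fractions at time t (vector over species)
active_phi_vector <- function(t, config) {
  cal <- config$calendar
  tau <- months_since_planting(t, cal)
  if (is.na(tau)) {
    rep(cal$parasitism_fraction_wild, nrow(config$species))
  } else if (tau >= cal$parasitism_onset_delay - 1e-9) {
    config$species$phi_crop
  } else {
    rep(0, nrow(config$species))
  }
}

#' Pest growth flow (Lotka-Volterra competition)
#'
#' The inflow of each pest stock follows the Lotka-Volterra interspecific
#' competition equation with a season-switching carrying capacity:
#' \deqn{G_i = \frac{r_i N_i}{K(t)}\Big(K(t) - N_i - \sum_{j \ne i} a_{ij}
#' N_j\Big).}
#' The flow can be negative when the stock overshoots the capacity (e.g.
#' just after a cropping season ends).
#'
#' @param state A [system_state()].
#' @param config A [pest_scenario()].
#' @param t Evaluation time; defaults to `state$t`.
#' @return Named vector of growth flows, individuals/ha/month.
#' @export
growth_flow <- function(state, config, t = state$t) {
  K <- carrying_capacity(t, config$calendar)
  N <- state$N
  crowd <- as.vector(unclass(config$matrix) %*% N) - N  # sum_{j != i} a_ij N_j
  stats::setNames(config$species$r * N / K * (K - N - crowd), names(N))
}

#' Parasitism loss flow
#'
#' Outflow of each pest stock due to parasitism by its lumped guild,
#' evaluated with the scenario's parasitism functional form and the
#' time-gated parasitism fraction (zero before the onset delay, wild value
#' during non-cropping months). Always non-negative, and zero whenever the
#' active fraction, the pest stock or the parasitoid stock is zero.
#'
#' @inheritParams growth_flow
#' @return Named vector of parasitism losses, individuals/ha/month.
#' @export
parasitism_flow <- function(state, config, t = state$t) {
  phi <- active_phi_vector(t, config)
  K <- carrying_capacity(t, config$calendar)
  f <- resolve_parasitism_form(config)
  stats::setNames(f(state$N, state$P, phi, K, config$parasitoid),
                  names(state$N))
}

#' Parasitoid guild inflow and outflow
#'
#' Each parasitized host yields `per_host_emergence` parasitoids of which a
#' fraction `sex_ratio` are female, so the guild inflow is
#' `per_host_emergence * sex_ratio * L_i` (2.3 `L_i` at the defaults); the
#' outflow is the fractional decrease `decrease_rate * P_i`.
#'
#' @inheritParams growth_flow
#' @param L Parasitism losses from [parasitism_flow()] at the same state
#'   and time.
#' @return List with named vectors `R` (inflow) and `D` (outflow),
#'   individuals/ha/month.
#' @export
parasitoid_flows <- function(state, config, t = state$t,
                             L = parasitism_flow(state, config, t)) {
  pp <- config$parasitoid
  list(R = pp$per_host_emergence * pp$sex_ratio * L,
       D = pp$decrease_rate * state$P)
}

## all flows at one state, as a flat list
compute_flows <- function(state, config) {
  G <- growth_flow(state, config)
  L <- parasitism_flow(state, config)
  RD <- parasitoid_flows(state, config, L = L)
  list(G = G, L = L, R = RD$R, D = RD$D)
}

#' Advance the system by one Euler step
#'
#' Forward-Euler update matching the fixed-step scheme of the original
#' stock-and-flow platform: stocks change by `dt` times the net flow and
#' are clipped at zero (clipping is recorded in the `"clipped"` attribute).
#'
#' @inheritParams growth_flow
#' @return The new `system_state` at `t + dt`, with the flows used for the
#'   step in attribute `"flows"` and any zero-clipping in `"clipped"`.
#' @export
step_state <- function(state, config) {
  fl <- compute_flows(state, config)
  dt <- config$dt
  N_raw <- state$N + dt * (fl$G - fl$L)
  P_raw <- state$P + dt * (fl$R - fl$D)
  clipped <- c(names(N_raw)[N_raw < 0], names(P_raw)[P_raw < 0])
  new <- state
  new$t <- state$t + dt
  new$N <- pmax(0, N_raw)
  new$P <- pmax(0, P_raw)
  attr(new, "flows") <- fl
  attr(new, "clipped") <- clipped
  new
}

#' Apply the between-season carryover
#'
#' At the instant a cropping season ends, only `carryover_fraction` of each
#' pest stock (10% by default) survives onto alternative host plants;
#' parasitoid stocks are not discounted (guilds decline through their own
#' decrease rate). The transition is instantaneous, applies exactly once
#' per boundary, and calling it off-boundary or twice at the same boundary
#' is an error.
#'
#' @inheritParams growth_flow
#' @return The state with pest stocks multiplied by the carryover fraction.
#' @export
apply_season_transition <- function(state, config) {
  if (!is_season_end(state$t, config$calendar))
    stop("t = ", state$t, " is not a cropping-to-non-cropping boundary")
  if (isTRUE(state$carryover_applied_at == state$t))
    stop("carryover already applied at t = ", state$t)
  state$N <- config$calendar$carryover_fraction * state$N
  state$carryover_applied_at <- state$t
  state
}

#' Simulate a scenario
#'
#' Runs the stock-and-flow system of a [pest_scenario()] over its horizon
#' with the fixed-step forward-Euler integrator: at every step the pest
#' growth ([growth_flow()]), parasitism loss ([parasitism_flow()]) and
#' parasitoid flows ([parasitoid_flows()]) are evaluated and integrated,
#' and at every cropping-to-non-cropping boundary the carryover haircut
#' ([apply_season_transition()]) is applied instantaneously before the
#' boundary state is recorded. The model is deterministic; `seed` and
#' `nsim` exist only for generic-signature compatibility.
#'
#' @param object A `pest_scenario`.
#' @param nsim Ignored (the model is deterministic); must be 1.
#' @param seed Ignored, accepted for signature compatibility.
#' @param ... Unused.
#' @return A `pest_trajectory`: a data frame with one row per sample time
#'   and columns `time_months`, `season`, then per species `N_<sp>`,
#'   `P_<sp>` (stocks) and `G_<sp>`, `L_<sp>`, `R_<sp>`, `D_<sp>` (flows
#'   evaluated at that row's state). The generating scenario is in
#'   attribute `"scenario"`, zero-clipping events in `"clip_events"`.
#' @export
#' @examples
#' traj <- simulate(pest_scenario("Cp"))
#' head(traj[, 1:6])
simulate.pest_scenario <- function(object, nsim = 1, seed = NULL, ...) {
  if (!identical(nsim, 1) && !identical(nsim, 1L))
    stop("the model is deterministic; nsim must be 1")
  problems <- validate_scenario(object)
  if (length(problems) > 0)
    stop("invalid scenario:\n  ", paste(problems, collapse = "\n  "))

  sp <- object$species$id
  n_steps <- round(object$horizon / object$dt)
  state <- system_state(0, object$init_pest, object$init_parasitoid)
  m <- length(sp)
  Ns <- Ps <- Gs <- Ls <- Rs <- Ds <- matrix(NA_real_, n_steps + 1, m,
                                             dimnames = list(NULL, sp))
  times <- numeric(n_steps + 1)
  clip <- list()
  for (k in seq_len(n_steps + 1)) {
    fl <- compute_flows(state, object)
    times[k] <- state$t
    Ns[k, ] <- state$N; Ps[k, ] <- state$P
    Gs[k, ] <- fl$G; Ls[k, ] <- fl$L; Rs[k, ] <- fl$R; Ds[k, ] <- fl$D
    if (k > n_steps) break
    state <- step_state(state, object)
    ## guard against cumulative float error in t
    state$t <- k * object$dt
    if (length(attr(state, "clipped")) > 0)
      clip[[length(clip) + 1]] <- data.frame(time_months = state$t,
                                             stock = attr(state, "clipped"),
                                             stringsAsFactors = FALSE)
    if (is_season_end(state$t, object$calendar))
      state <- apply_season_transition(state, object)
  }
  out <- data.frame(
    time_months = times,
    season = ifelse(in_cropping_season(times, object$calendar),
                    "cropping", "non-cropping"),
    stringsAsFactors = FALSE
  )
  for (pair in list(c("N", "Ns"), c("P", "Ps"), c("G", "Gs"), c("L", "Ls"),
                    c("R", "Rs"), c("D", "Ds"))) {
    mat <- get(pair[2])
    for (s in sp) out[[paste0(pair[1], "_", s)]] <- mat[, s]
  }
  attr(out, "scenario") <- object
  attr(out, "clip_events") <- if (length(clip) > 0) do.call(rbind, clip)
                              else data.frame(time_months = numeric(0),
                                              stock = character(0))
  class(out) <- c("pest_trajectory", "data.frame")
  out
}

#' Species codes covered by a trajectory
#' @param trajectory A `pest_trajectory`.
#' @return Character vector of species codes.
#' @export
trajectory_species <- function(trajectory) {
  sub("^N_", "", grep("^N_", names(trajectory), value = TRUE))
}

#' @export
print.pest_trajectory <- function(x, ...) {
  sp <- trajectory_species(x)
  cat("Pest-parasitoid trajectory:", paste(sp, collapse = " + "),
      sprintf("| %d samples over %g months (dt = %g)\n", nrow(x),
              max(x$time_months), x$time_months[2] - x$time_months[1]))
  print.data.frame(utils::head(x[, c("time_months", "season",
                                     paste0("N_", sp), paste0("P_", sp))]),
                   ...)
  cat("...\n")
  invisible(x)
}

#' @export
summary.pest_trajectory <- function(object, ...) {
  sp <- trajectory_species(object)
  pk <- peak_summary(object)
  cat("Trajectory of", paste(sp, collapse = " + "), "over",
      max(object$time_months), "months\n")
  cat("Mean total pest stock:",
      format(mean_total_pests(object), digits = 6), "individuals/ha\n")
  print(pk$table)
  invisible(pk)
}

#' @export
plot.pest_trajectory <- function(x, which = c("pests", "parasitoids"), ...) {
  which <- match.arg(which)
  sp <- trajectory_species(x)
  cols <- paste0(if (which == "pests") "N_" else "P_", sp)
  graphics::matplot(x$time_months, as.matrix(x[, cols, drop = FALSE]),
                    type = "l", lty = 1, xlab = "months",
                    ylab = paste(which, "(individuals/ha)"), ...)
  graphics::legend("topleft", legend = sp, lty = 1,
                   col = seq_along(sp), bty = "n")
  invisible(x)
}
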