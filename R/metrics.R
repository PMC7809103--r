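## indices of interior local maxima of a series (sign change of the
## discrete first difference: rising then falling)
interior_maxima <- function(x) {
  if (length(x) < 3) return(integer(0))
  d <- diff(x)
  which(d[-length(d)] > 0 & d[-1] < 0) + 1L
}

#' Dominance shares of pest species in a multi-species system
#'
#' Computes each species' fraction of the summed pest stocks, both
#' instantaneously at `eval_month` and time-averaged over `window` (the
#' mean over samples of \eqn{N_i(t) / \sum_j N_j(t)}). The published
#' dominance percentages are read "from month 6 onward", so the defaults
#' evaluate at month 6 and average over months 6 to the horizon; the
#' averaged share is the stabler of the two against phase jitter of the
#' fixed-step integrator.
#'
#' @param trajectory A `pest_trajectory`.
#' @param eval_month Month at which instantaneous shares are reported.
#' @param window Length-2 month interval for the time-averaged shares;
#'   defaults to `c(6, horizon)`.
#' @return A list of class `share_report` with named vectors
#'   `instantaneous` and `averaged` (fractions summing to 1), plus
#'   `eval_month` and `window`.
#' @export
#' @examples
#' dominance_shares(simulate(pest_scenario(c("Bf", "Cp"))))
dominance_shares <- function(trajectory, eval_month = 6, window = NULL) {
  sp <- trajectory_species(trajectory)
  tt <- trajectory$time_months
  if (is.null(window)) window <- c(6, max(tt))
  if (window[1] > max(tt) || window[2] < min(tt) || window[2] < window[1])
    stop("window must be an increasing interval within the horizon")
  if (eval_month < min(tt) || eval_month > max(tt))
    stop("eval_month outside the horizon")
  N <- as.matrix(trajectory[, paste0("N_", sp), drop = FALSE])
  colnames(N) <- sp
  i_eval <- which.min(abs(tt - eval_month))
  tot_eval <- sum(N[i_eval, ])
  inst <- if (tot_eval > 0) N[i_eval, ] / tot_eval
          else stats::setNames(rep(NA_real_, length(sp)), sp)
  in_win <- tt >= window[1] - 1e-9 & tt <= window[2] + 1e-9
  tot <- rowSums(N[in_win, , drop = FALSE])
  keep <- tot > 0
  if (!any(keep)) stop("total pest stock is zero over the whole window")
  shares <- N[in_win, , drop = FALSE][keep, , drop = FALSE] / tot[keep]
  avg <- colMeans(shares)
  structure(list(instantaneous = inst, averaged = avg,
                 eval_month = tt[i_eval], window = window),
            class = "share_report")
}

#' @export
print.share_report <- function(x, ...) {
  cat(sprintf("Dominance shares (instantaneous at month %g; averaged over [%g, %g]):\n",
              x$eval_month, x$window[1], x$window[2]))
  tab <- rbind(instantaneous = 100 * x$instantaneous,
               averaged = 100 * x$averaged)
  print(round(tab, 2), ...)
  invisible(x)
}

#' Peak summary of every stock in a trajectory
#'
#' Locates, for each pest and parasitoid stock, the global maximum and its
#' time, plus all interior local maxima (sample points where the discrete
#' first difference changes sign from positive to negative).
#'
#' @param trajectory A `pest_trajectory` (or any data frame with a
#'   `time_months` column and stock columns named `N_*` / `P_*`).
#' @return A list of class `peak_summary`: `table`, a data frame with one
#'   row per stock (`stock`, `max`, `t_max`), and `interior`, a named list
#'   of data frames (`time_months`, `value`) of interior maxima.
#' @export
peak_summary <- function(trajectory) {
  stopifnot(nrow(trajectory) > 0)
  cols <- grep("^[NP]_", names(trajectory), value = TRUE)
  tt <- trajectory$time_months
  tab <- data.frame(stock = cols, max = NA_real_, t_max = NA_real_,
                    stringsAsFactors = FALSE)
  interior <- list()
  for (k in seq_along(cols)) {
    x <- trajectory[[cols[k]]]
    i <- which.max(x)
    tab$max[k] <- x[i]
    tab$t_max[k] <- tt[i]
    im <- interior_maxima(x)
    interior[[cols[k]]] <- data.frame(time_months = tt[im], value = x[im])
  }
  structure(list(table = tab, interior = interior), class = "peak_summary")
}

#' @export
print.peak_summary <- function(x, ...) {
  cat("Stock peaks:\n")
  print(x$table, ...)
  invisible(x)
}

#' Time-mean of the summed pest stocks
#'
#' The "average total pest population" of a run: the mean over all sample
#' times of \eqn{\sum_i N_i(t)}.
#'
#' @param trajectory A `pest_trajectory`.
#' @return Individuals/ha.
#' @export
mean_total_pests <- function(trajectory) {
  stopifnot(nrow(trajectory) > 0)
  sp <- trajectory_species(trajectory)
  mean(rowSums(as.matrix(trajectory[, paste0("N_", sp), drop = FALSE])))
}

#' Cross-system ratio of average total pest populations
#'
#' Compares the average total pest population between two collections of
#' systems (e.g. all sole-species runs vs all pairwise runs):
#' `100 * mean_A(mean_total_pests) / mean_B(mean_total_pests)`.
#'
#' @param systems_A,systems_B Non-empty lists of `pest_trajectory` objects
#'   (a single trajectory is promoted to a list of one).
#' @return A percentage.
#' @export
cross_system_ratio <- function(systems_A, systems_B) {
  as_list <- function(x) if (inherits(x, "pest_trajectory")) list(x) else x
  systems_A <- as_list(systems_A); systems_B <- as_list(systems_B)
  stopifnot(length(systems_A) > 0, length(systems_B) > 0)
  denom <- mean(vapply(systems_B, mean_total_pests, numeric(1)))
  if (denom == 0) stop("zero average total pest population in systems_B")
  100 * mean(vapply(systems_A, mean_total_pests, numeric(1))) / denom
}

#' Detect host-parasitoid cycles and parasitoid tracking lags
#'
#' Lists the interior peaks of one pest stock and of its parasitoid guild
#' after a burn-in (the published single-species runs become cyclical
#' after month 4), and the lag of every parasitoid peak behind the nearest
#' preceding pest peak. Positive lags indicate the guild tracks its host.
#'
#' @param trajectory A `pest_trajectory`.
#' @param pest_id Species code present in the trajectory.
#' @param burn_in Months discarded before peak detection.
#' @return A list of class `cycle_summary` with `pest_peaks` and
#'   `parasitoid_peaks` (data frames `time_months`, `value`) and `lags`
#'   (months; one per parasitoid peak that has a preceding pest peak).
#' @export
#' @examples
#' detect_cycles(simulate(pest_scenario("Bf")), "Bf")
detect_cycles <- function(trajectory, pest_id, burn_in = 4) {
  sp <- trajectory_species(trajectory)
  if (!pest_id %in% sp) stop("trajectory does not contain species ", pest_id)
  tt <- trajectory$time_months
  peaks_of <- function(col) {
    x <- trajectory[[col]]
    im <- interior_maxima(x)
    im <- im[tt[im] > burn_in]
    data.frame(time_months = tt[im], value = x[im])
  }
  np <- peaks_of(paste0("N_", pest_id))
  pp <- peaks_of(paste0("P_", pest_id))
  lags <- vapply(pp$time_months, function(tp) {
    prev <- np$time_months[np$time_months < tp]
    if (length(prev) == 0) NA_real_ else tp - max(prev)
  }, numeric(1))
  structure(list(pest_peaks = np, parasitoid_peaks = pp,
                 lags = lags[!is.na(lags)], burn_in = burn_in,
                 pest_id = pest_id),
            class = "cycle_summary")
}

#' @export
print.cycle_summary <- function(x, ...) {
  cat(sprintf("Cycles of %s after month %g: %d pest peaks, %d parasitoid peaks\n",
              x$pest_id, x$burn_in, nrow(x$pest_peaks),
              nrow(x$parasitoid_peaks)))
  if (length(x$lags) > 0)
    cat("Parasitoid lags behind host peaks (months):",
        paste(signif(x$lags, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Aggregated parasitoid-host phase portrait
#'
#' Compiles all pest species into one host total and all guilds into one
#' parasitoid total and returns the ordered orbit, the standard
#' two-species phase-plane view of a host-parasitoid system. For the
#' closure diagnostic the portion of the orbit spanning the final
#' `cycle_months` (one full season cycle: a cropping block plus the
#' following non-cropping block) is treated as the final loop; the closure
#' gap is the distance between its first and last point, and a gap small
#' relative to the loop diameter indicates a closed (sustained) cycle.
#'
#' @param trajectory A `pest_trajectory`.
#' @param cycle_months Length of the final cycle used for the closure
#'   diagnostic; defaults to 6 months (the seasonal period).
#' @return A list of class `phase_portrait`: `points` (data frame
#'   `time_months`, `host`, `parasitoid`), `closure_gap`, `loop_diameter`
#'   and `relative_gap` (0 for a degenerate zero-diameter loop).
#' @export
#' @examples
#' phase_diagram(simulate(pest_scenario(pest_species_ids())))
phase_diagram <- function(trajectory, cycle_months = 6) {
  stopifnot(nrow(trajectory) > 0)
  sp <- trajectory_species(trajectory)
  pts <- data.frame(
    time_months = trajectory$time_months,
    host = rowSums(as.matrix(trajectory[, paste0("N_", sp), drop = FALSE])),
    parasitoid = rowSums(as.matrix(trajectory[, paste0("P_", sp),
                                              drop = FALSE]))
  )
  t_end <- max(pts$time_months)
  loop <- pts[pts$time_months >= t_end - cycle_months - 1e-9, , drop = FALSE]
  gap <- sqrt((loop$host[1] - loop$host[nrow(loop)])^2 +
              (loop$parasitoid[1] - loop$parasitoid[nrow(loop)])^2)
  diam <- sqrt(diff(range(loop$host))^2 + diff(range(loop$parasitoid))^2)
  structure(list(points = pts, closure_gap = gap, loop_diameter = diam,
                 relative_gap = if (diam > 0) gap / diam else 0,
                 cycle_months = cycle_months),
            class = "phase_portrait")
}

#' @export
print.phase_portrait <- function(x, ...) {
  cat(sprintf("Phase portrait: %d points; final %g-month loop closure gap %.4g (%.1f%% of loop diameter %.4g)\n",
              nrow(x$points), x$cycle_months, x$closure_gap,
              100 * x$relative_gap, x$loop_diameter))
  invisible(x)
}

#' @export
plot.phase_portrait <- function(x, ...) {
  graphics::plot(x$points$host, x$points$parasitoid, type = "l",
                 xlab = "host total (individuals/ha)",
                 ylab = "parasitoid total (individuals/ha)", ...)
  invisible(x)
}
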