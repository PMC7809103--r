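#' Design of a synthetic density-dependence experiment
#'
#' Describes a factorial larval-density experiment of the kind used to fit
#' competition coefficients: every species' density is varied over
#' `levels` (larvae per replicate arena), each design cell is replicated,
#' and the survival response carries additive Gaussian noise. Defaults are
#' laboratory-scale: density levels 0/10/20/40 larvae, 3 replicates,
#' noise standard deviation 0.5 larvae.
#'
#' @param species Character vector of species codes in the experiment.
#' @param levels Numeric vector (>= 2 distinct values) of density levels
#'   applied to every species.
#' @param replicates Replicates per design cell (>= 1).
#' @param noise_sd Standard deviation of the additive response noise
#'   (>= 0).
#' @param seed Integer seed making the generated experiment reproducible.
#' @return A list of class `experiment_design`.
#' @export
density_design <- function(species, levels = c(0, 10, 20, 40),
                           replicates = 3, noise_sd = 0.5, seed = 1) {
  species <- canonical_species(species)
  if (length(unique(levels)) < 2) stop("need >= 2 distinct density levels")
  if (any(levels < 0)) stop("density levels must be >= 0")
  if (replicates < 1) stop("replicates must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(species = species, levels = sort(unique(levels)),
                 replicates = as.integer(replicates), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "experiment_design")
}

#' Generate a synthetic density experiment from known coefficients
#'
#' Simulates the replicate table of a density-dependent larval-survival
#' experiment under the linear equilibrium interaction structure: for each
#' focal species \eqn{i} and each factorial combination of densities, the
#' recorded survival response is
#' \deqn{survived = N_i + \sum_{j \ne i} a_{ij} N_j + \varepsilon, \quad
#' \varepsilon \sim Normal(0, noise\_sd),} truncated at zero. With
#' `noise_sd = 0` every row satisfies [equilibrium_residual()] exactly, so
#' [fit_competition()] recovers the generating matrix to numerical
#' precision. The output is a pure function of `(true_matrix, design)`.
#'
#' @param true_matrix A `competition_matrix` over the design's species.
#' @param design An [density_design()].
#' @return A data frame with columns `focal`, `N_<sp>` per species,
#'   `survived` and `replicate`.
#' @export
#' @examples
#' d <- density_design(c("Bf", "Cp"), noise_sd = 0)
#' head(generate_density_experiment(competition_matrix(c("Bf", "Cp")), d))
generate_density_experiment <- function(true_matrix, design) {
  stopifnot(inherits(design, "experiment_design"))
  species <- design$species
  if (!identical(rownames(true_matrix), species))
    stop("matrix species do not match the design species")
  focal_levels <- design$levels[design$levels > 0]
  if (length(focal_levels) < 2)
    stop("need >= 2 positive density levels for the focal species")
  out <- list()
  set.seed(design$seed)
  for (i in species) {
    ## an arena needs focal larvae to record survival, so the focal density
    ## takes only positive levels; competitor densities may be 0 (controls)
    cell_levels <- stats::setNames(rep(list(design$levels), length(species)),
                                   species)
    cell_levels[[i]] <- focal_levels
    grid <- do.call(expand.grid, c(cell_levels, list(KEEP.OUT.ATTRS = FALSE)))
    grid <- grid[, species, drop = FALSE]
    for (rep_id in seq_len(design$replicates)) {
      a_row <- unclass(true_matrix)[i, ]
      mu <- as.matrix(grid) %*% a_row  # N_i + sum_{j != i} a_ij N_j
      eps <- stats::rnorm(nrow(grid), 0, design$noise_sd)
      block <- grid
      names(block) <- paste0("N_", species)
      block$focal <- i
      block$survived <- pmax(0, as.vector(mu) + eps)
      block$replicate <- rep_id
      out[[length(out) + 1]] <- block
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[, c("focal", paste0("N_", species), "survived", "replicate")]
}

#' Analytic trajectory fixtures with known ground truth
#'
#' Builds small trajectory-shaped data frames whose metric values are
#' known in closed form, for exercising the metrics independently of the
#' simulator: `"logistic"` (closed-form logistic pest series, no
#' parasitoids), `"sine_pair"` (pest and parasitoid sinusoids with a known
#' phase lag), `"circle"` (a closed phase-plane loop split evenly between
#' two species), and `"flat"` (constant stocks, zero by default). The
#' ground truth (peak times, lag, closure gap, ...) is attached as
#' attribute `"ground_truth"`.
#'
#' @param kind One of `"sine_pair"`, `"logistic"`, `"circle"`, `"flat"`.
#' @param params Named list overriding the fixture's parameters
#'   (`dt`, `horizon`, `species`; per kind: logistic `r`, `K`, `N0`;
#'   sine_pair `period`, `lag`, `baseline`, `amplitude`; circle `center`,
#'   `radius`, `cycles`; flat `value`).
#' @param seed Unused (all fixtures are deterministic); kept so every
#'   generator shares the `(params, seed)` signature.
#' @return A `pest_trajectory`-shaped data frame with attribute
#'   `"ground_truth"`.
#' @export
#' @examples
#' fx <- generate_trajectory_fixture("sine_pair", list(lag = 0.5))
#' attr(fx, "ground_truth")$lag
generate_trajectory_fixture <- function(kind = c("sine_pair", "logistic",
                                                 "circle", "flat"),
                                        params = list(), seed = 1) {
  kind <- match.arg(kind)
  p <- list(dt = 0.25, horizon = 24, species = "Cp")
  defaults <- switch(kind,
    logistic = list(r = 0.83, K = 62500, N0 = 156.25),
    sine_pair = list(period = 6, lag = 0.5, baseline = 1000, amplitude = 500),
    circle = list(center = c(2000, 1000), radius = 500, cycles = 2),
    flat = list(value = 0))
  p <- utils::modifyList(c(p, defaults), params)
  tt <- seq(0, p$horizon, by = p$dt)
  sp <- p$species
  truth <- list(kind = kind)
  if (kind == "logistic") {
    N <- p$K / (1 + ((p$K - p$N0) / p$N0) * exp(-p$r * tt))
    P <- rep(0, length(tt))
    truth <- c(truth, p[c("r", "K", "N0")])
  } else if (kind == "sine_pair") {
    w <- 2 * pi / p$period
    N <- p$baseline + p$amplitude * sin(w * tt)
    P <- p$baseline + p$amplitude * sin(w * (tt - p$lag))
    truth$lag <- p$lag
    truth$period <- p$period
    ## interior peak times of the host sinusoid
    truth$pest_peak_times <- tt[interior_maxima(N)]
  } else if (kind == "circle") {
    period <- p$horizon / p$cycles
    w <- 2 * pi / period
    N <- p$center[1] + p$radius * cos(w * tt)
    P <- p$center[2] + p$radius * sin(w * tt)
    truth$closure_gap <- 0
    truth$diameter <- 2 * p$radius
  } else {
    N <- rep(p$value, length(tt))
    P <- rep(p$value, length(tt))
    truth$value <- p$value
  }
  out <- data.frame(time_months = tt,
                    season = rep("non-cropping", length(tt)),
                    stringsAsFactors = FALSE)
  out[[paste0("N_", sp)]] <- N
  out[[paste0("P_", sp)]] <- P
  for (fl in c("G", "L", "R", "D")) out[[paste0(fl, "_", sp)]] <- 0
  attr(out, "ground_truth") <- truth
  class(out) <- c("pest_trajectory", "data.frame")
  out
}

#' Perturbed parameter ensembles for robustness analysis
#'
#' Produces `n` copies of a scenario with the growth rates, crop
#' parasitism fractions and off-diagonal competition coefficients each
#' multiplied by independent lognormal factors
#' \eqn{\exp(Normal(0, relative\_sd))}, for checking how robust dominance
#' orderings are to parameter uncertainty. Growth rates are capped at 1
#' and parasitism fractions below 1 to keep every member a valid scenario.
#' The ensemble is a pure function of `(config, relative_sd, n, seed)`.
#'
#' @param config A `pest_scenario`.
#' @param relative_sd Log-scale standard deviation of the multipliers
#'   (>= 0; 0 returns identical copies).
#' @param n Ensemble size (>= 1).
#' @param seed Integer seed.
#' @return List of `n` `pest_scenario` objects; each carries its member
#'   seed in attribute `"member_seed"`.
#' @export
perturb_parameters <- function(config, relative_sd, n, seed = 1) {
  stopifnot(inherits(config, "pest_scenario"), relative_sd >= 0, n >= 1)
  member_seeds <- local({
    set.seed(seed)
    sample.int(.Machine$integer.max %/% 2, n)
  })
  lapply(seq_len(n), function(k) {
    set.seed(member_seeds[k])
    sp <- config$species
    jit <- function(x) x * exp(stats::rnorm(length(x), 0, relative_sd))
    sp$r <- pmin(1, jit(sp$r))
    sp$phi_crop <- pmin(1 - 1e-9, jit(sp$phi_crop))
    a <- unclass(config$matrix)
    off <- which(row(a) != col(a))
    a[off] <- jit(a[off])
    cfg <- config
    cfg$species <- sp
    cfg$matrix <- structure(a, class = class(config$matrix))
    attr(cfg, "member_seed") <- member_seeds[k]
    cfg
  })
}
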