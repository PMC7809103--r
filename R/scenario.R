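#' Season calendar defaults
#'
#' Describes the bimodal Kenyan maize calendar the simulator assumes: a
#' 3-month variety planted April-June and October-December, with the
#' non-cropping months spent in a wild refuge. Time 0 is the April
#' planting; cropping blocks are the month intervals [0, 3) and [6, 9) of
#' every 12-month year. Pests enter the field only `pest_entry_delay`
#' months after planting (the field capacity stays at the wild value until
#' then), crop-level parasitism activates `parasitism_onset_delay` months
#' after planting, and at each cropping-to-non-cropping boundary only
#' `carryover_fraction` of the pest stock survives onto alternative hosts.
#'
#' @param K_crop Field carrying capacity, individuals/ha.
#' @param K_wild Wild-refuge (non-cropping) carrying capacity,
#'   individuals/ha; must be below `K_crop`.
#' @param carryover_fraction Fraction of pests surviving a
#'   cropping-to-non-cropping transition, in (0, 1].
#' @param pest_entry_delay Months after planting before pests occupy the
#'   field.
#' @param parasitism_onset_delay Months after planting before crop-level
#'   parasitism acts.
#' @param parasitism_fraction_wild Parasitism fraction in the wild refuge
#'   during non-cropping months. The published constants table prints both
#'   0.05 and 0.055 for this row; 0.05 is the default and the alternative
#'   is available as `wild_parasitism_preset("high")`.
#' @param start_month Calendar month of time 0.
#' @param cropping_blocks List of 2-vectors, month intervals (within a
#'   12-month year, relative to `start_month`) during which maize is in the
#'   field.
#' @return A list of class `season_calendar`.
#' @export
#' @examples
#' season_calendar()
season_calendar <- function(K_crop = 62500,
                            K_wild = 625,
                            carryover_fraction = 0.10,
                            pest_entry_delay = 1,
                            parasitism_onset_delay = 2,
                            parasitism_fraction_wild = 0.05,
                            start_month = "April",
                            cropping_blocks = list(c(0, 3), c(6, 9))) {
  structure(list(K_crop = K_crop, K_wild = K_wild,
                 carryover_fraction = carryover_fraction,
                 pest_entry_delay = pest_entry_delay,
                 parasitism_onset_delay = parasitism_onset_delay,
                 parasitism_fraction_wild = parasitism_fraction_wild,
                 start_month = start_month,
                 cropping_blocks = cropping_blocks),
            class = "season_calendar")
}

#' Named presets for the wild-habitat parasitism fraction
#'
#' @param preset `"default"` (0.05) or `"high"` (0.055, the alternative
#'   reading of the garbled constants-table row).
#' @return The parasitism fraction as a number.
#' @export
wild_parasitism_preset <- function(preset = c("default", "high")) {
  c(default = 0.05, high = 0.055)[[match.arg(preset)]]
}

#' Parasitoid guild parameter defaults
#'
#' Parameters shared by every lumped parasitoid guild: the number of
#' parasitoid adults emerging per parasitized host (gregarious and solitary
#' species averaged to 5), the female fraction among them, the fractional
#' guild decrease rate, and the per-parasitoid host-meeting probability.
#'
#' @param per_host_emergence Parasitoids emerging per parasitized host.
#' @param sex_ratio Fraction of emerging parasitoids that are female.
#' @param decrease_rate Guild fractional decrease rate, month^-1.
#' @param meeting_probability Host-parasitoid meeting probability.
#' @return A list of class `parasitoid_parameters`.
#' @export
parasitoid_parameters <- function(per_host_emergence = 5,
                                  sex_ratio = 0.46,
                                  decrease_rate = 0.7,
                                  meeting_probability = 0.035) {
  structure(list(per_host_emergence = per_host_emergence,
                 sex_ratio = sex_ratio,
                 decrease_rate = decrease_rate,
                 meeting_probability = meeting_probability),
            class = "parasitoid_parameters")
}

#' Build a fully resolved simulation scenario
#'
#' Assembles species constants, the subset-specific competition matrix, the
#' season calendar, parasitoid parameters, integrator settings and initial
#' stocks into one validated configuration object that [simulate()] can
#' run. Every default is a published constant (see
#' [parameter_provenance()]); any field can be overridden.
#'
#' Default initial stocks put each pest at
#' `reference_density_wild * K_wild / 2` = 156.25 individuals/ha (half the
#' refuge reference density) and each parasitoid guild at 10% of that, so
#' simulations start from the near-empty refuge state from which the
#' published trajectories grow.
#'
#' @param species Character vector of 1-4 species codes.
#' @param overrides Named list of overrides applied on top of the defaults;
#'   names are scenario fields (`dt`, `horizon`, `matrix`, `calendar`,
#'   `parasitoid`, `init_pest`, `init_parasitoid`, `parasitism_form`,
#'   `reference_density_crop`, `reference_density_wild`). `calendar` and
#'   `parasitoid` overrides may be partial named lists, merged field-wise.
#' @param ... Individual overrides given directly, e.g. `dt = 0.05`;
#'   merged after `overrides`.
#' @return A list of class `pest_scenario`.
#' @seealso [validate_scenario()], [simulate.pest_scenario()]
#' @export
#' @examples
#' pest_scenario("Cp")
#' pest_scenario(c("Bf", "Cp"), dt = 0.125)
pest_scenario <- function(species, overrides = list(), ...) {
  species <- canonical_species(species)
  cfg <- list(
    species = pest_species_table(species),
    matrix = competition_matrix(species),
    calendar = season_calendar(),
    parasitoid = parasitoid_parameters(),
    dt = 0.25,
    horizon = 24,
    reference_density_wild = 0.5,
    reference_density_crop = 2,
    parasitism_form = "saturating"
  )
  n0 <- cfg$reference_density_wild * cfg$calendar$K_wild / 2
  cfg$init_pest <- stats::setNames(rep(n0, length(species)), species)
  cfg$init_parasitoid <- stats::setNames(rep(0.1 * n0, length(species)), species)

  overrides <- c(overrides, list(...))
  if (length(overrides) > 0 &&
      (is.null(names(overrides)) || any(names(overrides) == "")))
    stop("all overrides must be named")
  for (nm in names(overrides)) {
    if (!nm %in% names(cfg)) stop("unknown scenario field: ", nm)
    val <- overrides[[nm]]
    if (nm %in% c("calendar", "parasitoid") && is.list(val) &&
        !inherits(val, c("season_calendar", "parasitoid_parameters"))) {
      bad <- setdiff(names(val), names(cfg[[nm]]))
      if (length(bad) > 0) stop("unknown ", nm, " field(s): ",
                                paste(bad, collapse = ", "))
      cfg[[nm]][names(val)] <- val
    } else {
      cfg[[nm]] <- val
    }
  }
  ## recompute default initial stocks if densities/capacities were
  ## overridden but stocks were not
  if (!any(c("init_pest", "init_parasitoid") %in% names(overrides))) {
    n0 <- cfg$reference_density_wild * cfg$calendar$K_wild / 2
    cfg$init_pest <- stats::setNames(rep(n0, length(species)), species)
    cfg$init_parasitoid <- stats::setNames(rep(0.1 * n0, length(species)),
                                           species)
  }
  class(cfg) <- "pest_scenario"
  problems <- validate_scenario(cfg)
  if (length(problems) > 0)
    stop("invalid scenario:\n  ", paste(problems, collapse = "\n  "))
  cfg
}

#' Validate a scenario configuration
#'
#' Checks every structural and range invariant of a scenario and returns
#' the violations as human-readable strings rather than raising, so
#' configuration files can be linted.
#'
#' @param config A `pest_scenario` (or a bare list with the same fields).
#' @return Character vector of violations; empty when the scenario is
#'   valid. Each entry names the offending field and the rule.
#' @export
#' @examples
#' validate_scenario(pest_scenario("Cp"))
validate_scenario <- function(config) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  sp <- config$species
  if (!is.data.frame(sp) || !all(c("id", "r", "phi_crop") %in% names(sp))) {
    add("species: must be a data frame with id, r, phi_crop")
    return(v)
  }
  if (any(sp$r <= 0 | sp$r > 1)) add("species$r: growth rates must lie in (0, 1]")
  if (any(sp$phi_crop < 0 | sp$phi_crop >= 1))
    add("species$phi_crop: parasitism fractions must lie in [0, 1)")
  a <- config$matrix
  if (!is.matrix(a) || nrow(a) != ncol(a)) {
    add("matrix: must be square")
  } else {
    if (nrow(a) != nrow(sp))
      add(sprintf("matrix: dimension %d does not match species count %d",
                  nrow(a), nrow(sp)))
    else if (!identical(rownames(a), sp$id))
      add("matrix: row order must match species order")
    if (any(abs(diag(a) - 1) > 0)) add("matrix: diagonal must be exactly 1")
    if (any(a < 0)) add("matrix: coefficients must be non-negative")
  }
  cal <- config$calendar
  if (cal$K_wild >= cal$K_crop) add("calendar$K_wild: must be below K_crop")
  if (cal$K_crop <= 0 || cal$K_wild <= 0) add("calendar: capacities must be positive")
  if (cal$carryover_fraction <= 0 || cal$carryover_fraction > 1)
    add("calendar$carryover_fraction: must lie in (0, 1]")
  if (cal$pest_entry_delay < 0 || cal$parasitism_onset_delay < 0)
    add("calendar: delays must be >= 0")
  if (cal$parasitism_fraction_wild < 0 || cal$parasitism_fraction_wild >= 1)
    add("calendar$parasitism_fraction_wild: must lie in [0, 1)")
  blocks <- cal$cropping_blocks
  if (length(blocks) > 0) {
    b <- do.call(rbind, blocks)
    if (any(b[, 2] <= b[, 1]) || any(b < 0) || any(b > 12))
      add("calendar$cropping_blocks: blocks must be increasing intervals within [0, 12]")
    if (length(blocks) > 1) {
      o <- order(b[, 1])
      if (any(b[o, 1][-1] < b[o, 2][-nrow(b)]))
        add("calendar$cropping_blocks: blocks must be disjoint")
    }
  }
  pp <- config$parasitoid
  if (pp$per_host_emergence <= 0) add("parasitoid$per_host_emergence: must be > 0")
  if (pp$sex_ratio <= 0 || pp$sex_ratio >= 1) add("parasitoid$sex_ratio: must lie in (0, 1)")
  if (pp$decrease_rate <= 0 || pp$decrease_rate > 1) add("parasitoid$decrease_rate: must lie in (0, 1]")
  if (pp$meeting_probability <= 0 || pp$meeting_probability >= 1)
    add("parasitoid$meeting_probability: must lie in (0, 1)")
  if (!is.numeric(config$dt) || config$dt <= 0) add("dt: must be > 0")
  else {
    if (config$horizon <= 0) add("horizon: must be > 0")
    steps <- config$horizon / config$dt
    if (abs(steps - round(steps)) > 1e-8)
      add("horizon: must be a positive multiple of dt")
  }
  for (fld in c("init_pest", "init_parasitoid")) {
    x <- config[[fld]]
    if (length(x) != nrow(sp) || !identical(names(x), sp$id))
      add(paste0(fld, ": must be named per species in species order"))
    else if (any(x < 0)) add(paste0(fld, ": stocks must be >= 0"))
  }
  if (!is.function(config$parasitism_form) &&
      !config$parasitism_form %in% names(parasitism_forms()))
    add("parasitism_form: unknown form (see parasitism_forms())")
  v
}

#' @export
print.pest_scenario <- function(x, ...) {
  cat("Pest-parasitoid scenario:", paste(x$species$id, collapse = " + "), "\n")
  cat("  species       :", paste(sprintf("%s (r=%.2f, phi=%.2f)", x$species$id,
                                         x$species$r, x$species$phi_crop),
                                 collapse = ", "), "\n")
  cat(sprintf("  integrator    : forward Euler, dt = %g months, horizon = %g months\n",
              x$dt, x$horizon))
  cat(sprintf("  capacities    : crop %g, wild %g individuals/ha; carryover %g\n",
              x$calendar$K_crop, x$calendar$K_wild,
              x$calendar$carryover_fraction))
  cat(sprintf("  delays        : pest entry %g, parasitism onset %g months\n",
              x$calendar$pest_entry_delay, x$calendar$parasitism_onset_delay))
  cat("  parasitism    :",
      if (is.function(x$parasitism_form)) "custom" else x$parasitism_form,
      sprintf("(p_meet=%g, wild phi=%g)\n",
              x$parasitoid$meeting_probability,
              x$calendar$parasitism_fraction_wild))
  cat("  initial stocks: N0 =", paste(signif(x$init_pest, 6), collapse = ", "),
      "; P0 =", paste(signif(x$init_parasitoid, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Write or read a scenario as JSON
#'
#' Serializes every field of a scenario to a structured key-value text file
#' and restores it losslessly (full floating-point precision), so a stored
#' snapshot re-runs to bit-identical trajectories.
#'
#' @param config A `pest_scenario`.
#' @param path File path.
#' @return `read_scenario()` returns a `pest_scenario`;
#'   `write_scenario()` returns `path` invisibly.
#' @export
write_scenario <- function(config, path) {
  stopifnot(inherits(config, "pest_scenario"))
  if (is.function(config$parasitism_form))
    stop("scenarios with a custom parasitism function cannot be serialized")
  x <- unclass(config)
  x$matrix <- list(species = rownames(config$matrix),
                   a = unclass(config$matrix))
  x$calendar <- unclass(x$calendar)
  x$parasitoid <- unclass(x$parasitoid)
  ## named stocks must survive serialization as key-value objects
  x$init_pest <- as.list(x$init_pest)
  x$init_parasitoid <- as.list(x$init_parasitoid)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ## JSON has no integer/double distinction; everything numeric is double
  to_double <- function(v) {
    if (is.integer(v)) storage.mode(v) <- "double"
    else if (is.list(v)) v[] <- lapply(v, to_double)
    else if (is.data.frame(v)) v[] <- lapply(v, to_double)
    v
  }
  x <- to_double(x)
  species <- x$species$id
  a <- as.matrix(x$matrix$a)
  dimnames(a) <- list(x$matrix$species, x$matrix$species)
  sp_tab <- as.data.frame(x$species, stringsAsFactors = FALSE)
  rownames(sp_tab) <- sp_tab$id
  pest_scenario(
    species,
    overrides = list(
      species = sp_tab,
      matrix = as_competition_matrix(a),
      calendar = do.call(season_calendar,
                         c(x$calendar[setdiff(names(x$calendar), "cropping_blocks")],
                           list(cropping_blocks = lapply(seq_len(nrow(x$calendar$cropping_blocks)),
                                                         function(i) x$calendar$cropping_blocks[i, ])))),
      parasitoid = do.call(parasitoid_parameters, x$parasitoid),
      dt = x$dt, horizon = x$horizon,
      reference_density_wild = x$reference_density_wild,
      reference_density_crop = x$reference_density_crop,
      parasitism_form = x$parasitism_form,
      init_pest = stats::setNames(as.numeric(x$init_pest), names(x$init_pest)),
      init_parasitoid = stats::setNames(as.numeric(x$init_parasitoid),
                                        names(x$init_parasitoid))
    )
  )
}
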