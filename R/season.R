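## Seasonal structure. Time is measured in months since the April planting
## of year 1 (t = 0); the calendar repeats every 12 months.

season_position <- function(t) t %% 12

## index of the cropping block containing t, or NA
containing_block <- function(t, calendar, eps = 1e-9) {
  pos <- season_position(t)
  for (i in seq_along(calendar$cropping_blocks)) {
    b <- calendar$cropping_blocks[[i]]
    if (pos >= b[1] - eps && pos < b[2] - eps) return(i)
  }
  NA_integer_
}

#' Is a time point inside a cropping season?
#'
#' @param t Months since simulation start (vectorized).
#' @param calendar A [season_calendar()].
#' @return Logical vector.
#' @export
in_cropping_season <- function(t, calendar = season_calendar()) {
  vapply(t, function(ti) !is.na(containing_block(ti, calendar)), logical(1))
}

## months elapsed since the planting date of the cropping block containing
## t (NA outside cropping seasons)
months_since_planting <- function(t, calendar) {
  i <- containing_block(t, calendar)
  if (is.na(i)) return(NA_real_)
  season_position(t) - calendar$cropping_blocks[[i]][1]
}

## is t exactly a cropping -> non-cropping boundary (end of a block)?
is_season_end <- function(t, calendar, eps = 1e-9) {
  if (t <= eps) return(FALSE)
  pos <- season_position(t)
  ends <- vapply(calendar$cropping_blocks, `[`, numeric(1), 2)
  any(abs(pos - ends) < eps)
}

#' Time-varying carrying capacity
#'
#' The pest carrying capacity switches between the field value `K_crop`
#' and the wild-refuge value `K_wild`. Because pests are first recorded in
#' the field only `pest_entry_delay` months after planting, the capacity
#' stays at `K_wild` for that initial stretch of each cropping block and
#' jumps to `K_crop` for the remainder; all non-cropping months use
#' `K_wild`.
#'
#' @param t Months since simulation start (vectorized).
#' @param calendar A [season_calendar()].
#' @return Carrying capacity in individuals/ha.
#' @export
#' @examples
#' carrying_capacity(c(0.25, 1.5, 4))
carrying_capacity <- function(t, calendar = season_calendar()) {
  vapply(t, function(ti) {
    tau <- months_since_planting(ti, calendar)
    if (!is.na(tau) && tau >= calendar$pest_entry_delay - 1e-9)
      calendar$K_crop
    else
      calendar$K_wild
  }, numeric(1))
}

#' Active parasitism fraction for one species
#'
#' Parasitism on a pest cohort is only recorded from the pest's second
#' field generation, about two months after planting: within each cropping
#' block the species' crop-level fraction `phi_crop` activates
#' `parasitism_onset_delay` months after planting and is zero before that.
#' During non-cropping months the low wild-habitat fraction applies.
#'
#' @param t Months since simulation start (vectorized).
#' @param species A species code (see [pest_species_ids()]) or a one-row
#'   species table.
#' @param calendar A [season_calendar()].
#' @return Dimensionless parasitism fraction.
#' @export
#' @examples
#' active_parasitism_fraction(c(1, 2.5, 4.5), "Cp")
active_parasitism_fraction <- function(t, species,
                                       calendar = season_calendar()) {
  phi <- if (is.data.frame(species)) species$phi_crop[1]
         else pest_species_table(species)$phi_crop
  vapply(t, function(ti) {
    tau <- months_since_planting(ti, calendar)
    if (is.na(tau)) return(calendar$parasitism_fraction_wild)
    if (tau >= calendar$parasitism_onset_delay - 1e-9) phi else 0
  }, numeric(1))
}
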