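#' Species identifiers in canonical order
#'
#' The four maize pests are identified by two-letter codes: `"Sf"`
#' (*Spodoptera frugiperda*, fall armyworm), `"Bf"` (*Busseola fusca*),
#' `"Sc"` (*Sesamia calamistis*) and `"Cp"` (*Chilo partellus*). All
#' internal objects order species as `Sf, Bf, Sc, Cp`; user input in any
#' order is reordered, and all output is labelled by code so the internal
#' ordering never matters to callers.
#'
#' @return Character vector of the four species codes in canonical order.
#' @export
#' @examples
#' pest_species_ids()
pest_species_ids <- function() c("Sf", "Bf", "Sc", "Cp")

## reorder a set of codes into canonical order, validating membership
canonical_species <- function(species) {
  species <- unique(as.character(species))
  bad <- setdiff(species, pest_species_ids())
  if (length(bad) > 0L) {
    stop("unknown species id(s): ", paste(bad, collapse = ", "),
         " (known: ", paste(pest_species_ids(), collapse = ", "), ")")
  }
  if (length(species) == 0L) stop("species set is empty")
  pest_species_ids()[pest_species_ids() %in% species]
}

#' Biological constants of the four pest species
#'
#' Per-species constants used throughout the simulator: the intrinsic
#' (reference fractional) growth rate `r` in month^-1 and the reference
#' fractional parasitism rate `phi_crop` exerted by the species' lumped
#' parasitoid guild during the cropping season. Parasitism of all
#' parasitoid species attacking one host is lumped into a single fraction.
#'
#' @param species Optional character vector of species codes; defaults to
#'   all four species.
#' @return A data frame with one row per species and columns `id`,
#'   `display_name`, `r` (per-month growth fraction, in (0, 1]) and
#'   `phi_crop` (dimensionless parasitism fraction, in [0, 1)).
#' @seealso [competition_matrix()], [pest_scenario()]
#' @export
#' @examples
#' pest_species_table()
#' pest_species_table(c("Cp", "Bf"))
pest_species_table <- function(species = pest_species_ids()) {
  tab <- data.frame(
    id = pest_species_ids(),
    display_name = c("Spodoptera frugiperda", "Busseola fusca",
                     "Sesamia calamistis", "Chilo partellus"),
    r = c(Sf = 0.70, Bf = 0.80, Sc = 0.80, Cp = 0.83),
    phi_crop = c(Sf = 0.22, Bf = 0.25, Sc = 0.28, Cp = 0.30),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- tab$id
  tab[canonical_species(species), , drop = FALSE]
}

#' Provenance of every numeric default
#'
#' Machine-readable map from each numeric default the package ships to the
#' published table cell it was taken from, so parameter values can be
#' audited without reading the source code. Competition coefficients are
#' covered collectively per system block.
#'
#' @return A data frame with columns `parameter`, `value` (the default, as
#'   numeric; `NA` for whole-matrix entries), `units` and `source`.
#' @export
#' @examples
#' head(parameter_provenance())
parameter_provenance <- function() {
  p <- function(parameter, value, units, source)
    data.frame(parameter = parameter, value = value, units = units,
               source = source, stringsAsFactors = FALSE)
  const <- "simulation-constants table"
  rbind(
    p("r.Cp", 0.83, "month^-1", paste(const, "- C. partellus reference fraction growth rate")),
    p("r.Bf", 0.80, "month^-1", paste(const, "- B. fusca reference fraction growth rate")),
    p("r.Sc", 0.80, "month^-1", paste(const, "- S. calamistis reference fraction growth rate")),
    p("r.Sf", 0.70, "month^-1", paste(const, "- S. frugiperda reference fraction growth rate")),
    p("phi_crop.Cp", 0.30, "fraction", paste(const, "- C. partellus reference fractional parasitism rate")),
    p("phi_crop.Bf", 0.25, "fraction", paste(const, "- B. fusca reference fractional parasitism rate")),
    p("phi_crop.Sc", 0.28, "fraction", paste(const, "- S. calamistis reference fractional parasitism rate")),
    p("phi_crop.Sf", 0.22, "fraction", paste(const, "- S. frugiperda reference fractional parasitism rate")),
    p("calendar.K_crop", 62500, "individuals/ha", paste(const, "- carrying capacity of 1 ha of maize field (31250 plants/ha x 2 per plant)")),
    p("calendar.K_wild", 625, "individuals/ha", paste(const, "- carrying capacity of 1 ha in non-cropping seasons (printed value cell)")),
    p("calendar.parasitism_fraction_wild", 0.05, "fraction", paste(const, "- reference fractional parasitism rate in wild habitat (garbled row; 0.05 adopted, 0.055 kept as preset)")),
    p("calendar.carryover_fraction", 0.10, "fraction", "assumption: 10% of field pests survive on alternative hosts between seasons"),
    p("calendar.pest_entry_delay", 1, "months", "assumption: pests first recorded 1 month after planting"),
    p("calendar.parasitism_onset_delay", 2, "months", "assumption: parasitism recorded from the second pest generation, ~2 months after planting"),
    p("calendar.cropping_blocks", NA_real_, "months", paste(const, "- two 3-month cropping seasons per year (April-June, October-December)")),
    p("parasitoid.per_host_emergence", 5, "parasitoids/host", paste(const, "- number of parasitoids per host")),
    p("parasitoid.sex_ratio", 0.46, "fraction female", paste(const, "- parasitoid sex ratio")),
    p("parasitoid.decrease_rate", 0.7, "month^-1", paste(const, "- parasitoid fractional decrease rate")),
    p("parasitoid.meeting_probability", 0.035, "dimensionless", paste(const, "- host-parasitoid meeting probability 3.5%")),
    p("dt", 0.25, "months", paste(const, "- time step (weekly recording)")),
    p("horizon", 24, "months", paste(const, "- period of the simulation")),
    p("reference_density_crop", 2, "individuals/plant", paste(const, "- reference pest density in maize field")),
    p("reference_density_wild", 0.5, "individuals/plant", paste(const, "- reference pest density in wild habitat")),
    p("matrix.two_species", NA_real_, "per individual", "pairwise competition-coefficients table (two multi-species combinations)"),
    p("matrix.three_species", NA_real_, "per individual", "competition-coefficients table (three multi-species combinations)"),
    p("matrix.four_species", NA_real_, "per individual", "competition-coefficients table (four multi-species combination)"),
    p("init.pest", 156.25, "individuals/ha", "package default: reference_density_wild x K_wild / 2 (growth starts from near-empty refuge)"),
    p("init.parasitoid", 15.625, "individuals/ha", "package default: 10% of the initial pest stock")
  )
}
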