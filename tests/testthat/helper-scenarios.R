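## A scenario with no seasonality: no cropping blocks, so the carrying
## capacity is constant at K and the wild parasitism fraction applies
## throughout (set to 0 here, with parasitoids seeded at 0), reducing the
## model to pure Lotka-Volterra competition.
constant_k_scenario <- function(species = "Cp", K = 62500, dt = 0.25,
                                horizon = 24, ...) {
  species <- pestdyn::pest_species_ids()[pestdyn::pest_species_ids() %in% species]
  pestdyn::pest_scenario(
    species,
    calendar = list(K_wild = K, K_crop = 2 * K,
                    parasitism_fraction_wild = 0,
                    cropping_blocks = list()),
    init_parasitoid = stats::setNames(rep(0, length(species)), species),
    dt = dt, horizon = horizon, ...
  )
}

## closed-form logistic solution
logistic_solution <- function(t, r, K, N0) {
  K / (1 + ((K - N0) / N0) * exp(-r * t))
}

## a valid competition matrix from a plain numeric matrix
labelled_matrix <- function(values, species) {
  a <- matrix(values, nrow = length(species), byrow = TRUE,
              dimnames = list(species, species))
  pestdyn::as_competition_matrix(a)
}
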