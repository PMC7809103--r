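test_that("species table carries the published constants", {
  tab <- pest_species_table()
  expect_setequal(tab$id, c("Sf", "Bf", "Sc", "Cp"))
  expect_equal(tab["Cp", "r"], 0.83)
  expect_equal(tab["Cp", "phi_crop"], 0.30)
  expect_equal(tab["Sf", "r"], 0.70)
  expect_equal(tab["Sf", "phi_crop"], 0.22)
  expect_equal(tab["Bf", "r"], 0.80)
  expect_equal(tab["Sc", "phi_crop"], 0.28)
  expect_true(all(tab$phi_crop > 0 & tab$phi_crop < 1))
  expect_true(all(tab$r > 0 & tab$r <= 1))
})

test_that("competition matrix lookup is subset-specific with unit diagonal", {
  a2 <- competition_matrix(c("Bf", "Cp"))
  expect_equal(a2["Bf", "Cp"], 9.12e-5)
  expect_equal(a2["Cp", "Bf"], 4.15e-4)
  a4 <- competition_matrix(c("Sf", "Bf", "Sc", "Cp"))
  expect_equal(a4["Cp", "Sc"], 8e-5)
  ## the same pair carries different values in different systems
  a3 <- competition_matrix(c("Bf", "Sc", "Cp"))
  expect_false(a3["Bf", "Cp"] == a2["Bf", "Cp"])
  ## singleton is the 1x1 identity
  a1 <- competition_matrix("Sf")
  expect_equal(unclass(a1), matrix(1, 1, 1, dimnames = list("Sf", "Sf")))
  for (a in list(a2, a3, a4)) expect_equal(unname(diag(a)), rep(1, nrow(a)))
  ## input order never matters: output is canonically ordered
  expect_identical(competition_matrix(c("Cp", "Bf")), a2)
  expect_error(competition_matrix(c("Bf", "Zz")), "unknown species")
})

test_that("scenario defaults come from the constants table and overrides pass through", {
  s <- pest_scenario("Cp")
  expect_equal(s$dt, 0.25)
  expect_equal(s$horizon, 24)
  expect_equal(s$calendar$K_crop, 62500)
  expect_equal(s$calendar$K_wild, 625)
  expect_equal(s$calendar$carryover_fraction, 0.10)
  expect_equal(s$calendar$pest_entry_delay, 1)
  expect_equal(s$calendar$parasitism_onset_delay, 2)
  expect_equal(s$calendar$parasitism_fraction_wild, 0.05)
  expect_equal(s$parasitoid$per_host_emergence, 5)
  expect_equal(s$parasitoid$sex_ratio, 0.46)
  expect_equal(s$parasitoid$decrease_rate, 0.7)
  expect_equal(s$parasitoid$meeting_probability, 0.035)
  expect_equal(unname(s$init_pest), 156.25)
  expect_equal(unname(s$init_parasitoid), 15.625)

  s2 <- pest_scenario("Cp", dt = 0.05)
  expect_equal(s2$dt, 0.05)
  expect_equal(s2$horizon, 24)
  s3 <- pest_scenario(c("Bf", "Sc"))
  expect_identical(s3$matrix, competition_matrix(c("Bf", "Sc")))
  ## partial calendar override merges field-wise
  s4 <- pest_scenario("Cp", calendar = list(carryover_fraction = 1))
  expect_equal(s4$calendar$carryover_fraction, 1)
  expect_equal(s4$calendar$K_crop, 62500)
  expect_error(pest_scenario("Cp", dt = 0), "invalid scenario")
  expect_error(pest_scenario("Cp", list(nonsense = 1)), "unknown scenario field")
})

test_that("validate_scenario names the field and rule of each violation", {
  s <- pest_scenario("Cp")
  expect_length(validate_scenario(s), 0)
  s_bad <- s
  s_bad$dt <- 0
  v <- validate_scenario(s_bad)
  expect_length(v, 1)
  expect_match(v, "dt")
  s3 <- pest_scenario(c("Sf", "Bf", "Sc"))
  s3$matrix <- competition_matrix(c("Sf", "Bf"))
  v3 <- validate_scenario(s3)
  expect_true(any(grepl("dimension", v3)))
  s_neg <- pest_scenario("Cp")
  s_neg$init_pest[] <- -1
  expect_true(any(grepl("init_pest", validate_scenario(s_neg))))
})

test_that("scenario JSON round trip is lossless field by field", {
  s <- pest_scenario(c("Bf", "Cp"), dt = 0.125,
                     calendar = list(carryover_fraction = 0.2))
  path <- withr::local_tempfile(fileext = ".json")
  write_scenario(s, path)
  s2 <- read_scenario(path)
  expect_equal(s2$species, s$species)
  expect_equal(unclass(s2$matrix), unclass(s$matrix))
  expect_equal(unclass(s2$calendar), unclass(s$calendar))
  expect_equal(unclass(s2$parasitoid), unclass(s$parasitoid))
  expect_identical(s2$dt, s$dt)
  expect_identical(s2$horizon, s$horizon)
  expect_identical(s2$init_pest, s$init_pest)
  expect_identical(s2$init_parasitoid, s$init_parasitoid)
  expect_identical(s2$parasitism_form, s$parasitism_form)
  ## snapshots re-run bit-identically
  expect_identical(as.data.frame(simulate(s2)), as.data.frame(simulate(s)))
})

test_that("competition matrix CSV round trip is exact", {
  a <- competition_matrix(c("Sf", "Sc", "Cp"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_competition_matrix(a, path)
  expect_identical(unclass(read_competition_matrix(path)), unclass(a))
})

test_that("the provenance map covers every numeric default", {
  prov <- parameter_provenance()
  tab <- pest_species_table()
  for (sp in tab$id) {
    expect_equal(prov$value[prov$parameter == paste0("r.", sp)], tab[sp, "r"])
    expect_equal(prov$value[prov$parameter == paste0("phi_crop.", sp)],
                 tab[sp, "phi_crop"])
  }
  cal <- season_calendar()
  for (fld in c("K_crop", "K_wild", "carryover_fraction", "pest_entry_delay",
                "parasitism_onset_delay", "parasitism_fraction_wild"))
    expect_equal(prov$value[prov$parameter == paste0("calendar.", fld)],
                 cal[[fld]])
  pp <- parasitoid_parameters()
  for (fld in names(pp))
    expect_equal(prov$value[prov$parameter == paste0("parasitoid.", fld)],
                 pp[[fld]])
  s <- pest_scenario("Cp")
  expect_equal(prov$value[prov$parameter == "dt"], s$dt)
  expect_equal(prov$value[prov$parameter == "horizon"], s$horizon)
  expect_equal(prov$value[prov$parameter == "reference_density_wild"],
               s$reference_density_wild)
  expect_equal(prov$value[prov$parameter == "reference_density_crop"],
               s$reference_density_crop)
  expect_equal(prov$value[prov$parameter == "init.pest"],
               unname(s$init_pest[1]))
  expect_equal(prov$value[prov$parameter == "init.parasitoid"],
               unname(s$init_parasitoid[1]))
  ## every coefficient block family is accounted for
  expect_true(all(c("matrix.two_species", "matrix.three_species",
                    "matrix.four_species") %in% prov$parameter))
})

test_that("the garbled wild-parasitism row keeps its alternative as a preset", {
  expect_equal(wild_parasitism_preset(), 0.05)
  expect_equal(wild_parasitism_preset("high"), 0.055)
  expect_equal(season_calendar()$parasitism_fraction_wild,
               wild_parasitism_preset("default"))
})
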