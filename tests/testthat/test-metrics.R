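test_that("dominance shares sum to one and respect symmetry", {
  tr1 <- simulate(pest_scenario("Cp"))
  sh1 <- dominance_shares(tr1)
  expect_equal(unname(sh1$averaged), 1)
  expect_equal(unname(sh1$instantaneous), 1)

  ## two clones of the same species parameters with a symmetric matrix
  s <- pest_scenario(c("Bf", "Sc"),
                     matrix = labelled_matrix(c(1, 2e-4, 2e-4, 1),
                                              c("Bf", "Sc")))
  s$species$r <- c(0.8, 0.8)
  s$species$phi_crop <- c(0.25, 0.25)
  sh <- dominance_shares(simulate(s))
  expect_equal(unname(sh$averaged), c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(sum(sh$averaged), 1, tolerance = 1e-9)
  expect_equal(sum(sh$instantaneous), 1, tolerance = 1e-9)

  ## default Cp + Bf system: Cp leads at month 6
  sh_cb <- dominance_shares(simulate(pest_scenario(c("Bf", "Cp"))))
  expect_gt(sh_cb$instantaneous[["Cp"]], sh_cb$instantaneous[["Bf"]])

  ## invariant under uniform rescaling of all pest stocks
  tr <- simulate(pest_scenario(c("Bf", "Cp")))
  tr_scaled <- tr
  tr_scaled$N_Bf <- 3 * tr$N_Bf
  tr_scaled$N_Cp <- 3 * tr$N_Cp
  expect_equal(dominance_shares(tr_scaled)$averaged,
               dominance_shares(tr)$averaged, tolerance = 1e-12)

  ## all-zero window errors
  flat <- generate_trajectory_fixture("flat")
  expect_error(dominance_shares(flat), "zero")
})

test_that("peak summary finds global and interior maxima", {
  ## monotone series: no interior maxima, peak at the final sample
  fx <- generate_trajectory_fixture("logistic", list(horizon = 6))
  pk <- peak_summary(fx)
  expect_equal(nrow(pk$interior$N_Cp), 0)
  expect_equal(pk$table$t_max[pk$table$stock == "N_Cp"], 6)
  ## [0, 1, 0] has one interior maximum at the middle sample
  toy <- data.frame(time_months = c(0, 1, 2), season = "non-cropping",
                    N_Cp = c(0, 1, 0))
  pk2 <- peak_summary(toy)
  expect_equal(pk2$interior$N_Cp$time_months, 1)
  expect_equal(pk2$table$max[1], 1)
  ## default single-Cp run: the first post-establishment pest peak falls
  ## between months 4 and 9 (one full season cycle after introduction)
  tr_cp <- simulate(pest_scenario("Cp"))
  first_peak <- detect_cycles(tr_cp, "Cp")$pest_peaks$time_months[1]
  expect_gt(first_peak, 4)
  expect_lt(first_peak, 9)
  ## appending post-horizon zeros below the max changes nothing
  tr <- simulate(pest_scenario("Cp"))
  ext <- as.data.frame(tr)
  pad <- ext[rep(1, 8), ]
  pad$time_months <- max(tr$time_months) + seq_len(8) * 0.25
  pad[, grep("^[NPGLRD]_", names(pad))] <- 0
  ext <- rbind(ext, pad)
  a <- peak_summary(tr)$table
  b <- peak_summary(ext)$table
  expect_equal(b$max, a$max)
  expect_equal(b$t_max, a$t_max)
})

test_that("mean total pests averages the summed stocks", {
  expect_equal(mean_total_pests(generate_trajectory_fixture("flat")), 0)
  const <- generate_trajectory_fixture("flat", list(value = 42))
  expect_equal(mean_total_pests(const), 42)
  ## linear ramp 0 -> c has mean c/2 when endpoints are included
  ramp <- data.frame(time_months = 0:10, season = "non-cropping",
                     N_Cp = seq(0, 100, by = 10))
  class(ramp) <- c("pest_trajectory", "data.frame")
  expect_equal(mean_total_pests(ramp), 50)
})

test_that("cross-system ratios are identity-normalized and antisymmetric", {
  trs <- lapply(c("Sf", "Cp"), function(sp) simulate(pest_scenario(sp)))
  expect_identical(cross_system_ratio(trs, trs), 100)
  flat <- generate_trajectory_fixture("flat")
  expect_equal(cross_system_ratio(list(flat), trs), 0)
  expect_error(cross_system_ratio(trs, list(flat)), "zero")
  r_ab <- cross_system_ratio(trs[1], trs[2])
  r_ba <- cross_system_ratio(trs[2], trs[1])
  expect_equal(r_ab * r_ba, 1e4, tolerance = 1e-6)
})

test_that("cycle detection recovers a constructed lag and handles no parasitoids", {
  fx <- generate_trajectory_fixture("sine_pair", list(lag = 0.5))
  cyc <- detect_cycles(fx, "Cp")
  expect_gte(length(cyc$lags), 2)
  expect_true(all(abs(cyc$lags - 0.5) <= 0.25 + 1e-9))
  ## pure logistic: parasitoids absent, no parasitoid peaks
  lg <- generate_trajectory_fixture("logistic")
  cyc0 <- detect_cycles(lg, "Cp")
  expect_equal(nrow(cyc0$parasitoid_peaks), 0)
  expect_error(detect_cycles(fx, "Bf"), "does not contain")
})

test_that("phase diagram aggregates stocks and measures loop closure", {
  flat <- generate_trajectory_fixture("flat", list(value = 7))
  ph <- phase_diagram(flat)
  expect_equal(ph$closure_gap, 0)
  expect_equal(ph$relative_gap, 0)
  expect_equal(nrow(ph$points), nrow(flat))
  ## constructed circle closes exactly after whole cycles
  circ <- generate_trajectory_fixture("circle", list(cycles = 2, horizon = 24))
  ph_c <- phase_diagram(circ, cycle_months = 12)
  expect_lt(ph_c$closure_gap, 1e-9)
  expect_equal(ph_c$loop_diameter, sqrt(2) * 1000, tolerance = 1e-6)
  ## aggregation sums species
  tr <- simulate(pest_scenario(c("Bf", "Cp")))
  ph_t <- phase_diagram(tr)
  expect_equal(ph_t$points$host, tr$N_Bf + tr$N_Cp)
  expect_equal(ph_t$points$parasitoid, tr$P_Bf + tr$P_Cp)
})
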