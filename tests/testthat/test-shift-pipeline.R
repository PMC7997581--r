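make_ensemble <- function(energies, shieldings) {
  # shieldings: matrix conformers x atoms
  out <- tibble::tibble(conformer_id = paste0("m", seq_along(energies)),
                        rel_energy = energies)
  for (a in seq_len(ncol(shieldings))) out[[paste0("C", a)]] <- shieldings[, a]
  out
}

test_that("energy window keeps conformers within the cutoff, minimum always survives", {
  ens <- make_ensemble(c(0, 2.9, 3.1), matrix(100, 3, 1))
  kept <- energy_window_filter(ens, window = 3.0)
  expect_equal(nrow(kept), 2L)          # 3.1 kcal/mol falls outside a 3.0 window
  expect_identical(kept$conformer_id, c("m1", "m2"))

  # window beyond the spread is the identity
  expect_equal(nrow(energy_window_filter(ens, window = 10)), 3L)

  # brute-force agreement on a larger random ensemble
  set.seed(21)
  e <- runif(50, 0, 6)
  big <- make_ensemble(e, matrix(rnorm(50), 50, 1))
  w <- 2.5
  kept2 <- energy_window_filter(big, w)
  expect_identical(kept2$conformer_id, big$conformer_id[(e - min(e)) <= w])

  expect_error(energy_window_filter(big[0, ], 1), "empty")
  expect_error(energy_window_filter(big, -1), "positive")
})

test_that("Boltzmann weights match the closed-form exponential ratio", {
  one <- make_ensemble(0, matrix(100, 1, 1))
  expect_equal(boltzmann_weights(one)$weight, 1.0)

  equal <- make_ensemble(c(1.3, 1.3), matrix(100, 2, 1))
  expect_equal(boltzmann_weights(equal)$weight, c(0.5, 0.5))

  # independently coded two-state ratio at 298.15 K, 1 kcal/mol apart
  R_kcal <- 1.987204259e-3
  ratio <- exp(-1.0 / (R_kcal * 298.15))
  w <- boltzmann_weights(make_ensemble(c(0, 1.0), matrix(100, 2, 1)))$weight
  expect_equal(w, c(1, ratio) / (1 + ratio), tolerance = 1e-12)

  # unit handling: same physical system expressed in kJ/mol
  w_kj <- boltzmann_weights(make_ensemble(c(0, 4.184), matrix(100, 2, 1)),
                            energy_unit = "kj_mol")$weight
  expect_equal(w_kj, w, tolerance = 1e-6)
})

test_that("weights are normalized, monotone in energy, and shift-invariant", {
  set.seed(33)
  for (rep in 1:20) {
    e <- runif(6, 0, 5)
    ens <- make_ensemble(e, matrix(rnorm(6), 6, 1))
    w <- boltzmann_weights(ens)$weight
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w >= 0 & w <= 1))
    expect_identical(order(w, decreasing = TRUE), order(e))
    # adding a constant to every energy changes nothing
    shifted <- ens
    shifted$rel_energy <- shifted$rel_energy + 7.7
    expect_equal(boltzmann_weights(shifted)$weight, w, tolerance = 1e-12)
  }
})

test_that("shielding averages equal the brute-force weighted mean and stay bounded", {
  one <- make_ensemble(0, matrix(c(120, 30), 1, 2))
  w1 <- boltzmann_weights(one)
  expect_equal(average_shieldings(one, w1)$shielding, c(120, 30))

  equal <- make_ensemble(c(0, 0), matrix(c(100, 102, 30, 34), 2, 2))
  weq <- boltzmann_weights(equal)
  expect_equal(average_shieldings(equal, weq)$shielding, c(101, 32))

  set.seed(44)
  sh <- matrix(rnorm(5 * 4, 100, 10), 5, 4)
  ens <- make_ensemble(runif(5, 0, 3), sh)
  w <- boltzmann_weights(ens)
  avg <- average_shieldings(ens, w)
  manual <- as.numeric(t(sh) %*% w$weight)
  expect_equal(avg$shielding, manual, tolerance = 1e-12)
  expect_true(all(avg$shielding >= apply(sh, 2, min) - 1e-12))
  expect_true(all(avg$shielding <= apply(sh, 2, max) + 1e-12))

  bad <- w
  bad$conformer_id[1] <- "nope"
  expect_error(average_shieldings(ens, bad), "conformer ids")
})

test_that("multistandard calibration routes each carbon type to its reference", {
  std <- calibration_standards(tms_sigma = 186.6, benzene_sigma = 57.3)
  idx <- tibble::tibble(label = paste0("C", 1:3),
                        hybridization = c("sp3", "sp2", "carbonyl"))

  # reference identities
  sig <- tibble::tibble(label = paste0("C", 1:3),
                        shielding = c(186.6, 57.3, 186.6))
  shifts <- calibrate_multistandard(sig, idx, std)
  v <- shift_values(shifts, "calc")
  expect_equal(unname(v[1]), 0)                    # sp3 at TMS sigma
  expect_equal(unname(v[2]), 128.37)               # sp2 at benzene sigma
  expect_equal(unname(v[3]), 0)                    # carbonyl under tms policy

  benz <- calibrate_multistandard(sig, idx, std, carbonyl_policy = "benzene")
  expect_equal(unname(shift_values(benz, "calc")[3]),
               57.3 - 186.6 + 128.37)

  # hand-computed mixed molecule
  sig2 <- tibble::tibble(label = paste0("C", 1:3),
                         shielding = c(150.0, 40.0, -10.0))
  v2 <- shift_values(calibrate_multistandard(sig2, idx, std), "calc")
  expect_equal(unname(v2), c(186.6 - 150.0,
                             57.3 - 40.0 + 128.37,
                             186.6 + 10.0))

  expect_error(
    calibrate_multistandard(tibble::tibble(label = "CX", shielding = 1), idx, std),
    "CX")
})

test_that("calibration is invariant to a common constant on sigmas and standards", {
  set.seed(55)
  idx <- tibble::tibble(label = paste0("C", 1:6),
                        hybridization = sample(c("sp3", "sp2", "carbonyl"), 6, TRUE))
  sig <- tibble::tibble(label = idx$label, shielding = runif(6, 0, 200))
  std <- calibration_standards(tms_sigma = 186.6, benzene_sigma = 57.3)
  base <- calibrate_multistandard(sig, idx, std)
  c0 <- 12.34
  sig_shift <- sig
  sig_shift$shielding <- sig_shift$shielding + c0
  std_shift <- calibration_standards(tms_sigma = 186.6 + c0,
                                     benzene_sigma = 57.3 + c0)
  moved <- calibrate_multistandard(sig_shift, idx, std_shift)
  expect_equal(shift_values(moved, "calc"), shift_values(base, "calc"),
               tolerance = 1e-12)
})

test_that("averaging shieldings then calibrating equals calibrating then averaging", {
  ens <- generate_conformer_ensemble(n_conformers = 6, n_atoms = 5, seed = 66)
  idx <- tibble::tibble(label = ensemble_atom_labels(ens),
                        hybridization = c("sp3", "sp2", "sp3", "carbonyl", "sp2"))
  std <- calibration_standards(tms_sigma = 186.6, benzene_sigma = 57.3)
  w <- boltzmann_weights(ens)

  route_a <- ensemble_to_shifts(ens, idx, std, set_id = "s", energy_window = NULL)

  # calibrate each conformer separately, then weight the shifts
  per_conf <- sapply(seq_len(nrow(ens)), function(i) {
    sig <- tibble::tibble(label = idx$label,
                          shielding = unlist(ens[i, idx$label], use.names = FALSE))
    shift_values(calibrate_multistandard(sig, idx, std), "calc")
  })
  route_b <- as.numeric(per_conf %*% w$weight)
  expect_equal(unname(shift_values(route_a, "s")), route_b, tolerance = 1e-12)
})
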