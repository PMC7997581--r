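test_that("alignment and pair counts follow the factorial and choose-2 laws", {
  expect_equal(count_alignments(1), 1)
  expect_equal(count_alignments(2), 2)
  expect_equal(count_alignments(3), 6)
  expect_equal(count_alignments(4), 24)
  expect_equal(count_alignments(6), factorial(6))
  expect_equal(count_pairs(2), 1)
  expect_equal(count_pairs(3), 3)
  expect_equal(count_pairs(4), 6)
  expect_error(count_alignments(0), "integer")
  expect_error(count_pairs(1), "integer")
})

test_that("enumeration is lexicographic, identity-first and complete", {
  expect_identical(enumerate_alignments(2), list(1:2, c(2L, 1L)))
  e3 <- enumerate_alignments(3)
  expect_identical(e3[[1]], 1:3)
  # the six schemes for a triad as a set
  expect_setequal(vapply(e3, paste, collapse = "", character(1)),
                  c("123", "132", "213", "231", "312", "321"))
  for (n in 2:6) {
    en <- enumerate_alignments(n)
    expect_length(en, count_alignments(n))
    expect_equal(anyDuplicated(vapply(en, paste, collapse = ",", character(1))), 0L)
  }
})

test_that("pair difference sets cover each unordered pair once with signed deltas", {
  two <- as_shift_tbl(matrix(c(100, 97), 1), c("A", "B"), hyb = "sp3")
  pd <- pair_difference_sets(two)
  expect_equal(nrow(pd), 1L)
  expect_equal(pd$delta, 3)

  same <- as_shift_tbl(matrix(c(5, 9, 5, 9), 2), c("A", "B"))
  expect_true(all(pair_difference_sets(same)$delta == 0))

  set.seed(81)
  m <- random_pair_matrices(4, 7)$calc
  tbl <- as_shift_tbl(m, paste0("s", 1:4))
  pd4 <- pair_difference_sets(tbl)
  expect_equal(nrow(pd4), 6 * 7)
  for (k in seq_len(nrow(pd4))) {
    row <- pd4[k, ]
    a <- as.integer(sub("s", "", row$set_i))
    b <- as.integer(sub("s", "", row$set_j))
    atom <- as.integer(sub("C", "", row$label))
    expect_lt(a, b)
    expect_equal(row$delta, m[atom, a] - m[atom, b])
  }
})

test_that("dd_delta takes the absolute difference of difference sets", {
  cp <- tibble::tibble(label = "C1", delta = 2.0)
  ep <- tibble::tibble(label = "C1", delta = -1.0)
  expect_equal(dd_delta(cp, ep)$dd_delta, 3.0)
  expect_equal(dd_delta(cp, cp)$dd_delta, 0)

  set.seed(82)
  labs <- paste0("C", 1:12)
  a <- tibble::tibble(label = labs, delta = rnorm(12))
  b <- tibble::tibble(label = sample(labs), delta = rnorm(12))
  got <- dd_delta(a, b)
  want <- abs(a$delta - b$delta[match(a$label, b$label)])
  expect_equal(got$dd_delta, want)

  expect_error(dd_delta(a, b[1:5, ]), "same atom labels")
})

test_that("mae_dddelta is zero at truth and cancels constant calibration offsets", {
  set.seed(83)
  m <- random_pair_matrices(4, 9)
  calc <- as_shift_tbl(m$calc, paste0("c", 1:4))
  self <- as_shift_tbl(m$calc, paste0("e", 1:4))
  expect_equal(mae_dddelta(calc, self, 1:4)$mae_dddelta, 0)

  # adding one constant to every calculated (or experimental) set changes nothing
  for (scheme in list(1:4, c(3L, 1L, 4L, 2L))) {
    base <- mae_dddelta(calc, as_shift_tbl(m$exp, paste0("e", 1:4)), scheme)
    off_calc <- as_shift_tbl(m$calc + 5.7, paste0("c", 1:4))
    off_exp <- as_shift_tbl(m$exp - 2.3, paste0("e", 1:4))
    expect_equal(mae_dddelta(off_calc, as_shift_tbl(m$exp, paste0("e", 1:4)),
                             scheme)$mae_dddelta,
                 base$mae_dddelta, tolerance = 1e-12)
    expect_equal(mae_dddelta(calc, off_exp, scheme)$mae_dddelta,
                 base$mae_dddelta, tolerance = 1e-12)
  }
})

test_that("mae_dddelta and avg_mae match the brute-force oracles", {
  set.seed(84)
  for (rep in 1:10) {
    n <- sample(2:4, 1)
    n_atoms <- sample(3:10, 1)
    m <- random_pair_matrices(n, n_atoms)
    calc <- as_shift_tbl(m$calc, paste0("c", 1:n))
    exp <- as_shift_tbl(m$exp, paste0("e", 1:n))
    for (scheme in enumerate_alignments(n)) {
      got <- mae_dddelta(calc, exp, scheme)
      expect_equal(got$mae_dddelta, oracle_mae_dddelta(m$calc, m$exp, scheme),
                   tolerance = 1e-12)
      expect_equal(got$n_terms, count_pairs(n) * n_atoms)
      expect_equal(avg_mae_per_alignment(calc, exp, scheme),
                   oracle_avg_mae(m$calc, m$exp, scheme), tolerance = 1e-12)
    }
  }
})

test_that("reversing a pair's orientation leaves the score untouched", {
  # swapping two columns in BOTH calc and the aligned exp flips the sign of
  # both difference sets, so every |DDdelta| term is unchanged
  set.seed(85)
  m <- random_pair_matrices(4, 6)
  calc <- as_shift_tbl(m$calc, paste0("c", 1:4))
  exp <- as_shift_tbl(m$exp, paste0("e", 1:4))
  ref <- mae_dddelta(calc, exp, 1:4)$mae_dddelta
  swap <- c(2L, 1L, 3L, 4L)
  calc_sw <- as_shift_tbl(m$calc[, swap], paste0("c", 1:4))
  exp_sw <- as_shift_tbl(m$exp[, swap], paste0("e", 1:4))
  expect_equal(mae_dddelta(calc_sw, exp_sw, 1:4)$mae_dddelta, ref,
               tolerance = 1e-12)
})

test_that("relabeling consistency: permuting exp columns composes with the scheme", {
  set.seed(86)
  m <- random_pair_matrices(4, 8)
  calc <- as_shift_tbl(m$calc, paste0("c", 1:4))
  for (rep in 1:10) {
    pi_ <- sample(4)
    sigma <- sample(4)
    exp_perm <- as_shift_tbl(m$exp[, pi_], paste0("e", 1:4))
    lhs <- mae_dddelta(calc, exp_perm, sigma)$mae_dddelta
    rhs <- mae_dddelta(as_shift_tbl(m$exp, paste0("e", 1:4)), calc,
                       order(pi_[sigma]))$mae_dddelta  # symmetry in sets
    lhs2 <- mae_dddelta(calc, as_shift_tbl(m$exp, paste0("e", 1:4)),
                        pi_[sigma])$mae_dddelta
    expect_equal(lhs, lhs2, tolerance = 1e-12)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("rank_alignments scores every scheme consistently and finds truth", {
  fx <- generate_bundle(fixture_spec(n_isomers = 4, n_atoms = 18,
                                     contrast_sd = 2, noise_sd = 0.3,
                                     seed = 87))
  rk <- rank_alignments(fx$bundle)
  expect_equal(nrow(rk$scores), 24L)
  expect_identical(rk$best, fx$true_permutation)
  expect_true(all(diff(rk$scores$mae_dddelta) >= 0))
  expect_equal(rk$gap, rk$scores$mae_dddelta[2] - rk$scores$mae_dddelta[1])

  # every listed score equals a direct mae_dddelta() call
  for (i in seq_len(nrow(rk$scores))) {
    expect_equal(rk$scores$mae_dddelta[i],
                 mae_dddelta(fx$bundle$calc, fx$bundle$exp,
                             rk$scores$scheme[[i]])$mae_dddelta,
                 tolerance = 1e-12)
    expect_equal(rk$scores$avg_mae[i],
                 avg_mae_per_alignment(fx$bundle$calc, fx$bundle$exp,
                                       rk$scores$scheme[[i]]),
                 tolerance = 1e-12)
  }
})

test_that("degenerate and guarded inputs fail with clear messages", {
  fx <- generate_bundle(fixture_spec(n_isomers = 4, n_atoms = 6, seed = 88))
  expect_error(rank_alignments(fx$bundle, max_sets = 3), "max_sets")
  expect_error(mae_dddelta(fx$bundle$calc, fx$bundle$exp, c(1, 1, 2, 3)),
               "permutation")
  expect_error(enumerate_alignments(1), "integer")
})

test_that("exact ties are reported, not silently broken", {
  # two identical experimental sets make the two schemes that swap them tie
  m <- matrix(c(10, 20, 30, 12, 24, 28), 3)
  calc <- as_shift_tbl(m, c("cA", "cB"))
  exp_m <- cbind(m[, 1], m[, 1])
  exp <- as_shift_tbl(exp_m, c("e1", "e2"))
  rk <- rank_alignments(study_bundle(calc, exp))
  expect_length(rk$ties, 2L)
  expect_true(all(rk$scores$tie))
  expect_identical(rk$best, 1:2)  # identity shown first among ties
})
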