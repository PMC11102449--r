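test_that("tumor cells divide only at the rim and at the modulated rate", {
  p <- small_params(N = 15)
  U <- matrix(p$U_boundary, 15, 15)
  # fully enclosed cell never divides even at forced probability 1
  pf <- p; pf$P_tumor <- 1; pf$r_Ht <- 0; pf$r_At <- 0
  lat <- new_lattice(15)
  for (r in 7:9) for (cc in 7:9) lat$kind[r, cc] <- 1L
  set.seed(1)
  lat2 <- tumor_division_step(lat, U, 0, pf)
  # only the 8 rim cells can divide; the center cannot create a 10th... all
  # rim cells have empty neighbors, so with p = 1 each adds one daughter
  expect_equal(sum(lat2$kind == 1L), 9 + 8)
  # single cell with forced p = 1: exactly one daughter
  lat3 <- new_lattice(15)
  lat3$kind[8, 8] <- 1L
  lat3 <- tumor_division_step(lat3, U, 0, pf)
  expect_equal(sum(lat3$kind == 1L), 2)
  expect_equal(sum(lat3$kind[7:9, 7:9] == 1L), 2)  # daughter adjacent
})

test_that("isolated rim cells divide at the empirical tumor_rate frequency", {
  p <- small_params(N = 150)
  U <- matrix(p$U_boundary, 150, 150)
  # 2500 isolated tumor cells, spaced 3 apart: independent Bernoulli trials
  lat <- new_lattice(150)
  rows <- seq(2, 149, by = 3)
  for (r in rows) for (cc in rows) lat$kind[r, cc] <- 1L
  n <- length(rows)^2
  set.seed(5)
  reps <- 4
  total <- 0
  for (i in seq_len(reps)) {
    lat2 <- tumor_division_step(lat, U, 0, p)
    total <- total + sum(lat2$kind == 1L) - n
  }
  p_true <- tumor_rate(p$U_boundary, 0, p)  # 0.003593 at U = 0.8, Ad = 0
  trials <- n * reps
  se <- sqrt(p_true * (1 - p_true) / trials)
  expect_lt(abs(total / trials - p_true), 4 * se)
})

test_that("DC activation requires tumor contact and occurs at rate D_act", {
  p <- small_params(N = 150)
  # no tumor neighbor: never activates even over many sweeps
  lat <- new_lattice(9)
  lat$kind[5, 5] <- 2L
  set.seed(2)
  for (i in 1:50) lat <- dc_activation_step(lat, p)
  expect_equal(lat$kind[5, 5], 2L)
  # forced rate 1 with tumor adjacent: activates in one step, goes Brownian
  pf <- p; pf$D_act <- 1
  lat <- new_lattice(9)
  lat$kind[5, 5] <- 2L; lat$dir[5, 5] <- 2L; lat$steps[5, 5] <- 4L
  lat$kind[5, 6] <- 1L
  lat <- dc_activation_step(lat, pf)
  expect_equal(lat$kind[5, 5], 3L)
  expect_equal(lat$steps[5, 5], 0L)
  # empirical frequency over 2500 x 16 adjacent pairs
  lat <- new_lattice(150)
  rows <- seq(2, 149, by = 3)
  for (r in rows) for (cc in rows) {
    lat$kind[r, cc] <- 2L
    lat$kind[r, cc + 1] <- 1L
  }
  n_dc <- sum(lat$kind == 2L)
  set.seed(3)
  reps <- 16
  act <- 0
  for (i in seq_len(reps)) {
    lat2 <- dc_activation_step(lat, p)
    act <- act + sum(lat2$kind == 3L)
  }
  se <- sqrt(p$D_act * (1 - p$D_act) / (n_dc * reps))
  expect_lt(abs(act / (n_dc * reps) - p$D_act), 4 * se)
})

test_that("T cells activate near active DCs and split into Treg/effector fates", {
  p <- small_params(N = 150)
  U <- matrix(p$U_boundary, 150, 150)
  # no adjacent active DC: nothing happens
  lat <- new_lattice(9)
  lat$kind[5, 5] <- 4L
  set.seed(4)
  lat <- t_activation_step(lat, matrix(0.8, 9, 9), 0, p)
  expect_equal(lat$kind[5, 5], 4L)
  # forced Treg polarization: every activation yields a Treg
  pf <- p; pf$C_act <- 1; pf$P_Treg <- 1; pf$r_Hr <- 0; pf$r_Ar <- 0
  lat <- new_lattice(9)
  lat$kind[5, 5] <- 4L; lat$kind[5, 6] <- 3L
  lat <- t_activation_step(lat, matrix(0.8, 9, 9), 0, pf)
  expect_equal(lat$kind[5, 5], 5L)
  # empirical Treg fraction at U = 0.8, Ad = 0 over ~40000 forced activations
  pf2 <- p; pf2$C_act <- 1
  lat <- new_lattice(150)
  rows <- seq(2, 149, by = 3)
  for (r in rows) for (cc in rows) {
    lat$kind[r, cc] <- 4L
    lat$kind[r, cc + 1] <- 3L
  }
  n_t <- sum(lat$kind == 4L)
  set.seed(6)
  reps <- 16
  tregs <- 0
  for (i in seq_len(reps)) {
    lat2 <- t_activation_step(lat, U, 0, pf2)
    tregs <- tregs + sum(lat2$kind == 5L)
  }
  p_treg <- treg_rate(0.8, 0, p)  # 0.30580
  se <- sqrt(p_treg * (1 - p_treg) / (n_t * reps))
  expect_lt(abs(tregs / (n_t * reps) - p_treg), 4 * se)
})

test_that("effectors kill one adjacent tumor cell at the cytotoxicity rate", {
  p <- small_params(N = 150)
  U <- matrix(p$U_boundary, 150, 150)
  # no tumor neighbor: no kill
  lat <- new_lattice(9)
  lat$kind[5, 5] <- 6L
  set.seed(7)
  out <- effector_kill_step(lat, matrix(0.8, 9, 9), 0, p)
  expect_equal(out$kills, 0L)
  # forced kill: tumor removed, site empty, effector survives
  pf <- p; pf$mu <- 1; pf$r_He <- 0; pf$r_Ae <- 0
  lat$kind[5, 6] <- 1L
  out <- effector_kill_step(lat, matrix(0.8, 9, 9), 0, pf)
  expect_equal(out$kills, 1L)
  expect_equal(out$lattice$kind[5, 6], 0L)
  expect_equal(out$lattice$kind[5, 5], 6L)
  # at most one kill per effector per step even with several tumor neighbors
  lat2 <- new_lattice(9)
  lat2$kind[5, 5] <- 6L
  lat2$kind[4, 5] <- 1L; lat2$kind[6, 5] <- 1L; lat2$kind[5, 4] <- 1L
  out2 <- effector_kill_step(lat2, matrix(0.8, 9, 9), 0, pf)
  expect_equal(out2$kills, 1L)
  expect_equal(sum(out2$lattice$kind == 1L), 2L)
  # empirical kill frequency ~ cytotoxicity_rate(0.8, 0) = 0.43272
  lat <- new_lattice(150)
  rows <- seq(2, 149, by = 3)
  for (r in rows) for (cc in rows) {
    lat$kind[r, cc] <- 6L
    lat$kind[r, cc + 1] <- 1L
  }
  n_e <- sum(lat$kind == 6L)
  set.seed(8)
  reps <- 8
  kills <- 0
  for (i in seq_len(reps)) kills <- kills + effector_kill_step(lat, U, 0, p)$kills
  mu_bar <- cytotoxicity_rate(0.8, 0, p)
  se <- sqrt(mu_bar * (1 - mu_bar) / (n_e * reps))
  expect_lt(abs(kills / (n_e * reps) - mu_bar), 4 * se)
})

test_that("Tregs deactivate adjacent active DCs at rate D_inact", {
  p <- small_params(N = 150)
  # no Treg neighbor: stays active
  lat <- new_lattice(9)
  lat$kind[5, 5] <- 3L
  set.seed(9)
  for (i in 1:50) lat <- dc_inactivation_step(lat, p)
  expect_equal(lat$kind[5, 5], 3L)
  # forced: deactivates in one step and resumes a fresh Levy walk
  pf <- p; pf$D_inact <- 1
  lat$kind[5, 6] <- 5L
  lat <- dc_inactivation_step(lat, pf)
  expect_equal(lat$kind[5, 5], 2L)
  expect_equal(lat$steps[5, 5], 0L)
  # empirical frequency
  lat <- new_lattice(150)
  rows <- seq(2, 149, by = 3)
  for (r in rows) for (cc in rows) {
    lat$kind[r, cc] <- 3L
    lat$kind[r, cc + 1] <- 5L
  }
  n_dc <- sum(lat$kind == 3L)
  set.seed(10)
  reps <- 16
  deact <- 0
  for (i in seq_len(reps)) {
    lat2 <- dc_inactivation_step(lat, p)
    deact <- deact + sum(lat2$kind == 2L)
  }
  se <- sqrt(p$D_inact * (1 - p$D_inact) / (n_dc * reps))
  expect_lt(abs(deact / (n_dc * reps) - p$D_inact), 4 * se)
})
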