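test_that("initialization places the published initial condition", {
  p <- default_parameters()
  st <- initialize_state(p, seed = 1)
  counts <- audit_lattice(st)
  expect_equal(unname(counts["tumor"]), 1L)
  expect_equal(unname(counts["dc_inactive"]), 100L)
  expect_equal(unname(counts["t_inactive"]), 750L)
  expect_equal(unname(counts["dc_active"]), 0L)
  expect_equal(st$kind[106, 106], 1L)  # center of the 210-grid
  expect_true(all(st$U == p$U_boundary))
  expect_equal(st$Ad, 0)
  expect_equal(st$px, 0)
  # determinism of placement
  st2 <- initialize_state(p, seed = 1)
  expect_identical(st$kind, st2$kind)
  # anoxic start keeps the boundary ring only
  stz <- initialize_state(p, seed = 1, oxygen_init = "zero")
  expect_equal(stz$U[1, 1], p$U_boundary)
  expect_equal(stz$U[50, 50], 0)
  # capacity error on a toy grid
  p2 <- small_params(N = 9)
  p2$N_D <- 100L
  expect_error(initialize_state(p2, seed = 1), "too small")
})

test_that("runs are bit-reproducible from (seed, params, protocol)", {
  p <- small_params(N = 60)
  r1 <- run_simulation(p, NULL, seed = 42, horizon_days = 1)
  r2 <- run_simulation(p, NULL, seed = 42, horizon_days = 1)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$state$kind, r2$state$kind)
  expect_identical(r1$state$U, r2$state$U)
  # an explicit Untreated protocol object is bit-identical to no protocol
  r3 <- run_simulation(p, group_protocol("Untreated"), seed = 42,
                       horizon_days = 1)
  expect_identical(r1$trajectory, r3$trajectory)
})

test_that("frozen dynamics: no immune cells and no division leaves one tumor cell", {
  p <- small_params(N = 30)
  p$N_T <- 0L; p$N_D <- 0L
  p$P_tumor <- 0; p$r_Ht <- 0; p$r_At <- 0
  r <- run_simulation(p, NULL, seed = 3, horizon_days = 1, record_every = 60)
  expect_true(all(r$trajectory$tumor_sites == 1))
  expect_true(all(r$trajectory$n_effector == 0))
})

test_that("tumor-only growth matches the draw-for-draw R mirror exactly", {
  p <- small_params(N = 33)
  p$N_T <- 0L; p$N_D <- 0L
  p$P_tumor <- 0.25; p$r_Ht <- 0; p$r_At <- 0
  st <- make_state(p, tumor_sites = rbind(c(17, 17), c(5, 25)))
  set.seed(99)
  res <- engine_steps(st, p, n_steps = 60, record_every = 60)
  set.seed(99)
  mask <- tumor_only_mirror(st, p, n_steps = 60)
  expect_gt(sum(mask), 10)  # something actually grew
  expect_identical(res$state$kind == 1L, mask)
})

test_that("one engine step reproduces the R module updates on a crafted state", {
  p <- small_params(N = 21)
  set.seed(13)
  U0 <- matrix(runif(21 * 21, 0.2, 0.9), 21, 21)
  st <- make_state(p, tumor_sites = rbind(c(10, 10), c(10, 11), c(11, 10)),
                   U = U0)
  st$Ad <- 50
  st$px <- 12
  st$s_raw <- 900
  st$s_buf <- rep(1, p$M)
  res <- engine_steps(st, p, n_steps = 1)
  # humoral scalars follow the module operations (no dose this step)
  h <- list(Ad = 50, px = 12, s_raw = 900, s_buf = rep(1, p$M), s_pos = 1L,
            S_t = 0)
  h <- step_px(h, FALSE, p)
  h <- step_s(h, FALSE, p)
  expect_equal(res$state$px, h$px, tolerance = 1e-12)
  expect_equal(res$state$s_raw, h$s_raw, tolerance = 1e-12)
  expect_equal(res$state$S_t, h$S_t, tolerance = 1e-12)
  # the oxygen field follows diffuse_step on the block-averaged input
  U1 <- diffuse_step(U0, st$kind == 1L, h$px, p)
  expect_equal(res$state$U, U1, tolerance = 1e-10)
  # adenosine follows step_adenosine at the engine's 1/720-day step, with
  # U_eff the mean oxygen over tumor sites and their Moore neighbors
  tumor <- which(st$kind == 1L, arr.ind = TRUE)
  nbhd <- unique(do.call(rbind, c(list(tumor), lapply(seq_len(nrow(tumor)),
    function(i) moore_neighbors(st, tumor[i, ])))))
  U_eff <- mean(U1[nbhd])
  h <- step_adenosine(h, U_eff, p, dt = adenosine_dt(p))
  expect_equal(res$state$Ad, h$Ad, tolerance = 1e-9)
})

test_that("conservation: immune lineages are conserved and tumor changes by +/-1 events", {
  p <- small_params(N = 90)
  r <- run_simulation(p, NULL, seed = 7, horizon_days = 3, record_every = 180)
  tr <- r$trajectory
  t_lineage <- tr$n_t_inactive + tr$n_treg + tr$n_effector
  expect_true(all(t_lineage == p$N_T))
  expect_true(all(tr$n_dc_inactive + tr$n_dc_active == p$N_D))
  # tumor count changes only through divisions (+1) and kills (-1)
  expect_true(all(diff(tr$tumor_sites) ==
                    diff(tr$divisions) - diff(tr$kills)))
  expect_equal(tr$tumor_sites[1], 1 + tr$divisions[1] - tr$kills[1])
  # final state passes the occupancy audit and matches the trajectory counts
  counts <- audit_lattice(r$state)
  n <- nrow(tr)
  expect_equal(unname(counts["tumor"]), as.integer(tr$tumor_sites[n]))
  expect_equal(unname(counts["effector"]), as.integer(tr$n_effector[n]))
  # DC vaccination adds to the DC pool, which stays conserved afterwards
  pro <- group_protocol("DC", p)
  pro$dc_events$count <- p$V_DC
  r2 <- run_simulation(p, pro, seed = 7, horizon_days = 8, record_every = 720)
  tr2 <- r2$trajectory
  expect_true(all(tr2$n_dc_inactive + tr2$n_dc_active ==
                    p$N_D + tr2$dc_injected))
  expect_equal(max(tr2$dc_injected), p$V_DC)
})

test_that("tumor volume conversion is 0.22 mm^3 per occupied site", {
  p <- default_parameters()
  expect_equal(tumor_volume_mm3(0, p), 0)
  expect_equal(tumor_volume_mm3(1, p), 0.22)
  expect_equal(tumor_volume_mm3(500, p), 110)
  expect_equal(tumor_volume_mm3(c(2, 10), p), c(0.44, 2.2))
  expect_error(tumor_volume_mm3(-1, p), "non-negative")
})

test_that("replicate aggregation reports daily means with 95% CIs", {
  p <- small_params(N = 30)
  rr <- run_replicates(p, NULL, seeds = 1:3, horizon_days = 1,
                       record_every = 360)
  expect_equal(rr$summary$n, 3)
  expect_length(rr$days, 1)  # one daily point on a 1-day horizon
  expect_true(all(rr$ci_hi$volume_mm3 >= rr$ci_lo$volume_mm3))
  # per-replicate scalars agree with direct recomputation
  tr1 <- run_simulation(p, NULL, seed = 1, horizon_days = 1,
                        record_every = 360)$trajectory
  expect_equal(rr$per_replicate$avg_volume_mm3[1], mean(tr1$volume_mm3))
  expect_equal(rr$per_replicate$final_volume_mm3[1],
               tr1$volume_mm3[nrow(tr1)])
  # a single replicate reports zero CI width
  r1 <- run_replicates(p, NULL, seeds = 5, horizon_days = 1,
                       record_every = 360)
  expect_equal(r1$summary$final_volume_ci, 0)
  expect_equal(r1$mean$volume_mm3, as.vector(r1$series$volume_mm3))
})
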