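test_that("the eight experimental groups carry the published schedules", {
  u <- group_protocol("Untreated")
  expect_length(u$px_days, 0)
  expect_length(u$s_days, 0)
  expect_equal(nrow(u$dc_events), 0)
  px <- group_protocol("Px-478")
  expect_equal(px$px_days, c(6L, 8L, 10L, 13L, 15L))
  expect_length(px$s_days, 0)
  expect_equal(nrow(px$dc_events), 0)
  si <- group_protocol("siRNA")
  expect_equal(si$s_days, c(6L, 9L, 12L, 15L))
  dc <- group_protocol("DC")
  expect_equal(dc$dc_events$day, 7L)
  expect_equal(dc$dc_events$count, 70L)
  all3 <- group_protocol("siRNA+Px-478+DC")
  expect_equal(all3$px_days, c(6L, 8L, 10L, 13L, 15L))
  expect_equal(all3$s_days, c(6L, 9L, 12L, 15L))
  expect_equal(all3$dc_events, data.frame(day = 7L, count = 70L))
  expect_equal(all3$px_dose_scale, 1)
  expect_equal(all3$s_dose_scale, 1)
  err <- tryCatch(group_protocol("nonsense"), error = function(e) conditionMessage(e))
  expect_match(err, "Untreated")  # the error lists the valid group names
  expect_match(err, "siRNA\\+Px-478\\+DC")
})

test_that("protocol variants modify only the requested component", {
  base <- group_protocol("siRNA+Px-478+DC")
  v <- variant_protocol(base, dc_day = 6)
  expect_equal(v$dc_events, data.frame(day = 6L, count = 70L))
  expect_equal(v$px_days, base$px_days)
  expect_equal(v$s_days, base$s_days)
  v2 <- variant_protocol(base, s_every = 1)
  expect_equal(v2$s_days, 6:17)
  expect_equal(v2$px_days, base$px_days)
  v3 <- variant_protocol(base, px_every = 2, s_every = 2,
                         px_scale = 1.5, s_scale = 1.5)
  expect_equal(v3$px_days, as.integer(seq(6, 16, 2)))
  expect_equal(v3$s_days, as.integer(seq(6, 16, 2)))
  expect_equal(v3$px_dose_scale, 1.5)
  expect_equal(v3$s_dose_scale, 1.5)
  v4 <- variant_protocol(base, dc_scale = 1.3)
  expect_equal(v4$dc_events$count, 91L)  # round(70 * 1.3)
  v5 <- variant_protocol(base, dc_times = 4, dc_interval = 2)
  expect_equal(v5$dc_events$day, c(7L, 9L, 11L, 13L))
  expect_equal(v5$dc_events$count, rep(70L, 4))
  v6 <- variant_protocol(base, alternate = "s")
  expect_equal(v6$s_days, as.integer(seq(6, 16, 2)))
  expect_equal(v6$px_days, as.integer(seq(7, 17, 2)))
  expect_error(variant_protocol(base, px_scale = -0.5), "positive")
})

test_that("day schedules expand losslessly into step events", {
  p <- default_parameters()
  pro <- group_protocol("siRNA+Px-478+DC")
  st <- protocol_steps(pro, p)
  expect_equal(st$px_steps, pro$px_days * 720L)
  expect_equal(st$s_steps, pro$s_days * 720L)
  expect_equal(st$dc_steps, 7L * 720L)
  expect_equal(st$px_amounts, rep(40, 5))
  expect_equal(st$s_amounts, rep(4200, 4))
  expect_equal(st$dc_counts, 70L)
  # inverse mapping recovers the day schedule exactly
  expect_equal(st$px_steps / 720L, as.numeric(pro$px_days))
  # scaled doses
  v <- variant_protocol(pro, px_scale = 1.5, s_scale = 0.7)
  stv <- protocol_steps(v, p)
  expect_equal(stv$px_amounts, rep(60, 5))
  expect_equal(stv$s_amounts, rep(2940, 4))
  # no protocol: empty schedule
  st0 <- protocol_steps(NULL, p)
  expect_length(st0$px_steps, 0)
  expect_length(st0$dc_steps, 0)
})

test_that("protocols round-trip through the YAML file format", {
  pro <- variant_protocol(group_protocol("siRNA+Px-478+DC"),
                          dc_times = 2, dc_interval = 2, px_scale = 1.5)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_protocol(pro, path)
  back <- read_protocol(path)
  expect_equal(back$px_days, pro$px_days)
  expect_equal(back$s_days, pro$s_days)
  expect_equal(back$dc_events, pro$dc_events)
  expect_equal(back$px_dose_scale, pro$px_dose_scale)
  expect_equal(back$s_dose_scale, pro$s_dose_scale)
  writeLines("bad_key: 1", path)
  expect_error(read_protocol(path), "unknown protocol key")
  writeLines(c("dc_days: [7, 9]", "dc_counts: [70]"), path)
  expect_error(read_protocol(path), "equal length")
})

test_that("DC vaccine placement fills distinct empty sites and saturates", {
  lat <- new_lattice(30)
  set.seed(1)
  lat2 <- inject_dc_vaccine(lat, 70)
  expect_equal(sum(lat2$kind == 3L), 70L)
  expect_equal(sum(lat2$kind != 0L), 70L)  # all on distinct sites
  expect_identical(inject_dc_vaccine(lat, 0), lat)
  # more cells than empty sites: fill all, warn
  small <- new_lattice(3)
  small$kind[1, 1] <- 1L
  expect_warning(out <- inject_dc_vaccine(small, 20), "empty sites")
  expect_equal(sum(out$kind == 3L), 8L)
})
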