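test_that("moment matching solves the closed-form equations", {
  p <- moment_match("lognormal", 5.37, 10.66)
  expect_equal(p$meanlog, 0.8820813, tolerance = 1e-6)
  expect_equal(p$sdlog, 1.263920, tolerance = 1e-6)

  p2 <- moment_match("lognormal", 1, 1)
  expect_equal(p2$sdlog^2, log(2), tolerance = 1e-12)
  expect_equal(p2$meanlog, -log(2) / 2, tolerance = 1e-12)

  g <- moment_match("gamma", 4, 2)
  expect_equal(g$shape, 4)
  expect_equal(g$scale, 1)

  expect_equal(moment_match("lognormal", 6, 0),
               list(family = "deterministic", value = 6))
  expect_error(moment_match("lognormal", 0, 1), "positive")
})

test_that("moment-matched draws reproduce the target moments", {
  n <- 2e5
  cases <- list(c(5.37, 10.66), c(4.00, 3.56), c(9.025, 7.13))
  for (fam in c("lognormal", "gamma")) {
    for (cs in cases) {
      set.seed(derive_seed(1, paste(fam, cs[1])))
      x <- draw_service_times(service_time_spec(fam, cs[1], cs[2]), n)
      se_mean <- cs[2] / sqrt(n)
      expect_lt(abs(mean(x) - cs[1]), 3 * se_mean)
      kurt <- mean((x - mean(x))^4) / stats::var(x)^2
      se_sd <- cs[2] * sqrt((kurt - 1) / (4 * n))
      expect_lt(abs(stats::sd(x) - cs[2]), 4 * se_sd)
    }
  }
  expect_equal(draw_service_times(service_time_spec("deterministic", 7, 0), 3),
               rep(7, 3))
})

test_that("linear-SDE simulation is exact in the noise-free limit", {
  dyn <- build_system_matrices(make_tandem(), tandem_k(),
                               Q = diag(0, 2))
  om <- observation_model(diag(1, 2), diag(1e-20, 2))
  times <- 0:60
  sim <- simulate_linear_sde(dyn, c(5, 10), 2, times, om, seed = 4)
  det <- integrate_state(dyn, c(5, 10), 2, times)
  expect_lt(max(abs(sim$trajectory$states - det$states)), 1e-10)
  expect_lt(max(abs(sim$series$values - det$states)), 1e-8)
})

test_that("linear-SDE simulation is reproducible from the seed", {
  dyn <- build_system_matrices(make_tandem(), tandem_k(), Q = diag(0.1, 2))
  om <- observation_model(diag(1, 2), diag(0.2, 2))
  s1 <- simulate_linear_sde(dyn, c(5, 10), 2, 0:50, om, seed = 99)
  s2 <- simulate_linear_sde(dyn, c(5, 10), 2, 0:50, om, seed = 99)
  expect_identical(s1, s2)
  s3 <- simulate_linear_sde(dyn, c(5, 10), 2, 0:50, om, seed = 100)
  expect_false(identical(s1$series$values, s3$series$values))
})

test_that("scalar Brownian increments have the nominal variance", {
  dyn <- linear_dynamics(matrix(0, 1, 1), Q = matrix(1, 1, 1))
  om <- observation_model(matrix(1, 1, 1), matrix(1e-12, 1, 1))
  sim <- simulate_linear_sde(dyn, 0, NULL, 0:10000, om, seed = 17)
  incr <- diff(sim$trajectory$states[, 1])
  v <- stats::var(incr)
  expect_gt(v, 0.94)   # chi-square band at n = 1e4
  expect_lt(v, 1.06)
})

test_that("porter DES handles degenerate and deterministic cases", {
  empty <- simulate_porter_day(porter_config(daily_orders = 0, seed = 1))
  expect_equal(nrow(empty), 0)

  det <- porter_config(
    arrivals = 100,
    searching = service_time_spec("deterministic", 5.37, 0),
    walking = service_time_spec("deterministic", 4.00, 0),
    migrating = service_time_spec("deterministic", 9.025, 0), seed = 2)
  log1 <- simulate_porter_day(det)
  expect_equal(nrow(log1), 1)
  expect_equal(log1$t_complete - log1$t_placed, 18.395)
  expect_equal(log1$t_search_done - log1$t_assign, 5.37)
  expect_equal(log1$t_pickup - log1$t_search_done, 4.00)
})

test_that("porter DES conserves orders and keeps stamps ordered", {
  log <- simulate_porter_day(porter_config(n_days = 2, seed = 12))
  expect_true(all(diff(log$t_placed) >= 0))
  expect_true(all(log$t_assign >= log$t_placed))
  expect_true(all(log$t_search_done >= log$t_assign))
  expect_true(all(log$t_pickup >= log$t_search_done))
  expect_true(all(log$t_complete >= log$t_pickup))
  expect_true(all(is.finite(log$t_complete)))   # no lost orders
  # a porter serves one order at a time
  by_porter <- split(log[, c("t_assign", "t_complete")], log$porter_id)
  overlaps <- vapply(by_porter, function(d) {
    d <- d[order(d$t_assign), ]
    any(d$t_assign[-1] < d$t_complete[-nrow(d)] - 1e-9)
  }, logical(1))
  expect_false(any(overlaps))
})

test_that("porter DES is bit-identical under a repeated seed", {
  l1 <- simulate_porter_day(porter_config(seed = 77))
  l2 <- simulate_porter_day(porter_config(seed = 77))
  expect_identical(l1, l2)
})

test_that("priority classes jump the queue under congestion", {
  # 2 porters and a burst of simultaneous arrivals forces queueing
  cfg <- porter_config(n_porters = 2, arrivals = rep(0, 200),
                       searching = service_time_spec("deterministic", 2, 0),
                       walking = service_time_spec("deterministic", 2, 0),
                       migrating = service_time_spec("deterministic", 2, 0),
                       seed = 5)
  log <- simulate_porter_day(cfg)
  w <- tapply(log$t_assign - log$t_placed, log$priority, mean)
  expect_lt(w[["very_urgent"]], w[["normal"]])
})

test_that("stage counts partition the in-flight orders", {
  log <- simulate_porter_day(porter_config(seed = 6))
  counts <- orders_to_counts(log, 10)
  expect_equal(counts$channels, c("queued", "searching", "walking", "migrating"))
  # independent recount straight from the raw stamps
  inflight <- vapply(counts$times, function(t)
    sum(log$t_placed <= t & log$t_complete > t), numeric(1))
  expect_equal(unname(rowSums(counts$values)), inflight)

  empty <- orders_to_counts(simulate_porter_day(porter_config(daily_orders = 0)),
                            60)
  expect_true(all(empty$values == 0))

  single <- data.frame(order_id = 1L, priority = "normal", t_placed = 5,
                       t_assign = 5, t_search_done = 5, t_pickup = 5,
                       t_complete = 30, porter_id = 1L)
  cs <- orders_to_counts(single, 10, t_max = 40)
  expect_equal(unname(cs$values[2, "migrating"]), 1)  # snapshot at t = 10
  expect_equal(sum(cs$values[2, ]), 1)
})

test_that("service-level statistics summarize the log correctly", {
  det <- porter_config(
    arrivals = c(100, 500, 900),
    searching = service_time_spec("deterministic", 5.37, 0),
    walking = service_time_spec("deterministic", 4.00, 0),
    migrating = service_time_spec("deterministic", 9.025, 0), seed = 2)
  log <- simulate_porter_day(det)
  s20 <- sla_statistics(log, 20)
  expect_equal(s20$exceed_fraction, 0)      # 18.395 < 20
  s0 <- sla_statistics(log, 0)
  expect_equal(s0$exceed_fraction, 1)
  expect_equal(s20$stages$mean[s20$stages$stage == "total"], 18.395)
  expect_equal(sla_statistics(log[0, ], 20)$n_orders, 0)
})

test_that("peak-window restriction picks out the configured hours", {
  log <- data.frame(order_id = 1:3, priority = "normal",
                    t_placed = c(650, 300, 900), t_assign = c(650, 300, 900),
                    t_search_done = c(655, 305, 905),
                    t_pickup = c(660, 310, 910),
                    t_complete = c(680, 310.5, 960), porter_id = 1L)
  s <- sla_statistics(log, 20)
  expect_equal(s$n_peak_orders, 2)             # 650 and 900 are in-peak
  expect_equal(s$peak_exceed_fraction, 1)      # both exceed 20 min
  expect_equal(s$offpeak_exceed_fraction, 0)
})

test_that("long-run DES satisfies Little's law", {
  cfg <- porter_config(daily_orders = 2000,
                       profile = data.frame(start = 0, end = 1440, rel = 1),
                       n_days = 6, seed = 9)
  log <- simulate_porter_day(cfg)
  lam <- nrow(log) / (6 * 1440)
  W <- mean(log$t_complete - log$t_placed)
  counts <- orders_to_counts(log, 1, t_max = 6 * 1440)
  keep <- counts$times > 240            # discard warm-up
  L <- mean(rowSums(counts$values[keep, ]))
  expect_lt(abs(L / (lam * W) - 1), 0.05)
})

test_that("the frozen peak preset reproduces the target service level", {
  log <- simulate_porter_day(porter_peak_preset(n_days = 10, seed = 42))
  s <- sla_statistics(log, 20)
  expect_gt(s$n_peak_orders, 4000)
  expect_gt(s$peak_exceed_fraction, 0.16)
  expect_lt(s$peak_exceed_fraction, 0.24)
})
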