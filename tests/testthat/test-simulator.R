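test_that("detected pair rate equals geometric acceptance when stopping is ideal", {
  # eta = 1 with an effectively opaque crystal: the only losses are geometric
  ideal <- detector_response(eta = 1, crystal_mu = 1e4, positioning_fwhm = 0)
  src <- point_source()
  dur <- 1.5
  acq <- simulate_acquisition(src, geom60, ideal, duration = dur, seed = 3,
                              include_randoms = FALSE, max_decays = Inf)
  n_pos <- src$activity_at_start * 1000 * dur *
    src$isotope$positron_branching_ratio
  p_true <- pair_acceptance_analytic(c(0, 0, 0), geom60)
  se <- sqrt(p_true * (1 - p_true) / n_pos)
  # Poisson spread of the decay count adds to the binomial spread
  expect_lt(abs(nrow(acq$events) / n_pos - p_true), 4 * (se + p_true / sqrt(n_pos)))
})

test_that("true events are collinear with the emission point", {
  resp0 <- resp_cal
  resp0$positioning_fwhm <- 0
  src <- point_source(position = c(10, 5, 0))
  acq <- simulate_acquisition(src, geom60, resp0, duration = 0.5, seed = 4,
                              include_randoms = FALSE)
  ev <- acq$events
  h <- geom60$separation / 2
  # distance from the source center to each LOR segment
  a <- cbind(ev$x1, ev$y1, h)
  b <- cbind(ev$x2, ev$y2, -h)
  ab <- b - a
  ap <- sweep(-a, 2, -c(10, 5, 0))
  tt <- rowSums(ap * ab) / rowSums(ab^2)
  closest <- a + ab * tt
  d <- sqrt(rowSums(sweep(closest, 2, c(10, 5, 0))^2))
  expect_true(all(d <= 0.151))
  expect_true(all(ev$label == "true"))
})

test_that("degenerate acquisitions give empty sets, not errors", {
  dead <- point_source(activity_kbq = 0)
  expect_identical(n_events(simulate_acquisition(dead, geom60, resp_cal,
                                                 duration = 1, seed = 1)), 0L)
  blind <- detector_response(eta = 0)
  expect_identical(n_events(simulate_acquisition(point_source(), geom60, blind,
                                                 duration = 1, seed = 1)), 0L)
})

test_that("Compton kinematics and Klein-Nishina sampling are correct", {
  expect_equal(compton_energy(511, 1), 511)
  expect_equal(compton_energy(511, cos(pi)), 511 / 3, tolerance = 1e-12)
  expect_equal(compton_energy(511, cos(pi)), 170.3, tolerance = 1e-3)
  # zero path length through the medium: always unscattered
  med <- attenuation_medium(radius = 5, length = 10, center = c(200, 0, 0))
  out <- compton_single_scatter(c(0, 0, 0), c(0, 0, 1), med, seed = 1)
  expect_identical(out$status, "unscattered")
  expect_equal(out$energy_kev, 511)
  # sampled cos(theta) mean matches numeric integration of the KN density
  ct <- seq(-1, 1, length.out = 4001)
  r <- 1 / (1 + (1 - ct))
  pdf <- r^2 * (r + 1 / r - (1 - ct^2))
  m_true <- sum(ct * pdf) / sum(pdf)
  s <- sample_klein_nishina(2e5, 511, seed = 5)
  expect_lt(abs(mean(s) - m_true), 4 * sd(s) / sqrt(length(s)))
  expect_true(all(s >= -1 & s <= 1))
})

test_that("random-coincidence rate is 2 tau S_A S_B and scales quadratically", {
  expect_identical(nrow(generate_randoms(0, 1e5, 4, 10, seed = 1,
                                         geom = geom60)), 0L)
  # S_A = S_B = 1e5 cps, tau = 4 ns -> 80 cps
  dur <- 100
  n <- nrow(generate_randoms(1e5, 1e5, 4, dur, seed = 2, geom = geom60))
  expect_lt(abs(n - 80 * dur), 4 * sqrt(80 * dur))
  # doubling both singles rates quadruples the rate: log-log slope 2 +/- 0.1
  rates <- 2^(0:4) * 2e4
  counts <- vapply(seq_along(rates), function(i)
    nrow(generate_randoms(rates[i], rates[i], 500, 50, seed = 10 + i,
                          geom = geom60)), integer(1))
  fit <- lm(log(counts) ~ log(rates))
  expect_equal(unname(coef(fit)[2]), 2, tolerance = 0.1)
})

test_that("paralyzable dead time reproduces m = n exp(-n tau)", {
  resp <- detector_response(dead_time_tau_us = 0)
  ev <- random_events(2000)
  expect_identical(apply_dead_time(ev, resp), ev)
  # Poisson stream with n * tau = 1: observed/true = exp(-1)
  n_rate <- 1e4
  tau <- 1e-4
  tt <- planarpet:::with_seed(8, sort(runif(rpois(1, n_rate * 20), 0, 20)))
  ev <- data.frame(x1 = 0, y1 = 0, x2 = 0, y2 = 0, e1 = 511, e2 = 511,
                   t = tt, label = "true")
  respt <- detector_response(dead_time_tau_us = tau * 1e6)
  kept <- nrow(apply_dead_time(ev, respt))
  ratio <- kept / nrow(ev)
  expect_equal(ratio, exp(-1), tolerance = 0.02)
  # unsorted input is rejected
  bad <- ev[c(2, 1, 3:10), ]
  expect_error(apply_dead_time(bad, respt), class = "planarpet_domain_error")
})

test_that("observed rate versus activity has a single interior maximum", {
  tau <- 2e-5
  rates <- seq(2e4, 2.5e5, length.out = 12)
  resp <- detector_response(dead_time_tau_us = tau * 1e6)
  obs <- vapply(seq_along(rates), function(i) {
    tt <- planarpet:::with_seed(40 + i, sort(runif(rpois(1, rates[i] * 2), 0, 2)))
    ev <- data.frame(x1 = 0, y1 = 0, x2 = 0, y2 = 0, e1 = 511, e2 = 511,
                     t = tt, label = "true")
    nrow(apply_dead_time(ev, resp)) / 2
  }, numeric(1))
  k <- which.max(obs)
  expect_gt(k, 1)
  expect_lt(k, length(obs))
  expect_true(all(diff(obs[1:k]) > 0))
  expect_true(all(diff(obs[k:length(obs)]) < 0))
})

test_that("decay series honors the frame grid, stop rules and bookkeeping", {
  ph <- nu4_scatter_phantom(activity_kbq = 500)
  frames <- simulate_decay_series(ph, geom60, resp_cal,
                                  frame_interval = 15, frame_duration = 0.02,
                                  max_decays_per_frame = 2000, seed = 6)
  expect_length(frames, 74)  # ceil(1097.7 / 15) frames starting at t = 0
  summ <- attr(frames, "frames")
  expect_lt(summ$activity_mid_kbq[74] / summ$activity_mid_kbq[1], 1e-3)
  # label bookkeeping: prompts partition exactly into the three classes
  f1 <- frames[[5]]
  tab <- table(factor(f1$events$label, c("true", "scatter", "random")))
  expect_identical(sum(tab), nrow(f1$events))
  # event cap stops the series early
  capped <- simulate_decay_series(ph, geom60, resp_cal,
                                  frame_interval = 15, frame_duration = 0.2,
                                  max_decays_per_frame = 5000,
                                  max_total_events = 1, seed = 6)
  expect_length(capped, 1)
})

test_that("true rate is proportional to activity at low dead-time losses", {
  acts <- c(50, 100, 200, 400, 800)
  rates <- vapply(seq_along(acts), function(i) {
    src <- point_source(activity_kbq = acts[i])
    dur <- 1.2e6 / (acts[i] * 1000)
    acq <- simulate_acquisition(src, geom60, resp_cal, duration = dur,
                                seed = 50 + i, include_randoms = FALSE,
                                max_decays = Inf)
    event_rate(acq)
  }, numeric(1))
  fit <- lm(rates ~ acts)
  expect_gt(summary(fit)$r.squared, 0.999)
})

test_that("without a scattering medium the scatter fraction is zero", {
  acq <- center_acq()
  expect_identical(truth_scatter_fraction(acq), 0)
})
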