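# Shared fixtures: geometries, a calibrated response, and small synthetic
# list-mode sets built in code.

geom60 <- build_detector(separation = 60)
geom80 <- build_detector(separation = 80)
resp_cal <- calibrate_pair_efficiency(geom60)

# A listmode_set built directly from an event table (detector frame, head A
# at z = +sep/2). Events are sorted by time.
make_set <- function(events, geom = geom60, duration = 1,
                     windows = acquisition_windows(), meta = list()) {
  events <- events[order(events$t), , drop = FALSE]
  rownames(events) <- NULL
  listmode_set(events, windows, geom, duration, meta = meta)
}

# n events with identical perpendicular LORs at (x, y) plus optional extras
perp_events <- function(n, x = 0, y = 0, t0 = 0) {
  data.frame(x1 = rep(x, n), y1 = rep(y, n), x2 = rep(x, n), y2 = rep(y, n),
             e1 = 511, e2 = 511, t = t0 + seq_len(n) * 1e-3, label = "true")
}

random_events <- function(n, geom = geom60, seed = 1) {
  planarpet:::with_seed(seed, {
    hx <- geom$head_size_x / 2 - 1e-6
    hy <- geom$head_size_y / 2 - 1e-6
    data.frame(x1 = runif(n, -hx, hx), y1 = runif(n, -hy, hy),
               x2 = runif(n, -hx, hx), y2 = runif(n, -hy, hy),
               e1 = runif(n, 100, 700), e2 = runif(n, 100, 700),
               t = sort(runif(n)), label = sample(c("true", "scatter"), n,
                                                  replace = TRUE))
  })
}

# small simulated point-source acquisition, cached across tests
center_acq <- local({
  val <- NULL
  function() {
    if (is.null(val))
      val <<- simulate_acquisition(point_source(), geom60, resp_cal,
                                   duration = 1, seed = 100,
                                   include_randoms = FALSE)
    val
  }
})
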