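test_that("Anger centroid recovers symmetric and corner cases", {
  ext <- c(57.66, 57.66)
  expect_equal(anger_position(c(ne = 1, nw = 1, se = 1, sw = 1), ext),
               c(x = 0, y = 0))
  expect_equal(anger_position(c(ne = 5, nw = 0, se = 0, sw = 0), ext),
               c(x = 57.66 / 2, y = 57.66 / 2))
  expect_equal(anger_position(c(sw = 2, se = 0, nw = 0, ne = 0), ext),
               c(x = -57.66 / 2, y = -57.66 / 2))
  expect_error(anger_position(c(ne = 0, nw = 0, se = 0, sw = 0), ext),
               class = "planarpet_domain_error")
})

test_that("light-sharing positioning lands within one crystal pitch", {
  n_trials <- 120
  errs <- planarpet:::with_seed(31, {
    vapply(seq_len(n_trials), function(i) {
      truth <- runif(2, -25, 25)
      sig <- anger_signal(truth, n_photons = 4000)
      est <- anger_position(sig)
      sqrt(sum((est - truth)^2))
    }, numeric(1))
  })
  expect_gte(mean(errs <= 2.32), 0.95)
})

test_that("SSRB assigns LORs to the midplane at the crossing point", {
  # perpendicular LOR bins at its own (x, y)
  set <- make_set(perp_events(7, x = 3.7, y = -2.1))
  img <- ssrb_rebin(set, pixel_size = 0.2)
  w <- which(img$data == max(img$data), arr.ind = TRUE)
  expect_equal(planarpet:::grid_axis(img$grid, 1)[w[1]], 3.7, tolerance = 0.2)
  expect_equal(planarpet:::grid_axis(img$grid, 2)[w[2]], -2.1, tolerance = 0.2)
  # oblique LOR with equidistant heads bins at the endpoint midpoint
  ob <- make_set(data.frame(x1 = 0, y1 = 0, x2 = 10, y2 = 6, e1 = 511,
                            e2 = 511, t = 0.1, label = "true"))
  img <- ssrb_rebin(ob, pixel_size = 0.2)
  w <- which(img$data == max(img$data), arr.ind = TRUE)
  expect_equal(planarpet:::grid_axis(img$grid, 1)[w[1]], 5, tolerance = 0.2)
  expect_equal(planarpet:::grid_axis(img$grid, 2)[w[2]], 3, tolerance = 0.2)
  # centered point source rebins symmetrically around the origin
  acq <- center_acq()
  img <- ssrb_rebin(acq, pixel_size = 0.5, extent_xy = 40)
  xs <- planarpet:::grid_axis(img$grid, 1)
  m <- apply(img$data[, , 1], 1, sum)
  expect_equal(sum(xs * m) / sum(m), 0, tolerance = 0.1)
})

test_that("ray traversal lengths match slab clipping and dense sampling", {
  grid <- recon_grid(geom60, extent_xy = c(20, 16), pixel_size = 0.5,
                     slice_depth = 2, n_slices = 9)
  lo <- grid$origin
  hi <- grid$origin + grid$dims * grid$vsize
  h <- geom60$separation / 2
  rays <- planarpet:::with_seed(17, replicate(15, list(
    a = c(runif(1, -15, 15), runif(1, -12, 12), h),
    b = c(runif(1, -15, 15), runif(1, -12, 12), -h)), simplify = FALSE))
  for (r in rays) {
    tr <- planarpet:::cpp_ray_lengths(r$a, r$b, grid$dims, grid$vsize,
                                      grid$origin)
    # oracle 1: total in-box length by slab clipping
    d <- r$b - r$a
    t0 <- 0; t1 <- 1
    for (ax in 1:3) {
      if (d[ax] != 0) {
        tt <- sort(c((lo[ax] - r$a[ax]) / d[ax], (hi[ax] - r$a[ax]) / d[ax]))
        t0 <- max(t0, tt[1]); t1 <- min(t1, tt[2])
      }
    }
    want <- max(t1 - t0, 0) * sqrt(sum(d^2))
    expect_equal(sum(tr$length), want, tolerance = 1e-8)
    # oracle 2: per-voxel lengths by dense point sampling along the ray
    if (length(tr$index) > 0) {
      ns <- 4e4
      tt <- (seq_len(ns) - 0.5) / ns
      pts <- outer(tt, d) + rep(r$a, each = ns)
      ii <- floor(sweep(sweep(pts, 2, lo), 2, grid$vsize, "/"))
      inb <- ii[, 1] >= 0 & ii[, 1] < grid$dims[1] &
             ii[, 2] >= 0 & ii[, 2] < grid$dims[2] &
             ii[, 3] >= 0 & ii[, 3] < grid$dims[3]
      vox <- ii[inb, 1] + grid$dims[1] * ii[inb, 2] +
        grid$dims[1] * grid$dims[2] * ii[inb, 3] + 1
      est <- tabulate(vox, nbins = prod(grid$dims)) / ns * sqrt(sum(d^2))
      full <- numeric(prod(grid$dims))
      full[tr$index] <- tr$length
      expect_lt(max(abs(full - est)), 0.2)
    }
  }
})

test_that("back-projection touches exactly the crossed voxels and conserves length", {
  grid <- recon_grid(geom60, extent_xy = 12, pixel_size = 0.4, n_slices = 11)
  set <- make_set(data.frame(x1 = 1.3, y1 = -2.2, x2 = -4.1, y2 = 3.3,
                             e1 = 511, e2 = 511, t = 0.1, label = "true"))
  img <- backproject(set, grid)
  h <- geom60$separation / 2
  tr <- planarpet:::cpp_ray_lengths(c(1.3, -2.2, h), c(-4.1, 3.3, -h),
                                    grid$dims, grid$vsize, grid$origin)
  nz <- which(img$data > 0)
  expect_setequal(nz, tr$index)
  expect_equal(sum(img$data), sum(tr$length), tolerance = 1e-10)
  # many rays: total intensity equals the summed per-ray in-grid lengths
  ev <- random_events(200)
  set <- make_set(ev)
  img <- backproject(set, grid)
  tot <- sum(vapply(seq_len(nrow(ev)), function(i) {
    sum(planarpet:::cpp_ray_lengths(c(ev$x1[i], ev$y1[i], h),
                                    c(ev$x2[i], ev$y2[i], -h),
                                    grid$dims, grid$vsize, grid$origin)$length)
  }, numeric(1)))
  expect_equal(sum(img$data), tot, tolerance = 1e-8)
})

test_that("MLEM concentrates repeated perpendicular LORs at their column", {
  grid <- recon_grid(geom60, extent_xy = 10, pixel_size = 0.5, n_slices = 5)
  set <- make_set(perp_events(40, x = 2.2, y = -1.4))
  img <- mlem_reconstruct(set, grid, n_iterations = 8, mrp = FALSE,
                          sensitivity = "uniform")
  w <- which(img$data == max(img$data), arr.ind = TRUE)[1, ]
  expect_equal(planarpet:::grid_axis(img$grid, 1)[w[1]], 2.2, tolerance = 0.5)
  expect_equal(planarpet:::grid_axis(img$grid, 2)[w[2]], -1.4, tolerance = 0.5)
  expect_true(all(img$data >= 0))
})

test_that("MLEM with uniform sensitivity conserves total counts each iteration", {
  grid <- recon_grid(geom60, extent_xy = 16, pixel_size = 0.8, n_slices = 7)
  set <- make_set(planarpet:::with_seed(19, data.frame(
    x1 = runif(150, -7, 7), y1 = runif(150, -7, 7),
    x2 = runif(150, -7, 7), y2 = runif(150, -7, 7),
    e1 = 511, e2 = 511, t = sort(runif(150)), label = "true")))
  for (it in c(1, 5)) {
    img <- mlem_reconstruct(set, grid, n_iterations = it, mrp = FALSE,
                            sensitivity = "uniform")
    expect_equal(sum(img$data), n_events(set), tolerance = 1e-9)
  }
})

test_that("Poisson log-likelihood is non-decreasing without the prior", {
  acq <- center_acq()
  sub <- acq
  sub$events <- head(sub$events, 1500)
  grid <- recon_grid(geom60, extent_xy = 12, pixel_size = 0.4, n_slices = 9)
  img <- mlem_reconstruct(sub, grid, n_iterations = 12, mrp = FALSE,
                          sensitivity = "uniform")
  ll <- attr(img, "loglik")
  expect_true(all(diff(ll) > -1e-6 * abs(ll[-length(ll)])))
  # with the median root prior the image stays finite and non-negative
  img2 <- mlem_reconstruct(sub, grid, n_iterations = 6, mrp = TRUE, beta = 0.3,
                           sensitivity = "uniform")
  expect_true(all(is.finite(img2$data)))
  expect_true(all(img2$data >= 0))
})

test_that("reconstruction is equivariant under event translation", {
  acq <- center_acq()
  sub <- acq
  sub$events <- head(sub$events, 4000)
  grid <- recon_grid(geom60, extent_xy = 16, pixel_size = 0.4, n_slices = 9)
  img0 <- mlem_reconstruct(sub, grid, n_iterations = 6, mrp = FALSE)
  shifted <- sub
  shifted$events$x1 <- shifted$events$x1 + 2
  shifted$events$x2 <- shifted$events$x2 + 2
  img1 <- mlem_reconstruct(shifted, grid, n_iterations = 6, mrp = FALSE)
  w0 <- which(img0$data == max(img0$data), arr.ind = TRUE)[1, ]
  w1 <- which(img1$data == max(img1$data), arr.ind = TRUE)[1, ]
  x0 <- planarpet:::grid_axis(grid, 1)[w0[1]]
  x1 <- planarpet:::grid_axis(grid, 1)[w1[1]]
  expect_equal(x1 - x0, 2, tolerance = 0.4 + 1e-9)
})

test_that("the 3x3x3 median filter matches a direct R implementation", {
  dims <- c(7L, 6L, 5L)
  arr <- planarpet:::with_seed(23, array(runif(prod(dims)), dim = dims))
  got <- array(planarpet:::cpp_median_filter3(as.numeric(arr), dims),
               dim = dims)
  want <- array(0, dims)
  cl <- function(i, n) pmin(pmax(i, 1), n)
  for (ix in 1:dims[1]) for (iy in 1:dims[2]) for (iz in 1:dims[3]) {
    nb <- arr[cl(ix + (-1:1), dims[1]), cl(iy + (-1:1), dims[2]),
              cl(iz + (-1:1), dims[3])]
    want[ix, iy, iz] <- median(nb)
  }
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("empty sets are rejected by both reconstructors", {
  grid <- recon_grid(geom60, extent_xy = 10, pixel_size = 1, n_slices = 3)
  emp <- make_set(planarpet:::empty_events())
  expect_error(backproject(emp, grid), class = "planarpet_domain_error")
  expect_error(mlem_reconstruct(emp, grid), class = "planarpet_domain_error")
})
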