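# Closed-population M0 estimation, MMDM buffers, hull geometry, and the
# non-spatial density quotient.

test_that("M0 hits the p = 1 boundary when everyone is always caught", {
  tr <- place_traps(2, 2, 1)
  det <- array(0L, dim = c(5, 4, 3))
  det[, 1, ] <- 1L
  ch <- toy_history(det, tr)
  expect_warning(est <- estimate_abundance_m0(ch), "boundary")
  expect_equal(est$n_hat, 5)
  expect_equal(est$se_n, 0)
})

test_that("M0 MLE matches an exhaustive likelihood grid scan", {
  tr <- place_traps(2, 2, 1)
  # M_t+1 = 5, 9 occasion-captures over K = 3: high capture probability
  # drives the maximizer to the N = M boundary, as the grid scan confirms
  visits <- list(c(1, 0, 2), c(2, 0, 0), c(0, 3, 1), c(4, 0, 0), c(1, 1, 0))
  ch <- history_from_visits(visits, tr, 3)
  est <- estimate_abundance_m0(ch)
  oracle <- m0_grid_oracle(m = 5, n_capt = 9, k = 3)
  expect_equal(est$n_hat, oracle, tolerance = 1e-3)
  expect_gte(est$n_hat, 5)

  # interior instance: 6 occasion-captures over K = 3 puts N_hat near 10
  visits2 <- list(c(1, 0, 2), c(2, 0, 0), c(0, 3, 0), c(4, 0, 0), c(0, 0, 1))
  ch2 <- history_from_visits(visits2, tr, 3)
  est2 <- estimate_abundance_m0(ch2)
  oracle2 <- m0_grid_oracle(m = 5, n_capt = 6, k = 3)
  expect_gt(est2$n_hat, 5)
  expect_equal(est2$n_hat, oracle2, tolerance = 1e-3)
  expect_gt(est2$se_n, 0)
})

test_that("M0 is invariant to doubling occasions at equal frequencies", {
  tr <- place_traps(2, 2, 1)
  visits <- list(c(1, 0, 2), c(2, 0, 0), c(0, 3, 1), c(4, 0, 0), c(1, 1, 0))
  ch1 <- history_from_visits(visits, tr, 3)
  ch2 <- history_from_visits(lapply(visits, function(v) c(v, v)), tr, 6)
  e1 <- estimate_abundance_m0(ch1)
  e2 <- estimate_abundance_m0(ch2)
  o2 <- m0_grid_oracle(m = 5, n_capt = 18, k = 6)
  expect_equal(e2$n_hat, o2, tolerance = 1e-3)
  expect_equal(e1$n_hat, e2$n_hat, tolerance = 1e-3)
})

test_that("M0 rejects unusable inputs", {
  tr <- place_traps(2, 2, 1)
  ch1 <- history_from_visits(list(c(1)), tr, 1)
  expect_error(estimate_abundance_m0(ch1), "2 occasions")
  expect_error(toy_history(array(0L, dim = c(1, 4, 3)), tr), "detection")
})

test_that("MMDM is the mean of per-individual maximum movements", {
  tr <- read_traps_csv_fixture <- data.frame(
    trap_id = c("T1", "T2", "T3", "T4", "T5"),
    x_km = c(0, 3, 0, 1, 5), y_km = c(0, 0, 4, 0, 0),
    session = "S1", stringsAsFactors = FALSE)
  class(tr) <- c("trap_array", "data.frame")
  # animal 1 at (0,0),(3,0): max 3; animal 2 at (0,0),(0,4): max 4
  ch <- history_from_visits(list(c(1, 2), c(1, 3)), tr, 2)
  expect_equal(as.numeric(mmdm(ch)), 3.5)
  expect_equal(as.numeric(half_mmdm(ch)), 1.75)

  # three collinear traps at x = 0, 1, 5: max pairwise distance 5
  ch3 <- history_from_visits(list(c(1, 4, 5)), tr, 3)
  expect_equal(as.numeric(mmdm(ch3)), 5)

  # single animal at a single trap: undefined
  ch0 <- history_from_visits(list(c(1, 1)), tr, 2)
  expect_error(mmdm(ch0), "undefined")
})

test_that("hull areas are exact on lattices and degenerate inputs", {
  expect_equal(mcp_hull(place_traps(2, 2, 1))$area_km2, 1)
  expect_equal(mcp_hull(place_traps(8, 8, 1.5))$area_km2, 110.25)
  two <- matrix(c(0, 0, 4, 0), 2, 2, byrow = TRUE)
  h <- mcp_hull(two)
  expect_true(h$degenerate)
  expect_equal(h$area_km2, 0)
  expect_equal(h$perimeter_km, 8)  # out-and-back segment
})

test_that("dilated areas follow the Steiner closed form", {
  tr <- place_traps(2, 2, 10)
  ea <- effective_area(tr, 9)
  expect_equal(ea$area_km2, 100 + 40 * 9 + pi * 81, tolerance = 1e-10)
  expect_equal(effective_area(tr, 0)$area_km2, 100)

  # random convex hulls: closed form vs independent grid integration
  set.seed(31)
  for (i in 1:5) {
    pts <- matrix(runif(24, 0, 10), ncol = 2)
    h <- mcp_hull(pts)
    b <- runif(1, 0.5, 3)
    closed <- dilated_area(h$area_km2, h$perimeter_km, b)
    box <- matrix(c(-5, -5, 15, -5, 15, 15, -5, 15), ncol = 2, byrow = TRUE)
    grid <- tigertrend:::clipped_dilated_area(h, b, box, cell_km = 0.02)
    expect_equal(grid, closed, tolerance = 0.01)
  }
})

test_that("hull and dilation are invariant under rigid motions", {
  set.seed(4)
  pts <- matrix(runif(20, 0, 8), ncol = 2)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  moved <- sweep(pts %*% R, 2, c(100, -40), "+")
  h1 <- mcp_hull(pts); h2 <- mcp_hull(moved)
  expect_equal(h1$area_km2, h2$area_km2, tolerance = 1e-10)
  expect_equal(h1$perimeter_km, h2$perimeter_km, tolerance = 1e-10)
  expect_equal(dilated_area(h1$area_km2, h1$perimeter_km, 2),
               dilated_area(h2$area_km2, h2$perimeter_km, 2),
               tolerance = 1e-10)
})

test_that("density is the abundance-area quotient with inherited SE", {
  n12 <- list(n_hat = 12, se_n = 0)
  a600 <- list(mcp_area_km2 = 500, mcp_perimeter_km = 0, buffer_km = 0,
               area_km2 = 600)
  expect_equal(cr_density(n12, a600)$density, 2)

  n6 <- list(n_hat = 6, se_n = 2)
  a300 <- list(mcp_area_km2 = 300, mcp_perimeter_km = 0, buffer_km = 0,
               area_km2 = 300)
  d <- cr_density(n6, a300)
  expect_equal(d$density, 2)
  expect_equal(d$se_density, 2 / 3, tolerance = 1e-12)

  a150 <- a300; a150$area_km2 <- 150
  d2 <- cr_density(n6, a150)
  expect_equal(d2$density, 2 * d$density)
  expect_equal(d2$se_density, 2 * d$se_density)

  a0 <- a300; a0$area_km2 <- 0
  expect_error(cr_density(n6, a0), "positive")
})

test_that("density strictly decreases with buffer width", {
  tr <- place_traps(5, 5, 1.2)
  n <- list(n_hat = 10, se_n = 3)
  buffers <- seq(0.5, 12, by = 0.5)
  dens <- vapply(buffers, function(b)
    cr_density(n, effective_area(tr, b))$density, 0)
  expect_true(all(diff(dens) < 0))
})
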