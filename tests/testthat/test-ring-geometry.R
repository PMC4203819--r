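test_that("circumcircle fit recovers known circles exactly", {
  f <- circle_through_points(c(0, 1), c(1, 0), c(0, -1))
  expect_equal(f$center, c(0, 0), tolerance = 1e-12)
  expect_equal(f$radius, 1, tolerance = 1e-12)
  expect_lt(f$residual, 1e-12)

  # right triangle: circumcenter at the hypotenuse midpoint
  f <- circle_through_points(c(0, 0), c(4, 0), c(0, 3))
  expect_equal(f$center, c(2, 1.5), tolerance = 1e-12)
  expect_equal(f$radius, 2.5, tolerance = 1e-12)
})

test_that("degenerate annotations are rejected", {
  expect_error(circle_through_points(c(0, 0), c(1, 1), c(2, 2)), "collinear")
  expect_error(circle_through_points(c(0, 0), c(0, 0), c(1, 2)), "duplicate")
  expect_error(circle_through_points(c(0, 0), c(1, NA), c(0, 1)), "finite")
  # near-collinear under the scale-free tolerance
  expect_error(circle_through_points(c(0, 0), c(1, 1e-8), c(2, 0)),
               "collinear")
})

test_that("fit agrees with the barycentric circumcenter oracle on random triples", {
  set.seed(42)
  worst <- 0
  for (i in 1:1000) {
    repeat {
      pts <- matrix(runif(6, -10, 10), 3, 2)
      v1 <- pts[2, ] - pts[1, ]
      v2 <- pts[3, ] - pts[1, ]
      area2 <- abs(v1[1] * v2[2] - v1[2] * v2[1])
      if (area2 > 1e-3 * max(dist(pts))^2) break
    }
    f <- circle_through_points(pts[1, ], pts[2, ], pts[3, ])
    o <- circumcircle_oracle(pts[1, ], pts[2, ], pts[3, ])
    worst <- max(worst,
                 sqrt(sum((f$center - o$center)^2)) / o$radius,
                 abs(f$radius - o$radius) / o$radius)
    expect_lt(f$residual, 1e-9 * f$radius)
  }
  expect_lt(worst, 1e-9)
})

test_that("closure percentage follows 100 (1 - r/R) with clamping", {
  circ <- function(r, cx = 0, cy = 0)
    structure(list(center = c(cx, cy), radius = r, residual = 0),
              class = "circle_fit")
  expect_equal(closure_percent(circ(5), circ(5)), 0)
  expect_equal(closure_percent(circ(1e-12), circ(5)), 100, tolerance = 1e-10)
  expect_equal(closure_percent(circ(2), circ(5)), 60)
  # jitter clamp: r/R in (1, 1.02] -> 0, beyond -> error
  expect_equal(closure_percent(circ(5.05), circ(5)), 0)
  expect_error(closure_percent(circ(5.2), circ(5)), "exceeds")
})

test_that("asymmetry percentage is D/R * 100", {
  circ <- function(r, cx = 0, cy = 0)
    structure(list(center = c(cx, cy), radius = r, residual = 0),
              class = "circle_fit")
  expect_equal(asymmetry_percent(circ(2), circ(5)), 0)
  expect_equal(asymmetry_percent(circ(2, 0, -2), circ(5)), 40)
  expect_equal(asymmetry_percent(circ(0.1, 0, 5), circ(5)), 100)
})

test_that("apical displacement is the projection onto the apical axis", {
  circ <- function(r, cx = 0, cy = 0)
    structure(list(center = c(cx, cy), radius = r, residual = 0),
              class = "circle_fit")
  cell <- circ(5)
  ring <- circ(2, 0, -2)
  expect_equal(apical_displacement(ring, cell, c(0, -1)), 2)
  expect_equal(apical_displacement(ring, cell, c(0, 1)), -2)
  expect_equal(apical_displacement(circ(2, 3, 0), cell, c(0, -1)), 0)
  expect_error(apical_displacement(ring, cell, c(0, -2)), "unit vector")
})

test_that("closure and asymmetry are invariant under similarity transforms", {
  set.seed(7)
  for (i in 1:50) {
    cell_pts <- matrix(runif(6, -5, 5), 3, 2)
    v1 <- cell_pts[2, ] - cell_pts[1, ]; v2 <- cell_pts[3, ] - cell_pts[1, ]
    if (abs(v1[1] * v2[2] - v1[2] * v2[1]) < 1e-2) next
    ring_pts <- 0.4 * cell_pts + matrix(runif(2, -0.5, 0.5), 3, 2,
                                        byrow = TRUE)
    base_cell <- circle_through_points(cell_pts[1, ], cell_pts[2, ],
                                       cell_pts[3, ])
    base_ring <- circle_through_points(ring_pts[1, ], ring_pts[2, ],
                                       ring_pts[3, ])
    cl0 <- closure_percent(base_ring, base_cell)
    as0 <- asymmetry_percent(base_ring, base_cell)

    th <- runif(1, 0, 2 * pi); s <- runif(1, 0.3, 3)
    shift <- runif(2, -20, 20)
    Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    tf <- function(p) s * as.numeric(Rm %*% p) + shift
    t_cell <- circle_through_points(tf(cell_pts[1, ]), tf(cell_pts[2, ]),
                                    tf(cell_pts[3, ]))
    t_ring <- circle_through_points(tf(ring_pts[1, ]), tf(ring_pts[2, ]),
                                    tf(ring_pts[3, ]))
    expect_equal(closure_percent(t_ring, t_cell), cl0, tolerance = 1e-9)
    expect_equal(asymmetry_percent(t_ring, t_cell), as0, tolerance = 1e-9)
  }
})

test_that("asymmetry never exceeds closure for an interior ring", {
  set.seed(11)
  circ <- function(r, cx = 0, cy = 0)
    structure(list(center = c(cx, cy), radius = r, residual = 0),
              class = "circle_fit")
  for (i in 1:200) {
    R <- runif(1, 1, 10)
    r <- runif(1, 0, R)
    dmax <- R - r                      # interior ring: D + r <= R
    d <- runif(1, 0, dmax)
    th <- runif(1, 0, 2 * pi)
    ring <- circ(r, d * cos(th), d * sin(th))
    cell <- circ(R)
    expect_lte(asymmetry_percent(ring, cell),
               closure_percent(ring, cell) + 1e-9)
  }
})

test_that("frame metrics compose the geometry and name the failing frame", {
  th_c <- c(0, 2, 4) * pi / 3
  th_r <- th_c + pi / 6
  fr <- annotated_frame(
    time = 30,
    cell_points = cbind(5 * cos(th_c), 5 * sin(th_c)),
    ring_points = cbind(2 * cos(th_r), 2 * sin(th_r))
  )
  m <- frame_metrics(fr)
  expect_equal(m$closure_pct, 60, tolerance = 1e-9)
  expect_equal(m$asymmetry_pct, 0, tolerance = 1e-9)
  expect_equal(m$r_over_R, 0.4, tolerance = 1e-12)

  bad <- annotated_frame(time = 30,
                         cell_points = cbind(5 * cos(th_c), 5 * sin(th_c)),
                         ring_points = rbind(c(0, 0), c(1, 1), c(2, 2)))
  expect_error(frame_metrics(bad, label = 7), "frame 7")
})

test_that("jittered annotations of a known circle recover its radius", {
  set.seed(21)
  sigma <- 0.05
  n <- 200
  radii <- replicate(n, {
    th <- c(30, 150, 270) * pi / 180
    pts <- cbind(2 * cos(th), 2 * sin(th)) + matrix(rnorm(6, 0, sigma), 3, 2)
    circle_through_points(pts[1, ], pts[2, ], pts[3, ])$radius
  })
  expect_lt(abs(mean(radii) - 2) / 2, 0.02)
})
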