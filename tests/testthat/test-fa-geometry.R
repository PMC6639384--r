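straight_edge <- function() membrane_edge(cbind(0, seq(-50, 50, by = 5)))

test_that("orientation classes follow the 90/180 +- 30 degree bands", {
  expect_equal(orientation_class(90, 0), "pointing")
  expect_equal(orientation_class(10, 0), "parallel")
  expect_equal(orientation_class(45, 0), "other")
  # band edges are inclusive
  expect_equal(orientation_class(60, 0), "pointing")
  expect_equal(orientation_class(30, 0), "parallel")
  expect_equal(orientation_class(30.5, 0), "other")
  expect_equal(orientation_class(150, 0), "parallel")
})

test_that("orientation is axially symmetric in both angles", {
  set.seed(3)
  th <- runif(200, 0, 360)
  te <- runif(200, 0, 360)
  expect_identical(orientation_class(th, te),
                   orientation_class(th + 180, te))
  expect_identical(orientation_class(th, te),
                   orientation_class(th, te - 180))
})

test_that("random orientations are excluded at the analytic one-third rate", {
  ana <- expected_random_exclusion()
  expect_equal(ana, 1 / 3)
  mc <- expected_random_exclusion(n_mc = 2e5, seed = 4)
  expect_equal(attr(mc, "mc_estimate"), 1 / 3, tolerance = 0.01)
  # widening the bands to +-45 degrees leaves nothing excluded
  expect_equal(expected_random_exclusion(band = 45), 0)
})

test_that("location classification detects blocking FAs", {
  edge <- straight_edge()
  # single FA: nothing can lie between it and the edge
  expect_equal(location_class(c(5, 0), edge), "outer")
  # blocker straddling the centroid-to-edge segment
  blocker <- ellipse_polygon(c(2.5, 0), c(0.8, 0.5), 0)
  expect_equal(location_class(c(5, 0), edge, list(blocker)), "inner")
  # side-by-side FAs at equal distance do not block each other
  a <- ellipse_polygon(c(5, 4), c(1, 0.4), 0)
  expect_equal(location_class(c(5, 0), edge, list(a)), "outer")
})

test_that("distal side is the axis endpoint nearest the edge", {
  edge <- straight_edge()
  ds <- distal_side(c(5, 0), 0, 4, edge)       # axis perpendicular to edge
  expect_equal(ds$distal, c(3, 0))
  expect_equal(ds$proximal, c(7, 0))
  expect_false(ds$tie)
  # axis parallel to the edge: endpoints equidistant, deterministic tie
  tie <- distal_side(c(5, 0), 90, 4, edge)
  expect_true(tie$tie)
  expect_equal(tie$distal, c(5, -2))
})

test_that("classification recovers all generator truth labels", {
  cell <- gen_cell_geometry(
    n_fas = 12,
    orientation_mix = c(pointing = 0.4, parallel = 0.4, other = 0.2),
    frac_inner = 0.4, seed = 21
  )
  rec <- classify_fas(cell$fas, cell$edge)
  expect_identical(rec$orientation, cell$fas$true_orientation)
  expect_identical(rec$location, cell$fas$true_location)
  # every FA gets exactly one orientation and one location class
  expect_true(all(rec$orientation %in% c("pointing", "parallel", "other")))
  expect_true(all(rec$location %in% c("outer", "inner")))
  # distal endpoints agree with the generator's labels (within the
  # polygon-axis discretization)
  d <- sqrt((rec$distal_x - cell$fas$true_distal_x)^2 +
              (rec$distal_y - cell$fas$true_distal_y)^2)
  expect_lt(max(d), 0.25)
})

test_that("polygon axes match the generating ellipse", {
  poly <- ellipse_polygon(c(3, -2), c(2, 0.5), 37)
  ax <- fadyn:::polygon_axes(poly)
  expect_equal(ax$centroid, c(3, -2), tolerance = 1e-6)
  expect_equal(ax$theta_deg, 37, tolerance = 0.5)
  expect_equal(ax$major, 4, tolerance = 0.05)
  expect_equal(ax$minor, 1, tolerance = 0.05)
})

test_that("classification output is serializable", {
  cell <- gen_cell_geometry(n_fas = 3, seed = 5)
  rec <- classify_fas(cell$fas, cell$edge)
  path <- withr::local_tempfile(fileext = ".csv")
  write_fa_classification(rec, path)
  back <- read.csv(path)
  expect_equal(back$orientation, rec$orientation)
  expect_equal(nrow(back), nrow(rec))
})
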