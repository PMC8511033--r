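cfg1 <- geometry_config(1, 18)

test_that("place_items respects separation, field and feasibility", {
  big <- geometry_config(1, 18, field_radius = 50)
  two <- place_items(2, big, seed = 1)
  expect_equal(nrow(two$dots), 2)
  expect_gte(min_clearance(two) - nrow(two$connectors) * 0, 0.5)

  layout <- place_items(18, cfg1, seed = 42)
  expect_equal(nrow(layout$dots), 18)
  expect_equal(nrow(layout$connectors), 9)
  expect_gte(min_clearance(layout), 0.5)
  rr <- sqrt(layout$dots$x^2 + layout$dots$y^2) + layout$dots$diameter / 2
  expect_true(all(rr <= cfg1$field_radius + 1e-9))

  tiny <- geometry_config(1, 50, field_radius = 1, max_iterations = 50)
  expect_error(place_items(50, tiny, seed = 1), "placement failed")
})

test_that("placement is deterministic given seed and config", {
  a <- place_items(18, cfg1, seed = 7)
  b <- place_items(18, cfg1, seed = 7)
  expect_identical(a$dots, b$dots)
  expect_identical(a$connectors, b$connectors)
})

test_that("connect_pairs builds a perfect matching within the length range", {
  layout <- place_items(18, cfg1, seed = 3)
  conn <- connect_pairs(layout, cfg1, seed = 3)
  expect_equal(nrow(conn$connectors), 9)
  expect_setequal(c(conn$connectors$dot1, conn$connectors$dot2), 1:18)
  lens <- sqrt((conn$connectors$x2 - conn$connectors$x1)^2 +
                 (conn$connectors$y2 - conn$connectors$y1)^2)
  expect_true(all(lens >= cfg1$connector_length_range[1] - 1e-9))
  expect_true(all(lens <= cfg1$connector_length_range[2] + 1e-9))

  cfg24 <- geometry_config(1, 24)
  conn24 <- connect_pairs(place_items(24, cfg24, seed = 4), cfg24, seed = 4)
  expect_equal(nrow(conn24$connectors), 12)

  ## four dots mutually far beyond the maximum line length
  far <- dot_array(data.frame(x = c(0, 20, 0, 20), y = c(0, 0, 20, 20),
                              diameter = 2.2))
  expect_error(connect_pairs(far, cfg1, seed = 1), "pairing")
})

test_that("isolate_by_displacement keeps dots, frees lines, preserves ink", {
  conn <- connect_pairs(place_items(18, cfg1, seed = 5), cfg1, seed = 5)
  iso <- isolate_by_displacement(conn, cfg1, seed = 5)
  expect_identical(iso$dots, conn$dots)
  expect_equal(nrow(iso$connectors), 9)
  expect_true(all(is.na(iso$connectors$dot1)))
  expect_gte(min_clearance(iso), 0.5)
  ## displaced lines no longer share junction pixels with the dots, so the
  ## union ink can only grow (up to raster noise)
  expect_gte(ink_area(iso, cfg1), ink_area(conn, cfg1) - 0.2)

  bare <- dot_array(conn$dots, NULL, connectedness = "isolated-removed")
  expect_identical(isolate_by_displacement(bare, cfg1, seed = 1), bare)
})

test_that("isolate_by_removal absorbs line ink into the dots", {
  cfg2 <- geometry_config(2, 18)
  conn <- connect_pairs(place_items(18, cfg2, seed = 6), cfg2, seed = 6)
  iso <- isolate_by_removal(conn, cfg2)
  expect_equal(nrow(iso$connectors), 0)
  expect_lt(abs(ink_area(iso, cfg2) - ink_area(conn, cfg2)),
            cfg2$ink_tolerance * ink_area(conn, cfg2))
  expect_true(all(iso$dots$diameter > conn$dots$diameter))

  ## near-zero line width: nothing to absorb, diameters almost unchanged
  thin <- conn
  thin$connectors$width[] <- 1e-3
  iso_thin <- isolate_by_removal(thin, cfg2)
  expect_lt(max(abs(iso_thin$dots$diameter - conn$dots$diameter)), 0.02)
})

test_that("single dumbbell: removal splits the line ink between the dots", {
  cfg <- geometry_config(2, 18, field_radius = 10, ppd = 40)
  d <- data.frame(x = c(-2, 2), y = c(0, 0), diameter = 2.2)
  co <- data.frame(x1 = -2 + 1.1, y1 = 0, x2 = 2 - 1.1, y2 = 0,
                   width = 0.6, dot1 = 1L, dot2 = 2L)
  conn <- dot_array(d, co, connectedness = "connected")
  iso <- isolate_by_removal(conn, cfg)
  line_ink <- 0.6 * (4 - 2.2)
  expected_area <- pi * 1.1^2 + line_ink / 2
  got_area <- pi * (iso$dots$diameter[1] / 2)^2
  expect_lt(abs(got_area - expected_area) / expected_area, 0.02)
})

test_that("match_constraints is a fixed point on matched input and converges", {
  conn <- connect_pairs(place_items(18, cfg1, seed = 8), cfg1, seed = 8)
  tgt <- list(ink = ink_area(conn, cfg1), hull = convex_hull_area(conn))
  same <- match_constraints(conn, tgt, cfg1)
  expect_equal(attr(same, "achieved")$iterations, 0L)
  expect_identical(same$dots, conn$dots)

  matched <- match_constraints(conn, list(ink = cfg1$target_ink,
                                          hull = cfg1$target_hull), cfg1)
  ach <- attr(matched, "achieved")
  expect_lt(abs(ach$ink - 92.7) / 92.7, cfg1$ink_tolerance)
  expect_lt(abs(ach$hull - 513) / 513, cfg1$hull_tolerance)
  expect_gte(min_clearance(matched), 0.5)
})

test_that("radial scaling of coordinates scales the hull area by s^2", {
  set.seed(11)
  pts <- cbind(runif(18, -10, 10), runif(18, -10, 10))
  a1 <- convex_hull_area(pts)
  for (s in c(0.5, 1.3, 2)) {
    expect_equal(convex_hull_area(pts * s), a1 * s^2, tolerance = 1e-10)
  }
})

test_that("rasterized ink uses union semantics and matches disc area", {
  cfg <- geometry_config(1, 18, ppd = 40)
  one <- dot_array(data.frame(x = 0, y = 0, diameter = 2))
  expect_lt(abs(ink_area(one, cfg) - pi) / pi, 0.02)

  two <- dot_array(data.frame(x = c(0, 0), y = c(0, 0),
                              diameter = c(2, 2)))
  expect_equal(ink_area(two, cfg), ink_area(one, cfg))
})

test_that("convex hull matches simple shapes and the gift-wrapping oracle", {
  tri <- matrix(c(0, 0, 1, 0, 0, 1), ncol = 2, byrow = TRUE)
  expect_equal(convex_hull_area(tri), 0.5)
  sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
  expect_equal(convex_hull_area(sq), 1.0)
  expect_error(convex_hull_area(matrix(c(0, 0, 1, 1, 2, 2), ncol = 2,
                                       byrow = TRUE)), "degenerate")

  ## tiny dots behave as points
  tiny <- dot_array(data.frame(x = c(0, 1, 0), y = c(0, 0, 1),
                               diameter = 1e-9))
  expect_equal(convex_hull_area(tiny), 0.5, tolerance = 1e-6)

  stim <- place_items(18, cfg1, seed = 12)
  pts <- pupilnum:::hull_support_points(stim)
  expect_equal(convex_hull_area(stim), oracle_hull_area(pts),
               tolerance = 1e-9)
})

test_that("generated condition sets conserve ink and hull and separation", {
  ## constraint conservation across seeded generations of both families
  for (i in 1:20) {
    exp_i <- if (i %% 2 == 1) 1 else 2
    set <- generate_stimulus_set(exp_i, seed = 100 + i)
    summ <- attr(set, "summary")
    ink_ref <- if (exp_i == 1) 92.7 else 82.3
    rel_ink <- max(abs(outer(summ$ink, summ$ink, "-"))) / ink_ref
    rel_hull <- max(abs(outer(summ$hull, summ$hull, "-"))) / 513
    expect_lte(rel_ink, 0.005 + 1e-9)
    expect_lte(rel_hull, 0.005 + 1e-9)
    for (s in set) expect_gte(min_clearance(s), 0.5 - 1e-9)
  }
})

test_that("stimulus set generation is reproducible from its seed", {
  a <- generate_stimulus_set(2, seed = 5, numerosities = 18)
  b <- generate_stimulus_set(2, seed = 5, numerosities = 18)
  expect_identical(a$N18_connected$dots, b$N18_connected$dots)
  expect_identical(a$N18_isolated$dots, b$N18_isolated$dots)
})
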