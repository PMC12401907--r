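# Per-frame measurement operators against analytic and brute-force oracles.

test_that("bias_geometry: direction, quadrant, degenerate concentric case", {
  cs <- demo_frame(off = 0.5)
  b <- bias_geometry(cs)
  expect_equal(b$bias_angle, 0, tolerance = 1e-6)
  expect_equal(b$quadrant, c(315, 45))
  expect_equal(b$offset, 0.5, tolerance = 1e-6)
  expect_equal(arc_length(b$quadrant), 90)

  cs_down <- cross_section(1L, 0, make_circle(2), catheter_pose(c(0, -1)))
  expect_equal(bias_geometry(cs_down)$bias_angle, 270, tolerance = 1e-6)
  expect_equal(bias_geometry(cs_down)$quadrant, c(225, 315),
               tolerance = 1e-6)

  cs_centered <- cross_section(1L, 0, make_circle(2), catheter_pose(c(0, 0)))
  expect_error(bias_geometry(cs_centered), class = "octbias_bias_undefined")
})

test_that("distance_indices: analytic circles, missing media, ellipse oracle", {
  cs <- cross_section(1L, 0, make_circle(2, n = 2048),
                      catheter_pose(c(0.5, 0)),
                      media = make_circle(2.25, n = 2048, role = "media"))
  d <- distance_indices(cs, bias_geometry(cs))
  expect_equal(unname(d), c(1.5, 2.5, 1.75, 2.75), tolerance = 1e-5)

  cs_nomedia <- cross_section(1L, 0, make_circle(2), catheter_pose(c(0.5, 0)))
  d2 <- distance_indices(cs_nomedia, bias_geometry(cs_nomedia))
  expect_true(all(is.na(d2[c("d_cmb", "d_cmo")])))
  expect_false(anyNA(d2[c("d_cib", "d_cio")]))

  # elliptical intima, offset catheter, vs scalar brute-force oracle
  ell <- make_ellipse(2, 1.3, rot = 25, n = 512)
  cs3 <- cross_section(1L, 0, ell, catheter_pose(c(0.4, -0.3)))
  b3 <- bias_geometry(cs3)
  d3 <- distance_indices(cs3, b3)
  expect_equal(unname(d3["d_cib"]),
               ray_dist_bf(c(0.4, -0.3), b3$bias_angle, ell),
               tolerance = 1e-6)
  expect_equal(unname(d3["d_cio"]),
               ray_dist_bf(c(0.4, -0.3), b3$bias_angle + 180, ell),
               tolerance = 1e-6)
})

test_that("media outside intima implies d_cib <= d_cmb and d_cio <= d_cmo", {
  set.seed(3)
  study <- generate_study(generator_config(seed = 5, n_patients = 3))
  for (pb in study$pre) {
    for (cs in pb$frames) {
      if (is.null(cs$media)) next
      b <- tryCatch(bias_geometry(cs), octbias_error = function(e) NULL)
      if (is.null(b)) next
      d <- distance_indices(cs, b)
      expect_lte(d[["d_cib"]], d[["d_cmb"]] + 1e-9)
      expect_lte(d[["d_cio"]], d[["d_cmo"]] + 1e-9)
    }
  }
})

test_that("touch_angle: no contact, co-circular, tangent closed form", {
  expect_equal(touch_angle(demo_frame(r_lumen = 2, off = 0)), 0)

  co <- cross_section(1L, 0, make_circle(0.45, n = 720),
                      catheter_pose(c(0, 0)), check = FALSE)
  expect_equal(touch_angle(co), 360)

  # internally tangent catheter: contact arc from circle-circle geometry
  # ray distance from center at angle a: -d cos(a) + sqrt(R^2 - d^2 sin^2 a)
  # <= rho  <=>  cos(a) >= (R^2 - rho^2 - d^2) / (2 rho d)
  R <- 2; rc <- 0.45; gap_tol <- 0.02
  d <- R - rc
  rho <- rc + gap_tol
  expected_arc <- 2 * acos((R^2 - rho^2 - d^2) / (2 * rho * d)) * 180 / pi
  cs <- cross_section(1L, 0, make_circle(R, n = 4096),
                      catheter_pose(c(d, 0)))
  dtheta <- 0.5
  expect_equal(touch_angle(cs, gap_tol = gap_tol, dtheta = dtheta),
               expected_arc, tolerance = 2 * dtheta)
})

test_that("touch_angle is non-decreasing in gap_tol and sum mode >= largest run", {
  R <- 1.4; press <- 0.12; rc <- 0.45
  d <- R - rc + press
  pts <- circle_pts(R, n = 128)
  dC <- sqrt((pts[, 1] - d)^2 + pts[, 2]^2)
  inside <- dC < rc + 0.005
  f <- (rc + 0.005) / dC[inside]
  pts[inside, ] <- cbind(d + (pts[inside, 1] - d) * f, pts[inside, 2] * f)
  cs <- cross_section(1L, 0, contour(pts, "intima"), catheter_pose(c(d, 0)))
  tols <- c(0.005, 0.01, 0.02, 0.05, 0.1)
  arcs <- vapply(tols, function(g) touch_angle(cs, gap_tol = g), numeric(1))
  expect_true(all(diff(arcs) >= 0))
  expect_gte(touch_angle(cs, mode = "sum"), touch_angle(cs))
})

test_that("lumen_diameters: circle, ellipse, irregular star vs fine-sweep oracle", {
  circ <- make_circle(1.5, n = 2048)
  ld <- lumen_diameters(circ)
  expect_equal(unname(ld), c(3, 3), tolerance = 3e-3)

  ell <- make_ellipse(2, 1, n = 4096)
  ld2 <- lumen_diameters(ell)
  expect_equal(unname(ld2), c(2, 4), tolerance = 0.1 / 100 * 4)

  set.seed(9)
  st <- random_star(n = 14, r_range = c(0.8, 1.4))
  ct <- contour(st$pts, "intima")
  ld3 <- lumen_diameters(ct, dtheta = 0.5)
  # oracle: scalar brute-force chords at a 0.05 degree sweep
  ctr <- fan_centroid_oracle(ct)
  th <- seq(0, 179.95, by = 0.05)
  chords <- vapply(th, function(a) {
    ray_dist_bf(ctr, a, ct) + ray_dist_bf(ctr, a + 180, ct)
  }, numeric(1))
  expect_equal(unname(ld3["min_ld"]), min(chords), tolerance = 2e-3)
  expect_equal(unname(ld3["max_ld"]), max(chords), tolerance = 2e-3)
})

test_that("halving dtheta converges min/max diameters and touch angle", {
  set.seed(21)
  st <- random_star(n = 16, r_range = c(1.0, 1.4))
  ct <- contour(st$pts, "intima")
  ref <- lumen_diameters(ct, dtheta = 0.05)
  e1 <- abs(unname(lumen_diameters(ct, dtheta = 1.0)) - unname(ref))
  e2 <- abs(unname(lumen_diameters(ct, dtheta = 0.5)) - unname(ref))
  e3 <- abs(unname(lumen_diameters(ct, dtheta = 0.25)) - unname(ref))
  expect_true(all(e2 <= e1 + 1e-9))
  expect_true(all(e3 <= e2 + 1e-9))
})

test_that("eccentricity formula and domain errors", {
  expect_equal(eccentricity(3, 3), 0)
  expect_equal(eccentricity(2, 4), 0.5)
  expect_equal(eccentricity(1, 8), 0.875)
  expect_error(eccentricity(4, 2), class = "octbias_domain")
  expect_error(eccentricity(-1, 2), class = "octbias_domain")
  # any circle polygon is nearly round at the default sweep
  ld <- lumen_diameters(make_circle(1.23, n = 1024), dtheta = 0.5)
  expect_lt(eccentricity(ld[["min_ld"]], ld[["max_ld"]]), 0.005)
})

test_that("eem_metrics: circle, ellipse, missing EEM", {
  cs <- cross_section(1L, 0, make_circle(1.2, n = 1024),
                      catheter_pose(c(0.3, 0)),
                      eem = make_circle(1.6, n = 1024, role = "eem"))
  em <- eem_metrics(cs)
  expect_equal(em[["eem_csa"]], pi * 1.6^2, tolerance = 1e-3)
  expect_equal(em[["avd"]], 3.2, tolerance = 3e-3)

  cs2 <- cross_section(1L, 0, make_circle(1.2, n = 512),
                       catheter_pose(c(0.3, 0)),
                       eem = make_ellipse(2, 1.5, n = 2048, role = "eem"))
  expect_equal(eem_metrics(cs2)[["avd"]], 3.5, tolerance = 3.5e-3)

  cs3 <- cross_section(1L, 0, make_circle(1.2), catheter_pose(c(0.3, 0)))
  expect_true(all(is.na(eem_metrics(cs3))))
})

test_that("compute_btv ratio and domain errors", {
  expect_equal(compute_btv(1.65, 3.18), 0.519, tolerance = 1e-3)
  expect_equal(compute_btv(2, 4), 0.5)
  expect_equal(compute_btv(1.5, 3), 0.5)
  expect_error(compute_btv(0, 3), class = "octbias_domain")
  expect_error(compute_btv(1.5, -1), class = "octbias_domain")
})

test_that("measure_frame composes the individual operators exactly", {
  set.seed(17)
  study <- generate_study(generator_config(seed = 11, n_patients = 2))
  frames <- unlist(lapply(study$pre, function(p) p$frames),
                   recursive = FALSE)
  for (cs in frames[seq(1, length(frames), by = 5)]) {
    m <- measure_frame(cs)
    b <- bias_geometry(cs)
    d <- distance_indices(cs, b)
    expect_equal(m$d_cib, unname(d[["d_cib"]]))
    expect_equal(m$d_cmb, unname(d[["d_cmb"]]))
    expect_equal(m$touch_angle, touch_angle(cs))
    expect_equal(m$la, polygon_area(cs$intima))
    ld <- lumen_diameters(cs$intima)
    expect_equal(m$min_ld, unname(ld[["min_ld"]]))
    expect_equal(m$le, eccentricity(ld[["min_ld"]], ld[["max_ld"]]))
    if (is.null(cs$eem)) expect_true(is.na(m$eem_csa))
  }
})

test_that("measure_frame handles missing layers and undefined bias", {
  cs <- cross_section(1L, 0, make_circle(2), catheter_pose(c(0.5, 0)))
  m <- measure_frame(cs)
  expect_true(is.na(m$d_cmb) && is.na(m$d_cmo) &&
                is.na(m$eem_csa) && is.na(m$avd))
  expect_false(anyNA(c(m$d_cib, m$d_cio, m$la, m$min_ld, m$max_ld, m$le)))

  cs0 <- cross_section(1L, 0, make_circle(2), catheter_pose(c(0, 0)))
  expect_warning(m0 <- measure_frame(cs0), class = "octbias_bias_undefined")
  expect_true(all(is.na(c(m0$d_cib, m0$d_cio, m0$d_cmb, m0$d_cmo))))
  expect_null(m0$bias)
  expect_false(is.na(m0$la))
})

test_that("all measurements are rigid-motion invariant", {
  set.seed(29)
  study <- generate_study(generator_config(seed = 13, n_patients = 2))
  frames <- unlist(lapply(study$pre, function(p) p$frames),
                   recursive = FALSE)
  for (cs in frames[c(2, 9, 20)]) {
    ang <- runif(1, 0, 360); shift <- runif(2, -4, 4)
    m1 <- measure_frame(cs)
    m2 <- measure_frame(rt_cross_section(cs, ang, shift))
    for (f in c("d_cib", "d_cio", "d_cmb", "d_cmo", "la",
                "min_ld", "max_ld", "le", "eem_csa", "avd")) {
      expect_equal(m2[[f]], m1[[f]], tolerance = 1e-6, label = f)
    }
    expect_equal(m2$touch_angle, m1$touch_angle, tolerance = 0.5 + 1e-9)
    dang <- (m2$bias$bias_angle - ang - m1$bias$bias_angle + 180) %% 360 - 180
    expect_lt(abs(dang), 1e-6)
  }
})
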