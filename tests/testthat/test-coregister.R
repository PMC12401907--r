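# Landmark alignment, 1-mm pairing, and coincidence/entrapment summaries.

# tiny pullback builder: circular frames at given z positions
tiny_pullback <- function(z, phase = "pre", patient_id = "P01",
                          landmark_z = z[1], analysis_span = NULL,
                          dissections = NULL) {
  frames <- lapply(seq_along(z), function(i) {
    cross_section(i, z[i], make_circle(2, n = 64),
                  catheter_pose(c(0.5, 0)),
                  dissection = if (is.null(dissections)) NULL else
                    dissections[[i]])
  })
  pullback(patient_id, phase, frames, landmark_z = landmark_z,
           analysis_span = analysis_span)
}

test_that("align: landmark arithmetic and missing-landmark error", {
  pre <- tiny_pullback(seq(0, 20, by = 1), landmark_z = 10)
  post <- tiny_pullback(seq(0, 20, by = 1), phase = "post", landmark_z = 12)
  expect_equal(align(pre, post), -2)
  post2 <- tiny_pullback(seq(0, 20, by = 1), phase = "post", landmark_z = 10)
  expect_equal(align(pre, post2), 0)
  pre3 <- tiny_pullback(seq(0, 10, by = 0.5), landmark_z = 7.3)
  post3 <- tiny_pullback(seq(0, 10, by = 0.5), phase = "post",
                         landmark_z = 4.1)
  expect_equal(align(pre3, post3), 3.2)
  post_nl <- tiny_pullback(seq(0, 20), phase = "post")
  post_nl$landmark_z <- NULL
  expect_error(align(pre, post_nl), class = "octbias_unalignable")
})

test_that("resample_pairs: grid arithmetic and gap dropping", {
  z <- seq(0, 4, by = 0.2)
  pre <- tiny_pullback(z, landmark_z = 2)
  post <- tiny_pullback(z, phase = "post", landmark_z = 2)
  pf <- resample_pairs(pre, post, measure_pre = FALSE)
  expect_equal(length(pf$pairs), 5)
  expect_equal(vapply(pf$pairs, function(p) p$grid_z, numeric(1)), 0:4)
  expect_equal(pf$n_dropped, 0L)

  # remove post frames within 0.5 mm of z = 2 -> that grid point drops
  keep <- abs(z - 2) > 0.5
  post_gap <- tiny_pullback(z[keep], phase = "post", landmark_z = 3)
  pf2 <- resample_pairs(pre, post_gap, offset = 0, measure_pre = FALSE)
  expect_equal(length(pf2$pairs), 4)
  expect_equal(pf2$n_dropped, 1L)
  expect_false(2 %in% vapply(pf2$pairs, function(p) p$grid_z, numeric(1)))

  # non-overlapping spans
  far <- tiny_pullback(z + 100, phase = "post", landmark_z = 101)
  expect_error(resample_pairs(pre, far, offset = 0, measure_pre = FALSE),
               class = "octbias_no_overlap")
})

test_that("resample_pairs matches a brute-force nearest-neighbor search", {
  set.seed(5)
  for (rep in 1:5) {
    z_pre <- sort(runif(25, 0, 12))
    z_post <- sort(runif(25, 0, 12))
    pre <- tiny_pullback(z_pre, landmark_z = z_pre[10])
    post <- tiny_pullback(z_post, phase = "post", landmark_z = z_post[10])
    off <- align(pre, post)
    pf <- resample_pairs(pre, post, measure_pre = FALSE)
    # oracle: exhaustive scan
    zp <- z_post + off
    lo <- max(min(z_pre), min(zp))
    hi <- min(max(z_pre), max(zp))
    grid <- lo + seq(0, floor(hi - lo + 1e-9))
    expected <- list()
    for (g in grid) {
      di <- abs(z_pre - g); dj <- abs(zp - g)
      if (min(di) > 0.5 || min(dj) > 0.5) next
      expected[[length(expected) + 1L]] <-
        c(which.min(di), which.min(dj))
    }
    got <- lapply(pf$pairs, function(p) c(p$pre$frame_id, p$post$frame_id))
    expect_equal(lapply(got, as.integer),
                 lapply(expected, as.integer))
  }
})

test_that("pair count is bounded by span length and z-shift is a no-op", {
  z <- seq(0, 7.7, by = 0.3)
  pre <- tiny_pullback(z, landmark_z = 3, analysis_span = c(0, 7.7))
  post <- tiny_pullback(z, phase = "post", landmark_z = 3)
  pf <- resample_pairs(pre, post, measure_pre = FALSE)
  expect_lte(length(pf$pairs), floor(7.7) + 1)

  shift <- 5.5
  pre_s <- tiny_pullback(z + shift, landmark_z = 3 + shift,
                         analysis_span = c(0, 7.7) + shift)
  post_s <- tiny_pullback(z + shift, phase = "post", landmark_z = 3 + shift)
  pf_s <- resample_pairs(pre_s, post_s, measure_pre = FALSE)
  expect_equal(length(pf_s$pairs), length(pf$pairs))
  expect_equal(vapply(pf_s$pairs, function(p) p$pre$frame_id, integer(1)),
               vapply(pf$pairs, function(p) p$pre$frame_id, integer(1)))
})

# build a pair record by hand
fake_pair <- function(bias_angle, arc, subintimal = TRUE, present = TRUE) {
  cs <- cross_section(1L, 0, make_circle(2, n = 64),
                      catheter_pose(0.5 * c(cos(bias_angle * pi / 180),
                                            sin(bias_angle * pi / 180))))
  list(grid_z = 0, pre = cs, post = cs,
       pre_measure = measure_frame(cs),
       post_dissection = if (present) {
         dissection(TRUE, arc = arc, depth = "intimal",
                    catheter_subintimal = subintimal)
       } else dissection(FALSE))
}

test_that("quadrant_coincidence: containment, disjoint, wrap-around vs sampling oracle", {
  p_in <- fake_pair(0, c(10, 40))
  p_out <- fake_pair(0, c(170, 200))
  expect_equal(quadrant_coincidence(list(p_in))$rate, 100)
  expect_equal(quadrant_coincidence(list(p_out))$rate, 0)
  co <- quadrant_coincidence(list(p_in, p_out))
  expect_equal(co$rate, 50)
  expect_equal(co$n_dissection, 2L)
  # no dissections -> missing, not zero
  expect_true(is.na(quadrant_coincidence(list(fake_pair(0, NULL,
                                                        present = FALSE)))$rate))

  # wrap-around arcs vs 0.1-degree membership oracle
  set.seed(31)
  for (i in 1:40) {
    b <- runif(1, 0, 360)
    lo <- runif(1, 0, 360); w <- runif(1, 5, 120)
    arc <- deg_norm(c(lo, lo + w))
    q <- deg_norm(c(b - 45, b + 45))
    grid <- seq(0, 359.95, by = 0.1)
    in_arc <- ((grid - arc[1]) %% 360) < w
    in_q <- ((grid - q[1]) %% 360) < 90
    oracle <- any(in_arc & in_q)
    pair <- fake_pair(b, arc)
    expect_equal(quadrant_coincidence(list(pair))$rate == 100, oracle,
                 label = sprintf("bias %.1f arc [%.1f,%.1f]", b, arc[1], arc[2]))
  }
})

test_that("entrapment_rate counts subintimal flags and order does not matter", {
  ps <- c(lapply(1:3, function(i) fake_pair(0, c(0, 30), subintimal = TRUE)),
          lapply(1:2, function(i) fake_pair(0, c(0, 30), subintimal = FALSE)))
  expect_equal(entrapment_rate(ps), 60)
  set.seed(1)
  expect_equal(entrapment_rate(sample(ps)), 60)
  expect_equal(quadrant_coincidence(sample(ps))$rate,
               quadrant_coincidence(ps)$rate)
  expect_true(is.na(entrapment_rate(list(fake_pair(0, NULL, present = FALSE)))))
})
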