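# Synthetic paired-pullback generator.  Emulates the structure of a
# pre/post rotational-atherectomy OCT study: per-patient bias direction,
# noisy elliptical lumens with wall layers, a catheter pressed toward the
# wall at the bias site, and a mechanistic dissection model driven by the
# catheter-to-media distance and the touch angle at the bias site.

#' Generator configuration
#'
#' Defaults describe the emulated study: 21 patients, 12-25 analyzable
#' 1-mm frames each (about 388 frames in total), a dissection event
#' fraction near 56/388, dissection mechanistically driven by short
#' catheter-to-media distance (threshold 0.72 mm) or large contact arc
#' (threshold 98.2 deg) at the bias site, flaps placed inside the bias
#' quadrant, and certain catheter entrapment beneath the flap.
#'
#' @param seed integer RNG seed; every generated artifact is a pure
#'   function of the config including this seed.
#' @param n_patients number of patients.
#' @param frames_per_patient integer range `c(min, max)` of analyzable
#'   frames per patient (1-mm spacing).
#' @param lumen list: `radius_range` (mm, uniform), `ellipticity_range`
#'   (lumen eccentricity, uniform), `noise_amp` (relative radial Fourier
#'   perturbation), `n_vertices`.
#' @param wall list: `im_thickness_range` (intima-to-media radial offset,
#'   mm), `me_thickness_range` (media-to-EEM offset, mm),
#'   `p_media_visible`, `p_eem_visible`.
#' @param calcium list: `p_frame` (probability a frame carries a calcium
#'   arc), `span_range` (degrees).
#' @param bias list: `p_contact` (probability the catheter presses into
#'   the wall), `press_range` (mm of indentation for contact frames),
#'   `gap_range` (mm of clearance for non-contact frames), `drift_sd`
#'   (degrees of frame-to-frame bias-direction drift).
#' @param catheter_radius mm (2.7F imaging catheter).
#' @param dissection list: `mode` (`"threshold"` or `"logistic"`), `tau_d`
#'   (mm; `0` disables the distance term), `tau_a` (degrees; `Inf` disables
#'   the angle term), `slope_d` (per mm), `slope_a` (per degree),
#'   `intercept` (logistic intercept; `NULL` = calibrate to `target_rate`
#'   over the generated cohort), `target_rate`.
#' @param flap list: `span_range` (degrees), `p_entrapment`.
#' @param observer list: `vertex_jitter_sd` (mm, for second-reader
#'   contours), `label_flip_p` (second-reader dissection-label flips).
#' @param lumen_growth relative post-ablation lumen enlargement range for
#'   non-dissected frames.
#' @return list of class `oct_generator_config`.
#' @export
generator_config <- function(
    seed = 20260909L,
    n_patients = 21L,
    frames_per_patient = c(12L, 25L),
    lumen = list(radius_range = c(1.1, 1.7), ellipticity_range = c(0, 0.3),
                 noise_amp = 0.02, n_vertices = 128L),
    wall = list(im_thickness_range = c(0.22, 0.42),
                me_thickness_range = c(0.12, 0.22),
                p_media_visible = 0.85, p_eem_visible = 0.7),
    calcium = list(p_frame = 0.6, span_range = c(30, 180)),
    bias = list(p_contact = 0.17, press_range = c(0.02, 0.22),
                gap_range = c(0.03, 0.6), drift_sd = 5),
    catheter_radius = 0.45,
    dissection = list(mode = "threshold", tau_d = 0.72, tau_a = 98.2,
                      slope_d = 40, slope_a = 0.12, intercept = NULL,
                      target_rate = 56 / 388),
    flap = list(span_range = c(20, 40), p_entrapment = 1.0),
    observer = list(vertex_jitter_sd = 0.01, label_flip_p = 0.02),
    lumen_growth = c(0.02, 0.08)) {
  cfg <- list(seed = as.integer(seed), n_patients = as.integer(n_patients),
              frames_per_patient = as.integer(frames_per_patient),
              lumen = lumen, wall = wall, calcium = calcium, bias = bias,
              catheter_radius = catheter_radius, dissection = dissection,
              flap = flap, observer = observer, lumen_growth = lumen_growth)
  probs <- c(wall$p_media_visible, wall$p_eem_visible, calcium$p_frame,
             bias$p_contact, flap$p_entrapment, observer$label_flip_p)
  if (any(probs < 0 | probs > 1)) {
    abort_oct("all probabilities must lie in [0, 1]", "octbias_domain")
  }
  if (any(c(wall$im_thickness_range, wall$me_thickness_range) <= 0) ||
      catheter_radius <= 0) {
    abort_oct("thicknesses and catheter radius must be > 0", "octbias_domain")
  }
  if (!dissection$mode %in% c("threshold", "logistic")) {
    abort_oct("dissection mode must be 'threshold' or 'logistic'",
              "octbias_domain")
  }
  class(cfg) <- "oct_generator_config"
  cfg
}

# Radial lumen model about the vessel center: rotated ellipse modulated by
# a low-order Fourier perturbation.  `shape` carries everything needed to
# evaluate the radius at any angle.
sample_lumen_shape <- function(cfg) {
  lu <- cfg$lumen
  R <- stats::runif(1, lu$radius_range[1], lu$radius_range[2])
  e <- stats::runif(1, lu$ellipticity_range[1], lu$ellipticity_range[2])
  psi <- stats::runif(1, 0, 360)
  ck <- stats::runif(3, -lu$noise_amp, lu$noise_amp)
  ph <- stats::runif(3, 0, 2 * pi)
  list(R = R, e = e, psi = psi, ck = ck, ph = ph)
}

lumen_radius_at <- function(shape, theta_deg) {
  a <- shape$R
  b <- shape$R * (1 - shape$e)
  th <- (theta_deg - shape$psi) * pi / 180
  r <- a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
  thr <- theta_deg * pi / 180
  mod <- 1
  for (k in 1:3) mod <- mod + shape$ck[k] * cos((k + 1) * thr + shape$ph[k])
  r * mod
}

# Build one pre-phase frame.  The catheter sits on the patient's bias ray
# at either a positive clearance (non-contact) or a negative clearance
# (pressed into the wall); the intima is clamped just outside the catheter
# so indentation produces a contact arc, as a soft wall molding around the
# probe would.
#' Generate one pre-phase cross-sectional frame
#'
#' @param config an [generator_config()].
#' @param patient_state list with at least `bias_dir` (degrees); see
#'   [generate_study()] for how per-patient state is built.
#' @param frame_id,z frame identity and pullback position (mm).
#' @return an [cross_section()]; draws from the current RNG stream.
#' @export
generate_frame <- function(config, patient_state, frame_id = 1L, z = 0) {
  cfg <- config
  rc <- cfg$catheter_radius
  clear <- 0.005  # radial clearance of the molded intima over the catheter
  for (attempt in 1:20) {
    shape <- sample_lumen_shape(cfg)
    V <- stats::runif(2, -0.5, 0.5)
    phi <- deg_norm(patient_state$bias_dir +
                      stats::rnorm(1, 0, cfg$bias$drift_sd))
    t_im <- stats::runif(1, cfg$wall$im_thickness_range[1],
                         cfg$wall$im_thickness_range[2])
    t_me <- stats::runif(1, cfg$wall$me_thickness_range[1],
                         cfg$wall$me_thickness_range[2])
    contact <- stats::runif(1) < cfg$bias$p_contact
    r_phi <- lumen_radius_at(shape, phi)
    if (contact) {
      press_hi <- min(cfg$bias$press_range[2], t_im - 0.05)
      if (press_hi <= cfg$bias$press_range[1]) next
      gap <- -stats::runif(1, cfg$bias$press_range[1], press_hi)
    } else {
      gap_hi <- min(cfg$bias$gap_range[2], r_phi - rc - 0.08)
      if (gap_hi <= cfg$bias$gap_range[1]) next
      gap <- stats::runif(1, cfg$bias$gap_range[1], gap_hi)
    }
    vc_dist <- r_phi - rc - gap
    if (vc_dist < 0.08) next
    C <- V + vc_dist * c(cos(phi * pi / 180), sin(phi * pi / 180))
    nv <- cfg$lumen$n_vertices
    th0 <- stats::runif(1, 0, 360 / nv)
    theta <- th0 + (seq_len(nv) - 1) * 360 / nv
    r <- lumen_radius_at(shape, theta)
    pts <- cbind(V[1] + r * cos(theta * pi / 180),
                 V[2] + r * sin(theta * pi / 180))
    # mold the wall around the catheter: no intima point inside rc + clear
    dC <- sqrt((pts[, 1] - C[1])^2 + (pts[, 2] - C[2])^2)
    inside <- dC < rc + clear
    if (any(inside)) {
      f <- (rc + clear) / dC[inside]
      pts[inside, 1] <- C[1] + (pts[inside, 1] - C[1]) * f
      pts[inside, 2] <- C[2] + (pts[inside, 2] - C[2]) * f
    }
    intima <- contour(pts, "intima", check_simple = FALSE)
    if (!point_in_contour(C, intima)) next
    media <- eem <- NULL
    media_pts <- cbind(V[1] + (r + t_im) * cos(theta * pi / 180),
                       V[2] + (r + t_im) * sin(theta * pi / 180))
    if (stats::runif(1) < cfg$wall$p_media_visible) {
      media <- contour(media_pts, "media", check_simple = FALSE)
    }
    if (stats::runif(1) < cfg$wall$p_eem_visible) {
      eem <- contour(cbind(V[1] + (r + t_im + t_me) * cos(theta * pi / 180),
                           V[2] + (r + t_im + t_me) * sin(theta * pi / 180)),
                     "eem", check_simple = FALSE)
    }
    arcs <- list()
    if (stats::runif(1) < cfg$calcium$p_frame) {
      w <- stats::runif(1, cfg$calcium$span_range[1], cfg$calcium$span_range[2])
      s0 <- stats::runif(1, 0, 360)
      arcs <- list(deg_norm(c(s0, s0 + w)))
    }
    cs <- cross_section(frame_id = frame_id, z = z, intima = intima,
                        catheter = catheter_pose(C, rc), media = media,
                        eem = eem, calcium_arcs = arcs)
    attr(cs, "wall_t_im") <- t_im
    return(cs)
  }
  abort_oct("could not sample a geometrically valid frame in 20 attempts",
            "octbias_domain")
}

# Mechanism values the dissection model thresholds on.
frame_mechanism <- function(cs, eps_bias = 0.05) {
  bias <- tryCatch(bias_geometry(cs, eps_bias = eps_bias),
                   octbias_bias_undefined = function(e) NULL)
  if (is.null(bias)) {
    return(list(bias = NULL, d_cmb = NA_real_, touch = NA_real_))
  }
  di <- distance_indices(cs, bias)
  list(bias = bias, d_cmb = unname(di[["d_cmb"]]),
       touch = touch_angle(cs))
}

# Linear predictor of the logistic dissection model (without intercept).
dissection_lp <- function(d_cmb, touch, dis) {
  lp <- dis$slope_a * (touch - dis$tau_a)
  if (!is.na(d_cmb)) lp <- lp + dis$slope_d * (dis$tau_d - d_cmb)
  lp
}

#' Apply the dissection model to a pre-phase frame
#'
#' Measures `d_cmb` and the touch angle on the pre frame and decides the
#' post-phase dissection status.  In threshold mode the frame dissects iff
#' `d_cmb < tau_d` or `touch_angle > tau_a` (a missing media drops the
#' distance term); in logistic mode the dissection is Bernoulli with a
#' logit linear in `(tau_d - d_cmb)` and `(touch_angle - tau_a)`.  A
#' dissected frame receives a flap arc placed inside the pre-phase bias
#' quadrant and a subintimal catheter flag with probability
#' `p_entrapment`; non-dissected frames get mild lumen enlargement (the
#' ablation effect).
#'
#' @param pre an [cross_section()] pre-phase frame.
#' @param config an [generator_config()].
#' @param mech optional precomputed [frame mechanism] list (internal use).
#' @return list with `post` (an [cross_section()]), `dissected`,
#'   `mechanism` (`"d_cmb"`, `"touch"`, `"both"`, `"none"` or
#'   `"logistic"`), `d_cmb`, `touch`, `entrapped`, `flap_arc`.  Draws from
#'   the current RNG stream.
#' @export
apply_dissection_model <- function(pre, config, mech = NULL) {
  cfg <- config
  dis <- cfg$dissection
  if (is.null(mech)) mech <- frame_mechanism(pre)
  d_cmb <- mech$d_cmb; touch <- mech$touch
  if (is.null(mech$bias)) {
    dissected <- FALSE
    mechanism <- "bias_undefined"
  } else if (dis$mode == "threshold") {
    hit_d <- !is.na(d_cmb) && d_cmb < dis$tau_d
    hit_a <- touch > dis$tau_a
    dissected <- hit_d || hit_a
    mechanism <- if (hit_d && hit_a) "both" else if (hit_d) "d_cmb"
                 else if (hit_a) "touch" else "none"
  } else {
    b0 <- if (is.null(dis$intercept)) 0 else dis$intercept
    p <- stats::plogis(b0 + dissection_lp(d_cmb, touch, dis))
    dissected <- stats::runif(1) < p
    mechanism <- "logistic"
  }
  # post-phase lumen: mild enlargement about the vessel center, re-molded
  # around the (unchanged) catheter pose
  g <- stats::runif(1, cfg$lumen_growth[1], cfg$lumen_growth[2])
  V <- centroid(pre$intima)
  pts <- pre$intima$vertices
  pts <- cbind(V[1] + (1 + g) * (pts[, 1] - V[1]),
               V[2] + (1 + g) * (pts[, 2] - V[2]))
  C <- pre$catheter$center
  rc <- pre$catheter$radius
  dC <- sqrt((pts[, 1] - C[1])^2 + (pts[, 2] - C[2])^2)
  inside <- dC < rc + 0.005
  if (any(inside)) {
    f <- (rc + 0.005) / dC[inside]
    pts[inside, ] <- cbind(C[1] + (pts[inside, 1] - C[1]) * f,
                           C[2] + (pts[inside, 2] - C[2]) * f)
  }
  post_intima <- contour(pts, "intima", check_simple = FALSE)
  flap_arc <- NULL
  entrapped <- FALSE
  ann <- NULL
  if (dissected) {
    q <- mech$bias$quadrant
    w <- stats::runif(1, cfg$flap$span_range[1], cfg$flap$span_range[2])
    ctr <- mech$bias$bias_angle + stats::runif(1, -(45 - w / 2), 45 - w / 2)
    flap_arc <- deg_norm(c(ctr - w / 2, ctr + w / 2))
    entrapped <- stats::runif(1) < cfg$flap$p_entrapment
    ann <- dissection(TRUE, arc = flap_arc, depth = "intimal",
                      catheter_subintimal = entrapped)
  }
  post <- cross_section(frame_id = pre$frame_id, z = pre$z,
                        intima = post_intima,
                        catheter = pre$catheter,
                        media = pre$media, eem = pre$eem,
                        calcium_arcs = pre$calcium_arcs,
                        dissection = ann, check = FALSE)
  list(post = post, dissected = dissected, mechanism = mechanism,
       d_cmb = d_cmb, touch = touch, entrapped = entrapped,
       flap_arc = flap_arc)
}

#' Generate a full paired synthetic study
#'
#' Draws per-patient state (bias direction, frame count, burr size,
#' reference vessel diameter), builds the pre-phase pullbacks at 1-mm
#' spacing, applies the dissection model frame by frame, and assembles the
#' post-phase pullbacks with a per-patient longitudinal shift (so the
#' landmark alignment stage has work to do).  In logistic mode with a
#' `NULL` intercept, the intercept is calibrated on the generated cohort
#' so the expected event fraction matches `target_rate`.
#'
#' Everything is a deterministic function of the config (including its
#' seed); the caller's RNG state is untouched.
#'
#' @param config an [generator_config()].
#' @return list of class `oct_study`: `pre` and `post` (lists of
#'   [pullback()]), `truth` (per-frame ground-truth data.frame), `meta`
#'   (per-patient data.frame with burr size, reference diameter, BTV),
#'   `config`.
#' @export
generate_study <- function(config = generator_config()) {
  cfg <- config
  local_rng(cfg$seed, {
    patients <- lapply(seq_len(cfg$n_patients), function(p) {
      burr <- min(max(stats::rnorm(1, 1.65, 0.20), 1.25), 2.15)
      ref <- min(max(stats::rnorm(1, 3.18, 0.47), 2.25), 4.25)
      list(patient_id = sprintf("P%02d", p),
           bias_dir = stats::runif(1, 0, 360),
           n_frames = sample(seq(cfg$frames_per_patient[1],
                                 cfg$frames_per_patient[2]), 1),
           burr = burr, ref = ref,
           z_shift = stats::runif(1, 0, 2))
    })
    # pass 1: pre-phase frames and mechanism values
    pre_frames <- vector("list", cfg$n_patients)
    mechs <- vector("list", cfg$n_patients)
    for (p in seq_len(cfg$n_patients)) {
      ps <- patients[[p]]
      z <- seq_len(ps$n_frames) - 1 + 0.05 +
        stats::runif(ps$n_frames, -0.05, 0.05)
      frames <- lapply(seq_len(ps$n_frames), function(i) {
        generate_frame(cfg, ps, frame_id = i, z = z[i])
      })
      pre_frames[[p]] <- frames
      mechs[[p]] <- lapply(frames, frame_mechanism)
    }
    # logistic intercept calibration against the cohort's mechanism values
    dis <- cfg$dissection
    if (dis$mode == "logistic" && is.null(dis$intercept)) {
      lp <- unlist(lapply(mechs, function(mm) {
        vapply(mm, function(m) {
          if (is.null(m$bias)) NA_real_ else dissection_lp(m$d_cmb, m$touch, dis)
        }, numeric(1))
      }))
      lp <- lp[!is.na(lp)]
      f <- function(b0) mean(stats::plogis(b0 + lp)) - dis$target_rate
      cfg$dissection$intercept <- stats::uniroot(f, c(-60, 60))$root
    }
    # pass 2: dissection outcomes and post-phase pullbacks
    pre_pb <- post_pb <- vector("list", cfg$n_patients)
    truth <- list()
    meta <- list()
    for (p in seq_len(cfg$n_patients)) {
      ps <- patients[[p]]
      frames <- pre_frames[[p]]
      post_frames <- vector("list", length(frames))
      for (i in seq_along(frames)) {
        m <- mechs[[p]][[i]]
        out <- apply_dissection_model(frames[[i]], cfg, mech = m)
        post <- out$post
        post$z <- post$z + ps$z_shift
        post_frames[[i]] <- post
        truth[[length(truth) + 1L]] <- data.frame(
          patient_id = ps$patient_id, frame_id = frames[[i]]$frame_id,
          z_pre = frames[[i]]$z,
          bias_angle = if (is.null(m$bias)) NA_real_ else m$bias$bias_angle,
          d_cmb = m$d_cmb, touch_angle = m$touch,
          media_visible = !is.null(frames[[i]]$media),
          dissected = out$dissected, mechanism = out$mechanism,
          entrapped = out$entrapped,
          flap_lo = if (is.null(out$flap_arc)) NA_real_ else out$flap_arc[1],
          flap_hi = if (is.null(out$flap_arc)) NA_real_ else out$flap_arc[2])
      }
      z <- vapply(frames, function(f) f$z, numeric(1))
      lm_z <- z[ceiling(length(z) / 2)]
      pre_pb[[p]] <- pullback(ps$patient_id, "pre", frames,
                              landmark_z = lm_z,
                              analysis_span = c(min(z), max(z)))
      post_pb[[p]] <- pullback(ps$patient_id, "post", post_frames,
                               landmark_z = lm_z + ps$z_shift)
      meta[[p]] <- data.frame(patient_id = ps$patient_id,
                              final_burr_size = ps$burr,
                              reference_vessel_diameter = ps$ref,
                              btv = compute_btv(ps$burr, ps$ref),
                              z_shift = ps$z_shift)
    }
    structure(list(pre = pre_pb, post = post_pb,
                   truth = do.call(rbind, truth),
                   meta = do.call(rbind, meta),
                   config = cfg),
              class = "oct_study")
  })
}

#' @export
print.oct_study <- function(x, ...) {
  cat(sprintf("<oct_study %d patients, %d frames, %d dissected (%.1f%%)>\n",
              length(x$pre), nrow(x$truth), sum(x$truth$dissected),
              100 * mean(x$truth$dissected)))
  invisible(x)
}

#' Second-reader copy of a pullback
#'
#' Emulates a second observer: every contour vertex is jittered with
#' isotropic Gaussian noise and the dissection-present label is flipped
#' with a small probability, leaving everything else identical.  Used for
#' the inter-observer agreement stage (ICC, kappa).
#'
#' @param pb an [pullback()].
#' @param config an [generator_config()] (its `observer` block is used).
#' @param seed integer seed.
#' @return a new [pullback()].
#' @export
second_reader <- function(pb, config = generator_config(), seed = 1L) {
  ob <- config$observer
  jit <- function(ct) {
    if (is.null(ct)) return(NULL)
    v <- ct$vertices
    v <- v + matrix(stats::rnorm(length(v), 0, ob$vertex_jitter_sd),
                    ncol = 2)
    contour(v, ct$role, check_simple = FALSE)
  }
  local_rng(seed, {
    frames <- lapply(pb$frames, function(cs) {
      ann <- cs$dissection
      if (!is.null(ann) && stats::runif(1) < ob$label_flip_p) {
        ann <- if (ann$present) dissection(FALSE) else
          dissection(TRUE, arc = c(0, 20), depth = "intimal")
      }
      cross_section(cs$frame_id, cs$z, jit(cs$intima),
                    cs$catheter, media = jit(cs$media), eem = jit(cs$eem),
                    calcium_arcs = cs$calcium_arcs, dissection = ann,
                    check = FALSE)
    })
    pullback(pb$patient_id, pb$phase, frames, landmark_z = pb$landmark_z,
             analysis_span = pb$analysis_span)
  })
}

#' Add index-level measurement noise
#'
#' Perturbs the distance indices and the touch angle of a measurement
#' table with independent Gaussian noise, emulating reader variability at
#' the index level (distances in mm, angle in degrees; the touch angle is
#' clamped at 0).
#'
#' @param df a measurement data.frame with columns `d_cib`, `d_cio`,
#'   `d_cmb`, `d_cmo`, `touch_angle_deg`.
#' @param distance_sd,angle_sd noise standard deviations.
#' @param seed integer seed.
#' @return the perturbed data.frame.
#' @export
add_measurement_noise <- function(df, distance_sd = 0, angle_sd = 0,
                                  seed = 1L) {
  local_rng(seed, {
    for (col in c("d_cib", "d_cio", "d_cmb", "d_cmo")) {
      if (col %in% names(df) && distance_sd > 0) {
        df[[col]] <- df[[col]] + stats::rnorm(nrow(df), 0, distance_sd)
      }
    }
    if ("touch_angle_deg" %in% names(df) && angle_sd > 0) {
      df$touch_angle_deg <- pmax(0, df$touch_angle_deg +
                                   stats::rnorm(nrow(df), 0, angle_sd))
    }
    df
  })
}
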