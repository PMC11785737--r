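#' Canonical neutral face layout
#'
#' A fixed 478 x 3 point cloud in a unit box, with the landmark indices used
#' by the canonical feature table placed at anatomically plausible relative
#' positions (brows, eyes, nose, mouth, jaw); the remaining indices are laid
#' out deterministically on concentric face-shaped ellipses. Coordinates are
#' in normalized image space with y pointing up and z a shallow depth
#' offset. The layout makes no claim of fidelity to any real face-mesh
#' topology beyond the index count.
#'
#' @return A 478 x 3 numeric matrix.
#' @export
canonical_face_layout <- function() {
  pts <- matrix(NA_real_, N_LANDMARKS, 3)
  # indices are 0-based (the mesh convention); +1 when writing into pts
  anchor <- rbind(
    # idx      x      y      z
    c(1,   0.500, 0.520, 0.100),  # nose tip
    c(5,   0.500, 0.480, 0.080),  # nose base
    c(6,   0.500, 0.620, 0.050),  # nose bridge
    c(14,  0.500, 0.390, 0.030),  # upper inner lip
    c(15,  0.500, 0.350, 0.030),  # lower inner lip
    c(18,  0.500, 0.280, 0.020),  # chin / lower lip midline
    c(25,  0.360, 0.600, 0.000),  # left eye outer region
    c(28,  0.620, 0.660, 0.000),  # right brow
    c(33,  0.400, 0.600, 0.000),  # left eye corner
    c(34,  0.300, 0.580, 0.000),  # left face edge
    c(42,  0.440, 0.370, 0.020),  # mouth ring left
    c(51,  0.480, 0.550, 0.060),  # nose side
    c(55,  0.430, 0.680, 0.000),  # left brow inner
    c(62,  0.420, 0.375, 0.020),  # mouth corner left
    c(71,  0.350, 0.720, 0.000),  # forehead left
    c(75,  0.460, 0.500, 0.050),  # nose wing
    c(79,  0.450, 0.375, 0.025),  # inner lip left
    c(106, 0.420, 0.300, 0.010),  # jaw left
    c(108, 0.450, 0.780, 0.000),  # forehead
    c(146, 0.470, 0.330, 0.020),  # lower lip left
    c(160, 0.380, 0.615, 0.000),  # left upper lid
    c(207, 0.400, 0.440, 0.020),  # cheek left
    c(292, 0.580, 0.375, 0.020),  # mouth corner right
    c(309, 0.550, 0.375, 0.025))  # inner lip right
  pts[anchor[, 1] + 1, ] <- anchor[, 2:4]
  free <- which(is.na(pts[, 1]))
  k <- seq_along(free)
  ring <- 0.12 + 0.28 * ((k * 7) %% length(free)) / length(free)
  ang <- 2 * pi * k / length(free)
  pts[free, 1] <- 0.5 + ring * cos(ang)
  pts[free, 2] <- 0.5 + 1.25 * ring * sin(ang)
  pts[free, 3] <- 0.04 * cos(ang) * (0.4 - ring)
  dimnames(pts) <- list(NULL, c("x", "y", "z"))
  pts
}

#' Generate a per-subject face template
#'
#' Jitters the canonical layout with seeded Gaussian offsets so subjects
#' differ in facial proportions, plus a per-subject global scale. Distance
#' ratios are reference-normalized downstream, so subject geometry mostly
#' cancels — exactly the robustness property the ratio features exist for.
#'
#' @param subject_seed Integer seed; identical seeds give identical
#'   templates.
#' @param jitter_sd Per-coordinate jitter standard deviation (normalized
#'   image units).
#' @return A `face_template`: list with `subject_id`, `base_points`,
#'   `scale`, `seed`.
#' @export
make_template <- function(subject_seed, jitter_sd = 0.004) {
  base <- canonical_face_layout()
  with_seed(subject_seed, {
    scale <- stats::runif(1, 0.9, 1.1)
    jitter <- matrix(stats::rnorm(length(base), 0, jitter_sd),
                     nrow(base), ncol(base))
    pts <- 0.5 + (base + jitter - 0.5) * scale
    structure(list(subject_id = sprintf("s%03d", as.integer(subject_seed %% 1000)),
                   base_points = pts, scale = scale,
                   seed = as.integer(subject_seed)),
              class = "face_template")
  })
}

# Displacement field (478 x 3, intensity 1) for one emotion.
# Positive expressions open/widen the mouth region (affected distance
# ratios fall below 1); negative expressions compress mouth and brow
# distances (ratios rise above 1); neutral is the identity. Magnitudes move
# the affected current-frame distances by roughly 20-100% at intensity 1.
expression_displacement <- function(emotion) {
  D <- matrix(0, N_LANDMARKS, 3)
  add <- function(idx0, dx, dy) {
    D[idx0 + 1, 1] <<- D[idx0 + 1, 1] + dx
    D[idx0 + 1, 2] <<- D[idx0 + 1, 2] + dy
  }
  switch(emotion,
    neutral = NULL,
    happiness = {
      add(62, -0.030, 0.012); add(292, 0.030, 0.012)   # corners out and up
      add(79, -0.018, 0.008); add(309, 0.018, 0.008)
      add(14, 0, 0.004); add(15, 0, -0.004)            # lips part slightly
      add(207, 0, 0.010)                               # cheek raise
    },
    surprise = {
      add(14, 0, 0.008); add(15, 0, -0.030)            # mouth opens wide
      add(18, 0, -0.045); add(146, 0, -0.030)          # jaw drops
      add(106, 0, -0.025)
      for (i in c(33, 55, 25, 160)) add(i, 0, 0.025)   # brows raise
      add(28, 0, 0.025); add(71, 0, 0.020)
    },
    anger = {
      add(55, 0.008, -0.022); add(28, -0.008, -0.022)  # brows down and in
      add(33, 0.006, -0.015); add(25, 0.006, -0.015); add(160, 0, -0.012)
      add(14, 0, -0.010); add(15, 0, 0.010)            # lips pressed
      add(62, 0.015, 0); add(292, -0.015, 0)           # mouth narrows
      add(18, 0, 0.010)
    },
    disgust = {
      add(51, 0, 0.012); add(75, 0, 0.010); add(5, 0, 0.006)  # nose scrunch
      add(15, 0, 0.014)                                # upper-lip raise closes gap
      add(62, 0.018, 0); add(292, -0.018, 0)
      add(55, 0, -0.012); add(28, 0, -0.012)
    },
    fear = {
      add(62, 0.012, -0.008); add(292, -0.012, -0.008) # corners retract
      add(15, 0, 0.008)
      add(55, 0.004, 0.015); add(28, -0.004, 0.015)    # inner brows up
      add(160, 0, 0.010)
    },
    sadness = {
      add(62, 0.010, -0.015); add(292, -0.010, -0.015) # corners droop
      add(79, 0.006, -0.008); add(309, -0.006, -0.008)
      add(15, 0, 0.006); add(55, 0, 0.010); add(18, 0, 0.008)
    },
    stop_fm("label", sprintf("unknown emotion: %s", emotion)))
  D
}

#' Deform a face template into an expression frame
#'
#' Applies the emotion's displacement field scaled by `intensity` (0 is the
#' identity; the deformation is deterministic given intensity), then adds
#' isotropic Gaussian coordinate noise emulating landmark-estimator jitter.
#'
#' @param template A `face_template`.
#' @param emotion Seven-class name.
#' @param intensity Expression intensity in \[0, 1\].
#' @param noise_sd Per-coordinate noise standard deviation.
#' @param noise_seed Integer seed for the noise draw.
#' @param frame_index Frame counter recorded in the output frame.
#' @return A `landmark_frame`.
#' @export
apply_expression <- function(template, emotion, intensity = 1,
                             noise_sd = 0, noise_seed = 0L,
                             frame_index = 0L) {
  stopifnot(inherits(template, "face_template"))
  if (intensity < 0 || intensity > 1) {
    stop_fm("config", "intensity must lie in [0, 1]")
  }
  pts <- template$base_points +
    intensity * template$scale * expression_displacement(emotion)
  if (noise_sd > 0) {
    pts <- pts + with_seed(noise_seed, {
      matrix(stats::rnorm(length(pts), 0, noise_sd), nrow(pts), ncol(pts))
    })
  }
  landmark_frame(pts, subject_id = template$subject_id,
                 frame_index = frame_index)
}

#' Cohort generation specification
#'
#' Defaults produce about 2000 labeled frames: 10 subjects, 29 frames per
#' expression across the seven expressions (2030 frames), expression
#' intensities drawn uniformly from \[0.5, 1\] (the strong representations
#' the study used), and coordinate noise of 0.0015 normalized units.
#'
#' @param n_subjects Number of synthetic subjects.
#' @param frames_per_expression Frames per subject per expression.
#' @param intensity_range Length-2 range of expression intensity.
#' @param noise_sd Coordinate noise standard deviation.
#' @param seed Master seed; identical specs yield identical cohorts.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 10L, frames_per_expression = 29L,
                        intensity_range = c(0.5, 1), noise_sd = 0.0015,
                        seed = 1L) {
  stopifnot(n_subjects >= 1, frames_per_expression >= 1, noise_sd >= 0,
            length(intensity_range) == 2,
            intensity_range[1] <= intensity_range[2],
            intensity_range[1] >= 0, intensity_range[2] <= 1)
  structure(list(n_subjects = as.integer(n_subjects),
                 frames_per_expression = as.integer(frames_per_expression),
                 intensity_range = as.numeric(intensity_range),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a labeled synthetic cohort
#'
#' For each subject: one neutral reference frame plus
#' `frames_per_expression` frames per expression, features extracted against
#' that subject's own reference, labels attached at the seven-class and
#' binary level.
#'
#' @param spec A [cohort_spec()].
#' @param table A `feature_table`.
#' @param include_frames Keep the raw `landmark_frame`s in the result.
#' @return List with `features` (data frame: `R_*`, `theta_*`, `label`,
#'   `binary`, `subject_id`), `references` (one neutral frame per subject)
#'   and, optionally, `frames`.
#' @export
generate_cohort <- function(spec = cohort_spec(),
                            table = default_feature_table(),
                            include_frames = FALSE) {
  scheme <- label_scheme()
  feats <- list(); refs <- list(); raw <- list()
  for (s in seq_len(spec$n_subjects)) {
    # seed arithmetic in doubles, reduced mod 2^31-1 downstream, so large
    # master seeds cannot overflow R's 32-bit integers
    subj_seed <- as.numeric(spec$seed) * 1000 + s
    template <- make_template(subj_seed)
    reference <- apply_expression(template, "neutral", intensity = 0,
                                  noise_sd = spec$noise_sd,
                                  noise_seed = subj_seed * 7L)
    refs[[template$subject_id]] <- reference
    for (e in seq_along(scheme$seven_classes)) {
      emo <- scheme$seven_classes[e]
      for (f in seq_len(spec$frames_per_expression)) {
        fseed <- (subj_seed * 3000 + e * 101 + f) %% 2147483647
        intensity <- with_seed(fseed, {
          stats::runif(1, spec$intensity_range[1], spec$intensity_range[2])
        })
        frame <- apply_expression(template, emo, intensity = intensity,
                                  noise_sd = spec$noise_sd,
                                  noise_seed = fseed + 1L, frame_index = f)
        fv <- extract_features(frame, reference, table)
        feats[[length(feats) + 1L]] <- c(
          as.list(c(fv$ratios, fv$angles)),
          list(label = emo, binary = scheme$binary_map[[emo]],
               subject_id = template$subject_id))
        if (include_frames) raw[[length(raw) + 1L]] <- frame
      }
    }
  }
  features <- do.call(rbind, lapply(feats, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  out <- list(features = features, references = refs)
  if (include_frames) out$frames <- raw
  out
}

#' Generate per-attempt session frame streams with controllable skill
#'
#' Emulates a participant mimicking the avatar: each frame of an attempt
#' window portrays the requested expression with the per-emotion success
#' probability `skill`, and otherwise a confuser expression drawn from the
#' opposite binary class — so an oracle-quality classifier sees exactly a
#' `skill` fraction of correct frames. Streams are deterministic given the
#' spec seed, expression and attempt number.
#'
#' @param spec A [cohort_spec()] (its `seed` and `noise_sd` are used; the
#'   subject is the spec's first subject).
#' @param skill Named numeric vector of per-emotion success probabilities in
#'   \[0, 1\] (missing names default to 1), or a single number.
#' @param config A [session_config()] fixing the window length.
#' @return List with `provider` — a function `(expression, attempt_number)`
#'   returning the window's frames, suitable for [run_session()] — and the
#'   subject's neutral `reference` frame.
#' @export
generate_session_streams <- function(spec = cohort_spec(),
                                     skill = 1,
                                     config = session_config()) {
  scheme <- label_scheme()
  if (length(skill) == 1 && is.null(names(skill))) {
    skill <- stats::setNames(rep(skill, 7), scheme$seven_classes)
  }
  full_skill <- stats::setNames(rep(1, 7), scheme$seven_classes)
  full_skill[names(skill)] <- skill
  if (any(full_skill < 0 | full_skill > 1)) {
    stop_fm("config", "skill probabilities must lie in [0, 1]")
  }
  subj_seed <- as.numeric(spec$seed) * 1000 + 1
  template <- make_template(subj_seed)
  reference <- apply_expression(template, "neutral", intensity = 0,
                                noise_sd = spec$noise_sd,
                                noise_seed = subj_seed * 7L)
  opposite <- list(positive = c("anger", "disgust", "fear", "sadness"),
                   negative = c("happiness", "surprise"))
  n_frames <- window_frames(config)
  provider <- function(expression, attempt_number) {
    e <- match(expression, scheme$seven_classes)
    base_seed <- (as.numeric(spec$seed) * 100000 + e * 1000 +
                    attempt_number * 50) %% 2147483647
    draws <- with_seed(base_seed, {
      list(ok = stats::runif(n_frames) < full_skill[[expression]],
           confuser = sample(opposite[[scheme$binary_map[[expression]]]],
                             n_frames, replace = TRUE))
    })
    lapply(seq_len(n_frames), function(f) {
      emo <- if (draws$ok[f]) expression else draws$confuser[f]
      apply_expression(template, emo, intensity = 0.9,
                       noise_sd = spec$noise_sd,
                       noise_seed = base_seed + f, frame_index = f)
    })
  }
  list(provider = provider, reference = reference, template = template)
}
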