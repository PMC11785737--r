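test_that("euclidean_distance matches hand geometry and its metric axioms", {
  expect_equal(euclidean_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(euclidean_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(euclidean_distance(c(1, 1, 1), c(2, 2, 2)), sqrt(3))
  expect_error(euclidean_distance(c(NA, 0, 0), c(0, 0, 0)),
               class = "fm_invalid_input_error")
  set.seed(101)
  for (i in 1:25) {
    p <- rnorm(3); q <- rnorm(3); r <- rnorm(3)
    expect_equal(euclidean_distance(p, q), euclidean_distance(q, p))
    expect_gte(euclidean_distance(p, q), 0)
    expect_lte(euclidean_distance(p, r),
               euclidean_distance(p, q) + euclidean_distance(q, r) + 1e-12)
  }
})

test_that("segment_angle is the planar atan2 difference wrapped to (-180, 180]", {
  expect_equal(segment_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  expect_equal(segment_angle(c(1, 0, 0), c(0, 0, 0), c(1, 0, 0)), 0)
  expect_equal(segment_angle(c(1, 0, 0), c(0, 0, 0), c(-1, 0, 0)), 180)
  # z must be ignored
  expect_equal(segment_angle(c(1, 0, 5), c(0, 0, -2), c(0, 1, 9)), 90)
  expect_error(segment_angle(c(0, 0, 1), c(0, 0, 0), c(1, 0, 0)),
               class = "fm_degenerate_geometry_error")
  set.seed(102)
  for (i in 1:50) {
    ang <- segment_angle(rnorm(3), rnorm(3), rnorm(3))
    expect_gt(ang, -180)
    expect_lte(ang, 180)
  }
})

test_that("distance_ratio puts the reference distance in the numerator", {
  expect_equal(distance_ratio(2, 2), 1)
  expect_equal(distance_ratio(2, 1), 2)
  expect_error(distance_ratio(2, 0, feature_index = 3),
               class = "fm_degenerate_distance_error")
  expect_error(distance_ratio(-1, 2), class = "fm_degenerate_distance_error")
})

test_that("feature tables validate indices and ship the canonical parse", {
  tab <- default_feature_table()
  expect_equal(nrow(tab$distance_pairs), 10)
  expect_equal(nrow(tab$angle_triples), 5)
  ext <- default_feature_table(extended = TRUE)
  expect_equal(nrow(ext$distance_pairs), 11)
  expect_equal(unname(ext$distance_pairs[11, ]), c(18L, 106L))
  expect_error(feature_table(rbind(c(1, 1)), rbind(c(1, 2, 3))),
               class = "fm_config_error")
  expect_error(feature_table(rbind(c(1, 500)), rbind(c(1, 2, 3))),
               class = "fm_config_error")
  expect_error(feature_table(rbind(c(1, 2)), rbind(c(1, 1, 3))),
               class = "fm_config_error")
  # index_base 1 shifts a table onto the same 0-based storage
  shifted <- feature_table(tab$distance_pairs + 1L, tab$angle_triples + 1L,
                           index_base = 1)
  expect_equal(shifted$distance_pairs, tab$distance_pairs)
})

test_that("extract_features is the identity on identical frames", {
  neutral <- fixture_neutral()
  for (tab in list(default_feature_table(), default_feature_table(TRUE))) {
    fv <- extract_features(neutral, neutral, tab)
    expect_equal(unname(fv$ratios), rep(1, nrow(tab$distance_pairs)))
    expect_equal(length(as.numeric(fv)),
                 nrow(tab$distance_pairs) + nrow(tab$angle_triples))
  }
  expect_length(as.numeric(extract_features(neutral, neutral)), 15)
  expect_length(
    as.numeric(extract_features(neutral, neutral,
                                default_feature_table(TRUE))), 16)
})

test_that("uniform scaling divides every ratio by s and keeps angles", {
  neutral <- fixture_neutral()
  base <- extract_features(neutral, neutral)
  for (s in c(0.5, 2, 3.7)) {
    scaled <- landmark_frame(0.5 + (neutral$points - 0.5) * s)
    fv <- extract_features(scaled, neutral)
    expect_equal(unname(fv$ratios), rep(1 / s, 10), tolerance = 1e-12)
    expect_equal(fv$angles, base$angles, tolerance = 1e-9)
  }
})

test_that("x-y rotation shifts all angles by a constant and keeps ratios", {
  neutral <- fixture_neutral()
  base <- extract_features(neutral, neutral)
  for (phi_deg in c(30, -75, 145)) {
    phi <- phi_deg * pi / 180
    R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
    pts <- neutral$points
    pts[, 1:2] <- sweep(sweep(pts[, 1:2], 2, c(0.5, 0.5)) %*% t(R),
                        2, c(0.5, 0.5), "+")
    fv <- extract_features(landmark_frame(pts), neutral)
    expect_equal(unname(fv$ratios), rep(1, 10), tolerance = 1e-9)
    # all angles change by the same additive constant mod 360 (here: zero,
    # because both rays rotate together)
    diffs <- (fv$angles - base$angles) %% 360
    diffs <- ifelse(diffs > 180, diffs - 360, diffs)
    expect_equal(unname(diffs), rep(0, 5), tolerance = 1e-9)
  }
})

test_that("degenerate reference distances raise an identifying error", {
  neutral <- fixture_neutral()
  pts <- neutral$points
  pts[15, ] <- pts[16, ]   # collapse the (14, 15) pair (0-based indices)
  broken <- landmark_frame(pts)
  err <- expect_error(extract_features(neutral, broken),
                      class = "fm_feature_extraction_error")
  expect_match(conditionMessage(err), "14, 15")
})

test_that("landmark frame and feature CSV/JSONL round-trips preserve data", {
  tmpl <- fixture_template()
  frames <- list(
    apply_expression(tmpl, "happiness", 0.7, 0.001, 5L, frame_index = 0L),
    apply_expression(tmpl, "anger", 0.9, 0.001, 6L, frame_index = 1L))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_landmarks_csv(frames, csv)
  back <- read_landmarks_csv(csv)
  expect_length(back, 2)
  expect_equal(back[[1]]$points, frames[[1]]$points, tolerance = 1e-12)
  expect_equal(back[[2]]$frame_index, 1L)

  jl <- withr::local_tempfile(fileext = ".jsonl")
  write_landmarks_jsonl(frames, jl)
  back2 <- read_landmarks_jsonl(jl)
  expect_equal(back2[[2]]$points, frames[[2]]$points, tolerance = 1e-12)

  feats <- extract_feature_frame(frames, fixture_neutral(),
                                 labels = c("happiness", "anger"))
  fcsv <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(feats, fcsv)
  expect_equal(read_feature_csv(fcsv), feats, tolerance = 1e-12)
})

test_that("feature table YAML round-trips, including 1-based declarations", {
  tab <- default_feature_table(extended = TRUE)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_feature_table_yaml(tab, path)
  back <- read_feature_table_yaml(path)
  expect_equal(back$distance_pairs, tab$distance_pairs)
  expect_equal(back$angle_triples, tab$angle_triples)
})
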