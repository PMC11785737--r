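#' Number of points in a face-mesh landmark frame
#'
#' The landmark estimator this toolkit targets emits 478 indexed 3D points
#' per face; every frame is validated against this count.
#' @export
N_LANDMARKS <- 478L

#' Euclidean distance between two 3D landmark points
#'
#' Standard 3D Euclidean norm of the coordinate difference. Used for the
#' distance features `d_n` between the landmark pairs of a feature table.
#'
#' @param p1,p2 Numeric length-3 vectors `(x, y, z)`.
#' @return Non-negative scalar distance.
#' @examples
#' euclidean_distance(c(0, 0, 0), c(3, 4, 0)) # 5
#' @export
euclidean_distance <- function(p1, p2) {
  p1 <- as.numeric(p1)
  p2 <- as.numeric(p2)
  if (length(p1) != 3L || length(p2) != 3L) {
    stop_fm("invalid_input", "points must have exactly 3 coordinates")
  }
  if (!all(is.finite(p1)) || !all(is.finite(p2))) {
    stop_fm("invalid_input", "non-finite coordinates in distance computation")
  }
  sqrt(sum((p1 - p2)^2))
}

#' Signed planar angle at a landmark vertex
#'
#' Angle at vertex `p2` between the rays `p2 -> p3` and `p2 -> p1`, computed
#' from the two-argument arctangent of each ray's `(dy, dx)` projection onto
#' the x-y plane and wrapped to `(-180, 180]` degrees. The z coordinate is
#' ignored: angle features are planar while distance features are 3D.
#'
#' @param p1,p2,p3 Numeric length-3 vectors; `p2` is the vertex.
#' @return Angle in degrees in `(-180, 180]`.
#' @examples
#' segment_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)) # 90
#' @export
segment_angle <- function(p1, p2, p3) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2); p3 <- as.numeric(p3)
  if (!all(is.finite(c(p1, p2, p3)))) {
    stop_fm("invalid_input", "non-finite coordinates in angle computation")
  }
  v1 <- p1[1:2] - p2[1:2]
  v3 <- p3[1:2] - p2[1:2]
  if (all(v1 == 0) || all(v3 == 0)) {
    stop_fm("degenerate_geometry",
            "zero-length ray projection in the x-y plane at the angle vertex")
  }
  deg <- (atan2(v3[2], v3[1]) - atan2(v1[2], v1[1])) * 180 / pi
  wrap_degrees(deg)
}

# wrap an angle in degrees to (-180, 180]
wrap_degrees <- function(deg) {
  out <- deg %% 360
  ifelse(out > 180, out - 360, out)
}

#' Reference-to-current distance ratio
#'
#' One ratio feature `R_n = d_ref / d_cur`: the distance measured on the
#' subject's neutral reference frame divided by the same pair's distance on
#' the current frame. Ratios below 1 mean the pair moved apart relative to
#' neutral; above 1, closer together.
#'
#' @param d_reference Distance on the neutral reference frame (positive).
#' @param d_current Distance on the current frame (positive).
#' @param feature_index Optional index used in error messages.
#' @return Positive scalar ratio.
#' @export
distance_ratio <- function(d_reference, d_current, feature_index = NA) {
  if (!is.finite(d_current) || d_current <= 0) {
    stop_fm("degenerate_distance", sprintf(
      "current-frame distance for ratio feature %s is not strictly positive",
      feature_index))
  }
  if (!is.finite(d_reference) || d_reference <= 0) {
    stop_fm("degenerate_distance", sprintf(
      "reference-frame distance for ratio feature %s is not strictly positive",
      feature_index))
  }
  d_reference / d_current
}

#' Construct a landmark frame
#'
#' One timestamped cloud of 478 3D facial points for one subject.
#'
#' @param points A 478 x 3 numeric matrix (columns x, y, z).
#' @param subject_id Subject identifier string.
#' @param frame_index Non-negative integer frame counter.
#' @return An object of class `landmark_frame`.
#' @export
landmark_frame <- function(points, subject_id = "s00", frame_index = 0L) {
  points <- as.matrix(points)
  if (nrow(points) != N_LANDMARKS || ncol(points) != 3L) {
    stop_fm("invalid_input", sprintf(
      "a landmark frame needs exactly %d points with 3 coordinates, got %d x %d",
      N_LANDMARKS, nrow(points), ncol(points)))
  }
  frame_index <- as.integer(frame_index)
  if (is.na(frame_index) || frame_index < 0L) {
    stop_fm("invalid_input", "frame_index must be a non-negative integer")
  }
  storage.mode(points) <- "double"
  dimnames(points) <- list(NULL, c("x", "y", "z"))
  structure(
    list(points = points, subject_id = as.character(subject_id),
         frame_index = frame_index),
    class = "landmark_frame")
}

#' @export
print.landmark_frame <- function(x, ...) {
  cat(sprintf("<landmark_frame> subject %s, frame %d, %d points\n",
              x$subject_id, x$frame_index, nrow(x$points)))
  invisible(x)
}

# TRUE when a frame carries usable geometry: finite and not all-zero.
# All-zero clouds are the estimator's "no face detected" sentinel.
frame_valid <- function(frame) {
  all(is.finite(frame$points)) && any(frame$points != 0)
}

#' Construct a feature table
#'
#' Names the landmark index pairs (distance features) and index triples
#' (angle features, vertex at the middle index) that define the geometric
#' feature space. Indices are 0-based over the 478-point mesh by default;
#' set `index_base = 1` for tables written against 1-based numbering.
#'
#' @param distance_pairs Integer matrix (or list of length-2 vectors), one
#'   row per distance feature.
#' @param angle_triples Integer matrix (or list of length-3 vectors), one row
#'   per angle feature; the vertex is the middle index.
#' @param index_base 0 or 1.
#' @return An object of class `feature_table` (indices stored 0-based).
#' @export
feature_table <- function(distance_pairs, angle_triples, index_base = 0L) {
  to_mat <- function(x, k) {
    if (is.list(x)) x <- do.call(rbind, x)
    x <- matrix(as.integer(x), ncol = k)
    x
  }
  pairs <- to_mat(distance_pairs, 2L)
  triples <- to_mat(angle_triples, 3L)
  index_base <- as.integer(index_base)
  if (!index_base %in% c(0L, 1L)) {
    stop_fm("config", "index_base must be 0 or 1")
  }
  pairs <- pairs - index_base
  triples <- triples - index_base
  idx <- c(pairs, triples)
  if (any(is.na(idx)) || any(idx < 0L) || any(idx >= N_LANDMARKS)) {
    stop_fm("config", sprintf("landmark indices must lie in [0, %d]",
                              N_LANDMARKS - 1L))
  }
  if (any(pairs[, 1] == pairs[, 2])) {
    stop_fm("config", "a distance pair repeats the same landmark index")
  }
  if (any(triples[, 2] == triples[, 1] | triples[, 2] == triples[, 3])) {
    stop_fm("config", "an angle triple reuses its vertex index")
  }
  structure(
    list(distance_pairs = pairs, angle_triples = triples),
    class = "feature_table")
}

#' The canonical geometric feature table
#'
#' The default configuration has 10 distance pairs and 5 angle triples
#' (a 15-dimensional feature space). The extended configuration appends an
#' eleventh distance pair, between landmarks 18 and 106, added after the
#' feasibility study to sharpen the surprise expression (16 features).
#'
#' @param extended If `TRUE`, include the (18, 106) pair.
#' @return A `feature_table` with 0-based indices.
#' @export
default_feature_table <- function(extended = FALSE) {
  pairs <- rbind(
    c(1L, 18L), c(14L, 15L), c(62L, 292L), c(79L, 309L), c(5L, 292L),
    c(6L, 25L), c(5L, 106L), c(33L, 55L), c(5L, 51L), c(28L, 15L))
  if (isTRUE(extended)) pairs <- rbind(pairs, c(18L, 106L))
  triples <- rbind(
    c(1L, 62L, 18L), c(292L, 1L, 62L), c(42L, 75L, 207L),
    c(160L, 34L, 146L), c(108L, 106L, 71L))
  feature_table(pairs, triples, index_base = 0L)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d distance pairs, %d angle triples (0-based)\n",
              nrow(x$distance_pairs), nrow(x$angle_triples)))
  invisible(x)
}

# distances for every pair of a table on one frame (names d_1..d_N)
table_distances <- function(frame, table) {
  pts <- frame$points
  i <- table$distance_pairs[, 1] + 1L
  j <- table$distance_pairs[, 2] + 1L
  d <- sqrt(rowSums((pts[i, , drop = FALSE] - pts[j, , drop = FALSE])^2))
  names(d) <- paste0("d_", seq_along(d))
  d
}

# planar angles for every triple of a table on one frame (degrees)
table_angles <- function(frame, table) {
  pts <- frame$points
  a <- pts[table$angle_triples[, 1] + 1L, 1:2, drop = FALSE]
  b <- pts[table$angle_triples[, 2] + 1L, 1:2, drop = FALSE]
  c_ <- pts[table$angle_triples[, 3] + 1L, 1:2, drop = FALSE]
  v1 <- a - b
  v3 <- c_ - b
  if (any(rowSums(v1^2) == 0) || any(rowSums(v3^2) == 0)) {
    stop_fm("degenerate_geometry",
            "an angle triple has a zero-length ray projection in the x-y plane")
  }
  deg <- (atan2(v3[, 2], v3[, 1]) - atan2(v1[, 2], v1[, 1])) * 180 / pi
  out <- wrap_degrees(deg)
  names(out) <- paste0("theta_", seq_along(out))
  out
}

#' Extract the geometric feature vector from a landmark frame
#'
#' Computes the reference-to-current distance ratios `R_n` over the table's
#' pairs and the planar angles `theta_m` (current frame only) over its
#' triples. The neutral reference frame is the denominator source for every
#' ratio, which normalizes away per-subject facial proportions.
#'
#' @param current `landmark_frame` captured during expression mimicry.
#' @param reference `landmark_frame` of the subject's neutral expression.
#' @param table A `feature_table`; default is [default_feature_table()].
#' @param label Optional expression label carried along with the vector.
#' @return A `feature_vector`: list with `ratios`, `angles` (degrees) and
#'   `label`. `as.numeric()` flattens it in table order.
#' @export
extract_features <- function(current, reference,
                             table = default_feature_table(), label = NULL) {
  stopifnot(inherits(current, "landmark_frame"),
            inherits(reference, "landmark_frame"),
            inherits(table, "feature_table"))
  d_ref <- table_distances(reference, table)
  d_cur <- table_distances(current, table)
  bad_ref <- which(!is.finite(d_ref) | d_ref <= 0)
  if (length(bad_ref)) {
    stop_fm("feature_extraction", sprintf(
      "degenerate reference distance for pair %d (landmarks %d, %d)",
      bad_ref[1],
      table$distance_pairs[bad_ref[1], 1], table$distance_pairs[bad_ref[1], 2]))
  }
  bad_cur <- which(!is.finite(d_cur) | d_cur <= 0)
  if (length(bad_cur)) {
    stop_fm("feature_extraction", sprintf(
      "degenerate current-frame distance for pair %d (landmarks %d, %d)",
      bad_cur[1],
      table$distance_pairs[bad_cur[1], 1], table$distance_pairs[bad_cur[1], 2]))
  }
  ratios <- d_ref / d_cur
  names(ratios) <- paste0("R_", seq_along(ratios))
  angles <- table_angles(current, table)
  structure(list(ratios = ratios, angles = angles, label = label),
            class = "feature_vector")
}

#' @export
as.double.feature_vector <- function(x, ...) {
  unname(c(x$ratios, x$angles))
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> %d ratios + %d angles%s\n",
              length(x$ratios), length(x$angles),
              if (is.null(x$label)) "" else paste0(", label ", x$label)))
  print(round(c(x$ratios, x$angles), 4))
  invisible(x)
}

#' Extract features for a list of frames into a data frame
#'
#' @param frames List of `landmark_frame`s.
#' @param reference Neutral `landmark_frame`.
#' @param table A `feature_table`.
#' @param labels Optional character vector of labels, recycled to the frames.
#' @return Data frame with columns `R_1..R_N`, `theta_1..theta_M` and,
#'   when labels are given, `label`.
#' @export
extract_feature_frame <- function(frames, reference,
                                  table = default_feature_table(),
                                  labels = NULL) {
  rows <- lapply(frames, function(f) {
    fv <- extract_features(f, reference, table)
    c(fv$ratios, fv$angles)
  })
  out <- as.data.frame(do.call(rbind, rows))
  if (!is.null(labels)) out$label <- rep_len(labels, nrow(out))
  out
}

# ---- file formats -----------------------------------------------------------

#' Write / read landmark frames as long-format CSV
#'
#' One row per point: `subject_id, frame_index, point_index, px, py, pz`,
#' point indices 0-based.
#'
#' @param frames List of `landmark_frame`s.
#' @param path Output path.
#' @return `write_landmarks_csv` returns `path` invisibly;
#'   `read_landmarks_csv` returns a list of `landmark_frame`s.
#' @export
write_landmarks_csv <- function(frames, path) {
  if (inherits(frames, "landmark_frame")) frames <- list(frames)
  tab <- do.call(rbind, lapply(frames, function(f) {
    data.frame(subject_id = f$subject_id, frame_index = f$frame_index,
               point_index = 0:(N_LANDMARKS - 1L),
               px = f$points[, 1], py = f$points[, 2], pz = f$points[, 3])
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmarks_csv
#' @export
read_landmarks_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  key <- paste(tab$subject_id, tab$frame_index, sep = "\r")
  lapply(split(tab, factor(key, levels = unique(key))), function(g) {
    g <- g[order(g$point_index), ]
    landmark_frame(cbind(g$px, g$py, g$pz),
                   subject_id = g$subject_id[1], frame_index = g$frame_index[1])
  }) |> unname()
}

#' Write / read landmark frames as JSON lines
#'
#' One frame object per line with fields `subject_id`, `frame_index` and a
#' 478 x 3 `points` array.
#'
#' @inheritParams write_landmarks_csv
#' @export
write_landmarks_jsonl <- function(frames, path) {
  if (inherits(frames, "landmark_frame")) frames <- list(frames)
  lines <- vapply(frames, function(f) {
    jsonlite::toJSON(list(subject_id = f$subject_id,
                          frame_index = f$frame_index,
                          points = f$points),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_landmarks_jsonl
#' @export
read_landmarks_jsonl <- function(path) {
  lapply(readLines(path), function(line) {
    obj <- jsonlite::fromJSON(line)
    landmark_frame(obj$points, subject_id = obj$subject_id,
                   frame_index = obj$frame_index)
  })
}

#' Write / read a feature data frame as CSV
#'
#' Header `R_1..R_N, theta_1..theta_M, label` as produced by
#' [extract_feature_frame()].
#'
#' @param features Data frame of features (and optional `label`).
#' @param path File path.
#' @export
write_feature_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a feature table as YAML
#'
#' Fields `distance_pairs`, `angle_triples`, `index_base`.
#'
#' @param table A `feature_table`.
#' @param path File path.
#' @export
write_feature_table_yaml <- function(table, path) {
  yaml::write_yaml(list(
    index_base = 0L,
    distance_pairs = apply(table$distance_pairs, 1, as.list),
    angle_triples = apply(table$angle_triples, 1, as.list)), path)
  invisible(path)
}

#' @rdname write_feature_table_yaml
#' @export
read_feature_table_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  feature_table(
    lapply(obj$distance_pairs, unlist),
    lapply(obj$angle_triples, unlist),
    index_base = if (is.null(obj$index_base)) 0L else obj$index_base)
}
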