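#' Canonical 49-point facial landmark layout
#'
#' The 49-point layout used throughout (a standard eyebrow/nose/eye/mouth
#' scheme without the jaw contour): points 1-5 left eyebrow (outer to inner),
#' 6-10 right eyebrow (inner to outer), 11-14 nose bridge (top to tip
#' approach), 15-19 nose bottom (left to right, 17 = nose tip), 20-25 left
#' eye, 26-31 right eye, 32-43 outer lip contour (32 = left corner, 38 =
#' right corner, 35/41 = upper/lower lip midpoints), 44-49 inner lip
#' contour. `face_landmark_template()` returns a bilaterally symmetric
#' template face in a 200 x 200 pixel box (x right, y down).
#'
#' @return `face_landmark_template()`: 49 x 2 numeric matrix.
#'   `face_landmark_groups()`: named list of index vectors.
#' @export
face_landmark_template <- function() {
  pts <- rbind(
    # left brow 1-5 (outer -> inner)
    c(25, 58), c(40, 53), c(55, 51), c(70, 53), c(85, 58),
    # right brow 6-10 (inner -> outer)
    c(115, 58), c(130, 53), c(145, 51), c(160, 53), c(175, 58),
    # nose bridge 11-14
    c(100, 60), c(100, 72), c(100, 84), c(100, 96),
    # nose bottom 15-19 (17 = tip)
    c(82, 105), c(91, 108), c(100, 110), c(109, 108), c(118, 105),
    # left eye 20-25
    c(48, 72), c(57, 68), c(67, 68), c(76, 72), c(67, 76), c(57, 76),
    # right eye 26-31
    c(124, 72), c(133, 68), c(143, 68), c(152, 72), c(143, 76), c(133, 76),
    # outer mouth 32-43
    c(70, 150), c(80, 143), c(90, 140), c(100, 139), c(110, 140), c(120, 143),
    c(130, 150), c(120, 157), c(110, 160), c(100, 161), c(90, 160), c(80, 157),
    # inner mouth 44-49
    c(78, 150), c(92, 147), c(108, 147), c(122, 150), c(108, 153), c(92, 153)
  )
  colnames(pts) <- c("x", "y")
  pts
}

#' @rdname face_landmark_template
#' @export
face_landmark_groups <- function() {
  list(left_brow = 1:5, right_brow = 6:10,
       nose_bridge = 11:14, nose_bottom = 15:19, nose_tip = 17L,
       nose_top = 11L,
       left_eye = 20:25, right_eye = 26:31,
       left_eye_top = c(21L, 22L), left_eye_bottom = c(24L, 25L),
       right_eye_top = c(27L, 28L), right_eye_bottom = c(30L, 31L),
       left_eye_outer = 20L, left_eye_inner = 23L,
       right_eye_inner = 26L, right_eye_outer = 29L,
       left_brow_inner = 5L, right_brow_inner = 6L,
       outer_mouth = 32:43, inner_mouth = 44:49,
       mouth_left = 32L, mouth_right = 38L,
       upper_lip = 35L, lower_lip = 41L,
       inner_top = c(45L, 46L), inner_bottom = c(48L, 49L))
}

#' The canonical 30 geometric landmark features
#'
#' The named list of 22 distances and 8 angles computed from the 49-point
#' layout. Each endpoint is the centroid of a landmark group (so "eyebrow
#' center" is the mean of that brow's 5 points). Horizontal distances are
#' normalized by the face-box width, vertical ones by its height, oblique
#' ones by the diagonal; angles (radians, at the middle endpoint) are not
#' normalized. Published descriptions of this feature family name only a few examples; this
#' concrete list is the package's documented reconstruction.
#'
#' @return data.frame with columns `id`, `name`, `kind`, `a`, `b`, `c`
#'   (group names; `c` is `NA` for distances, the vertex is `b` for angles)
#'   and `normalizer`.
#' @export
geometric_feature_specs <- function() {
  d <- function(name, a, b, norm) list(name = name, kind = "distance", a = a, b = b, c = NA, normalizer = norm)
  an <- function(name, a, v, b) list(name = name, kind = "angle", a = a, b = v, c = b, normalizer = "none")
  specs <- list(
    d("lbrow_leye", "left_brow", "left_eye", "face_h"),
    d("rbrow_reye", "right_brow", "right_eye", "face_h"),
    d("brow_brow", "left_brow", "right_brow", "face_w"),
    d("leye_width", "left_eye_outer", "left_eye_inner", "face_w"),
    d("reye_width", "right_eye_inner", "right_eye_outer", "face_w"),
    d("leye_height", "left_eye_top", "left_eye_bottom", "face_h"),
    d("reye_height", "right_eye_top", "right_eye_bottom", "face_h"),
    d("eye_eye", "left_eye", "right_eye", "face_w"),
    d("nose_lmouth", "nose_tip", "mouth_left", "diag"),
    d("nose_rmouth", "nose_tip", "mouth_right", "diag"),
    d("mouth_width", "mouth_left", "mouth_right", "face_w"),
    d("mouth_height", "upper_lip", "lower_lip", "face_h"),
    d("nose_ulip", "nose_tip", "upper_lip", "face_h"),
    d("nose_llip", "nose_tip", "lower_lip", "face_h"),
    d("lbrow_nosetop", "left_brow_inner", "nose_top", "diag"),
    d("rbrow_nosetop", "right_brow_inner", "nose_top", "diag"),
    d("leye_nose", "left_eye", "nose_tip", "diag"),
    d("reye_nose", "right_eye", "nose_tip", "diag"),
    d("lmouth_leye", "mouth_left", "left_eye", "diag"),
    d("rmouth_reye", "mouth_right", "right_eye", "diag"),
    d("brows_nose", "left_brow", "nose_tip", "diag"),
    d("lip_gap", "inner_top", "inner_bottom", "face_h"),
    an("mouth_at_nose", "mouth_left", "nose_tip", "mouth_right"),
    an("lmouth_corner", "mouth_right", "mouth_left", "upper_lip"),
    an("rmouth_corner", "mouth_left", "mouth_right", "upper_lip"),
    an("lbrow_bend", "nose_top", "left_brow", "left_eye"),
    an("rbrow_bend", "nose_top", "right_brow", "right_eye"),
    an("brows_at_nosetop", "left_brow_inner", "nose_top", "right_brow_inner"),
    an("leye_open_angle", "left_brow", "left_eye", "nose_tip"),
    an("reye_open_angle", "right_brow", "right_eye", "nose_tip")
  )
  out <- do.call(rbind, lapply(specs, as.data.frame, stringsAsFactors = FALSE))
  out$id <- sprintf("geo%02d", seq_len(nrow(out)))
  out[, c("id", "name", "kind", "a", "b", "c", "normalizer")]
}

# centroid of a landmark group, vectorized over frames
# pts: n_frames x 49 x 2 array
group_centroid <- function(pts, group) {
  idx <- face_landmark_groups()[[group]]
  if (length(idx) == 1) {
    cbind(pts[, idx, 1], pts[, idx, 2])
  } else {
    cbind(rowMeans(pts[, idx, 1, drop = FALSE]),
          rowMeans(pts[, idx, 2, drop = FALSE]))
  }
}

#' Geometric features from landmark frames
#'
#' Evaluates the canonical 30 distance/angle features
#' ([geometric_feature_specs()]) for one frame or a whole frame sequence.
#' Distances are normalized by the face-box dimensions so the features are
#' invariant to translation and uniform scaling of the landmark cloud;
#' angles are additionally rotation-invariant. A degenerate angle (coincident
#' points) yields 0 with a warning.
#'
#' @param frames a [landmark_sequence()], or a 49 x 2 matrix for a single
#'   frame (then `face_w`/`face_h` are required).
#' @param face_w,face_h face-box dimensions when `frames` is a bare matrix.
#' @return numeric matrix `n_frames x 30` (a single frame gives 1 row),
#'   columns named `geo01 ... geo30`.
#' @export
geometric_features <- function(frames, face_w = NULL, face_h = NULL) {
  if (inherits(frames, "landmark_sequence")) {
    pts <- frames$points
    face_w <- frames$face_w
    face_h <- frames$face_h
  } else {
    m <- as.matrix(frames)
    if (!all(dim(m) == c(49, 2))) stopf("expected a 49 x 2 landmark matrix")
    if (is.null(face_w) || is.null(face_h)) stopf("face_w and face_h required")
    pts <- array(0, c(1, 49, 2))
    pts[1, , ] <- m
  }
  n <- dim(pts)[1]
  face_w <- rep_len(face_w, n)
  face_h <- rep_len(face_h, n)
  diag_ <- sqrt(face_w^2 + face_h^2)
  specs <- geometric_feature_specs()
  out <- matrix(0, n, nrow(specs), dimnames = list(NULL, specs$id))
  degenerate <- FALSE
  for (k in seq_len(nrow(specs))) {
    sp <- specs[k, ]
    A <- group_centroid(pts, sp$a)
    B <- group_centroid(pts, sp$b)
    if (sp$kind == "distance") {
      dist <- sqrt((A[, 1] - B[, 1])^2 + (A[, 2] - B[, 2])^2)
      norm <- switch(sp$normalizer, face_w = face_w, face_h = face_h, diag = diag_)
      out[, k] <- dist / norm
    } else {
      C <- group_centroid(pts, sp$c)
      u <- A - B
      v <- C - B
      nu <- sqrt(rowSums(u^2))
      nv <- sqrt(rowSums(v^2))
      bad <- nu == 0 | nv == 0
      if (any(bad)) degenerate <- TRUE
      cosang <- rowSums(u * v) / pmax(nu * nv, .Machine$double.eps)
      ang <- acos(pmin(pmax(cosang, -1), 1))
      ang[bad] <- 0
      out[, k] <- ang
    }
  }
  if (degenerate) warnf("degenerate angle (coincident landmarks): feature set to 0")
  out
}

#' Aggregate framewise features over a trial
#'
#' Columnwise mean, 95th percentile and standard deviation across the frames
#' of a trial, flattened in stat-major order (all means, then all 95th
#' percentiles, then all standard deviations). The 95th percentile uses the
#' linear-interpolation quantile definition (R type 7), pinned for
#' reproducibility. Thirty geometric columns give 90 values; a 4096-column
#' embedding matrix gives 12288.
#'
#' @param framewise_matrix numeric matrix, rows = frames (at least 2).
#' @return object of class `trial_aggregate`: `mean_vec`, `p95_vec`,
#'   `std_vec` and `block` (the flattened named vector).
#' @export
aggregate_trial <- function(framewise_matrix) {
  m <- as.matrix(framewise_matrix)
  if (nrow(m) < 2) {
    stopf("need at least 2 frames to aggregate (std undefined), got %d", nrow(m))
  }
  cn <- colnames(m)
  if (is.null(cn)) cn <- sprintf("f%04d", seq_len(ncol(m)))
  mean_vec <- colMeans(m)
  p95_vec <- apply(m, 2, quantile, probs = 0.95, type = 7, names = FALSE)
  std_vec <- apply(m, 2, sd)
  block <- c(mean_vec, p95_vec, std_vec)
  names(block) <- c(paste0(cn, "_mean"), paste0(cn, "_p95"), paste0(cn, "_std"))
  structure(list(mean_vec = mean_vec, p95_vec = p95_vec, std_vec = std_vec,
                 block = block),
            class = "trial_aggregate")
}

#' @export
print.trial_aggregate <- function(x, ...) {
  cat(sprintf("<trial_aggregate> %d columns -> %d features\n",
              length(x$mean_vec), length(x$block)))
  invisible(x)
}

#' Framewise deep face embeddings
#'
#' Sends each face image through an [image_embedder()] and stacks the
#' 4096-vectors into a frames-by-4096 matrix, preserving frame order.
#'
#' @param face_images list of `224 x 224 x 3` arrays in [0, 1].
#' @param embedder an [image_embedder()].
#' @return numeric matrix `n_frames x 4096`.
#' @export
face_embedding_sequence <- function(face_images, embedder) {
  rows <- lapply(face_images, function(img) embed(img, embedder))
  widths <- lengths(rows)
  if (any(widths != embedder$output_dim)) {
    stopf("embedder returned width %d, expected %d", widths[widths != embedder$output_dim][1],
          embedder$output_dim)
  }
  do.call(rbind, rows)
}

#' Render a landmark cloud as a synthetic face image
#'
#' Rasterizes 49 landmark points as Gaussian splats on a dark canvas
#' (brows/eyes in red, nose in green, mouth in blue), producing a
#' deterministic stand-in for the camera's face crop when working with
#' landmark-only (synthetic) data.
#'
#' @param points 49 x 2 landmark matrix in face-box pixel coordinates.
#' @param face_w,face_h face-box dimensions in pixels.
#' @param size output image side.
#' @param sigma splat standard deviation in output pixels.
#' @return `size x size x 3` array in [0, 1].
#' @export
render_face_image <- function(points, face_w, face_h, size = 224, sigma = 3) {
  gx <- seq_len(size) - 0.5
  groups <- face_landmark_groups()
  chan_for <- integer(49)
  chan_for[c(groups$left_brow, groups$right_brow, groups$left_eye, groups$right_eye)] <- 1L
  chan_for[c(groups$nose_bridge, groups$nose_bottom)] <- 2L
  chan_for[c(groups$outer_mouth, groups$inner_mouth)] <- 3L
  img <- array(0, c(size, size, 3))
  px <- points[, 1] / face_w * size
  py <- points[, 2] / face_h * size
  for (k in 1:49) {
    wx <- exp(-(gx - px[k])^2 / (2 * sigma^2))
    wy <- exp(-(gx - py[k])^2 / (2 * sigma^2))
    img[, , chan_for[k]] <- img[, , chan_for[k]] + outer(wy, wx)
  }
  mx <- max(img)
  if (mx > 0) img <- img / mx
  img
}
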