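#' Load the packaged reference atlas
#'
#' Builds the reference ROI label image from the packaged JSON layout: 12
#' named dorsal-cortex regions per hemisphere (M1, M2, sspm, sspfl, ssphl,
#' sspun, sspn, sspbfd, ssptr, visp, rspagl, rspd) arranged in a
#' hemisphere-symmetric grid, plus named skull landmarks (bregma, lambda,
#' midline anchor, and a lateral anchor). The right hemisphere is
#' contralateral to the reaching (left) paw; region labels carry a
#' `_contra` / `_ipsi` suffix. The layout is synthetic — a rectangular
#' stand-in with standard region names, sufficient for ROI bookkeeping and
#' registration, not an anatomical tracing.
#'
#' @param shape image shape `c(H, W)`; the reference layout is scaled to it.
#' @return An `atlas_roi_map`: list with `label_image` (integer H x W
#'   matrix, 0 = background, row = y), `names` (label id -> ROI name),
#'   `landmarks` (n x 2 matrix, columns x, y), `shape`, and `affine`
#'   (2 x 3 matrix; identity for the reference atlas).
#' @export
default_atlas <- function(shape = c(128L, 128L)) {
  path <- system.file("extdata", "atlas.json", package = "mesoreach")
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  ref <- spec$reference_shape
  sy <- shape[1L] / ref[1L]
  sx <- shape[2L] / ref[2L]

  hemi <- spec$hemisphere
  cw <- hemi$width / hemi$ncols
  rh <- hemi$height / hemi$nrows
  label <- matrix(0L, nrow = shape[1L], ncol = shape[2L])
  nms <- character(2L * nrow(spec$regions))
  id <- 0L
  for (side in c("contra", "ipsi")) {
    for (k in seq_len(nrow(spec$regions))) {
      reg <- spec$regions[k, ]
      x0 <- hemi$left_x0 + reg$col * cw
      x1 <- x0 + cw
      if (side == "contra") {   # right hemisphere: mirror about the midline
        xm <- ref[2L] - x1
        x1 <- ref[2L] - x0
        x0 <- xm
      }
      y0 <- hemi$top_y0 + reg$row * rh
      y1 <- y0 + rh
      rows <- max(1L, floor(y0 * sy) + 1L):min(shape[1L], ceiling(y1 * sy))
      cols <- max(1L, floor(x0 * sx) + 1L):min(shape[2L], ceiling(x1 * sx))
      # trim one pixel so neighboring regions stay disjoint
      rows <- rows[rows <= (y1 * sy)]
      cols <- cols[cols <= (x1 * sx)]
      id <- id + 1L
      label[rows, cols] <- id
      nms[id] <- paste0(reg$name, "_", side)
    }
  }
  lm <- do.call(rbind, spec$landmarks)
  colnames(lm) <- c("x", "y")
  lm <- cbind(x = lm[, "x"] * sx, y = lm[, "y"] * sy)
  structure(
    list(label_image = label, names = nms, landmarks = lm,
         shape = as.integer(shape),
         affine = cbind(diag(2), c(0, 0))),
    class = "atlas_roi_map"
  )
}

#' @export
print.atlas_roi_map <- function(x, ...) {
  cat(sprintf("<atlas_roi_map> %d x %d, %d ROIs, landmarks: %s\n",
              x$shape[1L], x$shape[2L], length(x$names),
              paste(rownames(x$landmarks), collapse = ", ")))
  invisible(x)
}

# Least-squares affine fit mapping reference points to image points.
# Returns 2 x 3 matrix A so that img ~ A %*% c(x, y, 1).
fit_affine <- function(ref, img) {
  stopifnot(nrow(ref) == nrow(img), nrow(ref) >= 3L)
  centered <- sweep(ref, 2L, colMeans(ref))
  if (qr(centered)$rank < 2L) {
    stop("landmarks are collinear; at least 3 non-collinear points are required")
  }
  X <- cbind(ref, 1)
  beta <- qr.solve(X, img)          # 3 x 2
  A <- t(beta)                      # 2 x 3
  dimnames(A) <- NULL
  A
}

apply_affine <- function(A, xy) {
  xy <- rbind(t(xy), 1)
  t(A %*% xy)
}

#' Register the reference atlas onto an imaged cortex
#'
#' Fits the least-squares affine transform taking the packaged reference
#' landmarks to user-supplied landmark coordinates in the imaged frame,
#' then warps the reference label image into image coordinates by
#' nearest-neighbor lookup through the inverse transform. The residual
#' landmark error quantifies the registration quality.
#'
#' @param landmarks named n x 2 matrix (or data.frame) of landmark
#'   coordinates in the imaged frame (columns x, y; row names matching
#'   reference landmark names). At least 3 non-collinear points.
#' @param atlas reference `atlas_roi_map` (default [default_atlas()]).
#' @param shape output image shape `c(H, W)`; defaults to the atlas shape.
#' @return An `atlas_roi_map` in image coordinates with extra fields
#'   `residual_px` (RMS landmark residual) and `residual_max_px`.
#' @export
register_atlas <- function(landmarks, atlas = default_atlas(), shape = atlas$shape) {
  landmarks <- as.matrix(landmarks)
  common <- intersect(rownames(landmarks), rownames(atlas$landmarks))
  if (length(common) < 3L) {
    stop("need at least 3 landmarks shared with the reference atlas; got ",
         length(common))
  }
  ref <- atlas$landmarks[common, , drop = FALSE]
  img <- landmarks[common, , drop = FALSE]
  A <- fit_affine(ref, img)
  pred <- apply_affine(A, ref)
  res <- sqrt(rowSums((pred - img)^2))

  # invert the affine to pull back image pixels into reference coordinates
  M <- A[, 1:2]
  if (abs(det(M)) < 1e-12) stop("degenerate affine transform (zero determinant)")
  Minv <- solve(M)
  tinv <- -Minv %*% A[, 3L]

  H <- shape[1L]; W <- shape[2L]
  gx <- rep(seq_len(W), each = H)
  gy <- rep(seq_len(H), times = W)
  rx <- Minv[1L, 1L] * gx + Minv[1L, 2L] * gy + tinv[1L]
  ry <- Minv[2L, 1L] * gx + Minv[2L, 2L] * gy + tinv[2L]
  ix <- as.integer(round(rx))
  iy <- as.integer(round(ry))
  ok <- ix >= 1L & ix <= atlas$shape[2L] & iy >= 1L & iy <= atlas$shape[1L]
  lab <- integer(H * W)
  lab[ok] <- atlas$label_image[cbind(iy[ok], ix[ok])]
  warped <- matrix(lab, nrow = H, ncol = W)

  structure(
    list(label_image = warped, names = atlas$names,
         landmarks = apply_affine(A, atlas$landmarks),
         shape = as.integer(shape), affine = A,
         residual_px = sqrt(mean(res^2)), residual_max_px = max(res)),
    class = "atlas_roi_map"
  )
}

# Pixel indices (column-major over an H x W image) belonging to a named ROI.
roi_pixels <- function(roi_map, roi) {
  id <- match(roi, roi_map$names)
  if (is.na(id)) {
    stop("unknown ROI name(s): ", roi,
         " (known: ", paste(roi_map$names, collapse = ", "), ")")
  }
  which(roi_map$label_image == id)
}

# Centroid of a named ROI, rounded to the nearest pixel with ties toward the
# smaller index. Returns c(row, col).
roi_centroid <- function(roi_map, roi) {
  id <- match(roi, roi_map$names)
  if (is.na(id)) {
    stop("unknown ROI name(s): ", roi,
         " (known: ", paste(roi_map$names, collapse = ", "), ")")
  }
  idx <- which(roi_map$label_image == id, arr.ind = TRUE)
  if (!nrow(idx)) stop("ROI is empty after registration: ", roi)
  ctr <- colMeans(idx)
  as.integer(ceiling(ctr - 0.5))    # round half toward the smaller index
}
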