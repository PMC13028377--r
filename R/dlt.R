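# 11-parameter direct linear transformation (DLT): camera calibration and
# least-squares multi-camera 3D reconstruction.

#' Construct a DLT camera
#'
#' @param coefficients numeric vector of the 11 standard DLT coefficients
#'   L1..L11.
#' @param image_size sensor size in pixels, `c(width, height)`.
#' @param residual_px RMS reprojection error over the calibration points,
#'   pixels.
#' @param residual_m RMS object-space reconstruction error over the
#'   calibration points (requires a calibrated rig), metres.
#' @return Object of class `camera_dlt`.
#' @export
camera_dlt <- function(coefficients, image_size = c(2048, 1536),
                       residual_px = NA_real_, residual_m = NA_real_) {
  stopifnot(length(coefficients) == 11, all(is.finite(coefficients)))
  if (sqrt(sum(coefficients[9:11]^2)) < 1e-14)
    stop("invalid DLT camera: denominator coefficients L9..L11 are all zero")
  structure(list(coefficients = as.numeric(coefficients),
                 image_size = image_size,
                 residual_px = residual_px, residual_m = residual_m),
            class = "camera_dlt")
}

#' @export
print.camera_dlt <- function(x, ...) {
  cat(sprintf("<camera_dlt> %dx%d px, residual_px = %s, residual_m = %s\n",
              x$image_size[1], x$image_size[2],
              format(x$residual_px, digits = 4), format(x$residual_m, digits = 4)))
  invisible(x)
}

#' Project 3D points through a DLT camera
#'
#' Applies the DLT projection equations. Points outside the image bounds are
#' flagged (not clipped); points behind the camera raise a geometry error
#' unless `behind = "flag"`.
#'
#' @param camera a [camera_dlt()].
#' @param xyz `n x 3` matrix of object-space points, metres.
#' @param behind `"error"` (default) or `"flag"`: handling of points with
#'   non-positive projective depth.
#' @return data.frame with columns `u`, `v` (pixels) and logical `visible`.
#' @export
dlt_project <- function(camera, xyz, behind = c("error", "flag")) {
  behind <- match.arg(behind)
  xyz <- rbind(xyz)
  L <- camera$coefficients
  den <- xyz %*% L[9:11] + 1
  if (any(den <= 0)) {
    if (behind == "error")
      stop("geometry error: point behind camera (non-positive DLT denominator)")
  }
  u <- (xyz %*% L[1:3] + L[4]) / den
  v <- (xyz %*% L[5:7] + L[8]) / den
  visible <- den > 0 & u >= 0 & u <= camera$image_size[1] &
    v >= 0 & v <= camera$image_size[2]
  data.frame(u = as.numeric(u), v = as.numeric(v), visible = as.logical(visible))
}

#' Control points for camera calibration
#'
#' @param points `n x 3` matrix of known 3D positions, metres (`n >= 6`,
#'   non-coplanar).
#' @param observations list of per-camera data.frames with columns `u`, `v`
#'   (pixels), row-aligned with `points`.
#' @return Object of class `control_points`.
#' @export
control_points <- function(points, observations) {
  points <- as.matrix(points)
  if (nrow(points) < 6) stop("need at least 6 control points")
  check_noncoplanar(points)
  structure(list(points = points, observations = observations),
            class = "control_points")
}

check_noncoplanar <- function(points) {
  ctr <- sweep(points, 2, colMeans(points))
  sv <- svd(ctr)$d
  if (sv[3] < 1e-9 * max(sv[1], 1))
    stop("degenerate control-point geometry: points are coplanar (rank < 3)")
  invisible(TRUE)
}

#' Calibrate one DLT camera from control points
#'
#' Solves the overdetermined linear DLT system in least squares. The linear
#' system is normalised (control points and pixels centred and scaled) for
#' conditioning; the returned coefficients are in the original units.
#'
#' @param points `n x 3` matrix of control-point positions (`n >= 6`,
#'   non-coplanar), metres.
#' @param pixels data.frame or matrix with columns `u`, `v` for this camera.
#' @param image_size sensor size in pixels.
#' @return A [camera_dlt()] with `residual_px` populated.
#' @export
dlt_calibrate <- function(points, pixels, image_size = c(2048, 1536)) {
  points <- as.matrix(points)
  pixels <- as.matrix(as.data.frame(pixels)[, c("u", "v")])
  n <- nrow(points)
  if (n < 6) stop("need at least 6 control points to calibrate (got ", n, ")")
  stopifnot(nrow(pixels) == n)
  check_noncoplanar(points)

  # similarity normalisation of object and image coordinates
  c3 <- colMeans(points); s3 <- sqrt(3) / mean(sqrt(rowSums(sweep(points, 2, c3)^2)))
  c2 <- colMeans(pixels); s2 <- sqrt(2) / mean(sqrt(rowSums(sweep(pixels, 2, c2)^2)))
  Xn <- sweep(points, 2, c3) * s3
  pn <- sweep(pixels, 2, c2) * s2

  A <- matrix(0, 2 * n, 11)
  b <- numeric(2 * n)
  for (i in seq_len(n)) {
    X <- Xn[i, ]; u <- pn[i, 1]; v <- pn[i, 2]
    A[2 * i - 1, ] <- c(X, 1, 0, 0, 0, 0, -u * X)
    A[2 * i, ]     <- c(0, 0, 0, 0, X, 1, -v * X)
    b[2 * i - 1] <- u
    b[2 * i] <- v
  }
  Ln <- qr.solve(A, b)
  Pn <- rbind(c(Ln[1:4]), c(Ln[5:8]), c(Ln[9:11], 1))

  # de-normalise: P = T2^-1 Pn T3, then rescale so P[3,4] = 1
  T3 <- rbind(cbind(diag(3) * s3, -s3 * c3), c(0, 0, 0, 1))
  T2inv <- rbind(c(1 / s2, 0, c2[1]), c(0, 1 / s2, c2[2]), c(0, 0, 1))
  P <- T2inv %*% Pn %*% T3
  P <- P / P[3, 4]
  L <- c(P[1, 1:4], P[2, 1:4], P[3, 1:3])

  cam <- camera_dlt(L, image_size = image_size)
  prj <- dlt_project(cam, points, behind = "flag")
  cam$residual_px <- sqrt(mean((prj$u - pixels[, 1])^2 + (prj$v - pixels[, 2])^2))
  cam
}

#' Calibrate a multi-camera rig and fill object-space residuals
#'
#' Calibrates every camera from the same control points, then reconstructs
#' each control point from all calibrated cameras and stores the RMS 3D error
#' as `residual_m` on every camera.
#'
#' @param cps a [control_points()] object.
#' @param image_size sensor size in pixels.
#' @return list of [camera_dlt()] objects.
#' @export
dlt_calibrate_rig <- function(cps, image_size = c(2048, 1536)) {
  cams <- lapply(cps$observations, function(obs)
    dlt_calibrate(cps$points, obs, image_size = image_size))
  err2 <- vapply(seq_len(nrow(cps$points)), function(i) {
    px <- lapply(cps$observations, function(obs) c(obs$u[i], obs$v[i]))
    rec <- dlt_reconstruct(cams, px)
    sum((rec$xyz - cps$points[i, ])^2)
  }, numeric(1))
  rm3 <- sqrt(mean(err2))
  lapply(cams, function(cm) { cm$residual_m <- rm3; cm })
}

#' Reconstruct one 3D point from multi-camera DLT observations
#'
#' Linear least-squares intersection of the DLT ray equations across all
#' cameras with a non-missing observation.
#'
#' @param cameras list of [camera_dlt()] objects.
#' @param pixels list (same length) of length-2 numeric vectors `c(u, v)`;
#'   `NA` marks a missing observation for that camera.
#' @return list with `xyz` (length-3 point, metres), `condition` (condition
#'   number of the normal system, a triangulation-geometry diagnostic),
#'   `n_views`, and `rms_residual` of the linear system.
#' @export
dlt_reconstruct <- function(cameras, pixels) {
  use <- vapply(pixels, function(p) length(p) >= 2 && all(is.finite(p[1:2])),
                logical(1))
  k <- sum(use)
  if (k < 2)
    stop("reconstruction impossible: fewer than 2 cameras observe the point")
  A <- matrix(0, 2 * k, 3)
  b <- numeric(2 * k)
  row <- 0
  for (i in which(use)) {
    L <- cameras[[i]]$coefficients
    u <- pixels[[i]][1]; v <- pixels[[i]][2]
    row <- row + 1
    A[2 * row - 1, ] <- c(L[1] - u * L[9], L[2] - u * L[10], L[3] - u * L[11])
    b[2 * row - 1] <- u - L[4]
    A[2 * row, ] <- c(L[5] - v * L[9], L[6] - v * L[10], L[7] - v * L[11])
    b[2 * row] <- v - L[8]
  }
  sv <- svd(A)
  cond <- sv$d[1] / max(sv$d[3], .Machine$double.eps)
  xyz <- sv$v %*% ((t(sv$u) %*% b) / sv$d)
  res <- A %*% xyz - b
  list(xyz = as.numeric(xyz), condition = cond, n_views = k,
       rms_residual = sqrt(mean(res^2)))
}

#' Reconstruct a full trial from per-camera 2D observations
#'
#' Applies [dlt_reconstruct()] framewise per landmark. Frames/landmarks seen
#' by fewer than 2 cameras are marked missing (never fabricated) and reported
#' in the attached gap log.
#'
#' @param cameras list of [camera_dlt()] objects.
#' @param observations per-camera observation sets as returned by
#'   [project_to_cameras()]: each a list with `n x 17` matrices `u`, `v` and
#'   logical `visible`.
#' @param sample_rate sampling rate, Hz.
#' @param method method tag for the reconstructed trial.
#' @param trial_id trial identifier.
#' @return A [trial3d()]; attribute `"gap_log"` is a data.frame of missing
#'   frame/landmark pairs.
#' @export
dlt_reconstruct_trial <- function(cameras, observations, sample_rate = 100,
                                  method = "REC", trial_id = "trial1") {
  lm <- landmark_names()
  n <- nrow(observations[[1]]$u)
  coords <- array(NA_real_, c(n, 17, 3), dimnames = list(NULL, lm, c("x", "y", "z")))
  missing <- matrix(FALSE, n, 17, dimnames = list(NULL, lm))
  for (j in seq_along(lm)) {
    for (i in seq_len(n)) {
      px <- lapply(observations, function(o) {
        if (isTRUE(o$visible[i, j])) c(o$u[i, j], o$v[i, j]) else c(NA_real_, NA_real_)
      })
      nv <- sum(vapply(px, function(p) all(is.finite(p)), logical(1)))
      if (nv < 2) {
        missing[i, j] <- TRUE
      } else {
        coords[i, j, ] <- dlt_reconstruct(cameras, px)$xyz
      }
    }
  }
  out <- trial3d(coords, sample_rate = sample_rate, method = method,
                 trial_id = trial_id, missing = missing)
  gaps <- which(missing, arr.ind = TRUE)
  attr(out, "gap_log") <- data.frame(frame = as.integer(gaps[, 1]),
                                     landmark = lm[gaps[, 2]],
                                     stringsAsFactors = FALSE)
  out
}

#' Ideal pinhole camera expressed as DLT coefficients
#'
#' Builds the 3x4 projection matrix of an ideal (distortion-free) pinhole
#' camera from its position, viewing target and focal length, and converts it
#' to the 11 standard DLT coefficients.
#'
#' @param position camera centre, metres.
#' @param target point the optical axis passes through, metres.
#' @param focal_px focal length in pixels.
#' @param image_size sensor size in pixels; the principal point is the image
#'   centre.
#' @param up approximate up direction used to fix camera roll.
#' @return A [camera_dlt()].
#' @export
make_pinhole_camera <- function(position, target, focal_px = 1800,
                                image_size = c(2048, 1536), up = c(0, 0, 1)) {
  f <- target - position
  f <- f / sqrt(sum(f^2))
  r <- c(f[2] * up[3] - f[3] * up[2],
         f[3] * up[1] - f[1] * up[3],
         f[1] * up[2] - f[2] * up[1])
  if (sqrt(sum(r^2)) < 1e-12) stop("viewing direction parallel to up vector")
  r <- r / sqrt(sum(r^2))
  d <- c(r[2] * f[3] - r[3] * f[2],
         r[3] * f[1] - r[1] * f[3],
         r[1] * f[2] - r[2] * f[1])
  R <- rbind(r, d, f)
  K <- rbind(c(focal_px, 0, image_size[1] / 2),
             c(0, focal_px, image_size[2] / 2),
             c(0, 0, 1))
  P <- K %*% cbind(R, -R %*% position)
  P <- P / P[3, 4]
  camera_dlt(c(P[1, 1:4], P[2, 1:4], P[3, 1:3]), image_size = image_size)
}

#' Default four-camera rig for the runway capture volume
#'
#' Four roof-mounted 2048x1536 px cameras covering the last 12-15 m of the
#' runway from four different angles, mirroring a constrained competition
#' setup.
#'
#' @param centre approximate centre of the capture volume, metres.
#' @return list of four [camera_dlt()] objects.
#' @export
default_camera_rig <- function(centre = c(-4, 0, 1.2)) {
  spots <- list(c(-16, 9, 7), c(-2, 10, 8), c(6, 7, 7), c(-9, -10, 7))
  lapply(spots, function(p) make_pinhole_camera(p, centre, focal_px = 1600))
}

#' Write / read cameras as YAML
#'
#' @param cameras list of [camera_dlt()] objects.
#' @param path file path.
#' @return `write_cameras_yaml` returns `path` invisibly; `read_cameras_yaml`
#'   returns a list of [camera_dlt()] objects.
#' @export
write_cameras_yaml <- function(cameras, path) {
  obj <- lapply(cameras, function(cm)
    list(coefficients = cm$coefficients, image_size = cm$image_size,
         residual_px = cm$residual_px, residual_m = cm$residual_m))
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_cameras_yaml
#' @export
read_cameras_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  lapply(obj, function(o)
    camera_dlt(as.numeric(o$coefficients), as.numeric(o$image_size),
               residual_px = o$residual_px %||% NA_real_,
               residual_m = o$residual_m %||% NA_real_))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
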