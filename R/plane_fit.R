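# Total-least-squares plane fitting: the fitted plane minimizes the sum of
# squared orthogonal distances of the points, i.e. it passes through the
# centroid with normal along the smallest-variance direction of the centered
# cloud (smallest right singular vector).

#' Total-least-squares plane fit
#'
#' Fits the plane minimizing the sum of squared orthogonal point-plane
#' distances. The plane passes through the centroid of the points; its normal
#' is the right singular vector of the centered coordinate matrix with the
#' smallest singular value. The normal's sign is arbitrary at this stage;
#' callers impose an anatomical orientation afterwards.
#'
#' @param points numeric n x 3 matrix (or coercible) of points in mm, n >= 3.
#' @return A list with components
#'   \describe{
#'     \item{plane}{the fitted [plane()].}
#'     \item{centroid}{the point centroid (on the plane).}
#'     \item{rms_residual}{root-mean-square orthogonal distance, mm.}
#'     \item{n_points}{number of points used.}
#'   }
#'   Raises a degenerate-geometry error for collinear or coincident clouds
#'   (the two smallest singular values both vanish).
#' @examples
#' pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
#' fit_plane_least_squares(pts)$rms_residual  # 0
#' @export
fit_plane_least_squares <- function(points) {
  pts <- as.matrix(points)
  if (ncol(pts) != 3) stop("points must be an n x 3 matrix")
  if (!all(is.finite(pts))) stop("points contain non-finite coordinates")
  n <- nrow(pts)
  if (n < 3) stop_degenerate("plane fit needs at least 3 points, got ", n)

  centroid <- colMeans(pts)
  X <- sweep(pts, 2, centroid)
  sv <- svd(X, nu = 0, nv = 3)
  scale <- max(sv$d[1], 1)
  # collinear/coincident cloud: no unique normal (two vanishing directions)
  if (sv$d[2] < .DEGENERATE_TOL * scale) {
    stop_degenerate("points are (near-)collinear or coincident; plane is not unique")
  }
  normal <- sv$v[, 3]
  rms <- sv$d[3] / sqrt(n)
  list(plane = plane_from_normal_point(normal, centroid),
       centroid = unname(centroid),
       rms_residual = rms,
       n_points = n)
}
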