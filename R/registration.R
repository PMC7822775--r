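#' Labelled 3D point set
#'
#' Marker coordinates in one space (tomographic MRI/CT, or XR world).
#' Pairing between sets is by label.
#'
#' @param coords n x 3 numeric matrix or data frame of mm coordinates.
#' @param labels Unique point labels; defaults to row names or `"p1"..`.
#' @param space `"tomographic"` or `"xr-world"`.
#' @return A `point_set_3d`.
#' @export
point_set_3d <- function(coords, labels = NULL,
                         space = c("tomographic", "xr-world")) {
  space <- match.arg(space)
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, all(is.finite(coords)))
  if (is.null(labels)) {
    labels <- rownames(coords)
    if (is.null(labels)) labels <- paste0("p", seq_len(nrow(coords)))
  }
  if (anyDuplicated(labels)) stop("point labels must be unique")
  rownames(coords) <- labels
  colnames(coords) <- c("x", "y", "z")
  structure(list(coords = coords, labels = as.character(labels),
                 space = space),
            class = "point_set_3d")
}

#' @export
print.point_set_3d <- function(x, ...) {
  cat(sprintf("point set (%s), %d points\n", x$space, nrow(x$coords)))
  print(round(x$coords, 3))
  invisible(x)
}

pair_coords <- function(moving, fixed) {
  stopifnot(inherits(moving, "point_set_3d"), inherits(fixed, "point_set_3d"))
  common <- intersect(moving$labels, fixed$labels)
  miss <- union(setdiff(moving$labels, fixed$labels),
                setdiff(fixed$labels, moving$labels))
  if (length(miss))
    stop("unpaired labels: ", paste(miss, collapse = ", "))
  list(m = moving$coords[common, , drop = FALSE],
       f = fixed$coords[common, , drop = FALSE])
}

#' Rigid transform (rotation + translation)
#'
#' @param R 3x3 rotation matrix (orthonormal, det +1).
#' @param t Length-3 translation, mm.
#' @return A `rigid_transform`.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- as.matrix(R)
  stopifnot(all(dim(R) == c(3, 3)), length(t) == 3)
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0)
    stop("R must be a proper rotation (orthonormal, det +1)")
  structure(list(R = R, t = as.numeric(t)), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid transform (4x4 homogeneous):\n")
  print(signif(as_matrix4(x), 6))
  invisible(x)
}

#' Rigid transform as a 4x4 homogeneous matrix
#' @param T A [rigid_transform()].
#' @export
as_matrix4 <- function(T) {
  stopifnot(inherits(T, "rigid_transform"))
  rbind(cbind(T$R, T$t), c(0, 0, 0, 1))
}

#' Invert a rigid transform
#' @param T A [rigid_transform()].
#' @export
invert_transform <- function(T) {
  rigid_transform(t(T$R), as.numeric(-t(T$R) %*% T$t))
}

#' Paired-point rigid least-squares fit
#'
#' Finds the rigid transform minimizing the sum of squared distances
#' `sum ||R m_i + t - f_i||^2` over label-paired points, by the SVD (Kabsch)
#' solution of the cross-covariance with determinant correction, so the
#' result is always a proper rotation (no reflection). This is the
#' transform `T_rigid` mapping tomographic marker coordinates onto their
#' XR-reconstructed counterparts.
#'
#' @param moving,fixed [point_set_3d()] objects sharing >= 3 labels.
#' @return A [rigid_transform()] with attribute `"rmse"` (mm).
#' @examples
#' m <- point_set_3d(matrix(rnorm(18, sd = 40), 6, 3))
#' T0 <- rigid_transform(rotation_gantry(30, 10), c(5, -2, 8))
#' f <- point_set_3d(apply_transform(T0, m$coords), m$labels, "xr-world")
#' fit_rigid(m, f)
#' @export
fit_rigid <- function(moving, fixed) {
  pc <- pair_coords(moving, fixed)
  n <- nrow(pc$m)
  if (n < 3) stop("at least 3 paired points are required")
  cm <- colMeans(pc$m)
  cf <- colMeans(pc$f)
  Mc <- sweep(pc$m, 2, cm)
  Fc <- sweep(pc$f, 2, cf)
  # collinearity / coincidence guard: need 2 independent directions
  sv <- svd(Mc)$d
  if (sv[2] < 1e-8 * max(sv[1], 1))
    stop("degenerate point configuration (collinear or coincident)")
  H <- crossprod(Mc, Fc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  T <- rigid_transform(R, cf - as.numeric(R %*% cm))
  attr(T, "rmse") <- rmse(T, moving, fixed)
  T
}

#' Root-mean-squared registration error
#'
#' `sqrt(mean(||T p_moving_i - p_fixed_i||^2))` over the label-paired points:
#' the registration accuracy metric between transformed tomographic markers
#' and XR-reconstructed markers.
#'
#' @param T A [rigid_transform()].
#' @param moving,fixed Paired [point_set_3d()] objects.
#' @return RMSE in mm.
#' @export
rmse <- function(T, moving, fixed) {
  pc <- pair_coords(moving, fixed)
  d <- apply_transform(T, pc$m) - pc$f
  sqrt(mean(rowSums(d^2)))
}

#' Apply a rigid transform
#'
#' Maps points (n x 3 matrix, length-3 vector, [point_set_3d()]) or a
#' [surface_mesh()] through `T`; an isometry, so pairwise distances are
#' preserved.
#'
#' @param T A [rigid_transform()].
#' @param x Points or mesh to transform.
#' @return Transformed copy of `x`.
#' @export
apply_transform <- function(T, x) {
  stopifnot(inherits(T, "rigid_transform"))
  if (inherits(x, "point_set_3d")) {
    out <- x
    out$coords <- apply_transform(T, x$coords)
    return(out)
  }
  if (inherits(x, "surface_mesh")) {
    out <- x
    out$vertices <- apply_transform(T, x$vertices)
    if (!is.null(out$normals))
      out$normals <- out$normals %*% t(T$R)
    return(out)
  }
  one <- is.null(dim(x))
  p <- if (one) matrix(x, 1, 3) else as.matrix(x)
  out <- p %*% t(T$R) + matrix(T$t, nrow(p), 3, byrow = TRUE)
  dimnames(out) <- dimnames(p)
  if (one) as.numeric(out) else out
}
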