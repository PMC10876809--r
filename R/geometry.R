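# Rigid geometry: Euler angles (x-then-y-then-z), 4x4 homogeneous maps,
# composition/inversion, and voxel<->world coordinate plumbing.

#' Rotation matrix from Euler angles
#'
#' R = Rz(c) Ry(b) Rx(a): the x rotation is applied first.
#' @param angles numeric(3), radians about x, y, z.
#' @return 3x3 rotation matrix.
#' @export
eulerToMatrix <- function(angles) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  matrix(c(
    cz * cy, sz * cy, -sy,
    cz * sy * sx - sz * cx, sz * sy * sx + cz * cx, cy * sx,
    cz * sy * cx + sz * sx, sz * sy * cx - cz * sx, cy * cx
  ), nrow = 3)
}

#' Euler angles from a rotation matrix (x-then-y-then-z convention)
#' @param R 3x3 proper rotation matrix.
#' @return numeric(3) radians. Undefined at gimbal lock (|pitch| = 90 deg).
#' @export
matrixToEuler <- function(R) {
  b <- asin(max(-1, min(1, -R[3, 1])))
  a <- atan2(R[3, 2], R[3, 3])
  c <- atan2(R[2, 1], R[1, 1])
  c(a, b, c)
}

#' Construct a RigidTransform
#' @param angles rotations (radians) about x, y, z, applied in that order.
#' @param translation world translation, mm.
#' @param center rotation centre, world mm (default origin).
#' @return A \linkS4class{RigidTransform}.
#' @export
rigidTransform <- function(angles = c(0, 0, 0), translation = c(0, 0, 0),
                           center = c(0, 0, 0)) {
  new("RigidTransform", angles = as.numeric(angles),
      translation = as.numeric(translation), center = as.numeric(center))
}

#' Homogeneous 4x4 world-to-world matrix of a RigidTransform
#' @param transform A \linkS4class{RigidTransform}.
#' @return 4x4 matrix M with M x = R (x - c) + c + t.
#' @export
transformMatrix <- function(transform) {
  R <- eulerToMatrix(transform@angles)
  offset <- transform@center + transform@translation -
    as.vector(R %*% transform@center)
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- offset
  M
}

rigidFromMatrix <- function(M, center = c(0, 0, 0)) {
  R <- M[1:3, 1:3]
  angles <- matrixToEuler(R)
  # M x = R x + o; want R (x - c) + c + t = R x + (c + t - R c)
  translation <- M[1:3, 4] - center + as.vector(R %*% center)
  rigidTransform(angles, translation, center)
}

#' Compose two rigid transforms
#' @param second,first RigidTransforms; the result applies \code{first} then
#'   \code{second}.
#' @return A \linkS4class{RigidTransform} (centre taken from \code{first}).
#' @export
composeTransforms <- function(second, first) {
  rigidFromMatrix(transformMatrix(second) %*% transformMatrix(first),
                  center = first@center)
}

#' Invert a rigid transform
#' @param transform A \linkS4class{RigidTransform}.
#' @return Its inverse, with the same rotation centre.
#' @export
invertTransform <- function(transform) {
  rigidFromMatrix(solve(transformMatrix(transform)),
                  center = transform@center)
}

#' Apply a rigid transform to world points
#' @param transform A \linkS4class{RigidTransform}.
#' @param points n x 3 matrix of world coordinates (mm).
#' @return n x 3 matrix of mapped coordinates.
#' @export
transformPoints <- function(transform, points) {
  points <- rbind(t(points), 1)
  out <- transformMatrix(transform) %*% points
  t(out[1:3, , drop = FALSE])
}

#' Map 0-based voxel indices to world coordinates
#' @param vol A \linkS4class{VolumeImage}.
#' @param idx n x 3 matrix of 0-based voxel indices.
#' @return n x 3 matrix of world RAS coordinates (mm).
#' @export
voxelToWorld <- function(vol, idx) {
  out <- vol@affine %*% rbind(t(idx), 1)
  t(out[1:3, , drop = FALSE])
}

#' Map world coordinates to 0-based (continuous) voxel indices
#' @param vol A \linkS4class{VolumeImage}.
#' @param pts n x 3 matrix of world coordinates (mm).
#' @return n x 3 matrix of continuous voxel indices.
#' @export
worldToVoxel <- function(vol, pts) {
  out <- solve(vol@affine) %*% rbind(t(pts), 1)
  t(out[1:3, , drop = FALSE])
}

# world coordinates of every voxel centre, n x 3, voxel scan order (x fastest)
gridWorldCoords <- function(vol) {
  d <- dim(vol@voxels)
  idx <- cbind(
    rep.int(seq_len(d[1]) - 1, times = d[2] * d[3]),
    rep.int(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3]),
    rep(seq_len(d[3]) - 1, each = d[1] * d[2])
  )
  voxelToWorld(vol, idx)
}

centeredAffine <- function(dim, spacing) {
  A <- diag(4)
  diag(A)[1:3] <- spacing
  A[1:3, 4] <- -(dim - 1) / 2 * spacing
  A
}

#' Construct a VolumeImage
#' @param voxels 3D numeric array.
#' @param spacing voxel spacing in mm (default 1 mm isotropic).
#' @param affine optional 4x4 voxel-to-world matrix; defaults to a grid
#'   centred on the world origin with axis-aligned spacing.
#' @return A \linkS4class{VolumeImage}.
#' @export
volumeImage <- function(voxels, spacing = c(1, 1, 1), affine = NULL) {
  if (is.null(affine)) affine <- centeredAffine(dim(voxels), spacing)
  new("VolumeImage", voxels = voxels, spacing = as.numeric(spacing),
      affine = affine)
}

#' Construct a BinaryMask sharing a companion volume's geometry
#' @param voxels 3D array of 0/1 values.
#' @param like A \linkS4class{VolumeImage} supplying spacing and affine.
#' @return A \linkS4class{BinaryMask}.
#' @export
binaryMask <- function(voxels, like) {
  new("BinaryMask", voxels = voxels, spacing = like@spacing,
      affine = like@affine)
}

#' Construct a LabelMask sharing a companion volume's geometry
#' @param voxels 3D array of non-negative integer labels.
#' @param like A \linkS4class{VolumeImage} supplying spacing and affine.
#' @return A \linkS4class{LabelMask}.
#' @export
labelMask <- function(voxels, like) {
  new("LabelMask", voxels = voxels, spacing = like@spacing,
      affine = like@affine)
}
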