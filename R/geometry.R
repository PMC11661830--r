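## Contact geometry: distance from each contact to the resection margin in
## patient-MRI millimeter space, and the distance-based EZ label.

#' Read and write electrode coordinate tables
#'
#' Tab-separated tables with columns `name`, `x`, `y`, `z` (mm, patient-MRI
#' world space) and `soz_flag` (0/1).
#'
#' @param path TSV file path.
#' @param table data.frame to write.
#' @return `readElectrodeTable` returns a data.frame with `soz_flag` coerced
#'   to logical.
#' @export
readElectrodeTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "x", "y", "z", "soz_flag")
  if (!all(need %in% names(tab)))
    stop("electrode table must contain columns: ", paste(need, collapse = ", "))
  tab$soz_flag <- as.logical(tab$soz_flag)
  tab
}

#' @rdname readElectrodeTable
#' @export
writeElectrodeTable <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a binary resection mask from NIfTI
#'
#' @param path NIfTI file path.
#' @return `list(volume, affine)`: a logical voxel array and the 4 x 4
#'   0-based-voxel-index-to-mm transform.
#' @export
readResectionMask <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- matrix(as.numeric(RNifti::xform(img)), 4L, 4L)
  vol <- array(as.array(img) != 0, dim(img))
  list(volume = vol, affine = aff)
}

# World-space centers of mask voxels satisfying `which3` (logical array),
# via the affine on 0-based indices.
.voxelCenters <- function(which3, affine) {
  idx <- which(which3, arr.ind = TRUE) - 1 # 0-based
  t(affine[1:3, 1:3] %*% t(idx) + affine[1:3, 4])
}

# Boundary voxels: true voxels with at least one false 6-neighbor (array
# edges count as outside).
.maskBoundary <- function(volume) {
  d <- dim(volume)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- volume
  core <- pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)]
  nb <- pad[1:d[1], 2:(d[2] + 1L), 2:(d[3] + 1L)] &
        pad[3:(d[1] + 2L), 2:(d[2] + 1L), 2:(d[3] + 1L)] &
        pad[2:(d[1] + 1L), 1:d[2], 2:(d[3] + 1L)] &
        pad[2:(d[1] + 1L), 3:(d[2] + 2L), 2:(d[3] + 1L)] &
        pad[2:(d[1] + 1L), 2:(d[2] + 1L), 1:d[3]] &
        pad[2:(d[1] + 1L), 2:(d[2] + 1L), 3:(d[3] + 2L)]
  core & !nb
}

#' Euclidean distance from a contact to the closest resection margin
#'
#' Returns 0 when the coordinate falls inside a true voxel of the mask;
#' otherwise the minimum Euclidean distance in millimeters to the centers of
#' the mask's boundary voxels (true voxels with at least one false
#' 6-neighbor).
#'
#' @param coordinate length-3 numeric (x, y, z) in mm, or an n x 3 matrix of
#'   coordinates.
#' @param mask `list(volume, affine)` as returned by [readResectionMask()].
#' @return distance(s) in mm, >= 0.
#' @export
distanceToResection <- function(coordinate, mask) {
  if (!any(mask$volume)) stop("resection mask is empty")
  coords <- if (is.matrix(coordinate)) coordinate else matrix(coordinate, 1L)
  stopifnot(ncol(coords) == 3L)
  inv <- solve(mask$affine)
  d <- dim(mask$volume)
  bnd <- .voxelCenters(.maskBoundary(mask$volume), mask$affine)
  vapply(seq_len(nrow(coords)), function(i) {
    xyz <- coords[i, ]
    vox <- round(inv[1:3, 1:3] %*% xyz + inv[1:3, 4]) + 1 # 1-based index
    if (all(vox >= 1) && all(vox <= d) &&
        mask$volume[vox[1], vox[2], vox[3]]) return(0)
    sqrt(min(colSums((t(bnd) - xyz)^2)))
  }, 0)
}

#' Distance-based epileptogenic-zone label
#'
#' A contact is labeled within the EZ when its distance to the resection
#' margin is strictly below 5 mm (the margin absorbs post-operative brain
#' shift and co-registration error); exactly 5.0 mm is outside.
#'
#' @param distance distance(s) in mm, >= 0.
#' @param threshold labeling radius in mm (default 5).
#' @return logical vector.
#' @export
labelEZ <- function(distance, threshold = 5) {
  if (any(distance < 0)) stop("distances must be non-negative")
  distance < threshold
}

#' Per-contact geometry table
#'
#' Combines contact coordinates, SOZ flags, distance to the resection margin
#' and the EZ label into one table.
#'
#' @param electrodes data.frame with `name`, `x`, `y`, `z`, `soz_flag`
#'   (see [readElectrodeTable()]).
#' @param mask `list(volume, affine)`.
#' @return the input data.frame with `distance_mm` and `in_ez` appended.
#' @export
contactGeometry <- function(electrodes, mask) {
  dist <- distanceToResection(as.matrix(electrodes[, c("x", "y", "z")]), mask)
  electrodes$distance_mm <- dist
  electrodes$in_ez <- labelEZ(dist)
  electrodes
}
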