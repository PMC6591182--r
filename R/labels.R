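#' Labelled parcellation volumes
#'
#' A label volume is a 3D integer grid (0 = background) with a 4x4 affine
#' mapping 0-based voxel indices to world millimetres under the voxel-centre
#' convention: index (i, j, k) maps to the centre of that voxel. The voxel
#' volume in mm^3 is the absolute determinant of the affine's 3x3 block.
#'
#' @param labels 3D array of nonnegative integers.
#' @param affine 4x4 numeric matrix, voxel-index -> world-mm, invertible.
#' @return An object of class `label_volume`: list with `labels` (integer
#'   array), `affine`, and `voxel_volume` (mm^3).
#' @export
label_volume <- function(labels, affine = diag(4)) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  if (is.double(labels)) {
    if (max(abs(labels - round(labels))) > 1e-6)
      stop("label volume contains non-integer voxel values")
    labels <- round(labels)
  }
  labels <- array(as.integer(labels), dim = dim(labels)) # plain int array
  if (any(labels < 0L)) stop("labels must be >= 0")
  affine <- unclass(affine)
  attributes(affine)[setdiff(names(attributes(affine)), "dim")] <- NULL
  stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  d <- det(affine[1:3, 1:3])
  if (!is.finite(d) || abs(d) < .Machine$double.eps * 100)
    stop("affine is not invertible (|det| ~ 0)")
  structure(list(labels = labels, affine = affine, voxel_volume = abs(d)),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat("label_volume:", paste(dim(x$labels), collapse = " x "),
      "voxels,", format(x$voxel_volume), "mm^3/voxel,",
      length(setdiff(unique(as.vector(x$labels)), 0L)), "labels\n")
  invisible(x)
}

#' Read a NIfTI-1 parcellation as a label volume
#'
#' Loads a NIfTI file (any slope/intercept scaling is applied by the reader)
#' and validates that every voxel value is integral; the sform/qform affine
#' is taken as the 0-based voxel-to-world transform.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a [label_volume()].
#' @section Errors:
#' Voxel values deviating from integers by more than 1e-6, or a singular
#' affine, raise an error: parcellation labels are categorical and must be
#' exact.
#' @export
read_label_volume <- function(path) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) dim(a) <- dim(a)[1:3]
  if (length(dim(a)) != 3L)
    stop("expected a 3D label volume, got ", length(dim(a)), " dimensions")
  aff <- unclass(RNifti::xform(img))
  label_volume(a, aff)
}

#' Write a label volume as NIfTI-1
#'
#' @param x a [label_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(x, path) {
  stopifnot(inherits(x, "label_volume"))
  img <- RNifti::asNifti(x$labels)
  img <- RNifti::`sform<-`(img, structure(x$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Region volumes in mm^3
#'
#' Volume of each label as voxel count times voxel volume (|det| of the
#' affine 3x3 block). A requested label absent from the grid gets volume 0
#' with a warning — downstream density normalization refuses zero-volume
#' regions that carry streamlines.
#'
#' @param x a [label_volume()].
#' @param label_ids integer labels to report; default all nonzero labels
#'   present in the grid.
#' @return named numeric vector of volumes (mm^3), names = label ids.
#' @export
region_volumes <- function(x, label_ids = NULL) {
  stopifnot(inherits(x, "label_volume"))
  counts <- table(x$labels[x$labels > 0L])
  if (is.null(label_ids)) {
    ids <- as.integer(names(counts))
  } else {
    ids <- as.integer(label_ids)
    missing <- setdiff(ids, as.integer(names(counts)))
    if (length(missing))
      warning("label(s) absent from the parcellation, volume 0: ",
              paste(missing, collapse = ", "))
  }
  vols <- ifelse(is.na(match(ids, as.integer(names(counts)))), 0,
                 as.numeric(counts[match(ids, as.integer(names(counts)))]))
  vols <- vols * x$voxel_volume
  names(vols) <- ids
  vols
}
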