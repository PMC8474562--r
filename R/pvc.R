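#' Isotropic Gaussian smoothing of a 3D volume
#'
#' Separable discrete Gaussian convolution with zero padding, used both to
#' emulate the scanner point-spread function in the phantom simulator and to
#' build the geometric transfer matrix. `fwhm_mm = 0` returns the input
#' unchanged.
#'
#' @param vol 3D numeric array.
#' @param fwhm_mm PSF full width at half maximum, mm.
#' @param voxel_size_mm Isotropic voxel size, mm.
#' @export
gaussian_smooth_3d <- function(vol, fwhm_mm, voxel_size_mm) {
  if (fwhm_mm < 0) stopf("'fwhm_mm' must be >= 0")
  if (fwhm_mm == 0) return(vol)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  half <- max(1L, ceiling(4 * sigma_vox))
  kern <- exp(-0.5 * ((-half):half / sigma_vox)^2)
  kern <- kern / sum(kern)
  d <- dim(vol)

  conv_mat <- function(n) {
    # n x n band matrix applying the kernel with zero padding.
    M <- matrix(0, n, n)
    for (off in -half:half) {
      idx <- seq_len(n)
      src <- idx + off
      ok <- src >= 1 & src <= n
      M[cbind(idx[ok], src[ok])] <- M[cbind(idx[ok], src[ok])] + kern[off + half + 1]
    }
    M
  }

  # Axis 1
  M1 <- conv_mat(d[1])
  vol <- array(M1 %*% matrix(vol, d[1], d[2] * d[3]), dim = d)
  # Axis 2
  M2 <- conv_mat(d[2])
  vol <- aperm(array(M2 %*% matrix(aperm(vol, c(2, 1, 3)), d[2], d[1] * d[3]),
                     dim = c(d[2], d[1], d[3])), c(2, 1, 3))
  # Axis 3
  M3 <- conv_mat(d[3])
  vol <- aperm(array(M3 %*% matrix(aperm(vol, c(3, 1, 2)), d[3], d[1] * d[2]),
                     dim = c(d[3], d[1], d[2])), c(2, 3, 1))
  vol
}

#' Labelled ROI volume
#'
#' @param labels 3D integer array; 0 is background.
#' @param voxel_size_mm Isotropic voxel size, mm.
#' @param label_map Named integer vector mapping ROI names to label values;
#'   defaults to `region_<j>` for each foreground label.
#' @return A `label_volume` object. The whole brain is always available as
#'   the union of all foreground labels.
#' @export
label_volume <- function(labels, voxel_size_mm = 2, label_map = NULL) {
  if (any(labels < 0)) stopf("labels must be non-negative")
  ids <- sort(setdiff(unique(as.vector(labels)), 0L))
  if (!length(ids)) stopf("label volume has no foreground labels")
  if (is.null(label_map)) {
    label_map <- setNames(ids, paste0("region_", ids))
  }
  if (!all(label_map %in% ids)) stopf("label_map refers to absent labels")
  structure(list(labels = labels, voxel_size_mm = voxel_size_mm,
                 label_map = label_map),
            class = "label_volume")
}

#' Extract regional time-activity curves from a dynamic volume
#'
#' Per frame and per ROI, the unweighted mean over the ROI's voxels; the
#' whole brain is the mean over the union of all foreground voxels.
#'
#' @param volume4d 4D array (x, y, z, frame), or a 3D array treated as a
#'   single frame.
#' @param labels A [label_volume()].
#' @param scheme A [frame_scheme()] whose frame count matches the 4th
#'   dimension.
#' @param whole_brain Include the whole-brain union curve (default TRUE).
#' @return Named list of [time_activity_curve()] objects.
#' @export
extract_tacs <- function(volume4d, labels, scheme, whole_brain = TRUE) {
  if (length(dim(volume4d)) == 3) dim(volume4d) <- c(dim(volume4d), 1L)
  d <- dim(volume4d)
  if (!all(d[1:3] == dim(labels$labels))) stopf("volume and label grids differ")
  if (d[4] != scheme$n_frames) {
    stopf("frame count %d does not match scheme (%d frames)", d[4], scheme$n_frames)
  }
  lab <- as.vector(labels$labels)
  vmat <- matrix(volume4d, prod(d[1:3]), d[4])
  rois <- labels$label_map
  out <- list()
  for (nm in names(rois)) {
    sel <- lab == rois[[nm]]
    if (!any(sel)) stopf("ROI '%s' (label %d) has no voxels", nm, rois[[nm]])
    out[[nm]] <- time_activity_curve(nm, scheme$frame_start_s,
                                     scheme$frame_dur_s,
                                     colMeans(vmat[sel, , drop = FALSE]))
  }
  if (whole_brain) {
    sel <- lab > 0
    out[["whole_brain"]] <- time_activity_curve("whole_brain",
                                                scheme$frame_start_s,
                                                scheme$frame_dur_s,
                                                colMeans(vmat[sel, , drop = FALSE]))
  }
  out
}

#' Build the geometric transfer matrix
#'
#' `G[i, j]` = mean, over the voxels of region `i`, of the Gaussian-smoothed
#' indicator of region `j`. For a noiseless piecewise-constant image the
#' observed regional means satisfy `observed = G %*% true`, so `solve(G,
#' observed)` recovers the true values exactly. `fwhm_mm = 0` yields the
#' identity.
#'
#' @param labels A [label_volume()].
#' @param psf_fwhm_mm PSF FWHM in mm (>= 0).
#' @return A `gt_matrix` object: `G`, `regions`, `psf_fwhm_mm`, `condition`.
#' @export
build_gtm <- function(labels, psf_fwhm_mm) {
  if (psf_fwhm_mm < 0) stopf("'psf_fwhm_mm' must be >= 0")
  rois <- labels$label_map
  k <- length(rois)
  G <- matrix(0, k, k, dimnames = list(names(rois), names(rois)))
  masks <- lapply(rois, function(id) labels$labels == id)
  for (j in seq_len(k)) {
    ind <- gaussian_smooth_3d(array(as.numeric(masks[[j]]), dim = dim(labels$labels)),
                              psf_fwhm_mm, labels$voxel_size_mm)
    for (i in seq_len(k)) G[i, j] <- mean(ind[masks[[i]]])
  }
  cond <- kappa(G, exact = TRUE)
  if (!is.finite(cond)) stopf("geometric transfer matrix is singular")
  structure(list(G = G, regions = names(rois), psf_fwhm_mm = psf_fwhm_mm,
                 condition = cond),
            class = "gt_matrix")
}

#' Apply region-based (GTM) partial-volume correction
#'
#' Solves `G %*% corrected = observed` for the true regional means. Applies
#' per frame when `observed` is a matrix (regions x frames, TAC-level mode)
#' or to a single vector of regional values (e.g. V_T-level mode).
#'
#' @param observed Numeric vector (one value per region, in `gtm$regions`
#'   order) or a regions x frames matrix.
#' @param gtm A `gt_matrix` from [build_gtm()].
#' @param max_condition Refuse correction when the condition number exceeds
#'   this (default 1e6).
#' @return Corrected values, same shape as `observed`.
#' @export
apply_gtm_pvc <- function(observed, gtm, max_condition = 1e6) {
  if (gtm$condition > max_condition) {
    stopf("geometric transfer matrix too ill-conditioned (cond = %.3g > %.3g)",
          gtm$condition, max_condition)
  }
  k <- length(gtm$regions)
  if (is.matrix(observed)) {
    if (nrow(observed) != k) stopf("'observed' must have one row per region")
    return(solve(gtm$G, observed))
  }
  if (length(observed) != k) stopf("'observed' must have one value per region")
  drop(solve(gtm$G, observed))
}

#' Two-cube test geometry
#'
#' Two disjoint cubes in a 3D grid; the canonical exactly-solvable PVC
#' fixture.
#'
#' @param dim_vox Grid dimension (isotropic; default 40).
#' @param cube_side Cube side in voxels (default 10).
#' @param gap Gap between the cubes in voxels (default 6).
#' @param voxel_size_mm Voxel size (default 2).
#' @return A [label_volume()] with regions `cube_hot` and `cube_cold`.
#' @export
two_cube_labels <- function(dim_vox = 40, cube_side = 10, gap = 6,
                            voxel_size_mm = 2) {
  lab <- array(0L, dim = rep(dim_vox, 3))
  c0 <- floor((dim_vox - (2 * cube_side + gap)) / 2) + 1
  yz <- floor((dim_vox - cube_side) / 2) + seq_len(cube_side)
  lab[c0 + seq_len(cube_side) - 1, yz, yz] <- 1L
  lab[c0 + cube_side + gap + seq_len(cube_side) - 1, yz, yz] <- 2L
  label_volume(lab, voxel_size_mm,
               label_map = c(cube_hot = 1L, cube_cold = 2L))
}

#' Demo multi-region label geometry
#'
#' Six disjoint cuboid "regions" named after the study ROIs, laid out on a
#' 3D grid; a stand-in geometry for pipeline-level tests of TAC extraction
#' and partial-volume correction (not an anatomical atlas).
#'
#' @param dim_vox Grid dimension (default 42).
#' @param voxel_size_mm Voxel size (default 2).
#' @export
demo_label_geometry <- function(dim_vox = 42, voxel_size_mm = 2) {
  regions <- setdiff(default_regions(), "whole_brain")
  lab <- array(0L, dim = rep(dim_vox, 3))
  side <- 8
  origins <- list(c(4, 4, 4), c(22, 4, 4), c(4, 22, 4),
                  c(22, 22, 4), c(4, 4, 22), c(22, 13, 22))
  for (j in seq_along(regions)) {
    o <- origins[[j]]
    lab[o[1] + seq_len(side), o[2] + seq_len(side), o[3] + seq_len(side)] <- j
  }
  label_volume(lab, voxel_size_mm, label_map = setNames(seq_along(regions), regions))
}

#' Read/write NIfTI volumes
#'
#' Thin wrappers around RNifti preserving the affine; activity volumes are
#' written as-is, label volumes as integer images.
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @export
read_nifti_volume <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stopf("RNifti is required for NIfTI I/O")
  }
  img <- RNifti::readNifti(path)
  list(data = as.array(img), voxel_size_mm = RNifti::pixdim(img)[1],
       image = img)
}

#' @rdname read_nifti_volume
#' @param data Numeric array to write.
#' @param voxel_size_mm Isotropic voxel size.
#' @export
write_nifti_volume <- function(data, path, voxel_size_mm = 2) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stopf("RNifti is required for NIfTI I/O")
  }
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- rep(voxel_size_mm, min(3, length(dim(data))))
  RNifti::writeNifti(img, path)
  invisible(path)
}
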