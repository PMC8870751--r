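# Voxel-side densitometry: HU thresholding, compartment statistics, BMD
# calibration, mask volume and iso-surface area.

#' Labeled HU voxel volume
#'
#' @param hu numeric 3D array of Hounsfield units (voxel centers).
#' @param spacing voxel spacing in mm, scalar (isotropic) or length-3.
#' @param masks named list of logical arrays (same shape as `hu`), one per
#'   compartment; compartment masks must be pairwise disjoint.
#' @return an object of class `labeled_volume`.
#' @export
labeled_volume <- function(hu, spacing = 0.5, masks = list(),
                           labels = NULL, mask_names = NULL) {
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (length(dim(hu)) != 3L) stop("hu must be a 3D array")
  # masks are held as one integer label array (0 = background); logical
  # views come from compartment_mask()
  if (is.null(labels)) {
    labels <- array(0L, dim(hu))
    mask_names <- names(masks)
    for (i in seq_along(masks)) {
      m <- masks[[i]]
      if (!identical(dim(m), dim(hu)))
        stop("mask ", mask_names[i], " does not match the HU grid shape")
      if (any(labels[m] != 0L))
        stop("compartment masks are not pairwise disjoint (",
             mask_names[i], ")")
      labels[m] <- i
    }
  } else {
    if (!identical(dim(labels), dim(hu)))
      stop("labels must match the HU grid shape")
  }
  structure(list(hu = hu, spacing = spacing, labels = labels,
                 mask_names = mask_names),
            class = "labeled_volume")
}

#' Logical mask of one compartment
#' @param volume a [labeled_volume()].
#' @param name compartment name (one of `volume$mask_names`).
#' @return logical array.
#' @export
compartment_mask <- function(volume, name) {
  i <- match(name, volume$mask_names)
  if (is.na(i)) stop("no such compartment mask: ", name)
  volume$labels == i
}

#' @export
print.labeled_volume <- function(x, ...) {
  cat(sprintf("<labeled_volume %s, spacing %s mm, %d masks>\n",
              paste(dim(x$hu), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "/"),
              length(x$mask_names)))
  invisible(x)
}

#' Threshold a HU interval within a mask
#'
#' Keeps voxels with `lo <= HU <= hi` (inclusive at both ends) that are also
#' inside `within`. The cartilage default in the pipeline is 0-300 HU.
#'
#' @param volume a [labeled_volume()].
#' @param lo,hi HU bounds, `lo <= hi`.
#' @param within logical array; defaults to the whole grid.
#' @return logical array.
#' @export
threshold_mask <- function(volume, lo = 0, hi = 300, within = NULL) {
  if (lo > hi) stop("lo must not exceed hi")
  keep <- volume$hu >= lo & volume$hu <= hi
  if (!is.null(within)) keep <- keep & within
  keep
}

#' Density statistics and volume of a compartment mask
#'
#' @param volume a [labeled_volume()].
#' @param mask logical array (or the name of a stored compartment mask).
#' @param name compartment name used in error messages.
#' @return list with `mean_hu`, `sd_hu` (n-1 denominator), `volume_mm3`
#'   (voxel count times voxel volume) and `n_voxels`.
#' @export
mask_density_stats <- function(volume, mask, name = "compartment") {
  if (is.character(mask)) {
    name <- mask
    mask <- compartment_mask(volume, mask)
  }
  n <- sum(mask)
  if (n == 0L) stop("empty mask for ", name)
  v <- volume$hu[mask]
  list(mean_hu = mean(v),
       sd_hu = if (n > 1L) stats::sd(v) else 0,
       volume_mm3 = n * prod(volume$spacing),
       n_voxels = n)
}

#' Fit a linear HU-to-BMD calibration from phantom pairs
#'
#' Ordinary least squares on (HU, known density) phantom measurements.
#'
#' @param pairs data.frame or matrix with columns HU and density (g/cm^3).
#' @return object of class `bmd_calibration` with `slope` (g/cm^3 per HU),
#'   `intercept` (g/cm^3), `residual_rms` and the provenance pairs.
#' @export
calibrate_bmd <- function(pairs) {
  pairs <- as.data.frame(pairs)
  names(pairs)[1:2] <- c("hu", "density")
  if (nrow(pairs) < 2L) stop("need at least 2 phantom pairs")
  if (length(unique(pairs$hu)) < 2L)
    stop("phantom HU values must include at least 2 distinct values")
  fit <- stats::lm(density ~ hu, data = pairs)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 residual_rms = sqrt(mean(stats::residuals(fit)^2)),
                 provenance = pairs),
            class = "bmd_calibration")
}

#' Apply a BMD calibration
#' @param cal a [calibrate_bmd()] result.
#' @param hu numeric HU values.
#' @return densities in g/cm^3 (`slope * HU + intercept`).
#' @export
apply_bmd <- function(cal, hu) cal$slope * hu + cal$intercept

#' Inverse of a BMD calibration (g/cm^3 to HU)
#' @param cal a [calibrate_bmd()] result.
#' @param bmd densities in g/cm^3.
#' @return HU values.
#' @export
invert_bmd <- function(cal, bmd) (bmd - cal$intercept) / cal$slope

#' Surface area of a voxel mask
#'
#' Extracts the 0.5-level iso-surface between in- and out-voxels (mask
#' padded at the volume border when it touches it) and sums triangle areas.
#'
#' @param mask logical 3D array.
#' @param spacing voxel spacing (mm), scalar or length-3.
#' @param smooth box-smoothing passes before extraction; see
#'   [mask_isosurface()].
#' @return list with `area_mm2` and `surface`.
#' @export
mask_surface_area <- function(mask, spacing = 0.5, smooth = 2L) {
  iso <- mask_isosurface(mask, spacing = spacing, smooth = smooth)
  list(area_mm2 = iso$area, surface = iso$surface)
}

#' Write / read a labeled volume as NIfTI
#'
#' The HU grid is stored as one NIfTI image and the compartment masks as a
#' single uint8 label image (0 = background, i = i-th mask).
#' @param volume a [labeled_volume()].
#' @param hu_path,label_path output NIfTI paths (.nii or .nii.gz).
#' @return invisibly, the two paths.
#' @export
write_labeled_volume <- function(volume, hu_path, label_path) {
  hu_img <- RNifti::asNifti(volume$hu, internal = FALSE)
  RNifti::pixdim(hu_img) <- volume$spacing
  RNifti::writeNifti(hu_img, hu_path)
  lab_img <- RNifti::asNifti(volume$labels, internal = FALSE)
  RNifti::pixdim(lab_img) <- volume$spacing
  RNifti::writeNifti(lab_img, label_path, datatype = "uint8")
  invisible(c(hu_path, label_path))
}

#' @rdname write_labeled_volume
#' @param mask_names names for the labels in the label image.
#' @export
read_labeled_volume <- function(hu_path, label_path, mask_names = NULL) {
  hu <- as.array(RNifti::readNifti(hu_path))
  img <- RNifti::readNifti(label_path)
  spacing <- RNifti::pixdim(img)[1:3]
  lab <- as.array(img)
  storage.mode(lab) <- "integer"
  ids <- sort(setdiff(unique(as.vector(lab)), 0L))
  nm <- if (is.null(mask_names)) paste0("mask", seq_len(max(ids, 0))) else
    mask_names
  labeled_volume(hu, spacing = spacing, labels = lab, mask_names = nm)
}
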