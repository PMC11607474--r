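#' Specification of a synthetic PET phantom
#'
#' Defines a 3-D SUV-calibrated phantom: a uniform background with
#' non-overlapping ellipsoidal lesions of uniform interior uptake, optionally
#' degraded by additive Gaussian noise truncated at zero. Uniform ellipsoids
#' keep the ground truth exact: each lesion's true volume is the analytic
#' \eqn{\frac{4}{3}\pi r_1 r_2 r_3} and its true centroid is the specified
#' center, so segmentation accuracy can be scored without a reference
#' segmentation.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param voxel_spacing_mm numeric length-3, physical voxel spacing in mm.
#' @param background_suv background SUV (dimensionless), default 0.5.
#' @param noise_sd SD of additive Gaussian noise in SUV units (0 = noise-free).
#' @param lesions list of lesions, each a list with `center_mm` (length 3),
#'   `radii_mm` (length 3, all > 0) and `peak_suv` (> background).
#' @param seed integer RNG seed; recorded in the phantom metadata.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape, voxel_spacing_mm,
                         background_suv = 0.5, noise_sd = 0,
                         lesions = list(), seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  voxel_spacing_mm <- as.numeric(voxel_spacing_mm)
  if (length(grid_shape) != 3L || any(grid_shape < 1L)) {
    stop("grid_shape must be three positive integers", call. = FALSE)
  }
  if (length(voxel_spacing_mm) != 3L || any(voxel_spacing_mm <= 0)) {
    stop("voxel_spacing_mm must be three positive numbers", call. = FALSE)
  }
  if (background_suv < 0) stop("background_suv must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  extent <- grid_shape * voxel_spacing_mm
  for (i in seq_along(lesions)) {
    les <- lesions[[i]]
    if (!all(c("center_mm", "radii_mm", "peak_suv") %in% names(les))) {
      stop("each lesion needs center_mm, radii_mm, peak_suv", call. = FALSE)
    }
    if (length(les$center_mm) != 3L || length(les$radii_mm) != 3L) {
      stop("lesion center_mm and radii_mm must have length 3", call. = FALSE)
    }
    if (any(les$radii_mm <= 0)) {
      stop(sprintf("lesion %d: all radii must be > 0", i), call. = FALSE)
    }
    if (les$peak_suv <= background_suv) {
      stop(sprintf("lesion %d: peak_suv must exceed background_suv", i),
           call. = FALSE)
    }
    if (any(les$center_mm < 0) || any(les$center_mm > extent)) {
      stop(sprintf("lesion %d: center outside grid bounds", i), call. = FALSE)
    }
    if (any(les$center_mm - les$radii_mm < 0) ||
        any(les$center_mm + les$radii_mm > extent)) {
      stop(sprintf("lesion %d: ellipsoid extends outside the grid", i),
           call. = FALSE)
    }
  }
  structure(
    list(grid_shape = grid_shape, voxel_spacing_mm = voxel_spacing_mm,
         background_suv = background_suv, noise_sd = noise_sd,
         lesions = lesions, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Generate a PET phantom with exact ground truth
#'
#' Rasterizes the ellipsoids of a [phantom_spec()] onto the voxel grid
#' (a voxel belongs to a lesion when its center lies inside the ellipsoid),
#' adds truncated Gaussian noise if requested, and returns both the volume
#' and the analytic ground truth. Ground-truth volumes are the exact
#' ellipsoid volumes, not voxel counts; centroids are the specified centers.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `volume` (a `pet_volume` holding SUV values)
#'   and `ground_truth` (a `lesion_set` with analytic volumes and centroids).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$grid_shape
  sp <- spec$voxel_spacing_mm
  vol <- array(spec$background_suv, dim = dims)
  owner <- array(0L, dim = dims)
  gt <- vector("list", length(spec$lesions))
  for (i in seq_along(spec$lesions)) {
    les <- spec$lesions[[i]]
    # bounding box in voxel indices, then exact inside test on voxel centers
    lo <- pmax(1L, floor((les$center_mm - les$radii_mm) / sp - 1))
    hi <- pmin(dims, ceiling((les$center_mm + les$radii_mm) / sp + 1))
    ii <- seq.int(lo[1L], hi[1L]); jj <- seq.int(lo[2L], hi[2L])
    kk <- seq.int(lo[3L], hi[3L])
    grid <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
    ctr <- voxel_centers_mm(grid, sp)
    u <- sweep(ctr, 2L, les$center_mm, "-")
    u <- sweep(u, 2L, les$radii_mm, "/")
    inside <- rowSums(u^2) <= 1
    vox <- grid[inside, , drop = FALSE]
    if (nrow(vox) == 0L) {
      stop(sprintf("lesion %d covers no voxel center; enlarge radii or refine the grid", i),
           call. = FALSE)
    }
    lin <- vox[, 1L] + dims[1L] * (vox[, 2L] - 1L) +
      dims[1L] * dims[2L] * (vox[, 3L] - 1L)
    if (any(owner[lin] != 0L)) {
      stop(sprintf("lesion %d overlaps lesion %d; phantom lesions must be disjoint",
                   i, owner[lin][owner[lin] != 0L][1L]), call. = FALSE)
    }
    owner[lin] <- i
    vol[lin] <- les$peak_suv
    gt[[i]] <- new_lesion(
      voxels = lin, suv_max = les$peak_suv, suv_mean = les$peak_suv,
      n_voxels = length(lin),
      volume_cm3 = 4 / 3 * pi * prod(les$radii_mm) / 1000,
      centroid_mm = as.numeric(les$center_mm)
    )
  }
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    vol <- vol + array(stats::rnorm(length(vol), 0, spec$noise_sd), dim = dims)
    vol[vol < 0] <- 0
  }
  volume <- pet_volume(vol, spacing_mm = sp, kind = "suv",
                       meta = list(seed = spec$seed,
                                   background_suv = spec$background_suv,
                                   noise_sd = spec$noise_sd))
  list(volume = volume, ground_truth = lesion_set(gt))
}

#' PET volume container
#'
#' A light container for a 3-D grid of voxel values plus geometry and
#' acquisition metadata. `kind` records whether values are activity
#' concentration (kBq/mL) or already SUV-calibrated.
#'
#' @param data 3-D numeric array.
#' @param spacing_mm numeric length-3 voxel spacing in mm.
#' @param kind `"suv"` or `"activity"` (activity concentration in kBq/mL).
#' @param meta named list of acquisition metadata (free-form).
#' @return object of class `pet_volume`.
#' @export
pet_volume <- function(data, spacing_mm, kind = c("suv", "activity"),
                       meta = list()) {
  kind <- match.arg(kind)
  if (length(dim(data)) != 3L) stop("data must be a 3-D array", call. = FALSE)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0)) {
    stop("spacing_mm must be three positive numbers", call. = FALSE)
  }
  if (any(data < 0, na.rm = TRUE)) {
    stop("voxel values must be nonnegative", call. = FALSE)
  }
  structure(list(data = data, spacing_mm = as.numeric(spacing_mm),
                 kind = kind, meta = meta),
            class = "pet_volume")
}

#' @export
print.pet_volume <- function(x, ...) {
  cat(sprintf("<pet_volume> %s grid %s, spacing %s mm, range [%.3g, %.3g]\n",
              x$kind, paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing_mm), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Write / read a phantom as NIfTI-1 plus JSON ground-truth sidecar
#'
#' The volume goes to `<path>.nii.gz` with its voxel spacing in the header;
#' ground truth (analytic lesion volumes, centroids, peak SUV, seed) goes to
#' `<path>.json`.
#'
#' @param phantom the list returned by [generate_phantom()].
#' @param path file stem (no extension).
#' @return `write_phantom` returns `path` invisibly; `read_phantom` returns a
#'   list with `volume` and `ground_truth` (a data frame).
#' @export
write_phantom <- function(phantom, path) {
  img <- RNifti::asNifti(phantom$volume$data,
                         pixdim = phantom$volume$spacing_mm)
  RNifti::writeNifti(img, paste0(path, ".nii.gz"))
  gt <- phantom$ground_truth
  side <- list(
    spacing_mm = phantom$volume$spacing_mm,
    meta = phantom$volume$meta,
    lesions = lapply(gt$lesions, function(l) {
      list(volume_cm3 = l$volume_cm3, centroid_mm = l$centroid_mm,
           peak_suv = l$suv_max)
    })
  )
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(path) {
  img <- RNifti::readNifti(paste0(path, ".nii.gz"))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vol <- pet_volume(array(as.numeric(img), dim = dim(img)),
                    spacing_mm = as.numeric(side$spacing_mm),
                    kind = "suv", meta = as.list(side$meta))
  list(volume = vol, ground_truth = side$lesions)
}
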