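#' Lesion and lesion-set containers
#'
#' A `lesion` is one connected hypermetabolic component with its SUV
#' statistics, physical volume and intensity-weighted centroid. A
#' `lesion_set` aggregates per-patient burden: total metabolic tumor volume
#' (MTV, cm^3) is the sum of lesion volumes and total lesion glycolysis (TLG)
#' is the sum of volume x SUVmean over lesions (SUVmean in body-weight
#' units, the universal TLG convention).
#'
#' @param voxels integer vector of linear voxel indices.
#' @param suv_max,suv_mean lesion SUV statistics (dimensionless).
#' @param n_voxels voxel count.
#' @param volume_cm3 lesion volume in cm^3.
#' @param centroid_mm intensity-weighted centroid, physical mm.
#' @return `new_lesion` an object of class `lesion`; `lesion_set` an object
#'   of class `lesion_set` with `lesions`, `total_mtv_cm3`, `total_tlg`.
#' @export
new_lesion <- function(voxels, suv_max, suv_mean, n_voxels, volume_cm3,
                       centroid_mm) {
  if (n_voxels < 1L || volume_cm3 <= 0) {
    stop("lesion must contain at least one voxel", call. = FALSE)
  }
  if (suv_mean > suv_max + 1e-12) {
    stop("suv_mean cannot exceed suv_max", call. = FALSE)
  }
  structure(list(voxels = voxels, suv_max = suv_max, suv_mean = suv_mean,
                 n_voxels = n_voxels, volume_cm3 = volume_cm3,
                 centroid_mm = centroid_mm),
            class = "lesion")
}

#' @param lesions list of `lesion` objects.
#' @rdname new_lesion
#' @export
lesion_set <- function(lesions) {
  stopifnot(all(vapply(lesions, inherits, logical(1), "lesion")))
  structure(list(
    lesions = lesions,
    n_lesions = length(lesions),
    total_mtv_cm3 = sum(vapply(lesions, `[[`, numeric(1), "volume_cm3")),
    total_tlg = sum(vapply(lesions, function(l) l$volume_cm3 * l$suv_mean,
                           numeric(1)))
  ), class = "lesion_set")
}

#' @export
print.lesion_set <- function(x, ...) {
  cat(sprintf("<lesion_set> %d lesion(s), MTV %.2f cm^3, TLG %.2f\n",
              x$n_lesions, x$total_mtv_cm3, x$total_tlg))
  invisible(x)
}

#' Detect candidate hypermetabolic components
#'
#' Thresholds the SUV volume at a fixed seed level and returns the maximal
#' connected components, replacing the manual region placement of clinical
#' workstations with a reproducible rule. Components are ordered by
#' descending SUVmax; those smaller than `min_voxels` are discarded.
#'
#' @param suv_volume a `pet_volume` of kind `"suv"` or a 3-D SUV array.
#' @param seed_threshold_suv absolute SUV seed threshold (default 2.5).
#' @param connectivity 6, 18 or 26 (default 26: faces, edges, corners).
#' @param min_voxels minimum component size kept (default 2, suppressing
#'   single-voxel noise; use 1 for noise-free phantoms).
#' @return list of integer vectors of linear voxel indices (possibly empty).
#' @export
detect_candidates <- function(suv_volume, seed_threshold_suv = 2.5,
                              connectivity = 26L, min_voxels = 2L) {
  arr <- if (inherits(suv_volume, "pet_volume")) suv_volume$data else suv_volume
  if (any(arr < 0)) stop("SUV volume must be nonnegative", call. = FALSE)
  comps <- connected_components_3d(arr >= seed_threshold_suv, connectivity)
  comps <- comps[vapply(comps, length, integer(1)) >= min_voxels]
  if (length(comps) == 0L) return(list())
  peaks <- vapply(comps, function(v) max(arr[v]), numeric(1))
  comps[order(peaks, decreasing = TRUE)]
}

#' Segment one lesion at 41% of its SUVmax
#'
#' EANM-style isocontour segmentation: the threshold is 0.41 x the seed
#' component's SUVmax. The component's bounding box is dilated by
#' `dilate_voxels` so the isocontour can grow past the seed threshold when
#' 41% of SUVmax falls below it, then the retained region is the connected
#' piece (under `connectivity`) containing the component's hottest voxel.
#' Because the threshold is relative, the segmented voxel set is invariant
#' to rescaling the whole volume.
#'
#' @param component integer vector of linear voxel indices (a seed component).
#' @param suv_volume a `pet_volume` (kind `"suv"`) — needed for spacing.
#' @param fraction isocontour fraction of SUVmax (default 0.41).
#' @param dilate_voxels bounding-box dilation in voxels (default 5).
#' @param connectivity 6, 18 or 26.
#' @return a `lesion`.
#' @export
segment_41pct <- function(component, suv_volume, fraction = 0.41,
                          dilate_voxels = 5L, connectivity = 26L) {
  stopifnot(inherits(suv_volume, "pet_volume"))
  if (length(component) == 0L) stop("component is empty", call. = FALSE)
  arr <- suv_volume$data
  dims <- dim(arr)
  peak <- max(arr[component])
  peak_vox <- component[which.max(arr[component])]
  thr <- fraction * peak
  co <- arrayInd(component, dims)
  lo <- pmax(1L, apply(co, 2L, min) - dilate_voxels)
  hi <- pmin(dims, apply(co, 2L, max) + dilate_voxels)
  sub <- arr[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L], drop = FALSE]
  dim(sub) <- hi - lo + 1L
  comps <- connected_components_3d(sub >= thr, connectivity)
  # locate the hottest seed voxel in subvolume coordinates
  pk <- arrayInd(peak_vox, dims) - rep(lo, each = 1L)
  pk_lin <- (pk[1L] + 1L) + (hi[1L] - lo[1L] + 1L) * pk[2L] +
    (hi[1L] - lo[1L] + 1L) * (hi[2L] - lo[2L] + 1L) * pk[3L]
  keep <- comps[vapply(comps, function(v) pk_lin %in% v, logical(1))]
  vox_sub <- keep[[1L]]
  sub_ind <- arrayInd(vox_sub, dim(sub))
  full_ind <- sweep(sub_ind, 2L, lo - 1L, "+")
  vox <- full_ind[, 1L] + dims[1L] * (full_ind[, 2L] - 1L) +
    dims[1L] * dims[2L] * (full_ind[, 3L] - 1L)
  suv <- arr[vox]
  ctr <- voxel_centers_mm(full_ind, suv_volume$spacing_mm)
  w <- suv / sum(suv)
  new_lesion(
    voxels = sort(vox),
    suv_max = max(suv),
    suv_mean = mean(suv),
    n_voxels = length(vox),
    volume_cm3 = length(vox) * prod(suv_volume$spacing_mm) / 1000,
    centroid_mm = as.numeric(colSums(ctr * w))
  )
}

#' Detect and segment all lesions in a volume
#'
#' Convenience chain of [detect_candidates()] and [segment_41pct()]. Seeds
#' whose 41% isocontour grows onto the same hottest voxel are merged into a
#' single lesion.
#'
#' @inheritParams detect_candidates
#' @inheritParams segment_41pct
#' @return a `lesion_set` (possibly empty).
#' @export
segment_lesions <- function(suv_volume, seed_threshold_suv = 2.5,
                            connectivity = 26L, min_voxels = 2L,
                            fraction = 0.41, dilate_voxels = 5L) {
  comps <- detect_candidates(suv_volume, seed_threshold_suv, connectivity,
                             min_voxels)
  lesions <- lapply(comps, segment_41pct, suv_volume = suv_volume,
                    fraction = fraction, dilate_voxels = dilate_voxels,
                    connectivity = connectivity)
  if (length(lesions) > 1L) {
    peak_vox <- vapply(lesions, function(l) l$voxels[which.max(
      suv_volume$data[l$voxels])], integer(1))
    lesions <- lesions[!duplicated(peak_vox)]
  }
  lesion_set(lesions)
}

#' Per-patient burden features from segmented lesions
#'
#' @param maps output of [suv_maps()] (or a list with at least `suv_bw`,
#'   `suv_lbm`, `suv_bsa` as `pet_volume`s or arrays on the same grid).
#' @param lesions a non-empty `lesion_set` segmented on the bw map.
#' @return list with `suv_max_bw`, `suv_max_lbm`, `suv_max_bsa` (max over all
#'   lesion voxels, per normalization), `mtv_cm3`, `tlg`, `n_lesions`.
#' @export
quantify_patient <- function(maps, lesions) {
  stopifnot(inherits(lesions, "lesion_set"))
  if (lesions$n_lesions == 0L) {
    stop("empty lesion set: no hypermetabolic lesion found", call. = FALSE)
  }
  vox <- unlist(lapply(lesions$lesions, `[[`, "voxels"))
  grab <- function(m) if (inherits(m, "pet_volume")) m$data else m
  list(
    suv_max_bw  = max(grab(maps$suv_bw)[vox]),
    suv_max_lbm = max(grab(maps$suv_lbm)[vox]),
    suv_max_bsa = max(grab(maps$suv_bsa)[vox]),
    mtv_cm3 = lesions$total_mtv_cm3,
    tlg = lesions$total_tlg,
    n_lesions = lesions$n_lesions
  )
}

#' Spleen and bone-marrow involvement rules
#'
#' Spleen disease: focal splenic uptake, or diffuse splenic uptake above
#' 1.5 x the liver background. Bone-marrow disease: focal marrow uptake.
#'
#' @param liver_suv_mean liver background SUVmean (> 0, required).
#' @param spleen_suv_mean diffuse spleen SUVmean.
#' @param spleen_focal TRUE if focal splenic uptake present.
#' @param marrow_focal TRUE if focal bone-marrow uptake present.
#' @param spleen_ratio diffuse-uptake multiplier of liver (default 1.5).
#' @return list with logical `spleen_involved`, `marrow_involved`.
#' @export
organ_involvement <- function(liver_suv_mean, spleen_suv_mean = NA_real_,
                              spleen_focal = FALSE, marrow_focal = FALSE,
                              spleen_ratio = 1.5) {
  if (is.na(liver_suv_mean) || liver_suv_mean <= 0) {
    stop("liver reference SUV is required and must be > 0", call. = FALSE)
  }
  diffuse <- !is.na(spleen_suv_mean) &&
    spleen_suv_mean > spleen_ratio * liver_suv_mean
  list(spleen_involved = isTRUE(spleen_focal) || diffuse,
       marrow_involved = isTRUE(marrow_focal))
}
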