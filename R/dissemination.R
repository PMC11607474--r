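#' Maximum tumor dissemination (Dmax)
#'
#' Dmax is the largest Euclidean distance between any two lesions, taken
#' over all unordered pairs (nodal and extranodal alike) and reported in cm.
#' The lesion reference point is the intensity-weighted centroid by default;
#' `point = "peak"` uses each lesion's hottest-voxel position instead.
#' With fewer than two lesions the metric degenerates to 0 and is flagged
#' rather than raising an error.
#'
#' @param lesions a `lesion_set`, or a numeric matrix (n x 3) of lesion
#'   reference coordinates in mm.
#' @param point `"centroid"` (default) or `"peak"`; ignored for a matrix
#'   input.
#' @param suv_volume `pet_volume`, required only for `point = "peak"`.
#' @return list with `dmax_cm`, `argmax_pair` (indices of the two farthest
#'   lesions, lowest pair on ties), `degenerate` (TRUE when < 2 lesions).
#' @export
dmax <- function(lesions, point = c("centroid", "peak"), suv_volume = NULL) {
  point <- match.arg(point)
  if (inherits(lesions, "lesion_set")) {
    if (point == "centroid") {
      pts <- do.call(rbind, lapply(lesions$lesions, `[[`, "centroid_mm"))
    } else {
      stopifnot(inherits(suv_volume, "pet_volume"))
      dims <- dim(suv_volume$data)
      pts <- do.call(rbind, lapply(lesions$lesions, function(l) {
        pv <- l$voxels[which.max(suv_volume$data[l$voxels])]
        voxel_centers_mm(arrayInd(pv, dims), suv_volume$spacing_mm)
      }))
    }
  } else {
    pts <- as.matrix(lesions)
    if (ncol(pts) != 3L) stop("coordinate matrix must be n x 3", call. = FALSE)
  }
  n <- NROW(pts)
  if (is.null(pts) || n < 2L) {
    return(list(dmax_cm = 0, argmax_pair = NULL, degenerate = TRUE))
  }
  d <- as.matrix(stats::dist(pts))
  # lowest index pair on ties: scan column-major over the upper triangle
  best <- -Inf; pair <- c(1L, 2L)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (d[i, j] > best + 1e-12) {
        best <- d[i, j]; pair <- c(i, j)
      }
    }
  }
  list(dmax_cm = best / 10, argmax_pair = pair, degenerate = FALSE)
}

#' Body-surface-area-corrected dissemination
#'
#' Dmax-bsa is the plain quotient Dmax / BSA (cm per m^2), the convention
#' consistent with typical adult BSA and the relative magnitudes of the two
#' metrics in clinical series.
#'
#' @param dmax_cm Dmax in cm (>= 0).
#' @param bsa_m2 body surface area in m^2 (> 0), e.g. from [du_bois_bsa()].
#' @return Dmax / BSA.
#' @export
dmax_bsa <- function(dmax_cm, bsa_m2) {
  if (any(dmax_cm < 0)) stop("dmax_cm must be >= 0", call. = FALSE)
  stop_if_not_positive(bsa_m2, "bsa_m2")
  dmax_cm / bsa_m2
}
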