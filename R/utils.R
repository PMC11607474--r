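#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

stop_if_not_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("'%s' must be a finite positive number", name), call. = FALSE)
  }
  invisible(x)
}

#' Physical coordinates of voxel centers
#'
#' Voxel indices are 1-based grid coordinates; the center of voxel
#' `(i, j, k)` sits at `(i - 0.5) * spacing` mm along each axis, so the
#' volume's physical origin is the outer corner of the first voxel.
#'
#' @param ind integer matrix (n x 3) of voxel indices.
#' @param spacing_mm numeric length-3 voxel spacing in mm.
#' @return numeric matrix (n x 3) of coordinates in mm.
#' @keywords internal
voxel_centers_mm <- function(ind, spacing_mm) {
  sweep(ind - 0.5, 2L, spacing_mm, "*")
}

# Neighbour offsets for 3-D connectivity 6 (faces), 18 (faces+edges),
# 26 (faces+edges+corners).
neighbor_offsets <- function(connectivity = 26L) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L)) {
    stop("connectivity must be one of 6, 18, 26", call. = FALSE)
  }
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
    "6"  = d == 1L,
    "18" = d >= 1L & d <= 2L,
    "26" = d >= 1L
  )
  unname(g[keep, , drop = FALSE])
}

#' Label 3-D connected components
#'
#' Breadth-first labelling of the TRUE voxels of a 3-D logical mask under
#' 6/18/26 connectivity. Written in-package because no installed R package
#' exposes 3-D connectivity labelling.
#'
#' @param mask 3-D logical array.
#' @param connectivity 6, 18 or 26.
#' @return list of integer vectors, each the linear voxel indices of one
#'   component, in first-encounter order.
#' @keywords internal
connected_components_3d <- function(mask, connectivity = 26L) {
  dims <- dim(mask)
  if (length(dims) != 3L) stop("mask must be a 3-D array", call. = FALSE)
  offs <- neighbor_offsets(connectivity)
  seeds <- which(mask)
  if (length(seeds) == 0L) return(list())
  labelled <- logical(length(mask))
  comps <- list()
  for (s in seeds) {
    if (labelled[s]) next
    labelled[s] <- TRUE
    comp <- s
    frontier <- s
    while (length(frontier) > 0L) {
      co <- arrayInd(frontier, dims)
      # expand every frontier voxel by every offset at once
      nrep <- nrow(offs)
      cand <- co[rep(seq_len(nrow(co)), each = nrep), , drop = FALSE] +
        offs[rep(seq_len(nrep), times = nrow(co)), , drop = FALSE]
      ok <- cand[, 1L] >= 1L & cand[, 1L] <= dims[1L] &
        cand[, 2L] >= 1L & cand[, 2L] <= dims[2L] &
        cand[, 3L] >= 1L & cand[, 3L] <= dims[3L]
      cand <- cand[ok, , drop = FALSE]
      if (nrow(cand) == 0L) break
      lin <- cand[, 1L] + dims[1L] * (cand[, 2L] - 1L) +
        dims[1L] * dims[2L] * (cand[, 3L] - 1L)
      lin <- unique(lin[mask[lin] & !labelled[lin]])
      if (length(lin) == 0L) break
      labelled[lin] <- TRUE
      comp <- c(comp, lin)
      frontier <- lin
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}
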