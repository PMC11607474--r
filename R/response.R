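#' Deauville five-point score for end-of-treatment PET
#'
#' Grades residual uptake against the mediastinal blood pool and liver:
#' 1 = no uptake above background; 2 = uptake <= mediastinum; 3 = above
#' mediastinum but <= liver; 4 = moderately above liver (up to
#' `k_marked` x liver); 5 = markedly above liver (> `k_marked` x liver) or
#' new lesions. Residual exactly at the liver level scores 3 (standard
#' Deauville semantics: DS3 is uptake up to and including the liver).
#'
#' @param residual_suv_max SUVmax of the hottest residual lesion; 0 when no
#'   residual uptake is present.
#' @param mediastinum_suv mediastinal blood-pool reference SUV (> 0).
#' @param liver_suv liver reference SUV (> 0); expected above the
#'   mediastinum (a warning is issued otherwise).
#' @param new_lesions TRUE if new FDG-avid lesions appeared.
#' @param k_marked multiplier of liver uptake separating "moderately" from
#'   "markedly" increased (default 2, the conservative end of the 2-3x
#'   guidance range).
#' @param background_suv uptake level counted as "no uptake" (default 0).
#' @return integer score in 1..5.
#' @export
deauville_score <- function(residual_suv_max, mediastinum_suv, liver_suv,
                            new_lesions = FALSE, k_marked = 2,
                            background_suv = 0) {
  if (residual_suv_max < 0) stop("residual SUV must be >= 0", call. = FALSE)
  stop_if_not_positive(mediastinum_suv, "mediastinum_suv")
  stop_if_not_positive(liver_suv, "liver_suv")
  if (mediastinum_suv >= liver_suv) {
    warning("mediastinal reference is not below the liver reference")
  }
  if (isTRUE(new_lesions)) return(5L)
  if (residual_suv_max <= background_suv) 1L
  else if (residual_suv_max <= mediastinum_suv) 2L
  else if (residual_suv_max <= liver_suv) 3L
  else if (residual_suv_max <= k_marked * liver_suv) 4L
  else 5L
}

#' Lugano binary metabolic response from a Deauville score
#'
#' Complete metabolic response corresponds to Deauville 1-3 without new
#' lesions; scores 4-5 (or any new lesion) are not complete. Forcing
#' `not_complete` on new lesions even at low residual uptake follows the
#' Lugano convention.
#'
#' @param deauville integer score 1..5.
#' @param new_lesions TRUE if new FDG-avid lesions appeared.
#' @return `"complete"` or `"not_complete"`.
#' @export
lugano_response <- function(deauville, new_lesions = FALSE) {
  deauville <- as.integer(deauville)
  if (is.na(deauville) || deauville < 1L || deauville > 5L) {
    stop("deauville score must be in 1..5", call. = FALSE)
  }
  if (deauville <= 3L && !isTRUE(new_lesions)) "complete" else "not_complete"
}
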