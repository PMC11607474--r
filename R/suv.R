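#' Body surface area by the Du Bois formula
#'
#' \deqn{BSA = 0.007184 \times height_{cm}^{0.725} \times weight_{kg}^{0.425}}
#'
#' @param weight_kg body weight in kg (> 0).
#' @param height_cm height in cm (> 0).
#' @return body surface area in m^2.
#' @examples
#' du_bois_bsa(70, 170) # ~1.81 m^2
#' @export
du_bois_bsa <- function(weight_kg, height_cm) {
  stop_if_not_positive(weight_kg, "weight_kg")
  stop_if_not_positive(height_cm, "height_cm")
  0.007184 * height_cm^0.725 * weight_kg^0.425
}

#' Lean body mass (James equations)
#'
#' James (1976): male \eqn{1.10 W - 128 (W/H)^2}, female
#' \eqn{1.07 W - 148 (W/H)^2}, with W in kg and H in cm. The result must fall
#' strictly inside (0, W); anthropometrics extreme enough to violate that are
#' rejected rather than clamped silently.
#'
#' @param weight_kg body weight in kg.
#' @param height_cm height in cm.
#' @param sex `"male"` or `"female"`.
#' @return lean body mass in kg.
#' @export
lean_body_mass <- function(weight_kg, height_cm, sex = c("male", "female")) {
  sex <- match.arg(sex)
  stop_if_not_positive(weight_kg, "weight_kg")
  stop_if_not_positive(height_cm, "height_cm")
  r2 <- (weight_kg / height_cm)^2
  lbm <- if (sex == "male") 1.10 * weight_kg - 128 * r2
         else 1.07 * weight_kg - 148 * r2
  if (any(lbm <= 0) || any(lbm >= weight_kg)) {
    stop("implausible anthropometrics: lean body mass outside (0, weight)",
         call. = FALSE)
  }
  lbm
}

#' Patient acquisition metadata
#'
#' @param sex `"male"` or `"female"`.
#' @param age_years age in years.
#' @param weight_kg body weight in kg (> 0).
#' @param height_cm height in cm (> 0).
#' @param injected_activity_MBq injected activity in MBq, decay-corrected to
#'   scan time (> 0).
#' @param uptake_time_min uptake time in minutes (informational).
#' @return object of class `patient_meta`.
#' @export
patient_meta <- function(sex = c("male", "female"), age_years = NA_real_,
                         weight_kg, height_cm, injected_activity_MBq,
                         uptake_time_min = 60) {
  sex <- match.arg(sex)
  stop_if_not_positive(weight_kg, "weight_kg")
  stop_if_not_positive(height_cm, "height_cm")
  stop_if_not_positive(injected_activity_MBq, "injected_activity_MBq")
  structure(list(sex = sex, age_years = age_years, weight_kg = weight_kg,
                 height_cm = height_cm,
                 injected_activity_MBq = injected_activity_MBq,
                 uptake_time_min = uptake_time_min),
            class = "patient_meta")
}

#' Convert activity concentration to SUV
#'
#' SUV = tissue concentration / (injected activity / normalizer). With
#' concentration in kBq/mL and activity in MBq the normalizers are:
#' body weight in kg (`bw`), lean body mass in kg (`lbm`, James equations),
#' and body surface area (`bsa`, Du Bois). For `bsa` the conventional display
#' scale expresses BSA in cm^2 (x 10^4 on m^2), which puts SUVbsa at roughly
#' a quarter of SUVbw for typical adults; set `bsa_scale = 1` for the raw
#' m^2-normalized value.
#'
#' @param volume a `pet_volume` of kind `"activity"` (kBq/mL), or a plain
#'   numeric array/vector of concentrations in kBq/mL.
#' @param meta a [patient_meta()].
#' @param mode `"bw"`, `"lbm"` or `"bsa"`.
#' @param bsa_scale multiplier applied to BSA in m^2 before normalization
#'   (default 1e4, i.e. BSA in cm^2).
#' @return same shape as the input, SUV (dimensionless); a `pet_volume` input
#'   returns a `pet_volume` of kind `"suv"` whose metadata records the
#'   normalization constant.
#' @examples
#' meta <- patient_meta("male", 65, weight_kg = 74, height_cm = 175,
#'                      injected_activity_MBq = 185)
#' activity_to_suv(5, meta, "bw") # 2.0
#' @export
activity_to_suv <- function(volume, meta, mode = c("bw", "lbm", "bsa"),
                            bsa_scale = 1e4) {
  mode <- match.arg(mode)
  stopifnot(inherits(meta, "patient_meta"))
  normalizer_kg <- switch(mode,
    bw  = meta$weight_kg,
    lbm = lean_body_mass(meta$weight_kg, meta$height_cm, meta$sex),
    bsa = du_bois_bsa(meta$weight_kg, meta$height_cm) * bsa_scale / 1000
  )
  # kBq/mL divided by MBq/kg-equivalent: factors of 10^3 cancel with the
  # 1 g/mL tissue-density convention
  factor <- normalizer_kg / meta$injected_activity_MBq
  if (inherits(volume, "pet_volume")) {
    if (volume$kind != "activity") {
      stop("volume is already SUV-calibrated", call. = FALSE)
    }
    meta2 <- volume$meta
    meta2$suv_mode <- mode
    meta2$suv_factor <- factor
    pet_volume(volume$data * factor, volume$spacing_mm, kind = "suv",
               meta = meta2)
  } else {
    volume * factor
  }
}

#' All three SUV normalizations at once
#'
#' @inheritParams activity_to_suv
#' @return list with `suv_bw`, `suv_lbm`, `suv_bsa` (same shape as input) and
#'   `constants` (the per-normalization multiplicative factors applied to
#'   kBq/mL). SUVlbm is voxelwise below SUVbw since LBM < weight.
#' @export
suv_maps <- function(volume, meta, bsa_scale = 1e4) {
  out <- list(
    suv_bw  = activity_to_suv(volume, meta, "bw"),
    suv_lbm = activity_to_suv(volume, meta, "lbm"),
    suv_bsa = activity_to_suv(volume, meta, "bsa", bsa_scale = bsa_scale)
  )
  lbm <- lean_body_mass(meta$weight_kg, meta$height_cm, meta$sex)
  bsa <- du_bois_bsa(meta$weight_kg, meta$height_cm)
  out$constants <- c(
    bw = meta$weight_kg / meta$injected_activity_MBq,
    lbm = lbm / meta$injected_activity_MBq,
    bsa = bsa * bsa_scale / 1000 / meta$injected_activity_MBq
  )
  out
}
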