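#' Cohort descriptive table
#'
#' Simple and relative frequencies for categorical variables (percentages on
#' non-missing denominators) and mean, SD, range and median for numeric
#' variables — the usual baseline-characteristics layout.
#'
#' @param cohort cohort data frame.
#' @param categorical,numeric character vectors of column names; defaults
#'   cover the standard cohort dictionary of [generate_cohort()].
#' @return data frame with columns `variable`, `level`, `n`, `pct`, `mean`,
#'   `sd`, `min`, `max`, `median`.
#' @export
cohort_descriptives <- function(cohort,
    categorical = intersect(c("sex", "stage", "mipi", "ki67_high", "blastoid",
                              "b_symptoms", "ldh_increased", "b2m_increased",
                              "bulky", "splenomegaly", "response"),
                            names(cohort)),
    numeric = intersect(c("age_years", "suv_max_bw", "suv_max_lbm",
                          "suv_max_bsa", "mtv_cm3", "tlg", "dmax_cm",
                          "dmax_bsa"), names(cohort))) {
  rows <- list()
  for (v in categorical) {
    x <- cohort[[v]]
    denom <- sum(!is.na(x))
    tab <- table(x, useNA = "no")
    for (lev in names(tab)) {
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = lev, n = as.integer(tab[[lev]]),
        pct = count_pct(tab[[lev]], denom),
        mean = NA_real_, sd = NA_real_, min = NA_real_, max = NA_real_,
        median = NA_real_, stringsAsFactors = FALSE)
    }
  }
  for (v in numeric) {
    x <- cohort[[v]][!is.na(cohort[[v]])]
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, level = "", n = length(x), pct = NA_real_,
      mean = mean(x), sd = stats::sd(x), min = min(x), max = max(x),
      median = stats::median(x), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Relative frequency as a percentage
#'
#' @param n count.
#' @param denom denominator (non-missing total).
#' @return `100 * n / denom`.
#' @export
count_pct <- function(n, denom) {
  if (any(denom <= 0)) stop("denominator must be positive", call. = FALSE)
  100 * n / denom
}

#' Compare baseline features between response groups
#'
#' Welch t-tests for numeric features and Pearson chi-square tests (no
#' continuity correction) for categorical ones, complete vs not-complete
#' metabolic response.
#'
#' @inheritParams cohort_descriptives
#' @return data frame: `variable`, group means (numeric) or counts
#'   (categorical), `p`.
#' @export
compare_response_groups <- function(cohort,
    categorical = intersect(c("sex", "stage", "blastoid", "b_symptoms",
                              "ldh_increased", "b2m_increased", "bulky",
                              "splenomegaly", "ki67_high", "mipi"),
                            names(cohort)),
    numeric = intersect(c("age_years", "suv_max_bw", "suv_max_lbm",
                          "suv_max_bsa", "mtv_cm3", "tlg", "dmax_cm",
                          "dmax_bsa"), names(cohort))) {
  g <- cohort$response
  keep <- !is.na(g)
  cohort <- cohort[keep, , drop = FALSE]; g <- g[keep]
  cmr <- g == "complete"
  rows <- list()
  for (v in numeric) {
    x <- cohort[[v]]
    p <- tryCatch(stats::t.test(x[cmr], x[!cmr])$p.value,
                  error = function(e) NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, mean_cmr = mean(x[cmr], na.rm = TRUE),
      mean_noncmr = mean(x[!cmr], na.rm = TRUE), p = p,
      stringsAsFactors = FALSE)
  }
  for (v in categorical) {
    x <- cohort[[v]]
    p <- tryCatch(
      suppressWarnings(stats::chisq.test(table(x, cmr), correct = FALSE)$p.value),
      error = function(e) NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, mean_cmr = NA_real_, mean_noncmr = NA_real_, p = p,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# dichotomize continuous PET features at the ROC-optimal (Youden) cutoff
# against the endpoint's event indicator
dichotomize_features <- function(cohort, features, event_col) {
  cuts <- list()
  for (f in features) {
    rc <- roc_best_cutoff(cohort[[f]], cohort[[event_col]])
    cohort[[paste0(f, "_high")]] <- as.integer(cohort[[f]] > rc$threshold)
    cuts[[f]] <- rc$threshold
  }
  list(cohort = cohort, cutoffs = unlist(cuts))
}

#' Univariate Cox screening
#'
#' One Cox model per covariate against the chosen endpoint; continuous PET
#' features are dichotomized at their ROC-optimal cutoff first. The output
#' mirrors a typical univariate prognostic-screen table (HR, 95% CI, p).
#'
#' @param cohort cohort data frame with `<endpoint>_months` and
#'   `<endpoint>_event` columns.
#' @param endpoint `"pfs"` or `"os"`.
#' @param covariates named list mapping display names to 0/1 (or numeric)
#'   columns; `NULL` uses the standard set (clinical covariates plus
#'   dichotomized PET features).
#' @param ties passed to [cox_fit()].
#' @return list with `table` (data frame covariate/hr/ci/p), `cutoffs` (the
#'   ROC thresholds used), `fits` (the `cox_fit` objects).
#' @export
univariate_screen <- function(cohort, endpoint = c("pfs", "os"),
                              covariates = NULL, ties = "efron") {
  endpoint <- match.arg(endpoint)
  pet <- intersect(c("suv_max_bw", "suv_max_lbm", "suv_max_bsa", "mtv_cm3",
                     "tlg", "dmax_cm", "dmax_bsa"), names(cohort))
  dd <- dichotomize_features(cohort, pet, paste0(endpoint, "_event"))
  co <- dd$cohort
  if (is.null(covariates)) {
    covariates <- list()
    add <- function(name, vals) covariates[[name]] <<- as.numeric(vals)
    if ("sex" %in% names(co)) add("sex_male", co$sex == "male")
    if ("age_years" %in% names(co)) add("age_over_65", co$age_years > 65)
    if ("stage" %in% names(co)) add("stage_iv", co$stage == "IV")
    if ("b_symptoms" %in% names(co)) add("b_symptoms", co$b_symptoms)
    if ("blastoid" %in% names(co)) add("blastoid", co$blastoid)
    if ("ldh_increased" %in% names(co)) add("ldh_increased", co$ldh_increased)
    if ("b2m_increased" %in% names(co)) add("b2m_increased", co$b2m_increased)
    if ("bulky" %in% names(co)) add("bulky", co$bulky)
    if ("splenomegaly" %in% names(co)) add("splenomegaly", co$splenomegaly)
    if ("ki67_high" %in% names(co)) add("ki67_high", co$ki67_high)
    if ("mipi" %in% names(co)) add("mipi_high", co$mipi == "high")
    if ("response" %in% names(co)) {
      add("response_noncmr", co$response == "not_complete")
    }
    for (f in pet) add(paste0(f, "_high"), co[[paste0(f, "_high")]])
  }
  smp <- survival_sample(co[[paste0(endpoint, "_months")]],
                         co[[paste0(endpoint, "_event")]],
                         endpoint = toupper(endpoint))
  fits <- list(); rows <- list()
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    fit <- tryCatch(
      cox_fit(matrix(v, dimnames = list(NULL, nm)), smp, ties = ties),
      error = function(e) NULL)
    if (is.null(fit)) next
    cf <- fit$coefficients
    fits[[nm]] <- fit
    rows[[length(rows) + 1L]] <- data.frame(
      covariate = nm, hr = cf$hr, ci_lower = cf$ci_lower,
      ci_upper = cf$ci_upper, p = cf$p, converged = fit$converged,
      stringsAsFactors = FALSE)
  }
  list(table = do.call(rbind, rows), cutoffs = dd$cutoffs, fits = fits)
}

#' Multivariate Cox model from the univariate screen
#'
#' Fits one multivariate Cox model on the covariates whose univariate
#' p-value fell below `alpha` (no stepwise refinement).
#'
#' @param cohort cohort data frame.
#' @param screen output of [univariate_screen()].
#' @param endpoint `"pfs"` or `"os"`.
#' @param alpha univariate entry threshold (default 0.05).
#' @param ties passed to [cox_fit()].
#' @return a `cox_fit`, or `NULL` when fewer than one covariate enters.
#' @export
multivariate_fit <- function(cohort, screen, endpoint = c("pfs", "os"),
                             alpha = 0.05, ties = "efron") {
  endpoint <- match.arg(endpoint)
  sel <- screen$table$covariate[screen$table$p < alpha &
                                  screen$table$converged]
  if (length(sel) < 1L) return(NULL)
  co <- dichotomize_features(cohort,
    intersect(c("suv_max_bw", "suv_max_lbm", "suv_max_bsa", "mtv_cm3", "tlg",
                "dmax_cm", "dmax_bsa"), names(cohort)),
    paste0(endpoint, "_event"))$cohort
  build <- function(nm) {
    switch(nm,
      sex_male = as.numeric(co$sex == "male"),
      age_over_65 = as.numeric(co$age_years > 65),
      stage_iv = as.numeric(co$stage == "IV"),
      mipi_high = as.numeric(co$mipi == "high"),
      response_noncmr = as.numeric(co$response == "not_complete"),
      as.numeric(co[[nm]]))
  }
  xm <- do.call(cbind, lapply(sel, build))
  colnames(xm) <- sel
  smp <- survival_sample(co[[paste0(endpoint, "_months")]],
                         co[[paste0(endpoint, "_event")]],
                         endpoint = toupper(endpoint))
  cox_fit(xm, smp, ties = ties)
}

#' Quantify a set of PET volumes into a per-patient feature table
#'
#' For each patient: convert activity to the three SUV normalizations when
#' needed, detect and segment lesions at the 41% isocontour, and compute
#' SUVmax (bw/lbm/bsa), MTV, TLG, lesion count, Dmax and Dmax-bsa. Patients
#' whose volume fails to load or has no lesion are skipped with a logged
#' reason rather than aborting the run.
#'
#' @param volumes named list of `pet_volume` objects (names = patient ids),
#'   or a character vector of phantom file stems readable by
#'   [read_phantom()].
#' @param meta data frame with columns `patient_id`, `sex`, `weight_kg`,
#'   `height_cm`, `injected_MBq` (ignored for volumes already in SUV units
#'   except for BSA/LBM, which are always needed).
#' @param seed_threshold_suv,connectivity,min_voxels,fraction segmentation
#'   parameters, see [segment_lesions()].
#' @return list with `features` (data frame, one row per quantified patient)
#'   and `skipped` (data frame patient_id/reason).
#' @export
run_quantify <- function(volumes, meta, seed_threshold_suv = 2.5,
                         connectivity = 26L, min_voxels = 2L,
                         fraction = 0.41) {
  if (is.character(volumes)) {
    nm <- if (!is.null(names(volumes))) names(volumes) else basename(volumes)
    paths <- volumes
    volumes <- stats::setNames(vector("list", length(paths)), nm)
    for (i in seq_along(paths)) {
      volumes[[i]] <- tryCatch(read_phantom(paths[[i]])$volume,
                               error = function(e) e$message)
    }
  }
  rows <- list(); skipped <- list()
  skip <- function(id, why) {
    skipped[[length(skipped) + 1L]] <<- data.frame(
      patient_id = id, reason = why, stringsAsFactors = FALSE)
  }
  for (id in names(volumes)) {
    vol <- volumes[[id]]
    if (!inherits(vol, "pet_volume")) {
      skip(id, paste("unreadable volume:", vol)); next
    }
    m <- meta[meta$patient_id == id, , drop = FALSE]
    if (nrow(m) != 1L || anyNA(m[c("sex", "weight_kg", "height_cm")])) {
      skip(id, "missing metadata"); next
    }
    pm <- patient_meta(m$sex, weight_kg = m$weight_kg,
                       height_cm = m$height_cm,
                       injected_activity_MBq =
                         if (!is.null(m$injected_MBq) && !is.na(m$injected_MBq))
                           m$injected_MBq else 185)
    if (vol$kind == "activity") {
      maps <- suv_maps(vol, pm)
    } else {
      lbm <- lean_body_mass(pm$weight_kg, pm$height_cm, pm$sex)
      bsa <- du_bois_bsa(pm$weight_kg, pm$height_cm)
      maps <- list(
        suv_bw = vol,
        suv_lbm = pet_volume(vol$data * lbm / pm$weight_kg, vol$spacing_mm,
                             "suv", vol$meta),
        suv_bsa = pet_volume(vol$data * bsa * 10 / pm$weight_kg,
                             vol$spacing_mm, "suv", vol$meta))
    }
    lesions <- segment_lesions(maps$suv_bw, seed_threshold_suv, connectivity,
                               min_voxels, fraction)
    if (lesions$n_lesions == 0L) { skip(id, "no lesion detected"); next }
    q <- quantify_patient(maps, lesions)
    dm <- dmax(lesions)
    bsa <- du_bois_bsa(pm$weight_kg, pm$height_cm)
    rows[[length(rows) + 1L]] <- data.frame(
      patient_id = id, suv_max_bw = q$suv_max_bw, suv_max_lbm = q$suv_max_lbm,
      suv_max_bsa = q$suv_max_bsa, mtv_cm3 = q$mtv_cm3, tlg = q$tlg,
      n_lesions = q$n_lesions, dmax_cm = dm$dmax_cm,
      dmax_degenerate = dm$degenerate,
      dmax_bsa = dmax_bsa(dm$dmax_cm, bsa), stringsAsFactors = FALSE)
  }
  list(
    features = if (length(rows)) do.call(rbind, rows) else NULL,
    skipped = if (length(skipped)) do.call(rbind, skipped) else
      data.frame(patient_id = character(0), reason = character(0))
  )
}

#' Run the full prognostic analysis on a cohort table
#'
#' Chains the statistical stages on a feature table carrying PFS/OS columns:
#' descriptives, response-group comparison, ROC dichotomization, univariate
#' screen and multivariate Cox per endpoint, Kaplan-Meier medians and
#' 3-/5-year rates, and the combined MTV x response four-group
#' stratification. A JSON-able manifest records the cutoffs and seeds so a
#' run is fully reproducible.
#'
#' @param cohort cohort/feature data frame with `pfs_months`, `pfs_event`,
#'   `os_months`, `os_event` (and `response`, `mtv_cm3` for the combined
#'   strata).
#' @param ties Cox tie handling (`"efron"` or `"breslow"`).
#' @param alpha univariate-to-multivariate entry threshold.
#' @param output_dir optional directory; when given, tables are written as
#'   CSV and the manifest as JSON.
#' @return list: `descriptives`, `response_comparison`, per-endpoint
#'   `univariate`, `multivariate`, `km` (curve + medians + 3/5-year rates),
#'   `combined` (strata factor, per-group KM, log-rank extremes), `manifest`.
#' @export
run_survival <- function(cohort, ties = "efron", alpha = 0.05,
                         output_dir = NULL) {
  if (is.null(cohort) || nrow(cohort) == 0L) {
    stop("empty feature table", call. = FALSE)
  }
  out <- list()
  out$descriptives <- cohort_descriptives(cohort)
  if ("response" %in% names(cohort)) {
    out$response_comparison <- compare_response_groups(cohort)
  }
  for (ep in c("pfs", "os")) {
    tm <- cohort[[paste0(ep, "_months")]]
    ev <- cohort[[paste0(ep, "_event")]]
    if (is.null(tm) || sum(ev) < 2L) {
      warning(sprintf("endpoint %s skipped: fewer than 2 events", ep))
      next
    }
    smp <- survival_sample(tm, ev, toupper(ep))
    km <- km_estimate(smp)
    scr <- univariate_screen(cohort, ep, ties = ties)
    mv <- multivariate_fit(cohort, scr, ep, alpha = alpha, ties = ties)
    out[[ep]] <- list(
      km = km,
      median_months = km$median_months,
      surv_3y = km_surv_at(km, 36),
      surv_5y = km_surv_at(km, 60),
      univariate = scr$table,
      cutoffs = scr$cutoffs,
      multivariate = mv
    )
  }
  if (all(c("response", "mtv_cm3") %in% names(cohort)) &&
      !is.null(out$pfs)) {
    cutoff <- out$pfs$cutoffs[["mtv_cm3"]]
    strata <- combined_strata(cohort$mtv_cm3, cutoff, cohort$response)
    grp_km <- lapply(levels(strata), function(g) {
      sel <- !is.na(strata) & strata == g
      if (sum(sel) == 0L) return(NULL)
      km_estimate(survival_sample(cohort$pfs_months[sel],
                                  cohort$pfs_event[sel], "PFS"))
    })
    names(grp_km) <- levels(strata)
    best <- !is.na(strata) & strata == "lowMTV_CMR"
    worst <- !is.na(strata) & strata == "highMTV_nonCMR"
    lr <- if (sum(best) > 0L && sum(worst) > 0L) {
      logrank_test(
        survival_sample(cohort$pfs_months[best], cohort$pfs_event[best]),
        survival_sample(cohort$pfs_months[worst], cohort$pfs_event[worst]))
    } else NULL
    out$combined <- list(
      strata = strata, mtv_cutoff = cutoff, km = grp_km,
      medians = vapply(grp_km, function(k)
        if (is.null(k)) NA_real_ else k$median_months, numeric(1)),
      logrank_extremes = lr,
      n_missing_response = attr(strata, "n_missing_response"))
  }
  out$manifest <- list(
    package_version = as.character(utils::packageVersion("petburden")),
    n_patients = nrow(cohort),
    ties = ties, alpha = alpha,
    cutoffs = list(pfs = as.list(out$pfs$cutoffs),
                   os = as.list(out$os$cutoffs)),
    seed = if (!is.null(attr(cohort, "config"))) attr(cohort, "config")$seed
           else NA
  )
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out$descriptives,
                     file.path(output_dir, "descriptives.csv"),
                     row.names = FALSE)
    if (!is.null(out$response_comparison)) {
      utils::write.csv(out$response_comparison,
                       file.path(output_dir, "response_comparison.csv"),
                       row.names = FALSE)
    }
    for (ep in c("pfs", "os")) {
      if (is.null(out[[ep]])) next
      utils::write.csv(out[[ep]]$univariate,
                       file.path(output_dir, sprintf("univariate_%s.csv", ep)),
                       row.names = FALSE)
      if (!is.null(out[[ep]]$multivariate)) {
        utils::write.csv(out[[ep]]$multivariate$coefficients,
                         file.path(output_dir,
                                   sprintf("multivariate_%s.csv", ep)),
                         row.names = FALSE)
      }
      km <- out[[ep]]$km
      utils::write.csv(data.frame(time = km$time, n_risk = km$n_risk,
                                  n_event = km$n_event, surv = km$surv),
                       file.path(output_dir, sprintf("km_%s.csv", ep)),
                       row.names = FALSE)
    }
    jsonlite::write_json(out$manifest,
                         file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  }
  out
}
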