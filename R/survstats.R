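#' Right-censored survival sample
#'
#' @param time follow-up times in months (> 0).
#' @param event event indicators (1 = event, 0 = censored).
#' @param endpoint label, e.g. `"PFS"` or `"OS"`.
#' @return object of class `survival_sample`.
#' @export
survival_sample <- function(time, event, endpoint = "PFS") {
  time <- as.numeric(time)
  event <- as.integer(event != 0)
  if (length(time) != length(event)) {
    stop("time and event must have equal length", call. = FALSE)
  }
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("times must be finite and positive", call. = FALSE)
  }
  structure(list(time = time, event = event, endpoint = endpoint),
            class = "survival_sample")
}

#' Kaplan-Meier product-limit estimator
#'
#' \deqn{S(t) = \prod_{t_i \le t} (1 - d_i / n_i)} over distinct event times
#' \eqn{t_i} with \eqn{d_i} events among \eqn{n_i} at risk. The median is the
#' earliest event time with \eqn{S(t) \le 0.5}; when the curve never reaches
#' 0.5 the median is `NA` and flagged as not reached.
#'
#' @param sample a [survival_sample()].
#' @return object of class `km_curve` with `time` (distinct event times),
#'   `n_risk`, `n_event`, `surv`, `median_months`, `median_reached`, `n`,
#'   `n_events`.
#' @export
km_estimate <- function(sample) {
  stopifnot(inherits(sample, "survival_sample"))
  t <- sample$time; e <- sample$event
  et <- sort(unique(t[e == 1L]))
  if (length(et) == 0L) {
    return(structure(list(time = numeric(0), n_risk = integer(0),
                          n_event = integer(0), surv = numeric(0),
                          median_months = NA_real_, median_reached = FALSE,
                          n = length(t), n_events = 0L,
                          endpoint = sample$endpoint),
                     class = "km_curve"))
  }
  n_risk <- vapply(et, function(x) sum(t >= x), integer(1))
  n_event <- vapply(et, function(x) sum(t == x & e == 1L), integer(1))
  surv <- cumprod(1 - n_event / n_risk)
  med_i <- which(surv <= 0.5 + 1e-12)
  structure(list(
    time = et, n_risk = n_risk, n_event = n_event, surv = surv,
    median_months = if (length(med_i)) et[med_i[1L]] else NA_real_,
    median_reached = length(med_i) > 0L,
    n = length(t), n_events = sum(e), endpoint = sample$endpoint
  ), class = "km_curve")
}

#' Survival probability at arbitrary horizons
#'
#' Evaluates the right-continuous step estimate, e.g. at 36 and 60 months
#' for 3- and 5-year rates.
#'
#' @param curve a `km_curve`.
#' @param horizon_months numeric vector of times.
#' @return survival probabilities at the horizons.
#' @export
km_surv_at <- function(curve, horizon_months) {
  stopifnot(inherits(curve, "km_curve"))
  if (length(curve$time) == 0L) return(rep(1, length(horizon_months)))
  f <- stats::stepfun(curve$time, c(1, curve$surv), right = FALSE)
  f(horizon_months)
}

#' @export
print.km_curve <- function(x, ...) {
  med <- if (x$median_reached) sprintf("%.1f months", x$median_months)
         else "not reached"
  cat(sprintf("<km_curve> %s: n=%d, events=%d, median %s\n",
              x$endpoint, x$n, x$n_events, med))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank statistic on 1 degree of freedom with a
#' two-sided p-value, using the hypergeometric variance at each distinct
#' event time.
#'
#' @param group_a,group_b [survival_sample()] objects.
#' @return list with `chi2`, `p`, `observed` and `expected` events in group A.
#' @export
logrank_test <- function(group_a, group_b) {
  stopifnot(inherits(group_a, "survival_sample"),
            inherits(group_b, "survival_sample"))
  if (length(group_a$time) == 0L || length(group_b$time) == 0L) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  t <- c(group_a$time, group_b$time)
  e <- c(group_a$event, group_b$event)
  g <- rep(c(1L, 0L), c(length(group_a$time), length(group_b$time)))
  et <- sort(unique(t[e == 1L]))
  o_minus_e <- 0; v <- 0; obs <- 0; expd <- 0
  for (tt in et) {
    at_risk <- t >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1L)
    d <- sum(t == tt & e == 1L)
    d1 <- sum(t == tt & e == 1L & g == 1L)
    e1 <- d * n1 / n
    obs <- obs + d1; expd <- expd + e1
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- if (v > 0) o_minus_e^2 / v else 0
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       observed = obs, expected = expd)
}

#' Cox proportional-hazards regression
#'
#' Maximizes the partial likelihood by Newton-Raphson with step-halving,
#' handling tied event times by the Efron (default) or Breslow correction.
#' Hazard ratios are `exp(beta)` with Wald 95% confidence intervals
#' `exp(beta +- 1.96 se)`. Monotone likelihood (perfect separation) is
#' reported through the `converged`/`monotone` diagnostics instead of
#' silently returning a huge coefficient.
#'
#' @param x covariate matrix (n x p) or vector/data frame coercible to one;
#'   no covariate may be constant.
#' @param sample a [survival_sample()].
#' @param ties `"efron"` or `"breslow"`.
#' @param max_iter,tol Newton-Raphson controls.
#' @return object of class `cox_fit`: `coefficients` data frame (term, beta,
#'   se, hr, ci_lower, ci_upper, z, p), `loglik` (null, final), `iter`,
#'   `converged`, `monotone`, `ties`, `n`, `n_events`.
#' @export
cox_fit <- function(x, sample, ties = c("efron", "breslow"),
                    max_iter = 50L, tol = 1e-10) {
  ties <- match.arg(ties)
  stopifnot(inherits(sample, "survival_sample"))
  if (is.data.frame(x)) x <- data.matrix(x)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x); p <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(p))
  if (length(sample$time) != n) {
    stop("covariate rows must match the survival sample", call. = FALSE)
  }
  if (sum(sample$event) < 1L) stop("at least one event required", call. = FALSE)
  rng <- apply(x, 2L, function(col) diff(range(col)))
  if (any(rng == 0)) {
    stop(sprintf("covariate constant across subjects: %s",
                 paste(colnames(x)[rng == 0], collapse = ", ")), call. = FALSE)
  }
  # center covariates for numerical stability; beta is unaffected
  xc <- scale(x, center = TRUE, scale = FALSE)
  ord <- order(sample$time)
  xs <- xc[ord, , drop = FALSE]
  ts <- sample$time[ord]
  es <- sample$event[ord]
  # block bookkeeping for distinct event times
  et <- unique(ts[es == 1L])
  death_rows <- lapply(et, function(tt) which(ts == tt & es == 1L))
  first_risk <- vapply(et, function(tt) match(TRUE, ts >= tt), integer(1))

  pl_quantities <- function(beta) {
    eta <- drop(xs %*% beta)
    eta <- pmin(eta, 500)  # guard overflow during divergent steps
    w <- exp(eta)
    wx <- xs * w
    # suffix (risk-set) sums: position i holds sum over rows i..n
    S0 <- rev(cumsum(rev(w)))
    S1 <- apply(wx, 2L, function(col) rev(cumsum(rev(col))))
    S1 <- matrix(S1, ncol = p)
    # S2 suffix sums for each covariate pair
    S2 <- array(0, c(n, p, p))
    for (a in seq_len(p)) for (b in a:p) {
      sab <- rev(cumsum(rev(wx[, a] * xs[, b])))
      S2[, a, b] <- sab; S2[, b, a] <- sab
    }
    ll <- 0
    U <- numeric(p)
    I <- matrix(0, p, p)
    for (j in seq_along(et)) {
      dr <- death_rows[[j]]
      d <- length(dr)
      f <- first_risk[j]
      s0 <- S0[f]; s1 <- S1[f, ]; s2 <- S2[f, , ]
      sxd <- colSums(xs[dr, , drop = FALSE])
      ll <- ll + sum(eta[dr])
      U <- U + sxd
      if (ties == "breslow" || d == 1L) {
        ll <- ll - d * log(s0)
        z <- s1 / s0
        U <- U - d * z
        I <- I + d * (matrix(s2, p, p) / s0 - tcrossprod(z))
      } else {
        s0d <- sum(w[dr])
        s1d <- colSums(wx[dr, , drop = FALSE])
        s2d <- matrix(0, p, p)
        for (a in seq_len(p)) for (b in a:p) {
          v <- sum(wx[dr, a] * xs[dr, b])
          s2d[a, b] <- v; s2d[b, a] <- v
        }
        for (l in 0:(d - 1L)) {
          r <- l / d
          den <- s0 - r * s0d
          z <- (s1 - r * s1d) / den
          ll <- ll - log(den)
          U <- U - z
          I <- I + (matrix(s2, p, p) - r * s2d) / den - tcrossprod(z)
        }
      }
    }
    list(ll = ll, U = U, I = I)
  }

  beta <- numeric(p)
  q <- pl_quantities(beta)
  ll0 <- q$ll
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    step <- tryCatch(solve(q$I, q$U), error = function(e) NULL)
    if (is.null(step)) break
    new_beta <- beta + step
    qn <- pl_quantities(new_beta)
    halves <- 0L
    while ((!is.finite(qn$ll) || qn$ll < q$ll - 1e-12) && halves < 30L) {
      new_beta <- (beta + new_beta) / 2
      qn <- pl_quantities(new_beta)
      halves <- halves + 1L
    }
    done <- abs(qn$ll - q$ll) < tol * (abs(q$ll) + 1)
    beta <- new_beta; q <- qn
    if (done) { converged <- TRUE; break }
  }
  monotone <- any(abs(beta) > 15)
  vcov <- tryCatch(solve(q$I), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(diag(vcov))
  zst <- beta / se
  coef <- data.frame(
    term = colnames(x), beta = beta, se = se, hr = exp(beta),
    ci_lower = exp(beta - stats::qnorm(0.975) * se),
    ci_upper = exp(beta + stats::qnorm(0.975) * se),
    z = zst, p = 2 * stats::pnorm(-abs(zst)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(coefficients = coef, loglik = c(null = ll0, final = q$ll),
                 iter = iter, converged = converged && !monotone,
                 monotone = monotone, ties = ties, n = n,
                 n_events = sum(es), vcov = vcov),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n=%d, events=%d, ties=%s, %s\n", x$n, x$n_events,
              x$ties, if (x$converged) "converged" else "NOT converged"))
  cf <- x$coefficients
  cf$hr <- sprintf("%.3f (%.3f-%.3f)", cf$hr, cf$ci_lower, cf$ci_upper)
  print(cf[, c("term", "hr", "p")], row.names = FALSE)
  invisible(x)
}

#' ROC-optimal cutoff by the Youden index
#'
#' Evaluates every midpoint between consecutive sorted unique feature values
#' as a candidate threshold (positive call = value above threshold), returns
#' the threshold maximizing Youden's J = sensitivity + specificity - 1
#' (lowest threshold on ties), and the trapezoidal AUC of the full ROC
#' curve. Dichotomization against a survival endpoint uses the event
#' indicator, ignoring censoring time.
#'
#' @param values numeric feature values.
#' @param outcome binary outcome (1 = positive class); both classes required.
#' @return object of class `roc_cutoff`: `threshold`, `sensitivity`,
#'   `specificity`, `youden_j`, `auc`, and the full `curve` data frame.
#' @export
roc_best_cutoff <- function(values, outcome) {
  outcome <- as.integer(outcome != 0)
  ok <- is.finite(values) & !is.na(outcome)
  values <- values[ok]; outcome <- outcome[ok]
  n_pos <- sum(outcome == 1L); n_neg <- sum(outcome == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  u <- sort(unique(values))
  thr <- if (length(u) > 1L) (u[-length(u)] + u[-1L]) / 2 else u
  sens <- vapply(thr, function(tt) mean(values[outcome == 1L] > tt), numeric(1))
  spec <- vapply(thr, function(tt) mean(values[outcome == 0L] <= tt), numeric(1))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)[1L]  # thresholds ascending: lowest wins
  # full ROC polygon including the degenerate corners
  fpr <- c(1, 1 - spec, 0); tpr <- c(1, sens, 0)
  o <- order(fpr, tpr)
  auc <- sum(diff(fpr[o]) * (tpr[o][-1L] + tpr[o][-length(tpr)]) / 2)
  structure(list(threshold = thr[best], sensitivity = sens[best],
                 specificity = spec[best], youden_j = j[best], auc = auc,
                 curve = data.frame(threshold = thr, sensitivity = sens,
                                    specificity = spec)),
            class = "roc_cutoff")
}

#' Combined baseline-MTV and metabolic-response stratification
#'
#' Four prognostic groups crossing the MTV dichotomy (high = strictly above
#' the cutoff) with the Lugano binary response. Patients with a missing
#' response (e.g. death before the end-of-treatment scan) are returned as
#' `NA` and counted in the `n_missing_response` attribute.
#'
#' @param mtv_value numeric MTV values (cm^3).
#' @param mtv_cutoff dichotomization cutoff, e.g. from [roc_best_cutoff()].
#' @param response character vector, `"complete"` / `"not_complete"` (NA
#'   allowed).
#' @return factor with levels `lowMTV_CMR`, `lowMTV_nonCMR`, `highMTV_CMR`,
#'   `highMTV_nonCMR`.
#' @export
combined_strata <- function(mtv_value, mtv_cutoff, response) {
  stopifnot(length(mtv_value) == length(response))
  high <- mtv_value > mtv_cutoff
  cmr <- ifelse(is.na(response), NA, response == "complete")
  lab <- ifelse(is.na(cmr), NA_character_,
                paste0(ifelse(high, "highMTV", "lowMTV"),
                       ifelse(cmr, "_CMR", "_nonCMR")))
  out <- factor(lab, levels = c("lowMTV_CMR", "lowMTV_nonCMR",
                                "highMTV_CMR", "highMTV_nonCMR"))
  attr(out, "n_missing_response") <- sum(is.na(response))
  out
}
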