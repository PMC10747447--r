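#' Two-way mean squares of a ratings table
#'
#' Exact two-way, one-observation-per-cell ANOVA decomposition of an
#' n subjects x k raters table: between-subject (rows), between-rater
#' (columns) and residual mean squares, the building blocks of every ICC
#' form.
#'
#' @param table numeric matrix, n >= 2 rows (subjects) x k >= 2 columns
#'   (raters), all entries finite.
#' @return List of class `mean_squares`: `MSR`, `MSC`, `MSE`, their degrees
#'   of freedom `df_r`, `df_c`, `df_e`, the sums of squares `SSR`, `SSC`,
#'   `SSE`, `SST`, and `n`, `k`.
#' @examples
#' two_way_mean_squares(cbind(c(1, 3, 6, 2), c(2, 5, 6, 2)))
#' @export
two_way_mean_squares <- function(table) {
  table <- as.matrix(table)
  n <- nrow(table)
  k <- ncol(table)
  if (n < 2L || k < 2L) stopf("ratings table must be at least 2 x 2")
  if (any(!is.finite(table))) stopf("ratings table entries must be finite")
  gm <- mean(table)
  rm <- rowMeans(table)
  cm <- colMeans(table)
  SSR <- k * sum((rm - gm)^2)
  SSC <- n * sum((cm - gm)^2)
  SST <- sum((table - gm)^2)
  SSE <- SST - SSR - SSC
  structure(
    list(MSR = SSR / (n - 1), MSC = SSC / (k - 1),
         MSE = SSE / ((n - 1) * (k - 1)),
         df_r = n - 1L, df_c = k - 1L, df_e = (n - 1L) * (k - 1L),
         SSR = SSR, SSC = SSC, SSE = SSE, SST = SST,
         grand_mean = gm, n = n, k = k),
    class = "mean_squares"
  )
}

#' Intraclass correlation coefficient with 95% confidence interval
#'
#' Single-score and average-score ICC estimators from the two-way mean
#' squares (Shrout & Fleiss forms): `ICC21` -- two-way random effects,
#' absolute agreement, single score; `ICC31` -- two-way mixed effects,
#' consistency, single score; `ICC3k` -- two-way mixed effects,
#' consistency, average of the k scores. Confidence intervals use the exact
#' F-distribution bounds (the ICC(2,1) interval uses the
#' Satterthwaite-style approximate denominator degrees of freedom of the
#' standard derivation).
#'
#' @param table n x k ratings matrix (see [two_way_mean_squares()]). For
#'   concurrent-validity analysis the subjects are the 100 normalised
#'   frames and the raters are the two measurement systems.
#' @param form `"ICC21"`, `"ICC31"` or `"ICC3k"`.
#' @param alpha two-sided confidence level is `1 - alpha` (default 0.05).
#' @return List of class `mvk_icc`: `form`, `estimate`, `lower`, `upper`,
#'   `alpha`, `n`, `k`, and the underlying `mean_squares`.
#' @examples
#' icc(cbind(c(1, 3, 6, 2), c(2, 5, 6, 2)), "ICC21")
#' @export
icc <- function(table, form = c("ICC21", "ICC31", "ICC3k"), alpha = 0.05) {
  form <- match.arg(form)
  ms <- two_way_mean_squares(table)
  n <- ms$n
  k <- ms$k
  if (ms$MSR <= .Machine$double.eps * max(1, abs(ms$grand_mean))^2 ||
      ms$SSR < 1e-12 * max(ms$SST, 1e-300)) {
    stopf("ICC undefined: no between-subject variance in the ratings table")
  }
  MSR <- ms$MSR; MSC <- ms$MSC; MSE <- ms$MSE
  est <- switch(form,
    ICC21 = (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n),
    ICC31 = (MSR - MSE) / (MSR + (k - 1) * MSE),
    ICC3k = (MSR - MSE) / MSR)
  qq <- stats::qf(1 - alpha / 2, ms$df_r, ms$df_e)
  qq_rev <- stats::qf(1 - alpha / 2, ms$df_e, ms$df_r)
  if (form == "ICC21") {
    Fj <- MSC / MSE
    icc2 <- est
    vn <- ms$df_e * (k * icc2 * Fj + n * (1 + (k - 1) * icc2) - k * icc2)^2
    vd <- ms$df_r * k^2 * icc2^2 * Fj^2 +
      (n * (1 + (k - 1) * icc2) - k * icc2)^2
    v <- vn / vd
    f_u <- stats::qf(1 - alpha / 2, n - 1, v)
    f_l <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (MSR - f_u * MSE) /
      (f_u * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    upper <- n * (f_l * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * f_l * MSR)
  } else {
    F0 <- MSR / MSE
    FL <- F0 / qq
    FU <- F0 * qq_rev
    if (form == "ICC31") {
      lower <- (FL - 1) / (FL + k - 1)
      upper <- (FU - 1) / (FU + k - 1)
    } else {
      lower <- 1 - 1 / FL
      upper <- 1 - 1 / FU
    }
  }
  structure(
    list(form = form, estimate = est, lower = lower, upper = upper,
         alpha = alpha, n = n, k = k, mean_squares = ms),
    class = "mvk_icc"
  )
}

#' @export
print.mvk_icc <- function(x, ...) {
  cat(sprintf("%s = %.4f, %g%% CI [%.4f, %.4f] (n = %d, k = %d)\n",
              x$form, x$estimate, 100 * (1 - x$alpha), x$lower, x$upper,
              x$n, x$k))
  invisible(x)
}

#' Method-error coefficient of variation
#'
#' Between-system method error expressed as a percentage of the grand
#' mean. The default `dahlberg` variant divides the standard deviation of
#' the paired differences by `sqrt(2)` (each difference carries the error
#' of two measurements) and relates it to the mean of the two systems'
#' means; the `literal` variant is the same ratio without the radical,
#' i.e. `100 * SD(diff) / (mean(x1) + mean(x2))`.
#'
#' @param x1,x2 paired measurement series of equal length >= 2.
#' @param variant `"dahlberg"` (default) or `"literal"`.
#' @return CV in percent, with the variant recorded in attribute
#'   `"variant"`.
#' @examples
#' cv_method_error(c(10, 12, 14), c(11, 13, 13))
#' @export
cv_method_error <- function(x1, x2, variant = c("dahlberg", "literal")) {
  variant <- match.arg(variant)
  if (length(x1) != length(x2)) stopf("series lengths differ")
  if (length(x1) < 2L) stopf("need >= 2 paired measurements")
  if (any(is.na(x1)) || any(is.na(x2))) stopf("missing values in series")
  msum <- mean(x1) + mean(x2)
  if (abs(msum) < 1e-12) {
    stopf("CV undefined: combined mean of the two series is zero")
  }
  sdd <- stats::sd(x1 - x2)
  cv <- switch(variant,
               dahlberg = 100 * (sdd / sqrt(2)) / (msum / 2),
               literal = 100 * sdd / msum)
  structure(cv, variant = variant)
}

#' Standard error of measurement
#'
#' `SEM = SD * sqrt(1 - ICC)` (default `rooted` variant, the standard
#' form); the `literal` variant omits the radical, `SD * (1 - ICC)`.
#'
#' @param sd standard deviation of the measurements (degrees), >= 0.
#' @param icc reliability estimate, <= 1.
#' @param variant `"rooted"` (default) or `"literal"`.
#' @return SEM in the units of `sd`.
#' @examples
#' sem_measurement(11.27, 0.895)
#' @export
sem_measurement <- function(sd, icc, variant = c("rooted", "literal")) {
  variant <- match.arg(variant)
  if (sd < 0) stopf("sd must be >= 0")
  if (icc > 1) stopf("icc must be <= 1")
  switch(variant,
         rooted = sd * sqrt(1 - icc),
         literal = sd * (1 - icc))
}

#' Minimal detectable change at 95% confidence
#'
#' `MDC95 = 1.96 * sqrt(2) * SEM`: the smallest change between two
#' measurements that exceeds measurement error with 95% confidence.
#'
#' @param sem_value standard error of measurement, >= 0.
#' @return MDC95 in the units of `sem_value`.
#' @examples
#' mdc95(1) # 1.96 * sqrt(2)
#' @export
mdc95 <- function(sem_value) {
  if (any(sem_value < 0)) stopf("sem_value must be >= 0")
  stats::qnorm(0.975) * sqrt(2) * sem_value
}

#' Qualitative band of an ICC estimate
#'
#' Default `"results"` scheme: < 0.4 poor, 0.4--0.6 normal, 0.6--0.75 good,
#' 0.75--1.00 very good. The alternative `"methods"` scheme uses the
#' clinical banding < 0.5 poor, 0.5--0.75 moderate, 0.75--0.9 good,
#' >= 0.9 high. Boundary values fall in the upper band.
#'
#' @param estimate ICC estimate, <= 1.
#' @param scheme `"results"` (default) or `"methods"`.
#' @return Character band label (vectorised).
#' @examples
#' classify_icc(c(0.895, 0.5, 0.39))
#' @export
classify_icc <- function(estimate, scheme = c("results", "methods")) {
  scheme <- match.arg(scheme)
  if (any(estimate > 1)) stopf("ICC estimates cannot exceed 1")
  if (scheme == "results") {
    cuts <- c(0.4, 0.6, 0.75)
    labs <- c("poor", "normal", "good", "very good")
  } else {
    cuts <- c(0.5, 0.75, 0.9)
    labs <- c("poor", "moderate", "good", "high")
  }
  labs[findInterval(estimate, cuts) + 1L]
}

#' Agreement report for aligned trace pairs
#'
#' One row per pair (participant/task/side cell): mean and SD pooled over
#' the two systems' 2 x n values, the requested ICC form with its 95% CI,
#' the method-error CV, SEM and MDC95, plus the qualitative ICC band.
#'
#' @param pairs a single `aligned_pair` or a list of them (see
#'   [pair_traces()]).
#' @param form ICC form for the report (default `"ICC21"`).
#' @param cv_variant,sem_variant passed to [cv_method_error()] and
#'   [sem_measurement()].
#' @param pooled if `FALSE`, M and SD describe the test trace alone rather
#'   than both systems pooled.
#' @return data.frame with columns `participant`, `task`, `side`, `n`, `M`,
#'   `SD`, `icc_form`, `ICC`, `ci_lower`, `ci_upper`, `band`, `CV_pct`,
#'   `SEM`, `MDC95`.
#' @examples
#' prof <- motion_profile("side_dip_left")
#' pr <- pair_traces(generate_angle_profile(prof),
#'                   generate_angle_profile(prof, rate_hz = 100))
#' reliability_report(pr)
#' @export
reliability_report <- function(pairs, form = c("ICC21", "ICC31", "ICC3k"),
                               cv_variant = "dahlberg",
                               sem_variant = "rooted",
                               pooled = TRUE) {
  form <- match.arg(form)
  if (inherits(pairs, "aligned_pair")) pairs <- list(pairs)
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    stopifnot(inherits(p, "aligned_pair"))
    tab <- cbind(test = p$test, reference = p$reference)
    vals <- if (pooled) as.numeric(tab) else p$test
    M <- mean(vals)
    SD <- stats::sd(vals)
    ic <- icc(tab, form = form)
    cv <- cv_method_error(p$test, p$reference, variant = cv_variant)
    sem_v <- sem_measurement(SD, ic$estimate, variant = sem_variant)
    prov <- p$provenance
    data.frame(
      participant = prov$participant %||% i,
      task = prov$task %||% p$task,
      side = prov$side %||% side_of_task(p$task),
      n = length(p$test),
      M = M, SD = SD,
      icc_form = form,
      ICC = ic$estimate, ci_lower = ic$lower, ci_upper = ic$upper,
      band = classify_icc(ic$estimate),
      CV_pct = as.numeric(cv),
      SEM = sem_v,
      MDC95 = mdc95(sem_v),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

side_of_task <- function(task) {
  switch(task,
         side_dip_left = "left",
         side_dip_right = "right",
         "right")
}
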