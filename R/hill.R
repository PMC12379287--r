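# Hill dose-response fitting, maximal fold change, and cell-density
# detection limits.

.check_dose_data <- function(data) {
  stopifnot(
    is.data.frame(data),
    all(c("concentration", "response") %in% names(data)),
    "concentrations must be nonnegative" = all(data$concentration >= 0),
    "responses must be nonnegative" = all(data$response >= 0)
  )
  if (length(unique(data$concentration)) < 4) {
    stop("at least 4 distinct concentrations are required for fitting",
         call. = FALSE)
  }
  invisible(data)
}

# Given (K, n), the Hill model is linear in (y0, ymax): solve that pair by
# ordinary least squares and return the residual sum of squares.
.hill_profile_rss <- function(conc, y, k, n) {
  h <- ifelse(conc > 0, conc^n / (k^n + conc^n), 0)
  X <- cbind(1 - h, h)                      # y = y0*(1-h) + ymax*h
  fit <- stats::lm.fit(X, y)
  list(y0 = unname(fit$coefficients[1]), ymax = unname(fit$coefficients[2]),
       rss = sum(fit$residuals^2))
}

#' Fit the Hill equation to a dose-response table
#'
#' Least-squares fit of `y(c) = y0 + (ymax - y0) c^n / (K^n + c^n)` to
#' replicate responses. The fit is deterministic: a fixed multi-start grid —
#' `K` over the quantiles of the positive concentrations crossed with Hill
#' coefficients `n` in `{0.5, 1, 1.5, 2, 3, 4}`, each start solved for
#' `(y0, ymax)` in closed form — seeds a Levenberg-Marquardt polish of all
#' four parameters; among equal-residual starts the smallest `K` wins. A
#' flat response (zero variance) is flagged unidentifiable with `K`
#' undetermined and fold change 1.
#'
#' @param data Data frame with columns `concentration` (uM, >= 4 distinct
#'   values including replicates rows) and `response` (nonnegative).
#' @return A `hill_fit` object: parameters `y0`, `ymax`, `k`, `n`, the
#'   fitted-curve fold change `ymax / y0`, residual summary, and the data.
#'   Supports [tidy()], [glance()], `predict()`, and `autoplot()`.
#' @export
fit_hill <- function(data) {
  .check_dose_data(data)
  conc <- data$concentration
  y <- data$response
  if (stats::sd(y) == 0) {
    return(structure(
      list(y0 = y[1], ymax = y[1], k = NA_real_, n = NA_real_,
           fold_change = 1, rss = 0, sigma = 0, n_obs = length(y),
           identifiable = FALSE, data = tibble::as_tibble(data)),
      class = "hill_fit"
    ))
  }
  pos <- sort(unique(conc[conc > 0]))
  k_grid <- unique(stats::quantile(pos, probs = seq(0.05, 0.95, by = 0.1),
                                   names = FALSE, type = 7))
  n_grid <- c(0.5, 1, 1.5, 2, 3, 4)
  starts <- tidyr::expand_grid(k = k_grid, n = n_grid)
  rss <- purrr::pmap_dbl(starts, function(k, n)
    .hill_profile_rss(conc, y, k, n)$rss)
  # best residual; ties broken toward the smallest K
  ord <- order(rss, starts$k)
  best <- starts[ord[1], ]
  lin <- .hill_profile_rss(conc, y, best$k, best$n)
  start <- list(y0 = max(lin$y0, 0), ymax = max(lin$ymax, min(y)),
                k = best$k, n = best$n)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      response ~ y0 + (ymax - y0) * ifelse(concentration > 0,
        concentration^n / (k^n + concentration^n), 0),
      data = data.frame(concentration = conc, response = y),
      start = start,
      lower = c(y0 = 0, ymax = 0, k = 1e-9, n = 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    pars <- start
    resid <- y - hill_response(conc, pars$y0, pars$ymax, pars$k, pars$n)
  } else {
    cf <- stats::coef(fit)
    pars <- list(y0 = unname(cf["y0"]), ymax = unname(cf["ymax"]),
                 k = unname(cf["k"]), n = unname(cf["n"]))
    resid <- stats::residuals(fit)
  }
  rss_final <- sum(resid^2)
  structure(
    list(
      y0 = pars$y0, ymax = pars$ymax, k = pars$k, n = pars$n,
      fold_change = if (pars$y0 > 0) pars$ymax / pars$y0 else Inf,
      rss = rss_final,
      sigma = sqrt(rss_final / max(length(y) - 4, 1)),
      n_obs = length(y),
      identifiable = TRUE,
      data = tibble::as_tibble(data)
    ),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  if (!x$identifiable) {
    cat("<hill_fit> unidentifiable (flat response); K not determined\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<hill_fit> y0 = %.4g, ymax = %.4g, K = %.4g uM, n = %.3g\n  fitted fold change ymax/y0 = %.4g; residual sd %.3g on %d obs\n",
    x$y0, x$ymax, x$k, x$n, x$fold_change, x$sigma, x$n_obs
  ))
  invisible(x)
}

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$concentration
          else newdata$concentration
  if (!object$identifiable) return(rep(object$y0, length(conc)))
  hill_response(conc, object$y0, object$ymax, object$k, object$n)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Hill fit into one row per parameter
#'
#' @param x A `hill_fit`.
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`.
#' @export
tidy.hill_fit <- function(x, ...) {
  tibble::tibble(
    term = c("y0", "ymax", "k", "n", "fold_change"),
    estimate = c(x$y0, x$ymax, x$k, x$n, x$fold_change)
  )
}

#' One-row summary of a Hill fit
#'
#' @param x A `hill_fit`.
#' @param ... Unused.
#' @return Tibble with `rss`, `sigma`, `n_obs`, `identifiable`.
#' @export
glance.hill_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, sigma = x$sigma, n_obs = x$n_obs,
                 identifiable = x$identifiable)
}

#' Maximal fold change of a dose-response table
#'
#' The maximum over concentrations of the mean response at that
#' concentration divided by the mean response at zero dose (condition means,
#' not per-replicate ratios). The fitted-curve variant `ymax / y0` from
#' [fit_hill()] is reported alongside.
#'
#' @param data Data frame with `concentration` and `response` columns; the
#'   zero-concentration condition must be present with positive mean.
#' @param fit Optional precomputed [fit_hill()] result for the fitted
#'   variant (computed from `data` when omitted and the data are fittable).
#' @return A one-row tibble: `fold_change` (empirical), `at_concentration`,
#'   `fitted_fold_change` (`NA` when no fit is available).
#' @export
max_fold_change <- function(data, fit = NULL) {
  stopifnot(all(c("concentration", "response") %in% names(data)))
  if (!any(data$concentration == 0)) {
    stop("a zero-concentration baseline condition is required",
         call. = FALSE)
  }
  means <- data |>
    dplyr::group_by(.data$concentration) |>
    dplyr::summarise(mean_response = mean(.data$response), .groups = "drop")
  base <- means$mean_response[means$concentration == 0]
  if (base <= 0) {
    stop("zero-dose mean response must be positive for a fold change",
         call. = FALSE)
  }
  i <- which.max(means$mean_response)
  fitted_fc <- NA_real_
  if (is.null(fit) && length(unique(data$concentration)) >= 4) {
    fit <- tryCatch(fit_hill(data), error = function(e) NULL)
  }
  if (!is.null(fit)) fitted_fc <- fit$fold_change
  tibble::tibble(
    fold_change = means$mean_response[i] / base,
    at_concentration = means$concentration[i],
    fitted_fold_change = fitted_fc
  )
}

#' Cell-density detection limit
#'
#' The lowest tested density whose mean SBR exceeds the detection criterion.
#' The default criterion is the blank (0 cells/mL) mean plus three blank
#' standard deviations; the criterion value used is recorded in the output.
#'
#' @param data Data frame with columns `density` (cells/mL, a 0 blank must
#'   be present) and `sbr`.
#' @param criterion Optional fixed numeric criterion overriding the default
#'   blank-based rule.
#' @return One-row tibble: `detection_limit` (cells/mL, `NA` when no tested
#'   density exceeds the criterion), `criterion`, `detected`.
#' @export
detection_limit <- function(data, criterion = NULL) {
  stopifnot(all(c("density", "sbr") %in% names(data)))
  if (!any(data$density == 0)) {
    stop("a blank (0 cells/mL) condition is required", call. = FALSE)
  }
  blank <- data$sbr[data$density == 0]
  if (is.null(criterion)) {
    criterion <- mean(blank) + 3 * stats::sd(blank)
    if (is.na(criterion)) criterion <- mean(blank)  # single blank replicate
  }
  means <- data |>
    dplyr::filter(.data$density > 0) |>
    dplyr::group_by(.data$density) |>
    dplyr::summarise(mean_sbr = mean(.data$sbr), .groups = "drop") |>
    dplyr::arrange(.data$density)
  hit <- means$density[means$mean_sbr > criterion]
  tibble::tibble(
    detection_limit = if (length(hit)) min(hit) else NA_real_,
    criterion = criterion,
    detected = length(hit) > 0,
    max_tested = max(means$density)
  )
}
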