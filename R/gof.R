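# Goodness-of-fit battery and the ordered model-selection rule.

check_pair <- function(obs, pred, min_n = 2L) {
  if (!is.numeric(obs) || !is.numeric(pred)) {
    stop("`obs` and `pred` must be numeric.", call. = FALSE)
  }
  if (length(obs) != length(pred)) {
    stop("`obs` and `pred` must have equal length.", call. = FALSE)
  }
  if (length(obs) < min_n) {
    stop(sprintf("need at least %d paired points.", min_n), call. = FALSE)
  }
  if (any(!is.finite(obs)) || any(!is.finite(pred))) {
    stop("`obs` and `pred` must be finite.", call. = FALSE)
  }
  invisible(NULL)
}

#' Uncentered R squared
#'
#' `(sum(obs * pred))^2 / (sum(obs^2) * sum(pred^2))`: the squared cosine
#' similarity of the observed and predicted vectors. By Cauchy-Schwarz it
#' lies in `[0, 1]` and equals 1 exactly when `pred` is proportional to
#' `obs` — including proportionality constants other than 1, so a fit
#' that is merely proportional to the data scores perfectly. Report
#' [r2_conventional()] alongside as the guard against that scale
#' blindness.
#'
#' @param obs,pred Paired observed and predicted values (length >= 2).
#' @return A number in `[0, 1]`.
#' @export
r2_uncentered <- function(obs, pred) {
  check_pair(obs, pred)
  so <- sum(obs^2); sp <- sum(pred^2)
  if (so == 0 || sp == 0) {
    stop("undefined statistic: zero-norm vector.", call. = FALSE)
  }
  sum(obs * pred)^2 / (so * sp)
}

#' Conventional coefficient of determination
#'
#' `1 - RSS / TSS` with the total sum of squares about the observed
#' mean. Can be negative for fits worse than the mean; undefined for
#' constant observations.
#'
#' @inheritParams r2_uncentered
#' @export
r2_conventional <- function(obs, pred) {
  check_pair(obs, pred)
  tss <- sum((obs - mean(obs))^2)
  if (tss == 0) {
    stop("undefined statistic: constant observations.", call. = FALSE)
  }
  1 - rss(obs, pred) / tss
}

#' Reduced chi squared
#'
#' Residual sum of squares divided by the degrees of freedom
#' `N - n_params`.
#'
#' @inheritParams r2_uncentered
#' @param n_params Number of fitted parameters `n` (< N).
#' @export
chi2_reduced <- function(obs, pred, n_params) {
  check_pair(obs, pred)
  check_scalar(n_params, "n_params", lower = 0)
  if (length(obs) <= n_params) {
    stop("degrees of freedom error: N must exceed n_params.", call. = FALSE)
  }
  rss(obs, pred) / (length(obs) - n_params)
}

#' Root mean square error
#'
#' @inheritParams r2_uncentered
#' @export
rmse <- function(obs, pred) {
  check_pair(obs, pred, min_n = 1L)
  sqrt(rss(obs, pred) / length(obs))
}

#' Residual sum of squares
#'
#' @inheritParams r2_uncentered
#' @export
rss <- function(obs, pred) {
  check_pair(obs, pred, min_n = 1L)
  sum((obs - pred)^2)
}

#' Mean absolute percentage error
#'
#' `(100 / N) * sum(|obs - pred| / |obs|)` over the points with
#' `obs != 0`; zero-observation points are excluded (their count is
#' attached as attribute `n_excluded` and reported via `message()`).
#'
#' @inheritParams r2_uncentered
#' @return MAPE in percent.
#' @export
mape <- function(obs, pred) {
  check_pair(obs, pred, min_n = 1L)
  keep <- obs != 0
  if (!any(keep)) {
    stop("undefined statistic: all observations are zero.", call. = FALSE)
  }
  n_excluded <- sum(!keep)
  if (n_excluded > 0) {
    message(sprintf("mape: excluded %d zero-observation point(s).", n_excluded))
  }
  out <- 100 * mean(abs(obs[keep] - pred[keep]) / abs(obs[keep]))
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Full goodness-of-fit battery for one fit
#'
#' Computes all six statistics on a pair of observed/predicted vectors.
#' Statistics that are undefined for the input at hand (for example the
#' conventional R squared of constant observations) are returned as `NA`
#' rather than raising.
#'
#' @inheritParams chi2_reduced
#' @return A one-row tibble with columns `r2_uncentered`,
#'   `r2_conventional`, `chi2_reduced`, `rmse`, `rss`, `mape`,
#'   `n_points`, `n_params`.
#' @export
gof_stats <- function(obs, pred, n_params) {
  check_pair(obs, pred, min_n = 1L)
  safe <- function(expr) tryCatch(as.numeric(expr), error = function(e) NA_real_)
  tibble::tibble(
    r2_uncentered = safe(r2_uncentered(obs, pred)),
    r2_conventional = safe(r2_conventional(obs, pred)),
    chi2_reduced = safe(chi2_reduced(obs, pred, n_params)),
    rmse = rmse(obs, pred),
    rss = rss(obs, pred),
    mape = safe(suppressMessages(mape(obs, pred))),
    n_points = length(obs),
    n_params = as.integer(n_params)
  )
}

# ordered pairwise comparison: TRUE if fit a ranks strictly ahead of b
rank_before <- function(a, b, tol = 1e-6) {
  if (abs(a$r2_uncentered - b$r2_uncentered) > tol) {
    return(a$r2_uncentered > b$r2_uncentered)
  }
  for (key in c("chi2_reduced", "rmse", "mape", "rss")) {
    if (abs(a[[key]] - b[[key]]) > tol) return(a[[key]] < b[[key]])
  }
  FALSE
}

#' Rank competing fits by the ordered goodness-of-fit rule
#'
#' Orders fits by uncentered R squared (descending); ties within 1e-6
#' are broken by reduced chi squared, then RMSE, then MAPE, then RSS
#' (all ascending). Fits whose statistics are tied throughout keep their
#' input order. All fits must be evaluated on the same data window.
#'
#' @param fits A (preferably named) list of fit objects from
#'   [fit_growth()] or [fit_product()].
#' @return A tibble with one row per fit in ranked order: `rank`,
#'   `model`, the six statistics, `converged`.
#' @export
rank_models <- function(fits) {
  if (!is.list(fits) || length(fits) < 2L) {
    stop("`fits` must be a list of at least two fits.", call. = FALSE)
  }
  if (!all(vapply(fits, inherits, logical(1), "ferm_fit"))) {
    stop("all elements of `fits` must be ferm_fit objects.", call. = FALSE)
  }
  windows <- lapply(fits, function(f) f$window)
  if (!all(vapply(windows, identical, logical(1), windows[[1]]))) {
    stop("cannot compare fits computed on different data windows.",
         call. = FALSE)
  }
  rows <- lapply(fits, function(f) f$gof)
  ord <- seq_along(fits)
  # stable insertion sort under the ordered comparator (few fits)
  for (i in seq_along(ord)[-1]) {
    j <- i
    while (j > 1 && rank_before(rows[[ord[j]]], rows[[ord[j - 1]]])) {
      ord[c(j - 1, j)] <- ord[c(j, j - 1)]
      j <- j - 1
    }
  }
  nm <- names(fits) %||% vapply(fits, function(f) f$model, character(1))
  out <- dplyr::bind_rows(rows[ord])[, c("r2_uncentered", "r2_conventional",
                                         "chi2_reduced", "rmse", "mape", "rss")]
  dplyr::bind_cols(
    tibble::tibble(rank = seq_along(ord), model = nm[ord]),
    out,
    tibble::tibble(converged = unname(vapply(fits[ord],
                                             function(f) f$converged,
                                             logical(1))))
  )
}
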