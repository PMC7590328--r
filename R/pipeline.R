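# End-to-end workflow: file I/O, fitting every model, ranking, report
# serialization, recovery summaries, and the command-line driver.

series_header <- c(time = "time_hr", cfu = "cfu_per_g",
                   acidity = "acidity_g_per_l", pH = "pH")

#' Read and write fermentation series files
#'
#' The on-disk dialect is comma-separated UTF-8 with '.' decimals and
#' header `time_hr,cfu_per_g,acidity_g_per_l,pH`; time is always in
#' hours. Acidity is accepted either in g/L (`acidity_g_per_l`) or as
#' percent lactic acid w/v (`acidity_pct`), the latter converted at
#' ingest by the factor 10 (1 percent w/v = 10 g/L) with a note.
#' Channels other than `time_hr` are optional.
#'
#' @param path File path.
#' @param data Series tibble with columns among `time`, `cfu`,
#'   `acidity`, `pH`.
#' @return `read_series()`: a tibble with internal column names `time`,
#'   `cfu`, `acidity`, `pH` (present channels only). `write_series()`:
#'   `path`, invisibly.
#' @export
read_series <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) == 0L) stop("input error: empty series file.", call. = FALSE)
  if (!"time_hr" %in% names(raw)) {
    stop("input error: missing required column `time_hr`.", call. = FALSE)
  }
  out <- tibble::tibble(time = as.numeric(raw$time_hr))
  if ("cfu_per_g" %in% names(raw)) out$cfu <- as.numeric(raw$cfu_per_g)
  if ("acidity_g_per_l" %in% names(raw)) {
    out$acidity <- as.numeric(raw$acidity_g_per_l)
  } else if ("acidity_pct" %in% names(raw)) {
    message("read_series: converting acidity_pct to g/L (x10).")
    out$acidity <- as.numeric(raw$acidity_pct) * 10
  }
  if ("pH" %in% names(raw)) out$pH <- as.numeric(raw$pH)
  if (any(diff(out$time) <= 0)) {
    stop("input error: `time_hr` must be strictly increasing.", call. = FALSE)
  }
  out
}

#' @rdname read_series
#' @export
write_series <- function(data, path) {
  if (!is.data.frame(data) || !"time" %in% names(data)) {
    stop("`data` must contain a `time` column.", call. = FALSE)
  }
  keep <- intersect(names(series_header), names(data))
  out <- data[keep]
  names(out) <- series_header[keep]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Fit every requested model and rank them
#'
#' The full analysis on one series: fits the requested growth models on
#' the automatic fit window, ranks them with [rank_models()], fits the
#' requested product models over the best converged growth fit, and
#' ranks those. A model whose required channel is absent (for instance
#' the undissociated-acid model without pH measurements) is skipped
#' with a warning recorded in the report rather than failing the run.
#'
#' @param data Series tibble (columns among `time`, `cfu`, `acidity`,
#'   `pH`).
#' @param growth_models,product_models Character vectors of model names
#'   to fit.
#' @param pKa Dissociation constant for the undissociated-acid model.
#' @param seed Seed recorded in the report (the fits themselves are
#'   deterministic).
#' @return An object of class `run_report`: growth and product fits,
#'   both rankings, the selected growth model, accumulated warnings,
#'   package version and seed.
#' @export
fit_all_models <- function(data,
                           growth_models = c("gompertz", "logistic"),
                           product_models = c("luedeking_piret", "monteagudo",
                                              "balannec"),
                           pKa = 3.86, seed = NA_integer_) {
  warnings <- character()
  note <- function(msg) warnings <<- c(warnings, msg)

  growth <- list()
  if (length(growth_models)) {
    if (!"cfu" %in% names(data)) {
      note("no cfu channel: growth models skipped.")
    } else {
      for (gm in growth_models) {
        growth[[gm]] <- tryCatch(fit_growth(data, gm), error = function(e) {
          note(sprintf("growth model %s skipped: %s", gm, conditionMessage(e)))
          NULL
        })
      }
      growth <- growth[!vapply(growth, is.null, logical(1))]
    }
  }
  growth_ranking <- if (length(growth) >= 2L) rank_models(growth)
  best_growth <- NULL
  if (length(growth)) {
    conv <- growth[vapply(growth, function(f) f$converged, logical(1))]
    if (length(conv)) {
      best_growth <- if (length(conv) >= 2L) {
        rank_models(conv)$model[1]
      } else {
        names(conv)[1]
      }
    } else {
      note("no growth model converged.")
    }
  }

  product <- list()
  if (length(product_models)) {
    if (!"acidity" %in% names(data)) {
      note("no acidity channel: product models skipped.")
    } else if (is.null(best_growth)) {
      note("no converged growth fit: product models skipped.")
    } else {
      for (pm in product_models) {
        if (pm == "balannec" && !"pH" %in% names(data)) {
          note("product model balannec skipped: no pH channel.")
          next
        }
        product[[pm]] <- tryCatch(
          fit_product(data, growth[[best_growth]], pm, pKa = pKa),
          error = function(e) {
            note(sprintf("product model %s skipped: %s", pm,
                         conditionMessage(e)))
            NULL
          })
      }
      product <- product[!vapply(product, is.null, logical(1))]
    }
  }
  product_ranking <- if (length(product) >= 2L) rank_models(product)

  structure(
    list(series = tibble::as_tibble(data), growth = growth,
         growth_ranking = growth_ranking, best_growth = best_growth,
         product = product, product_ranking = product_ranking,
         warnings = warnings,
         version = as.character(utils::packageVersion("fermkin")),
         seed = seed),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

#' Render a run report as plain-text tables
#'
#' Two tables in the layout of a kinetics report: fitted parameters per
#' model, then the goodness-of-fit statistics per model.
#'
#' @param report A `run_report` from [fit_all_models()].
#' @return Character vector of lines.
#' @export
format_report <- function(report) {
  lines <- c(sprintf("fermkin run report (version %s, seed %s)",
                     report$version, report$seed))
  fmt_fit_params <- function(f) {
    paste(sprintf("%s = %.6g", names(f$estimates), f$estimates),
          collapse = ", ")
  }
  section <- function(fits, ranking, label) {
    if (!length(fits)) return(character())
    out <- c("", sprintf("%s model parameters", label),
             vapply(names(fits), function(nm) {
               sprintf("  %-16s %s", nm, fmt_fit_params(fits[[nm]]))
             }, character(1)))
    stats <- if (!is.null(ranking)) ranking else {
      f <- fits[[1]]
      dplyr::bind_cols(tibble::tibble(rank = 1L, model = names(fits)[1]),
                       f$gof[, c("r2_uncentered", "r2_conventional",
                                 "chi2_reduced", "rmse", "mape", "rss")],
                       tibble::tibble(converged = f$converged))
    }
    c(out, "", sprintf("%s goodness of fit (ranked)", label),
      sprintf("  %-4s %-16s %-8s %-8s %-8s %-8s %-8s", "rank", "model",
              "R2", "chi2", "RMSE", "MAPE", "RSS"),
      sprintf("  %-4d %-16s %-8.4f %-8.4g %-8.4g %-8.4g %-8.4g",
              stats$rank, stats$model, stats$r2_uncentered,
              stats$chi2_reduced, stats$rmse, stats$mape, stats$rss))
  }
  lines <- c(lines, section(report$growth, report$growth_ranking, "Growth"),
             section(report$product, report$product_ranking, "Product"))
  if (length(report$warnings)) {
    lines <- c(lines, "", "Warnings:",
               paste0("  - ", report$warnings))
  }
  lines
}

fit_to_list <- function(f) {
  list(model = f$model, type = f$type,
       estimates = as.list(f$estimates), units = as.list(f$units),
       gof = as.list(f$gof), predicted = as.list(f$predicted),
       window = f$window, converged = f$converged, n_iter = f$n_iter,
       warnings = f$warnings,
       N0 = f$N0, P0 = f$P0, pKa = f$pKa, time_unit = f$time_unit)
}

fit_from_list <- function(x) {
  gof <- tibble::as_tibble(x$gof)
  gof$n_points <- as.integer(gof$n_points)
  gof$n_params <- as.integer(gof$n_params)
  new_ferm_fit(
    paste0(x$type, "_fit"), x$model, x$type, params = NULL,
    estimates = unlist(x$estimates), units = unlist(x$units), gof = gof,
    predicted = tibble::as_tibble(x$predicted),
    window = as.integer(x$window), converged = x$converged,
    n_iter = x$n_iter, warnings = as.character(unlist(x$warnings)),
    extra = list(N0 = x$N0, P0 = x$P0, pKa = x$pKa, time_unit = x$time_unit)
  )
}

#' Serialize and restore a run report
#'
#' Reports round-trip losslessly through JSON (numbers are written at
#' full precision). Restored fit objects carry estimates, statistics,
#' predictions, windows and flags; the heavyweight closures (`params`
#' objects) are rebuilt from the estimates where possible.
#'
#' @param report A `run_report`.
#' @param path JSON file path.
#' @return `write_report()` returns `path` invisibly; `read_report()`
#'   the restored `run_report`.
#' @export
write_report <- function(report, path) {
  x <- list(
    series = as.list(report$series),
    growth = lapply(report$growth, fit_to_list),
    growth_ranking = if (!is.null(report$growth_ranking))
      as.list(report$growth_ranking),
    best_growth = report$best_growth,
    product = lapply(report$product, fit_to_list),
    product_ranking = if (!is.null(report$product_ranking))
      as.list(report$product_ranking),
    warnings = report$warnings,
    version = report$version,
    seed = report$seed
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rebuild_ranking <- function(r) {
    if (is.null(r) || length(r) == 0L) return(NULL)
    out <- tibble::as_tibble(r)
    out$rank <- as.integer(out$rank)
    out
  }
  structure(
    list(series = tibble::as_tibble(x$series),
         growth = lapply(x$growth, fit_from_list),
         growth_ranking = rebuild_ranking(x$growth_ranking),
         best_growth = x$best_growth,
         product = lapply(x$product, fit_from_list),
         product_ranking = rebuild_ranking(x$product_ranking),
         warnings = as.character(unlist(x$warnings)),
         version = x$version, seed = x$seed),
    class = "run_report"
  )
}

#' Parameter-recovery summary over simulated replicates
#'
#' Simulates `n_reps` series from `config` (replicate `i` seeded
#' `base_seed + i - 1`), refits the generating growth and product models
#' on each, and summarizes per-parameter recovery against the generating
#' values.
#'
#' @param config A [sim_config()].
#' @param n_reps Number of replicates.
#' @param base_seed Seed of the first replicate.
#' @return A tibble with one row per parameter: `parameter`, `truth`,
#'   `mean`, `median`, `bias`, `rmse`, `n_reps`.
#' @export
recovery_summary <- function(config, n_reps = 50L, base_seed = config$seed) {
  reps <- replicate_batch(config, n_reps, base_seed)
  g <- config$growth
  p <- config$product
  truth <- c(A = g$A, mu_m = g$mu_m, lambda = g$lambda,
             m = p$m, n = p$n,
             if (p$model == "monteagudo") c(P_max = p$P_max),
             if (p$model == "balannec") c(HL_inh = p$HL_inh))
  ests <- lapply(reps, function(d) {
    gf <- fit_growth(d, g$model)
    pf <- fit_product(d, gf, p$model, pKa = config$pKa)
    c(gf$estimates, pf$estimates)
  })
  est_mat <- do.call(rbind, ests)[, names(truth), drop = FALSE]
  tibble::tibble(
    parameter = names(truth),
    truth = unname(truth),
    mean = colMeans(est_mat),
    median = apply(est_mat, 2, stats::median),
    bias = colMeans(est_mat) - unname(truth),
    rmse = sqrt(colMeans(sweep(est_mat, 2, truth)^2)),
    n_reps = as.integer(n_reps)
  )
}

# --- command-line driver -------------------------------------------------

parse_cli_args <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop(sprintf("unexpected argument `%s`.", a),
                                   call. = FALSE)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      opts[[key]] <- TRUE
      i <- i + 1L
    } else {
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  opts
}

config_to_list <- function(config) {
  g <- config$growth
  p <- config$product
  c(list(growth = list(model = g$model, A = g$A, mu_m = g$mu_m,
                       lambda = g$lambda, time_unit = g$time_unit),
         product = list(model = p$model, m = p$m, n = p$n,
                        P_max = p$P_max, HL_inh = p$HL_inh)),
    config[setdiff(names(config), c("growth", "product"))])
}

config_from_list <- function(x) {
  g <- x$growth
  p <- x$product
  args <- x[setdiff(names(x), c("growth", "product"))]
  args$growth <- growth_params(g$model, A = g$A, mu_m = g$mu_m,
                               lambda = g$lambda,
                               time_unit = g$time_unit %||% "hr")
  args$product <- product_params(p$model, m = p$m, n = p$n,
                                 P_max = p$P_max, HL_inh = p$HL_inh)
  do.call(sim_config, args)
}

#' Command-line entry point
#'
#' Drives the three subcommands of the `inst/cli/fermkin.R` script:
#'
#' * `simulate --out <csv> [--config <json>] [--seed <int>]`: write a
#'   simulated series (default scenario: [gundruk_scenario()]) plus a
#'   sidecar `<csv>.config.json` with the effective configuration.
#' * `fit --in <csv> [--models <comma-list>] [--out <json>]`: fit all
#'   requested models, print the report tables, optionally write the
#'   JSON report.
#' * `recover [--config <json>] [--n-reps <int>] [--seed <int>]
#'   [--count-cv <x>] [--acid-sd <x>] [--ph-sd <x>]`: simulate, refit
#'   and print the per-parameter recovery summary.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status: 0 success, 2 input error, 3 no model
#'   converged.
#' @export
fermkin_cli <- function(args) {
  if (length(args) == 0L) {
    message("usage: fermkin <simulate|fit|recover> [--options]")
    return(2L)
  }
  cmd <- args[1]
  res <- tryCatch({
    opts <- parse_cli_args(args[-1])
    switch(cmd,
      simulate = cli_simulate(opts),
      fit = cli_fit(opts),
      recover = cli_recover(opts),
      stop(sprintf("unknown subcommand `%s`.", cmd), call. = FALSE)
    )
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  as.integer(res)
}

cli_simulate <- function(opts) {
  if (is.null(opts$out)) stop("simulate requires --out <path>.", call. = FALSE)
  config <- if (!is.null(opts$config)) {
    config_from_list(jsonlite::read_json(opts$config, simplifyVector = TRUE))
  } else {
    gundruk_scenario()
  }
  seed <- if (!is.null(opts$seed)) as.integer(opts$seed)
  series <- simulate_fermentation(config, seed = seed)
  write_series(series, opts$out)
  jsonlite::write_json(c(config_to_list(config),
                         list(effective_seed = attr(series, "seed"))),
                       paste0(opts$out, ".config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  message(sprintf("wrote %d rows to %s (seed %d)", nrow(series), opts$out,
                  attr(series, "seed")))
  0L
}

cli_fit <- function(opts) {
  path <- opts[["in"]]
  if (is.null(path)) stop("fit requires --in <path>.", call. = FALSE)
  data <- read_series(path)
  growth_models <- c("gompertz", "logistic")
  product_models <- c("luedeking_piret", "monteagudo", "balannec")
  if (!is.null(opts$models)) {
    sel <- strsplit(opts$models, ",")[[1]]
    growth_models <- intersect(growth_models, sel)
    product_models <- intersect(product_models, sel)
  }
  seed <- if (!is.null(opts$seed)) as.integer(opts$seed) else NA_integer_
  report <- fit_all_models(data, growth_models, product_models, seed = seed)
  cat(format_report(report), sep = "\n")
  if (!is.null(opts$out)) write_report(report, opts$out)
  for (w in report$warnings) message("warning: ", w)
  n_fit <- length(report$growth) + length(report$product)
  conv <- c(vapply(report$growth, function(f) f$converged, logical(1)),
            vapply(report$product, function(f) f$converged, logical(1)))
  if (n_fit == 0L || !any(conv)) return(3L)
  0L
}

cli_recover <- function(opts) {
  config <- if (!is.null(opts$config)) {
    config_from_list(jsonlite::read_json(opts$config, simplifyVector = TRUE))
  } else {
    gundruk_scenario()
  }
  if (!is.null(opts[["count-cv"]])) config$count_cv <- as.numeric(opts[["count-cv"]])
  if (!is.null(opts[["acid-sd"]])) config$acid_sd <- as.numeric(opts[["acid-sd"]])
  if (!is.null(opts[["ph-sd"]])) config$pH_sd <- as.numeric(opts[["ph-sd"]])
  n_reps <- if (!is.null(opts[["n-reps"]])) as.integer(opts[["n-reps"]]) else 10L
  base_seed <- if (!is.null(opts$seed)) as.integer(opts$seed) else config$seed
  summary <- recovery_summary(config, n_reps = n_reps, base_seed = base_seed)
  print(summary, n = Inf)
  if (!is.null(opts$out)) {
    jsonlite::write_json(summary, opts$out, dataframe = "rows",
                         digits = NA)
  }
  0L
}
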