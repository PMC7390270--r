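#' Specify an experiment sweep
#'
#' Declarative description of one of the packaged experiments or a custom
#' run: which parameter grids to sweep, fixed overrides, and an optional
#' seed recorded for provenance (the packaged experiments are fully
#' deterministic).
#'
#' @param experiment One of \code{"fig3"} (platelet-count titration of the
#'   generation assay), \code{"fig6"} (shear-rate threshold of initiation,
#'   1D and/or 2D tier), \code{"fig7"} (shear threshold vs platelet count
#'   for several prothrombin/antithrombin levels), \code{"fig8"}
#'   (tissue-factor patch-size threshold at fixed shear), or
#'   \code{"custom"}.
#' @param grids Named list of parameter grids; experiment-specific defaults
#'   are filled in by [run_experiment()].
#' @param overrides Named list of fixed parameter overrides.
#' @param tier For \code{"fig6"}: \code{"1d"}, \code{"2d"} or \code{"both"}.
#' @param t_end Horizon (s) for simulation-based experiments.
#' @param seed Integer recorded with the results.
#' @param fun For \code{"custom"}: a function(spec) returning a result
#'   table.
#' @return A list of class \code{sweep_spec}.
#' @export
sweep_spec <- function(experiment = c("fig3", "fig6", "fig7", "fig8", "custom"),
                       grids = list(), overrides = list(), tier = "1d",
                       t_end = NULL, seed = NULL, fun = NULL) {
  experiment <- match.arg(experiment)
  stopifnot(is.list(grids), is.list(overrides))
  if (length(grids) && any(vapply(grids, length, 1L) == 0L)) {
    stop("empty parameter grid in sweep specification")
  }
  structure(list(experiment = experiment, grids = grids,
                 overrides = overrides, tier = tier, t_end = t_end,
                 seed = seed, fun = fun), class = "sweep_spec")
}

.result_row <- function(experiment, run_id, params, metric, value, unit,
                        param_set, status = "ok") {
  data.frame(experiment = experiment, run_id = run_id,
             params = paste(names(params), unlist(params), sep = "=",
                            collapse = ";"),
             metric = metric, value = value, unit = unit,
             param_set = param_set, status = status,
             stringsAsFactors = FALSE)
}

#' Run a packaged experiment sweep
#'
#' Executes the sweep described by a [sweep_spec()] and returns a
#' long-format result table with one row per (run, metric), each row
#' carrying the parameter-set provenance. Failures of individual runs are
#' recorded as rows with \code{status = "error"} and do not abort the
#' sweep.
#'
#' @param spec A \code{sweep_spec}.
#' @return A data frame of class \code{result_table}.
#' @export
run_experiment <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  rows <- switch(spec$experiment,
    fig3 = .run_fig3(spec),
    fig6 = .run_fig6(spec),
    fig7 = .run_fig7(spec),
    fig8 = .run_fig8(spec),
    custom = {
      if (!is.function(spec$fun)) stop("custom experiment requires 'fun'")
      spec$fun(spec)
    })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "seed") <- spec$seed
  class(out) <- c("result_table", "data.frame")
  out
}

.run_fig3 <- function(spec) {
  phis <- if (!is.null(spec$grids$phi0)) spec$grids$phi0 else seq(0, 400, 50)
  set <- load_parameters("table1")
  gp <- do.call(generation_params,
                c(spec$overrides[names(spec$overrides) %in% names(set$values)],
                  list(set = set)))
  tab <- platelet_sweep(gp, phis,
                        t_end = if (is.null(spec$t_end)) 2000 else spec$t_end)
  pid <- paste0(set$name, "@", set$version)
  lapply(seq_len(nrow(tab)), function(i) {
    prm <- list(phi0 = tab$phi0[i])
    rbind(
      .result_row("fig3", i, prm, "peak_nM", tab$peak_nM[i], "nM", pid),
      .result_row("fig3", i, prm, "ttp_s", tab$ttp_s[i], "s", pid),
      .result_row("fig3", i, prm, "ETP_nMs", tab$ETP_nMs[i], "nM s", pid),
      .result_row("fig3", i, prm, "lag_s", tab$lag_s[i], "s", pid)
    )
  })
}

.run_fig6 <- function(spec) {
  gammas <- if (!is.null(spec$grids$gamma)) spec$grids$gamma else
    c(5, 10, 20, 40, 80)
  plasmas <- if (!is.null(spec$grids$plasma)) spec$grids$plasma else
    c("NPP", "PRP")
  t_end <- if (is.null(spec$t_end)) 1200 else spec$t_end
  set <- load_parameters("table2")
  pid <- paste0(set$name, "@", set$version)
  rows <- list()
  run_id <- 0L
  for (pl in plasmas) for (g in gammas) {
    run_id <- run_id + 1L
    prm <- list(plasma = pl, gamma = g)
    if (spec$tier %in% c("1d", "both")) {
      res <- tryCatch({
        wp <- do.call(wave_params, c(
          list(gamma = g, phi0 = if (pl == "PRP") set$values$phi_f0 else 0,
               set = set),
          spec$overrides))
        wf <- simulate_wave(wp, t_end = t_end)
        list(init = initiation_time(wf),
             occ = occluded_fraction(wf, min(800, t_end)))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        rows[[length(rows) + 1]] <- .result_row("fig6", run_id, prm,
          "initiation_1d_s", NA_real_, "s", pid, status = conditionMessage(res))
      } else {
        rows[[length(rows) + 1]] <- rbind(
          .result_row("fig6", run_id, prm, "initiation_1d_s",
                      res$init, "s", pid),
          .result_row("fig6", run_id, prm, "occluded_pct_800s",
                      res$occ, "%", pid))
      }
    }
    if (spec$tier %in% c("2d", "both")) {
      res <- tryCatch({
        geom <- if (!is.null(spec$grids$geom)) spec$grids$geom else
          channel_geometry()
        run_scenario(geom, gamma = g, plasma = pl, t_end = t_end, set = set,
                     stop_at = "initiation")
      }, error = function(e) e)
      rows[[length(rows) + 1]] <- if (inherits(res, "error")) {
        .result_row("fig6", run_id, prm, "initiation_2d_s", NA_real_, "s",
                    pid, status = conditionMessage(res))
      } else {
        .result_row("fig6", run_id, prm, "initiation_2d_s",
                    res$initiation_time, "s", pid)
      }
    }
  }
  rows
}

.run_fig7 <- function(spec) {
  phis <- if (!is.null(spec$grids$phi0)) spec$grids$phi0 else seq(0, 400, 100)
  P0s <- if (!is.null(spec$grids$P0)) spec$grids$P0 else c(1200, 1400)
  A0s <- if (!is.null(spec$grids$A0)) spec$grids$A0 else c(3400, 4500)
  set <- load_parameters("table2")
  pid <- paste0(set$name, "@", set$version)
  rows <- list()
  run_id <- 0L
  for (P0 in P0s) for (A0 in A0s) for (phi in phis) {
    run_id <- run_id + 1L
    prm <- list(phi0 = phi, P0 = P0, A0 = A0)
    res <- tryCatch({
      wp <- do.call(wave_params, c(
        list(phi0 = phi, P0 = P0, A0 = A0, set = set), spec$overrides))
      shear_threshold(wp, y = 0)
    }, error = function(e) e)
    rows[[length(rows) + 1]] <- if (inherits(res, "error")) {
      .result_row("fig7", run_id, prm, "gamma_star_s1", NA_real_, "s^-1",
                  pid, status = conditionMessage(res))
    } else {
      .result_row("fig7", run_id, prm, "gamma_star_s1", res, "s^-1", pid)
    }
  }
  rows
}

.run_fig8 <- function(spec) {
  widths <- if (!is.null(spec$grids$patch_width)) spec$grids$patch_width else
    c(0.05, 0.1, 0.2, 0.4)
  gamma <- if (!is.null(spec$grids$gamma)) spec$grids$gamma[1] else 40
  plasmas <- if (!is.null(spec$grids$plasma)) spec$grids$plasma else "NPP"
  t_end <- if (is.null(spec$t_end)) 600 else spec$t_end
  geom0 <- if (!is.null(spec$grids$geom)) spec$grids$geom else
    channel_geometry()
  set <- load_parameters("table2")
  pid <- paste0(set$name, "@", set$version)
  rows <- list()
  run_id <- 0L
  for (pl in plasmas) for (w in widths) {
    run_id <- run_id + 1L
    prm <- list(plasma = pl, patch_width = w, gamma = gamma)
    res <- tryCatch({
      geom <- channel_geometry(L = geom0$L, H = geom0$H,
                               patch_start = geom0$patch_start,
                               patch_width = w, h = geom0$h)
      run_scenario(geom, gamma = gamma, plasma = pl, t_end = t_end,
                   set = set, stop_at = "initiation")
    }, error = function(e) e)
    rows[[length(rows) + 1]] <- if (inherits(res, "error")) {
      .result_row("fig8", run_id, prm, "initiation_s", NA_real_, "s", pid,
                  status = conditionMessage(res))
    } else {
      .result_row("fig8", run_id, prm, "initiation_s",
                  res$initiation_time, "s", pid)
    }
  }
  rows
}

#' Export a result table
#'
#' Writes CSV and/or JSON with a deterministic column order; exporting and
#' re-importing yields an identical table.
#'
#' @param table A \code{result_table}.
#' @param path Output path; the extension selects the format unless
#'   \code{format} is given.
#' @param format \code{"csv"} or \code{"json"}.
#' @return \code{path}, invisibly.
#' @export
export_results <- function(table, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(table, "data.frame"), nrow(table) >= 1L)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  cols <- c("experiment", "run_id", "params", "metric", "value", "unit",
            "param_set", "status")
  df <- as.data.frame(table)[, cols]
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Import a previously exported result table
#'
#' @param path CSV or JSON file produced by [export_results()].
#' @return A \code{result_table}.
#' @export
import_results <- function(path) {
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  class(df) <- c("result_table", "data.frame")
  df
}
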