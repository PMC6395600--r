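# Cell-table and raster serialization, and the end-to-end pipeline runner.

#' Write / read a cell table as CSV
#'
#' Lossless round-trip of all numeric columns at full double precision
#' (17 significant digits); unknown columns are preserved; variable names
#' with `&` or `/` survive (`check.names` is never applied).
#'
#' @param table Data frame with at least `cell_id`, `row`, `col`.
#' @param path CSV path.
#' @return `write_cell_table` returns `path` invisibly; `read_cell_table`
#'   returns the table.
#' @export
write_cell_table <- function(table, path) {
  out <- table
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
    if (is.character(out[[j]])) out[[j]][out[[j]] %in% c("NA", "nan")] <- NA
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  x <- utils::read.csv(path, check.names = FALSE, na.strings = "")
  mandatory <- c("cell_id", "row", "col")
  miss <- setdiff(mandatory, names(x))
  if (length(miss)) stop("missing mandatory column(s) in ", path, ": ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(x$cell_id)) stop("duplicate cell_id in ", path)
  if (nrow(x) == 0L) warning("empty cell table: ", path)
  x
}

#' Export per-cell values as an ESRI ASCII grid raster
#'
#' Writes a single-band text raster (`.asc`) aligned with the grid: row 0
#' (north) is the first data row, the affine transform is the planar-km cell
#' size, and masked-out cells carry the nodata value. The format is readable
#' by QGIS/ArcGIS and round-trips exactly.
#'
#' @param grid An [sdm_grid()].
#' @param values Numeric vector aligned with `grid$cells`.
#' @param path Output path (conventionally `.asc`).
#' @param nodata Nodata sentinel.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, values, path, nodata = -9999) {
  if (length(values) != nrow(grid$cells))
    stop("values must align with grid$cells")
  m <- matrix(nodata, grid$n_rows, grid$n_cols)
  m[cbind(grid$cells$row + 1L, grid$cells$col + 1L)] <- values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    "xllcorner 0",
    sprintf("yllcorner %.17g", -grid$n_rows * grid$cell_size_km),
    sprintf("cellsize %.17g", grid$cell_size_km),
    sprintf("NODATA_value %.17g", nodata)), con)
  for (r in seq_len(grid$n_rows))
    writeLines(paste(sprintf("%.17g", m[r, ]), collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII grid raster
#'
#' @param path Raster path written by [write_ascii_grid()].
#' @return List with `n_rows`, `n_cols`, `cellsize`, `nodata`, and the value
#'   `matrix` (nodata as `NA`).
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  vals <- as.numeric(vapply(hdr, `[[`, "", 2L))
  names(vals) <- tolower(vapply(hdr, `[[`, "", 1L))
  m <- do.call(rbind, lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1L]])))
  m[m == vals[["nodata_value"]]] <- NA
  list(n_rows = as.integer(vals[["nrows"]]),
       n_cols = as.integer(vals[["ncols"]]),
       cellsize = vals[["cellsize"]], nodata = vals[["nodata_value"]],
       matrix = m)
}

#' Run the full analysis pipeline on a synthetic landscape
#'
#' End-to-end orchestration: simulate the landscape, fit and compare the
#' five hypotheses, map favourability from the best model, validate against
#' independent presences (cells with latent occupancy outside the survey),
#' project the 2040 A1B climate scenario, and write every artifact plus a
#' machine-readable manifest to `out_dir`.
#'
#' @param config Named list (or path to a YAML file) overriding the
#'   defaults: `seed`, `n_rows`, `n_cols`, `region_cells`,
#'   `n_surveyed_coarse`, `hypotheses` (named list of variable sets),
#'   `control` (list of [brt_control()] arguments), `tune`, `simplify`,
#'   `n_validation_cells`, `scenarios` (list of [scenario()] objects).
#' @param out_dir Output directory (created; partial outputs are retained on
#'   failure).
#' @return Invisibly, a list with the fitted `hypothesis_set`, maps,
#'   validation, shift summary, and the manifest.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  defaults <- list(seed = 1, n_rows = 33, n_cols = 30, region_cells = 987,
                   n_surveyed_coarse = 136, hypotheses = hypothesis_registry(),
                   control = list(), tune = FALSE, simplify = TRUE,
                   n_validation_cells = 68, scenarios = NULL)
  # wholesale replacement, not recursive merging: a user-supplied hypothesis
  # list or control must override the default completely
  defaults[names(config)] <- config
  config <- defaults
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  log <- character(0)
  note <- function(fmt, ...) {
    msg <- sprintf("[%6.1fs] %s", as.numeric(Sys.time() - t0, units = "secs"),
                   sprintf(fmt, ...))
    log <<- c(log, msg)
    message(msg)
  }

  note("simulate: landscape seed %d", config$seed)
  land <- simulate_landscape(seed = config$seed, n_rows = config$n_rows,
                             n_cols = config$n_cols,
                             region_cells = config$region_cells,
                             n_surveyed_coarse = config$n_surveyed_coarse)
  cells <- cbind(land$grid$cells[c("row", "col", "x_km", "y_km")],
                 land$cells)
  cells <- cells[c("cell_id", setdiff(names(cells), "cell_id"))]
  write_cell_table(cells, file.path(out_dir, "cells.csv"))

  ctl <- do.call(brt_control, utils::modifyList(
    list(seed = stage_seed(config$seed, "brt")), config$control))
  note("fit: %d hypotheses + hybrid", length(config$hypotheses))
  hs <- fit_hypotheses(land$cells, land$grid, hypotheses = config$hypotheses,
                       control = ctl, tune = config$tune,
                       simplify = config$simplify)
  utils::write.csv(as.data.frame(hs$comparison),
                   file.path(out_dir, "hypothesis_comparison.csv"),
                   row.names = FALSE)
  for (h in names(hs$results)) {
    infl <- relative_influence(hs$results[[h]])
    utils::write.csv(data.frame(variable = names(infl),
                                relative_influence = unname(infl)),
                     file.path(out_dir, sprintf("influence_%s.csv", h)),
                     row.names = FALSE)
  }
  best <- hs$results[[attr(hs$comparison, "best")]]

  note("map: favourability from best model (%s)", best$hypothesis)
  fmap <- favourability_map(best, land$cells, model_id = best$hypothesis)
  write_cell_table(cbind(fmap, rac = as.numeric(best$rac)),
                   file.path(out_dir, "favourability.csv"))
  write_ascii_grid(land$grid, fmap$P, file.path(out_dir, "predictability.asc"))
  write_ascii_grid(land$grid, fmap$F, file.path(out_dir, "favourability.asc"))

  note("validate: independent presences")
  pool <- land$cells$cell_id[!land$cells$sampled &
                               land$cells$latent_occupancy == 1L]
  set.seed(stage_seed(config$seed, "validation"))
  test_cells <- sample(pool, min(config$n_validation_cells, length(pool)))
  val <- validate_independent(fmap, test_cells)
  writeLines(utils::capture.output(print(val)),
             file.path(out_dir, "validation.txt"))

  note("project: scenarios")
  scns <- config$scenarios
  if (is.null(scns)) scns <- list(A1B_2040 = scenario_a1b_2040())
  smaps <- lapply(scns, function(s)
    project_scenario(best, land$cells, s))
  names(smaps) <- vapply(scns, `[[`, "", "name")
  for (nm in names(smaps))
    write_ascii_grid(land$grid, smaps[[nm]]$F,
                     file.path(out_dir, sprintf("favourability_%s.asc", nm)))
  shift <- summarize_shift(fmap, smaps)
  writeLines(utils::capture.output(print(shift)),
             file.path(out_dir, "shift_summary.txt"))

  note("report: manifest")
  files <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("racbrt")),
    n_cells = n_cells(land$grid), n_sampled = length(land$design$sampled_cells),
    best_hypothesis = attr(hs$comparison, "best"),
    artifacts = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, files))), files)),
    log = log, timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(landscape = land, hypotheses = hs, favourability = fmap,
                 validation = val, scenario_maps = smaps, shift = shift,
                 manifest = manifest))
}
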