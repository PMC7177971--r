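#' Pipeline run configuration
#'
#' Defaults reproduce the full study design: both geography classes crossed
#' with the five CTD values (5 x 2 = 10 model cells), the union of the
#' study's independent variables, log population density, county controls,
#' and the 500 x 100 measurement-error bootstrap.
#'
#' Inputs come either from files (`input_paths`: named list with
#' `use_records`, `geography`, `blocks`, `demographics`) or from the
#' synthetic generator (`synthetic`: arguments for [gen_landscape()] plus
#' optional `dgp`).
#'
#' @param input_paths named list of the four input files, or NULL.
#' @param synthetic named list of synthetic-landscape arguments, or NULL.
#' @param geography_classes classes to run (default tract and place).
#' @param ctd_km CTD values in km (default 1, 10, 30, 60, 90).
#' @param iv_vars demographic proportion IVs.
#' @param include_density include log population density as an IV.
#' @param include_county_controls include county-level log density and
#'   agricultural-employment controls.
#' @param use_mode section aggregation mode, `"period_total"` or
#'   `"annual_mean"`.
#' @param k number of nearest neighbors for the spatial weights.
#' @param bootstrap a [bootstrap_config()].
#' @param out_dir output directory (NULL: nothing written).
#' @param seed run-level seed; every cell derives its own substream.
#' @return object of class `run_config`.
#' @export
run_config <- function(input_paths = NULL, synthetic = NULL,
                       geography_classes = c("tract", "place"),
                       ctd_km = c(1, 10, 30, 60, 90),
                       iv_vars = c("hispanic", "black", "indigenous", "asian",
                                   "children", "poverty", "noncitizens",
                                   "women", "ag_employment"),
                       include_density = TRUE,
                       include_county_controls = TRUE,
                       use_mode = "period_total",
                       k = 3L,
                       bootstrap = bootstrap_config(),
                       out_dir = NULL, seed = 1L) {
  if (is.null(input_paths) && is.null(synthetic))
    stop("run_config: provide input_paths or a synthetic spec")
  structure(list(input_paths = input_paths, synthetic = synthetic,
                 geography_classes = geography_classes, ctd_km = ctd_km,
                 iv_vars = iv_vars, include_density = include_density,
                 include_county_controls = include_county_controls,
                 use_mode = use_mode, k = as.integer(k),
                 bootstrap = bootstrap, out_dir = out_dir, seed = seed),
            class = "run_config")
}

load_pipeline_inputs <- function(cfg) {
  if (!is.null(cfg$input_paths)) {
    p <- cfg$input_paths
    for (f in unlist(p)) if (!file.exists(f)) stop("missing input file: ", f)
    list(records = utils::read.csv(p$use_records, stringsAsFactors = FALSE),
         units = read_geography(p$geography),
         blocks = utils::read.csv(p$blocks, stringsAsFactors = FALSE),
         demographics = utils::read.csv(p$demographics, stringsAsFactors = FALSE))
  } else {
    sy <- cfg$synthetic
    dgp <- sy$dgp %||% dgp_config()
    land_args <- sy[setdiff(names(sy), "dgp")]
    land_args$seed <- land_args$seed %||% derive_seed(cfg$seed, "synthetic")
    landscape <- do.call(gen_landscape, land_args)
    demographics <- gen_demographics(landscape, dgp, seed = land_args$seed)
    records <- gen_use_records(landscape$sections, seed = land_args$seed)
    list(records = records, units = landscape$units,
         blocks = landscape$blocks, demographics = demographics)
  }
}

#' Run the full study design
#'
#' Orchestrates every geography-class x CTD cell: census preparation
#' (exclusion filter, derived proportions with MOEs, density, county
#' controls, weighted centroids), section aggregation, decay-weighted local
#' use and the log10 dependent variable, k-nearest-neighbor weights on the
#' retained units, and the measurement-error bootstrap. Cells run
#' sequentially with per-cell derived seeds, so subsetting cells never
#' changes another cell's results.
#'
#' @param cfg a [run_config()].
#' @return object of class `pipeline_result`: `cells` (named list of
#'   [run_bootstrap()] summaries, name `<class>_ctd<km>`), `table` (combined
#'   long-format report from [report_tables()]), `failed_cells`, `exclusions`
#'   and `manifest`. When `cfg$out_dir` is set, per-cell CSVs, the combined
#'   CSV, plot data and a manifest JSON are written there.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  inputs <- load_pipeline_inputs(cfg)
  sections <- aggregate_sections(inputs$records, mode = cfg$use_mode)

  design_vars <- c(cfg$iv_vars,
                   if (cfg$include_density) "log_density",
                   if (cfg$include_county_controls)
                     c("county_log_density", "county_ag_employment"))

  cells <- list()
  failed <- character()
  exclusions <- list()
  for (cl in cfg$geography_classes) {
    demo_cl <- inputs$demographics[inputs$demographics$geography_class == cl, , drop = FALSE]
    units_cl <- inputs$units[inputs$units$geography_class == cl, , drop = FALSE]
    if (!nrow(demo_cl)) stop("run_pipeline: no units of class ", cl)
    prep <- prepare_units(demo_cl, inputs$blocks, iv_names = cfg$iv_vars)
    exclusions[[cl]] <- prep$excluded
    expo_all <- exposure_vectors(units_cl, prep$centroids, sections,
                                 ctd_km = cfg$ctd_km)
    for (ctd in cfg$ctd_km) {
      cell_id <- sprintf("%s_ctd%g", cl, ctd)
      res <- tryCatch({
        expo <- expo_all[expo_all$ctd_km == ctd, , drop = FALSE]
        keep <- !is.na(expo$log_q_i)
        if (sum(!keep) > 0)
          message(sprintf("cell %s: excluding %d unit(s) with zero local use",
                          cell_id, sum(!keep)))
        ids <- expo$unit_id[keep]
        ivs <- prep$ivs[match(ids, prep$ivs$unit_id), , drop = FALSE]
        cents <- prep$centroids[match(ids, prep$centroids$unit_id), , drop = FALSE]
        w <- knn_weights(cents, k = cfg$k)
        boot_cfg <- cfg$bootstrap
        boot_cfg$seed <- derive_seed(cfg$seed, cell_id)
        run_bootstrap(expo$log_q_i[keep], ivs, w, boot_cfg,
                      iv_vars = design_vars,
                      proportion_vars = cfg$iv_vars)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        warning(sprintf("cell %s aborted: %s", cell_id, conditionMessage(res)))
        failed <- c(failed, cell_id)
      } else {
        cells[[cell_id]] <- res
      }
    }
  }

  table <- report_tables(cells)
  manifest <- list(
    seed = cfg$seed,
    geography_classes = cfg$geography_classes, ctd_km = cfg$ctd_km,
    iv_vars = cfg$iv_vars, design_vars = design_vars,
    use_mode = cfg$use_mode, k = cfg$k,
    n_resamples = cfg$bootstrap$n_resamples,
    mc_draws_per_resample = cfg$bootstrap$mc_draws_per_resample,
    moe_to_sd = cfg$bootstrap$moe_to_sd,
    cells_completed = names(cells), cells_failed = failed,
    package_version = as.character(utils::packageVersion("localuse")),
    r_version = R.version.string
  )

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(cells))
      utils::write.csv(cells[[nm]]$summary,
                       file.path(cfg$out_dir, paste0("cell_", nm, ".csv")),
                       row.names = FALSE)
    utils::write.csv(table, file.path(cfg$out_dir, "combined_impacts.csv"),
                     row.names = FALSE)
    cfg_path <- file.path(cfg$out_dir, "config.json")
    jsonlite::write_json(manifest[setdiff(names(manifest), "cells_completed")],
                         cfg_path, auto_unbox = TRUE, pretty = TRUE)
    manifest$config_md5 <- unname(tools::md5sum(cfg_path))
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  structure(list(cells = cells, table = table, failed_cells = failed,
                 exclusions = exclusions, manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d cell(s) completed, %d failed\n",
              length(x$cells), length(x$failed_cells)))
  if (length(x$failed_cells))
    cat("failed:", paste(x$failed_cells, collapse = ", "), "\n")
  invisible(x)
}

#' Combined long-format report of cell summaries
#'
#' Stacks the per-cell bootstrap summaries into one table suitable for an
#' interval plot grouped by IV, colored by geography class and faceted by
#' CTD: each row carries raw and transformed median and 5/95 percentiles of
#' the pooled total-impact draws, plus the cell's median rho and residual
#' Moran's I and its resample failure count.
#'
#' @param cells named list of [run_bootstrap()] results, names
#'   `<class>_ctd<km>`.
#' @return long data frame, one row per (IV, geography class, CTD).
#' @export
report_tables <- function(cells) {
  if (!length(cells)) return(data.frame())
  rows <- lapply(names(cells), function(nm) {
    parts <- regmatches(nm, regexec("^(.*)_ctd([0-9.]+)$", nm))[[1]]
    b <- cells[[nm]]
    s <- b$summary
    data.frame(iv = s$iv, geography_class = parts[2],
               ctd_km = as.numeric(parts[3]),
               total_median = s$total_median, total_p5 = s$total_p5,
               total_p95 = s$total_p95,
               total_trans_median = s$total_trans_median,
               total_trans_p5 = s$total_trans_p5,
               total_trans_p95 = s$total_trans_p95,
               rho_median = stats::median(b$rho),
               residual_moran_median = stats::median(b$residual_moran),
               n_failed = b$n_failed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
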