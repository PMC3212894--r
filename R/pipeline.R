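#' Default pipeline configuration
#'
#' Returns the full two-phase workflow configuration as a nested list; any
#' entry can be overridden via `...` (top level) or by editing the list.
#' `read_pipeline_config()` loads and validates a YAML file against these
#' defaults.
#'
#' @param ... top-level overrides, e.g. `total_n = 200`.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    mode = "synthetic",            # synthetic simulation drives the demo
    landscape = list(extent_m = 640, cell_size_m = 20, seed = 1),
    baf = 4.6, min_dbh_cm = 14,
    n_initial = 40,                # phase-1 training plots
    pca_k = 8,
    lasso_folds = 10, lasso_seed = 1,
    k_strata = 6, min_area_ha = 4.05,
    closure_threshold_pct = 10, height_threshold_m = 2,
    total_n = 60,                  # phase-2 plots
    alloc_floor = 2,
    alpha = 0.10,
    seed = 1)
  dots <- list(...)
  cfg[names(dots)] <- dots
  validate_pipeline_config(cfg)
}

#' @rdname pipeline_config
#' @param path YAML file with (a subset of) the configuration entries.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    stop("read_pipeline_config: no such file: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  for (nm in names(user)) {
    if (is.list(cfg[[nm]]) && is.list(user[[nm]]))
      cfg[[nm]][names(user[[nm]])] <- user[[nm]]
    else cfg[[nm]] <- user[[nm]]
  }
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  num <- c("baf", "min_dbh_cm", "n_initial", "pca_k", "lasso_folds",
           "k_strata", "min_area_ha", "total_n", "alloc_floor", "alpha",
           "seed")
  for (nm in num)
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1)
      stop("pipeline_config: '", nm, "' must be a single number",
           call. = FALSE)
  if (cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("pipeline_config: alpha must be in (0,1)", call. = FALSE)
  if (cfg$mode != "synthetic")
    stop("pipeline_config: only synthetic mode is bundled; supply rasters ",
         "and plots to the stage functions directly otherwise",
         call. = FALSE)
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Run the full two-phase stratification workflow
#'
#' Stages: simulate a landscape, summarize layers to the analysis grid,
#' reduce image feature blocks by PCA, install the phase-1 training sample
#' and fit the basal-area / stem-density / conifer-share models, predict all
#' cells and stratify the basal-area by height volume proxy, allocate and
#' place the phase-2 sample, cruise it, and produce post-stratified
#' estimates. Every artifact is written under `out_dir` together with a
#' manifest of input hashes, seeds and stage timings. Any stage failure
#' aborts with the stage name.
#'
#' @param config a [pipeline_config()] (or path to a YAML file).
#' @param out_dir artifact directory (created if missing).
#' @return the manifest, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(config), stages = list())
  t_all <- proc.time()[3]

  stage <- function(name, fun) {
    t0 <- proc.time()[3]
    res <- tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- list(seconds = round(proc.time()[3] - t0, 2))
    res
  }

  land <- stage("simulate", function() {
    lc <- do.call(landscape_config, config$landscape)
    L <- simulate_landscape(lc)
    write.csv(L$stems, file.path(out_dir, "stems.csv"), row.names = FALSE)
    write.csv(L$truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
    write_asc(L$rasters$chm, file.path(out_dir, "chm.asc"))
    write_asc(L$rasters$dem, file.path(out_dir, "dem.asc"))
    if (!is.null(L$crowns))
      crowns_to_geojson(L$crowns, file.path(out_dir, "crowns.geojson"))
    L
  })

  cells <- stage("summarize", function() {
    cf <- summarize_cells(land$grid, dem = land$rasters$dem,
                          chm = land$rasters$chm, cir = land$rasters$cir,
                          rgb = land$rasters$rgb, crowns = land$crowns)
    write.csv(cf, file.path(out_dir, "cell_features.csv"),
              row.names = FALSE)
    cf
  })

  cells <- stage("reduce", function() {
    add_scores <- function(cf, prefix, name) {
      block <- cf[, grep(paste0("^", prefix, "_"), names(cf)),
                  drop = FALSE]
      block <- block[, vapply(block, function(v) !anyNA(v), TRUE),
                     drop = FALSE]
      cs <- suppressWarnings(
        pca_reduce(block, k = config$pca_k, name = name))
      cbind(cf, as.data.frame(cs$scores))
    }
    cf <- add_scores(cells, "cir", "CIR")
    cf <- add_scores(cf, "rgb", "RGB")
    cf <- add_scores(cf, "chm", "LI")
    write.csv(cf, file.path(out_dir, "cell_features_scores.csv"),
              row.names = FALSE)
    cf
  })

  models <- stage("fit", function() {
    set.seed(config$seed)
    cand <- which(!cells$partial)
    pick <- sample(cand, min(config$n_initial, length(cand)))
    locs <- cells[pick, c("x", "y")]
    plots <- simulate_prism_plots(land$stems, locs, baf = config$baf,
                                  min_dbh_cm = config$min_dbh_cm,
                                  gps_error_95_m =
                                    land$config$gps_error_95_m,
                                  seed = config$seed + 1)
    ps <- summarize_plots(plots)
    ps$cell <- cells$cell[pick]
    write.csv(ps, file.path(out_dir, "phase1_plots.csv"),
              row.names = FALSE)
    feat_names <- c(grep("^(CIR|RGB|LI)[0-9]+$", names(cells), value = TRUE),
                    "crown_closure", "crown_cell_height", "crown_pcount",
                    "elev_mean", "slope_mean")
    X <- as.matrix(cells[pick, feat_names])
    fit_one <- function(yraw, transform, weights = NULL) {
      yt <- if (transform == "log") log(yraw + 1) else yraw
      sel <- tryCatch(
        suppressWarnings(lasso_screen(X, yt, folds = config$lasso_folds,
                                      seed = config$lasso_seed)$selected),
        error = function(e) character(0))
      fit_model(X[, sel, drop = FALSE], yraw, transform = transform,
                weights = weights)
    }
    list(ba = fit_one(ps$ba, "log"),
         tph = fit_one(ps$tph, "log"),
         pcon = fit_one(ps$pcon / 100, "logit", weights = ps$n_tally + 1))
  })

  strat <- stage("stratify", function() {
    pred_ba <- predict_cells(models$ba, cells)
    pred_tph <- predict_cells(models$tph, cells)
    pred_pcon <- predict_cells(models$pcon, cells)
    proxy <- volume_proxy(pred_ba, pmax(cells$chm_mean, 0))
    nf <- nonforest_mask(cells, config$closure_threshold_pct,
                         config$height_threshold_m)
    attrs <- data.frame(ba = pred_ba, height = pmax(cells$chm_mean, 0),
                        tph = pred_tph, pcon = pred_pcon)
    sa <- stratify_cells(proxy, nf, k = config$k_strata,
                         cell_area_ha = cell_area_ha(land$grid),
                         attributes = attrs,
                         min_area_ha = config$min_area_ha)
    write.csv(cbind(cells[, c("cell", "x", "y")],
                    stratum = sa$labels),
              file.path(out_dir, "strata_cells.csv"), row.names = FALSE)
    write.csv(sa$table, file.path(out_dir, "strata_table.csv"),
              row.names = FALSE)
    sa
  })

  plan <- stage("allocate", function() {
    tab <- strat$table[strat$table$stratum > 0, ]
    S <- sqrt(tab$proxy_var)
    alloc <- neyman_allocate(tab$n_cells, S, config$total_n,
                             floor = config$alloc_floor)
    alloc$stratum <- tab$stratum
    pts <- place_plots(strat$labels, land$grid, alloc$n,
                       seed = config$seed + 2)
    write.csv(alloc, file.path(out_dir, "allocation.csv"),
              row.names = FALSE)
    write.csv(pts, file.path(out_dir, "phase2_points.csv"),
              row.names = FALSE)
    list(alloc = alloc, points = pts)
  })

  report <- stage("estimate", function() {
    plots2 <- simulate_prism_plots(land$stems, plan$points,
                                   baf = config$baf,
                                   min_dbh_cm = config$min_dbh_cm,
                                   gps_error_95_m =
                                     land$config$gps_error_95_m,
                                   seed = config$seed + 3)
    ps2 <- summarize_plots(plots2)
    ps2$stratum <- plan$points$stratum
    write.csv(ps2, file.path(out_dir, "phase2_plots.csv"),
              row.names = FALSE)
    tab <- strat$table[strat$table$stratum > 0,
                       c("stratum", "area_ha")]
    vars <- c("ba", "tph", "pcon", "carbon_mg", "bf")
    rows <- lapply(vars, function(v) {
      es <- poststratified_estimate(ps2[[v]], ps2$stratum, tab,
                                    alpha = config$alpha)
      data.frame(variable = v, mean = es$mean, se = es$se,
                 half_width = es$half_width,
                 accuracy_pct = es$accuracy_pct, df = es$df)
    })
    rep_ <- do.call(rbind, rows)
    write.csv(rep_, file.path(out_dir, "estimates.csv"),
              row.names = FALSE)
    rep_
  })

  arts <- list.files(out_dir, full.names = TRUE)
  arts <- arts[!grepl("manifest\\.json$", arts)]
  manifest$artifacts <- lapply(setNames(basename(arts), basename(arts)),
                               function(f)
                                 unname(tools::md5sum(file.path(out_dir,
                                                                f))))
  manifest$seconds_total <- round(proc.time()[3] - t_all, 2)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(manifest)
}
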