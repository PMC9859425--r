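pipeline_defaults <- function() {
  list(
    rows = 64, cols = 64, epochs = 3, seed = 1,
    cell_size = 300,            # metres; block 3 below -> 900 m analysis cells
    n_zones = 6,
    pca_threshold = 85, classes = 5, pca_use = "correlation",
    moran_block = 3, weights_scheme = "rook", permutations = 999,
    lisa_alpha = 0.05,
    geodetector_k = 5, geodetector_method = "jenks",
    interaction_pairs = 15,     # top-q factor pairs run through the detector
    ca_window = 5, ca_iterations = 5,
    out_dir = NULL
  )
}

#' Validate a pipeline configuration
#'
#' Reads a YAML configuration (or takes a list), fills in documented
#' defaults, rejects unknown keys and checks ranges. The returned list is
#' what [run_pipeline()] consumes.
#'
#' @param config path to a YAML file, or a named list (possibly empty).
#' @return A complete configuration list of class `eco_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop_ecovuln(sprintf("config file not found: %s", config),
                   "ecovuln_validation_error")
    }
    config <- yaml::read_yaml(config) %||% list()
  }
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop_ecovuln(paste0("unknown config key(s): ",
                        paste(unknown, collapse = ", ")),
                 "ecovuln_validation_error")
  }
  cfg <- utils::modifyList(defaults, config)
  check <- function(cond, msg) {
    if (!cond) stop_ecovuln(msg, "ecovuln_validation_error")
  }
  check(cfg$rows >= 16 && cfg$cols >= 16, "rows and cols must be >= 16")
  check(cfg$epochs >= 2, "epochs must be >= 2")
  check(cfg$pca_threshold > 0 && cfg$pca_threshold <= 100,
        "pca_threshold must be in (0, 100]")
  check(cfg$classes >= 2, "classes must be >= 2")
  check(cfg$permutations >= 99, "permutations must be >= 99")
  check(cfg$moran_block >= 1, "moran_block must be >= 1")
  check(cfg$weights_scheme %in% c("rook", "queen"),
        "weights_scheme must be rook or queen")
  check(cfg$geodetector_k >= 2, "geodetector_k must be >= 2")
  check(cfg$geodetector_method %in% c("jenks", "quantile"),
        "geodetector_method must be jenks or quantile")
  check(cfg$ca_window >= 3 && cfg$ca_window %% 2 == 1,
        "ca_window must be an odd integer >= 3")
  check(cfg$ca_iterations >= 1, "ca_iterations must be >= 1")
  check(cfg$lisa_alpha > 0 && cfg$lisa_alpha < 1,
        "lisa_alpha must be in (0, 1)")
  structure(cfg, class = c("eco_config", "list"))
}

#' Run the full vulnerability analysis pipeline
#'
#' Orchestrates the complete analysis on a synthetic study region:
#' indicator synthesis, standardization, PCA-weighted EVI per epoch,
#' natural-breaks grading, zonal reporting, spatial autocorrelation on
#' aggregated analysis cells (global Moran's I, LISA clusters), geodetector
#' driver analysis (factor q and interactions), and CA-Markov validation
#' and forecasting. All randomness derives from the configured seed, so a
#' given configuration reproduces its outputs exactly; when `out_dir` is
#' set, tables (CSV), maps (ASCII grids) and a provenance record (JSON with
#' the full configuration) are written there.
#'
#' @param config a configuration accepted by [validate_config()].
#' @return An object of class `eco_pipeline` with per-epoch results
#'   (`pca`, `evi`, `classes`, `zonal`, `moran`, `lisa_map`), `factor_q`
#'   and `interactions` tables, and the `ca` block (estimated transition,
#'   validation kappa, forecast map and area-change table).
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  log_lines <- character(0)
  say <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  epochs <- seq_len(cfg$epochs)
  say("stage synth: %d epoch(s) of %dx%d indicators", cfg$epochs, cfg$rows,
      cfg$cols)
  # latent vulnerability evolves as an AR(1) sequence across epochs so class
  # maps are temporally persistent, as observed vulnerability surfaces are
  rho <- 0.97
  L <- max(4, cfg$rows / 10)
  lat <- gaussian_field(cfg$rows, cfg$cols, correlation_length = L,
                        seed = cfg$seed + 37L)
  scenes <- lapply(epochs, function(e) {
    if (e > 1) {
      innov <- gaussian_field(cfg$rows, cfg$cols, correlation_length = L,
                              seed = cfg$seed + 37L * e)
      lat <<- eco_grid(rho * lat$values + sqrt(1 - rho^2) * innov$values,
                       cell_size = lat$cell_size)
    }
    synth_indicator_stack(cfg$rows, cfg$cols, seed = cfg$seed + 37L * e,
                          latent = lat)
  })
  zones <- synth_zones(cfg$rows, cfg$cols, n_zones = cfg$n_zones,
                       seed = cfg$seed)

  say("stage prep: polarity-aware standardization")
  stacks <- lapply(scenes, function(sc) {
    layers <- sc$stack
    layers[[13]]$grid <- assign_landuse_vulnerability(layers[[13]]$grid)
    layers[[13]]$spec$polarity <- "positive"
    build_stack(layers)
  })

  say("stage evi: PCA at %.4g%% cumulative threshold", cfg$pca_threshold)
  per_epoch <- lapply(epochs, function(e) {
    pca <- fit_pca(stacks[[e]], use = cfg$pca_use)
    n <- select_components(pca, cfg$pca_threshold)
    evi <- compute_evi(pca, n)
    cls <- classify_natural_breaks(evi, k = cfg$classes)
    list(pca = pca, n_components = n, evi = evi, classes = cls,
         summary = evi_summary(evi),
         zonal = zonal_class_share(cls, zones))
  })

  say("stage moran: block %d aggregation, %s weights, %d permutations",
      cfg$moran_block, cfg$weights_scheme, cfg$permutations)
  moran <- lapply(epochs, function(e) {
    evi_agg <- aggregate_blocks(per_epoch[[e]]$evi, cfg$moran_block, "mean")
    W <- build_weights(evi_agg, scheme = cfg$weights_scheme)
    glob <- global_morans_i(evi_agg, W, permutations = cfg$permutations,
                            seed = cfg$seed + e)
    lisa <- local_morans_i(evi_agg, W, permutations = cfg$permutations,
                           seed = cfg$seed + 100L + e)
    lisa_map <- lisa_classify(lisa, evi_agg, W, alpha = cfg$lisa_alpha)
    list(global = glob, lisa = lisa, lisa_map = lisa_map, weights = W,
         evi_agg = evi_agg)
  })

  say("stage detect: factor and interaction detectors (k = %d, %s)",
      cfg$geodetector_k, cfg$geodetector_method)
  specs <- indicator_specs()
  strata_by_epoch <- lapply(epochs, function(e) {
    lapply(seq_len(13), function(p) {
      if (specs$polarity[p] == "categorical") {
        scenes[[e]]$stack[[p]]$grid  # land use enters as native categories
      } else {
        discretize_factor(scenes[[e]]$stack[[p]]$grid,
                          k = cfg$geodetector_k,
                          method = cfg$geodetector_method)
      }
    })
  })
  q_tab <- do.call(rbind, lapply(epochs, function(e) {
    do.call(rbind, lapply(seq_len(13), function(p) {
      qr <- factor_q(per_epoch[[e]]$evi, strata_by_epoch[[e]][[p]])
      data.frame(epoch = e, code = specs$code[p], factor = specs$name[p],
                 q = qr$q, p_value = qr$p_value, stringsAsFactors = FALSE)
    }))
  }))
  last <- cfg$epochs
  qs_last <- q_tab$q[q_tab$epoch == last]
  pair_rank <- utils::combn(13, 2)
  pair_score <- qs_last[pair_rank[1, ]] + qs_last[pair_rank[2, ]]
  keep <- order(pair_score, decreasing = TRUE)[
    seq_len(min(cfg$interaction_pairs, ncol(pair_rank)))]
  interactions <- do.call(rbind, lapply(keep, function(ix) {
    i <- pair_rank[1, ix]; j <- pair_rank[2, ix]
    ir <- interaction_q(per_epoch[[last]]$evi,
                        strata_by_epoch[[last]][[i]],
                        strata_by_epoch[[last]][[j]])
    data.frame(factor1 = specs$code[i], factor2 = specs$code[j],
               q1 = ir$q1, q2 = ir$q2, q12 = ir$q12,
               category = ir$category, stringsAsFactors = FALSE)
  }))

  say("stage forecast: CA-Markov (window %d, %d iterations)",
      cfg$ca_window, cfg$ca_iterations)
  cls <- lapply(per_epoch, `[[`, "classes")
  tm_fit <- transition_matrix(cls[[last - 1]], cls[[last]])
  ca <- list(transition = tm_fit)
  if (cfg$epochs >= 3) {
    tm_val <- transition_matrix(cls[[last - 2]], cls[[last - 1]])
    sim_val <- ca_simulate(cls[[last - 1]], tm_val$prob,
                           evi = per_epoch[[last - 1]]$evi,
                           iterations = cfg$ca_iterations,
                           window = cfg$ca_window, seed = cfg$seed + 7L)
    ca$validation <- kappa_agreement(cls[[last]], sim_val$map)
    ca$simulated_map <- sim_val$map
  }
  forecast <- ca_simulate(cls[[last]], tm_fit$prob,
                          evi = per_epoch[[last]]$evi,
                          iterations = cfg$ca_iterations,
                          window = cfg$ca_window, seed = cfg$seed + 11L)
  ca$forecast <- forecast
  ca$area_change <- area_change_table(cls[[last]], forecast$map)
  ca$transfer <- transfer_report(transition_matrix(cls[[last]],
                                                   forecast$map))

  result <- structure(
    list(config = cfg, epochs = per_epoch, zones = zones, moran = moran,
         factor_q = q_tab, interactions = interactions, ca = ca,
         log = log_lines),
    class = "eco_pipeline"
  )
  if (!is.null(cfg$out_dir)) write_pipeline_bundle(result, cfg$out_dir)
  invisible(result)
}

#' @export
print.eco_pipeline <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<eco_pipeline: %d epoch(s), %dx%d scene, seed %d>\n",
              cfg$epochs, cfg$rows, cfg$cols, cfg$seed))
  for (e in seq_along(x$epochs)) {
    s <- x$epochs[[e]]$summary
    cat(sprintf("  epoch %d: EVI mean %.3f [%.3f, %.3f], %d PCs, Moran I %.3f (p %.3g)\n",
                e, s["mean"], s["min"], s["max"], x$epochs[[e]]$n_components,
                x$moran[[e]]$global$I, x$moran[[e]]$global$p_value))
  }
  if (!is.null(x$ca$validation)) {
    cat(sprintf("  CA-Markov validation kappa: %.3f\n",
                x$ca$validation$kappa))
  }
  top <- x$factor_q[x$factor_q$epoch == max(x$factor_q$epoch), ]
  top <- top[order(top$q, decreasing = TRUE)[1:3], ]
  cat(sprintf("  top drivers (last epoch): %s\n",
              paste(sprintf("%s q=%.3f", top$factor, top$q), collapse = "; ")))
  invisible(x)
}

# write the report bundle: CSV tables, ASCII-grid maps, provenance JSON, log
write_pipeline_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  wcsv <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  for (e in seq_along(result$epochs)) {
    pe <- result$epochs[[e]]
    pca_tab <- data.frame(
      component = paste0("PC", seq_along(pe$pca$eigenvalues)),
      eigenvalue = round(pe$pca$eigenvalues, 3),
      contribution_rate = round(pe$pca$contribution, 3),
      cumulative_contribution_rate = round(pe$pca$cumulative, 3))
    wcsv(pca_tab, sprintf("pca_epoch%d.csv", e))
    wcsv(pe$zonal, sprintf("zonal_shares_epoch%d.csv", e))
    write_grid(pe$evi, file.path(out_dir, sprintf("evi_epoch%d.asc", e)))
    write_grid(pe$classes,
               file.path(out_dir, sprintf("classes_epoch%d.asc", e)))
    write_grid(result$moran[[e]]$lisa_map,
               file.path(out_dir, sprintf("lisa_epoch%d.asc", e)))
    W <- result$moran[[e]]$weights
    evi_agg <- result$moran[[e]]$evi_agg
    x <- evi_agg$values[W$cells]
    z <- x - mean(x)
    deg <- neighbor_counts(W)
    lag <- numeric(W$n)
    tmp <- rowsum(z[W$to], W$from)
    lag[as.integer(rownames(tmp))] <- tmp
    wcsv(data.frame(value = x, neighbor_mean = mean(x) + lag / pmax(deg, 1)),
         sprintf("moran_scatter_epoch%d.csv", e))
  }
  moran_tab <- do.call(rbind, lapply(seq_along(result$moran), function(e) {
    g <- result$moran[[e]]$global
    data.frame(epoch = e, moran_i = g$I, expected = g$expected,
               p_value = g$p_value, n = g$n)
  }))
  wcsv(moran_tab, "global_moran.csv")
  wcsv(result$factor_q, "factor_q.csv")
  wcsv(result$interactions, "interaction_q.csv")
  A <- round(result$ca$transition$area, 3)
  tr <- transfer_report(result$ca$transition)
  A_out <- rbind(cbind(A, Decrease = round(tr$decrease, 3)),
                 Increase = c(round(tr$increase, 3), NA))
  utils::write.csv(A_out, file.path(out_dir, "transition_area.csv"))
  acd <- result$ca$area_change
  for (nm in c("area_t", "area_t1", "change")) acd[[nm]] <- round(acd[[nm]], 3)
  for (nm in c("pct_t", "pct_t1", "change_pct")) acd[[nm]] <- round(acd[[nm]], 2)
  wcsv(acd, "area_change.csv")
  write_grid(result$ca$forecast$map, file.path(out_dir, "forecast.asc"))
  provenance <- list(
    config = unclass(cfg),
    config_hash = config_hash(cfg),
    generated_by = paste0("ecovuln ",
                          as.character(utils::packageVersion("ecovuln")))
  )
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  writeLines(result$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(v) paste(format(v),
                                                       collapse = ","),
                                character(1)),
             sep = "=", collapse = ";")
  # small rolling hash; stable across sessions, no external dependency
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%d", h)
}
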