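#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end run. All stage seeds are derived
#' from the single master `seed` plus stage names and species ids
#' ([derive_seed()]), so a configuration fully determines a run.
#'
#' @param seed master seed.
#' @param shape grid shape c(nrows, ncols).
#' @param n_species number of virtual species.
#' @param effort_centres list of c(row, col) sampling hotspots, or `NULL`
#'   to place two default centres on land.
#' @param niche_config see [default_niche_config()].
#' @param scenario_params see [default_scenario_params()].
#' @param n_bins environmental-filter bins per variable.
#' @param min_records minimum-record acceptance threshold.
#' @param sre_q surface-range-envelope quantile.
#' @param boyce_window,boyce_n_windows Boyce curve parameters.
#' @param boyce_background Boyce evaluation background,
#'   `"calibration"` (default) or `"landscape"` (see [cross_validate()]).
#' @param retention ensemble retention threshold on cv Boyce.
#' @param hotspot_fractions pool fractions for hotspot cut-offs.
#' @param algorithms model families to fit.
#' @param predictor_set_ids which of the two predictor sets to run.
#' @param turnover_method `"jaccard"` or `"rate"`.
#' @param out_dir artifact directory, or `NULL` to keep results in memory.
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1, shape = c(60, 60), n_species = 10,
                       effort_centres = NULL,
                       niche_config = default_niche_config(),
                       scenario_params = default_scenario_params(),
                       n_bins = 6, min_records = 30, sre_q = 0.025,
                       boyce_window = 0.1, boyce_n_windows = 101,
                       boyce_background = "calibration",
                       retention = 0.6,
                       hotspot_fractions = c(0.05, 0.10, 0.15),
                       algorithms = c("glm", "gam", "rf", "brt"),
                       predictor_set_ids = c("set1", "set2"),
                       turnover_method = "jaccard", out_dir = NULL) {
  algorithms <- match.arg(algorithms, ALGORITHMS, several.ok = TRUE)
  predictor_set_ids <- match.arg(predictor_set_ids,
                                 names(predictor_sets()), several.ok = TRUE)
  cfg <- list(
    seed = as.integer(seed), shape = as.integer(shape),
    n_species = as.integer(n_species),
    effort_centres = if (is.null(effort_centres)) NULL else {
      lapply(effort_centres, as.integer)
    },
    niche_config = utils::modifyList(default_niche_config(), niche_config),
    scenario_params = utils::modifyList(default_scenario_params(),
                                        scenario_params),
    n_bins = as.integer(n_bins), min_records = as.integer(min_records),
    sre_q = as.numeric(sre_q), boyce_window = as.numeric(boyce_window),
    boyce_n_windows = as.integer(boyce_n_windows),
    boyce_background = match.arg(boyce_background,
                                 c("calibration", "landscape")),
    retention = as.numeric(retention),
    hotspot_fractions = as.numeric(hotspot_fractions),
    algorithms = algorithms, predictor_set_ids = predictor_set_ids,
    turnover_method = match.arg(turnover_method, c("jaccard", "rate")),
    out_dir = out_dir
  )
  cfg$niche_config$lambda <- as.numeric(cfg$niche_config$lambda)
  cfg$niche_config$max_continents <- as.integer(cfg$niche_config$max_continents)
  cfg$scenario_params$realization_seeds <- stats::setNames(
    as.integer(unlist(cfg$scenario_params$realization_seeds)), c("r1", "r2")
  )
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration (YAML)
#'
#' The YAML file round-trips losslessly: `read_config(write_config(cfg))`
#' reproduces `cfg` exactly up to the machine-local `out_dir`, which is not
#' serialized (fields are re-normalized through [run_config()]).
#'
#' @param config a `run_config`.
#' @param path YAML file path.
#' @return `path` (write) or a `run_config` (read).
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  lst <- unclass(config)
  lst$out_dir <- NULL
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("invalid config key(s): ", paste(bad, collapse = ", "))
  raw$niche_config$variables <- as.character(raw$niche_config$variables)
  do.call(run_config, raw)
}

.default_centres <- function(ls) {
  cells <- land_cells(ls)
  idx <- unique(pmax(1, round(c(0.2, 0.4, 0.6, 0.8) * length(cells))))
  lapply(idx, function(i) {
    rc <- cell_rowcol(ls, cells[i])
    c(rc$row, rc$col)
  })
}

#' Run the full stacked-SDM pipeline
#'
#' Executes, in order: world simulation (five scenario landscapes), effort
#' field, virtual species, biased occurrence sampling; per species and
#' predictor set: occurrence preparation, surface-range-envelope
#' pseudo-absences, spatial-block cross-validation of the four model
#' families, Boyce-weighted ensembling, projection to all five scenario
#' tags and Boyce-maximization binarization; then richness stacking per
#' ensemble member, consensus richness, hotspot/change/turnover/CV maps,
#' biome summaries and the continent-restricted dispersal sensitivity.
#' Per-species failures are logged in the attrition table and never abort
#' the run. If `config$out_dir` is set, artifacts (CSV/JSON/TIFF) are
#' written and listed with checksums in `manifest.json`.
#'
#' @param config a [run_config()].
#' @param quiet suppress per-stage progress messages.
#' @return object of class `invstack_run`; see the package vignette for the
#'   component inventory.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  seed <- cfg$seed
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()

  say("simulating world %dx%d", cfg$shape[1], cfg$shape[2])
  world <- make_world(seed, cfg$shape, cfg$scenario_params)
  cur <- world$current
  centres <- if (is.null(cfg$effort_centres)) .default_centres(cur) else {
    cfg$effort_centres
  }
  effort <- make_effort(derive_seed(seed, "effort"), cur, centres)
  species <- make_species(seed, cur, cfg$n_species, cfg$niche_config)

  future_tags <- setdiff(names(world), "current")
  attrition <- list()
  filter_report <- list()
  model_report <- list()
  ensemble_report <- list()
  ensembles <- list()   # [[species]][[pset]]
  binaries <- list()    # [[species]][[pset]][[scenario]]
  occurrences <- list()
  calibration <- list() # [[pset]] presence/PA csv rows

  note <- function(sp, pset, stage, reason) {
    attrition[[length(attrition) + 1]] <<- data.frame(
      species_id = sp, predictor_set = pset, stage = stage, reason = reason
    )
  }

  # occurrence preparation uses the union of the active predictor sets'
  # climatic variables: one environmental filter per species, shared by the
  # parallel predictor-set ensembles
  union_cvars <- unique(unlist(lapply(cfg$predictor_set_ids, climatic_vars)))

  for (sp in species) {
    raw <- sample_occurrences(seed, sp, effort, cur)
    occurrences[[sp$id]] <- raw
    prep <- prepare_occurrences(raw, union_cvars, n_bins = cfg$n_bins,
                                min_records = cfg$min_records,
                                seed = derive_seed(seed, "prep"))
    filter_report[[sp$id]] <- prep$report
    if (!prep$accepted) {
      note(sp$id, "all", "min_records",
           sprintf("%d < %d records", nrow(prep$occ$records),
                   cfg$min_records))
      next
    }
    for (pset_id in cfg$predictor_set_ids) {
      pvars <- predictor_sets()[[pset_id]]
      cvars <- climatic_vars(pset_id)
      res <- tryCatch({
        {
          pres <- prep$occ
          pres_cells <- cell_index(cur, pres$records$row, pres$records$col)
          sre <- fit_sre(pres$records[cvars], q = cfg$sre_q)
          pa <- sample_pa(sre, cur, effort, n = nrow(pres$records),
                          presence_cells = pres_cells,
                          seed = derive_seed(seed, pset_id),
                          species_id = sp$id)
          stopifnot(nrow(pa$records) == nrow(pres$records)) # |PA| = |presences|
          calibration[[pset_id]][[sp$id]] <- list(pres = pres, pa = pa)
          pts <- rbind(pres$records[c("row", "col")],
                       pa$records[c("row", "col")])
          blocks <- make_blocks(pts)
          models <- lapply(cfg$algorithms, function(alg) {
            m <- fit_cv_sdm(alg, pres, pa, pvars, blocks, cur,
                            seed = derive_seed(seed, "fit", sp$id, pset_id),
                            boyce_window = cfg$boyce_window,
                            boyce_n_windows = cfg$boyce_n_windows,
                            background = cfg$boyce_background)
            fb <- if (is.null(m)) rep(NA_real_, 4) else m$fold_boyce
            model_report[[paste(sp$id, pset_id, alg)]] <<- data.frame(
              species_id = sp$id, predictor_set = pset_id, algorithm = alg,
              boyce_f1 = fb[1], boyce_f2 = fb[2], boyce_f3 = fb[3],
              boyce_f4 = fb[4],
              cv_boyce = if (is.null(m)) NA_real_ else m$cv_boyce,
              retained = !is.null(m) && !is.na(m$cv_boyce) &&
                m$cv_boyce > cfg$retention
            )
            m
          })
          ens <- build_ensemble(models, retention = cfg$retention)
          if (!ens$retained) {
            note(sp$id, pset_id, "ensemble", "no model with cv_boyce above retention")
            return_value <- NULL
          } else {
            stopifnot(abs(sum(ens$weights) - 1) < 1e-9)
            for (tag in names(world)) {
              ens <- predict_ensemble(ens, world[[tag]])
            }
            cursuit <- ens$projections$current
            pa_cells <- cell_index(cur, pa$records$row, pa$records$col)
            tstar <- boyce_max_threshold(
              cursuit[pres_cells],
              if (cfg$boyce_background == "landscape") {
                cursuit[land_cells(cur)]
              } else {
                cursuit[c(pres_cells, pa_cells)]
              },
              window_width = cfg$boyce_window,
              n_windows = cfg$boyce_n_windows
            )
            if (is.na(tstar)) {
              note(sp$id, pset_id, "threshold", "no stable P/E >= 1 crossing")
              return_value <- NULL
            } else {
              ens$threshold <- tstar
              bins <- lapply(ens$projections, binarize, threshold = tstar)
              return_value <- list(ens = ens, bins = bins)
            }
          }
        }
        return_value
      }, error = function(e) {
        note(sp$id, pset_id, "error", conditionMessage(e))
        NULL
      })
      if (!is.null(res)) {
        ensembles[[sp$id]][[pset_id]] <- res$ens
        binaries[[sp$id]][[pset_id]] <- res$bins
        ensemble_report[[paste(sp$id, pset_id)]] <- data.frame(
          species_id = sp$id, predictor_set = pset_id,
          n_members = length(res$ens$members),
          members = paste(vapply(res$ens$members, `[[`, character(1),
                                 "algorithm"), collapse = "+"),
          weights = paste(sprintf("%.4f", res$ens$weights), collapse = "+"),
          threshold = res$ens$threshold
        )
      }
    }
    # bookkeeping: a species retained for both predictor sets carries
    # exactly 2 sets x 2 scenarios x 2 realizations = 8 future projections
    if (!is.null(binaries[[sp$id]]) &&
        length(binaries[[sp$id]]) == length(cfg$predictor_set_ids) &&
        length(cfg$predictor_set_ids) == 2) {
      n_future <- sum(vapply(binaries[[sp$id]], function(b) {
        length(intersect(names(b), future_tags))
      }, integer(1)))
      stopifnot(n_future == 8L)
    }
    say("species %s done", sp$id)
  }

  retained_ids <- names(binaries)
  M <- length(retained_ids)
  if (M == 0) stop("no species survived modelling; nothing to stack")

  # --- stacking: members and consensus per scenario tag --------------------
  member_stacks <- list() # [[scenario]][[member name]]
  for (pset_id in cfg$predictor_set_ids) {
    ids <- retained_ids[vapply(retained_ids, function(s) {
      pset_id %in% names(binaries[[s]])
    }, logical(1))]
    if (!length(ids)) next
    for (tag in names(world)) {
      maps <- lapply(ids, function(s) binaries[[s]][[pset_id]][[tag]])
      member_stacks[[tag]][[paste0(pset_id, if (tag != "current") {
        sub("^(mild|severe)", "", tag)
      } else "")]] <- stack_richness(maps)
    }
  }
  scenarios <- list(
    current = "current",
    mild = grep("^mild_", names(world), value = TRUE),
    severe = grep("^severe_", names(world), value = TRUE)
  )
  stacks <- list()
  for (scen in names(scenarios)) {
    members <- unlist(lapply(scenarios[[scen]], function(tag) {
      member_stacks[[tag]]
    }), recursive = FALSE)
    consensus <- Reduce(`+`, members) / length(members)
    stacks[[scen]] <- list(
      members = members, consensus = consensus,
      cv = if (length(members) >= 2) cv_map(members) else NULL
    )
  }

  # --- hotspots, change, turnover, persistence -----------------------------
  hotspots <- list()
  persistence <- list()
  for (f in cfg$hotspot_fractions) {
    key <- sprintf("f%02d", round(100 * f))
    cur_h <- hotspot_map(stacks$current$consensus, M, f)
    hotspots[["current"]][[key]] <- cur_h
    for (scen in c("mild", "severe")) {
      fut_h <- hotspot_map(stacks[[scen]]$consensus, M, f,
                           cutoff = cur_h$cutoff)
      stopifnot(fut_h$cutoff == cur_h$cutoff) # future uses current cut-off
      hotspots[[scen]][[key]] <- fut_h
      persistence[[paste(scen, key, sep = "_")]] <- data.frame(
        scenario = scen, f = f, cutoff = cur_h$cutoff,
        persistence_pct = tryCatch(hotspot_persistence(cur_h, fut_h),
                                   error = function(e) NA_real_)
      )
    }
  }

  change <- lapply(stacks[c("mild", "severe")], function(st) {
    change_maps(stacks$current$consensus, st$consensus)
  })

  turnover_maps <- list()
  for (scen in c("mild", "severe")) {
    per_member <- list()
    for (pset_id in cfg$predictor_set_ids) {
      ids <- retained_ids[vapply(retained_ids, function(s) {
        pset_id %in% names(binaries[[s]])
      }, logical(1))]
      if (!length(ids)) next
      cur_maps <- lapply(ids, function(s) binaries[[s]][[pset_id]]$current)
      for (tag in scenarios[[scen]]) {
        fut_maps <- lapply(ids, function(s) binaries[[s]][[pset_id]][[tag]])
        per_member[[paste(pset_id, tag)]] <-
          turnover(cur_maps, fut_maps, method = cfg$turnover_method)
      }
    }
    turnover_maps[[scen]] <- Reduce(`+`, per_member) / length(per_member)
  }

  # --- biome space ----------------------------------------------------------
  assignment <- biome_raster(cur)
  land_idx <- land_cells(cur)
  tvals <- cur$layers$temp_mean[land_idx]
  pvals <- cur$layers$precip_annual[land_idx] / 10
  biome <- list(
    assignment = assignment,
    means = lapply(stacks, function(st) {
      biome_means(st$consensus, assignment)
    }),
    density = lapply(stacks, function(st) {
      tryCatch(richness_density(tvals, pvals, st$consensus[land_idx]),
               error = function(e) NULL)
    })
  )

  # --- continental (dispersal) sensitivity ---------------------------------
  sp_by_id <- stats::setNames(species, vapply(species, `[[`, character(1), "id"))
  filt_members <- list()
  for (pset_id in cfg$predictor_set_ids) {
    ids <- retained_ids[vapply(retained_ids, function(s) {
      pset_id %in% names(binaries[[s]])
    }, logical(1))]
    if (!length(ids)) next
    maps <- lapply(ids, function(s) {
      continental_filter(binaries[[s]][[pset_id]]$current,
                         sp_by_id[[s]]$continents, cur$continent)
    })
    filt_members[[pset_id]] <- stack_richness(maps)
  }
  filt_consensus <- Reduce(`+`, filt_members) / length(filt_members)
  stopifnot(all(filt_consensus[land_idx] <= stacks$current$consensus[land_idx] + 1e-9))
  continental <- list(
    consensus = filt_consensus,
    hotspot = hotspot_map(filt_consensus, M, 0.10,
                          cutoff = hotspots$current$f10$cutoff)
  )

  run <- structure(
    list(
      config = cfg, world = world, effort = effort, species = species,
      occurrences = occurrences,
      filter_report = do.call(rbind, unname(filter_report)),
      model_report = do.call(rbind, unname(model_report)),
      ensemble_report = if (length(ensemble_report)) {
        do.call(rbind, unname(ensemble_report))
      } else NULL,
      attrition = if (length(attrition)) {
        do.call(rbind, unname(attrition))
      } else NULL,
      ensembles = ensembles, binaries = binaries, M = M,
      retained_ids = retained_ids, calibration = calibration,
      stacks = stacks, hotspots = hotspots,
      persistence = do.call(rbind, unname(persistence)),
      change = change, turnover = turnover_maps, biome = biome,
      continental = continental,
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    ),
    class = "invstack_run"
  )
  if (!is.null(cfg$out_dir)) {
    run$manifest <- write_run_artifacts(run, cfg$out_dir)
  }
  run
}

#' @export
print.invstack_run <- function(x, ...) {
  cat(sprintf(
    "<invstack_run: %d/%d species retained, %.1f s>\n",
    x$M, x$config$n_species, x$elapsed_s
  ))
  invisible(x)
}

# write CSV/JSON/TIFF artifacts; returns the manifest (file -> md5)
write_run_artifacts <- function(run, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", out_dir)
  }
  paths <- character(0)
  put_csv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  write_config(run$config, file.path(out_dir, "config.yaml"))
  paths <- c(paths, file.path(out_dir, "config.yaml"))
  for (tag in names(run$world)) {
    p <- file.path(out_dir, paste0("landscape_", tag, ".tif"))
    write_landscape(run$world[[tag]], p)
    paths <- c(paths, p, paste0(p, ".json"))
  }
  occ_all <- do.call(rbind, lapply(run$occurrences, function(o) {
    if (nrow(o$records)) cbind(species_id = o$species_id, o$records)
  }))
  put_csv(occ_all, "occurrences_raw.csv")
  for (pset_id in names(run$calibration)) {
    cal <- do.call(rbind, lapply(run$calibration[[pset_id]], function(x) {
      pres <- cbind(species_id = x$pres$species_id, x$pres$records,
                    presence = 1L)
      pa <- cbind(species_id = x$pa$species_id, x$pa$records, presence = 0L)
      rbind(pres, pa)
    }))
    put_csv(cal, sprintf("calibration_%s.csv", pset_id))
  }
  put_csv(run$filter_report, "filter_report.csv")
  put_csv(run$model_report, "model_report.csv")
  if (!is.null(run$ensemble_report)) {
    put_csv(run$ensemble_report, "ensemble_report.csv")
  }
  if (!is.null(run$attrition)) put_csv(run$attrition, "attrition.csv")
  hs <- do.call(rbind, unlist(lapply(names(run$hotspots), function(scen) {
    lapply(run$hotspots[[scen]], function(h) {
      data.frame(scenario = scen, f = h$f, cutoff = h$cutoff,
                 land_fraction = h$land_fraction)
    })
  }), recursive = FALSE))
  put_csv(hs, "hotspots.csv")
  put_csv(run$persistence, "persistence.csv")
  bm <- do.call(rbind, lapply(names(run$biome$means), function(scen) {
    cbind(scenario = scen, run$biome$means[[scen]])
  }))
  put_csv(bm, "biome_means.csv")
  sm <- report(run)
  p <- file.path(out_dir, "summary.json")
  jsonlite::write_json(sm, p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  manifest <- list(
    files = lapply(stats::setNames(nm = basename(paths)), function(b) {
      unname(tools::md5sum(file.path(out_dir, b)))
    }),
    n_species = run$config$n_species, retained = run$M
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}

#' Summarize a pipeline run
#'
#' Medians and interquartile ranges of consensus richness per scenario,
#' hotspot land fractions per cut-off, hotspot persistence, per-biome mean
#' richness and mean turnover. Regeneration is idempotent: the summary is a
#' pure function of the run object.
#'
#' @param run an `invstack_run`.
#' @return nested list (serializable to JSON).
#' @export
report <- function(run) {
  stopifnot(inherits(run, "invstack_run"))
  if (is.null(run$stacks)) stop("run has no stacked results to report")
  land_idx <- land_cells(run$world$current)
  richness <- lapply(run$stacks, function(st) {
    v <- st$consensus[land_idx]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    list(median = q[2], iqr_low = q[1], iqr_high = q[3], mean = mean(v),
         max = max(v))
  })
  hotspot <- lapply(run$hotspots, function(hh) {
    lapply(hh, function(h) {
      list(f = h$f, cutoff = h$cutoff, land_fraction = h$land_fraction)
    })
  })
  turn <- lapply(run$turnover, function(tm) {
    list(mean = mean(tm[land_idx]), max = max(tm[land_idx]))
  })
  list(
    modelled_pool = run$M,
    candidate_pool = run$config$n_species,
    modelled_fraction_pct = pool_fraction(run$M, run$config$n_species),
    richness = richness,
    hotspots = hotspot,
    persistence = if (is.null(run$persistence)) NULL else {
      lapply(split(run$persistence, seq_len(nrow(run$persistence))),
             function(r) as.list(r))
    },
    turnover = turn,
    biome_means = lapply(run$biome$means, function(df) {
      stats::setNames(as.list(df$mean_richness), df$biome)
    }),
    centroids = lapply(run$biome$density, function(d) {
      if (is.null(d)) NULL else as.list(d$centroid)
    })
  )
}
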