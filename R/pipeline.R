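#' End-to-end analysis and pipeline plumbing
#'
#' `analyze_study()` wires the stages together on in-memory objects (the
#' form used by tests and simulations); `run_pipeline()` is the file-based
#' front end with config validation, logging and a provenance manifest.
#'
#' @name pipeline
NULL

#' Run the dual-modality analysis on one mutant/WT pair
#'
#' Stages: least-squares scaling of the mutant amplitudes onto WT; weighted
#' difference structure factors (phases from the reference model);
#' difference-map synthesis; per-residue IADDAT, normalized to [0, 1];
#' peptide %D, mutant-minus-WT differences, greedy short-peptide selection,
#' and residue-level projection at the analysis timepoint; thresholding of
#' both tracks; pooling into the combined network.
#'
#' @param wt_refl,mut_refl [reflection_set]s.
#' @param phase_model [atomic_model] used for phases (typically WT).
#' @param score_model [atomic_model] whose residues receive IADDAT. The
#'   reference (WT) structure is the natural choice: disappearance density
#'   sits on reference atom positions, and residue numbering is shared.
#' @param hdx_table peptide measurement table containing both states.
#' @param wt_state,mut_state state labels in `hdx_table`.
#' @param alpha difference-weight sharpness (default 0.05).
#' @param iaddat_threshold map threshold, e-/Angstrom^3 (default 0.04).
#' @param iaddat_radius atom radius, Angstrom (default 1.5).
#' @param iaddat_cutoff network cutoff on the normalized IADDAT scale
#'   (default 0.13).
#' @param cap display cap for normalized IADDAT (default 0.3).
#' @param hdx_timepoint analysis timepoint, seconds (default 300).
#' @param hdx_cutoff |delta %D| network cutoff, points (default 7).
#' @param d2o_fraction labeling D2O fraction (default 0.90).
#' @param select_peptides restrict the projection to the greedy
#'   minimal-spanning peptide selection (default FALSE: the projection
#'   weights peptides by inverse amide count, so short peptides already
#'   dominate, and a minimal cover leaves systematic blind spots at peptide
#'   N-termini; the selection is still computed and returned for
#'   single-peptide track displays).
#' @param population `"auto"` (residues both modeled in the crystal and
#'   measured by shared HDX peptides) or `"full"` (all modeled residues).
#' @return list with the per-stage products: `iaddat_track`, `hdx_track`,
#'   `iaddat_set`, `hdx_set`, `network` (pooled [residue_set]),
#'   `population` (character keys), plus intermediates (`diffs`, `grid`,
#'   `exchange`, `differences`, `selected_spans`).
#' @export
analyze_study <- function(wt_refl, mut_refl, phase_model, score_model,
                          hdx_table, wt_state = "WT", mut_state = "MUT",
                          alpha = 0.05, iaddat_threshold = 0.04,
                          iaddat_radius = 1.5, iaddat_cutoff = 0.13,
                          cap = 0.3, hdx_timepoint = 300, hdx_cutoff = 7,
                          d2o_fraction = 0.90, select_peptides = FALSE,
                          population = c("auto", "full")) {
  population <- match.arg(population)

  # -- crystallographic arm ---------------------------------------------
  mut_scaled <- scale_to_reference(mut_refl, wt_refl)
  diffs <- weighted_differences(mut_scaled, wt_refl, alpha = alpha,
                                phase_source = phase_model)
  grid <- synthesize_map(diffs)
  track_x <- iaddat(grid, score_model, threshold = iaddat_threshold,
                    radius = iaddat_radius)
  track_x <- normalize_track(track_x, cap = cap)

  # -- HDX arm ----------------------------------------------------------
  exch <- percent_deuteration(hdx_table, d2o_fraction = d2o_fraction)
  wt_rec <- exch[exch$state == wt_state, , drop = FALSE]
  mut_rec <- exch[exch$state == mut_state, , drop = FALSE]
  dif <- difference_records(mut_rec, wt_rec)
  L <- max(dif$end)
  sel_spans <- select_spanning_peptides(dif, length_out = L)
  dif_proj <- dif
  if (select_peptides) {
    keep <- paste(dif$start, dif$end) %in% paste(sel_spans$start, sel_spans$end)
    dif_proj <- dif[keep, , drop = FALSE]
  }
  track_h <- residue_projection(dif_proj, timepoint = hdx_timepoint,
                                length_out = L)

  # -- network ----------------------------------------------------------
  modeled <- res_key(track_x$chain, track_x$resnum)
  # measurable universe: residues carrying an exchangeable amide of at least
  # one shared (both-state) peptide, regardless of the projection subset
  covered <- sort(unique(unlist(mapply(exchangeable_positions,
                                       dif$sequence, dif$start,
                                       SIMPLIFY = FALSE))))
  covered <- res_key(track_h$chain[1], covered)
  pop <- if (population == "auto") intersect(modeled, covered) else modeled
  set_x <- restrict_to_population(
    threshold_track(track_x, iaddat_cutoff, "greater", label = "iaddat"), pop)
  set_h <- restrict_to_population(
    threshold_track(track_h, hdx_cutoff, "abs_greater", label = "delta_hdx"),
    pop)
  net <- pool_sets(list(set_x, set_h), label = "combined_network")

  list(iaddat_track = track_x, hdx_track = track_h,
       iaddat_set = set_x, hdx_set = set_h, network = net,
       population = pop, diffs = diffs, grid = grid, exchange = exch,
       differences = dif, selected_spans = sel_spans)
}

#' Pipeline run configuration
#'
#' Collects every tunable of [run_pipeline] with the study defaults: alpha
#' 0.05, IADDAT voxel threshold 0.04 e-/Angstrom^3, radius 1.5 Angstrom,
#' network cutoff 0.13 (normalized), delta-HDX cutoff 7 points at 300 s,
#' D2O fraction 0.90. Either file inputs (`wt_model`, `mut_models`,
#' `wt_reflections`, `mut_reflections`, `hdx_table`) or a synthetic preset
#' (`preset = "toy-study"`) must be given.
#'
#' @param out_dir output directory.
#' @param preset `NULL` or `"toy-study"` (synthetic end-to-end run).
#' @param wt_model,mut_models,wt_reflections,mut_reflections,hdx_table
#'   input file paths (models PDB/mmCIF, reflections CSV, peptide CSV);
#'   `mut_models`/`mut_reflections` are vectors, one per variant.
#' @param mut_states HDX state labels, one per variant.
#' @param sectors named character vector of sector file paths.
#' @param cell unit cell for reflection CSVs (numeric length 6); taken from
#'   the WT model when omitted.
#' @param seed integer seed (used by the preset).
#' @param alpha,iaddat_threshold,iaddat_radius,iaddat_cutoff,cap,
#'   hdx_timepoint,hdx_cutoff,d2o_fraction,population see [analyze_study].
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, preset = NULL, wt_model = NULL,
                       mut_models = NULL, wt_reflections = NULL,
                       mut_reflections = NULL, hdx_table = NULL,
                       mut_states = NULL, sectors = character(0),
                       cell = NULL, seed = 1, alpha = 0.05,
                       iaddat_threshold = 0.04, iaddat_radius = 1.5,
                       iaddat_cutoff = 0.13, cap = 0.3, hdx_timepoint = 300,
                       hdx_cutoff = 7, d2o_fraction = 0.90,
                       population = "auto") {
  structure(list(out_dir = out_dir, preset = preset, wt_model = wt_model,
                 mut_models = mut_models, wt_reflections = wt_reflections,
                 mut_reflections = mut_reflections, hdx_table = hdx_table,
                 mut_states = mut_states, sectors = sectors, cell = cell,
                 seed = seed, alpha = alpha,
                 iaddat_threshold = iaddat_threshold,
                 iaddat_radius = iaddat_radius,
                 iaddat_cutoff = iaddat_cutoff, cap = cap,
                 hdx_timepoint = hdx_timepoint, hdx_cutoff = hdx_cutoff,
                 d2o_fraction = d2o_fraction, population = population),
            class = "run_config")
}

#' Read/write a run configuration as YAML or JSON
#' @param path config file (.yaml/.yml or .json).
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg$sectors <- unlist(cfg$sectors) %||% character(0)
  do.call(run_config, cfg)
}

#' @rdname read_run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  cfg <- unclass(config)
  cfg <- cfg[!vapply(cfg, is.null, TRUE)]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

validate_run_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  thr <- c(config$alpha, config$iaddat_threshold, config$iaddat_radius,
           config$iaddat_cutoff, config$hdx_cutoff)
  if (any(thr < 0)) stop("all thresholds must be >= 0", call. = FALSE)
  files <- c(config$wt_model, config$mut_models, config$wt_reflections,
             config$mut_reflections, config$hdx_table, config$sectors)
  missing <- files[!vapply(files, file.exists, TRUE)]
  if (length(missing)) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(config$preset)) {
    need <- c("wt_model", "mut_models", "wt_reflections", "mut_reflections",
              "hdx_table")
    absent <- need[vapply(config[need], is.null, TRUE)]
    if (length(absent)) {
      stop("config lacks inputs: ", paste(absent, collapse = ", "),
           call. = FALSE)
    }
    if (length(config$mut_models) != length(config$mut_reflections)) {
      stop("one reflection file per mutant model is required", call. = FALSE)
    }
  }
  invisible(config)
}

#' Execute the full pipeline from a configuration
#'
#' Runs the difference-map arm per mutant, the HDX arm per mutant, pools the
#' per-mutant sets into the combined network, and tests overlap with each
#' supplied sector. Per-stage outputs (residue-track CSVs, Woods tables,
#' network JSON) and a provenance manifest (input hashes, parameters,
#' package version, stage status) are written under `config$out_dir`.
#' Defaults substituted for unset options are logged. On a stage failure the
#' manifest records the failed stage and partial outputs are preserved.
#'
#' @param config a [run_config].
#' @return The manifest list, invisibly; component `network_summary` carries
#'   the overlap statistics.
#' @export
run_pipeline <- function(config) {
  validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = as.character(utils::packageVersion("allonet")),
    parameters = unclass(config)[c("alpha", "iaddat_threshold",
                                   "iaddat_radius", "iaddat_cutoff", "cap",
                                   "hdx_timepoint", "hdx_cutoff",
                                   "d2o_fraction", "population", "seed")],
    inputs = list(), stages = list(), failed_stage = NULL)
  infiles <- c(config$wt_model, config$mut_models, config$wt_reflections,
               config$mut_reflections, config$hdx_table, config$sectors)
  if (length(infiles)) {
    manifest$inputs <- as.list(tools::md5sum(infiles))
  }
  finish <- function(m) {
    jsonlite::write_json(m, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    invisible(m)
  }
  result <- tryCatch({
    if (!is.null(config$preset)) {
      if (!identical(config$preset, "toy-study")) {
        stop("unknown preset '", config$preset, "'", call. = FALSE)
      }
      sim <- simulate_study(seed = config$seed)
      runs <- list(MUT = list(wt_refl = sim$wt_refl,
                              mut_refl = sim$mut_refl,
                              phase_model = sim$wt_model,
                              score_model = sim$wt_model,
                              hdx = sim$hdx_table, mut_state = "MUT"))
      truth <- sim$truth
    } else {
      wt_model <- read_model(config$wt_model)
      cell <- config$cell %||% wt_model$cell
      wt_refl <- read_reflections_csv(config$wt_reflections, cell = cell)
      hdx <- read_peptide_table(config$hdx_table)
      states <- config$mut_states %||%
        setdiff(unique(hdx$state), "WT")
      runs <- list()
      for (i in seq_along(config$mut_models)) {
        runs[[states[i]]] <- list(
          wt_refl = wt_refl,
          mut_refl = read_reflections_csv(config$mut_reflections[i],
                                          cell = cell),
          phase_model = wt_model,
          score_model = wt_model,
          mut_model = read_model(config$mut_models[i]),
          hdx = hdx, mut_state = states[i])
      }
      truth <- NULL
    }

    per_mutant <- list()
    for (nm in names(runs)) {
      r <- runs[[nm]]
      message("stage diffmap+hdx [", nm, "]")
      res <- analyze_study(r$wt_refl, r$mut_refl, r$phase_model,
                           r$score_model, r$hdx, mut_state = r$mut_state,
                           alpha = config$alpha,
                           iaddat_threshold = config$iaddat_threshold,
                           iaddat_radius = config$iaddat_radius,
                           iaddat_cutoff = config$iaddat_cutoff,
                           cap = config$cap,
                           hdx_timepoint = config$hdx_timepoint,
                           hdx_cutoff = config$hdx_cutoff,
                           d2o_fraction = config$d2o_fraction,
                           population = config$population)
      write_track_csv(res$iaddat_track,
                      file.path(config$out_dir, paste0("iaddat_", nm, ".csv")))
      write_track_csv(res$hdx_track,
                      file.path(config$out_dir, paste0("hdx_", nm, ".csv")))
      utils::write.csv(attr(res$differences, "woods"),
                       file.path(config$out_dir, paste0("woods_", nm, ".csv")),
                       row.names = FALSE)
      per_mutant[[nm]] <- res
      manifest$stages[[paste0("analysis_", nm)]] <- "ok"
    }

    message("stage network")
    pop <- Reduce(intersect, lapply(per_mutant, `[[`, "population"))
    sets <- unlist(lapply(per_mutant, function(r) {
      lapply(list(r$iaddat_set, r$hdx_set), restrict_to_population, pop)
    }), recursive = FALSE)
    network <- pool_sets(sets, label = "combined_network")
    summary <- list(population_size = length(pop),
                    network_size = length(network$members),
                    network = network$members,
                    thresholds = list(iaddat = config$iaddat_cutoff,
                                      hdx = config$hdx_cutoff),
                    sectors = list())
    for (i in seq_along(config$sectors)) {
      sec <- load_sector(config$sectors[i])
      sec <- restrict_to_population(sec, pop)
      ov <- hypergeometric_overlap(network, sec, pop)
      summary$sectors[[sec$label]] <-
        list(size = ov$n_y, intersection = ov$intersection,
             union = ov$union, jaccard = ov$jaccard, p_value = ov$p_value)
    }
    if (!is.null(truth)) {
      planted <- res_key("A", truth$planted_network)
      summary$truth_comparison <- list(
        planted_size = length(planted),
        jaccard_vs_planted = jaccard(network$members,
                                     intersect(planted, pop)))
    }
    jsonlite::write_json(summary,
                         file.path(config$out_dir, "network.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$stages$network <- "ok"
    manifest$network_summary <- summary
    manifest$status <- "ok"
    finish(manifest)
  }, error = function(e) {
    manifest$failed_stage <- names(manifest$stages)[length(manifest$stages)] %||% "setup"
    manifest$status <- "failed"
    manifest$error <- conditionMessage(e)
    finish(manifest)
    stop(e)
  })
  result
}
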