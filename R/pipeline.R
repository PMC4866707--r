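# Stage orchestration: reproducible runs with a config (R list or YAML), TSV
# outputs and a JSON manifest recording config hash, seed and input
# checksums. Stages are pure functions of (inputs, config, seed); reruns
# with identical config and seed give identical deterministic outputs.

pipeline_stages <- c("parse", "simulate", "geometry", "ss", "energy",
                     "phasespace", "helixcoil", "report")

#' Default pipeline configuration
#'
#' @param seed Integer seed for stochastic stages.
#' @param output_dir Directory for stage outputs and the manifest.
#' @return Nested configuration list; every entry may be overridden either
#'   in R or through a YAML file with the same structure.
#' @export
default_config <- function(seed = 1, output_dir = tempfile("fuzzytraj_run")) {
  list(
    seed = seed,
    output_dir = output_dir,
    input = NULL,  # list(pdb =, dcd =, frame_interval_ns =, run_lengths =)
    selections = NULL,  # list(pocket =, anchor_a =, anchor_b =, vec1 =, vec2 =)
    simulate = list(),  # overrides for synth_spec()
    geometry = list(d_in = 6.5, d_out = 8.5),
    ss = list(include_310 = FALSE, min_persistence = 0.5),
    energy = list(cutoff = 12, sample_interval_ns = NULL),
    phasespace = list(bin_widths = c(10, 1, 1), min_frac = 0.001,
                      neighborhood = TRUE),
    helixcoil = list(temperature = 300, nterm_acetyl = TRUE,
                     cterm_amide = TRUE, activity_table = NULL)
  )
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file mirroring the [default_config()] structure; given
#'   keys override the defaults.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file '%s' not found", path))
  user <- yaml::read_yaml(path)
  utils::modifyList(default_config(), user)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config[sort(names(config))], tmp)
  unname(tools::md5sum(tmp))
}

manifest_entry <- function(stage, config, outputs, inputs = character(0)) {
  list(stage = stage,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       seed = config$seed,
       config_hash = config_hash(config),
       package_version = as.character(utils::packageVersion("fuzzytraj")),
       inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
       outputs = as.list(outputs))
}

# fail-fast resolution of author-numbered selections before any trajectory
# is read
resolve_selections <- function(state, config) {
  if (is.null(config$selections)) return(state)
  nm <- build_numbering_map(state$topology)
  sel <- config$selections
  state$observables <- list(
    pocket_residue = resolve_label(nm, sel$pocket),
    anchor_a = resolve_label(nm, sel$anchor_a),
    anchor_b = resolve_label(nm, sel$anchor_b),
    coact_vec = resolve_label(nm, sel$vec1),
    peptide_vec = resolve_label(nm, sel$vec2)
  )
  state$numbering <- nm
  state
}

require_state <- function(state, field, needed_stage) {
  if (is.null(state[[field]])) {
    abort(sprintf("dependency error: run stage '%s' first", needed_stage))
  }
  state[[field]]
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (synthetic trajectory + ground truth), `parse` (read
#' PDB/DCD inputs and fail-fast-resolve selections), `geometry` (pocket
#' distances, occupancy states, helix angles), `ss` (secondary-structure
#' timeline and occupancies), `energy` (per-residue decomposition and
#' binding series), `phasespace` (3-D density and optional reference
#' placement), `helixcoil` (helicity of an activity panel plus regression),
#' `report` (write the JSON manifest).
#'
#' @param name Stage name.
#' @param config Configuration list (see [default_config()]) or a YAML path.
#' @param state State list returned by earlier stages (`NULL` to start).
#' @return Updated state; written file paths accumulate in
#'   `state$manifest`.
#' @export
run_stage <- function(name, config = default_config(), state = NULL) {
  if (is.character(config)) config <- read_config(config)
  if (!name %in% pipeline_stages) {
    abort(sprintf("unknown stage '%s' (stages: %s)", name,
                  paste(pipeline_stages, collapse = ", ")))
  }
  if (is.null(state)) state <- list(manifest = list())
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out_path <- function(f) file.path(config$output_dir, f)
  outputs <- character(0)
  inputs <- character(0)

  if (name == "simulate") {
    spec <- do.call(synth_spec, config$simulate)
    gen <- generate_trajectory(spec, seed = config$seed)
    state$topology <- gen$topology
    state$frames <- gen$frames
    state$truth <- gen$truth
    state$observables <- gen$observables
    write_pdb(gen$topology, frame_coords(gen$frames, 1),
              out_path("synthetic.pdb"))
    write_dcd(gen$frames, out_path("synthetic.dcd"))
    truth_tl <- tibble(
      frame = rep(seq_len(nrow(gen$truth$helix_state)),
                  ncol(gen$truth$helix_state)),
      peptide_position = rep(seq_len(ncol(gen$truth$helix_state)),
                             each = nrow(gen$truth$helix_state)),
      helical = as.vector(gen$truth$helix_state))
    readr::write_tsv(truth_tl, out_path("truth_helix.tsv"))
    readr::write_tsv(tibble(frame = seq_along(gen$truth$occupancy),
                            state = as.character(gen$truth$occupancy),
                            orientation_deg = gen$truth$orientation_deg),
                     out_path("truth_occupancy.tsv"))
    yaml::write_yaml(c(config$simulate, list(seed = config$seed)),
                     out_path("spec.yaml"))
    outputs <- c(outputs, out_path(c("synthetic.pdb", "synthetic.dcd",
                                     "truth_helix.tsv",
                                     "truth_occupancy.tsv", "spec.yaml")))
  } else if (name == "parse") {
    inp <- config$input
    if (is.null(inp$pdb)) abort("parse stage needs input$pdb")
    parsed <- read_pdb_models(inp$pdb)
    state$topology <- parsed$topology
    state$models <- parsed$models
    state <- resolve_selections(state, config)  # fail fast
    if (!is.null(inp$dcd)) {
      state$frames <- read_dcd(
        inp$dcd, parsed$topology,
        frame_interval_ns = inp$frame_interval_ns %||% 10,
        run_lengths = inp$run_lengths)
      inputs <- c(inp$pdb, inp$dcd)
    } else {
      state$frames <- frame_series(
        array(unlist(lapply(parsed$models, identity)),
              dim = c(length(parsed$models), parsed$topology$n_atoms, 3)),
        frame_interval_ns = inp$frame_interval_ns %||% 1,
        source = inp$pdb)
      state$frames$coords <- aperm(
        array(unlist(parsed$models),
              dim = c(parsed$topology$n_atoms, 3, length(parsed$models))),
        c(3, 1, 2))
      inputs <- inp$pdb
    }
  } else if (name == "geometry") {
    frames <- require_state(state, "frames", "simulate/parse")
    ob <- require_state(state, "observables", "simulate/parse")
    d_a <- pocket_distance_series(frames, state$topology, ob$pocket_residue,
                                  ob$anchor_a)
    d_b <- pocket_distance_series(frames, state$topology, ob$pocket_residue,
                                  ob$anchor_b)
    occ <- classify_occupancy(d_a, d_b, d_in = config$geometry$d_in,
                              d_out = config$geometry$d_out)
    ang <- helix_angle_series(frames, state$topology, ob$coact_vec,
                              ob$peptide_vec)
    state$distance_a <- d_a
    state$distance_b <- d_b
    state$occupancy <- occ
    state$angles <- ang
    readr::write_tsv(mutate(d_a, anchor = "A"), out_path("distance_a.tsv"))
    readr::write_tsv(mutate(d_b, anchor = "B"), out_path("distance_b.tsv"))
    readr::write_tsv(as_tibble(occ), out_path("occupancy_states.tsv"))
    readr::write_tsv(ang, out_path("helix_angles.tsv"))
    outputs <- out_path(c("distance_a.tsv", "distance_b.tsv",
                          "occupancy_states.tsv", "helix_angles.tsv"))
  } else if (name == "ss") {
    frames <- require_state(state, "frames", "simulate/parse")
    ob <- require_state(state, "observables", "simulate/parse")
    tl <- ss_timeline(frames, state$topology,
                      residues = ob$peptide_residues)
    occ_a <- helical_occupancy(tl, include_310 = FALSE)
    occ_ag <- helical_occupancy(tl, include_310 = TRUE)
    occ_tab <- left_join(rename(occ_a, occupancy_alpha = "occupancy"),
                         rename(occ_ag, occupancy_alpha_310 = "occupancy"),
                         by = "residue_index")
    bounds <- helix_boundaries(tl,
                               min_persistence = config$ss$min_persistence,
                               include_310 = config$ss$include_310)
    state$ss_timeline <- tl
    state$ss_occupancy <- occ_tab
    state$helix_bounds <- bounds
    readr::write_tsv(as_tibble(tl), out_path("ss_timeline.tsv"))
    readr::write_tsv(occ_tab, out_path("ss_occupancy.tsv"))
    readr::write_tsv(bounds, out_path("helix_boundaries.tsv"))
    outputs <- out_path(c("ss_timeline.tsv", "ss_occupancy.tsv",
                          "helix_boundaries.tsv"))
  } else if (name == "energy") {
    frames <- require_state(state, "frames", "simulate/parse")
    ob <- require_state(state, "observables", "simulate/parse")
    ptop <- assign_params(state$topology)
    decomp <- decomposition_matrix(
      frames, ptop, group_ad = ob$peptide_residues,
      group_coact = ob$coact_residues,
      sample_interval_ns = config$energy$sample_interval_ns,
      cutoff = config$energy$cutoff)
    bind <- binding_series(decomp)
    state$decomposition <- decomp
    state$binding <- bind
    readr::write_tsv(as_tibble(decomp), out_path("energy_decomposition.tsv"))
    readr::write_tsv(bind, out_path("binding_series.tsv"))
    outputs <- out_path(c("energy_decomposition.tsv", "binding_series.tsv"))
  } else if (name == "phasespace") {
    ang <- require_state(state, "angles", "geometry")
    pts <- phase_points(ang, state$distance_a, state$distance_b)
    dens <- phase_density(pts, bin_widths = config$phasespace$bin_widths)
    state$phase_points <- pts
    state$phase_density <- dens
    readr::write_tsv(pts, out_path("phase_points.tsv"))
    outputs <- out_path("phase_points.tsv")
    if (!is.null(state$reference_points)) {
      placement <- populated_fraction(
        dens, state$reference_points,
        min_frac = config$phasespace$min_frac,
        neighborhood = config$phasespace$neighborhood)
      sweep_tab <- populated_fraction_sweep(
        dens, state$reference_points,
        neighborhood = config$phasespace$neighborhood)
      state$reference_placement <- placement
      readr::write_tsv(placement$placements,
                       out_path("reference_placement.tsv"))
      readr::write_tsv(sweep_tab, out_path("min_frac_sensitivity.tsv"))
      outputs <- c(outputs, out_path(c("reference_placement.tsv",
                                       "min_frac_sensitivity.tsv")))
    }
  } else if (name == "helixcoil") {
    hc <- config$helixcoil
    params <- lr_params(temperature = hc$temperature,
                        nterm_acetyl = hc$nterm_acetyl,
                        cterm_amide = hc$cterm_amide)
    tab <- if (is.null(hc$activity_table)) load_activity_table() else
      load_activity_table(hc$activity_table)
    tab$helicity <- vapply(tab$sequence,
                           function(s) mean_helicity(helicity(s, params)),
                           numeric(1))
    state$activity <- tab
    readr::write_tsv(as_tibble(tab), out_path("variant_helicity.tsv"))
    outputs <- out_path("variant_helicity.tsv")
    if (nrow(tab) >= 3 && sd(tab$helicity) > 1e-12) {
      fit <- correlate_activity(tab)
      state$activity_fit <- fit
      readr::write_tsv(tidy(fit), out_path("regression_terms.tsv"))
      readr::write_tsv(fit$data, out_path("regression_data.tsv"))
      outputs <- c(outputs, out_path(c("regression_terms.tsv",
                                       "regression_data.tsv")))
    }
  } else if (name == "report") {
    manifest_file <- out_path("manifest.json")
    state$manifest[[length(state$manifest) + 1]] <-
      manifest_entry("report", config, manifest_file)
    jsonlite::write_json(state$manifest, manifest_file, auto_unbox = TRUE,
                         pretty = TRUE)
    return(state)
  }

  state$manifest[[length(state$manifest) + 1]] <-
    manifest_entry(name, config, outputs, inputs)
  state
}

#' Run the full pipeline
#'
#' Executes the stages in order. With no external `input` configured the
#' run starts from the synthetic generator (`simulate`); with `input$pdb`
#' (and optionally `input$dcd`) it starts from `parse`.
#'
#' @param config Configuration list or YAML path; see [default_config()].
#' @param stages Stage subset to run, in order.
#' @return Final state list (see [run_stage()]).
#' @export
run_pipeline <- function(config = default_config(), stages = NULL) {
  if (is.character(config)) config <- read_config(config)
  if (is.null(stages)) {
    first <- if (is.null(config$input)) "simulate" else "parse"
    stages <- c(first, "geometry", "ss", "energy", "phasespace",
                "helixcoil", "report")
  }
  state <- NULL
  for (s in stages) state <- run_stage(s, config, state)
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a
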