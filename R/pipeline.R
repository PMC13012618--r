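# Config-driven orchestration: validate a YAML/list configuration, run the
# requested stages in order, and record a deterministic manifest (config
# echo, package version, output hashes). Wall-clock timings go to a
# separate log file so that re-running an identical configuration
# reproduces the manifest byte for byte.

.known_stages <- c("synth", "network", "paths", "communities",
                   "orderparams", "pca", "contacts", "wham", "report")

.pipeline_defaults <- list(
  network = list(cutoff_nm = 0.45, persistence = 0.75, k_neighbours = 7),
  paths = list(n_suboptimal = 20),
  communities = list(seed = 0, discard_below = 0.01),
  contacts = list(threshold_pp = 40),
  wham = list(n_bins = 100, tolerance_kT = 1e-8,
              n_boot = 0)
)

#' Validate a pipeline configuration
#'
#' Checks stage names, parameter ranges and cross-stage dependencies, and
#' fills defaults. Validation never throws; failures are collected in the
#' report.
#'
#' @param config a list (e.g. from [yaml::read_yaml()]) or a path to a
#'   YAML file
#' @return list with `ok` (logical), `failures` (character vector) and
#'   `config` (defaults filled in)
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  failures <- character(0)
  fail <- function(msg) failures <<- c(failures, msg)
  if (is.null(config$stages) || !length(config$stages)) {
    fail("no stages given")
    config$stages <- character(0)
  }
  unknown <- setdiff(config$stages, .known_stages)
  for (u in unknown) fail(paste0("unknown stage name '", u, "'"))
  if (is.null(config$seed)) fail("seed is required")
  for (st in names(.pipeline_defaults)) {
    for (key in names(.pipeline_defaults[[st]])) {
      if (is.null(config[[st]][[key]]))
        config[[st]][[key]] <- .pipeline_defaults[[st]][[key]]
    }
  }
  pe <- config$network$persistence
  if (!is.numeric(pe) || pe <= 0 || pe > 1)
    fail("network persistence must be in (0, 1]")
  if (config$network$cutoff_nm <= 0)
    fail("network cutoff_nm must be positive")
  if (config$contacts$threshold_pp < 0 ||
      config$contacts$threshold_pp > 100)
    fail("contacts threshold_pp must be in [0, 100]")
  if (config$wham$n_bins < 2) fail("wham n_bins must be at least 2")
  needs_ensemble <- intersect(config$stages,
                              c("network", "orderparams", "pca",
                                "contacts"))
  if (length(needs_ensemble) && !"synth" %in% config$stages &&
      is.null(config$input$topology))
    fail("stages need an ensemble: add a synth stage or an input topology")
  if ("paths" %in% config$stages) {
    if (!"network" %in% config$stages)
      fail("paths stage requires the network stage")
    synth_kind <- config$synth$kind %||% "planted_network"
    if (is.null(config$paths$source) && synth_kind != "planted_network")
      fail("paths stage needs a source selection")
    if (is.null(config$paths$sink) && synth_kind != "planted_network")
      fail("paths stage needs a sink selection")
  }
  if ("communities" %in% config$stages && !"network" %in% config$stages)
    fail("communities stage requires the network stage")
  if ("wham" %in% config$stages && !"synth" %in% config$stages &&
      is.null(config$input$umbrella_dir))
    fail("wham stage needs umbrella input or a synth stage")
  list(ok = length(failures) == 0, failures = failures, config = config)
}

#' Run the analysis pipeline described by a configuration
#'
#' Stages execute in dependency order on the objects produced by earlier
#' stages; every stage writes its outputs under the output directory and
#' the run ends with a deterministic `manifest.json` (config snapshot,
#' package version, md5 per output). All randomness flows from the config
#' seeds.
#'
#' @param config list or YAML path (see [validate_config()])
#' @param output_dir overrides `config$output_dir`
#' @return the manifest, invisibly
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  v <- validate_config(config)
  if (!v$ok) stop("configuration invalid:\n  ",
                  paste(v$failures, collapse = "\n  "))
  cfg <- v$config
  out <- output_dir %||% cfg$output_dir %||% "allonet_out"
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  t_start <- proc.time()[3]
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))

  state <- new.env(parent = emptyenv())
  outputs <- character(0)
  emit <- function(name) outputs <<- c(outputs, name)

  for (stage in cfg$stages) {
    note(sprintf("stage %s", stage))
    switch(stage,
      synth = {
        sy <- cfg$synth %||% list(kind = "planted_network")
        kind <- sy$kind %||% "planted_network"
        if (kind == "planted_network") {
          g <- make_planted_network_ensemble(
            n_residues = sy$n_residues %||% 30,
            n_intermediates = sy$n_intermediates %||% 4,
            rho = sy$rho %||% 0.8, rho_bg = sy$rho_bg %||% 0.05,
            sigma = sy$sigma %||% 0.03,
            n_frames = sy$n_frames %||% 5000, seed = cfg$seed)
        } else if (kind == "planted_partition") {
          g <- make_planted_partition_ensemble(
            block_sizes = unlist(sy$block_sizes) %||% c(10, 10),
            rho_within = sy$rho_within %||% 0.6,
            sigma = sy$sigma %||% 0.03,
            n_frames = sy$n_frames %||% 3000, seed = cfg$seed)
        } else if (kind == "umbrella") {
          pot <- sy$potential %||% list(kind = "harmonic", kappa = 100,
                                        xi0 = 0.6)
          g <- make_umbrella_dataset(
            potential = pot,
            windows = unlist(sy$windows) %||%
              seq(0.3, 1.2, length.out = 10),
            k = sy$spring_k %||% 1500, n = sy$n_per_window %||% 5000,
            temperature = sy$temperature %||% 310, seed = cfg$seed)
          state$umbrella <- g$dataset
          state$truth <- g$truth
          write_umbrella_dataset(g$dataset, file.path(out, "umbrella"))
          emit(file.path("umbrella", "windows.tsv"))
        } else stop("unknown synth kind '", kind, "'")
        if (kind != "umbrella") {
          state$topology <- g$topology
          state$ensemble <- g$ensemble
          state$truth <- g$truth
          write_structure(
            frame_ensemble(g$topology, get_frame(g$ensemble, 1)),
            file.path(out, "topology.gro"))
          write_trajectory(g$ensemble, file.path(out, "ensemble.dcd"))
          emit("topology.gro"); emit("ensemble.dcd")
        }
        truth_json <- file.path(out, "ground_truth.json")
        jsonlite::write_json(
          list(planted_path = state$truth$planted_path,
               planted_partition = state$truth$planted_partition,
               analytic_pmf = state$truth$analytic_pmf,
               scripted_contacts = state$truth$scripted_contacts),
          truth_json, auto_unbox = TRUE, digits = NA, pretty = TRUE,
          null = "null")
        emit("ground_truth.json")
      },
      network = {
        nodes <- assign_nodes(state$topology,
                              select_atoms(state$topology, "all"))
        state$nodes <- nodes
        state$network <- network_from_ensemble(
          state$ensemble, nodes,
          cutoff = cfg$network$cutoff_nm,
          persistence = cfg$network$persistence,
          k = cfg$network$k_neighbours)
        write_network(state$network, file.path(out, "network.tsv"))
        emit("network.tsv")
      },
      paths = {
        src <- cfg$paths$source %||% state$truth$planted_path[1]
        snk <- cfg$paths$sink %||%
          state$truth$planted_path[length(state$truth$planted_path)]
        ps <- suboptimal_paths(state$network, src, snk,
                               cfg$paths$n_suboptimal)
        state$paths <- ps
        write_path_set(ps, state$network, file.path(out, "paths.json"))
        emit("paths.json")
      },
      communities = {
        cm <- detect_communities(state$network,
                                 seed = cfg$communities$seed,
                                 discard_below =
                                   cfg$communities$discard_below)
        state$communities <- cm
        bc <- community_betweenness(state$network, cm)
        jsonlite::write_json(list(
          membership = as.list(cm$membership),
          discarded = cm$discarded,
          community_matrix = bc$community_matrix,
          node_betweenness = as.list(round(bc$node_betweenness, 12))),
          file.path(out, "communities.json"), auto_unbox = TRUE,
          digits = NA, pretty = TRUE, null = "null")
        emit("communities.json")
      },
      wham = {
        ds <- state$umbrella %||%
          read_umbrella_dataset(cfg$input$umbrella_dir)
        prof <- wham(ds, n_bins = cfg$wham$n_bins,
                     tolerance = cfg$wham$tolerance_kT)
        if ((cfg$wham$n_boot %||% 0) >= 2) {
          bt <- bootstrap_error(ds, n_bins = cfg$wham$n_bins,
                                n_boot = cfg$wham$n_boot,
                                seed = cfg$seed)
          prof <- bt$profile
        }
        state$profile <- prof
        write_profile(prof, file.path(out, "profile.tsv"))
        emit("profile.tsv")
      },
      report = {
        rep <- list(package_version =
                      as.character(utils::packageVersion("allonet")))
        if (!is.null(state$paths) && !is.null(state$truth$planted_path)) {
          opt_labels <- vapply(state$network$nodes, `[[`, character(1),
                               "label")[state$paths$paths[[1]]]
          rep$optimal_path <- opt_labels
          rep$planted_path <- as.character(state$truth$planted_path)
          rep$path_recovered <- identical(
            sort(opt_labels), sort(as.character(state$truth$planted_path)))
        }
        if (!is.null(state$communities))
          rep$n_communities <- length(state$communities$sizes)
        jsonlite::write_json(rep, file.path(out, "report.json"),
                             auto_unbox = TRUE, digits = NA,
                             pretty = TRUE)
        emit("report.json")
      },
      stop("stage '", stage, "' is not runnable in this configuration")
    )
  }
  hashes <- as.list(tools::md5sum(file.path(out, outputs)))
  names(hashes) <- outputs
  manifest <- list(
    package_version = as.character(utils::packageVersion("allonet")),
    config = cfg,
    outputs = hashes)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  note(sprintf("total wall time %.2f s", proc.time()[3] - t_start))
  writeLines(log_lines, file.path(out, "run.log"))
  invisible(manifest)
}
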