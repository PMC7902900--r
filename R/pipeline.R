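#' Build a pipeline configuration
#'
#' A declarative description of a full analysis run: where the input
#' trajectory comes from (files or a synthetic block), which stages to run,
#' and every stage parameter (all defaulted as documented in the individual
#' functions).  Configurations serialize losslessly to JSON with
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param input Either `list(mode = "files", topology = <pdb>, trajectory =
#'   <pdb|dcd>, parameters = <table or NULL>)` or `list(mode = "synthetic",
#'   generator = "correlated"|"contact", args = list(...))` where `args` are
#'   forwarded to the generator ([sample_correlated_trajectory()] /
#'   [sample_contact_schedule()]) on a default toy system of
#'   `args$n_residues` residues.
#' @param stages Character vector out of `"geometry"`, `"landscape"`,
#'   `"clustering"`, `"energetics"`, `"network"`.
#' @param geometry,landscape,clustering,energetics,network Per-stage
#'   parameter lists; unset entries take the documented defaults.
#' @param seed Global integer seed; per-stage seeds are derived by fixed
#'   offsets so toggling one stage never changes another's randomness.
#' @param outdir Output directory.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input, stages = c("geometry"), geometry = list(),
                            landscape = list(), clustering = list(),
                            energetics = list(), network = list(),
                            seed = 1L, outdir = tempfile("trajan_run_")) {
  known <- c("geometry", "landscape", "clustering", "energetics", "network")
  bad <- setdiff(stages, known)
  if (length(bad)) abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  if (!is.list(input) || is.null(input$mode)) {
    abort("input must be a list with a 'mode' field")
  }
  structure(list(input = input, stages = stages, geometry = geometry,
                 landscape = landscape, clustering = clustering,
                 energetics = energetics, network = network,
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, x)
}

resolve_input <- function(input, seed) {
  if (input$mode == "files") {
    for (p in c(input$topology, input$trajectory, input$parameters)) {
      if (!is.null(p) && !file.exists(p)) {
        abort(paste0("input file not found: ", p))
      }
    }
    top <- read_pdb_trajectory(input$topology)$topology
    traj <- read_trajectory(input$trajectory, topology = top)
    if (!is.null(input$parameters)) {
      traj$topology <- set_parameters(traj$topology,
                                      read_parameter_table(input$parameters))
    }
    traj
  } else if (input$mode == "synthetic") {
    args <- input$args
    nres <- if (is.null(args$n_residues)) 20 else args$n_residues
    sys <- build_toy_system(synthetic_spec(
      n_residues = nres,
      charges = if (is.null(args$charges)) 0 else args$charges,
      seed = seed))
    if (identical(input$generator, "correlated")) {
      sigma2 <- if (is.null(args$sigma2)) 0.25 else args$sigma2
      rho <- if (is.null(args$rho)) 0.5 else args$rho
      cov <- sigma2 * (rho ^ abs(outer(seq_len(nres), seq_len(nres), `-`)))
      nf <- if (is.null(args$n_frames)) 2000 else args$n_frames
      sample_correlated_trajectory(sys, cov, nf, seed = seed)$trajectory
    } else if (identical(input$generator, "contact")) {
      pf <- as_tibble(args$pair_fractions)
      nf <- if (is.null(args$n_frames)) 1000 else args$n_frames
      sample_contact_schedule(sys, pf,
                              contact_distance = args$contact_distance,
                              apart_distance = args$apart_distance,
                              n_frames = nf, seed = seed)$trajectory
    } else {
      abort(paste0("unknown synthetic generator: ", input$generator))
    }
  } else {
    abort(paste0("unknown input mode: ", input$mode))
  }
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

#' Run a configured analysis pipeline
#'
#' Resolves the input (all files are checked before any computation),
#' executes the enabled stages in a fixed order, writes each stage's tables
#' under `config$outdir`, and returns (and writes) a machine-readable
#' summary listing every artifact with its stage provenance.  Outputs are
#' deterministic under a fixed seed; a failing stage aborts with a
#' stage-named error, leaving earlier outputs intact.
#'
#' @param config A [pipeline_config()].
#' @return The summary list, invisibly; artifacts on disk under
#'   `config$outdir`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) abort("config must be a pipeline_config")
  traj <- resolve_input(config$input, config$seed)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- list()
  note <- function(stage, file, what) {
    artifacts[[length(artifacts) + 1]] <<- list(stage = stage, file = basename(file),
                                                what = what)
  }
  stage_seed <- function(stage) {
    config$seed + match(stage, c("geometry", "landscape", "clustering",
                                 "energetics", "network")) * 1000L
  }
  run_stage <- function(stage, fn) {
    set.seed(stage_seed(stage))
    tryCatch(fn(), error = function(e) {
      abort(paste0("stage '", stage, "' failed: ", conditionMessage(e)))
    })
  }

  if ("geometry" %in% config$stages) {
    run_stage("geometry", function() {
      p <- config$geometry
      sel <- select_atoms(traj, name = "CA")
      aligned <- superpose(traj, selection = sel)
      f <- write_tsv(frame_rmsd(aligned), file.path(config$outdir, "rmsd.tsv"))
      note("geometry", f, "per-frame RMSD after superposition")
      if (n_frames(traj) >= 2) {
        f <- write_tsv(rmsf(aligned, sel), file.path(config$outdir, "rmsf.tsv"))
        note("geometry", f, "per-atom RMSF")
      }
      if (!is.null(p$distances)) {
        gs <- geometry_series(traj, distances = do.call(rbind, p$distances))
        f <- write_tsv(gs, file.path(config$outdir, "geometry_series.tsv"))
        note("geometry", f, "per-frame distances")
        bw <- if (is.null(p$bin_width)) 0.1 else p$bin_width
        f <- write_tsv(geometry_histogram(gs, bw),
                       file.path(config$outdir, "geometry_hist.tsv"))
        note("geometry", f, "distance histograms")
      }
    })
  }
  if ("landscape" %in% config$stages) {
    run_stage("landscape", function() {
      p <- config$landscape
      if (is.null(p$cv_atoms) || length(p$cv_atoms) < 2) {
        abort("landscape stage needs cv_atoms = list(c(i, j), c(k, l))")
      }
      gs <- geometry_series(traj, distances = do.call(rbind, p$cv_atoms))
      labs <- unique(gs$label)
      cv1 <- gs$value[gs$label == labs[1]]
      cv2 <- gs$value[gs$label == labs[2]]
      bins <- if (is.null(p$bins)) 50 else p$bins
      temp <- if (is.null(p$temperature)) 300 else p$temperature
      grid <- pmf_2d(cv1, cv2, bins = bins, temperature = temp)
      cutoff <- if (is.null(p$depth_cutoff)) 1.0 else p$depth_cutoff
      grid <- segment_basins(grid, cutoff)
      f <- write_tsv(tidy(grid), file.path(config$outdir, "pmf_grid.tsv"))
      note("landscape", f, "2D free-energy grid with basin labels")
      f <- write_tsv(grid$frame_basins, file.path(config$outdir, "frame_basins.tsv"))
      note("landscape", f, "per-frame basin assignment")
    })
  }
  if ("clustering" %in% config$stages) {
    run_stage("clustering", function() {
      p <- config$clustering
      k <- if (is.null(p$n_clusters)) 2 else p$n_clusters
      sel <- select_atoms(traj, name = "CA")
      ca <- cluster_average_linkage(traj, sel, n_clusters = k)
      f <- write_tsv(ca$assignments, file.path(config$outdir, "clusters.tsv"))
      note("clustering", f, "per-frame cluster labels")
      f <- write_tsv(ca$medoids, file.path(config$outdir, "medoids.tsv"))
      note("clustering", f, "representative (medoid) frames")
    })
  }
  if ("energetics" %in% config$stages) {
    run_stage("energetics", function() {
      p <- config$energetics
      if (is.null(p$receptor) || is.null(p$ligand)) {
        abort("energetics stage needs receptor and ligand atom selections")
      }
      grid <- do.call(pb_grid_spec, if (is.null(p$grid)) list() else p$grid)
      stride <- if (is.null(p$frame_stride)) 10 else p$frame_stride
      include_pb <- !isFALSE(p$include_pb)
      rep <- mmpbsa_binding(traj, unlist(p$receptor), unlist(p$ligand),
                            grid = grid, frame_stride = stride,
                            include_pb = include_pb)
      f <- write_tsv(rep$summary, file.path(config$outdir, "binding_summary.tsv"))
      note("energetics", f, "MM/PBSA component means and sds")
      f <- write_tsv(rep$frames, file.path(config$outdir, "binding_frames.tsv"))
      note("energetics", f, "per-frame MM/PBSA components")
      dec <- per_residue_decomposition(traj, unlist(p$receptor), unlist(p$ligand),
                                       grid = grid, frame_stride = stride,
                                       include_pb = include_pb)
      f <- write_tsv(dec, file.path(config$outdir, "residue_decomposition.tsv"))
      note("energetics", f, "per-residue energy contributions")
    })
  }
  if ("network" %in% config$stages) {
    run_stage("network", function() {
      p <- config$network
      sel <- select_atoms(traj, name = "CA")
      aligned <- superpose(traj, selection = sel)
      C <- dccm(aligned, sel)
      cutoff <- if (is.null(p$contact_cutoff)) 4.5 else p$contact_cutoff
      pers <- if (is.null(p$persistence)) 0.75 else p$persistence
      net <- build_network(traj, C, contact_cutoff = cutoff, persistence = pers)
      f <- file.path(config$outdir, "dccm.tsv")
      utils::write.table(unclass(C), f, sep = "\t", row.names = FALSE,
                         col.names = FALSE)
      note("network", f, "dynamic cross-correlation matrix")
      f <- write_tsv(net$edges, file.path(config$outdir, "network_edges.tsv"))
      note("network", f, "persistence-gated edge list")
      if (nrow(net$edges)) {
        com <- detect_communities(net)
        f <- write_tsv(com$membership, file.path(config$outdir, "communities.tsv"))
        note("network", f, "community membership")
        if (!is.null(p$source) && !is.null(p$sink)) {
          tol <- if (is.null(p$tolerance)) 20 else p$tolerance
          ps <- optimal_paths(net, p$source, p$sink, tolerance = tol)
          f <- write_tsv(tidy(ps), file.path(config$outdir, "paths.tsv"))
          note("network", f, "optimal and suboptimal paths")
        }
      }
    })
  }

  summary <- list(seed = config$seed, stages = config$stages,
                  n_frames = n_frames(traj), n_atoms = n_atoms(traj),
                  artifacts = artifacts)
  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
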