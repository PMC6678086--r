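# Config-driven orchestration: simulate synthetic ensembles, analyze
# trajectory sets into distance / orientation / RMSD / RMSF products,
# and compare scalar series between bound and free states. All outputs
# are plain CSV/JSON with a provenance block (config hash, package
# version, seeds); the analysis path contains no randomness, so rerunning
# on identical inputs reproduces identical files.

#' Read and validate an analysis configuration
#'
#' YAML (or JSON) with fields: `reference` (PDB path), `domains` (list of
#' `{name, chain, intervals, atoms}`), `pairs` (list of 2-element domain
#' name lists), `states` (named lists, each run `{run, files}`),
#' optional `fit_selection` (domain name or `"all_ca"`, default),
#' `stride_ns` (analysis stride, default 0.2), `dt_ns` (frame spacing of
#' the input files, default 0.04). Relative paths are resolved against
#' the config file's directory. Validation happens before any
#' trajectory I/O.
#'
#' @param path Path to a YAML or JSON config file.
#' @return A validated config list (class `analysis_config`).
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  cfg$.dir <- dirname(normalizePath(path))
  cfg$.hash <- unname(tools::md5sum(path))
  validate_analysis_config(cfg)
}

validate_analysis_config <- function(cfg) {
  for (f in c("reference", "domains", "pairs", "states"))
    if (is.null(cfg[[f]])) stop("config: missing field '", f, "'")
  if (is.null(cfg$stride_ns)) cfg$stride_ns <- 0.2
  if (is.null(cfg$dt_ns)) cfg$dt_ns <- 0.04
  if (cfg$stride_ns <= 0) stop("config: stride_ns must be > 0")
  if (is.null(cfg$fit_selection)) cfg$fit_selection <- "all_ca"
  specs <- lapply(cfg$domains, function(d) {
    if (is.null(d$name) || is.null(d$chain) || is.null(d$intervals))
      stop("config: each domain needs 'name', 'chain', 'intervals'")
    domain_spec(d$name, as.character(d$chain),
                lapply(d$intervals, unlist),
                atom_filter = if (is.null(d$atoms)) "CA"
                              else unlist(d$atoms))
  })
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(names(specs)))
    stop("config: duplicate domain names")
  cfg$.specs <- specs
  for (p in cfg$pairs) {
    p <- unlist(p)
    if (length(p) != 2L)
      stop("config: each pair must name exactly two domains")
    bad <- setdiff(p, names(specs))
    if (length(bad))
      stop("config: pair references undefined domain '", bad[1], "'")
  }
  if (cfg$fit_selection != "all_ca" &&
      !cfg$fit_selection %in% names(specs))
    stop("config: fit_selection '", cfg$fit_selection,
         "' is not a defined domain")
  if (length(cfg$states) == 0L) stop("config: no states defined")
  for (s in names(cfg$states)) {
    runs <- cfg$states[[s]]
    if (length(runs) == 0L) stop("config: state '", s, "' has no runs")
    for (r in runs)
      if (is.null(r$run) || is.null(r$files))
        stop("config: every run in state '", s,
             "' needs 'run' and 'files'")
  }
  class(cfg) <- c("analysis_config", "list")
  cfg
}

cfg_path <- function(cfg, p) {
  if (is.null(cfg$.dir) || grepl("^(/|[A-Za-z]:)", p)) p
  else file.path(cfg$.dir, p)
}

#' Run the full analysis pipeline
#'
#' For every configured run: read the multi-model PDB trajectory, thin it
#' to the analysis stride, remove global motion by superposing each frame
#' onto the reference structure via the fit selection, then compute (i)
#' inter-domain distance series and (ii) orientation-angle series for
#' every configured domain pair (local frames standardized against the
#' crystal reference), and (iii) per-domain RMSD series (first analysis
#' frame as reference, domain-local fit) and RMSF profiles. Pooled
#' per-state samples of every scalar are then compared between the first
#' two states via [compare_states()].
#'
#' @param cfg An `analysis_config` (from [read_analysis_config()]).
#' @param out_dir Output directory for CSV/JSON products (created).
#' @return A `report_bundle` list (also serialized to `out_dir`).
#' @export
run_analysis <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "analysis_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- read_structure(cfg_path(cfg, cfg$reference))
  specs <- cfg$.specs
  sel <- lapply(specs, function(sp) select_domain(ref$topology, sp))
  fit_idx <- if (cfg$fit_selection == "all_ca")
    which(toupper(ref$topology$atoms$atom_name) == "CA")
  else sel[[cfg$fit_selection]]
  every <- max(1L, as.integer(round(cfg$stride_ns / cfg$dt_ns)))
  pairs <- lapply(cfg$pairs, unlist)

  dist_rows <- list(); angle_rows <- list(); rmsd_rows <- list()
  rmsf_rows <- list()
  for (state in names(cfg$states)) {
    for (run in cfg$states[[state]]) {
      files <- vapply(unlist(run$files), function(p) cfg_path(cfg, p),
                      character(1))
      traj <- read_trajectory(files, ref$topology, dt_ns = cfg$dt_ns)
      traj <- thin_trajectory(traj, every)
      traj <- remove_global_motion(traj, fit_idx, ref$coords)
      fs <- lapply(specs, function(sp) frame_series(traj, sp, ref$coords))
      for (p in pairs) {
        ds <- interdomain_distance_series(traj, specs[[p[1]]],
                                          specs[[p[2]]])
        os <- orientation_series(fs[[p[1]]], fs[[p[2]]])
        tag <- data.frame(pair = paste(p, collapse = "-"),
                          run_id = run$run, state = state)
        dist_rows[[length(dist_rows) + 1L]] <-
          cbind(as.data.frame(ds), tag)
        angle_rows[[length(angle_rows) + 1L]] <-
          cbind(as.data.frame(os), tag)
      }
      for (dn in names(specs)) {
        rs <- rmsd_series(traj, specs[[dn]])
        rmsd_rows[[length(rmsd_rows) + 1L]] <-
          cbind(as.data.frame(rs),
                data.frame(domain = dn, run_id = run$run, state = state))
        rp <- rmsf_profile(traj, specs[[dn]])
        rmsf_rows[[length(rmsf_rows) + 1L]] <-
          cbind(as.data.frame(rp),
                data.frame(domain = dn, run_id = run$run, state = state))
      }
    }
  }
  distances <- do.call(rbind, dist_rows)
  angles <- do.call(rbind, angle_rows)
  rmsd <- do.call(rbind, rmsd_rows)
  rmsf <- do.call(rbind, rmsf_rows)

  states <- names(cfg$states)
  comparisons <- list()
  if (length(states) >= 2L) {
    s1 <- states[1]; s2 <- states[2]
    # convention: the state literally named "bound" is the bound sample;
    # otherwise the second state plays that role
    bound_state <- if ("bound" %in% states) "bound" else s2
    free_state <- setdiff(c(s1, s2), bound_state)[1]
    for (p in pairs) {
      pname <- paste(p, collapse = "-")
      block <- list()
      for (ch in c("alpha_deg", "beta_deg", "gamma_deg")) {
        fv <- angles[[ch]][angles$pair == pname & angles$state == free_state]
        bv <- angles[[ch]][angles$pair == pname & angles$state == bound_state]
        block[[ch]] <- comparison_to_list(compare_states(fv, bv))
      }
      fv <- distances$distance_nm[distances$pair == pname &
                                    distances$state == free_state]
      bv <- distances$distance_nm[distances$pair == pname &
                                    distances$state == bound_state]
      block$distance_nm <- comparison_to_list(compare_states(fv, bv))
      comparisons[[pname]] <- block
    }
    rmsd_cmp <- list()
    for (dn in names(specs)) {
      fv <- rmsd$rmsd_nm[rmsd$domain == dn & rmsd$state == free_state]
      bv <- rmsd$rmsd_nm[rmsd$domain == dn & rmsd$state == bound_state]
      rmsd_cmp[[dn]] <- comparison_to_list(compare_states(fv, bv))
    }
    comparisons$rmsd <- rmsd_cmp
  }
  rmsd_summary <- summarize_runs(
    split(rmsd$rmsd_nm, paste(rmsd$run_id, rmsd$domain, sep = ":")),
    vapply(split(rmsd$state, paste(rmsd$run_id, rmsd$domain, sep = ":")),
           `[`, character(1), 1L))

  provenance <- list(config_hash = cfg$.hash,
                     package = "domainmotion",
                     version = as.character(utils::packageVersion("domainmotion")),
                     r_version = R.version.string,
                     stride_ns = cfg$stride_ns,
                     generated = "deterministic (no RNG in analysis path)")
  bundle <- structure(list(distances = distances, angles = angles,
                           rmsd = rmsd, rmsf = rmsf,
                           comparisons = comparisons,
                           rmsd_summary = rmsd_summary,
                           provenance = provenance),
                      class = "report_bundle")
  write_csv_det(distances, file.path(out_dir, "distance_series.csv"))
  write_csv_det(angles, file.path(out_dir, "orientation_series.csv"))
  write_csv_det(rmsd, file.path(out_dir, "rmsd_series.csv"))
  write_csv_det(rmsf, file.path(out_dir, "rmsf_profile.csv"))
  write_csv_det(rmsd_summary$runs, file.path(out_dir, "rmsd_run_summary.csv"))
  jsonlite::write_json(list(comparisons = comparisons,
                            provenance = provenance),
                       file.path(out_dir, "comparisons.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(bundle)
}

comparison_to_list <- function(cmp) {
  list(mean_free = cmp$mean_free, sd_free = cmp$sd_free,
       mean_bound = cmp$mean_bound, sd_bound = cmp$sd_bound,
       ks_D = cmp$ks$D, n_free = cmp$ks$n1, n_bound = cmp$ks$n2)
}

write_csv_det <- function(df, path) {
  utils::write.csv(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
}

#' Simulate a bound + free synthetic ensemble to disk
#'
#' Generates `n_runs` bound-like and `n_runs` free-like runs (see
#' [make_state_ensemble()]), writes each as a multi-model PDB plus a
#' ground-truth CSV, a shared reference PDB, and a JSON manifest with
#' per-file MD5 hashes, frame counts and seeds.
#'
#' @param out_dir Output directory (created).
#' @param n_runs Runs per state (default 10, the study design).
#' @param base_spec A `motion_spec` for the shared parameters.
#' @param master_seed Integer master seed.
#' @return Path to the manifest JSON, invisibly.
#' @export
run_simulation <- function(out_dir, n_runs = 10L,
                           base_spec = motion_spec(),
                           master_seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(master_seed = master_seed, n_runs = n_runs,
                   duration_ns = base_spec$duration,
                   output_interval_ns = base_spec$output_interval,
                   files = list())
  ref_written <- FALSE
  for (state in c("bound", "free")) {
    runs <- make_state_ensemble(state, n_runs, base_spec, master_seed)
    for (i in seq_along(runs)) {
      run <- runs[[i]]
      base <- sprintf("%s_run%02d", state, i)
      traj_path <- file.path(out_dir, paste0(base, ".pdb"))
      gt_path <- file.path(out_dir, paste0(base, "_truth.csv"))
      write_trajectory(run$trajectory, traj_path)
      write_csv_det(run$ground_truth, gt_path)
      if (!ref_written) {
        write_structure(run$trajectory$topology, run$reference,
                        file.path(out_dir, "reference.pdb"))
        ref_written <- TRUE
      }
      manifest$files[[base]] <- list(
        trajectory = basename(traj_path),
        ground_truth = basename(gt_path),
        state = state, run_id = base, seed = run$spec$seed,
        n_frames = n_frames(run$trajectory),
        md5 = unname(tools::md5sum(traj_path)))
    }
  }
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest_path)
}

#' Build the analysis config matching a [run_simulation()] output
#'
#' Writes a YAML analysis config next to the simulated files so that
#' `run_simulation()` output can be fed straight into [run_analysis()].
#'
#' @param sim_dir Directory produced by [run_simulation()].
#' @param base_spec The `motion_spec` used for the simulation.
#' @param stride_ns Analysis stride (default 0.2 ns).
#' @return Path to the written config, invisibly.
#' @export
write_simulation_config <- function(sim_dir, base_spec = motion_spec(),
                                    stride_ns = 0.2) {
  manifest <- jsonlite::fromJSON(file.path(sim_dir, "manifest.json"),
                                 simplifyVector = FALSE)
  states <- list(free = list(), bound = list())
  for (f in manifest$files) {
    states[[f$state]][[length(states[[f$state]]) + 1L]] <-
      list(run = f$run_id, files = list(f$trajectory))
  }
  cfg <- list(
    reference = "reference.pdb",
    dt_ns = base_spec$output_interval,
    stride_ns = stride_ns,
    domains = list(
      list(name = "domA", chain = "A",
           intervals = list(c(1L, base_spec$n_atoms[1]))),
      list(name = "domB", chain = "B",
           intervals = list(c(1L, base_spec$n_atoms[2])))),
    pairs = list(c("domA", "domB")),
    states = states)
  path <- file.path(sim_dir, "analysis_config.yaml")
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Compare a scalar column between two sets of series CSV files
#'
#' Reads homogeneous CSV files (as written by [run_analysis()] or any
#' source with the same column), pools the chosen column per state and
#' returns the pooled [compare_states()] result plus a per-run table.
#'
#' @param free_files,bound_files Character vectors of CSV paths.
#' @param column Column to compare (e.g. `"beta_deg"`, `"rmsd_nm"`).
#' @param out_json Optional path; if given, the result is written as JSON.
#' @return List with `pooled` (a `state_comparison` as a list) and
#'   `per_run` (data frame).
#' @export
run_comparison <- function(free_files, bound_files, column,
                           out_json = NULL) {
  read_col <- function(path) {
    if (!file.exists(path)) stop("series file not found: ", path)
    df <- utils::read.csv(path)
    if (nrow(df) == 0L) stop("series file is empty: ", path)
    if (!column %in% names(df))
      stop("column '", column, "' not present in ", path,
           " (schema mismatch)")
    as.numeric(df[[column]])
  }
  free_vals <- lapply(free_files, read_col)
  bound_vals <- lapply(bound_files, read_col)
  per_run <- rbind(
    data.frame(file = basename(free_files), state = "free",
               n = vapply(free_vals, length, integer(1)),
               mean = vapply(free_vals, mean, numeric(1)),
               sd = vapply(free_vals, function(v)
                 if (length(v) > 1) stats::sd(v) else 0, numeric(1))),
    data.frame(file = basename(bound_files), state = "bound",
               n = vapply(bound_vals, length, integer(1)),
               mean = vapply(bound_vals, mean, numeric(1)),
               sd = vapply(bound_vals, function(v)
                 if (length(v) > 1) stats::sd(v) else 0, numeric(1))))
  pooled <- compare_states(unlist(free_vals), unlist(bound_vals))
  out <- list(column = column, pooled = comparison_to_list(pooled),
              per_run = per_run)
  if (!is.null(out_json))
    jsonlite::write_json(out, out_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "rows")
  out
}
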