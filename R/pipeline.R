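# Pipeline orchestration: run configured stages and emit a consolidated
# report, a manifest sufficient to replay the run, and per-stage tables.

stage_vocabulary <- c("simulate", "distances", "sites", "traj", "conserve",
                      "ephys")

yaml_ref <- function(x) residue_ref(x$chain, x$resid, x$icode %||% "",
                                    x$resname %||% NULL)

yaml_pair <- function(x) pair_spec(x$label, yaml_ref(x$a), yaml_ref(x$b),
                                   chain_mode = x$chain_mode %||% "intra")

# Collect every input path referenced by the config.
config_input_paths <- function(cfg) {
  paths <- character()
  for (st in cfg$stages) {
    s <- cfg[[st]]
    paths <- c(paths,
               unlist(s$conditions, use.names = FALSE), s$files, s$file,
               s$fasta, s$groups)
  }
  paths <- unlist(paths, use.names = FALSE)
  unique(as.character(paths[!is.na(paths)]))
}

validate_config <- function(cfg, out_dir) {
  if (is.null(cfg$stages) || length(cfg$stages) == 0L)
    stop("config error: no stages requested")
  bad <- setdiff(cfg$stages, stage_vocabulary)
  if (length(bad))
    stop("config error: unknown stage(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(stage_vocabulary, collapse = ", "), ")")
  for (st in cfg$stages)
    if (is.null(cfg[[st]]))
      stop("config error: stage '", st, "' has no configuration block")
  # inputs must exist up front, except paths an earlier simulate stage will
  # produce under the output directory
  paths <- config_input_paths(cfg)
  external <- paths[!startsWith(normalizePath(paths, mustWork = FALSE),
                                normalizePath(out_dir, mustWork = FALSE))]
  missing <- external[!file.exists(external)]
  if (length(missing))
    stop("config error: input file(s) not found: ",
         paste(missing, collapse = ", "))
  invisible(cfg)
}

write_df <- function(df, path, sep = ",") {
  df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
}

stage_simulate <- function(s, dir, seed, log) {
  nf <- s$n_frames %||% 300L
  sc <- trpv_scenario(seed = s$seed %||% seed, n_frames = nf,
                      changepoint = s$changepoint %||%
                        max(2L, as.integer(round(0.3 * nf))),
                      n_traces = s$n_traces %||% 5L)
  sdir <- function(...) {
    p <- file.path(dir, ...)
    dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
    p
  }
  for (ch in names(sc$structures))
    for (cond in names(sc$structures[[ch]]))
      for (k in seq_along(sc$structures[[ch]][[cond]])) {
        e <- sc$structures[[ch]][[cond]][[k]]
        write_pdb(e, sdir("structures", sprintf("%s_%s_%d.pdb", ch, cond, k)))
        write_df(attr(e, "ground_truth"),
                 sdir("structures", sprintf("%s_%s_%d.truth.csv", ch, cond, k)))
      }
  for (ch in names(sc$trajectories))
    for (cond in names(sc$trajectories[[ch]])) {
      e <- sc$trajectories[[ch]][[cond]]
      write_pdb(e, sdir("traj", sprintf("%s_%s.pdb", ch, cond)))
      write_df(attr(e, "ground_truth")$pairs,
               sdir("traj", sprintf("%s_%s.truth.csv", ch, cond)))
    }
  for (ch in names(sc$traces))
    for (k in seq_along(sc$traces[[ch]])) {
      tr <- sc$traces[[ch]][[k]]
      write_df(data.frame(time_ms = tr$t, current_pA = tr$i),
               sdir("traces", sprintf("%s_%02d.csv", ch, k)))
    }
  writeLines(sc$alignment$fasta, sdir("alignment", "alignment.fasta"))
  writeLines(sc$alignment$groups, sdir("alignment", "groups.tsv"))
  write_pdb(sc$ca_site, sdir("sites", "ca_site.pdb"))
  log("simulate: scenario written (seed ", sc$seed, ")")
  paste0("Scenario generated with seed ", sc$seed, ": ",
         "2 channel classes x 2 conditions, trajectories of ",
         n_models(sc$trajectories$v6_like$NaCl), " frames, ",
         length(sc$traces$v6_like), " traces per class.")
}

stage_distances <- function(s, dir, seed, log) {
  pairs <- lapply(s$pairs, yaml_pair)
  conditions <- lapply(s$conditions, function(files)
    lapply(files, read_pdb, source_label = ""))
  tab <- state_comparison_table(conditions, pairs)
  write_df(tab$long, file.path(dir, "distances_long.csv"))
  write_df(tab$wide, file.path(dir, "distances_wide.tsv"), sep = "\t")
  lines <- c("### Interdomain distances", "",
             utils::capture.output(print(tab$wide, row.names = FALSE)))
  if (!is.null(s$delta)) {
    d <- delta_table(tab, s$delta[[1]], s$delta[[2]])
    write_df(d, file.path(dir, "delta.csv"))
    lines <- c(lines, "", sprintf("### Delta mean (%s - %s)", s$delta[[1]],
                                  s$delta[[2]]), "",
               utils::capture.output(print(d, row.names = FALSE)))
  }
  log("distances: ", nrow(tab$long), " cells")
  paste(lines, collapse = "\n")
}

stage_sites <- function(s, dir, seed, log) {
  cfg <- coordination_config(
    distance_cutoff = s$distance_cutoff %||% 2.5,
    min_oxygens = s$min_oxygens %||% 4L, max_oxygens = s$max_oxygens %||% 8L,
    include_water = s$include_water %||% TRUE)
  rows <- do.call(rbind, lapply(s$files, function(f) {
    e <- read_pdb(f, keep_hetero = TRUE)
    out <- do.call(rbind, lapply(seq_len(n_models(e)), function(m)
      find_coordination_sites(e, cfg, model = m)))
    if (!is.null(out) && nrow(out)) out$file <- basename(f)
    out
  }))
  write_df(rows, file.path(dir, "sites.csv"))
  log("sites: ", if (is.null(rows)) 0L else nrow(rows), " ion-model pairs")
  paste(c("### Coordination sites", "",
          utils::capture.output(print(
            rows[, setdiff(names(rows), "oxygen_indices")],
            row.names = FALSE))), collapse = "\n")
}

stage_traj <- function(s, dir, seed, log) {
  e <- read_pdb(s$file, keep_hetero = TRUE,
                source_label = s$condition %||% "")
  rs <- rmsd_series(e, frame_interval = s$frame_interval %||% 0.2)
  write_df(as.data.frame(rs), file.path(dir, "rmsd.csv"))
  onset <- stability_onset(rs, window = s$window %||% 50L,
                           slope_tol = s$slope_tol %||% 0.05)
  jsonlite::write_json(onset[c("onset_index", "onset_time", "window",
                               "slope_tol")],
                       file.path(dir, "onset.json"), auto_unbox = TRUE)
  stats_rows <- list(); series <- list()
  for (p in lapply(s$pairs, yaml_pair)) {
    pd <- pair_distance_series(e, p, onset,
                               frame_interval = s$frame_interval %||% 0.2)
    ser <- pd$series; ser$pair_label <- p$label
    series[[p$label]] <- ser
    stats_rows[[p$label]] <- pd$stats
  }
  write_df(do.call(rbind, series), file.path(dir, "pair_series.csv"))
  st <- do.call(rbind, stats_rows)
  write_df(st, file.path(dir, "pair_stats.csv"))
  log("traj: onset frame ", onset$onset_index, ", ", nrow(st), " pairs")
  paste(c("### Trajectory analysis", "",
          sprintf("Stability onset: frame %d (t = %.2f ns).",
                  onset$onset_index, onset$onset_time), "",
          utils::capture.output(print(st, row.names = FALSE))),
        collapse = "\n")
}

stage_conserve <- function(s, dir, seed, log) {
  ga <- read_alignment(s$fasta, s$groups)
  groups <- unique(ga$groups)
  prof <- do.call(rbind, lapply(groups, function(g) {
    p <- column_identity(ga, g)
    p$group <- g
    p
  }))
  write_df(prof, file.path(dir, "conservation.tsv"), sep = "\t")
  lines <- c("### Conservation", "",
             sprintf("%d sequences, %d columns, %d groups.",
                     nrow(ga$seq), ncol(ga$seq), length(groups)))
  if (!is.null(s$focal) && !is.null(s$contrast)) {
    fp <- fingerprint_positions(column_identity(ga, s$focal),
                                column_identity(ga, s$contrast),
                                t_high = s$t_high %||% 80,
                                t_low = s$t_low %||% 50)
    write_df(fp, file.path(dir, "fingerprints.tsv"), sep = "\t")
    sw <- scaffold_windows(column_identity(ga, s$focal),
                           threshold = s$threshold %||% 70)
    write_df(sw, file.path(dir, "scaffolds.tsv"), sep = "\t")
    lines <- c(lines, "",
               sprintf("Fingerprint columns (%s vs %s): %s", s$focal,
                       s$contrast,
                       if (nrow(fp)) paste(fp$column, collapse = ", ")
                       else "none"))
  }
  log("conserve: ", length(groups), " group profiles")
  paste(lines, collapse = "\n")
}

stage_ephys <- function(s, dir, seed, log) {
  traces <- lapply(s$files, function(f)
    read_trace(f, sampling_rate = s$sampling_rate %||% 10000,
               pulse_start = s$pulse_start %||% 5,
               pulse_duration = s$pulse_duration %||% 60))
  names(traces) <- basename(unlist(s$files))
  res <- inactivation_summary(traces, blank_ms = s$blank_ms %||% 0)
  write_df(res$per_trace, file.path(dir, "metrics.csv"))
  write_df(res$summary, file.path(dir, "metrics_summary.csv"))
  log("ephys: ", nrow(res$per_trace), " traces, ",
      res$summary$n_converged, " converged fits")
  paste(c("### Inactivation kinetics", "",
          utils::capture.output(print(res$per_trace, row.names = FALSE)), "",
          utils::capture.output(print(res$summary, row.names = FALSE))),
        collapse = "\n")
}

#' Run the configured analysis pipeline
#'
#' Validates the configuration (stage names against the fixed vocabulary,
#' existence of referenced input files) before any stage runs, then
#' executes the requested stages in declared order, writing per-stage
#' output directories, a consolidated `report.md`, a `run.log`, and a
#' `manifest.json` (input digests, parameters with defaults filled in,
#' seed, package version) sufficient to replay the run.  A stage failure
#' aborts with the stage name; outputs of earlier stages are preserved.
#'
#' @param config path to a YAML configuration file, or an equivalent
#'   nested list.  Top-level keys: `stages` (subset of `simulate`,
#'   `distances`, `sites`, `traj`, `conserve`, `ephys`), `seed`, `out_dir`,
#'   plus one block per requested stage.
#' @param out_dir output directory (overrides the config's `out_dir`).
#' @return The output directory path, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  out_dir <- out_dir %||% cfg$out_dir %||% stop("config error: no out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  log <- function(...) {
    msg <- paste0(...)
    message("[gatemap] ", msg)
    log_lines <<- c(log_lines, msg)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  validate_config(cfg, out_dir)
  seed <- cfg$seed %||% 1L

  runners <- list(simulate = stage_simulate, distances = stage_distances,
                  sites = stage_sites, traj = stage_traj,
                  conserve = stage_conserve, ephys = stage_ephys)
  report <- c("# gatemap pipeline report", "",
              sprintf("Seed: %d. Stages: %s.", seed,
                      paste(cfg$stages, collapse = ", ")), "")
  for (st in cfg$stages) {
    sdir <- file.path(out_dir, st)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    section <- tryCatch(
      runners[[st]](cfg[[st]], sdir, seed, log),
      error = function(e)
        stop("stage '", st, "' failed: ", conditionMessage(e), call. = FALSE))
    report <- c(report, sprintf("## Stage: %s", st), "", section, "")
  }
  writeLines(report, file.path(out_dir, "report.md"))

  inputs <- config_input_paths(cfg)
  inputs <- inputs[file.exists(inputs)]
  manifest <- list(
    package = "gatemap",
    version = as.character(utils::packageVersion("gatemap")),
    seed = seed, stages = cfg$stages, config = cfg,
    inputs = if (length(inputs))
      as.list(stats::setNames(unname(tools::md5sum(inputs)), inputs))
    else list())
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
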