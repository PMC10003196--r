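# Calcium coordination-site detection.
#
# A site qualifies when the ion is surrounded by four to eight oxygens at
# 2.5 Angstrom or less -- the generic geometry of Ca2+ coordination in
# proteins.  Oxygens are counted within the cutoff (carboxylate, carbonyl,
# hydroxyl and water oxygens all count; no chemistry typing), so the mean
# distance over counted oxygens automatically satisfies the bound.

#' Coordination-rule configuration
#'
#' @param distance_cutoff Angstrom; oxygens within this distance of the ion
#'   count as coordinating (default 2.5).
#' @param min_oxygens,max_oxygens inclusive bounds on the coordinating-oxygen
#'   count for a qualifying site (defaults 4 and 8).
#' @param ion_names atom names (among HETATM records) treated as ions.
#' @param include_water whether water oxygens (HOH/WAT/SOL residues) count.
#' @export
coordination_config <- function(distance_cutoff = 2.5, min_oxygens = 4L,
                                max_oxygens = 8L, ion_names = "CA",
                                include_water = TRUE) {
  stopifnot(distance_cutoff > 0, min_oxygens >= 1L,
            min_oxygens <= max_oxygens)
  structure(list(distance_cutoff = distance_cutoff,
                 min_oxygens = as.integer(min_oxygens),
                 max_oxygens = as.integer(max_oxygens),
                 ion_names = ion_names, include_water = include_water),
            class = "coordination_config")
}

water_resnames <- c("HOH", "WAT", "SOL")

# Indices of candidate coordinating oxygens and of ions in the topology.
site_atom_sets <- function(e, cfg) {
  a <- e$atoms
  ions <- which(a$is_hetero & a$atom_name %in% cfg$ion_names)
  ox <- which(toupper(a$element) == "O")
  if (!cfg$include_water) ox <- ox[!(a$resname[ox] %in% water_resnames)]
  list(ions = ions, oxygens = setdiff(ox, ions))
}

#' Detect coordination sites in one model
#'
#' For each ion matching the configuration, collects every oxygen within
#' the distance cutoff and reports the count, the mean ion-oxygen distance
#' over the counted oxygens, and whether the site qualifies
#' (count within `[min_oxygens, max_oxygens]`).
#'
#' @param e a `pdb_ensemble` read with `keep_hetero = TRUE`.
#' @param cfg a [coordination_config()].
#' @param model model (frame) index.
#' @return data.frame with one row per ion: `model_id`, `ion_index`,
#'   `ion_name`, `ion_resid`, `count`, `mean_distance_A`, `qualifies`, and a
#'   list-column `oxygen_indices`.  Zero ions gives a zero-row frame with a
#'   message (not an error).
#' @export
find_coordination_sites <- function(e, cfg = coordination_config(), model = 1L) {
  stopifnot(inherits(cfg, "coordination_config"))
  sets <- site_atom_sets(e, cfg)
  empty <- data.frame(model_id = integer(), ion_index = integer(),
                      ion_name = character(), ion_resid = integer(),
                      count = integer(), mean_distance_A = numeric(),
                      qualifies = logical())
  if (length(sets$ions) == 0L) {
    message("find_coordination_sites: no ions matching ",
            paste(cfg$ion_names, collapse = "/"), " in model")
    empty$oxygen_indices <- list()
    return(empty)
  }
  xyz <- model_coords(e, model)
  rows <- lapply(sets$ions, function(i) {
    d <- sqrt(colSums((t(xyz[sets$oxygens, , drop = FALSE]) - xyz[i, ])^2))
    hit <- sets$oxygens[d <= cfg$distance_cutoff]
    cnt <- length(hit)
    df <- data.frame(
      model_id = model, ion_index = i, ion_name = e$atoms$atom_name[i],
      ion_resid = e$atoms$resid[i], count = cnt,
      mean_distance_A = if (cnt) mean(d[d <= cfg$distance_cutoff]) else NA_real_,
      qualifies = cnt >= cfg$min_oxygens && cnt <= cfg$max_oxygens,
      stringsAsFactors = FALSE)
    df$oxygen_indices <- list(hit)
    df
  })
  do.call(rbind, rows)
}

#' Fraction of frames in which an ion's site qualifies
#'
#' @param traj a trajectory as `pdb_ensemble` (frames as models).
#' @param ion_index row index of the ion atom in the shared topology.
#' @param cfg a [coordination_config()].
#' @param from_frame first frame of the analysis window (1-based), e.g. a
#'   stability onset; frames `from_frame:n_models(traj)` are used.
#' @return Fraction in `[0, 1]`.
#' @export
site_occupancy <- function(traj, ion_index, cfg = coordination_config(),
                           from_frame = 1L) {
  a <- traj$atoms
  if (ion_index < 1L || ion_index > nrow(a) || !a$is_hetero[ion_index] ||
      !(a$atom_name[ion_index] %in% cfg$ion_names))
    stop("topology error: atom ", ion_index, " is not an ion matching ",
         paste(cfg$ion_names, collapse = "/"))
  frames <- seq.int(from_frame, n_models(traj))
  if (length(frames) == 0L) stop("analysis window is empty")
  q <- vapply(frames, function(m) {
    s <- find_coordination_sites(traj, cfg, model = m)
    s$qualifies[s$ion_index == ion_index]
  }, logical(1))
  mean(q)
}
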