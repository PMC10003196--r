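# Packaged two-channel synthetic scenario.
#
# Emulates the study design for a fast-inactivating channel ("V6-like":
# the HLH approaches the TRP-domain helix on binding, the ARD6-HLH pair
# stays apart, currents decay with tau ~ 10 ms) and its non-inactivating
# paralog ("V5-like": ARD6-HLH short in every state, HLH-TDh never closes,
# currents stay flat).  Every planted number is a generator input, so the
# downstream sign pattern of the delta tables is known ground truth.

#' The four canonical interdomain residue pairs
#'
#' Residue pairs of the inactivation motif in TRPV6 author numbering, one
#' chain per pair so each reference resolves uniquely:
#' HLH to TDh C-terminal (E294-R606), HLH to TDh N-terminal (R302-E588),
#' ARD6 to HLH (K245-E288), and S2-S3 linker to TDh (D406-R606).
#'
#' @return Named list of [pair_spec()]s.
#' @export
canonical_pairs <- function() {
  list(
    hlh_tdh = pair_spec("HLH-TDh(E294-R606)",
                        residue_ref("A", 294, resname = "GLU"),
                        residue_ref("A", 606, resname = "ARG")),
    hlh_tdhN = pair_spec("HLH-TDhN(R302-E588)",
                         residue_ref("B", 302, resname = "ARG"),
                         residue_ref("B", 588, resname = "GLU")),
    ard6_hlh = pair_spec("ARD6-HLH(K245-E288)",
                         residue_ref("C", 245, resname = "LYS"),
                         residue_ref("C", 288, resname = "GLU")),
    s2s3_tdh = pair_spec("S2S3-TDh(D406-R606)",
                         residue_ref("D", 406, resname = "ASP"),
                         residue_ref("D", 606, resname = "ARG"))
  )
}

scenario_struct_means <- function() {
  # planted mean distances (Angstrom) per pair, condition and channel class
  list(
    v6_like = list(apo   = c(hlh_tdh = 12, hlh_tdhN = 11, ard6_hlh = 15, s2s3_tdh = 6),
                   bound = c(hlh_tdh = 4, hlh_tdhN = 4.5, ard6_hlh = 15, s2s3_tdh = 10)),
    v5_like = list(apo   = c(hlh_tdh = 12, hlh_tdhN = 11, ard6_hlh = 4, s2s3_tdh = 6),
                   bound = c(hlh_tdh = 13, hlh_tdhN = 12, ard6_hlh = 3.8, s2s3_tdh = 4.5))
  )
}

scenario_traj_means <- function() {
  list(
    v6_like = list(NaCl  = c(hlh_tdh = 10, ard6_hlh = 15),
                   CaCl2 = c(hlh_tdh = 4.5, ard6_hlh = 14.5)),
    v5_like = list(NaCl  = c(hlh_tdh = 10, ard6_hlh = 7),
                   CaCl2 = c(hlh_tdh = 9.5, ard6_hlh = 4))
  )
}

# Alignment plan: 40 columns, 4 clade groups.  Scaffold block (columns
# 5-20) conserved in the two amniote-like groups, variable in the
# amphibian/fish-like groups; five fingerprint columns where the focal
# group fixes a residue that the fish-like group replaces by a different
# conserved residue; the remainder conserved everywhere (TDh-like).
scenario_alignment_plan <- function() {
  L <- 40
  fingerprints <- c(8L, 12L, 18L, 25L, 31L)
  groups <- c("mammalia_v6", "sauropsida", "amphibia", "fish")
  consensus <- rep_len(aa_alphabet, L)
  plan <- vector("list", L)
  for (j in seq_len(L)) {
    col <- list()
    for (g in groups) {
      if (j %in% fingerprints) {
        col[[g]] <- switch(g,
          mammalia_v6 = list(residue = "T", identity = 100),
          sauropsida  = list(residue = "T", identity = 100),
          amphibia    = list(residue = "R", identity = 75),
          fish        = list(residue = "R", identity = 100))
      } else if (j >= 5 && j <= 20) {
        col[[g]] <- switch(g,
          mammalia_v6 = list(residue = consensus[j], identity = 100),
          sauropsida  = list(residue = consensus[j], identity = 100),
          amphibia    = list(residue = consensus[j], identity = 50),
          fish        = list(residue = consensus[j], identity = 50))
      } else {
        col[[g]] <- list(residue = consensus[j], identity = 100)
      }
    }
    plan[[j]] <- col
  }
  attr(plan, "fingerprints") <- fingerprints
  plan
}

#' Generate the packaged two-channel scenario bundle
#'
#' @param seed master seed; every sub-generator seed derives from it.
#' @param n_models models per structure ensemble (2 ensembles per
#'   condition); @param sd_A planted distance scatter.
#' @param n_frames,changepoint trajectory size and planted equilibration
#'   frame; @param n_traces current traces per phenotype class.
#' @return List of class `trpv_scenario`:
#'   `pairs`; `structures` (`v6_like`/`v5_like`, each a named condition
#'   list of ensembles); `trajectories` (`v6_like`/`v5_like`, each with
#'   `NaCl`/`CaCl2` trajectories); `traces` (`v6_like` decaying with
#'   tau = 10 ms, `v5_like` non-decaying); `alignment` (with planted
#'   fingerprint columns as attribute); `ca_site`; `planted` (all planted
#'   means).
#' @export
trpv_scenario <- function(seed = 1L, n_models = 3L, sd_A = 0.4,
                          n_frames = 300L, changepoint = 90L,
                          n_traces = 5L) {
  sub <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 40L))
  pairs <- canonical_pairs()
  sm <- scenario_struct_means()
  tm <- scenario_traj_means()
  mk_pairs <- function(means) lapply(names(means), function(k)
    list(spec = pairs[[k]], mean_A = unname(means[k]), sd_A = sd_A))

  s <- 0L
  next_seed <- function() { s <<- s + 1L; sub[s] }

  structures <- lapply(sm, function(ch) {
    out <- lapply(names(ch), function(cond) {
      lapply(1:2, function(entry)
        gen_bridge_ensemble(mk_pairs(ch[[cond]]), n_models = n_models,
                            seed = next_seed(), source_label = cond))
    })
    stats::setNames(out, names(ch))
  })

  trajectories <- lapply(tm, function(ch) {
    out <- lapply(names(ch), function(cond)
      gen_trajectory(mk_pairs(ch[[cond]]), n_frames = n_frames,
                     changepoint = changepoint, seed = next_seed(),
                     source_label = cond))
    stats::setNames(out, names(ch))
  })

  traces <- list(
    v6_like = lapply(seq_len(n_traces), function(k)
      gen_current_trace(i0 = -500, i_inf = -50, tau = 10, noise_sd = 5,
                        seed = next_seed())$trace),
    v5_like = lapply(seq_len(n_traces), function(k)
      gen_current_trace(i0 = -500, i_inf = -500, tau = 10, noise_sd = 5,
                        seed = next_seed())$trace))

  plan <- scenario_alignment_plan()
  aln <- gen_alignment(c(mammalia_v6 = 6L, sauropsida = 6L,
                         amphibia = 4L, fish = 4L),
                       plan, seed = next_seed())
  ca <- gen_ca_site(6, 2.3, decoys = 4L, seed = next_seed())

  structure(list(pairs = pairs, structures = structures,
                 trajectories = trajectories, traces = traces,
                 alignment = aln,
                 fingerprint_columns = attr(plan, "fingerprints"),
                 ca_site = ca,
                 planted = list(structures = sm, trajectories = tm,
                                tau_ms = 10, changepoint = changepoint),
                 seed = as.integer(seed)),
            class = "trpv_scenario")
}

#' @export
print.trpv_scenario <- function(x, ...) {
  cat(sprintf("<trpv_scenario> seed %d: 2 channel classes x 2 conditions x %d ensembles;\n",
              x$seed, length(x$structures$v6_like$apo)))
  cat(sprintf("  trajectories %d frames (changepoint %d); %d traces/class; %d seqs x %d columns\n",
              n_models(x$trajectories$v6_like$NaCl), x$planted$changepoint,
              length(x$traces$v6_like), nrow(x$alignment$alignment$seq),
              ncol(x$alignment$alignment$seq)))
  invisible(x)
}
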