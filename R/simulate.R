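# Seeded synthetic-data generators.
#
# Every input class consumed by the pipeline can be generated with known
# ground truth: multi-model ensembles with planted charged-pair distances,
# trajectories with a planted equilibration changepoint, ion coordination
# shells with planted oxygen counts and radii, grouped alignments with
# exact per-column conservation, and exponential current traces.  All
# generators are pure functions of their arguments (seed included):
# identical arguments give byte-identical output, and the caller's RNG
# state is never disturbed.
#
# Geometry is deliberately minimal -- backbone CA plus the terminal charged
# atoms of each residue -- which is sufficient for every consumer operation.
# The planted distance controls the MINIMUM over terminal-atom pairs (the
# measured quantity); every non-minimal partner atom is placed strictly
# farther away.

# Atom rows for one charged residue: CA + terminal charged atoms.
# `place` maps atom name -> xyz.  Returns list(atoms=df, xyz=matrix).
residue_block <- function(ref, place) {
  nm <- c("CA", terminal_atom_table[[ref$resname]])
  atoms <- data.frame(
    chain_id = ref$chain_id, resid = ref$resid, icode = ref$icode,
    resname = ref$resname, atom_name = nm,
    element = substr(nm, 1, 1), altloc = "", is_hetero = FALSE,
    stringsAsFactors = FALSE)
  xyz <- t(vapply(nm, place, numeric(3)))
  list(atoms = atoms, xyz = xyz)
}

# Place one planted pair at base point B with gap d along unit vector u.
# Primary terminal atoms sit exactly d apart; all other terminal atoms
# are strictly farther from every atom of the partner residue.
place_pair_atoms <- function(acid, base, B, u, d, ca_gap = d) {
  a_names <- terminal_atom_table[[acid$resname]]
  b_names <- terminal_atom_table[[base$resname]]
  a_pos <- list(CA = B - 3.5 * u)
  a_pos[[a_names[1]]] <- B
  if (length(a_names) > 1L)
    for (k in 2:length(a_names)) a_pos[[a_names[k]]] <- B - 1.5 * (k - 1) * u
  b_pos <- list(CA = B + (ca_gap + 3.5) * u)
  for (k in seq_along(b_names)) b_pos[[b_names[k]]] <- B + (d + 1.5 * (k - 1)) * u
  ab <- residue_block(acid, function(nm) a_pos[[nm]])
  bb <- residue_block(base, function(nm) b_pos[[nm]])
  list(atoms = rbind(ab$atoms, bb$atoms), xyz = rbind(ab$xyz, bb$xyz))
}

# Split a pair entry into acid-first order; errors if not one acid + one base.
pair_acid_base <- function(p) {
  if (p$a$resname %in% acidic_resnames && p$b$resname %in% basic_resnames)
    list(acid = p$a, base = p$b)
  else if (p$b$resname %in% acidic_resnames && p$a$resname %in% basic_resnames)
    list(acid = p$b, base = p$a)
  else stop("generator pairs must combine one acidic and one basic residue")
}

draw_trunc_normal <- function(mean, sd, floor = 0.5) {
  for (k in 1:100) {
    d <- stats::rnorm(1, mean, sd)
    if (d > floor) return(d)
  }
  stop("generation error: could not draw a distance > ", floor,
       " A from Normal(", mean, ", ", sd, ")")
}

#' Generate a multi-model ensemble with planted pair distances
#'
#' Each requested residue pair is emitted as two minimal residues whose
#' minimum terminal-atom distance in model `m` is an independent draw from
#' `Normal(mean_A, sd_A)` truncated above 0.5 Angstrom, along a random
#' direction per model.  Pair blocks are separated by 60 Angstrom so they
#' cannot interfere; decoy carbon atoms are placed far (> 10 Angstrom) from
#' every pair atom.
#'
#' @param pairs list of entries `list(spec = pair_spec(...), mean_A =,
#'   sd_A =)`; the residue refs must carry resnames (one acidic, one basic).
#' @param n_models number of models.
#' @param decoy_atoms number of decoy carbon atoms (default 0).
#' @param seed RNG seed.
#' @param source_label condition tag for the ensemble.
#' @return A `pdb_ensemble` with attribute `ground_truth`: data.frame
#'   `model`, `pair_label`, `distance_A` of the planted draws.
#' @export
gen_bridge_ensemble <- function(pairs, n_models, decoy_atoms = 0L, seed = 1L,
                                source_label = "") {
  stopifnot(n_models >= 1L, length(pairs) >= 1L)
  for (p in pairs) stopifnot(inherits(p$spec, "pair_spec"),
                             p$mean_A > 0, p$sd_A >= 0)
  with_seed(seed, {
    truth <- list()
    coords <- NULL
    topo <- NULL
    for (m in seq_len(n_models)) {
      blocks <- lapply(seq_along(pairs), function(k) {
        p <- pairs[[k]]
        ab <- pair_acid_base(p$spec)
        d <- draw_trunc_normal(p$mean_A, p$sd_A)
        u <- runif_unit3()
        pl <- place_pair_atoms(ab$acid, ab$base, c(60 * k, 0, 0), u, d)
        pl$d <- d
        pl
      })
      truth[[m]] <- data.frame(
        model = m,
        pair_label = vapply(pairs, function(p) p$spec$label, ""),
        distance_A = vapply(blocks, `[[`, numeric(1), "d"),
        stringsAsFactors = FALSE)
      at <- do.call(rbind, lapply(blocks, `[[`, "atoms"))
      xyz <- do.call(rbind, lapply(blocks, `[[`, "xyz"))
      if (decoy_atoms > 0L) {
        at <- rbind(at, data.frame(
          chain_id = "Z", resid = 900L + seq_len(decoy_atoms), icode = "",
          resname = "DUM", atom_name = "C", element = "C", altloc = "",
          is_hetero = FALSE, stringsAsFactors = FALSE))
        xyz <- rbind(xyz, cbind(stats::runif(decoy_atoms, -20, 20),
                                stats::runif(decoy_atoms, -20, 20),
                                200 + 5 * seq_len(decoy_atoms)))
      }
      if (is.null(topo)) {
        topo <- at
        coords <- array(NA_real_, dim = c(nrow(at), 3L, n_models))
      }
      coords[, , m] <- xyz
    }
    e <- pdb_ensemble(topo, coords, source_label = source_label)
    attr(e, "ground_truth") <- do.call(rbind, truth)
    e
  })
}

#' Generate a trajectory with planted changepoint and distance processes
#'
#' Frames share one topology.  A block of `n_mobile` alpha carbons is
#' displaced along fixed per-atom directions by a scale that rises linearly
#' from 0 to `rmsd_amplitude` at the `changepoint` frame and stays flat
#' (plus noise) afterwards, producing a ramp-then-plateau RMSD profile.
#' Each pair's distance fluctuates around its mean with optional pre-onset
#' drift (linearly decaying to zero at the changepoint).  Optionally a
#' calcium ion with an oxygen shell is planted whose site qualifies in a
#' stated set of frames.
#'
#' @param pairs list as in [gen_bridge_ensemble()], each entry optionally
#'   with `drift_A` (initial excess distance, default 0).
#' @param n_frames number of frames (>= 2); @param frame_interval ns.
#' @param changepoint frame index of the planted equilibration point.
#' @param rmsd_amplitude plateau displacement scale, Angstrom.
#' @param rmsd_noise per-frame scale noise sd, Angstrom.
#' @param n_mobile number of mobile alpha carbons.
#' @param ca_site optional `list(qualify = logical(n_frames), n_oxygens =,
#'   radius =)`: plant an ion whose shell sits at `radius` in qualifying
#'   frames and well beyond the cutoff otherwise.
#' @param seed RNG seed; @param source_label condition tag.
#' @return A `pdb_ensemble` with attribute `ground_truth`: list
#'   `changepoint`, `scale` (planted displacement scale per frame),
#'   `pairs` (data.frame `frame`, `pair_label`, `distance_A`),
#'   `site_qualify` (logical per frame or NULL), `ion_index`.
#' @export
gen_trajectory <- function(pairs, n_frames = 500L, frame_interval = 0.2,
                           changepoint = 150L, rmsd_amplitude = 5.0,
                           rmsd_noise = 0.05, n_mobile = 30L,
                           ca_site = NULL, seed = 1L, source_label = "") {
  stopifnot(n_frames >= 2L, changepoint >= 1L, changepoint < n_frames)
  with_seed(seed, {
    base <- matrix(stats::rnorm(n_mobile * 3, sd = 6), ncol = 3)
    base <- sweep(base, 2, colMeans(base))
    dirs <- matrix(stats::rnorm(n_mobile * 3), ncol = 3)
    dirs <- sweep(dirs, 2, colMeans(dirs))          # no net translation
    dirs <- dirs / sqrt(mean(rowSums(dirs^2)))      # rms length 1
    mobile_atoms <- data.frame(
      chain_id = "M", resid = seq_len(n_mobile), icode = "", resname = "ALA",
      atom_name = "CA", element = "C", altloc = "", is_hetero = FALSE,
      stringsAsFactors = FALSE)

    scale <- numeric(n_frames)
    ramp <- rmsd_amplitude * (seq_len(n_frames) - 1) / (changepoint - 1)
    scale <- pmin(ramp, rmsd_amplitude)
    scale[-1] <- pmax(scale[-1] + stats::rnorm(n_frames - 1L, 0, rmsd_noise), 0)
    scale[1] <- 0

    ion_atoms <- NULL; ox_dirs <- NULL
    if (!is.null(ca_site)) {
      stopifnot(length(ca_site$qualify) == n_frames)
      nox <- ca_site$n_oxygens %||% 6L
      ox_dirs <- separated_directions(nox, ca_site$radius %||% 2.3, 1.5)
      ion_atoms <- data.frame(
        chain_id = "I", resid = c(700L, 701L + seq_len(nox)), icode = "",
        resname = c("CA", rep("HOH", nox)),
        atom_name = c("CA", rep("O", nox)),
        element = c("CA", rep("O", nox)), altloc = "",
        is_hetero = TRUE, stringsAsFactors = FALSE)
    }

    # one placement direction per pair, fixed along the trajectory, so the
    # pair backbone does not inject motion into the RMSD selection
    pair_dirs <- lapply(pairs, function(p) runif_unit3())

    pair_truth <- list()
    topo <- NULL; coords <- NULL
    for (f in seq_len(n_frames)) {
      blocks <- lapply(seq_along(pairs), function(k) {
        p <- pairs[[k]]
        ab <- pair_acid_base(p$spec)
        drift <- (p$drift_A %||% 0) * max(changepoint - f, 0) / (changepoint - 1)
        d <- draw_trunc_normal(p$mean_A + drift, p$sd_A)
        # backbone CA anchored at the mean-gap position so the planted
        # distance process never leaks into the RMSD selection
        pl <- place_pair_atoms(ab$acid, ab$base, c(100 + 60 * k, 0, 0),
                               pair_dirs[[k]], d, ca_gap = p$mean_A)
        pl$d <- d
        pl
      })
      pair_truth[[f]] <- data.frame(
        frame = f,
        pair_label = vapply(pairs, function(p) p$spec$label, ""),
        distance_A = vapply(blocks, `[[`, numeric(1), "d"),
        stringsAsFactors = FALSE)
      at <- rbind(mobile_atoms, do.call(rbind, lapply(blocks, `[[`, "atoms")))
      xyz <- rbind(base + scale[f] * dirs,
                   do.call(rbind, lapply(blocks, `[[`, "xyz")))
      if (!is.null(ion_atoms)) {
        r <- if (ca_site$qualify[f]) 1 else
          (4.0 / (ca_site$radius %||% 2.3))  # push shell beyond the cutoff
        ion_xyz <- rbind(c(0, 100, 0),
                         sweep(ox_dirs * r, 2, c(0, 100, 0), "+"))
        at <- rbind(at, ion_atoms)
        xyz <- rbind(xyz, ion_xyz)
      }
      if (is.null(topo)) {
        topo <- at
        coords <- array(NA_real_, dim = c(nrow(at), 3L, n_frames))
      }
      coords[, , f] <- xyz
    }
    e <- pdb_ensemble(topo, coords, source_label = source_label)
    attr(e, "ground_truth") <- list(
      changepoint = as.integer(changepoint), scale = scale,
      pairs = do.call(rbind, pair_truth),
      site_qualify = if (is.null(ca_site)) NULL else ca_site$qualify,
      ion_index = if (is.null(ion_atoms)) NULL else
        which(topo$atom_name == "CA" & topo$is_hetero)[1])
    e
  })
}

# n points at the given radii (scalar or per-point) in random directions
# with minimum mutual separation `min_sep`.  Rejection sampling first; for
# shells too crowded for random placement, fall back to an evenly spaced
# Fibonacci-sphere layout under a random rotation.
separated_directions <- function(n, radius, min_sep) {
  radius <- rep_len(radius, n)
  pts <- matrix(NA_real_, n, 3)
  ok <- TRUE
  for (k in seq_len(n)) {
    placed <- FALSE
    for (try in 1:500) {
      cand <- runif_unit3() * radius[k]
      if (k == 1L ||
          min(sqrt(rowSums(sweep(pts[seq_len(k - 1L), , drop = FALSE],
                                 2, cand)^2))) >= min_sep) {
        pts[k, ] <- cand; placed <- TRUE; break
      }
    }
    if (!placed) { ok <- FALSE; break }
  }
  if (ok) return(pts)
  # Fibonacci sphere: near-maximal mutual separation, randomly rotated
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r2 <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(r2 * cos(phi), r2 * sin(phi), z)
  axis <- runif_unit3(); ang <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
  pts <- (dirs %*% t(R)) * radius
  if (n > 1L && min(stats::dist(pts)) < min_sep)
    stop("generation error: could not place ", n, " oxygens at radius ",
         min(radius), " with separation ", min_sep)
  pts
}

#' Generate an ion with a planted oxygen coordination shell
#'
#' One HETATM calcium ion at the origin surrounded by `n_oxygens` water
#' oxygens at the stated radius/radii in random directions (minimum mutual
#' separation 1.5 Angstrom), plus optional decoy carbon atoms beyond
#' 5 Angstrom.
#'
#' @param n_oxygens number of shell oxygens (0 allowed).
#' @param radius Angstrom, scalar or per-oxygen vector.
#' @param decoys number of decoy carbons (default 0).
#' @param seed RNG seed.
#' @return Single-model `pdb_ensemble` (HETATM records), with attribute
#'   `ground_truth`: list `n_oxygens`, `radius`.
#' @export
gen_ca_site <- function(n_oxygens, radius = 2.3, decoys = 0L, seed = 1L) {
  stopifnot(n_oxygens >= 0L, all(radius > 0))
  with_seed(seed, {
    atoms <- data.frame(
      chain_id = "I", resid = 500L, icode = "", resname = "CA",
      atom_name = "CA", element = "CA", altloc = "", is_hetero = TRUE,
      stringsAsFactors = FALSE)
    xyz <- matrix(0, 1, 3)
    if (n_oxygens > 0L) {
      pts <- separated_directions(n_oxygens, radius, 1.5)
      atoms <- rbind(atoms, data.frame(
        chain_id = "I", resid = 500L + seq_len(n_oxygens), icode = "",
        resname = "HOH", atom_name = "O", element = "O", altloc = "",
        is_hetero = TRUE, stringsAsFactors = FALSE))
      xyz <- rbind(xyz, pts)
    }
    if (decoys > 0L) {
      pts <- separated_directions(decoys, 8 + 2 * seq_len(decoys), 1.5)
      atoms <- rbind(atoms, data.frame(
        chain_id = "I", resid = 800L + seq_len(decoys), icode = "",
        resname = "DUM", atom_name = "C", element = "C", altloc = "",
        is_hetero = TRUE, stringsAsFactors = FALSE))
      xyz <- rbind(xyz, pts)
    }
    e <- pdb_ensemble(atoms, array(xyz, dim = c(nrow(xyz), 3, 1)))
    attr(e, "ground_truth") <- list(n_oxygens = n_oxygens, radius = radius)
    e
  })
}

aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Generate a grouped alignment with exact per-column conservation
#'
#' The plan fixes, for every column and group, the modal residue and its
#' identity percent; the generator emits exact residue counts (no
#' sampling), so `column_identity()` recovers the planted levels exactly.
#' Non-modal sequences receive distinct filler residues (or gaps when
#' `filler = "gap"`).
#'
#' @param group_sizes named integer vector, group label -> sequence count.
#' @param plan list of length L (columns); each element a named list
#'   `group -> list(residue =, identity =, filler = "distinct"|"gap")`.
#'   `identity/100 * size` must be a whole number.
#' @param seed RNG seed (only permutes which sequences carry the modal
#'   residue per column).
#' @return List of class `synthetic_alignment`: `fasta` (text), `groups`
#'   (TSV text), `alignment` (a `grouped_alignment`), `plan`.
#' @export
gen_alignment <- function(group_sizes, plan, seed = 1L) {
  stopifnot(!is.null(names(group_sizes)), all(group_sizes >= 1L),
            length(plan) >= 1L)
  L <- length(plan)
  with_seed(seed, {
    mats <- lapply(names(group_sizes), function(g) {
      n <- group_sizes[[g]]
      m <- matrix("-", n, L)
      for (j in seq_len(L)) {
        spec <- plan[[j]][[g]]
        if (is.null(spec)) stop("plan column ", j, " lacks group ", g)
        k_exact <- spec$identity / 100 * n
        k <- round(k_exact)
        if (abs(k - k_exact) > 1e-9)
          stop("identity ", spec$identity, "% is not an exact count for ",
               "group size ", n, " (column ", j, ")")
        rows <- sample.int(n)
        m[rows[seq_len(k)], j] <- spec$residue
        rest <- rows[setdiff(seq_len(n), seq_len(k))]
        if (length(rest)) {
          if (identical(spec$filler %||% "distinct", "gap")) {
            m[rest, j] <- "-"
          } else {
            fill <- setdiff(aa_alphabet, spec$residue)
            m[rest, j] <- rep_len(fill, length(rest))
          }
        }
      }
      rownames(m) <- sprintf("%s_%02d", g, seq_len(n))
      m
    })
    m <- do.call(rbind, mats)
    ids <- rownames(m)
    groups <- rep(names(group_sizes), group_sizes)
    fasta <- paste0(">", ids, "\n", apply(m, 1, paste, collapse = ""),
                    collapse = "\n")
    gtsv <- paste(ids, groups, sep = "\t", collapse = "\n")
    ga <- read_alignment(fasta, stats::setNames(groups, ids))
    structure(list(fasta = fasta, groups = gtsv, alignment = ga, plan = plan),
              class = "synthetic_alignment")
  })
}

#' Generate a single-exponential current trace
#'
#' `i(t) = i_inf + (i0 - i_inf) * exp(-(t - pulse_start)/tau)` during the
#' pulse (plus optional Gaussian noise); 0 pA baseline before the pulse.
#'
#' @param i0,i_inf initial and steady-state currents, pA.
#' @param tau time constant, ms.
#' @param noise_sd additive Gaussian noise sd, pA (pulse samples only).
#' @param sampling_rate Hz; @param pulse_start,pulse_duration ms.
#' @param seed RNG seed.
#' @return List: `trace` (a [current_trace()]) and `csv` (two-column text,
#'   `time_ms`, `current_pA`, fixed formatting so equal seeds give
#'   byte-identical output).
#' @export
gen_current_trace <- function(i0 = -100, i_inf = 0, tau = 10, noise_sd = 0,
                              sampling_rate = 10000, pulse_start = 5,
                              pulse_duration = 60, seed = 1L) {
  stopifnot(tau > 0, noise_sd >= 0, sampling_rate > 0)
  with_seed(seed, {
    dt <- 1000 / sampling_rate
    t <- seq(0, pulse_start + pulse_duration, by = dt)
    in_pulse <- t >= pulse_start - 1e-12
    i <- numeric(length(t))
    i[in_pulse] <- i_inf + (i0 - i_inf) * exp(-(t[in_pulse] - pulse_start) / tau)
    if (noise_sd > 0)
      i[in_pulse] <- i[in_pulse] + stats::rnorm(sum(in_pulse), 0, noise_sd)
    csv <- paste(c("time_ms,current_pA",
                   sprintf("%.6f,%.6f", t, i)), collapse = "\n")
    list(trace = current_trace(t, i, sampling_rate = sampling_rate,
                               pulse_start = pulse_start,
                               pulse_duration = pulse_duration),
         csv = csv)
  })
}
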