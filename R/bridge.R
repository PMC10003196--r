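# Salt-bridge proxy distances and state-comparison tables.
#
# The measured quantity is the distance between the last (terminal) charged
# oxygen of an acidic side chain and the terminal charged nitrogen of a
# basic one.  Where a carboxylate or guanidinium offers two equivalent
# terminal atoms the MINIMUM over all terminal-atom pairs is taken -- the
# standard salt-bridge convention; deterministic and never larger than any
# single-atom choice.

#' Specify a residue pair to measure
#'
#' @param label unique human-readable tag (e.g. `"HLH-TDh"`).
#' @param a,b [residue_ref()]s; conventionally one acidic (Asp/Glu) and one
#'   basic (Lys/Arg/His) residue.  A pair that is not acid/base triggers a
#'   warning and falls back to the generic terminal-atom rule.
#' @param chain_mode `"intra"` measures between the chains named in `a` and
#'   `b`; `"min_over_chain_pairs"` evaluates `a`'s residue in every chain
#'   against `b`'s residue in every chain of the homotetramer and returns
#'   the global minimum.
#' @export
pair_spec <- function(label, a, b, chain_mode = c("intra", "min_over_chain_pairs")) {
  chain_mode <- match.arg(chain_mode)
  stopifnot(inherits(a, "residue_ref"), inherits(b, "residue_ref"))
  if (identical(a, b)) stop("pair members must differ")
  structure(list(label = as.character(label), a = a, b = b,
                 chain_mode = chain_mode), class = "pair_spec")
}

#' @export
print.pair_spec <- function(x, ...) {
  cat(sprintf("<pair_spec> %s: %s -- %s [%s]\n", x$label, format(x$a),
              format(x$b), x$chain_mode))
  invisible(x)
}

# Coordinates of the terminal charged atoms of `ref` in model `m`,
# as a k x 3 matrix (k >= 1 or error).
terminal_atom_coords <- function(e, ref, m) {
  idx <- resolve_residue(e, ref)
  nm <- terminal_charged_atoms(e, ref, model = m)
  sel <- idx[e$atoms$atom_name[idx] %in% nm]
  model_coords(e, m)[sel, , drop = FALSE]
}

# Chains in which a residue with this resid/icode(/resname) occurs.
chains_with_residue <- function(e, ref) {
  a <- e$atoms
  sel <- a$resid == ref$resid & a$icode == ref$icode
  if (!is.null(ref$resname)) sel <- sel & a$resname == ref$resname
  unique(a$chain_id[sel])
}

#' Charged-pair minimum distance in one model
#'
#' Minimum Euclidean distance over the cross product of the terminal
#' charged atoms of the two residues of `p`, in Angstrom.
#'
#' @param e a `pdb_ensemble`.
#' @param p a [pair_spec()].
#' @param model model (frame) index.
#' @return Distance in Angstrom (single numeric).
#' @export
charged_pair_distance <- function(e, p, model = 1L) {
  stopifnot(inherits(p, "pair_spec"))
  rn <- function(ref) {
    if (!is.null(ref$resname)) return(ref$resname)
    e$atoms$resname[resolve_residue(e, ref)[1]]
  }
  ra <- rn(p$a); rb <- rn(p$b)
  ok <- (ra %in% acidic_resnames && rb %in% basic_resnames) ||
    (rb %in% acidic_resnames && ra %in% basic_resnames)
  if (!ok)
    warning("pair ", p$label, " is not one acidic + one basic residue (",
            ra, "/", rb, "); using generic terminal-atom rule", call. = FALSE)

  pair_min <- function(ca, cb) {
    d2 <- outer(seq_len(nrow(ca)), seq_len(nrow(cb)),
                Vectorize(function(i, j) sum((ca[i, ] - cb[j, ])^2)))
    sqrt(min(d2))
  }
  if (p$chain_mode == "intra")
    return(pair_min(terminal_atom_coords(e, p$a, model),
                    terminal_atom_coords(e, p$b, model)))

  ch_a <- chains_with_residue(e, p$a)
  ch_b <- chains_with_residue(e, p$b)
  if (length(ch_a) == 0L || length(ch_b) == 0L)
    stop("lookup error: no chain combination resolvable for pair ", p$label)
  best <- Inf
  for (ca in ch_a) for (cb in ch_b) {
    refa <- residue_ref(ca, p$a$resid, p$a$icode, p$a$resname)
    refb <- residue_ref(cb, p$b$resid, p$b$icode, p$b$resname)
    best <- min(best, pair_min(terminal_atom_coords(e, refa, model),
                               terminal_atom_coords(e, refb, model)))
  }
  best
}

#' Per-ensemble distance statistics for one pair
#'
#' Collects [charged_pair_distance()] over every model and reports the
#' arithmetic mean, the sample standard deviation (n-1 denominator, 0 when
#' n = 1) and the model count.
#'
#' @inheritParams charged_pair_distance
#' @param condition condition label; defaults to the ensemble's
#'   `source_label`.
#' @return data.frame with columns `pair_label`, `condition`, `mean_A`,
#'   `sd_A`, `n`.
#' @export
ensemble_distance_stats <- function(e, p, condition = e$source_label) {
  d <- vapply(seq_len(n_models(e)), function(m)
    tryCatch(charged_pair_distance(e, p, m),
             error = function(err)
               stop("model ", m, ": ", conditionMessage(err), call. = FALSE)),
    numeric(1))
  data.frame(pair_label = p$label, condition = condition,
             mean_A = mean(d), sd_A = sample_sd(d), n = length(d),
             stringsAsFactors = FALSE)
}

# Per-model distances for one pair across all ensembles of one condition.
pooled_distances <- function(ensembles, p) {
  unlist(lapply(ensembles, function(e)
    vapply(seq_len(n_models(e)), function(m) charged_pair_distance(e, p, m),
           numeric(1))))
}

#' State-comparison table over conditions
#'
#' One distance statistic per (pair, condition), pooling every model of
#' every ensemble of that condition with equal weight per model.  This is
#' the table behind heat-map style apo-versus-bound comparisons.
#'
#' @param conditions named list: condition label -> list of `pdb_ensemble`s
#'   (a bare ensemble is accepted).
#' @param pairs list of [pair_spec()]s.
#' @return Object of class `state_comparison` with elements `long`
#'   (data.frame `pair_label`, `condition`, `mean_A`, `sd_A`, `n`) and
#'   `wide` (pairs x conditions, cells `"mean±sd (n)"`).
#' @export
state_comparison_table <- function(conditions, pairs) {
  stopifnot(length(conditions) >= 1L, length(pairs) >= 1L,
            !is.null(names(conditions)), all(nzchar(names(conditions))))
  if (anyDuplicated(vapply(pairs, `[[`, "", "label")))
    stop("pair labels must be unique")
  rows <- list()
  for (cond in names(conditions)) {
    ens <- conditions[[cond]]
    if (inherits(ens, "pdb_ensemble")) ens <- list(ens)
    for (p in pairs) {
      d <- tryCatch(pooled_distances(ens, p), error = function(err) NULL)
      if (is.null(d) || length(d) == 0L) {
        warning("condition '", cond, "', pair '", p$label,
                "': no resolvable models; cell dropped", call. = FALSE)
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        pair_label = p$label, condition = cond, mean_A = mean(d),
        sd_A = sample_sd(d), n = length(d), stringsAsFactors = FALSE)
    }
  }
  long <- do.call(rbind, rows)
  wide <- stats::reshape(
    transform(long,
              cell = sprintf("%.2f±%.2f (%d)", long$mean_A, long$sd_A, long$n),
              mean_A = NULL, sd_A = NULL, n = NULL),
    idvar = "pair_label", timevar = "condition", direction = "wide")
  names(wide) <- sub("^cell\\.", "", names(wide))
  rownames(wide) <- NULL
  structure(list(long = long, wide = wide), class = "state_comparison")
}

#' @export
print.state_comparison <- function(x, ...) {
  cat("<state_comparison>\n")
  print(x$wide, row.names = FALSE)
  invisible(x)
}

#' Signed mean-distance difference between two conditions
#'
#' @param x a `state_comparison`.
#' @param cond_a,cond_b condition labels; the result is
#'   `mean(cond_a) - mean(cond_b)` per pair, so
#'   `delta_table(x, a, b)$delta_mean_A == -delta_table(x, b, a)$delta_mean_A`.
#' @return data.frame `pair_label`, `condition_a`, `condition_b`,
#'   `delta_mean_A`.
#' @export
delta_table <- function(x, cond_a, cond_b) {
  stopifnot(inherits(x, "state_comparison"))
  la <- x$long[x$long$condition == cond_a, ]
  lb <- x$long[x$long$condition == cond_b, ]
  if (nrow(la) == 0L || nrow(lb) == 0L)
    stop("condition not present in table: ",
         if (nrow(la) == 0L) cond_a else cond_b)
  m <- merge(la[, c("pair_label", "mean_A")], lb[, c("pair_label", "mean_A")],
             by = "pair_label", suffixes = c("_a", "_b"))
  data.frame(pair_label = m$pair_label, condition_a = cond_a,
             condition_b = cond_b, delta_mean_A = m$mean_A_a - m$mean_A_b,
             stringsAsFactors = FALSE)
}

#' Qualitative contact classification
#'
#' A pair at or below the cutoff is `"formed"`, otherwise `"broken"`.
#' The 4.0 Angstrom default is the common salt-bridge threshold; it is used
#' only for qualitative labelling, never inside the distance statistics.
#'
#' @param d distance(s), Angstrom, `> 0`.
#' @param cutoff contact threshold, Angstrom (boundary inclusive).
#' @return Character vector `"formed"`/`"broken"`.
#' @export
classify_contact <- function(d, cutoff = 4.0) {
  stopifnot(all(d > 0), cutoff > 0)
  ifelse(d <= cutoff, "formed", "broken")
}
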