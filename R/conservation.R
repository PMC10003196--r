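# Clade-grouped alignment conservation: per-column identity profiles,
# conserved scaffold windows, and group-specific fingerprint positions.

#' Read an aligned FASTA plus a sequence-to-group map
#'
#' @param fasta path to an aligned amino-acid FASTA file (or its text).
#' @param groups path to a two-column TSV (id, group) without header, or a
#'   named character vector `id -> group`, or a data.frame with columns
#'   `id`, `group`.
#' @return Object of class `grouped_alignment`: `ids`, `seq` (character
#'   matrix, sequences x columns), `groups` (named vector id -> group).
#' @export
read_alignment <- function(fasta, groups) {
  if (length(fasta) == 1L && !grepl("\n", fasta) && file.exists(fasta)) {
    aa <- Biostrings::readAAStringSet(fasta)
  } else {
    tf <- tempfile(fileext = ".fasta")
    on.exit(unlink(tf))
    writeLines(fasta, tf)
    aa <- Biostrings::readAAStringSet(tf)
  }
  if (length(aa) == 0L) stop("empty alignment")
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  w <- Biostrings::width(aa)
  if (length(unique(w)) != 1L)
    stop("alignment error: sequences have unequal lengths (",
         paste(range(w), collapse = "-"), ")")
  if (is.data.frame(groups)) {
    gm <- stats::setNames(as.character(groups$group), groups$id)
  } else if (is.character(groups) && !is.null(names(groups))) {
    gm <- groups
  } else {
    tab <- utils::read.table(groups, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE,
                             col.names = c("id", "group"))
    gm <- stats::setNames(tab$group, tab$id)
  }
  unmapped <- setdiff(ids, names(gm))
  if (length(unmapped))
    stop("sequence id(s) without a group: ", paste(unmapped, collapse = ", "))
  m <- do.call(rbind, strsplit(toupper(as.character(aa)), ""))
  rownames(m) <- ids
  structure(list(ids = ids, seq = m, groups = gm[ids]),
            class = "grouped_alignment")
}

#' @export
print.grouped_alignment <- function(x, ...) {
  cat(sprintf("<grouped_alignment> %d sequences x %d columns; groups: %s\n",
              nrow(x$seq), ncol(x$seq),
              paste(names(table(x$groups)), table(x$groups),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Per-column identity profile of one clade group
#'
#' For each alignment column the modal (most frequent) non-gap residue is
#' found; ties break to the lexicographically smallest residue (reported
#' via a message).  Identity is the modal-residue count over the full group
#' size -- gapped sequences stay in the denominator, matching the visual
#' per-column identity convention of standard alignment viewers.  A column
#' that is all gaps in the group has `modal_residue = NA` and identity 0.
#'
#' @param ga a [read_alignment()] result.
#' @param group group label.
#' @return Object of class `conservation_profile`: data.frame `column`,
#'   `modal_residue`, `identity_percent`, `n_nongap`, with attribute
#'   `group`.
#' @export
column_identity <- function(ga, group) {
  stopifnot(inherits(ga, "grouped_alignment"))
  rows <- which(ga$groups == group)
  if (length(rows) == 0L) stop("group not present: ", group)
  sub <- ga$seq[rows, , drop = FALSE]
  n <- length(rows)
  ties <- 0L
  prof <- lapply(seq_len(ncol(sub)), function(j) {
    col <- sub[, j]
    res <- col[col != "-"]
    if (length(res) == 0L)
      return(data.frame(column = j, modal_residue = NA_character_,
                        identity_percent = 0, n_nongap = 0L,
                        stringsAsFactors = FALSE))
    tab <- table(res)
    top <- tab[tab == max(tab)]
    if (length(top) > 1L) ties <<- ties + 1L
    modal <- sort(names(top))[1]
    data.frame(column = j, modal_residue = modal,
               identity_percent = 100 * max(tab) / n,
               n_nongap = length(res), stringsAsFactors = FALSE)
  })
  if (ties > 0L)
    message("column_identity: ", ties,
            " column(s) had modal-residue ties broken lexicographically")
  out <- do.call(rbind, prof)
  attr(out, "group") <- group
  class(out) <- c("conservation_profile", "data.frame")
  out
}

#' Conserved scaffold windows
#'
#' Maximal runs of at least `min_len` consecutive columns with identity at
#' or above `threshold`, returned as half-open 1-based intervals
#' `[start, end)`.
#'
#' @param p a [column_identity()] profile.
#' @param threshold identity threshold, percent (default 70).
#' @param min_len minimum run length in columns (default 3).
#' @return data.frame `start`, `end` (half-open), `length`.
#' @export
scaffold_windows <- function(p, threshold = 70, min_len = 3L) {
  stopifnot(nrow(p) >= 1L, min_len >= 1L)
  ok <- p$identity_percent >= threshold
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep] + 1L,
             length = r$lengths[keep])
}

#' Fingerprint positions between a focal and a contrast group
#'
#' Columns conserved in the focal group (identity at or above `t_high`)
#' where the contrast group either fixes a different modal residue or is
#' poorly conserved (identity below `t_low`).  Such columns are the
#' signature of a phenotype present in the focal clade and absent in the
#' contrast clade.
#'
#' @param pa focal-group profile; @param pb contrast-group profile (same
#'   alignment, same length).
#' @param t_high focal conservation threshold, percent (default 80).
#' @param t_low contrast conservation floor, percent (default 50).
#' @return data.frame `column`, `focal_modal`, `focal_identity`,
#'   `contrast_modal`, `contrast_identity`.
#' @export
fingerprint_positions <- function(pa, pb, t_high = 80, t_low = 50) {
  if (nrow(pa) != nrow(pb))
    stop("profiles cover different numbers of columns (",
         nrow(pa), " vs ", nrow(pb), ")")
  hit <- !is.na(pa$modal_residue) & pa$identity_percent >= t_high &
    (is.na(pb$modal_residue) | pb$modal_residue != pa$modal_residue |
       pb$identity_percent < t_low)
  data.frame(column = pa$column[hit],
             focal_modal = pa$modal_residue[hit],
             focal_identity = pa$identity_percent[hit],
             contrast_modal = pb$modal_residue[hit],
             contrast_identity = pb$identity_percent[hit],
             stringsAsFactors = FALSE)
}
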