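# Multi-model PDB coordinate model.
#
# A `pdb_ensemble` holds one shared atom topology plus a coordinate slab,
# so topology constancy across models (the requirement that every model of a
# cryo-EM ensemble or every trajectory frame contain the same atoms in the
# same order) holds by construction.  Coordinates are Angstrom throughout.

#' Terminal charged side-chain atoms by residue type
#'
#' Static lookup of the side-chain atoms that carry the formal charge of the
#' five charged amino acids: the carboxylate oxygens of Asp/Glu and the
#' basic nitrogens of Lys/Arg/His.  Salt-bridge proxy distances are measured
#' between these atoms only (heavy atoms; hydrogens are ignored throughout).
#'
#' @format Named list mapping a 3-letter residue code to a character vector
#'   of atom names.
#' @export
terminal_atom_table <- list(
  ASP = c("OD1", "OD2"),
  GLU = c("OE1", "OE2"),
  LYS = "NZ",
  ARG = c("NE", "NH1", "NH2"),
  HIS = c("ND1", "NE2")
)

acidic_resnames <- c("ASP", "GLU")
basic_resnames  <- c("LYS", "ARG", "HIS")

#' Construct a structure ensemble
#'
#' @param atoms data.frame with one row per atom and columns `chain_id`,
#'   `resid`, `icode`, `resname`, `atom_name`, `element`, `altloc`,
#'   `is_hetero`.  The same topology is shared by every model.
#' @param coords numeric array of dimension `c(n_atoms, 3, n_models)`, in
#'   Angstrom.
#' @param source_label condition tag carried through downstream statistics
#'   (e.g. `"apo"`, `"Ca2+/CaM"`, `"NaCl"`, `"CaCl2"`).
#' @return An object of class `pdb_ensemble`.
#' @export
pdb_ensemble <- function(atoms, coords, source_label = "") {
  stopifnot(is.data.frame(atoms))
  need <- c("chain_id", "resid", "icode", "resname", "atom_name",
            "element", "altloc", "is_hetero")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols))
    stop("atoms is missing columns: ", paste(missing_cols, collapse = ", "))
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L)
    stop("coords must be an n_atoms x 3 x n_models array")
  if (nrow(atoms) == 0L) stop("empty-input error: ensemble has zero atoms")
  if (dim(coords)[1] != nrow(atoms))
    stop("coords row count does not match atom count")
  if (dim(coords)[3] < 1L) stop("ensemble must contain at least one model")
  if (!all(is.finite(coords))) stop("non-finite coordinates in ensemble")
  if (any(!nzchar(atoms$resname))) stop("empty resname in atom table")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, coords = coords,
                 source_label = as.character(source_label)),
            class = "pdb_ensemble")
}

#' @rdname pdb_ensemble
#' @param e a `pdb_ensemble`
#' @export
n_models <- function(e) dim(e$coords)[3]

#' @rdname pdb_ensemble
#' @export
n_atoms <- function(e) nrow(e$atoms)

#' @export
print.pdb_ensemble <- function(x, ...) {
  cat(sprintf("<pdb_ensemble> %d model(s), %d atoms, %d chain(s)%s\n",
              n_models(x), n_atoms(x), length(unique(x$atoms$chain_id)),
              if (nzchar(x$source_label))
                paste0(", label '", x$source_label, "'") else ""))
  invisible(x)
}

# Coordinates of model m as an n_atoms x 3 matrix.
model_coords <- function(e, m = 1L) {
  if (m < 1L || m > n_models(e))
    stop("model index ", m, " out of range (ensemble has ",
         n_models(e), " models)")
  matrix(e$coords[, , m], ncol = 3L)
}

#' Reference to a single residue
#'
#' Identifies one residue by author numbering exactly as written in the file
#' (no renumbering).  Insertion codes must match exactly during resolution.
#'
#' @param chain_id single-character chain identifier.
#' @param resid integer author residue number.
#' @param icode insertion code, `""` when absent.
#' @param resname optional 3-letter code; when given, resolution checks it.
#' @export
residue_ref <- function(chain_id, resid, icode = "", resname = NULL) {
  structure(list(chain_id = as.character(chain_id),
                 resid = as.integer(resid),
                 icode = as.character(icode),
                 resname = if (is.null(resname)) NULL else as.character(resname)),
            class = "residue_ref")
}

#' @exportS3Method base::format
format.residue_ref <- function(x, ...) {
  sprintf("%s%d%s/%s", x$resname %||% "", x$resid,
          if (nzchar(x$icode)) x$icode else "", x$chain_id)
}

#' @export
print.residue_ref <- function(x, ...) {
  cat("<residue_ref>", format(x), "\n"); invisible(x)
}

# Row indices of the atoms of the residue `ref` in the shared topology.
# Errors unless the reference resolves to exactly one residue.
resolve_residue <- function(e, ref) {
  a <- e$atoms
  sel <- a$chain_id == ref$chain_id & a$resid == ref$resid &
    a$icode == ref$icode
  if (!is.null(ref$resname)) sel <- sel & a$resname == ref$resname
  idx <- which(sel)
  if (length(idx) == 0L)
    stop("lookup error: residue ", format(ref), " not found")
  if (length(unique(a$resname[idx])) > 1L)
    stop("lookup error: residue ", format(ref),
         " resolves to more than one residue")
  idx
}

#' Terminal charged atoms present for one residue
#'
#' Looks up the side-chain terminal charged atoms of a residue
#' (see [terminal_atom_table]) and returns the names of those actually
#' present in the model.  Missing atoms are dropped with a warning;
#' a residue with none present is an error.
#'
#' @param e a `pdb_ensemble`.
#' @param ref a [residue_ref()].
#' @param model model index (topology is shared, so this only matters for
#'   error reporting).
#' @return Character vector of atom names, a subset of the static table.
#' @export
terminal_charged_atoms <- function(e, ref, model = 1L) {
  idx <- resolve_residue(e, ref)
  resname <- e$atoms$resname[idx[1]]
  expected <- terminal_atom_table[[resname]]
  if (is.null(expected))
    stop("unsupported-residue error: no terminal charged atoms defined for ",
         resname)
  present <- intersect(expected, e$atoms$atom_name[idx])
  missing <- setdiff(expected, present)
  if (length(present) == 0L)
    stop("empty-selection error: residue ", format(ref),
         " has none of its terminal charged atoms (",
         paste(expected, collapse = ", "), ")")
  if (length(missing))
    warning("residue ", format(ref), " is missing terminal atom(s): ",
            paste(missing, collapse = ", "), call. = FALSE)
  present
}

# ---- PDB text I/O ----------------------------------------------------------

#' Read a (multi-model) PDB file
#'
#' Parses the fixed-column ATOM/HETATM dialect into a [pdb_ensemble()].
#' `MODEL`/`ENDMDL` blocks delimit models; their absence means a single
#' model.  Topology constancy across models is verified.  Alternate
#' locations other than `' '` or `'A'` are dropped (with a message giving
#' the count), approximating the highest-occupancy convention
#' deterministically.  Hydrogens are kept in the atom table but all
#' geometric operations ignore them via their element.
#'
#' @param source path to a PDB file, or a character vector of lines, or a
#'   single string containing newlines.
#' @param keep_hetero ingest HETATM records (needed for ions and waters);
#'   default `FALSE`.
#' @param source_label condition tag to attach.
#' @return A `pdb_ensemble`.
#' @export
read_pdb <- function(source, keep_hetero = FALSE, source_label = "") {
  lines <- if (length(source) == 1L && !grepl("\n", source) &&
               file.exists(source)) readLines(source, warn = FALSE)
  else unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)

  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  is_model_open <- startsWith(lines, "MODEL")
  model_of <- cumsum(is_model_open)
  has_models <- any(is_model_open)
  if (!has_models) model_of[] <- 1L

  keep <- is_atom
  rec <- lines[keep]
  line_no <- which(keep)
  model_id <- model_of[keep]
  if (has_models && any(model_id == 0L))
    stop("parse error: coordinate record before first MODEL at line ",
         line_no[which(model_id == 0L)[1]])
  if (length(rec) == 0L) stop("empty-input error: no coordinate records")

  rec <- formatC(rec, width = 80, flag = "-")  # pad short lines
  hetero <- startsWith(rec, "HETATM")
  atom_name <- trimws(substr(rec, 13, 16))
  altloc <- substr(rec, 17, 17)
  resname <- trimws(substr(rec, 18, 20))
  chain_id <- substr(rec, 22, 22)
  resid_s <- trimws(substr(rec, 23, 26))
  icode <- sub(" ", "", substr(rec, 27, 27), fixed = TRUE)
  xs <- substr(rec, 31, 38); ys <- substr(rec, 39, 46); zs <- substr(rec, 47, 54)
  element <- trimws(substr(rec, 77, 78))

  num <- function(s, what) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v) | !nzchar(trimws(s)))
    if (length(bad))
      stop("parse error: malformed ", what, " field at line ", line_no[bad[1]])
    v
  }
  x <- num(xs, "x"); y <- num(ys, "y"); z <- num(zs, "z")
  resid <- suppressWarnings(as.integer(resid_s))
  if (anyNA(resid))
    stop("parse error: malformed residue number at line ",
         line_no[which(is.na(resid))[1]])

  drop <- !(altloc %in% c(" ", "A"))
  if (!keep_hetero) drop <- drop | hetero
  n_alt <- sum(!(altloc %in% c(" ", "A")))
  if (n_alt > 0L)
    message("read_pdb: dropped ", n_alt,
            " atom(s) with alternate location other than ' '/'A'")
  if (all(drop)) stop("empty-input error: no coordinate records retained")

  keep_i <- !drop
  model_id <- model_id[keep_i]
  atoms <- data.frame(
    chain_id = chain_id[keep_i], resid = resid[keep_i], icode = icode[keep_i],
    resname = resname[keep_i], atom_name = atom_name[keep_i],
    element = element[keep_i],
    altloc = sub(" ", "", altloc[keep_i], fixed = TRUE),
    is_hetero = hetero[keep_i], stringsAsFactors = FALSE)
  xyz <- cbind(x[keep_i], y[keep_i], z[keep_i])

  models <- unique(model_id)
  key <- paste(atoms$chain_id, atoms$resid, atoms$icode, atoms$resname,
               atoms$atom_name, sep = "|")
  first <- key[model_id == models[1]]
  coords <- array(NA_real_, dim = c(length(first), 3L, length(models)))
  for (j in seq_along(models)) {
    sel <- model_id == models[j]
    if (sum(sel) != length(first) || !identical(key[sel], first))
      stop("ensemble error: topology of model ", models[j],
           " does not match model ", models[1])
    coords[, , j] <- xyz[sel, , drop = FALSE]
  }
  topo <- atoms[model_id == models[1], , drop = FALSE]
  pdb_ensemble(topo, coords, source_label = source_label)
}

#' Write a structure ensemble as PDB text
#'
#' Emits fixed-column ATOM/HETATM records, wrapped in `MODEL`/`ENDMDL`
#' blocks when the ensemble holds more than one model, terminated by `END`.
#' Coordinates are written to 3 decimals; `write_pdb(read_pdb(x))` is
#' byte-stable on text produced by this writer.
#'
#' @param e a `pdb_ensemble`.
#' @param path optional file path; when given, the text is also written there.
#' @return The PDB text as a single string, invisibly when `path` is given.
#' @export
write_pdb <- function(e, path = NULL) {
  stopifnot(inherits(e, "pdb_ensemble"))
  if (any(nchar(sprintf("%8.3f", e$coords)) > 8L))
    stop("format-overflow error: coordinate does not fit the 8.3 PDB field")
  a <- e$atoms
  nm <- ifelse(nchar(a$atom_name) >= 4L | nchar(a$element) == 2L,
               formatC(a$atom_name, width = -4),
               paste0(" ", formatC(a$atom_name, width = -3)))
  fmt_model <- function(m) {
    xyz <- model_coords(e, m)
    sprintf("%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            ifelse(a$is_hetero, "HETATM", "ATOM"), seq_len(nrow(a)), nm,
            ifelse(nzchar(a$altloc), a$altloc, " "), a$resname, a$chain_id,
            a$resid, ifelse(nzchar(a$icode), a$icode, " "),
            xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, a$element)
  }
  out <- if (n_models(e) > 1L) {
    unlist(lapply(seq_len(n_models(e)), function(m)
      c(sprintf("MODEL     %4d", m), fmt_model(m), "ENDMDL")))
  } else fmt_model(1L)
  txt <- paste0(paste(c(out, "END"), collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(sub("\n$", "", txt), path)
    return(invisible(txt))
  }
  txt
}
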