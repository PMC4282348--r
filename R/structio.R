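# Structure input/output and residue correspondence.
#
# A structure is a list(id, source, atoms) where atoms is one row per heavy
# atom with columns chain, resno, icode, resid (3-letter code), elety (atom
# name), x, y, z, o (occupancy).  Hydrogens, waters and HETATM records are
# dropped on reading; alternate locations are resolved to a single atom.

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

MAINCHAIN_ATOMS <- c("N", "CA", "C", "O")

new_structure <- function(id, source, atoms) {
  stopifnot(is.data.frame(atoms))
  need <- c("chain", "resno", "icode", "resid", "elety", "x", "y", "z", "o")
  if (!all(need %in% names(atoms)))
    stop("atoms table is missing columns: ",
         paste(setdiff(need, names(atoms)), collapse = ", "))
  if (nrow(atoms) == 0L) stop("structure '", id, "' has no atoms")
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("structure '", id, "' has non-finite coordinates")
  akey <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$elety)
  if (anyDuplicated(akey))
    stop("duplicate atom (residue, name) in structure '", id, "'")
  rownames(atoms) <- NULL
  structure(list(id = id, source = source, atoms = atoms),
            class = "ref_structure")
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM records (wwPDB v3.3 fixed columns, via \pkg{bio3d}),
#' dropping HETATM records, waters and hydrogens.  Alternate locations are
#' resolved to the highest-occupancy copy, first listed on ties.  All
#' chains are read and kept in file order; author residue numbering is
#' preserved verbatim.
#'
#' @param path Path to a PDB file containing at least one ATOM record.
#' @param source One of `"prediction"`, `"native"`, `"starting"`; recorded
#'   on the returned object.
#' @param id Structure identifier; defaults to the file name without
#'   extension.
#' @return An object of class `ref_structure`: a list with elements `id`,
#'   `source` and `atoms` (one row per heavy atom).
#' @seealso [write_pdb()], [map_common_residues()]
#' @export
read_pdb <- function(path, source = c("prediction", "native", "starting"),
                     id = NULL) {
  source <- match.arg(source)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  atom_idx <- grep("^ATOM", lines)
  if (length(atom_idx) == 0L)
    stop("parse error in '", path, "': no ATOM record found (line 1)")
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE,
                                     rm.alt = FALSE)),
    error = function(e)
      stop("parse error in '", path, "' near line ", atom_idx[1L], ": ",
           conditionMessage(e))
  )
  a <- pdb$atom
  a <- a[a$type == "ATOM", , drop = FALSE]
  bad <- which(!is.finite(a$x) | !is.finite(a$y) | !is.finite(a$z))
  if (length(bad) > 0L)
    stop("parse error in '", path, "': unreadable coordinates at line ",
         atom_idx[min(bad[1L], length(atom_idx))])
  # drop waters and hydrogens/deuteriums
  a <- a[!(a$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  elem <- ifelse(is.na(a$elesy) | a$elesy == "",
                 substr(gsub("[0-9']", "", a$elety), 1L, 1L),
                 toupper(trimws(a$elesy)))
  a <- a[!(elem %in% c("H", "D")), , drop = FALSE]
  if (nrow(a) == 0L)
    stop("parse error in '", path, "': no heavy protein atoms")
  a$chain <- ifelse(is.na(a$chain), "A", a$chain)
  a$insert <- ifelse(is.na(a$insert), "", a$insert)
  a$o <- ifelse(is.na(a$o), 1, a$o)
  # altloc resolution: highest occupancy, first listed on ties
  akey <- paste(a$chain, a$resno, a$insert, a$elety, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(a)), akey),
                        function(ix) ix[which.max(a$o[ix])]),
                 use.names = FALSE)
  a <- a[sort(keep), , drop = FALSE]
  atoms <- data.frame(chain = a$chain, resno = a$resno, icode = a$insert,
                      resid = a$resid, elety = a$elety,
                      x = a$x, y = a$y, z = a$z,
                      o = pmin(pmax(a$o, 0), 1),
                      stringsAsFactors = FALSE)
  new_structure(id %||% sub("\\.(pdb|ent)$", "", basename(path)),
                source, atoms)
}

#' Write a structure as a minimal PDB file
#'
#' Emits ATOM records (one per heavy atom, occupancy as stored, B-factor
#' 0), a TER record per chain and END.  Coordinates are written to three
#' decimals, so [read_pdb()] round-trips them exactly at that precision.
#'
#' @param s A `ref_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  stopifnot(inherits(s, "ref_structure"))
  a <- s$atoms
  name4 <- ifelse(nchar(a$elety) >= 4L, substr(a$elety, 1L, 4L),
                  sprintf(" %-3s", a$elety))
  elem <- substr(gsub("[0-9']", "", a$elety), 1L, 1L)
  rec <- sprintf("ATOM  %5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                 seq_len(nrow(a)), name4, a$resid, a$chain, a$resno,
                 ifelse(a$icode == "", " ", a$icode),
                 a$x, a$y, a$z, a$o, 0, elem)
  # TER after the last atom of each chain (file order)
  out <- character(0)
  for (ch in unique(a$chain)) {
    out <- c(out, rec[a$chain == ch], "TER")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' @export
print.ref_structure <- function(x, ...) {
  rk <- residue_keys(x)
  cat(sprintf("<ref_structure> %s (%s): %d residues, %d heavy atoms, chains %s\n",
              x$id, x$source, nrow(rk), nrow(x$atoms),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Residues of a structure in atom-file order
#'
#' @param s A `ref_structure`.
#' @return Data frame with one row per residue: `chain`, `resno`,
#'   `icode`, `resid`, and the internal `key` string used for matching.
#' @export
residue_keys <- function(s) {
  a <- s$atoms
  key <- paste(a$chain, a$resno, a$icode, sep = "\r")
  first <- !duplicated(key)
  data.frame(chain = a$chain[first], resno = a$resno[first],
             icode = a$icode[first], resid = a$resid[first],
             key = key[first], stringsAsFactors = FALSE)
}

heavy_atom_count <- function(s) nrow(s$atoms)

#' Pair model and target residues by author numbering
#'
#' Residues are paired by identical (chain, residue number, insertion
#' code); residues present on only one side are excluded and the pair
#' order follows the target.  A residue-name mismatch at a shared key is
#' retained but flagged, since submissions occasionally carry sequence
#' errors.
#'
#' @param model,target `ref_structure` objects.
#' @return An object of class `residue_map`: list with `pairs` (data frame
#'   with chain, resno, icode, target and model residue names, mismatch
#'   flag), `n_common` and `n_mismatch`.
#' @export
map_common_residues <- function(model, target) {
  stopifnot(inherits(model, "ref_structure"), inherits(target, "ref_structure"))
  rt <- residue_keys(target)
  rm_ <- residue_keys(model)
  i <- match(rt$key, rm_$key)
  sel <- !is.na(i)
  if (!any(sel)) stop("no residues in common between '", model$id,
                      "' and '", target$id, "'")
  pairs <- data.frame(chain = rt$chain[sel], resno = rt$resno[sel],
                      icode = rt$icode[sel], key = rt$key[sel],
                      resid_target = rt$resid[sel],
                      resid_model = rm_$resid[i[sel]],
                      stringsAsFactors = FALSE)
  pairs$mismatch <- pairs$resid_target != pairs$resid_model
  structure(list(pairs = pairs, n_common = nrow(pairs),
                 n_mismatch = sum(pairs$mismatch)),
            class = "residue_map")
}

#' @export
print.residue_map <- function(x, ...) {
  cat(sprintf("<residue_map> %d paired residues (%d name mismatches)\n",
              x$n_common, x$n_mismatch))
  invisible(x)
}

#' Accept or reject a submission against its starting model
#'
#' A refinement submission is discarded when it has fewer heavy atoms
#' than the starting model it was derived from: it either lost residues
#' or is not an all-atom model, and cannot be scored on an equal footing.
#'
#' @param model Submitted `ref_structure`.
#' @param starting The starting model for the same target.
#' @return List with `accept` (logical), `reason`, `n_model`,
#'   `n_starting`.
#' @export
validate_submission <- function(model, starting) {
  nm <- heavy_atom_count(model)
  ns <- heavy_atom_count(starting)
  if (nm < ns) {
    list(accept = FALSE,
         reason = sprintf("fewer atoms than starting model (%d < %d)", nm, ns),
         n_model = nm, n_starting = ns)
  } else {
    list(accept = TRUE, reason = "", n_model = nm, n_starting = ns)
  }
}

# --- paired coordinate extraction -------------------------------------

# coordinates of one named atom for every paired residue having it in
# both structures; rows follow the map (i.e. target) order
paired_atom_coords <- function(model, target, map, elety = "CA") {
  stopifnot(inherits(map, "residue_map"))
  tm <- atom_lookup(target, elety)
  mm <- atom_lookup(model, elety)
  it <- match(map$pairs$key, tm$key)
  im <- match(map$pairs$key, mm$key)
  sel <- !is.na(it) & !is.na(im)
  list(model = as.matrix(mm[im[sel], c("x", "y", "z")]),
       target = as.matrix(tm[it[sel], c("x", "y", "z")]),
       key = map$pairs$key[sel])
}

atom_lookup <- function(s, elety) {
  a <- s$atoms[s$atoms$elety == elety, , drop = FALSE]
  data.frame(key = paste(a$chain, a$resno, a$icode, sep = "\r"),
             x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
}

# full-atom correspondence over paired residues: all target atoms, with
# model counterparts matched by (residue key, atom name); `present` marks
# atoms the model actually has
matched_atoms <- function(model, target, map) {
  at <- target$atoms
  tkey <- paste(at$chain, at$resno, at$icode, sep = "\r")
  keep <- tkey %in% map$pairs$key
  at <- at[keep, , drop = FALSE]
  tkey <- tkey[keep]
  am <- model$atoms
  mfull <- paste(am$chain, am$resno, am$icode, am$elety, sep = "\r")
  i <- match(paste(tkey, at$elety, sep = "\r"), mfull)
  present <- !is.na(i)
  mcoord <- matrix(NA_real_, nrow(at), 3)
  mcoord[present, ] <- as.matrix(am[i[present], c("x", "y", "z")])
  list(target = as.matrix(at[, c("x", "y", "z")]),
       model = mcoord, present = present,
       res_key = tkey, elety = at$elety)
}
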