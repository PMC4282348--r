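# The five per-model quality measures: GDT-HA, Calpha RMSD, GDC-SC,
# SphereGrinder, and the externally supplied MolProbity score.

GDT_HA_CUTOFFS <- c(0.5, 1, 2, 4)
GDC_SC_CUTOFFS <- seq(0.5, 5, by = 0.5)

#' Characteristic side-chain atom per residue type
#'
#' GDC-SC represents each side chain by a single, amino-acid-dependent
#' atom; the default table uses the distal functional atom of each of the
#' 19 non-glycine standard residues and ships as an editable TSV under
#' `inst/extdata/characteristic_atoms.tsv`.
#'
#' @param path Optional path to a two-column TSV (resname, atom) to
#'   replace the default table.
#' @return Named character vector mapping residue name to atom name.
#' @export
characteristic_atom_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "characteristic_atoms.tsv",
                                package = "refassess", mustWork = TRUE)
  tb <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  setNames(tb$atom, tb$resname)
}

#' High-accuracy Global Distance Test
#'
#' Arithmetic mean of the GDT inlier percentage at the 0.5, 1, 2 and 4
#' Angstrom cutoffs, each under its own best superposition, over the
#' paired Calpha atoms.
#'
#' @param model,target `ref_structure` objects.
#' @param map Their [map_common_residues()] correspondence.
#' @param cutoffs Distance cutoffs in Angstrom.
#' @param exclude Optional residue-key character vector to drop before
#'   scoring (masked re-evaluation).
#' @return Percentage in \[0, 100\].
#' @export
gdt_ha <- function(model, target, map, cutoffs = GDT_HA_CUTOFFS,
                   exclude = NULL) {
  ca <- paired_atom_coords(model, target, map, "CA")
  if (!is.null(exclude)) {
    keep <- !(ca$key %in% exclude)
    if (sum(keep) < 3L) stop("fewer than 3 residues remain after masking")
    ca$model <- ca$model[keep, , drop = FALSE]
    ca$target <- ca$target[keep, , drop = FALSE]
  }
  mean(gdt_fractions(ca$model, ca$target, cutoffs))
}

#' Calpha RMSD after optimal superposition
#' @inheritParams gdt_ha
#' @return RMSD in Angstrom.
#' @export
ca_rmsd <- function(model, target, map) {
  ca <- paired_atom_coords(model, target, map, "CA")
  kabsch(ca$model, ca$target)$rmsd
}

#' Side-chain Global Distance Calculation (GDC-SC)
#'
#' Threshold-weighted mean of GDT inlier percentages computed on one
#' characteristic side-chain atom per paired residue, over ten cutoffs
#' 0.5, 1.0, ..., 5.0 Angstrom with linearly decreasing weights
#' w_i = (k - i + 1) / sum(1..k), k = 10, so tighter thresholds dominate.
#' Glycine has no side chain and never contributes.  When the named atom
#' is absent from both structures (e.g. reduced side-chain
#' representations) the beta carbon substitutes if `cb_fallback` is TRUE.
#'
#' @inheritParams gdt_ha
#' @param table Characteristic-atom table, see
#'   [characteristic_atom_table()].
#' @param cutoffs The ten distance thresholds in Angstrom.
#' @param cb_fallback Substitute CB when the characteristic atom is
#'   missing from the target.
#' @return Percentage in \[0, 100\].
#' @export
gdc_sc <- function(model, target, map, table = characteristic_atom_table(),
                   cutoffs = GDC_SC_CUTOFFS, cb_fallback = TRUE) {
  sel <- gdc_atom_coords(model, target, map, table, cb_fallback)
  if (nrow(sel$model) < 3L)
    stop("fewer than 3 paired residues carry a characteristic atom")
  ci <- gdt_fractions(sel$model, sel$target, cutoffs)
  sum(gdc_weights(length(cutoffs)) * ci)
}

# linearly decreasing threshold weights w_i = (k - i + 1) / sum(1..k);
# they sum to 1 exactly
gdc_weights <- function(k) {
  (k - seq_len(k) + 1) / (k * (k + 1) / 2)
}

# one characteristic atom per paired residue, present in both structures
gdc_atom_coords <- function(model, target, map, table, cb_fallback) {
  pr <- map$pairs
  at <- target$atoms
  am <- model$atoms
  tfull <- paste(at$chain, at$resno, at$icode, at$elety, sep = "\r")
  mfull <- paste(am$chain, am$resno, am$icode, am$elety, sep = "\r")
  want <- table[pr$resid_target]
  ok <- !is.na(want)  # glycine and nonstandard residues drop out
  keys <- pr$key[ok]
  want <- want[ok]
  it <- match(paste(keys, want, sep = "\r"), tfull)
  if (cb_fallback) {
    miss <- is.na(it)
    it[miss] <- match(paste(keys[miss], "CB", sep = "\r"), tfull)
    want[miss] <- "CB"
  }
  im <- match(paste(keys, want, sep = "\r"), mfull)
  sel <- !is.na(it) & !is.na(im)
  list(model = as.matrix(am[im[sel], c("x", "y", "z")]),
       target = as.matrix(at[it[sel], c("x", "y", "z")]),
       key = keys[sel])
}

#' SphereGrinder local-environment score
#'
#' For every target residue, the target atoms within `radius` (default 6)
#' Angstrom of its Calpha define a local sphere.  The model counterparts
#' of those atoms (matched by residue key and atom name) are superposed
#' onto the sphere by Kabsch, and the fraction within `tol` (default 2)
#' Angstrom is recorded; atoms the model lacks count as outside.  The
#' score is 100 times the mean fraction over all spheres holding at least
#' 3 target atoms.  Spheres with fewer than 3 matched atoms cannot be
#' superposed and score 0.
#'
#' @inheritParams gdt_ha
#' @param radius Sphere radius around each Calpha, Angstrom (inclusive).
#' @param tol Counterpart distance tolerance, Angstrom (inclusive).
#' @return Percentage in \[0, 100\].
#' @export
sphere_grinder <- function(model, target, map, radius = 6, tol = 2) {
  ma <- matched_atoms(model, target, map)
  ca_rows <- which(ma$elety == "CA")
  if (length(ca_rows) == 0L) stop("target has no Calpha atoms")
  Tall <- ma$target
  pres <- which(ma$present)
  if (length(pres) < 3L) stop("no residue sphere has 3 matched atoms")
  # rows of the matched (present-in-both) submatrices
  row_of <- match(seq_len(nrow(Tall)), pres)  # NA where absent
  idx_list <- vector("list", length(ca_rows))
  n_total <- integer(length(ca_rows))
  r2 <- radius^2
  for (i in seq_along(ca_rows)) {
    ctr <- Tall[ca_rows[i], ]
    d2 <- (Tall[, 1] - ctr[1])^2 + (Tall[, 2] - ctr[2])^2 +
      (Tall[, 3] - ctr[3])^2
    memb <- which(d2 <= r2)
    n_total[i] <- length(memb)
    sub <- row_of[memb]
    idx_list[[i]] <- as.integer(sub[!is.na(sub)] - 1L)  # 0-based
  }
  qualify <- n_total >= 3L
  if (!any(qualify)) stop("no residue sphere holds 3 or more atoms")
  f <- sphere_fracs_cpp(ma$model[pres, , drop = FALSE],
                        ma$target[pres, , drop = FALSE],
                        idx_list[qualify], n_total[qualify], tol)
  100 * mean(f)
}

#' Read a two-column external score table
#'
#' External scalar scores (MolProbity, LLG) arrive as tab-separated
#' tables with columns `model_id` and `value`; `#` comment lines are
#' ignored.  Duplicate model ids are an error.
#'
#' @param path TSV path.
#' @return Data frame with columns `model_id`, `value`.
#' @export
read_score_table <- function(path) {
  tb <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  names(tb)[1:2] <- c("model_id", "value")
  if (anyDuplicated(tb$model_id))
    stop("duplicate model id in score table '", path, "': ",
         tb$model_id[duplicated(tb$model_id)][1L])
  tb
}

#' Join external scores onto model ids
#'
#' Scores are joined by model id.  Ids missing from the table yield NA
#' and are flagged in the `absent` attribute; they are never defaulted
#' or imputed, and downstream Z statistics exclude them.
#'
#' @param ids Character vector of model ids.
#' @param table Data frame from [read_score_table()].
#' @return Named numeric vector of scores (NA where absent), with
#'   attribute `absent` listing the missing ids.
#' @export
attach_external_scores <- function(ids, table) {
  if (anyDuplicated(table$model_id))
    stop("duplicate model id in score table: ",
         table$model_id[duplicated(table$model_id)][1L])
  v <- setNames(table$value[match(ids, table$model_id)], ids)
  attr(v, "absent") <- ids[is.na(v)]
  v
}

#' Compute the full metric vector for one model
#'
#' Convenience wrapper returning the five quality measures of a model
#' against its target: `gdt_ha`, `rmsd`, `gdc_sc`, `sphgr` and the
#' externally supplied `mp` (NA when absent).
#'
#' @inheritParams gdt_ha
#' @param mp External MolProbity score for this model, or NA.
#' @param table Characteristic-atom table for GDC-SC.
#' @return Named list with the five scores and `n_common`.
#' @export
compute_metrics <- function(model, target, map = NULL, mp = NA_real_,
                            table = characteristic_atom_table()) {
  if (is.null(map)) map <- map_common_residues(model, target)
  list(gdt_ha = gdt_ha(model, target, map),
       rmsd = ca_rmsd(model, target, map),
       gdc_sc = gdc_sc(model, target, map, table),
       sphgr = sphere_grinder(model, target, map),
       mp = mp,
       n_common = map$n_common)
}
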