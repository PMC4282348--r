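# Geometric hydrogen-bond assignment and model-vs-target comparison.
#
# Structures carry no hydrogens, so bonds are assigned from heavy-atom
# geometry alone: a donor-acceptor pair is bonded when the heavy-atom
# distance is at most 3.5 A and the antecedent-donor-acceptor angle is at
# least 90 degrees.  Covalently adjacent pairs (same residue, or a
# backbone amide against the preceding residue's carbonyl oxygen) are
# excluded.  Thresholds are arguments, the contract is ordinal group
# comparison rather than identity with any particular assignment program.

# side-chain donor atoms with the antecedent used for the angle check
SC_DONORS <- data.frame(
  resid = c("SER", "THR", "TYR", "CYS", "LYS", "ARG", "ARG", "ARG",
            "ASN", "GLN", "HIS", "HIS", "TRP"),
  atom = c("OG", "OG1", "OH", "SG", "NZ", "NE", "NH1", "NH2",
           "ND2", "NE2", "ND1", "NE2", "NE1"),
  ante = c("CB", "CB", "CZ", "CB", "CE", "CD", "CZ", "CZ",
           "CG", "CD", "CG", "CD2", "CD1"),
  stringsAsFactors = FALSE)

SC_ACCEPTORS <- data.frame(
  resid = c("ASN", "ASP", "ASP", "GLN", "GLU", "GLU", "HIS", "HIS",
            "SER", "THR", "TYR", "MET", "CYS"),
  atom = c("OD1", "OD1", "OD2", "OE1", "OE1", "OE2", "ND1", "NE2",
           "OG", "OG1", "OH", "SD", "SG"),
  stringsAsFactors = FALSE)

#' Assign hydrogen bonds from heavy-atom geometry
#'
#' Donors are backbone amide nitrogens (except proline) and standard
#' side-chain N/O/S donors; acceptors are backbone carbonyl oxygens
#' (including OXT) and standard side-chain N/O/S acceptors.  A bond is
#' recorded when the donor-acceptor distance is at most `dist_max` and
#' the angle antecedent-donor-acceptor is at least `angle_min` degrees.
#' Each (donor atom, acceptor atom) pair is listed once.
#'
#' @param s `ref_structure`.
#' @param dist_max Heavy-atom donor-acceptor distance cutoff, Angstrom.
#' @param angle_min Minimum antecedent-donor-acceptor angle, degrees.
#' @return Object of class `hbond_set`: data frame of bonds (donor and
#'   acceptor residue key fields and atom names, `mainchain` flag), with
#'   attributes `n_all` and `n_mainchain`.  May hold zero rows.
#' @export
assign_hbonds <- function(s, dist_max = 3.5, angle_min = 90) {
  stopifnot(inherits(s, "ref_structure"))
  a <- s$atoms
  rkey <- paste(a$chain, a$resno, a$icode, sep = "\r")
  full <- paste(rkey, a$elety, sep = "\r")
  rk <- residue_keys(s)
  res_ord <- match(rkey, rk$key)  # ordinal residue index, file order

  # donors: backbone N (not PRO, needs CA antecedent) + side chains
  don <- data.frame(idx = integer(0), ante = integer(0))
  bbN <- which(a$elety == "N" & a$resid != "PRO")
  anteCA <- match(paste(rkey[bbN], "CA", sep = "\r"), full)
  ok <- !is.na(anteCA)
  don <- rbind(don, data.frame(idx = bbN[ok], ante = anteCA[ok]))
  for (r in seq_len(nrow(SC_DONORS))) {
    d <- which(a$resid == SC_DONORS$resid[r] & a$elety == SC_DONORS$atom[r])
    if (length(d) == 0L) next
    an <- match(paste(rkey[d], SC_DONORS$ante[r], sep = "\r"), full)
    ok <- !is.na(an)
    don <- rbind(don, data.frame(idx = d[ok], ante = an[ok]))
  }

  acc <- which(a$elety %in% c("O", "OXT"))
  for (r in seq_len(nrow(SC_ACCEPTORS))) {
    acc <- c(acc, which(a$resid == SC_ACCEPTORS$resid[r] &
                          a$elety == SC_ACCEPTORS$atom[r]))
  }
  acc <- sort(unique(acc))

  empty <- data.frame(donor_chain = character(0), donor_resno = integer(0),
                      donor_icode = character(0), donor_atom = character(0),
                      acceptor_chain = character(0),
                      acceptor_resno = integer(0),
                      acceptor_icode = character(0),
                      acceptor_atom = character(0),
                      mainchain = logical(0), stringsAsFactors = FALSE)
  if (nrow(don) == 0L || length(acc) == 0L)
    return(new_hbond_set(empty))

  xyz <- as.matrix(a[, c("x", "y", "z")])
  # all donor-acceptor combinations
  nd <- nrow(don); na_ <- length(acc)
  di <- rep(seq_len(nd), times = na_)
  ai <- rep(acc, each = nd)
  D <- don$idx[di]
  dv <- xyz[ai, , drop = FALSE] - xyz[D, , drop = FALSE]
  dist2 <- rowSums(dv * dv)
  sel <- dist2 <= dist_max^2 & dist2 > 0
  # same-residue exclusion
  sel <- sel & rkey[D] != rkey[ai]
  # covalent adjacency: donor backbone N against previous residue's O
  prev <- a$elety[D] == "N" & a$elety[ai] == "O" &
    res_ord[D] == res_ord[ai] + 1L & a$chain[D] == a$chain[ai]
  sel <- sel & !prev
  idx <- which(sel)
  if (length(idx) == 0L) return(new_hbond_set(empty))
  # angle criterion: antecedent-donor-acceptor >= angle_min
  An <- don$ante[di[idx]]
  v1 <- xyz[An, , drop = FALSE] - xyz[D[idx], , drop = FALSE]
  v2 <- xyz[ai[idx], , drop = FALSE] - xyz[D[idx], , drop = FALSE]
  cosang <- rowSums(v1 * v2) /
    (sqrt(rowSums(v1 * v1)) * sqrt(rowSums(v2 * v2)))
  keep <- idx[cosang <= cos(angle_min * pi / 180) + 1e-12]
  if (length(keep) == 0L) return(new_hbond_set(empty))
  Dk <- D[keep]; Ak <- ai[keep]
  bonds <- data.frame(donor_chain = a$chain[Dk], donor_resno = a$resno[Dk],
                      donor_icode = a$icode[Dk], donor_atom = a$elety[Dk],
                      acceptor_chain = a$chain[Ak],
                      acceptor_resno = a$resno[Ak],
                      acceptor_icode = a$icode[Ak],
                      acceptor_atom = a$elety[Ak],
                      mainchain = a$elety[Dk] == "N" & a$elety[Ak] == "O",
                      stringsAsFactors = FALSE)
  bonds <- bonds[order(bonds$donor_chain, bonds$donor_resno,
                       bonds$donor_icode, bonds$donor_atom,
                       bonds$acceptor_chain, bonds$acceptor_resno,
                       bonds$acceptor_icode, bonds$acceptor_atom), ,
                 drop = FALSE]
  rownames(bonds) <- NULL
  new_hbond_set(bonds)
}

new_hbond_set <- function(bonds) {
  structure(bonds, class = c("hbond_set", "data.frame"),
            n_all = nrow(bonds), n_mainchain = sum(bonds$mainchain))
}

#' @export
print.hbond_set <- function(x, ...) {
  cat(sprintf("<hbond_set> %d bonds (%d main chain)\n",
              attr(x, "n_all"), attr(x, "n_mainchain")))
  invisible(x)
}

hbond_ids <- function(set, scope = c("all", "mainchain")) {
  scope <- match.arg(scope)
  b <- as.data.frame(set)
  if (scope == "mainchain") b <- b[b$mainchain, , drop = FALSE]
  paste(b$donor_chain, b$donor_resno, b$donor_icode, b$donor_atom,
        b$acceptor_chain, b$acceptor_resno, b$acceptor_icode,
        b$acceptor_atom, sep = "\r")
}

#' Precision/recall/F1 of a model's hydrogen-bond set
#'
#' Bond identity is the (donor residue key, donor atom, acceptor residue
#' key, acceptor atom) quadruple, so bonds in the model are true
#' positives when the target holds the same bond.  Degenerate cases
#' (empty denominators) score 0.
#'
#' @param model_set,target_set [assign_hbonds()] sets computed on
#'   correspondence-matched residue numbering.
#' @param scope `"all"` for every bond, `"mainchain"` for bonds between
#'   backbone N and O only.
#' @return Object of class `prf`: list with `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`.
#' @export
hbond_prf <- function(model_set, target_set, scope = c("all", "mainchain")) {
  scope <- match.arg(scope)
  m <- hbond_ids(model_set, scope)
  t_ <- hbond_ids(target_set, scope)
  tp <- length(intersect(m, t_))
  fp <- length(setdiff(m, t_))
  fn <- length(setdiff(t_, m))
  precision <- if (tp + fp > 0L) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0L) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall /
    (precision + recall) else 0
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1), class = "prf")
}

#' @export
print.prf <- function(x, ...) {
  cat(sprintf("<prf> tp %d fp %d fn %d | precision %.3f recall %.3f F1 %.3f\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Group scores from hydrogen-bond F1 values
#'
#' Turns per-model F1 scores into target-wise robust Z-scores (higher F1
#' better), clips negative Z to zero, and scores each group by the median
#' of its clipped Z over targets.
#'
#' @param f1_records Data frame with columns `group`, `target`, `f1`,
#'   one row per assessed model (model 1 per group per target).
#' @param variant,mad_constant Passed to [robust_z()].
#' @return Data frame with `group`, `n_targets`, `median_z`, sorted
#'   descending.
#' @export
hbond_group_scores <- function(f1_records, variant = c("mad", "mean_sd"),
                               mad_constant = 1) {
  variant <- match.arg(variant)
  stopifnot(all(c("group", "target", "f1") %in% names(f1_records)))
  recs <- f1_records
  recs$z <- NA_real_
  for (t_ in unique(recs$target)) {
    i <- which(recs$target == t_)
    if (length(i) < 2L)
      stop("target '", t_, "' has fewer than 2 models")
    z <- robust_z(recs$f1[i], variant = variant, mad_constant = mad_constant)
    recs$z[i] <- pmax(z, 0)
  }
  med <- vapply(split(recs$z, recs$group), median, numeric(1))
  out <- data.frame(group = names(med),
                    n_targets = as.integer(table(recs$group)[names(med)]),
                    median_z = as.numeric(med), stringsAsFactors = FALSE)
  out <- out[order(-out$median_z, out$group), , drop = FALSE]
  rownames(out) <- NULL
  out
}
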