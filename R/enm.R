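# Hookean elastic-network deformation energy.
#
# A pairwise Calpha network with uniform spring constant approximates the
# deformation energy between two conformations.  Because the energy is a
# function of internal distances only, it is invariant to rigid motion
# and needs no superposition.  The contract is ordinal (thermal-ensemble
# filtering, ranking how adventurous a refinement move is); absolute
# values are not calibrated against any particular normal-mode model.

#' Build a Calpha elastic network
#'
#' Every Calpha pair within `cutoff` Angstrom in the reference structure
#' becomes a Hookean spring at its reference distance.
#'
#' @param reference `ref_structure` providing the rest geometry.
#' @param cutoff Spring distance cutoff in Angstrom.
#' @param k Uniform spring constant, kcal/mol/Angstrom^2.
#' @return Object of class `elastic_network`: list with `keys` (residue
#'   keys of the nodes), `coords`, `springs` (i, j, d0), `k`, `cutoff`.
#' @export
build_network <- function(reference, cutoff = 12, k = 1) {
  stopifnot(inherits(reference, "ref_structure"))
  ca <- reference$atoms[reference$atoms$elety == "CA", , drop = FALSE]
  if (nrow(ca) < 2L) stop("reference has fewer than 2 Calpha atoms")
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  d <- as.matrix(dist(xyz))
  sel <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  if (nrow(sel) == 0L)
    stop("no Calpha pair within ", cutoff, " A: cutoff too small")
  springs <- data.frame(i = sel[, 1], j = sel[, 2],
                        d0 = d[sel])
  structure(list(keys = paste(ca$chain, ca$resno, ca$icode, sep = "\r"),
                 coords = xyz, springs = springs, k = k, cutoff = cutoff),
            class = "elastic_network")
}

#' @export
print.elastic_network <- function(x, ...) {
  cat(sprintf("<elastic_network> %d nodes, %d springs (cutoff %.1f A, k %.2f)\n",
              length(x$keys), nrow(x$springs), x$cutoff, x$k))
  invisible(x)
}

#' Deformation energy of a conformation against a network
#'
#' Sum over springs of k/2 (d - d0)^2, where d is the distance between
#' the corresponding Calpha atoms in `other`.  Every network node must
#' have a counterpart (matched by residue key) in `other`.
#'
#' @param net An [build_network()] elastic network.
#' @param other `ref_structure` to evaluate.
#' @return Object of class `deformation_energy`: list with `total`
#'   (kcal/mol), `per_residue` (total / number of nodes) and `n`.
#' @export
deformation_energy <- function(net, other) {
  stopifnot(inherits(net, "elastic_network"), inherits(other, "ref_structure"))
  ca <- other$atoms[other$atoms$elety == "CA", , drop = FALSE]
  okey <- paste(ca$chain, ca$resno, ca$icode, sep = "\r")
  i <- match(net$keys, okey)
  if (anyNA(i))
    stop("structure '", other$id, "' is missing a Calpha for ",
         sum(is.na(i)), " network node(s)")
  xyz <- as.matrix(ca[i, c("x", "y", "z")])
  sp <- net$springs
  dv <- xyz[sp$i, , drop = FALSE] - xyz[sp$j, , drop = FALSE]
  d <- sqrt(rowSums(dv * dv))
  total <- sum(0.5 * net$k * (d - sp$d0)^2)
  structure(list(total = total, per_residue = total / length(net$keys),
                 n = length(net$keys)),
            class = "deformation_energy")
}

#' @export
print.deformation_energy <- function(x, ...) {
  cat(sprintf("<deformation_energy> total %.3f kcal/mol, %.4f kcal/mol/residue (%d residues)\n",
              x$total, x$per_residue, x$n))
  invisible(x)
}

#' Thermal-ensemble filter
#'
#' A candidate starting model whose deformation energy from the native is
#' at or below the threshold is deemed within the thermal ensemble of the
#' target (too close to pose a refinement challenge).  The comparison is
#' inclusive.
#'
#' @param e A [deformation_energy()] computed with the native as
#'   reference.
#' @param threshold kcal/mol/residue.
#' @return List with `within` (logical), `per_residue`, `threshold`.
#' @export
thermal_ensemble_filter <- function(e, threshold = 0.89) {
  stopifnot(inherits(e, "deformation_energy"))
  list(within = e$per_residue <= threshold,
       per_residue = e$per_residue, threshold = threshold)
}

#' Adventurousness report
#'
#' Summarises, per group, the deformation energy of its model-1
#' submissions relative to the starting model, restricted to targets
#' where the group improved GDT-HA.  Large mean energies mark groups
#' making bold conformational moves that pay off.
#'
#' @param records Data frame with columns `group`, `target`,
#'   `delta_gdt_ha` and `flexe` (per-residue deformation energy vs the
#'   starting model), one row per model-1 submission.
#' @return Data frame with `group`, `n_positive_targets`, `mean_flexe`,
#'   `max_flexe` (NA when no target qualifies), one row per group.
#' @export
adventurousness_report <- function(records) {
  need <- c("group", "target", "delta_gdt_ha", "flexe")
  stopifnot(all(need %in% names(records)))
  groups <- unique(records$group)
  out <- lapply(groups, function(g) {
    r <- records[records$group == g & records$delta_gdt_ha > 0 &
                   !is.na(records$flexe), , drop = FALSE]
    if (nrow(r) == 0L)
      data.frame(group = g, n_positive_targets = 0L,
                 mean_flexe = NA_real_, max_flexe = NA_real_)
    else
      data.frame(group = g, n_positive_targets = nrow(r),
                 mean_flexe = mean(r$flexe), max_flexe = max(r$flexe))
  })
  do.call(rbind, out)
}
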