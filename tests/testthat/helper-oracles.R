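# Independent oracle implementations and small fixture builders.  The
# oracles deliberately re-derive everything with plain R loops so they
# share no code path with the package internals they check.

# --- plain-R Kabsch (proper rotation), returns rmsd and fitted coords ---
oracle_kabsch <- function(P, Q) {
  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp)
  Qc <- sweep(Q, 2, cq)
  s <- svd(t(Pc) %*% Qc)
  d <- sign(det(s$u) * det(s$v))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  F <- Pc %*% R
  list(rmsd = sqrt(mean(rowSums((F - Qc)^2))),
       fitted = sweep(F, 2, -cq))
}

# numerical minimisation of RMSD over rotations (grid of Euler-angle
# starts + Nelder-Mead refinement); translation handled by centering
oracle_rmsd_min <- function(P, Q, n_starts = 8) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  rot <- function(a) {
    cx <- cos(a[1]); sx <- sin(a[1])
    cy <- cos(a[2]); sy <- sin(a[2])
    cz <- cos(a[3]); sz <- sin(a[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(a) sqrt(mean(rowSums((Pc %*% rot(a) - Qc)^2)))
  best <- Inf
  for (i in seq_len(n_starts)) {
    a0 <- runif(3, -pi, pi)
    fit <- optim(a0, obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
    best <- min(best, fit$value)
  }
  best
}

# exhaustive subset-seeded GDT: superpose on every subset of >= 3 pairs,
# count paired atoms within the cutoff, keep the maximum
oracle_gdt_count <- function(P, Q, cutoff) {
  n <- nrow(P)
  best <- 0L
  for (k in 3:n) {
    subsets <- utils::combn(n, k)
    for (j in seq_len(ncol(subsets))) {
      idx <- subsets[, j]
      # fit on the subset, apply the transform to all points
      cp <- colMeans(P[idx, , drop = FALSE])
      cq <- colMeans(Q[idx, , drop = FALSE])
      Pc <- sweep(P[idx, , drop = FALSE], 2, cp)
      s <- svd(t(Pc) %*% sweep(Q[idx, , drop = FALSE], 2, cq))
      d <- sign(det(s$u) * det(s$v))
      R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
      F <- sweep(sweep(P, 2, cp) %*% R, 2, -cq)
      cnt <- sum(sqrt(rowSums((F - Q)^2)) <= cutoff)
      if (cnt > best) best <- cnt
    }
  }
  best
}

# naive all-pairs hydrogen-bond oracle; tables re-entered on purpose
oracle_hbonds <- function(s, dist_max = 3.5, angle_min = 90) {
  a <- s$atoms
  sc_don <- list(
    SER = c("OG", "CB"), THR = c("OG1", "CB"), TYR = c("OH", "CZ"),
    CYS = c("SG", "CB"), LYS = c("NZ", "CE"))
  sc_don_multi <- list(
    ARG = list(c("NE", "CD"), c("NH1", "CZ"), c("NH2", "CZ")),
    ASN = list(c("ND2", "CG")), GLN = list(c("NE2", "CD")),
    HIS = list(c("ND1", "CG"), c("NE2", "CD2")),
    TRP = list(c("NE1", "CD1")))
  sc_acc <- list(
    ASN = "OD1", ASP = c("OD1", "OD2"), GLN = "OE1",
    GLU = c("OE1", "OE2"), HIS = c("ND1", "NE2"), SER = "OG",
    THR = "OG1", TYR = "OH", MET = "SD", CYS = "SG")
  key <- paste(a$chain, a$resno, a$icode)
  res_keys <- unique(key)
  res_ord <- match(key, res_keys)
  find_atom <- function(rk, name) which(key == rk & a$elety == name)
  bonds <- character(0)
  out <- list()
  for (di in seq_len(nrow(a))) {
    dn <- a$elety[di]
    dres <- a$resid[di]
    ante <- NULL
    if (dn == "N" && dres != "PRO") {
      ante <- find_atom(key[di], "CA")
    } else if (!is.null(sc_don[[dres]]) && sc_don[[dres]][1] == dn) {
      ante <- find_atom(key[di], sc_don[[dres]][2])
    } else if (!is.null(sc_don_multi[[dres]])) {
      for (pair in sc_don_multi[[dres]]) {
        if (pair[1] == dn) ante <- find_atom(key[di], pair[2])
      }
    }
    if (is.null(ante) || length(ante) == 0L) next
    for (ai in seq_len(nrow(a))) {
      an <- a$elety[ai]
      ares <- a$resid[ai]
      is_acc <- an %in% c("O", "OXT") || an %in% sc_acc[[ares]]
      if (!is_acc) next
      if (key[ai] == key[di]) next
      if (dn == "N" && an == "O" && a$chain[ai] == a$chain[di] &&
          res_ord[di] == res_ord[ai] + 1L) next
      dv <- as.numeric(a[ai, c("x", "y", "z")]) -
        as.numeric(a[di, c("x", "y", "z")])
      dd <- sqrt(sum(dv^2))
      if (dd > dist_max || dd == 0) next
      av <- as.numeric(a[ante, c("x", "y", "z")]) -
        as.numeric(a[di, c("x", "y", "z")])
      ang <- acos(sum(av * dv) / (sqrt(sum(av^2)) * dd)) * 180 / pi
      if (ang < angle_min - 1e-9) next
      out[[length(out) + 1L]] <- paste(key[di], dn, key[ai], an)
    }
  }
  sort(unique(unlist(out)))
}

# term-by-term elastic-network energy
oracle_deformation <- function(ref_ca, other_ca, cutoff = 12, k = 1) {
  n <- nrow(ref_ca)
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d0 <- sqrt(sum((ref_ca[i, ] - ref_ca[j, ])^2))
      if (d0 <= cutoff) {
        d <- sqrt(sum((other_ca[i, ] - other_ca[j, ])^2))
        total <- total + 0.5 * k * (d - d0)^2
      }
    }
  }
  total
}

# exact one-sided signed-rank p by explicit enumeration of all 2^n sign
# assignments (zeros dropped, average ranks)
oracle_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(mask) {
    sum(r[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0])
  }, numeric(1))
  mean(ws >= W - 1e-9)
}

# --- fixture builders ---------------------------------------------------

mk_structure <- function(atoms, id = "fix", source = "native") {
  refassess:::new_structure(id, source, atoms)
}

# n-residue Calpha-only random coil structure
mk_ca_structure <- function(n, scale = 5, id = "ca") {
  xyz <- matrix(cumsum(rnorm(n * 3, 0, scale / 2)), ncol = 3)
  mk_structure(data.frame(chain = "A", resno = seq_len(n), icode = "",
                          resid = "ALA", elety = "CA",
                          x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1,
                          stringsAsFactors = FALSE), id = id)
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b),
           a^2 - b^2 - c^2 + d^2), 3, 3, byrow = TRUE)
}

rigid_move <- function(X, R = random_rotation(), t = rnorm(3, 0, 20)) {
  sweep(X %*% R, 2, -t)
}

apply_rigid_to_structure <- function(s, R = random_rotation(),
                                     t = rnorm(3, 0, 20)) {
  xyz <- rigid_move(as.matrix(s$atoms[, c("x", "y", "z")]), R, t)
  s$atoms$x <- xyz[, 1]
  s$atoms$y <- xyz[, 2]
  s$atoms$z <- xyz[, 3]
  s
}

# minimal PDB text fixtures
pdb_one_ala <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1       1.988  -0.773  -1.199  1.00  0.00           C",
    "TER", "END"), path)
  path
}

pdb_altloc <- function(path, occ_a = 0.6, occ_b = 0.4) {
  writeLines(c(
    "ATOM      1  N   SER A   1       0.000   0.000   0.000  1.00  0.00           N",
    sprintf("ATOM      2  CA ASER A   1       1.458   0.000   0.000%6.2f  0.00           C", occ_a),
    sprintf("ATOM      3  CA BSER A   1       1.500   0.100   0.000%6.2f  0.00           C", occ_b),
    "ATOM      4  C   SER A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      5  N   GLY A   2       3.300   1.500   0.000  1.00  0.00           N",
    "ATOM      6  CA  GLY A   2       4.100   2.700   0.000  1.00  0.00           C",
    "ATOM      7  C   GLY A   2       5.600   2.500   0.000  1.00  0.00           C",
    "ATOM      8  N   ALA A   3       6.300   3.600   0.000  1.00  0.00           N",
    "ATOM      9  CA  ALA A   3       7.800   3.600   0.000  1.00  0.00           C",
    "ATOM     10  C   ALA A   3       8.400   5.000   0.000  1.00  0.00           C",
    "TER", "END"), path)
  path
}

# drop whole residues (by resno) from a structure
drop_residues <- function(s, resnos) {
  s$atoms <- s$atoms[!(s$atoms$resno %in% resnos), , drop = FALSE]
  s
}
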