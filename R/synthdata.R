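# Synthetic refinement rounds: natives, starting models, and group
# submissions with planted skill, so the whole pipeline is testable
# without any external data.
#
# Natives are ideal-geometry backbones (N, CA, C, O) plus CB, built from
# standard bond lengths/angles and fold-specific torsions; side chains
# beyond CB are not modelled (the characteristic-atom table falls back
# to CB).  All randomness is behind one seeded generator; every artifact
# is reproducible per seed.

# standard backbone geometry (Angstrom, degrees)
BB_GEOM <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                ca_cb = 1.521, ang_n_ca_c = 111.2, ang_ca_c_n = 116.2,
                ang_c_n_ca = 121.7, ang_ca_c_o = 120.8,
                ang_n_ca_cb = 110.5, omega = 180)

FOLD_TORSIONS <- list(
  helix = c(phi = -57, psi = -47),
  strand = c(phi = -119, psi = 113),
  turn = c(phi = -75, psi = 140))

# four-residue hairpin turn closing two antiparallel beta strands at
# ~4.9 A Calpha registry (torsions fitted once against that registry so
# the strands actually hydrogen-bond)
HAIRPIN_TURN <- matrix(c(-167.3, -31.8,
                         -12.0, -175.1,
                         10.8, -40.8,
                         -142.9, -72.8),
                       nrow = 4, ncol = 2, byrow = TRUE,
                       dimnames = list(NULL, c("phi", "psi")))

# NeRF atom placement: position d with |c-d| = bond, angle(b,c,d) = ang,
# torsion(a,b,c,d) = tor (degrees)
place_atom <- function(a, b, c_, bond, ang, tor) {
  ang <- ang * pi / 180
  tor <- tor * pi / 180
  d2 <- c(-bond * cos(ang), bond * cos(tor) * sin(ang),
          bond * sin(tor) * sin(ang))
  bc <- c_ - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m2 <- c(n[2] * bc[3] - n[3] * bc[2],
          n[3] * bc[1] - n[1] * bc[3],
          n[1] * bc[2] - n[2] * bc[1])
  c_ + cbind(bc, m2, n) %*% d2
}

# per-residue torsion schedule for a fold
fold_schedule <- function(fold, n_res) {
  pick <- function(name, n) {
    t(matrix(FOLD_TORSIONS[[name]], nrow = 2, ncol = n))
  }
  if (fold == "helix") {
    tor <- pick("helix", n_res)
  } else if (fold == "helix-turn-helix") {
    n1 <- max(4L, floor(n_res * 0.45))
    nt <- 4L
    tor <- rbind(pick("helix", n1), pick("turn", nt),
                 pick("helix", n_res - n1 - nt))
  } else if (fold == "sheet-like") {
    n1 <- max(4L, floor((n_res - 4L) / 2))
    tor <- rbind(pick("strand", n1), HAIRPIN_TURN,
                 pick("strand", n_res - n1 - 4L))
  } else {
    stop("unknown fold: '", fold, "'")
  }
  colnames(tor) <- c("phi", "psi")
  tor[seq_len(n_res), , drop = FALSE]
}

#' Generate an ideal-geometry native structure
#'
#' Builds an all-backbone (N, CA, C, O) plus CB protein chain from
#' standard covalent geometry and fold-specific phi/psi torsions, with a
#' small seeded torsional jitter (sd 2 degrees) so different seeds give
#' different, but equally ideal, natives.  Helical stretches have the
#' canonical ~1.5 Angstrom rise and ~100 degree twist per residue, and
#' consecutive Calpha atoms sit 3.8 +/- 0.1 Angstrom apart in every
#' fold (trans peptide).
#'
#' @param seed Integer seed; the same seed gives bit-identical
#'   coordinates.
#' @param n_res Number of residues, at least 8.
#' @param fold `"helix"`, `"helix-turn-helix"` or `"sheet-like"`.
#' @param id Structure id.
#' @return A `ref_structure` with source `"native"`.
#' @export
generate_native <- function(seed, n_res,
                            fold = c("helix", "helix-turn-helix",
                                     "sheet-like"),
                            id = sprintf("T%03d", seed %% 1000L)) {
  fold <- match.arg(fold)
  if (n_res < 8L) stop("n_res must be at least 8")
  with_seed(seed, {
    tor <- fold_schedule(fold, n_res)
    tor <- tor + matrix(rnorm(2L * n_res, 0, 2), ncol = 2)
    seq_aa <- sample(STANDARD_AA, n_res, replace = TRUE)
    g <- BB_GEOM
    # backbone trace
    N <- CA <- C <- matrix(NA_real_, n_res, 3)
    N[1, ] <- c(0, 0, 0)
    CA[1, ] <- c(g$n_ca, 0, 0)
    ang <- g$ang_n_ca_c * pi / 180
    C[1, ] <- CA[1, ] + g$ca_c * c(-cos(ang), sin(ang), 0)
    for (i in 2:n_res) {
      N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           g$c_n, g$ang_ca_c_n, tor[i - 1, "psi"])
      CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                            g$n_ca, g$ang_c_n_ca, g$omega)
      C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                           g$ca_c, g$ang_n_ca_c, tor[i, "phi"])
    }
    rows <- list()
    for (i in seq_len(n_res)) {
      O <- place_atom(N[i, ], CA[i, ], C[i, ], g$c_o, g$ang_ca_c_o,
                      tor[i, "psi"] + 180)
      atoms <- rbind(N = N[i, ], CA = CA[i, ], C = C[i, ], O = as.numeric(O))
      if (seq_aa[i] != "GLY") {
        CB <- place_atom(C[i, ], N[i, ], CA[i, ], g$ca_cb,
                         g$ang_n_ca_cb, -122.6)
        atoms <- rbind(atoms, CB = as.numeric(CB))
      }
      rows[[i]] <- data.frame(chain = "A", resno = i, icode = "",
                              resid = seq_aa[i],
                              elety = rownames(atoms),
                              x = atoms[, 1], y = atoms[, 2],
                              z = atoms[, 3], o = 1,
                              stringsAsFactors = FALSE)
    }
    atoms <- do.call(rbind, rows)
    atoms[, c("x", "y", "z")] <- round(atoms[, c("x", "y", "z")], 3)
    new_structure(id, "native", atoms)
  })
}

#' Perturb a native into a starting model
#'
#' Adds zero-mean Gaussian displacement (sd `sigma` Angstrom, per atom
#' coordinate) and rigidly rotates one contiguous loop segment about a
#' random axis through its centroid, emulating a template-based server
#' model that is close -- but not too close -- to the experimental
#' structure.  `sigma = 0` returns the native unchanged.
#'
#' @param native A [generate_native()] structure.
#' @param seed Integer seed.
#' @param sigma Noise scale in Angstrom.
#' @return A `ref_structure` with source `"starting"`.
#' @export
make_starting_model <- function(native, seed, sigma = 1.0) {
  stopifnot(inherits(native, "ref_structure"), sigma >= 0)
  atoms <- native$atoms
  if (sigma > 0) {
    with_seed(seed, {
      xyz <- as.matrix(atoms[, c("x", "y", "z")])
      n_res <- length(unique(atoms$resno))
      seg_len <- max(5L, n_res %/% 6L)
      seg_start <- sample.int(n_res - seg_len + 1L, 1L)
      seg <- atoms$resno %in% seq(seg_start, seg_start + seg_len - 1L)
      axis <- rnorm(3)
      axis <- axis / sqrt(sum(axis^2))
      theta <- runif(1, 8, 20) * pi / 180
      K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                    -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
      R <- diag(3) + sin(theta) * K + (1 - cos(theta)) * K %*% K
      ctr <- colMeans(xyz[seg, , drop = FALSE])
      xyz[seg, ] <- sweep(sweep(xyz[seg, , drop = FALSE], 2, ctr) %*% t(R),
                          2, -ctr)
      xyz <- xyz + matrix(rnorm(length(xyz), 0, sigma), ncol = 3)
      atoms[, c("x", "y", "z")] <- round(xyz, 3)
      atoms
    }) -> atoms
  }
  new_structure(paste0(native$id, "_start"), "starting", atoms)
}

#' Group behaviour profiles for synthetic rounds
#'
#' Each group is described by four behavioural axes: `skill` (mean
#' fraction of the starting-to-native gap closed; negative groups move
#' away from the native), `consistency` (target-to-target sd of that
#' fraction), `adventurousness` (RMS amplitude, Angstrom, of smooth
#' non-native conformational change) and `ranking_acumen` (probability
#' that the truly best of the five submissions is labeled model 1).
#'
#' The default panel of 10 groups spans the range seen in refinement
#' experiments: one perfect refiner (skill 1, fully deterministic), a
#' graded middle field, one naive-equivalent group that resubmits the
#' starting model, and one model-degrading group; one skilled group has
#' `ranking_acumen` 0.2 (labels essentially at random among 5 models).
#'
#' @param n_groups Number of groups (profiles are recycled/truncated
#'   from the default panel).
#' @return Data frame with columns `group`, `skill`, `consistency`,
#'   `adventurousness`, `ranking_acumen`.
#' @export
default_group_profiles <- function(n_groups = 10L) {
  base <- data.frame(
    group = sprintf("G%02d", 1:10),
    skill = c(1.0, 0.8, 0.65, 0.5, 0.4, 0.3, 0.2, 0.1, 0.0, -0.2),
    consistency = c(0, 0.15, 0.15, 0.15, 0.15, 0.15, 0.15, 0.15, 0, 0.15),
    adventurousness = c(0, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0, 0.3),
    ranking_acumen = c(1, 0.2, 0.6, 0.6, 0.6, 0.6, 0.6, 0.6, 1, 0.5),
    stringsAsFactors = FALSE)
  base[seq_len(min(n_groups, 10L)), , drop = FALSE]
}

#' Generate one submission from a group profile
#'
#' Interpolates the starting model towards the native by a fraction
#' drawn from Normal(skill, consistency), clamped to \[-0.5, 1\], then
#' adds a sequence-smoothed Gaussian displacement field scaled to the
#' profile's adventurousness (RMS Angstrom).  With probability
#' `p_missing` the terminal residue is deleted, producing a submission
#' that [validate_submission()] must reject.
#'
#' @param starting,native Matched `ref_structure` objects.
#' @param profile One row of [default_group_profiles()].
#' @param model_index Submission index 1-5 (bookkeeping only).
#' @param seed Integer seed.
#' @param p_missing Probability of deleting the terminal residue.
#' @return A `ref_structure` with source `"prediction"`; the drawn
#'   interpolation fraction is in attribute `frac`.
#' @export
generate_submission <- function(starting, native, profile, model_index,
                                seed, p_missing = 0.02) {
  stopifnot(inherits(starting, "ref_structure"),
            inherits(native, "ref_structure"))
  with_seed(seed, {
    S <- as.matrix(starting$atoms[, c("x", "y", "z")])
    N <- as.matrix(native$atoms[, c("x", "y", "z")])
    stopifnot(nrow(S) == nrow(N))
    frac <- min(max(rnorm(1, profile$skill, profile$consistency), -0.5), 1)
    xyz <- S + frac * (N - S)
    if (profile$adventurousness > 0) {
      e <- matrix(rnorm(length(xyz)), ncol = 3)
      # smooth along the chain so the perturbation is a conformational
      # move, not atomic jitter
      w <- 9L
      e <- apply(e, 2, function(col) {
        f <- stats::filter(col, rep(1 / w, w), sides = 2)
        f[is.na(f)] <- col[is.na(f)]
        as.numeric(f)
      })
      rms <- sqrt(mean(rowSums(e^2)))
      xyz <- xyz + e * (profile$adventurousness / rms)
    }
    atoms <- starting$atoms
    atoms[, c("x", "y", "z")] <- round(xyz, 3)
    if (runif(1) < p_missing) {
      atoms <- atoms[atoms$resno != max(atoms$resno), , drop = FALSE]
    }
    s <- new_structure(sprintf("%s_%s_%d", native$id, profile$group,
                               model_index),
                       "prediction", atoms)
    attr(s, "frac") <- frac
    s
  })
}

#' Generate a complete synthetic refinement round on disk
#'
#' Writes `targets/<T>/native.pdb` and `targets/<T>/starting.pdb` for
#' each target, `submissions/<T>/<group>_<index>.pdb` for each
#' submission, fabricated external score tables `scores/mp.tsv` and
#' `scores/llg.tsv` (MolProbity-like scores increase with the model's
#' Calpha RMSD from native; LLG-like scores increase with the fraction
#' of well-placed Calpha atoms -- both clearly marked synthetic in their
#' headers), a `manifest.json`, and returns the manifest with the
#' planted truth.  Within each group and target the five drawn
#' submissions are relabeled so that the truly best one carries index 1
#' with probability `ranking_acumen`, and a random other one otherwise.
#'
#' @param seed Integer master seed; everything derives from it.
#' @param n_targets Number of targets.
#' @param profiles Group profile data frame, see
#'   [default_group_profiles()].
#' @param n_models Submissions per group and target.
#' @param dir Output directory (created); defaults to a seed-named
#'   directory under `tempdir()`.
#' @param n_res_range Range from which each target's residue count is
#'   drawn.
#' @param sigma Starting-model noise scale, Angstrom.
#' @param p_missing Per-submission probability of a deleted terminal
#'   residue.
#' @return Object of class `round_manifest`: list with `dir`, `seed`,
#'   `targets`, `submissions` (including the planted interpolation
#'   fraction and best-of-group flag), `profiles`, `params`.
#' @export
generate_round <- function(seed, n_targets = 27L,
                           profiles = default_group_profiles(),
                           n_models = 5L, dir = NULL,
                           n_res_range = c(40L, 60L), sigma = 1.0,
                           p_missing = 0.02) {
  if (anyDuplicated(profiles$group))
    stop("duplicate group ids in profiles")
  dir <- dir %||% file.path(tempdir(), sprintf("synth_round_%d", seed))
  dir.create(file.path(dir, "targets"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "submissions"), showWarnings = FALSE)
  dir.create(file.path(dir, "scores"), showWarnings = FALSE)
  folds <- c("helix", "helix-turn-helix", "sheet-like")

  targets <- list()
  subs <- list()
  mp_rows <- list()
  llg_rows <- list()
  for (ti in seq_len(n_targets)) {
    tseed <- derive_seed(seed, ti)
    tid <- sprintf("T%02d", ti)
    n_res <- with_seed(tseed, sample(seq(n_res_range[1], n_res_range[2]), 1))
    fold <- folds[(ti - 1L) %% 3L + 1L]
    native <- generate_native(derive_seed(tseed, 1), n_res, fold, id = tid)
    start <- make_starting_model(native, derive_seed(tseed, 2), sigma)
    tdir <- file.path(dir, "targets", tid)
    dir.create(tdir, showWarnings = FALSE)
    write_pdb(native, file.path(tdir, "native.pdb"))
    write_pdb(start, file.path(tdir, "starting.pdb"))
    sdir <- file.path(dir, "submissions", tid)
    dir.create(sdir, showWarnings = FALSE)
    targets[[ti]] <- data.frame(target = tid, n_res = n_res, fold = fold,
                                stringsAsFactors = FALSE)
    st_fit <- ca_fit_stats(start, native)
    mp_rows[[length(mp_rows) + 1L]] <-
      data.frame(model_id = paste0(tid, "_starting"),
                 value = fake_mp(st_fit, coord_seed(start, 3L)))
    llg_rows[[length(llg_rows) + 1L]] <-
      data.frame(model_id = paste0(tid, "_starting"),
                 value = fake_llg(st_fit, coord_seed(start, 4L)))

    for (gi in seq_len(nrow(profiles))) {
      prof <- profiles[gi, , drop = FALSE]
      drawn <- vector("list", n_models)
      fracs <- numeric(n_models)
      for (k in seq_len(n_models)) {
        sseed <- derive_seed(tseed, 100L * gi + k)
        drawn[[k]] <- generate_submission(start, native, prof, k, sseed,
                                          p_missing)
        fracs[k] <- attr(drawn[[k]], "frac")
      }
      # relabel: truly best gets index 1 with probability ranking_acumen
      labels <- with_seed(derive_seed(tseed, 100L * gi + 99L), {
        best <- which.max(fracs)
        lab <- integer(n_models)
        one <- if (runif(1) < prof$ranking_acumen || n_models == 1L) best
               else sample(setdiff(seq_len(n_models), best), 1L)
        lab[one] <- 1L
        lab[-one] <- sample(seq_len(n_models - 1L) + 1L)
        lab
      })
      for (k in seq_len(n_models)) {
        idx <- labels[k]
        model_id <- sprintf("%s_%s_%d", tid, prof$group, idx)
        path <- file.path(sdir, sprintf("%s_%d.pdb", prof$group, idx))
        s <- drawn[[k]]
        s$id <- model_id
        write_pdb(s, path)
        subs[[length(subs) + 1L]] <-
          data.frame(target = tid, group = prof$group, model_index = idx,
                     model_id = model_id, path = path, frac = fracs[k],
                     best_planted = k == which.max(fracs),
                     stringsAsFactors = FALSE)
        fit <- ca_fit_stats(s, native)
        mp_rows[[length(mp_rows) + 1L]] <-
          data.frame(model_id = model_id,
                     value = fake_mp(fit, coord_seed(s, 3L)))
        llg_rows[[length(llg_rows) + 1L]] <-
          data.frame(model_id = model_id,
                     value = fake_llg(fit, coord_seed(s, 4L)))
      }
    }
  }
  targets <- do.call(rbind, targets)
  subs <- do.call(rbind, subs)
  write_score_tsv(do.call(rbind, mp_rows), file.path(dir, "scores", "mp.tsv"),
                  "synthetic MolProbity-like score (lower is better)")
  write_score_tsv(do.call(rbind, llg_rows),
                  file.path(dir, "scores", "llg.tsv"),
                  "synthetic molecular-replacement LLG-like score (higher is better)")
  manifest <- structure(list(dir = dir, seed = seed, targets = targets,
                             submissions = subs, profiles = profiles,
                             params = list(n_models = n_models,
                                           sigma = sigma,
                                           p_missing = p_missing,
                                           n_res_range = n_res_range)),
                        class = "round_manifest")
  json <- manifest
  json$submissions$path <- sub(paste0("^", gsub("([.\\\\])", "\\\\\\1", dir),
                                      "/?"), "", json$submissions$path)
  json$dir <- NULL
  jsonlite::write_json(unclass(json), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

#' @export
print.round_manifest <- function(x, ...) {
  cat(sprintf("<round_manifest> seed %d: %d targets, %d groups, %d submissions\n  %s\n",
              x$seed, nrow(x$targets), nrow(x$profiles),
              nrow(x$submissions), x$dir))
  invisible(x)
}

write_score_tsv <- function(df, path, what) {
  con <- file(path, "w")
  writeLines(paste0("# ", what, " -- fabricated by generate_round()"), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
}

# a seed that is a pure function of the (rounded) coordinates, so that
# fabricated external scores behave like real ones: identical structures
# always receive identical scores
coord_seed <- function(s, salt) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  as.integer((round(sum(abs(xyz)) * 1000) + salt) %% 2147483629)
}

# quick Calpha superposition diagnostics used only to fabricate
# plausible external scores
ca_fit_stats <- function(model, native) {
  mca <- model$atoms[model$atoms$elety == "CA", , drop = FALSE]
  nca <- native$atoms[native$atoms$elety == "CA", , drop = FALSE]
  i <- match(paste(mca$chain, mca$resno, mca$icode),
             paste(nca$chain, nca$resno, nca$icode))
  ok <- !is.na(i)
  P <- as.matrix(mca[ok, c("x", "y", "z")])
  Q <- as.matrix(nca[i[ok], c("x", "y", "z")])
  sp <- kabsch(P, Q)
  d <- sqrt(rowSums((apply_transform(P, sp) - Q)^2))
  list(rmsd = sp$rmsd, frac2 = mean(d <= 2))
}

fake_mp <- function(st, seed) {
  with_seed(seed, round(max(0.3, 0.8 + 0.55 * st$rmsd + rnorm(1, 0, 0.25)), 2))
}

fake_llg <- function(st, seed) {
  with_seed(seed, round(15 + 160 * st$frac2 + rnorm(1, 0, 8), 2))
}
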