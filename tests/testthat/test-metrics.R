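# The five quality measures.

# per-sphere brute-force oracle for SphereGrinder
oracle_sphere_grinder <- function(model, target, radius = 6, tol = 2) {
  at <- target$atoms
  am <- model$atoms
  tkey <- paste(at$chain, at$resno, at$icode, at$elety)
  mkey <- paste(am$chain, am$resno, am$icode, am$elety)
  ca_rows <- which(at$elety == "CA")
  fs <- c()
  for (i in ca_rows) {
    ctr <- as.numeric(at[i, c("x", "y", "z")])
    d <- sqrt((at$x - ctr[1])^2 + (at$y - ctr[2])^2 + (at$z - ctr[3])^2)
    memb <- which(d <= radius)
    if (length(memb) < 3) next
    mi <- match(tkey[memb], mkey)
    ok <- !is.na(mi)
    if (sum(ok) < 3) {
      fs <- c(fs, 0)
      next
    }
    Tm <- as.matrix(at[memb[ok], c("x", "y", "z")])
    Mm <- as.matrix(am[mi[ok], c("x", "y", "z")])
    fit <- oracle_kabsch(Mm, Tm)
    within <- sum(sqrt(rowSums((fit$fitted - Tm)^2)) <= tol)
    fs <- c(fs, within / length(memb))
  }
  100 * mean(fs)
}

test_that("all measures are exact for a model identical to its target", {
  for (fold in c("helix", "helix-turn-helix", "sheet-like")) {
    nat <- generate_native(17, 30, fold)
    map <- map_common_residues(nat, nat)
    expect_equal(gdt_ha(nat, nat, map), 100)
    expect_equal(ca_rmsd(nat, nat, map), 0, tolerance = 1e-9)
    expect_equal(gdc_sc(nat, nat, map), 100)
    expect_equal(sphere_grinder(nat, nat, map), 100)
  }
})

test_that("gdt_ha averages the four per-cutoff fractions", {
  nat <- generate_native(19, 35, "helix")
  model <- make_starting_model(nat, 23, sigma = 1.5)
  map <- map_common_residues(model, nat)
  ca <- refassess:::paired_atom_coords(model, nat, map, "CA")
  expect_equal(gdt_ha(model, nat, map),
               mean(gdt_fractions(ca$model, ca$target, c(0.5, 1, 2, 4))))
})

test_that("GDC-SC weights decrease linearly and sum to one", {
  w <- refassess:::gdc_weights(10)
  expect_equal(sum(w), 1)
  expect_equal(w[1], 10 / 55)
  expect_equal(diff(w), rep(-1 / 55, 9))
  # a model losing only the tightest threshold scores 100 * 45/55
  expect_equal(sum(w * c(0, rep(100, 9))), 100 * 45 / 55)
})

test_that("gdc_sc uses one characteristic atom per residue with CB fallback", {
  nat <- generate_native(29, 30, "helix")
  map <- map_common_residues(nat, nat)
  sel <- refassess:::gdc_atom_coords(nat, nat, map,
                                     characteristic_atom_table(), TRUE)
  # backbone+CB natives: every non-GLY residue contributes its CB
  n_gly <- sum(residue_keys(nat)$resid == "GLY")
  expect_equal(nrow(sel$model), 30 - n_gly)
  # a custom table is honoured
  tab <- c(ALA = "CB")
  sel2 <- refassess:::gdc_atom_coords(nat, nat, map, tab, FALSE)
  expect_equal(nrow(sel2$model), sum(residue_keys(nat)$resid == "ALA"))
})

test_that("sphere_grinder matches the per-sphere brute-force oracle", {
  nat <- generate_native(31, 25, "helix-turn-helix")
  map <- map_common_residues(nat, nat)

  # one side chain rotated far away, everything else identical
  model <- nat
  cb <- which(model$atoms$elety == "CB" & model$atoms$resno == 12)
  model$atoms[cb, c("x", "y", "z")] <- model$atoms[cb, c("x", "y", "z")] + 15
  got <- sphere_grinder(model, nat, map)
  expect_lt(got, 100)
  expect_equal(got, oracle_sphere_grinder(model, nat), tolerance = 1e-9)

  # noisy model
  set.seed(4)
  noisy <- nat
  noisy$atoms[, c("x", "y", "z")] <-
    noisy$atoms[, c("x", "y", "z")] + matrix(rnorm(nrow(noisy$atoms) * 3, 0, 1.2),
                                             ncol = 3)
  expect_equal(sphere_grinder(noisy, nat, map),
               oracle_sphere_grinder(noisy, nat), tolerance = 1e-9)

  # rigid motion invariance
  moved <- apply_rigid_to_structure(noisy)
  expect_equal(sphere_grinder(moved, nat, map),
               sphere_grinder(noisy, nat, map), tolerance = 1e-6)
})

test_that("a single-residue identity model scores a full sphere", {
  f <- pdb_one_ala(tempfile(fileext = ".pdb"))
  s <- read_pdb(f, "native")
  map <- map_common_residues(s, s)
  expect_equal(sphere_grinder(s, s, map), 100)
})

test_that("external scores join by id, flag absences, reject duplicates", {
  tab <- data.frame(model_id = c("m1", "m2", "m3"), value = c(2.1, 3.0, 1.2))
  v <- attach_external_scores(c("m1", "m2", "m3"), tab)
  expect_equal(as.numeric(v), c(2.1, 3.0, 1.2))
  expect_length(attr(v, "absent"), 0)

  v2 <- attach_external_scores(c("m1", "m4"), tab)
  expect_true(is.na(v2[["m4"]]))
  expect_equal(attr(v2, "absent"), "m4")

  dup <- rbind(tab, tab[1, ])
  expect_error(attach_external_scores("m1", dup), "duplicate")

  f <- tempfile(fileext = ".tsv")
  writeLines(c("# comment", "model_id\tvalue", "a\t1.5", "b\t2.5"), f)
  expect_equal(read_score_table(f)$value, c(1.5, 2.5))
  writeLines(c("model_id\tvalue", "a\t1.5", "a\t2.5"), f)
  expect_error(read_score_table(f), "duplicate")
})

test_that("scores degrade monotonically with coordinate noise", {
  sigmas <- c(0.3, 1.0, 2.5)
  reps <- 20
  med <- matrix(NA_real_, length(sigmas), 4,
                dimnames = list(NULL, c("gdt_ha", "rmsd", "gdc_sc", "sphgr")))
  nat <- generate_native(37, 30, "helix")
  map <- map_common_residues(nat, nat)
  for (si in seq_along(sigmas)) {
    set.seed(100 + si)
    vals <- replicate(reps, {
      noisy <- nat
      noisy$atoms[, c("x", "y", "z")] <-
        noisy$atoms[, c("x", "y", "z")] +
        matrix(rnorm(nrow(nat$atoms) * 3, 0, sigmas[si]), ncol = 3)
      c(gdt_ha(noisy, nat, map), ca_rmsd(noisy, nat, map),
        gdc_sc(noisy, nat, map), sphere_grinder(noisy, nat, map))
    })
    med[si, ] <- apply(vals, 1, median)
  }
  expect_true(all(diff(med[, "gdt_ha"]) <= 0))
  expect_true(all(diff(med[, "gdc_sc"]) <= 0))
  expect_true(all(diff(med[, "sphgr"]) <= 0))
  expect_true(all(diff(med[, "rmsd"]) >= 0))
})
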