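# Synthetic natives, starting models, submissions and whole rounds.

test_that("generated natives have ideal chain geometry, per fold", {
  for (fold in c("helix", "helix-turn-helix", "sheet-like")) {
    nat <- generate_native(101, 20, fold)
    expect_equal(nrow(residue_keys(nat)), 20L)
    ca <- as.matrix(nat$atoms[nat$atoms$elety == "CA", c("x", "y", "z")])
    d <- sqrt(rowSums(diff(ca)^2))
    expect_true(all(abs(d - 3.8) < 0.1))
  }
  # helical rise ~1.5 A per residue along the axis
  helix <- generate_native(103, 30, "helix")
  ca <- as.matrix(helix$atoms[helix$atoms$elety == "CA", c("x", "y", "z")])
  axis_len <- sqrt(sum((colMeans(ca[21:30, ]) - colMeans(ca[1:10, ]))^2))
  expect_equal(axis_len / 20, 1.5, tolerance = 0.1)
})

test_that("native generation is deterministic and validates input", {
  a <- generate_native(107, 25, "sheet-like")
  b <- generate_native(107, 25, "sheet-like")
  expect_identical(a$atoms, b$atoms)
  c_ <- generate_native(108, 25, "sheet-like")
  expect_false(identical(a$atoms$x, c_$atoms$x))
  expect_error(generate_native(1, 4), "at least 8")
  expect_error(generate_native(1, 20, "coil"))
})

test_that("starting models degrade with sigma and vanish at zero", {
  nat <- generate_native(109, 30, "helix")
  map <- map_common_residues(nat, nat)
  st0 <- make_starting_model(nat, 1, sigma = 0)
  expect_identical(st0$atoms[, c("x", "y", "z")],
                   nat$atoms[, c("x", "y", "z")])
  expect_equal(gdt_ha(st0, nat, map), 100)

  g_small <- vapply(1:20, function(k)
    gdt_ha(make_starting_model(nat, 200 + k, sigma = 0.5), nat, map),
    numeric(1))
  g_large <- vapply(1:20, function(k)
    gdt_ha(make_starting_model(nat, 400 + k, sigma = 2.0), nat, map),
    numeric(1))
  expect_lt(median(g_large), median(g_small))

  s1 <- make_starting_model(nat, 77, sigma = 1)
  s2 <- make_starting_model(nat, 77, sigma = 1)
  expect_identical(s1$atoms, s2$atoms)
})

test_that("submissions interpolate by planted skill", {
  nat <- generate_native(113, 30, "helix")
  start <- make_starting_model(nat, 5, sigma = 1.2)
  map <- map_common_residues(nat, nat)

  perfect <- data.frame(group = "P", skill = 1, consistency = 0,
                        adventurousness = 0, ranking_acumen = 1)
  sub <- generate_submission(start, nat, perfect, 1, seed = 3, p_missing = 0)
  expect_equal(attr(sub, "frac"), 1)
  expect_equal(as.matrix(sub$atoms[, c("x", "y", "z")]),
               as.matrix(nat$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)

  naive <- data.frame(group = "N", skill = 0, consistency = 0,
                      adventurousness = 0, ranking_acumen = 1)
  sub0 <- generate_submission(start, nat, naive, 1, seed = 3, p_missing = 0)
  expect_identical(sub0$atoms[, c("x", "y", "z")],
                   start$atoms[, c("x", "y", "z")])

  # a degrading group lands below the starting model in expectation
  bad <- data.frame(group = "B", skill = -0.2, consistency = 0.05,
                    adventurousness = 0, ranking_acumen = 1)
  g_start <- gdt_ha(start, nat, map_common_residues(start, nat))
  g_bad <- vapply(1:20, function(k) {
    s <- generate_submission(start, nat, bad, 1, seed = 600 + k,
                             p_missing = 0)
    gdt_ha(s, nat, map_common_residues(s, nat))
  }, numeric(1))
  expect_lt(median(g_bad), g_start)
})

test_that("a round writes the full tree and reproduces per seed", {
  profiles <- default_group_profiles(3)
  d1 <- file.path(tempdir(), "r1")
  d2 <- file.path(tempdir(), "r2")
  man1 <- generate_round(555, n_targets = 2, profiles = profiles, dir = d1,
                         n_res_range = c(20, 28))
  man2 <- generate_round(555, n_targets = 2, profiles = profiles, dir = d2,
                         n_res_range = c(20, 28))
  expect_equal(nrow(man1$targets), 2L)
  expect_lte(nrow(man1$submissions), 30L)
  expect_true(all(file.exists(man1$submissions$path)))
  expect_true(all(file.exists(file.path(d1, "targets", man1$targets$target,
                                        "native.pdb"))))
  expect_true(file.exists(file.path(d1, "scores", "mp.tsv")))
  expect_true(file.exists(file.path(d1, "manifest.json")))

  # same seed, different directory: identical content
  expect_identical(man1$targets, man2$targets)
  expect_identical(man1$submissions$frac, man2$submissions$frac)
  for (k in seq_len(nrow(man1$submissions))) {
    expect_identical(readLines(man1$submissions$path[k]),
                     readLines(man2$submissions$path[k]))
  }
  expect_error(generate_round(1, profiles = rbind(profiles, profiles[1, ])),
               "duplicate group")
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("generated files re-parse cleanly with no flagged mismatches", {
  d <- file.path(tempdir(), "r3")
  man <- generate_round(556, n_targets = 2,
                        profiles = default_group_profiles(3), dir = d,
                        n_res_range = c(20, 28), p_missing = 0)
  for (ti in man$targets$target) {
    nat <- read_pdb(file.path(d, "targets", ti, "native.pdb"), "native")
    subs <- man$submissions[man$submissions$target == ti, ]
    for (p in subs$path) {
      m <- read_pdb(p, "prediction")
      map <- map_common_residues(m, nat)
      expect_equal(map$n_mismatch, 0L)
      expect_equal(map$n_common, nrow(residue_keys(nat)))
    }
  }
  unlink(d, recursive = TRUE)
})

test_that("external score tables track model quality in the right direction", {
  d <- file.path(tempdir(), "r4")
  man <- generate_round(557, n_targets = 3,
                        profiles = default_group_profiles(4), dir = d,
                        n_res_range = c(20, 28), p_missing = 0)
  mp <- read_score_table(file.path(d, "scores", "mp.tsv"))
  llg <- read_score_table(file.path(d, "scores", "llg.tsv"))
  sub <- man$submissions
  sub$mp <- mp$value[match(sub$model_id, mp$model_id)]
  sub$llg <- llg$value[match(sub$model_id, llg$model_id)]
  # closeness to native (frac) should mean better MP (lower) and LLG (higher)
  expect_lt(cor(sub$frac, sub$mp), -0.3)
  expect_gt(cor(sub$frac, sub$llg), 0.3)
  unlink(d, recursive = TRUE)
})
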