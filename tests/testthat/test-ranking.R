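# Delta scores, robust Z, clipping, S_p, baseline and ranking.

test_that("delta scores subtract componentwise with the sign convention", {
  mv <- list(gdt_ha = 55, rmsd = 3.0, gdc_sc = 40, sphgr = 70, mp = 2.0)
  st <- list(gdt_ha = 50, rmsd = 2.5, gdc_sc = 42, sphgr = 70, mp = 2.5)
  d <- delta_scores(mv, st)
  expect_equal(d$gdt_ha, 5)
  expect_equal(d$rmsd, 0.5)               # positive = worsening for RMSD
  expect_equal(d$gdc_sc, -2)
  expect_equal(d$sphgr, 0)
  expect_equal(d$mp, -0.5)
  expect_true(all(unlist(delta_scores(st, st)) == 0))
  expect_true(is.na(delta_scores(list(gdt_ha = 1, mp = NA), st)$mp))
  expect_error(delta_scores(c(mv, target = "a"), c(st, target = "b")),
               "different targets")
})

test_that("robust Z uses median/MAD and resists outliers", {
  z <- robust_z(c(1, 2, 3, 4, 100))
  expect_equal(z, c(-2, -1, 0, 1, 97))    # median 3, MAD 1
  expect_true(all(robust_z(c(5, 5, 5)) == 0))

  # MAD degenerates to zero: standard deviation takes over
  x <- c(0, 0, 0, 0, 10)
  s_oracle <- sqrt(sum((x - mean(x))^2) / (length(x) - 1))
  expect_equal(robust_z(x), (x - 0) / s_oracle)

  expect_error(robust_z(2), "at least 2")
  # NA values are excluded from the statistics and stay NA
  z2 <- robust_z(c(1, 2, 3, NA))
  expect_true(is.na(z2[4]))
  expect_equal(median(z2[1:3]), 0)
})

test_that("unclipped Z always has median zero per population", {
  set.seed(15)
  for (i in 1:20) {
    x <- rnorm(sample(3:40, 1), sample(-5:5, 1), runif(1, 0.1, 10))
    expect_equal(median(robust_z(x)), 0)
    expect_equal(median(robust_z(x, variant = "mean_sd")),
                 median(scale(x)[, 1]))
  }
})

test_that("clipping keeps each measure's helpful sign and S_p is a sum", {
  cc <- clip_and_combine(c(gdt_ha = 1, rmsd = -1, gdc_sc = 0.5,
                           sphgr = 0.5, mp = 0))
  expect_equal(cc$s_p, 3)                 # 1 + 0.5 + 0.5 - (-1) - 0

  cc2 <- clip_and_combine(c(gdt_ha = -2, rmsd = 0.4, gdc_sc = 0,
                            sphgr = 0, mp = 1.5))
  expect_equal(unname(cc2$z_clipped[c("gdt_ha", "rmsd", "mp")]), c(0, 0, 0))
  expect_equal(cc2$s_p, 0)

  expect_equal(clip_and_combine(c(gdt_ha = 0, rmsd = 0, gdc_sc = 0,
                                  sphgr = 0, mp = 0))$s_p, 0)
  # absent MP contributes nothing and is flagged
  cc3 <- clip_and_combine(c(gdt_ha = 1, rmsd = 0, gdc_sc = 0, sphgr = 0,
                            mp = NA))
  expect_equal(cc3$s_p, 1)
  expect_true(cc3$mp_absent)
})

test_that("S_p is non-negative and zero only when every term clips away", {
  set.seed(16)
  for (i in 1:50) {
    z <- rnorm(5, 0, 2)
    names(z) <- c("gdt_ha", "rmsd", "gdc_sc", "sphgr", "mp")
    cc <- clip_and_combine(z)
    expect_gte(cc$s_p, 0)
    expect_equal(cc$s_p == 0, all(cc$z_clipped == 0))
  }
})

test_that("the naive baseline is scored from participant statistics", {
  mk <- function(d_gdt) {
    df <- data.frame(d_gdt_ha = d_gdt, d_rmsd = 0, d_gdc_sc = 0,
                     d_sphgr = 0, d_mp = 0)
    naive_baseline(df)
  }
  # participants improved (median +2, MAD 1): naive Z = -2, clipped away
  nb <- mk(c(0, 1, 2, 3, 4))
  expect_equal(unname(nb$z_clipped["gdt_ha"]), 0)
  # participants worsened the model: the baseline earns +2
  nb2 <- mk(c(-4, -3, -2, -1, 0))
  expect_equal(unname(nb2$z_clipped["gdt_ha"]), 2)
  expect_equal(nb2$s_p, 2)
  # symmetric participants: nothing to gain
  expect_equal(mk(c(-2, -1, 0, 1, 2))$s_p, 0)
})

test_that("group ranking applies the eligibility cut and sorts by median", {
  recs <- data.frame(group = "solo", target = paste0("t", 1:25), s_p = 0.5)
  tab <- group_ranking(recs, min_targets = 23)
  expect_equal(tab$median_sp, 0.5)
  expect_equal(tab$n_targets, 25L)

  recs2 <- rbind(recs,
                 data.frame(group = "late", target = paste0("t", 1:20),
                            s_p = 9))
  tab2 <- group_ranking(recs2, min_targets = 23)
  expect_false("late" %in% tab2$group)
  expect_true("late" %in% attr(tab2, "unranked")$group)

  tab3 <- group_ranking(recs2, min_targets = 23, naive_sp = rep(0.1, 25))
  expect_true("naive" %in% tab3$group)
  expect_equal(tab3$median_sp[tab3$group == "naive"], 0.1)
  expect_error(group_ranking(recs, min_targets = 26), "no group")
})

test_that("rankings are invariant to positive rescaling of a raw measure", {
  set.seed(17)
  recs <- expand.grid(group = paste0("G", 1:6), target = paste0("t", 1:10),
                      stringsAsFactors = FALSE)
  for (q in c("gdt_ha", "rmsd", "gdc_sc", "sphgr", "mp"))
    recs[[paste0("d_", q)]] <- rnorm(nrow(recs))
  base <- refassess:::score_records(recs)
  scaled <- recs
  scaled$d_gdt_ha <- scaled$d_gdt_ha * 10
  rescored <- refassess:::score_records(scaled)
  expect_equal(rescored$s_p, base$s_p, tolerance = 1e-12)
})

test_that("improvement tallies are direction-aware", {
  recs <- data.frame(d_gdt_ha = c(0, 0), d_rmsd = c(0, 0), d_gdc_sc = c(0, 0),
                     d_sphgr = c(0, 0), d_mp = c(0, 0))
  st <- aggregate_improvement_stats(recs)
  expect_true(all(st$pct_tied == 100))

  recs2 <- data.frame(d_gdt_ha = c(3, -1), d_rmsd = c(-0.5, 0.5),
                      d_gdc_sc = c(1, 1), d_sphgr = c(0, 0),
                      d_mp = c(NA, -1))
  st2 <- aggregate_improvement_stats(recs2)
  expect_equal(st2$pct_better[st2$metric == "gdt_ha"], 50)
  expect_equal(st2$pct_worse[st2$metric == "gdt_ha"], 50)
  # negative RMSD delta is an improvement
  expect_equal(st2$pct_better[st2$metric == "rmsd"], 50)
  expect_equal(st2$pct_better[st2$metric == "gdc_sc"], 100)
  expect_equal(st2$n[st2$metric == "mp"], 1)
  expect_equal(st2$pct_better[st2$metric == "mp"], 100)
})

test_that("parametric and robust standardisation agree on the table top", {
  # planted skills shift every measure in its direction of merit
  set.seed(23)
  groups <- paste0("G", sprintf("%02d", 1:10))
  skill <- seq(1, -0.2, length.out = 10)
  recs <- expand.grid(group = groups, target = paste0("t", 1:25),
                      stringsAsFactors = FALSE)
  eff <- skill[match(recs$group, groups)]
  recs$d_gdt_ha <- 10 * eff + rnorm(nrow(recs), 0, 2)
  recs$d_gdc_sc <- 8 * eff + rnorm(nrow(recs), 0, 2)
  recs$d_sphgr <- 6 * eff + rnorm(nrow(recs), 0, 2)
  recs$d_rmsd <- -0.8 * eff + rnorm(nrow(recs), 0, 0.3)
  recs$d_mp <- -0.5 * eff + rnorm(nrow(recs), 0, 0.3)
  top3 <- function(variant) {
    sc <- refassess:::score_records(recs, variant = variant)
    tab <- group_ranking(sc, min_targets = 23)
    tab$group[1:3]
  }
  expect_setequal(top3("mad"), top3("mean_sd"))
})
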