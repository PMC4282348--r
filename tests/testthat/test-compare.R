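# Wilcoxon comparisons, cherry-picking, MR viability.

test_that("the signed-rank test handles degenerate and textbook cases", {
  x <- c(1, 2, 3, 4)
  expect_equal(wilcoxon_one_tailed(x, x)$p, 1)

  # ten uniform wins with distinct magnitudes: one tail of 2^10
  res <- wilcoxon_one_tailed(2:11 / 10, rep(0, 10))
  expect_equal(res$p, 1 / 1024)
  expect_true(res$significant)

  # six uniform wins: p = 1/64 > 0.01, not significant at alpha = 0.01
  res6 <- wilcoxon_one_tailed(1:6, rep(0, 6))
  expect_equal(res6$p, 1 / 64)
  expect_false(res6$significant)
  expect_equal(res6$significant, res6$p < res6$alpha)

  # better_is = -1 flips the direction of merit
  worse <- wilcoxon_one_tailed(rep(0, 10), 2:11 / 10, better_is = -1)
  expect_equal(worse$p, 1 / 1024)
})

test_that("exact p equals full sign-assignment enumeration, ties included", {
  set.seed(18)
  for (i in 1:12) {
    n <- sample(4:11, 1)
    # integer-valued differences force tied magnitudes
    d <- sample(c(-3:-1, 1:3), n, replace = TRUE)
    p_pkg <- wilcoxon_one_tailed(d, rep(0, n))$p
    expect_equal(p_pkg, oracle_wilcoxon_p(d), tolerance = 1e-12)
  }
})

test_that("exact p agrees with stats::wilcox.test when it is exact", {
  set.seed(19)
  for (i in 1:8) {
    n <- sample(6:20, 1)
    a <- rnorm(n)
    b <- rnorm(n)
    p_pkg <- wilcoxon_one_tailed(a, b)$p
    p_ref <- stats::wilcox.test(a, b, paired = TRUE,
                                alternative = "greater", exact = TRUE)$p.value
    expect_equal(p_pkg, p_ref, tolerance = 1e-12)
  }
})

test_that("the normal approximation is close to exact around the boundary", {
  set.seed(20)
  a <- rnorm(30, 0.4)
  b <- rnorm(30)
  p_norm <- wilcoxon_one_tailed(a, b)$p                 # n = 30: approx
  p_exact <- wilcoxon_one_tailed(a, b, exact_max_n = 40L)$p
  expect_equal(p_norm, p_exact, tolerance = 0.005)
})

test_that("head-to-head counts find a planted dominant group", {
  set.seed(22)
  groups <- paste0("G", 1:6)
  recs <- expand.grid(group = groups, target = paste0("t", 1:25),
                      stringsAsFactors = FALSE)
  for (q in c("gdt_ha", "rmsd", "gdc_sc", "sphgr", "mp"))
    recs[[paste0("d_", q)]] <- rnorm(nrow(recs))
  recs$d_gdt_ha[recs$group == "G1"] <- recs$d_gdt_ha[recs$group == "G1"] + 8
  counts <- head_to_head_counts(recs, groups)
  expect_equal(counts$n_outperformed[counts$group == "G1" &
                                       counts$metric == "gdt_ha"], 5L)
  # two identical groups never beat each other
  recs2 <- recs[recs$group %in% c("G2", "G3"), ]
  recs2[recs2$group == "G3", paste0("d_", c("gdt_ha", "rmsd", "gdc_sc",
                                            "sphgr", "mp"))] <-
    recs2[recs2$group == "G2", paste0("d_", c("gdt_ha", "rmsd", "gdc_sc",
                                              "sphgr", "mp"))]
  c2 <- head_to_head_counts(recs2, c("G2", "G3"))
  expect_true(all(c2$n_outperformed == 0L))
  # groups outside the list are never tested
  c3 <- head_to_head_counts(recs, c("G1", "G2"))
  expect_false("G3" %in% c3$group)
})

test_that("cherry-picking maximises pooled S_p with deterministic ties", {
  mkrec <- function(group, idx, d) {
    data.frame(group = group, target = "t1", model_index = idx,
               d_gdt_ha = d, d_rmsd = -d / 10, d_gdc_sc = d / 2,
               d_sphgr = d / 2, d_mp = -d / 5, stringsAsFactors = FALSE)
  }
  # five identical submissions: pick model 1
  recs <- rbind(mkrec("A", 1:5, rep(2, 5)),
                mkrec("B", 1:5, c(0, 1, 5, 1, 0)),
                mkrec("C", 1, 3))
  picks <- cherry_pick(recs)
  expect_equal(picks$model_index[picks$group == "A"], 1L)
  # planted best at index 3
  expect_equal(picks$model_index[picks$group == "B"], 3L)
  expect_false(picks$was_model1[picks$group == "B"])
  # single submission: picked, was_model1 iff index 1
  expect_equal(picks$model_index[picks$group == "C"], 1L)
  expect_true(picks$was_model1[picks$group == "C"])
  # the pick never scores below the group's model 1
  expect_true(all(picks$pooled_sp >= picks$model1_sp - 1e-12))
})

test_that("model-1 identification rates count qualifying targets", {
  picks <- data.frame(group = "G", target = paste0("t", 1:24),
                      model_index = 1L,
                      was_model1 = rep(c(TRUE, FALSE), 12),
                      n_submissions = 5L)
  r <- model1_identification_rate(picks, min_targets = 23)
  expect_equal(r$rate, 50)
  picks$was_model1 <- TRUE
  expect_equal(model1_identification_rate(picks, min_targets = 23)$rate, 100)
  # targets with under 5 submissions do not qualify
  picks$n_submissions[1:5] <- 4L
  r2 <- model1_identification_rate(picks, min_targets = 19)
  expect_equal(r2$n_targets, 19L)
})

test_that("MR viability thresholds the printed LLG example correctly", {
  llg <- casp10_mr_example()
  mr <- mr_viability(llg, threshold = 60)
  pt <- mr$per_target
  expect_equal(nrow(pt), 13L)
  expect_equal(sum(pt$rescued), 3L)
  expect_setequal(pt$target[pt$rescued], c("TR663", "TR671", "TR747"))
  expect_true(all(pt$best_llg > pt$starting_llg))
  expect_true(pt$starting_viable[pt$target == "TR704"])     # 62.07
  expect_false(pt$rescued[pt$target == "TR679"])            # best 54.35
})

test_that("an LLG of exactly 60 is not viable and gaps are skipped", {
  llg <- data.frame(target = c("t1", "t1", "t2"),
                    model_id = c("t1_starting", "t1_m", "t2_m"),
                    llg = c(30, 60, 70),
                    role = c("starting", "prediction", "prediction"))
  mr <- mr_viability(llg)
  expect_false(mr$per_target$best_viable)                   # strict >
  expect_false(mr$per_target$rescued)
  expect_equal(mr$skipped, "t2")                            # no starting LLG
})
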