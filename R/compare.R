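# Head-to-head statistical comparison, cherry-picking, model-1
# identification, and molecular-replacement viability summaries.

#' One-tailed Wilcoxon signed-rank test on paired deltas
#'
#' Tests the null hypothesis that group A does not perform better than
#' group B on their common targets.  Differences are `(a - b) *
#' better_is`, so `better_is = -1` handles measures where lower raw
#' values are better.  Zero differences are dropped (Wilcoxon's original
#' treatment; `zero = "pratt"` ranks them first and then discards their
#' ranks); tied magnitudes receive average ranks.  For up to
#' `exact_max_n` non-zero differences the p-value comes from the exact
#' null distribution of the signed-rank sum (computed by dynamic
#' programming over the doubled ranks, so ties are handled exactly);
#' above that a normal approximation with continuity and tie correction
#' is used.
#'
#' @param a,b Paired numeric vectors (same targets, same order).
#' @param better_is +1 if larger deltas are better, -1 otherwise.
#' @param alpha Significance level.
#' @param zero `"drop"` or `"pratt"`.
#' @param exact_max_n Largest n for the exact distribution.
#' @return Object of class `pairwise_result`: list with `p`,
#'   `significant`, `statistic` (rank sum of positive differences),
#'   `n_used`, `alpha`.
#' @examples
#' # ten wins with distinct magnitudes: p = 1/1024
#' wilcoxon_one_tailed(2:11 / 10, rep(0, 10))$p
#' @export
wilcoxon_one_tailed <- function(a, b, better_is = 1, alpha = 0.01,
                                zero = c("drop", "pratt"),
                                exact_max_n = 25L) {
  zero <- match.arg(zero)
  stopifnot(length(a) == length(b))
  d <- (a - b) * better_is
  d <- d[!is.na(d)]
  if (length(d) == 0L) stop("no paired differences")
  if (all(d == 0)) {
    return(structure(list(p = 1, significant = FALSE, statistic = 0,
                          n_used = 0L, alpha = alpha),
                     class = "pairwise_result"))
  }
  if (zero == "pratt") {
    r_all <- rank(abs(d))
    r <- r_all[d != 0]
    sgn <- sign(d[d != 0])
  } else {
    d <- d[d != 0]
    r <- rank(abs(d))
    sgn <- sign(d)
  }
  n <- length(r)
  W <- sum(r[sgn > 0])
  if (n <= exact_max_n) {
    p <- signed_rank_tail_p(r, W)
  } else {
    mu <- sum(r) / 2
    sig2 <- sum(r^2) / 4  # tie-corrected: ties shrink sum(r^2) via average ranks
    z <- (W - mu - 0.5) / sqrt(sig2)
    p <- pnorm(z, lower.tail = FALSE)
  }
  structure(list(p = p, significant = p < alpha, statistic = W,
                 n_used = n, alpha = alpha),
            class = "pairwise_result")
}

# exact P(W >= w) for the signed-rank sum with ranks r (possibly
# half-integer average ranks): dynamic programme over doubled ranks,
# equivalent to enumerating all 2^n sign assignments
signed_rank_tail_p <- function(r, w) {
  r2 <- as.integer(round(2 * r))
  w2 <- as.integer(round(2 * w))
  total <- sum(r2)
  cnt <- numeric(total + 1L)
  cnt[1L] <- 1
  for (x in r2) {
    shifted <- c(numeric(x), cnt[seq_len(total + 1L - x)])
    cnt <- cnt + shifted
  }
  sum(cnt[seq.int(w2 + 1L, total + 1L)]) / 2^length(r2)
}

#' @export
print.pairwise_result <- function(x, ...) {
  cat(sprintf("<pairwise_result> W = %.1f, n = %d, one-tailed p = %.5g (%ssignificant at %.2g)\n",
              x$statistic, x$n_used, x$p,
              if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' Count significantly outperformed groups, per group and measure
#'
#' For every ordered pair of the listed groups, a one-tailed Wilcoxon
#' signed-rank test on their paired per-target deltas over common
#' targets; a significant result at `alpha` counts as one outperformed
#' group for the winner.  No multiple-testing correction is applied.
#'
#' @param records Data frame of model-1 rows with columns `group`,
#'   `target` and delta columns `d_<metric>`.
#' @param groups Character vector of groups to compare (e.g. the top 11
#'   of the ranking); pairs outside this list are never tested.
#' @param metrics Measures to test.
#' @param alpha Significance level.
#' @return Data frame with `group`, `metric`, `n_outperformed`;
#'   attribute `skipped` lists pairs without common targets.
#' @export
head_to_head_counts <- function(records, groups, metrics = METRICS,
                                alpha = 0.01) {
  stopifnot(length(groups) >= 2L)
  counts <- expand.grid(group = groups, metric = metrics,
                        stringsAsFactors = FALSE)
  counts$n_outperformed <- 0L
  skipped <- character(0)
  for (ga in groups) {
    ra <- records[records$group == ga, , drop = FALSE]
    for (gb in setdiff(groups, ga)) {
      rb <- records[records$group == gb, , drop = FALSE]
      common <- intersect(ra$target, rb$target)
      if (length(common) == 0L) {
        skipped <- c(skipped, paste(ga, gb, sep = " vs "))
        next
      }
      ia <- match(common, ra$target)
      ib <- match(common, rb$target)
      for (q in metrics) {
        da <- ra[[paste0("d_", q)]][ia]
        db <- rb[[paste0("d_", q)]][ib]
        ok <- !is.na(da) & !is.na(db)
        if (sum(ok) == 0L || all((da[ok] - db[ok]) == 0)) next
        res <- wilcoxon_one_tailed(da[ok], db[ok],
                                   better_is = METRIC_DIRECTIONS[[q]],
                                   alpha = alpha)
        if (res$significant) {
          i <- counts$group == ga & counts$metric == q
          counts$n_outperformed[i] <- counts$n_outperformed[i] + 1L
        }
      }
    }
  }
  structure(counts, skipped = skipped)
}

#' Pooled S_p scores and a posteriori cherry-picking
#'
#' For each target, all assessed submissions (every group, every model
#' index) are pooled; robust Z-scores and S_p are recomputed on this
#' larger population.  `cherry_pick()` then selects, per group and
#' target, the submission with the largest pooled S_p, ties going to the
#' lowest model index.
#'
#' @param records Data frame of all assessed submissions with columns
#'   `group`, `target`, `model_index` and delta columns `d_<metric>`.
#' @param variant,mad_constant Passed to [robust_z()].
#' @return `pooled_sp()`: `records` with pooled `z_`, `zc_`, `s_p`
#'   columns.  `cherry_pick()`: data frame with one row per (group,
#'   target): `model_index` of the pick, its `pooled_sp`, `was_model1`,
#'   and `model1_sp` (the pooled S_p of the model-1 entry, NA when the
#'   group submitted no model 1 for that target).
#' @export
pooled_sp <- function(records, variant = "mad", mad_constant = 1) {
  score_records(records, variant = variant, mad_constant = mad_constant)
}

#' @rdname pooled_sp
#' @export
cherry_pick <- function(records, variant = "mad", mad_constant = 1) {
  pooled <- pooled_sp(records, variant, mad_constant)
  out <- list()
  for (t_ in unique(pooled$target)) {
    rt <- pooled[pooled$target == t_, , drop = FALSE]
    for (g in unique(rt$group)) {
      rg <- rt[rt$group == g, , drop = FALSE]
      rg <- rg[order(-rg$s_p, rg$model_index), , drop = FALSE]
      m1 <- rg$s_p[rg$model_index == 1L]
      out[[length(out) + 1L]] <-
        data.frame(target = t_, group = g,
                   model_index = rg$model_index[1L],
                   pooled_sp = rg$s_p[1L],
                   was_model1 = rg$model_index[1L] == 1L,
                   model1_sp = if (length(m1)) m1[1L] else NA_real_,
                   n_submissions = nrow(rg),
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Rate at which groups correctly labeled their best model as model 1
#'
#' Over targets where a group submitted `n_models_required` assessed
#' models, the percentage for which the a posteriori cherry-pick is the
#' model-1 entry.  Groups qualifying on fewer than `min_targets` targets
#' are dropped.
#'
#' @param picks Output of [cherry_pick()].
#' @param n_models_required Submissions needed for a target to qualify.
#' @param min_targets Minimum qualifying targets per group.
#' @return Data frame with `group`, `n_targets`, `rate` (percent).
#' @export
model1_identification_rate <- function(picks, n_models_required = 5L,
                                       min_targets = 23L) {
  p <- picks[picks$n_submissions >= n_models_required, , drop = FALSE]
  if (nrow(p) == 0L) stop("no target with ", n_models_required,
                          " assessed submissions")
  out <- lapply(split(p, p$group), function(r) {
    data.frame(group = r$group[1L], n_targets = nrow(r),
               rate = 100 * mean(r$was_model1), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[out$n_targets >= min_targets, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Molecular-replacement viability from LLG scores
#'
#' A model with a log-likelihood gain strictly above the threshold
#' (default 60) is deemed a viable molecular-replacement search model.
#' A target is "rescued" when its starting model is below the threshold
#' but the best submitted model is above it.
#'
#' @param llg Data frame with columns `target`, `model_id`, `llg` and
#'   `role` (`"starting"` or `"prediction"`); an optional `group` column
#'   enables the per-group summary.
#' @param threshold Viability threshold on the LLG (strict inequality).
#' @return List with `per_target` (starting and best LLG, viability and
#'   rescue flags), `per_group` (count of viable models and mean delta
#'   LLG; NULL without a `group` column), and `skipped` (targets lacking
#'   a starting LLG).
#' @export
mr_viability <- function(llg, threshold = 60) {
  stopifnot(all(c("target", "model_id", "llg", "role") %in% names(llg)))
  per_target <- list()
  skipped <- character(0)
  for (t_ in unique(llg$target)) {
    rt <- llg[llg$target == t_, , drop = FALSE]
    s <- rt[rt$role == "starting", , drop = FALSE]
    p <- rt[rt$role == "prediction", , drop = FALSE]
    if (nrow(s) == 0L || nrow(p) == 0L) {
      skipped <- c(skipped, t_)
      next
    }
    best <- p[which.max(p$llg), , drop = FALSE]
    per_target[[length(per_target) + 1L]] <-
      data.frame(target = t_, starting_llg = s$llg[1L],
                 best_model = best$model_id, best_llg = best$llg,
                 starting_viable = s$llg[1L] > threshold,
                 best_viable = best$llg > threshold,
                 rescued = s$llg[1L] < threshold & best$llg > threshold,
                 stringsAsFactors = FALSE)
  }
  per_target <- if (length(per_target)) do.call(rbind, per_target) else NULL
  per_group <- NULL
  if ("group" %in% names(llg) && !is.null(per_target)) {
    p <- llg[llg$role == "prediction" & !is.na(llg$group), , drop = FALSE]
    p <- p[p$target %in% per_target$target, , drop = FALSE]
    if (nrow(p) > 0L) {
      p$start_llg <- per_target$starting_llg[match(p$target, per_target$target)]
      per_group <- do.call(rbind, lapply(split(p, p$group), function(r) {
        data.frame(group = r$group[1L],
                   n_viable = sum(r$llg > threshold),
                   mean_delta_llg = mean(r$llg - r$start_llg),
                   n_models = nrow(r), stringsAsFactors = FALSE)
      }))
      per_group <- per_group[order(-per_group$n_viable,
                                   -per_group$mean_delta_llg), , drop = FALSE]
      rownames(per_group) <- NULL
    }
  }
  list(per_target = per_target, per_group = per_group, skipped = skipped)
}

#' The CASP10 molecular-replacement worked example
#'
#' The LLG scores of the starting model and best submitted model for the
#' 13 crystallographic refinement targets of the CASP10 round, shipped
#' under `inst/extdata/casp10_mr_llg.tsv`, reshaped for
#' [mr_viability()]: thresholding at 60 identifies exactly three rescued
#' targets, and the best model beats the starting model in all 13 cases.
#'
#' @return Data frame with columns `target`, `model_id`, `llg`, `role`.
#' @export
casp10_mr_example <- function() {
  path <- system.file("extdata", "casp10_mr_llg.tsv", package = "refassess",
                      mustWork = TRUE)
  tb <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  rbind(
    data.frame(target = tb$target,
               model_id = paste0(tb$target, "_starting"),
               llg = tb$starting_llg, role = "starting",
               stringsAsFactors = FALSE),
    data.frame(target = tb$target, model_id = tb$best_model,
               llg = tb$best_llg, role = "prediction",
               stringsAsFactors = FALSE))
}
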