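# Delta scores, target-wise robust Z-scores, clipping, the combined S_p
# score, the naive baseline and group ranking tables.

# direction of merit: +1 higher is better, -1 lower is better
METRIC_DIRECTIONS <- c(gdt_ha = 1, rmsd = -1, gdc_sc = 1, sphgr = 1, mp = -1)
METRICS <- names(METRIC_DIRECTIONS)

#' Delta scores of a prediction relative to the starting model
#'
#' Componentwise difference Q(prediction) - Q(starting) for the five
#' quality measures.  An absent MolProbity score propagates as NA.
#'
#' @param mv_model,mv_start Metric vectors from [compute_metrics()] (or
#'   named lists with elements gdt_ha, rmsd, gdc_sc, sphgr, mp) for the
#'   same target.
#' @param target Optional target id carried through for bookkeeping; when
#'   both vectors carry a `target` element the ids must agree.
#' @return Named list of the five deltas.
#' @export
delta_scores <- function(mv_model, mv_start, target = NULL) {
  tm <- mv_model$target %||% target
  ts <- mv_start$target %||% target
  if (!is.null(tm) && !is.null(ts) && !identical(tm, ts))
    stop("metric vectors belong to different targets: ", tm, " vs ", ts)
  out <- lapply(METRICS, function(q) {
    a <- mv_model[[q]]; b <- mv_start[[q]]
    if (is.null(a) || is.null(b)) NA_real_ else a - b
  })
  setNames(out, METRICS)
}

#' Target-wise robust Z-scores
#'
#' Z = (x - median) / MAD with MAD the plain median absolute deviation of
#' the values (no normal-consistency constant by default; set
#' `mad_constant = 1.4826` for sensitivity checks).  When the MAD is zero
#' the sample standard deviation substitutes (the center stays at the
#' median); when that is also zero every Z is 0.  NA values are excluded
#' from the statistics and return NA.  The `"mean_sd"` variant uses the
#' parametric mean/standard-deviation standardisation instead.
#'
#' @param x Numeric vector of at least 2 non-NA values (the delta scores
#'   of all assessed predictions for one target, for one measure).
#' @param variant `"mad"` (robust, default) or `"mean_sd"`.
#' @param mad_constant Multiplier on the MAD.
#' @return Numeric vector of Z-scores, same length as `x`.
#' @examples
#' robust_z(c(1, 2, 3, 4, 100))  # the outlier barely moves the others
#' @export
robust_z <- function(x, variant = c("mad", "mean_sd"), mad_constant = 1) {
  variant <- match.arg(variant)
  ok <- !is.na(x)
  if (sum(ok) < 2L) stop("need at least 2 values to standardise")
  v <- x[ok]
  if (variant == "mean_sd") {
    ctr <- mean(v)
    scl <- sd(v)
  } else {
    ctr <- median(v)
    scl <- median(abs(v - ctr)) * mad_constant
    if (scl == 0) scl <- sd(v)
  }
  z <- rep(NA_real_, length(x))
  z[ok] <- if (is.na(scl) || scl == 0) 0 else (v - ctr) / scl
  z
}

#' Clip Z-scores by each measure's direction of merit
#'
#' Negative Z is set to zero for measures where higher raw values are
#' better (GDT-HA, GDC-SC, SphGr); positive Z is set to zero where lower
#' raw values are better (RMSD, MP).  Clipping avoids punishing
#' adventurous predictions that score badly.
#'
#' @param z Numeric vector of raw Z-scores.
#' @param metric One of `r paste(METRICS, collapse = ", ")`.
#' @return Clipped Z, NA preserved.
#' @export
clip_z <- function(z, metric) {
  dir <- METRIC_DIRECTIONS[[metric]]
  if (dir > 0) pmin(pmax(z, 0), Inf) * 1 else pmax(pmin(z, 0), -Inf) * 1
}

#' Combine clipped Z-scores into the overall S_p score
#'
#' S_p = Z_GDT-HA + Z_GDC-SC + Z_SphGr - Z_RMSD - Z_MP on the clipped
#' scores, so every term contributes non-negatively.  An absent MP score
#' contributes 0 and is flagged.
#'
#' @param z_raw Named list/vector of raw Z-scores per measure (NA for an
#'   absent MP).
#' @return List with `z_clipped` (named numeric), `s_p` and `mp_absent`.
#' @examples
#' clip_and_combine(c(gdt_ha = 1, rmsd = -1, gdc_sc = 0.5,
#'                    sphgr = 0.5, mp = 0))$s_p  # 3
#' @export
clip_and_combine <- function(z_raw) {
  zc <- vapply(METRICS, function(q) {
    z <- z_raw[[q]]
    if (is.null(z) || is.na(z)) NA_real_ else clip_z(z, q)
  }, numeric(1))
  contrib <- ifelse(is.na(zc), 0, zc * METRIC_DIRECTIONS[METRICS])
  list(z_clipped = zc, s_p = sum(contrib),
       mp_absent = is.na(zc[["mp"]]))
}

# per-target standardisation of a block of delta columns; records must
# carry d_<metric> columns.  Returns records with z_<metric> (raw),
# zc_<metric> (clipped) and s_p appended.  Statistics are estimated from
# the records themselves (one population per target).
score_records <- function(records, variant = "mad", mad_constant = 1) {
  for (q in METRICS) {
    records[[paste0("z_", q)]] <- NA_real_
  }
  for (t_ in unique(records$target)) {
    i <- which(records$target == t_)
    for (q in METRICS) {
      d <- records[[paste0("d_", q)]][i]
      if (sum(!is.na(d)) >= 2L)
        records[[paste0("z_", q)]][i] <-
          robust_z(d, variant = variant, mad_constant = mad_constant)
    }
  }
  for (q in METRICS) {
    records[[paste0("zc_", q)]] <- clip_z(records[[paste0("z_", q)]], q)
  }
  contrib <- sapply(METRICS, function(q) {
    zc <- records[[paste0("zc_", q)]]
    ifelse(is.na(zc), 0, zc * METRIC_DIRECTIONS[[q]])
  })
  records$s_p <- if (is.matrix(contrib)) rowSums(contrib) else sum(contrib)
  records$mp_absent <- is.na(records$zc_mp)
  records
}

#' Score the naive baseline (the starting model resubmitted)
#'
#' The starting model has all deltas zero by construction.  Its Z-scores
#' are computed from the participants' per-target statistics (the naive
#' model never enters those statistics), then clipped and combined as
#' usual: the baseline earns credit exactly on measures where the median
#' participant made the model worse.
#'
#' @param participant_deltas Data frame of participants' delta columns
#'   `d_gdt_ha`, ..., `d_mp` for one target (model-1 rows).
#' @param variant,mad_constant Passed to [robust_z()].
#' @return List with `z_clipped` and `s_p` for the baseline.
#' @export
naive_baseline <- function(participant_deltas, variant = c("mad", "mean_sd"),
                           mad_constant = 1) {
  variant <- match.arg(variant)
  z <- lapply(METRICS, function(q) {
    d <- participant_deltas[[paste0("d_", q)]]
    d <- d[!is.na(d)]
    if (length(d) < 2L) return(NA_real_)
    # standardise 0 with the participants' center/scale
    if (variant == "mean_sd") {
      ctr <- mean(d); scl <- sd(d)
    } else {
      ctr <- median(d)
      scl <- median(abs(d - ctr)) * mad_constant
      if (scl == 0) scl <- sd(d)
    }
    if (is.na(scl) || scl == 0) 0 else (0 - ctr) / scl
  })
  clip_and_combine(setNames(z, METRICS))
}

#' Rank groups by median S_p over predicted targets
#'
#' Only groups that predicted at least `min_targets` targets are ranked;
#' the others are kept in the unranked remainder.  The naive baseline can
#' be appended as a reference row.
#'
#' @param sp_records Data frame with columns `group`, `target`, `s_p`
#'   (model-1 rows only).
#' @param min_targets Eligibility threshold on the number of predicted
#'   targets.
#' @param naive_sp Optional numeric vector of per-target baseline S_p
#'   values to summarise in a reference row.
#' @param types Optional named character vector group -> type
#'   (human/server).
#' @return Object of class `group_table`: data frame with `group`,
#'   `type`, `n_targets`, `median_sp`, sorted descending by `median_sp`;
#'   ineligible groups in attribute `unranked`.
#' @export
group_ranking <- function(sp_records, min_targets = 23, naive_sp = NULL,
                          types = NULL) {
  stopifnot(all(c("group", "target", "s_p") %in% names(sp_records)))
  med <- vapply(split(sp_records$s_p, sp_records$group), median, numeric(1))
  n <- vapply(split(sp_records$target, sp_records$group),
              function(t_) length(unique(t_)), integer(1))
  tab <- data.frame(group = names(med),
                    type = if (is.null(types)) NA_character_
                           else unname(types[names(med)]),
                    n_targets = as.integer(n[names(med)]),
                    median_sp = as.numeric(med), stringsAsFactors = FALSE)
  eligible <- tab[tab$n_targets >= min_targets, , drop = FALSE]
  if (nrow(eligible) == 0L) stop("no group reaches ", min_targets, " targets")
  unranked <- tab[tab$n_targets < min_targets, , drop = FALSE]
  if (!is.null(naive_sp)) {
    eligible <- rbind(eligible,
                      data.frame(group = "naive", type = "baseline",
                                 n_targets = length(naive_sp),
                                 median_sp = median(naive_sp),
                                 stringsAsFactors = FALSE))
  }
  eligible <- eligible[order(-eligible$median_sp, eligible$group), ,
                       drop = FALSE]
  rownames(eligible) <- NULL
  structure(eligible, class = c("group_table", "data.frame"),
            unranked = unranked, min_targets = min_targets)
}

#' Fractions of models improved, worsened, unchanged per measure
#'
#' Direction-aware tallies of the delta columns: for GDT-HA, GDC-SC and
#' SphGr a positive delta is an improvement, for RMSD and MP a negative
#' one.
#'
#' @param records Data frame carrying delta columns `d_gdt_ha` ...
#'   `d_mp`.
#' @return Data frame with `metric`, `pct_better`, `pct_worse`,
#'   `pct_tied`, `n`.
#' @export
aggregate_improvement_stats <- function(records) {
  out <- lapply(METRICS, function(q) {
    d <- records[[paste0("d_", q)]]
    d <- d[!is.na(d)] * METRIC_DIRECTIONS[[q]]
    n <- length(d)
    data.frame(metric = q,
               pct_better = if (n) 100 * sum(d > 0) / n else NA_real_,
               pct_worse = if (n) 100 * sum(d < 0) / n else NA_real_,
               pct_tied = if (n) 100 * sum(d == 0) / n else NA_real_,
               n = n)
  })
  do.call(rbind, out)
}
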