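# Orchestration: one call from a round directory to the full report
# bundle.
#
# Directory convention:
#   <round>/targets/<T>/native.pdb, <round>/targets/<T>/starting.pdb
#   <round>/submissions/<T>/<group>_<index>.pdb
#   <round>/scores/mp.tsv, <round>/scores/llg.tsv      (optional)
#   <round>/masks/<T>.tsv                              (optional)

#' Build and validate an assessment configuration
#'
#' Collects every tunable of the pipeline with its default: the GDT-HA
#' and GDC-SC cutoff lists, the SphereGrinder radius/tolerance, the
#' Z-score variant and MAD constant, the ranking eligibility threshold,
#' the head-to-head significance level and top-k, the MR viability
#' threshold, and the elastic-network parameters.
#'
#' @param round_dir Round directory (layout above).
#' @param out_dir Report output directory (created on run).
#' @param gdt_cutoffs,gdc_cutoffs Distance cutoff lists, Angstrom.
#' @param sphere_radius,sphere_tol SphereGrinder parameters, Angstrom.
#' @param char_atom_path Optional path to a characteristic-atom TSV.
#' @param min_targets Ranking eligibility threshold.
#' @param variant `"mad"` or `"mean_sd"` Z-score statistics.
#' @param mad_constant Multiplier on the MAD.
#' @param alpha Head-to-head significance level, in (0, 1).
#' @param top_k Number of top-ranked groups entering head-to-head tests.
#' @param mr_threshold LLG viability threshold (strict).
#' @param enm_cutoff,enm_k Elastic-network cutoff (Angstrom) and spring
#'   constant.
#' @param flexe_threshold Thermal-ensemble filter, kcal/mol/residue
#'   (inclusive).
#' @param seed Recorded in the run log (the assessment itself is
#'   deterministic).
#' @return Validated list of class `run_config`.
#' @export
assessment_config <- function(round_dir, out_dir = file.path(round_dir, "reports"),
                              gdt_cutoffs = GDT_HA_CUTOFFS,
                              gdc_cutoffs = GDC_SC_CUTOFFS,
                              sphere_radius = 6, sphere_tol = 2,
                              char_atom_path = NULL,
                              min_targets = 23L,
                              variant = c("mad", "mean_sd"),
                              mad_constant = 1,
                              alpha = 0.01, top_k = 11L,
                              mr_threshold = 60,
                              enm_cutoff = 12, enm_k = 1,
                              flexe_threshold = 0.89,
                              seed = 1L) {
  variant <- match.arg(variant)
  if (!dir.exists(file.path(round_dir, "targets")))
    stop("round directory has no targets/ subdirectory: ", round_dir)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  structure(list(round_dir = round_dir, out_dir = out_dir,
                 gdt_cutoffs = gdt_cutoffs, gdc_cutoffs = gdc_cutoffs,
                 sphere_radius = sphere_radius, sphere_tol = sphere_tol,
                 char_atom_path = char_atom_path,
                 min_targets = as.integer(min_targets), variant = variant,
                 mad_constant = mad_constant, alpha = alpha,
                 top_k = as.integer(top_k), mr_threshold = mr_threshold,
                 enm_cutoff = enm_cutoff, enm_k = enm_k,
                 flexe_threshold = flexe_threshold, seed = as.integer(seed)),
            class = "run_config")
}

#' Run a full refinement assessment
#'
#' Executes the whole pipeline on a round directory: parses every
#' structure, discards submissions with fewer atoms than their starting
#' model, computes the five quality measures and their deltas, the
#' target-wise robust Z-scores, clipping and S_p, the naive baseline and
#' the group ranking, pooled cherry-picking and model-1 identification
#' rates, head-to-head Wilcoxon comparisons among the top groups,
#' hydrogen-bond F1 group scores, elastic-network deformation energies
#' with the adventurousness report, and molecular-replacement viability.
#' Reports are written as versioned TSV files plus a JSON run log; the
#' run is deterministic for fixed inputs and configuration.
#'
#' @param config A [assessment_config()].
#' @return Invisibly, a list with every table of the bundle.
#' @export
run_assessment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cf <- config
  dir.create(cf$out_dir, recursive = TRUE, showWarnings = FALSE)
  char_table <- characteristic_atom_table(cf$char_atom_path)

  tdirs <- list.dirs(file.path(cf$round_dir, "targets"), recursive = FALSE)
  if (length(tdirs) == 0L) stop("stage discovery: no target directories")
  mp_tab <- maybe_score_table(file.path(cf$round_dir, "scores", "mp.tsv"))
  llg_tab <- maybe_score_table(file.path(cf$round_dir, "scores", "llg.tsv"))

  records <- list()
  discards <- list()
  hb_rows <- list()
  flexe_rows <- list()
  start_metrics <- list()
  thermal_rows <- list()

  for (tdir in tdirs) {
    tid <- basename(tdir)
    native <- run_stage(paste("parse native", tid),
                        read_pdb(file.path(tdir, "native.pdb"), "native",
                                 id = tid))
    start <- run_stage(paste("parse starting model", tid),
                       read_pdb(file.path(tdir, "starting.pdb"), "starting"))
    smap <- map_common_residues(start, native)
    mask <- read_mask(file.path(cf$round_dir, "masks", paste0(tid, ".tsv")))
    mv_start <- model_metrics(start, native, smap, char_table, cf,
                              mp_lookup(mp_tab, paste0(tid, "_starting")),
                              mask)
    start_metrics[[tid]] <- mv_start
    net <- build_network(start, cutoff = cf$enm_cutoff, k = cf$enm_k)
    net_native <- build_network(native, cutoff = cf$enm_cutoff, k = cf$enm_k)
    e_start <- deformation_energy(net_native, start)
    tf <- thermal_ensemble_filter(e_start, cf$flexe_threshold)
    thermal_rows[[tid]] <- data.frame(
      target = tid, starting_vs_native = e_start$per_residue,
      within_thermal_ensemble = tf$within, stringsAsFactors = FALSE)
    hb_native <- assign_hbonds(native)

    sdir <- file.path(cf$round_dir, "submissions", tid)
    files <- if (dir.exists(sdir))
      list.files(sdir, pattern = "^.+_[0-9]+\\.pdb$", full.names = TRUE)
    else character(0)
    for (f in files) {
      gi <- sub("\\.pdb$", "", basename(f))
      group <- sub("_[0-9]+$", "", gi)
      index <- as.integer(sub("^.*_", "", gi))
      model_id <- sprintf("%s_%s_%d", tid, group, index)
      model <- run_stage(paste("parse submission", model_id),
                         read_pdb(f, "prediction", id = model_id))
      verdict <- validate_submission(model, start)
      if (!verdict$accept) {
        discards[[length(discards) + 1L]] <-
          data.frame(model_id = model_id, target = tid, group = group,
                     model_index = index, reason = verdict$reason,
                     stringsAsFactors = FALSE)
        next
      }
      map <- map_common_residues(model, native)
      mv <- run_stage(paste("score", model_id),
                      model_metrics(model, native, map, char_table, cf,
                                    mp_lookup(mp_tab, model_id), mask))
      d <- delta_scores(mv, mv_start)
      records[[length(records) + 1L]] <- data.frame(
        target = tid, group = group, model_index = index,
        model_id = model_id, n_common = mv$n_common,
        gdt_ha = mv$gdt_ha, rmsd = mv$rmsd, gdc_sc = mv$gdc_sc,
        sphgr = mv$sphgr, mp = mv$mp,
        masked_gdt_ha = mv$masked_gdt_ha,
        d_gdt_ha = d$gdt_ha, d_rmsd = d$rmsd, d_gdc_sc = d$gdc_sc,
        d_sphgr = d$sphgr, d_mp = d$mp, stringsAsFactors = FALSE)
      if (index == 1L) {
        e <- deformation_energy(net, model)
        flexe_rows[[length(flexe_rows) + 1L]] <- data.frame(
          target = tid, group = group, flexe = e$per_residue,
          delta_gdt_ha = d$gdt_ha, stringsAsFactors = FALSE)
        hb_model <- assign_hbonds(model)
        prf_all <- hbond_prf(hb_model, hb_native, "all")
        prf_mc <- hbond_prf(hb_model, hb_native, "mainchain")
        hb_rows[[length(hb_rows) + 1L]] <- data.frame(
          target = tid, group = group, model_id = model_id,
          f1_all = prf_all$f1, precision_all = prf_all$precision,
          recall_all = prf_all$recall, f1_mainchain = prf_mc$f1,
          precision_mainchain = prf_mc$precision,
          recall_mainchain = prf_mc$recall, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(records) == 0L) stop("stage scoring: no assessable submission")
  records <- do.call(rbind, records)
  discards <- if (length(discards)) do.call(rbind, discards) else
    data.frame(model_id = character(0), target = character(0),
               group = character(0), model_index = integer(0),
               reason = character(0), stringsAsFactors = FALSE)

  # model-1 ranking
  m1 <- records[records$model_index == 1L, , drop = FALSE]
  m1 <- score_records(m1, variant = cf$variant,
                      mad_constant = cf$mad_constant)
  naive_sp <- vapply(split(m1, m1$target),
                     function(r) naive_baseline(r, variant = cf$variant,
                                                mad_constant = cf$mad_constant)$s_p,
                     numeric(1))
  ranking <- group_ranking(m1, min_targets = cf$min_targets,
                           naive_sp = naive_sp)
  improvement <- aggregate_improvement_stats(records)

  # pooled cherry-picking
  picks <- cherry_pick(records, variant = cf$variant,
                       mad_constant = cf$mad_constant)
  m1_rates <- tryCatch(
    model1_identification_rate(picks, min_targets = cf$min_targets),
    error = function(e) NULL)

  # head-to-head among the top-k ranked groups (baseline row excluded)
  top <- setdiff(ranking$group, "naive")
  top <- top[seq_len(min(cf$top_k, length(top)))]
  pairwise <- if (length(top) >= 2L)
    head_to_head_counts(m1, top, alpha = cf$alpha) else NULL

  # hydrogen bonds
  hb <- if (length(hb_rows)) do.call(rbind, hb_rows) else NULL
  hb_groups <- if (!is.null(hb) && length(unique(hb$group)) >= 2L) {
    hbf <- data.frame(group = hb$group, target = hb$target, f1 = hb$f1_all,
                      stringsAsFactors = FALSE)
    hbond_group_scores(hbf, variant = cf$variant,
                       mad_constant = cf$mad_constant)
  } else NULL

  # elastic network
  flexe <- if (length(flexe_rows)) do.call(rbind, flexe_rows) else NULL
  adventure <- if (!is.null(flexe)) adventurousness_report(flexe) else NULL
  thermal <- do.call(rbind, thermal_rows)

  # molecular replacement
  mr <- NULL
  if (!is.null(llg_tab)) {
    ids <- llg_tab$model_id
    starting_rows <- grepl("_starting$", ids)
    tid_of <- ifelse(starting_rows, sub("_starting$", "", ids),
                     sub("^([^_]+)_.*$", "\\1", ids))
    group_of <- ifelse(starting_rows, NA_character_,
                       sub("^[^_]+_(.*)_[0-9]+$", "\\1", ids))
    llg_df <- data.frame(target = tid_of, model_id = ids,
                         group = group_of, llg = llg_tab$value,
                         role = ifelse(starting_rows, "starting",
                                       "prediction"),
                         stringsAsFactors = FALSE)
    # only assessed submissions count
    llg_df <- llg_df[llg_df$role == "starting" |
                       llg_df$model_id %in% records$model_id, , drop = FALSE]
    mr <- mr_viability(llg_df, threshold = cf$mr_threshold)
  }

  bundle <- list(records = records, model1 = m1, naive_sp = naive_sp,
                 ranking = ranking, improvement = improvement,
                 picks = picks, model1_rates = m1_rates,
                 pairwise = pairwise, hbonds = hb, hbond_groups = hb_groups,
                 flexe = flexe, adventurousness = adventure,
                 thermal = thermal, mr = mr, discards = discards,
                 config = cf)
  write_bundle(bundle, cf)
  invisible(bundle)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
}

model_metrics <- function(model, native, map, char_table, cf, mp, mask) {
  mv <- list(gdt_ha = gdt_ha(model, native, map, cutoffs = cf$gdt_cutoffs),
             rmsd = ca_rmsd(model, native, map),
             gdc_sc = gdc_sc(model, native, map, char_table,
                             cutoffs = cf$gdc_cutoffs),
             sphgr = sphere_grinder(model, native, map,
                                    radius = cf$sphere_radius,
                                    tol = cf$sphere_tol),
             mp = mp, n_common = map$n_common)
  mv$masked_gdt_ha <- if (is.null(mask)) NA_real_ else
    gdt_ha(model, native, map, cutoffs = cf$gdt_cutoffs, exclude = mask)
  mv
}

mp_lookup <- function(tab, id) {
  if (is.null(tab)) return(NA_real_)
  v <- tab$value[match(id, tab$model_id)]
  if (length(v)) v else NA_real_
}

maybe_score_table <- function(path) {
  if (file.exists(path)) read_score_table(path) else NULL
}

# residue exclusion mask: TSV with columns chain, resno and optional
# icode; returns residue-key strings or NULL
read_mask <- function(path) {
  if (!file.exists(path)) return(NULL)
  m <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                  stringsAsFactors = FALSE)
  icode <- if ("icode" %in% names(m)) m$icode else ""
  paste(m$chain, m$resno, icode, sep = "\r")
}

REPORT_VERSION <- "refassess-report-v1"

write_bundle <- function(bundle, cf) {
  wt <- function(df, name) {
    if (is.null(df)) return(invisible(NULL))
    path <- file.path(cf$out_dir, name)
    con <- file(path, "w")
    writeLines(paste0("# ", REPORT_VERSION), con)
    write.table(as.data.frame(df), con, sep = "\t", quote = FALSE,
                row.names = FALSE)
    close(con)
  }
  wt(bundle$records, "metrics.tsv")
  keep <- c("target", "group", "model_index", "model_id",
            paste0("d_", METRICS), paste0("z_", METRICS),
            paste0("zc_", METRICS), "s_p", "mp_absent")
  wt(bundle$model1[, keep], "scores.tsv")
  wt(bundle$ranking, "ranking.tsv")
  wt(bundle$pairwise, "pairwise.tsv")
  wt(bundle$picks, "cherrypick.tsv")
  wt(bundle$hbonds, "hbonds.tsv")
  wt(bundle$adventurousness, "flexe.tsv")
  if (!is.null(bundle$mr) && !is.null(bundle$mr$per_target))
    wt(bundle$mr$per_target, "mr.tsv")
  log <- list(report_version = REPORT_VERSION,
              seed = cf$seed,
              round_dir = cf$round_dir,
              n_targets = length(unique(bundle$records$target)),
              n_assessed = nrow(bundle$records),
              n_discarded = nrow(bundle$discards),
              discarded = bundle$discards,
              thermal = bundle$thermal,
              mr_skipped = bundle$mr$skipped %||% character(0),
              pairwise_skipped = attr(bundle$pairwise, "skipped") %||%
                character(0),
              params = cf[setdiff(names(cf), c("round_dir", "out_dir"))])
  jsonlite::write_json(log, file.path(cf$out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(NULL)
}
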