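#' Twin pedigree for heritability simulations
#'
#' Builds a pedigree of independent nuclear families, each contributing one
#' monozygotic or dizygotic twin pair. Twin ids are attached as attribute
#' `"twin_ids"` so phenotype simulation and fitting can be restricted to
#' the twins.
#'
#' @param n_mz,n_dz Numbers of MZ and DZ twin pairs.
#' @return A `pedigree` data.frame (parents included as founders).
#' @export
make_twin_pedigree <- function(n_mz, n_dz) {
  rows <- list()
  twins <- character(0)
  fam <- 0
  add_family <- function(mz) {
    fam <<- fam + 1
    fid <- sprintf("F%04d", fam)
    mid <- sprintf("M%04d", fam)
    t1 <- sprintf("T%04da", fam)
    t2 <- sprintf("T%04db", fam)
    grp <- if (mz) sprintf("MZ%04d", fam) else NA_character_
    rows[[length(rows) + 1]] <<- data.frame(
      id = c(fid, mid, t1, t2),
      father = c(NA, NA, fid, fid),
      mother = c(NA, NA, mid, mid),
      mz_group = c(NA, NA, grp, grp))
    twins <<- c(twins, t1, t2)
  }
  for (i in seq_len(n_mz)) add_family(TRUE)
  for (i in seq_len(n_dz)) add_family(FALSE)
  ped <- validate_pedigree(do.call(rbind, rows))
  attr(ped, "twin_ids") <- twins
  ped
}

#' Demo configuration for the full pipeline
#'
#' A small, fully seeded cohort that exercises every stage: 16 subjects, 4
#' homotopic pairs, 300 frames, two resting sessions, one task run with a
#' block design, a planted negative HoFC-LI coupling and age drift, a twin
#' sample for heritability, and both mediation models.
#'
#' @param seed Integer master seed.
#' @return A named list understood by [run_full_analysis()].
#' @export
make_demo_config <- function(seed = 42) {
  list(
    seed = as.integer(seed),
    n_subjects = 16, n_pairs = 4, n_frames = 300, tr = 0.72,
    rho_homotopic = 0.5, intra_base = 0.2, asym = 0.1, cross_bg = 0.05,
    coupling = -0.8, rho_sd = 0.08, asym_sd = 0.05,
    age_range = c(20, 80), age_slopes = list(rho = -0.003, asym = 0.0005),
    ar1 = 0.3,
    task_rho_scale = 0.7,
    events = data.frame(
      onset = c(0, 30, 60, 120, 150, 180),
      duration = c(30, 30, 30, 30, 30, 30),
      condition = c("fixation", "A", "B", "fixation", "A", "B")),
    task_beta = 1,
    n_mz = 25, n_dz = 25, h2 = c(0.6, 0.3), rho_g = -0.5,
    n_cog = 4, cca_noise = 1,
    n_perm = 199, n_boot = 500,
    stages = c("simulate", "measures", "reliability", "groupstats",
               "cca", "heritability", "mediation"))
}

stage_meta <- function(config, stage) {
  tmp <- tempfile()
  writeLines(deparse(config[order(names(config))]), tmp)
  h <- unname(tools::md5sum(tmp))
  unlink(tmp)
  list(config_hash = h, seed = config$seed, stage = stage)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes, in dependency order, every enabled stage of the analysis:
#' cohort simulation (two resting sessions plus a task run), time-series
#' preparation, HoFC/LI measurement, test-retest reliability, across-
#' subject association and zone statistics, brain-cognition CCA,
#' twin-sample heritability, and the two mediation models. Every output is
#' a TSV with a metadata header; the returned manifest lists each file with
#' its MD5 checksum, so a rerun under the same configuration is verifiably
#' byte-identical.
#'
#' @param config Configuration list, see [make_demo_config()].
#' @param out_dir Output directory; must be empty unless `force = TRUE`.
#' @param force Overwrite existing outputs.
#' @return data.frame manifest (`file`, `md5`), invisibly; also written as
#'   `manifest.tsv`.
#' @export
run_full_analysis <- function(config = make_demo_config(),
                              out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force)
    stop("output directory is not empty (use force = TRUE)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages
  outputs <- character(0)
  log_lines <- character(0)
  current_stage <- "init"
  emit <- function(df, name, stage) {
    path <- file.path(out_dir, name)
    write_result_table(df, path, meta = stage_meta(config, stage))
    outputs <<- c(outputs, path)
  }

  withCallingHandlers({
    atlas <- make_synthetic_atlas(config$n_pairs)
    scfg <- simulation_config(
      atlas, config$n_subjects, config$n_frames, config$tr,
      rho_homotopic = config$rho_homotopic, intra_base = config$intra_base,
      asym = config$asym, cross_bg = config$cross_bg,
      coupling = config$coupling, rho_sd = config$rho_sd,
      asym_sd = config$asym_sd, age_range = config$age_range,
      age_slopes = config$age_slopes, ar1 = config$ar1, seed = config$seed)
    tcfg <- scfg
    tcfg$rho_homotopic <- scfg$rho_homotopic * config$task_rho_scale

    current_stage <- "simulate"
    if (!"simulate" %in% stages)
      stop("stage 'simulate' is required by every downstream stage")
    rest1 <- suppressWarnings(simulate_cohort(scfg, session = 1))
    rest2 <- suppressWarnings(simulate_cohort(scfg, session = 2))
    task <- suppressWarnings(simulate_cohort(tcfg, session = 3,
                                             events = config$events,
                                             betas = config$task_beta))
    emit(rest1$covariates, "covariates.tsv", "simulate")
    emit(rest1$truth, "truth.tsv", "simulate")

    prep1 <- lapply(rest1$timeseries, prep_rest)
    prep2 <- lapply(rest2$timeseries, prep_rest)
    prept <- lapply(task$timeseries, prep_task, events = config$events)

    m1 <- cohort_measures(prep1, atlas)
    m2 <- cohort_measures(prep2, atlas)
    mt <- cohort_measures(prept, atlas)
    if ("measures" %in% stages) {
      current_stage <- "measures"
      long <- function(mm, state) data.frame(
        subject_id = rep(rownames(mm$hofc), ncol(mm$hofc)),
        pair_id = rep(colnames(mm$hofc), each = nrow(mm$hofc)),
        state = state, hofc = as.vector(mm$hofc), L = as.vector(mm$L),
        R = as.vector(mm$R), li = as.vector(mm$li))
      emit(rbind(long(m1, "rest1"), long(m2, "rest2"), long(mt, "task")),
           "subject_measures.tsv", "measures")
      emit(data.frame(subject_id = rownames(m1$hofc),
                      mean_fc_rest1 = m1$mean_fc, mean_fc_rest2 = m2$mean_fc,
                      mean_fc_task = mt$mean_fc),
           "meanfc.tsv", "measures")
    }

    if ("reliability" %in% stages) {
      current_stage <- "reliability"
      rh <- reliability_summary(m1$hofc, m2$hofc)
      rl <- reliability_summary(m1$li, m2$li)
      emit(data.frame(measure = rep(c("hofc", "li"),
                                    each = length(rh$icc)),
                      pair_id = rep(colnames(m1$hofc), 2),
                      icc = c(rh$icc, rl$icc)),
           "reliability_icc.tsv", "reliability")
      emit(data.frame(measure = rep(c("hofc", "li"),
                                    each = length(rh$pattern_similarity)),
                      subject_id = rep(rownames(m1$hofc), 2),
                      pattern_similarity = c(rh$pattern_similarity,
                                             rl$pattern_similarity)),
           "reliability_similarity.tsv", "reliability")
    }

    cov_design <- cbind(age = rest1$covariates$age,
                        sex = rest1$covariates$sex,
                        mean_fc = m1$mean_fc)
    if ("groupstats" %in% stages) {
      current_stage <- "groupstats"
      assoc <- li_hofc_association(m1$li, m1$hofc, cov_design)
      emit(assoc, "association.tsv", "groupstats")
      zsub <- zone_average(m1$hofc, atlas)
      zone_rows <- data.frame(zone = colnames(zsub),
                              mean_hofc = colMeans(zsub),
                              mean_li = colMeans(zone_average(m1$li, atlas)))
      emit(zone_rows, "zones.tsv", "groupstats")
      age_eff <- do.call(rbind, lapply(seq_len(n_pairs(atlas)), function(j) {
        g <- glm_effect(m1$li[, j], rest1$covariates$age,
                        cbind(sex = rest1$covariates$sex,
                              mean_fc = m1$mean_fc))
        data.frame(pair_id = atlas$pairs$pair_id[j], beta_age = g$beta,
                   p = g$p)
      }))
      age_eff$p_bonferroni <- bonferroni(age_eff$p)
      emit(age_eff, "age_effects.tsv", "groupstats")
      ph <- paired_ttest(rowMeans(m1$hofc), rowMeans(mt$hofc))
      pl <- paired_ttest(rowMeans(m1$li), rowMeans(mt$li))
      r_rest <- stats::cor(as.vector(m1$hofc), as.vector(m1$li))
      r_task <- stats::cor(as.vector(mt$hofc), as.vector(mt$li))
      fz <- fisher_z_compare(r_rest, length(m1$hofc), r_task, length(mt$hofc))
      emit(data.frame(contrast = c("hofc_rest_vs_task", "li_rest_vs_task",
                                   "hofc_li_corr_rest_vs_task"),
                      statistic = c(ph$t, pl$t, fz$zstat),
                      p = c(ph$p, pl$p, fz$p)),
           "state_compare.tsv", "groupstats")
    }

    if ("cca" %in% stages) {
      current_stage <- "cca"
      set.seed(config$seed + 1L)
      gfac <- as.numeric(scale(rowMeans(m1$hofc) - rowMeans(m1$li)))
      wts <- seq(1, 0.4, length.out = config$n_cog)
      cog <- outer(gfac, wts) +
        matrix(stats::rnorm(config$n_subjects * config$n_cog,
                            sd = config$cca_noise),
               config$n_subjects)
      colnames(cog) <- paste0("cog", seq_len(config$n_cog))
      brain <- cbind(m1$hofc, m1$li)
      colnames(brain) <- c(paste0("hofc_", colnames(m1$hofc)),
                           paste0("li_", colnames(m1$li)))
      Xb <- residualize_table(brain, cov_design)
      Yc <- residualize_table(cog, cov_design[, c("age", "sex"), drop = FALSE])
      fit <- suppressWarnings(cca_fit(Xb, Yc))
      perm <- suppressWarnings(
        cca_permutation_test(Xb, Yc, n_perm = config$n_perm,
                             seed = config$seed + 2L))
      emit(data.frame(mode = seq_along(fit$cor), canonical_r = fit$cor,
                      p_perm = perm$p_perm[seq_along(fit$cor)]),
           "cca_modes.tsv", "cca")
      lo <- cca_loadings(Xb, fit$xscores)
      hl <- lo$loadings[seq_len(n_pairs(atlas)), 1]
      ll <- lo$loadings[n_pairs(atlas) + seq_len(n_pairs(atlas)), 1]
      lc <- loading_correlation(hl, ll)
      emit(data.frame(variable = rownames(lo$loadings),
                      loading_mode1 = lo$loadings[, 1],
                      contributive = lo$contributive[, 1]),
           "cca_loadings.tsv", "cca")
      emit(data.frame(quantity = "hofc_li_loading_correlation",
                      r = lc$r, p = lc$p),
           "cca_loading_correlation.tsv", "cca")
    }

    if ("heritability" %in% stages) {
      current_stage <- "heritability"
      ped <- make_twin_pedigree(config$n_mz, config$n_dz)
      twins <- attr(ped, "twin_ids")
      phi <- kinship_from_pedigree(ped)[twins, twins]
      ph <- simulate_family_phenotypes(phi, h2 = config$h2, n_traits = 2,
                                       rho_g = config$rho_g,
                                       seed = config$seed + 3L)
      eig <- kinship_eigen(phi)
      f1 <- fit_univariate_vc(ph[, 1], phi, eig)
      f2 <- fit_univariate_vc(ph[, 2], phi, eig)
      fb <- fit_bivariate_vc(ph[, 1], ph[, 2], phi, eig)
      emit(data.frame(trait = c("hofc_like", "li_like"),
                      h2 = c(f1$h2, f2$h2),
                      lrt_p = c(f1$lrt_p, f2$lrt_p)),
           "heritability.tsv", "heritability")
      emit(data.frame(pair = "hofc_like~li_like", rho_g = fb$rho_g,
                      rho_e = fb$rho_e, p = fb$rho_g_p),
           "genetic_correlations.tsv", "heritability")
    }

    if ("mediation" %in% stages) {
      current_stage <- "mediation"
      between <- mediate_between(
        x = rest1$covariates$age,
        m = rowMeans(m1$hofc), y = rowMeans(m1$li),
        covariates = cbind(sex = rest1$covariates$sex, mean_fc = m1$mean_fc),
        n_boot = config$n_boot, seed = config$seed + 4L)
      within <- mediate_within(
        m1 = rowMeans(m1$hofc), m2 = rowMeans(mt$hofc),
        y1 = rowMeans(m1$li), y2 = rowMeans(mt$li),
        covariates = cbind(age = rest1$covariates$age,
                           sex = rest1$covariates$sex),
        n_boot = config$n_boot, seed = config$seed + 5L)
      med_row <- function(model, r) data.frame(
        model = model, path_a = r$path_a, path_b = r$path_b,
        path_c = r$path_c, path_c_prime = r$path_c_prime,
        indirect = r$indirect, ci_low = r$ci_low, ci_high = r$ci_high,
        significant = r$significant)
      emit(rbind(med_row("between_age", between),
                 med_row("within_state", within)),
           "mediation.tsv", "mediation")
    }
  },
  warning = function(w) {
    log_lines <<- c(log_lines,
                    paste0(current_stage, "\t", conditionMessage(w)))
    invokeRestart("muffleWarning")
  })

  log_df <- if (length(log_lines) > 0)
    data.frame(stage = sub("\t.*", "", log_lines),
               message = sub("^[^\t]*\t", "", log_lines))
  else data.frame(stage = character(0), message = character(0))
  write_result_table(log_df, file.path(out_dir, "pipeline_log.tsv"),
                     meta = stage_meta(config, "log"))
  outputs <- c(outputs, file.path(out_dir, "pipeline_log.tsv"))
  manifest <- data.frame(file = basename(outputs),
                         md5 = unname(tools::md5sum(outputs)))
  write_result_table(manifest, file.path(out_dir, "manifest.tsv"),
                     meta = stage_meta(config, "manifest"))
  invisible(manifest)
}
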