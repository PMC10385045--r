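#' Study configuration
#'
#' Collects every setting of the end-to-end analysis. Defaults mirror the
#' standard acquisition and inference settings of the thermal-coupling
#' protocol: 5 Hz sampling, 150-s segments, 1000 permutations, a 0.45 s RR
#' artifact threshold and alpha = 0.05. The configuration round-trips
#' losslessly through JSON via [write_study_config()] /
#' [read_study_config()].
#'
#' @param input `"synthetic"` or `"csv-dir"`.
#' @param out_dir output directory for result files.
#' @param n_subjects,n_female cohort shape for synthetic input (default
#'   30 subjects, 20 female).
#' @param fs sampling rate in Hz.
#' @param segment_s analysis segment length in seconds.
#' @param n_perm permutation count for significance testing.
#' @param rr_threshold_s RR artifact detection threshold in seconds.
#' @param alpha significance level.
#' @param master_seed master seed; all per-subject seeds derive from it.
#' @param couplings_rest,couplings_stress length-3 driver couplings
#'   (thermal, RR, tonic EDA) used by the synthetic generator per
#'   condition.
#' @param noise_sd synthetic observation noise.
#' @param csv_dir root directory for `csv-dir` input, laid out as
#'   `<subject>/<condition>/<channel>.csv` with a `cohort.csv` metadata
#'   table (`subject`, `gender`).
#' @param rois thermal channel labels treated as regions of interest.
#' @param predictors physiological channel labels used as predictors.
#' @return object of class `study_config`.
#' @export
study_config <- function(input = c("synthetic", "csv-dir"),
                         out_dir = tempfile("thermocm_run_"),
                         n_subjects = 30L, n_female = 20L,
                         fs = 5, segment_s = 150, n_perm = 1000L,
                         rr_threshold_s = 0.45, alpha = 0.05,
                         master_seed = 1L,
                         couplings_rest = c(0.5, 0.5, 0.5),
                         couplings_stress = c(1, 1, 1),
                         noise_sd = 0.05,
                         csv_dir = NULL,
                         rois = "Thermal",
                         predictors = c("HRV", "EDAtonic")) {
  input <- match.arg(input)
  if (input == "csv-dir" && is.null(csv_dir))
    stop("`csv_dir` required for csv-dir input")
  structure(list(input = input, out_dir = out_dir,
                 n_subjects = as.integer(n_subjects),
                 n_female = as.integer(n_female),
                 fs = fs, segment_s = segment_s, n_perm = as.integer(n_perm),
                 rr_threshold_s = rr_threshold_s, alpha = alpha,
                 master_seed = as.integer(master_seed),
                 couplings_rest = as.numeric(couplings_rest),
                 couplings_stress = as.numeric(couplings_stress),
                 noise_sd = noise_sd, csv_dir = csv_dir,
                 rois = rois, predictors = predictors),
            class = "study_config")
}

#' @rdname study_config
#' @param config a `study_config`.
#' @param path JSON file path.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname study_config
#' @export
read_study_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(study_config, x[!vapply(x, is.null, TRUE)])
}

# counter-based per-subject/per-condition sub-seed, kept below 2^31
derive_seed <- function(master_seed, subject, condition_idx, stream = 0L) {
  (as.numeric(master_seed) * 7919 + subject * 1009 +
     condition_idx * 101 + stream * 13) %% 2147483647
}

# synthetic subject record: one triplet per condition, stress typically
# more strongly coupled to the driver
synth_subject <- function(config, i) {
  conds <- list(rest = config$couplings_rest, stress = config$couplings_stress)
  channels <- lapply(seq_along(conds), function(ci) {
    tr <- gen_physio_triplet(duration_s = config$segment_s, fs = config$fs,
                             couplings = conds[[ci]],
                             noise_sd = config$noise_sd,
                             seed = derive_seed(config$master_seed, i, ci))
    list(Thermal = tr$thermal, HRV = tr$rr_like, EDAtonic = tr$eda_tonic_like)
  })
  names(channels) <- names(conds)
  list(subject = sprintf("S%02d", i),
       gender = if (i <= config$n_female) "female" else "male",
       channels = channels)
}

# load one subject from <csv_dir>/<subject>/<condition>/<channel>.csv
load_subject <- function(config, subject, gender) {
  conds <- c("rest", "stress")
  channels <- lapply(conds, function(cond) {
    dir <- file.path(config$csv_dir, subject, cond)
    files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
    if (length(files) == 0L) stop("no channel files in ", dir)
    chans <- lapply(files, function(f)
      read_series_csv(f, label = sub("\\.csv$", "", basename(f))))
    names(chans) <- vapply(chans, function(s) s$label, "")
    chans
  })
  names(channels) <- conds
  list(subject = subject, gender = gender, channels = channels)
}

subject_features <- function(channels, config) {
  out <- numeric(0)
  if ("HRV" %in% names(channels)) {
    hr <- channels$HRV
    # treat the uniformly sampled HRV values as the RR sequence for the
    # time-domain statistics; spectral statistics use the series directly
    pseudo_rr <- rr_series(cumsum(c(0, pmax(hr$values, 1e-3))))
    out <- c(out, feature_row(hrv = hrv_features(pseudo_rr, hr)))
  }
  if ("EDAtonic" %in% names(channels)) {
    dec <- decompose_eda(channels$EDAtonic)
    out <- c(out, feature_row(eda = eda_features(dec)))
  }
  out
}

#' Run the full cross-mapping study
#'
#' End-to-end replica of the analysis: build (or load) the cohort, extract
#' per-condition features, run every predictor-by-ROI cross-mapping per
#' subject and condition with a block permutation test (block length = the
#' target series' embedding delay) on both the cross-map score `rho_YhatY`
#' and the linear baseline `rho_XY`, then the group statistics: paired
#' Wilcoxon tests with two-stage FDR control on the features, Bonferroni-
#' corrected ROI comparisons of the cross-map scores, and a split-plot
#' ANOVA (gender x condition) per predictor and ROI. Subjects whose
#' channels fail preprocessing are excluded from group tests and logged in
#' the manifest.
#'
#' All result files under `config$out_dir` (`results.csv`, `features.csv`,
#' `group_tests.csv`, `roi_tests.csv`, `spanova.csv`, `manifest.json`) are
#' reproducible byte-for-byte from the configuration and master seed.
#'
#' @param config a [study_config()].
#' @return (invisibly) object of class `stat_report` with the pair-level
#'   table, feature table, group tables and the manifest.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (config$input == "synthetic") {
    subjects <- lapply(seq_len(config$n_subjects),
                       function(i) synth_subject(config, i))
  } else {
    meta <- read.csv(file.path(config$csv_dir, "cohort.csv"))
    subjects <- Map(function(s, g) load_subject(config, s, g),
                    meta$subject, meta$gender)
  }

  results <- list()
  feats <- list()
  excluded <- character(0)
  for (si in seq_along(subjects)) {
    sub <- subjects[[si]]
    ok <- TRUE
    for (ci in c(1L, 2L)) {
      cond <- c("rest", "stress")[ci]
      chans <- sub$channels[[cond]]
      row <- tryCatch({
        fr <- subject_features(chans, config)
        feats[[length(feats) + 1L]] <- data.frame(
          subject = sub$subject, gender = sub$gender, condition = cond,
          t(fr), check.names = FALSE)
        for (pred in config$predictors) {
          for (roi in config$rois) {
            res <- suppressWarnings(
              cross_map_pair(chans[[pred]], chans[[roi]]))
            vr <- res$valid_range[1]:res$valid_range[2]
            # block length = target-series delay, capped to keep >= 10
            # blocks in the null
            L <- max(1L, min(res$params_y$tau, length(vr) %/% 10L))
            perm_cm <- block_permutation_test(
              chans[[roi]]$values[vr], res$y_hat, block_length = L,
              n_perm = config$n_perm,
              seed = derive_seed(config$master_seed, si, ci, stream = 1L))
            rho_xy <- spearman_rho(chans[[pred]]$values, chans[[roi]]$values)
            perm_xy <- block_permutation_test(
              chans[[roi]]$values, chans[[pred]]$values, block_length = L,
              n_perm = config$n_perm,
              seed = derive_seed(config$master_seed, si, ci, stream = 2L))
            results[[length(results) + 1L]] <- data.frame(
              subject = sub$subject, gender = sub$gender, condition = cond,
              predictor = pred, roi = roi,
              rho_yhat_y = res$rho, p_yhat_y = perm_cm$p_value,
              rho_xy = rho_xy, p_xy = perm_xy$p_value,
              tau_x = res$params_x$tau, m_x = res$params_x$m,
              tau_y = res$params_y$tau, m_y = res$params_y$m, k = res$k)
          }
        }
        TRUE
      }, error = function(e) {
        message(sprintf("subject %s (%s) excluded: %s",
                        sub$subject, cond, conditionMessage(e)))
        FALSE
      })
      if (!isTRUE(row)) ok <- FALSE
    }
    if (!ok) excluded <- c(excluded, sub$subject)
  }
  results <- do.call(rbind, results)
  feats <- do.call(rbind, feats)
  keep <- !(results$subject %in% excluded)
  results <- results[keep, , drop = FALSE]
  feats <- feats[!(feats$subject %in% excluded), , drop = FALSE]

  # group-level feature comparisons (rest vs stress), two-stage FDR
  feat_cols <- setdiff(names(feats), c("subject", "gender", "condition"))
  group_tests <- do.call(rbind, lapply(feat_cols, function(fc) {
    wide <- merge(feats[feats$condition == "rest", c("subject", fc)],
                  feats[feats$condition == "stress", c("subject", fc)],
                  by = "subject", suffixes = c("_rest", "_stress"))
    a <- wide[[paste0(fc, "_rest")]]
    b <- wide[[paste0(fc, "_stress")]]
    res <- tryCatch(wilcoxon_signed_rank(a, b),
                    error = function(e) list(statistic = NA_real_,
                                             p_value = NA_real_))
    data.frame(feature = fc, statistic = res$statistic, p_value = res$p_value)
  }))
  pv <- group_tests$p_value
  group_tests$significant_fdr_bky <- FALSE
  okp <- !is.na(pv)
  if (any(okp))
    group_tests$significant_fdr_bky[okp] <- fdr_bky(pv[okp], q = config$alpha)

  # ROI comparisons of the cross-map score, Bonferroni within predictor
  roi_tests <- NULL
  if (length(config$rois) >= 2L) {
    combos <- expand.grid(predictor = config$predictors,
                          condition = c("rest", "stress"),
                          stringsAsFactors = FALSE)
    roi_tests <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
      sel <- results$predictor == combos$predictor[i] &
        results$condition == combos$condition[i]
      pairs <- utils::combn(config$rois, 2)
      tests <- apply(pairs, 2, function(pr) {
        a <- results$rho_yhat_y[sel & results$roi == pr[1]]
        b <- results$rho_yhat_y[sel & results$roi == pr[2]]
        wilcoxon_signed_rank(a, b)$p_value
      })
      data.frame(predictor = combos$predictor[i],
                 condition = combos$condition[i],
                 roi_a = pairs[1, ], roi_b = pairs[2, ], p_value = tests,
                 significant_bonferroni = bonferroni(tests, config$alpha))
    }))
  }

  # split-plot ANOVA per predictor x ROI on the cross-map scores
  spanova_tab <- do.call(rbind, lapply(config$predictors, function(pred) {
    do.call(rbind, lapply(config$rois, function(roi) {
      sel <- results$predictor == pred & results$roi == roi
      d <- data.frame(subject = results$subject[sel],
                      gender = results$gender[sel],
                      condition = results$condition[sel],
                      value = results$rho_yhat_y[sel])
      sp <- spanova(d)
      data.frame(predictor = pred, roi = roi,
                 F_between = sp$F_between, p_between = sp$p_between,
                 F_within = sp$F_within, p_within = sp$p_within,
                 F_interaction = sp$F_interaction,
                 p_interaction = sp$p_interaction)
    }))
  }))

  # manifest covers the scientific settings only; output/input paths are
  # excluded so identical analyses give byte-identical result files
  cfg_sci <- unclass(config)
  cfg_sci$out_dir <- NULL
  cfg_sci$csv_dir <- NULL
  cfg_json <- jsonlite::toJSON(cfg_sci, auto_unbox = TRUE,
                               digits = NA, null = "null")
  tf <- tempfile(fileext = ".json"); writeLines(cfg_json, tf)
  manifest <- list(master_seed = config$master_seed,
                   config = cfg_sci,
                   config_md5 = unname(tools::md5sum(tf)),
                   package_version = as.character(utils::packageVersion("thermocm")),
                   n_subjects_analysed = length(subjects) - length(excluded),
                   excluded_subjects = excluded,
                   n_pairs = nrow(results))
  unlink(tf)

  write.csv(results, file.path(config$out_dir, "results.csv"), row.names = FALSE)
  write.csv(feats, file.path(config$out_dir, "features.csv"), row.names = FALSE)
  write.csv(group_tests, file.path(config$out_dir, "group_tests.csv"),
            row.names = FALSE)
  if (!is.null(roi_tests))
    write.csv(roi_tests, file.path(config$out_dir, "roi_tests.csv"),
              row.names = FALSE)
  write.csv(spanova_tab, file.path(config$out_dir, "spanova.csv"),
            row.names = FALSE)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)

  invisible(structure(list(results = results, features = feats,
                           group_tests = group_tests, roi_tests = roi_tests,
                           spanova = spanova_tab, manifest = manifest),
                      class = "stat_report"))
}

#' @export
print.stat_report <- function(x, ...) {
  cat(sprintf("<stat_report> %d cross-map pairs, %d subjects analysed (%d excluded)\n",
              nrow(x$results), x$manifest$n_subjects_analysed,
              length(x$manifest$excluded_subjects)))
  cat(sprintf("  significant cross-map couplings (p < 0.05): %.1f%%\n",
              100 * mean(x$results$p_yhat_y < 0.05)))
  invisible(x)
}
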