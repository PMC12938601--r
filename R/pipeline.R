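#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end pipeline with its default.
#' Defaults follow the reference analysis: 30-channel montage, 8-30 Hz
#' zero-phase FIR, [-1, 4) s epochs with a [-1, 0) s baseline, the
#' four-stage rejection thresholds, per-class Infomax, 15% dipole
#' residual-variance and 0.6 focality screens, 3-40 Hz spectral fits,
#' 200-resample pseudo-T maps at FDR alpha 0.05, [0, 4) s covariance
#' window with 0.05 shrinkage, and 10-fold CV.
#'
#' @param ... Overrides for any default (name = value).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    channels = motor_montage(),
    low_hz = 8, high_hz = 30,
    window = c(-1, 4),
    rejection = rejection_criteria(),
    ica_max_iter = 150, ica_tol = 1e-6,
    rv_threshold = 0.15, focality_threshold = 0.6,
    psd_range = c(8, 30),   # fit within the filtered passband
    band = c(8, 30),
    n_resamples = 500, alpha = 0.05, resel_ms = 100,
    relax_rule2 = FALSE,
    cov_window = c(0, 4), shrinkage = 0.05,
    cv_folds = 10, kmeans_nstart = 20,
    seed = 1)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Run the full pipeline for one subject
#'
#' Preprocesses the recording (channel subset, band-pass, epoching,
#' artifact rejection), decomposes each task class with Infomax, screens
#' and profiles the components, applies the selection rules to obtain
#' the four ERD/ERS components, computes ClassDis from the sensor-space
#' trial covariances, and assembles the eight-feature vector.
#'
#' @param recording A [raw_recording()] containing both task classes.
#' @param config A [pipeline_config()].
#' @param hm A shared [head_model()] (built if omitted).
#' @param subject_id Identifier for logs and outputs.
#' @param subject_index Integer used (with `config$seed`) to fork the
#'   per-subject ICA seed, keeping cohorts reproducible.
#' @return List of class `subject_bundle`: `subject_id`, `selections`
#'   (4-row tibble), `features` (1-row tibble), `classdis`
#'   (a `classdis_result`), `profiles` (per task class), `n_trials`
#'   (kept per class), `log` (tibble of stage decisions).
#' @export
run_subject <- function(recording, config = pipeline_config(), hm = NULL,
                        subject_id = "S001", subject_index = 1L) {
  if (is.null(hm)) hm <- head_model()
  log <- list()
  note <- function(stage, decision, value = NA) {
    log[[length(log) + 1]] <<- tibble::tibble(
      subject = subject_id, stage = stage, decision = decision,
      value = as.character(value))
  }
  rec <- select_channels(recording, config$channels)
  rec <- bandpass_fir(rec, config$low_hz, config$high_hz)
  eps <- extract_epochs(rec, config$window, labels = c("left", "right"))
  selections <- list()
  cov_sets <- list()
  profiles_by_class <- list()
  for (ti in 1:2) {
    task <- c("left", "right")[ti]
    es <- reject_epochs(eps[[task]], config$rejection)
    note(paste0("reject/", task), "kept_trials", sum(es$kept_mask))
    if (sum(es$kept_mask) < 2)
      rlang::abort(paste0("subject ", subject_id, ": all '", task,
                          "' trials rejected"), class = "erdica_no_candidate")
    seed_st <- .fork_seed(config$seed, subject_index * 4L + ti)
    dec <- infomax(es, seed = seed_st, max_iter = config$ica_max_iter,
                   tol = config$ica_tol)
    note(paste0("ica/", task), "converged", dec$converged)
    dec <- reject_ic_epochs(dec, config$rejection)
    note(paste0("ica_reject/", task), "removed", length(dec$rejected_trials))
    # sensor covariances from the same surviving trials
    keep_idx <- which(es$kept_mask)
    if (length(dec$rejected_trials))
      es$kept_mask[keep_idx[dec$rejected_trials]] <- FALSE
    cov_sets[[task]] <- trial_covariances(es, config$cov_window,
                                          config$shrinkage)
    prof <- ic_profiles(dec, hm, band = config$band,
                        rv_threshold = config$rv_threshold,
                        focality_threshold = config$focality_threshold,
                        psd_range = config$psd_range)
    note(paste0("profiles/", task), "screened_ics", nrow(prof))
    # candidates whose significance maps the rules can consult
    contra <- .contra_hemisphere(task)
    r1c <- .rule1_filter(prof, contra, default_motor_atlas())
    topc <- r1c$ic[order(-r1c$relative_power, r1c$center_frequency,
                         r1c$ic)][seq_len(min(3, nrow(r1c)))]
    r1i <- .rule1_filter(prof, task, default_motor_atlas())
    ipsi <- r1i$ic[r1i$peak_present]
    if (!length(ipsi) && config$relax_rule2) ipsi <- r1i$ic
    prof <- with_sig_summaries(prof, dec, ics = union(topc, ipsi),
                               n_resamples = config$n_resamples,
                               alpha = config$alpha, band = config$band,
                               resel_ms = config$resel_ms, seed = seed_st)
    profiles_by_class[[task]] <- prof
    sel_c <- select_contralateral_erd(prof, task, context = subject_id)
    sel_i <- select_ipsilateral_ers(prof, task,
                                    relax_rule2 = config$relax_rule2,
                                    context = subject_id)
    note(paste0("select/", task), "contra_ic", sel_c$ic)
    note(paste0("select/", task), "ipsi_ic", sel_i$ic)
    selections[[task]] <- dplyr::bind_rows(sel_c, sel_i)
  }
  sel <- dplyr::bind_rows(selections)
  cd <- class_distinctiveness(cov_sets$left, cov_sets$right)
  features <- extract_features(sel, cd$classdis, subject_id)
  structure(list(subject_id = subject_id, selections = sel,
                 features = features, classdis = cd,
                 profiles = profiles_by_class,
                 n_trials = vapply(cov_sets, function(s) length(s$mats),
                                   integer(1)),
                 log = dplyr::bind_rows(log)),
            class = "subject_bundle")
}

#' Run the pipeline over a cohort
#'
#' Accepts either a [make_cohort()] profile tibble (subjects are then
#' simulated on the fly and discarded after processing) or a list of
#' [raw_recording()] objects. Per-subject failures are caught and
#' reported; the cohort run continues. With at least 10 successful
#' subjects the cohort stages run: feature regression with k-fold CV,
#' two-stage k-means stratification, and group statistics.
#'
#' @param cohort Profile tibble or list of recordings.
#' @param config A [pipeline_config()].
#' @param hm Shared [head_model()] (built if omitted).
#' @param n_trials_per_hand Trials per hand when simulating from
#'   profiles.
#' @param progress Print per-subject progress lines.
#' @return List of class `cohort_report`: `features`, `stratification`,
#'   `regression`, `cv`, `group_stats`, `classdis_by_group`,
#'   `failures`, `skipped` (cohort stages skipped with reason, if any).
#' @export
run_cohort <- function(cohort, config = pipeline_config(), hm = NULL,
                       n_trials_per_hand = 45, progress = TRUE) {
  if (is.null(hm)) hm <- head_model()
  from_profiles <- is.data.frame(cohort)
  n <- if (from_profiles) nrow(cohort) else length(cohort)
  feats <- list(); fails <- list(); truth <- character(n)
  for (i in seq_len(n)) {
    sid <- if (from_profiles) cohort$subject_id[i] else sprintf("S%03d", i)
    truth[i] <- if (from_profiles) cohort$group_label[i] else NA_character_
    t0 <- Sys.time()
    res <- tryCatch({
      rec <- if (from_profiles)
        simulate_subject(cohort$profile[[i]], n_trials_per_hand,
                         hm = hm)$recording
      else cohort[[i]]
      run_subject(rec, config, hm, subject_id = sid, subject_index = i)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1]] <- tibble::tibble(
        subject_id = sid, error = conditionMessage(res))
      if (progress) message(sprintf("[%s] FAILED: %s", sid,
                                    conditionMessage(res)))
    } else {
      f <- res$features
      f$true_group <- truth[i]
      sel <- res$selections
      pick <- function(role, side, col) {
        v <- sel[[col]][sel$role == role & sel$task_side == side]
        if (length(v)) v[1] else NA_real_
      }
      f$erd_latency_lh <- pick("contra-ERD", "left", "erd_latency")
      f$erd_latency_rh <- pick("contra-ERD", "right", "erd_latency")
      f$erd_area_lh <- pick("contra-ERD", "left", "erd_area")
      f$erd_area_rh <- pick("contra-ERD", "right", "erd_area")
      feats[[length(feats) + 1]] <- f
      if (progress)
        message(sprintf("[%s] ok (%.1f s, ClassDis %.3f)", sid,
                        as.numeric(Sys.time() - t0, units = "secs"),
                        f$classdis))
    }
  }
  features <- dplyr::bind_rows(feats)
  failures <- if (length(fails)) dplyr::bind_rows(fails) else
    tibble::tibble(subject_id = character(), error = character())
  out <- list(features = features, failures = failures, skipped = NULL)
  if (nrow(features) < 10) {
    out$skipped <- paste0("cohort stages skipped: only ", nrow(features),
                          " subjects (need 10)")
    message(out$skipped)
    return(structure(out, class = "cohort_report"))
  }
  out$regression <- fit_regression(features)
  out$cv <- cross_validate(features, k = min(config$cv_folds, nrow(features)),
                           seed = config$seed)
  left <- cluster_one_hand(features, "left", seed = config$seed,
                           nstart = config$kmeans_nstart)
  right <- cluster_one_hand(features, "right", seed = config$seed,
                            nstart = config$kmeans_nstart)
  strat <- assign_groups(left, right, features$subject_id)
  strat$true_group <- features$true_group
  out$stratification <- strat
  fx <- dplyr::left_join(features, strat[, c("subject_id", "group")],
                         by = "subject_id")
  out$group_stats <- tryCatch(group_statistics(fx),
                              error = function(e) conditionMessage(e))
  out$classdis_by_group <- fx |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_classdis = mean(.data$classdis),
                     sd_classdis = stats::sd(.data$classdis),
                     proportion = dplyr::n() / nrow(fx))
  structure(out, class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d subjects (%d failed)\n",
              nrow(x$features), nrow(x$failures)))
  if (!is.null(x$classdis_by_group)) print(x$classdis_by_group)
  if (!is.null(x$skipped)) cat(x$skipped, "\n")
  invisible(x)
}

#' Write a cohort report to disk
#'
#' Writes the features and stratification tables as CSV, the regression
#' and summary quantities as JSON, into `dir`.
#'
#' @param report A [run_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_cohort_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$features, file.path(dir, "features.csv"),
                   row.names = FALSE)
  if (!is.null(report$stratification)) {
    utils::write.csv(report$stratification,
                     file.path(dir, "stratification.csv"), row.names = FALSE)
    utils::write.csv(report$classdis_by_group,
                     file.path(dir, "classdis_by_group.csv"),
                     row.names = FALSE)
  }
  summ <- list(n_subjects = nrow(report$features),
               n_failures = nrow(report$failures))
  if (!is.null(report$regression)) {
    summ$regression <- as.list(generics::glance(report$regression))
    summ$cv <- as.list(report$cv)
    utils::write.csv(generics::tidy(report$regression),
                     file.path(dir, "regression_coefficients.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
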