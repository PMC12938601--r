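#' Assemble IC profiles for the selection rules
#'
#' Runs the non-neural screens (focality, dipole residual variance) on
#' every component of a decomposition and, for the survivors, fits the
#' spectral model and extracts the dominant mu/beta peak. Significance
#' summaries (ERD/ERS region areas and latencies) are filled lazily by
#' [with_sig_summaries()] for the components a selection rule actually
#' needs, since they are the expensive part.
#'
#' @param dec An [infomax()] decomposition.
#' @param hm A [head_model()] (built if omitted).
#' @param band Mu/beta band for the dominant peak.
#' @param rv_threshold Dipole residual-variance screen (see
#'   [screen_rv()]).
#' @param focality_threshold See [screen_focal_components()].
#' @param psd_range Spectral-model fit range in Hz.
#' @return Tibble with one row per component passing both screens:
#'   `ic`, `x`, `y`, `z`, `rv`, `hemisphere`, `peak_present`,
#'   `relative_power` (`-Inf` when no in-band peak, so such components
#'   rank last but remain selectable by the fallback rule),
#'   `center_frequency`, `frequency_width`, and `NA` placeholders for
#'   `erd_area`, `ers_area`, `erd_latency`, `ers_latency`,
#'   `erd_mean_change`, `ers_mean_change`, `scalar_percent`.
#' @export
ic_profiles <- function(dec, hm = NULL, band = c(8, 30), rv_threshold = 0.15,
                        focality_threshold = 0.6, psd_range = c(3, 40)) {
  if (is.null(hm)) hm <- head_model()
  keep_focal <- screen_focal_components(dec, focality_threshold)
  rows <- list()
  for (k in which(keep_focal)) {
    fit <- fit_dipole(dec$topographies[, k], hm)
    if (!screen_rv(fit, rv_threshold)) next
    pk <- tryCatch({
      psd <- welch_psd(dec$activations[, k, ], dec$fs)
      dominant_peak(fit_spectral_model(psd, range_hz = psd_range), band)
    }, error = function(e) NULL)
    rows[[length(rows) + 1]] <- tibble::tibble(
      ic = k, x = fit$position[1], y = fit$position[2], z = fit$position[3],
      rv = fit$residual_variance, hemisphere = fit$hemisphere,
      peak_present = !is.null(pk) && pk$present,
      relative_power = if (!is.null(pk) && pk$present) pk$relative_power else -Inf,
      center_frequency = if (!is.null(pk) && pk$present) pk$center_frequency else NA_real_,
      frequency_width = if (!is.null(pk) && pk$present) pk$frequency_width else NA_real_)
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(ic = integer(), x = numeric(), y = numeric(),
                   z = numeric(), rv = numeric(), hemisphere = character(),
                   peak_present = logical(), relative_power = numeric(),
                   center_frequency = numeric(), frequency_width = numeric())
  out$erd_area <- NA_integer_; out$ers_area <- NA_integer_
  out$erd_latency <- NA_real_; out$ers_latency <- NA_real_
  out$erd_mean_change <- NA_real_; out$ers_mean_change <- NA_real_
  out$scalar_percent <- NA_real_
  out
}

#' Fill significance summaries for selected components
#'
#' Computes the Morlet map, percent-change map, pseudo-T significance
#' and signed connected regions for the given components and writes the
#' largest-ERD / largest-ERS region summaries (and the scalar percent
#' change) into the profile rows.
#'
#' @param profiles An [ic_profiles()] tibble.
#' @param dec The decomposition the profiles came from.
#' @param ics Component indices to evaluate (default: all profile rows).
#' @param n_resamples,alpha See [pseudo_t_significance()].
#' @param band Analysis band for the scalar percent change.
#' @param resel_ms Resel width in ms (see [morlet_tf()]).
#' @param seed Resampling seed.
#' @return The profiles tibble with summaries filled for those rows.
#' @export
with_sig_summaries <- function(profiles, dec, ics = profiles$ic,
                               n_resamples = 200, alpha = 0.05,
                               band = c(8, 30), resel_ms = 50, seed = 1) {
  for (k in intersect(ics, profiles$ic)) {
    i <- which(profiles$ic == k)
    if (!is.na(profiles$erd_area[i])) next
    tf <- morlet_tf(dec$activations, dec$fs, window = dec$window,
                    resel_ms = resel_ms, channel = k)
    ep <- erd_percent(tf, band = band)
    sg <- pseudo_t_significance(tf, n_resamples = n_resamples, alpha = alpha,
                                seed = seed + k)
    regs <- connected_regions(sg, ep$percent)
    erd <- largest_region(regs, "ERD"); ers <- largest_region(regs, "ERS")
    profiles$erd_area[i] <- erd$area
    profiles$ers_area[i] <- ers$area
    profiles$erd_latency[i] <- erd$latency_s
    profiles$ers_latency[i] <- ers$latency_s
    profiles$erd_mean_change[i] <- erd$mean_change
    profiles$ers_mean_change[i] <- ers$mean_change
    profiles$scalar_percent[i] <- ep$scalar_percent
  }
  profiles
}

.contra_hemisphere <- function(task_side) {
  switch(task_side, left = "right", right = "left",
         stop("task_side must be 'left' or 'right'"))
}

.rule1_filter <- function(profiles, hemisphere, atlas) {
  keep <- vapply(seq_len(nrow(profiles)), function(i)
    in_region(c(profiles$x[i], profiles$y[i], profiles$z[i]),
              atlas, hemisphere),
    logical(1))
  profiles[keep, ]
}

.no_candidate <- function(role, task_side, context) {
  rlang::abort(
    message = paste0("no candidate IC for ", role, " during ", task_side,
                     "-hand imagery",
                     if (!is.null(context)) paste0(" (", context, ")")),
    class = "erdica_no_candidate")
}

# shared Rule-3 logic: largest significant area of the requested sign,
# falling back to highest relative power when no candidate has any
.rule3_pick <- function(cand, area_col, change_col) {
  area <- cand[[area_col]]
  area[is.na(area)] <- 0L
  if (any(area > 0)) {
    ord <- order(-area, -abs(cand[[change_col]]), cand$ic)
    list(row = cand[ord[1], ], provenance = "rule3-area")
  } else {
    ord <- order(-cand$relative_power, cand$center_frequency, cand$ic)
    list(row = cand[ord[1], ], provenance = "rule3-fallback-power")
  }
}

#' Select all four components for a subject
#'
#' Applies the contralateral-ERD and ipsilateral-ERS rules to both task
#' classes, yielding the four component picks a subject's feature
#' vector is built from (contralateral for left-hand imagery is the
#' right hemisphere, and so on).
#'
#' @param profiles_left,profiles_right [ic_profiles()] tibbles for the
#'   left- and right-hand task-class decompositions, with significance
#'   summaries filled for the rule candidates.
#' @param atlas Region atlas.
#' @param relax_rule2 See [select_ipsilateral_ers()].
#' @param context Optional subject identifier for error messages.
#' @return Four-row tibble (role x task side) with `provenance`.
#' @export
select_all <- function(profiles_left, profiles_right,
                       atlas = default_motor_atlas(),
                       relax_rule2 = FALSE, context = NULL) {
  profs <- list(left = profiles_left, right = profiles_right)
  dplyr::bind_rows(lapply(c("left", "right"), function(task)
    dplyr::bind_rows(
      select_contralateral_erd(profs[[task]], task, atlas, context),
      select_ipsilateral_ers(profs[[task]], task, atlas, relax_rule2,
                             context))))
}

#' Select the contralateral ERD component
#'
#' Rule 1: the dipole must lie in a contralateral motor-imagery-related
#' region. Rule 2: among survivors, the three components with the
#' highest relative mu/beta power are retained (components without an
#' in-band peak rank last). Rule 3: of those, the component with the
#' largest significant-ERD 4-connected region area wins; when none has
#' a significant ERD region, the highest relative power wins.
#'
#' @param profiles An [ic_profiles()] tibble with significance
#'   summaries filled for the candidates (see [with_sig_summaries()]).
#' @param task_side `"left"` or `"right"` (the imagined hand).
#' @param atlas Region atlas, see [default_motor_atlas()].
#' @param context Optional subject/task identifier used in error
#'   messages.
#' @return One-row tibble: the selected profile row plus `role`,
#'   `task_side` and `provenance` (`"rule3-area"` or
#'   `"rule3-fallback-power"`).
#' @export
select_contralateral_erd <- function(profiles, task_side,
                                     atlas = default_motor_atlas(),
                                     context = NULL) {
  hemi <- .contra_hemisphere(task_side)
  r1 <- .rule1_filter(profiles, hemi, atlas)
  if (!nrow(r1)) .no_candidate("contralateral ERD", task_side, context)
  ord <- order(-r1$relative_power, r1$center_frequency, r1$ic)
  top <- r1[ord[seq_len(min(3, nrow(r1)))], ]
  pick <- .rule3_pick(top, "erd_area", "erd_mean_change")
  dplyr::mutate(pick$row, role = "contra-ERD", task_side = task_side,
                provenance = pick$provenance)
}

#' Select the ipsilateral ERS component
#'
#' Rule 1: the dipole must lie in an ipsilateral motor-imagery-related
#' region. Rule 2: the spectrum must show a prominent oscillatory peak
#' in the mu/beta band (a hard gate). Rule 3: the component with the
#' largest significant-ERS region area wins, falling back to the
#' highest relative mu/beta power when none has significant ERS.
#'
#' @inheritParams select_contralateral_erd
#' @param relax_rule2 If `TRUE` and no Rule-1 survivor has an in-band
#'   peak, fall back to all Rule-1 survivors with provenance
#'   `"rule2-relaxed"` instead of failing (off by default).
#' @return One-row tibble as in [select_contralateral_erd()], with
#'   `provenance` one of `"rule3-area"`, `"rule3-fallback-power"`,
#'   `"rule2-relaxed"`.
#' @export
select_ipsilateral_ers <- function(profiles, task_side,
                                   atlas = default_motor_atlas(),
                                   relax_rule2 = FALSE,
                                   context = NULL) {
  if (!task_side %in% c("left", "right"))
    stop("task_side must be 'left' or 'right'")
  r1 <- .rule1_filter(profiles, task_side, atlas)
  if (!nrow(r1)) .no_candidate("ipsilateral ERS", task_side, context)
  r2 <- r1[r1$peak_present, ]
  relaxed <- FALSE
  if (!nrow(r2)) {
    if (!relax_rule2) .no_candidate("ipsilateral ERS (mu/beta peak)",
                                    task_side, context)
    r2 <- r1; relaxed <- TRUE
  }
  pick <- .rule3_pick(r2, "ers_area", "ers_mean_change")
  prov <- if (relaxed) "rule2-relaxed" else pick$provenance
  dplyr::mutate(pick$row, role = "ipsi-ERS", task_side = task_side,
                provenance = prov)
}
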