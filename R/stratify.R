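#' Assemble a subject's eight-feature vector
#'
#' Collects ERD%, ERS%, relative ERD power and relative ERS power for
#' both imagery sides from the four selected components, plus the
#' subject's ClassDis score. A selected component without an in-band
#' spectral peak contributes relative power 0 (flagged).
#'
#' @param selections Tibble of the four selected component rows (from
#'   the selection rules), carrying `role`, `task_side`,
#'   `scalar_percent`, `relative_power`, `peak_present`.
#' @param classdis The subject's ClassDis value.
#' @param subject_id Identifier carried through.
#' @return One-row tibble: `subject_id`, `erd_pct_lh`, `ers_pct_lh`,
#'   `erd_pct_rh`, `ers_pct_rh`, `rel_erd_power_lh`, `rel_ers_power_lh`,
#'   `rel_erd_power_rh`, `rel_ers_power_rh`, `classdis`,
#'   `missing_peak_flags`.
#' @export
extract_features <- function(selections, classdis, subject_id = "S001") {
  need <- expand.grid(role = c("contra-ERD", "ipsi-ERS"),
                      task_side = c("left", "right"),
                      stringsAsFactors = FALSE)
  get_row <- function(role, side) {
    r <- selections[selections$role == role & selections$task_side == side, ]
    if (nrow(r) != 1)
      rlang::abort(paste0("missing selection for ", role, " / ", side,
                          "-hand imagery (subject ", subject_id, ")"),
                   class = "erdica_no_candidate")
    r
  }
  flags <- character(0)
  relpow <- function(r) {
    if (!isTRUE(r$peak_present) || !is.finite(r$relative_power)) {
      flags <<- c(flags, paste0(r$role, "/", r$task_side))
      0
    } else r$relative_power
  }
  erd_l <- get_row("contra-ERD", "left");  erd_r <- get_row("contra-ERD", "right")
  ers_l <- get_row("ipsi-ERS", "left");    ers_r <- get_row("ipsi-ERS", "right")
  out <- tibble::tibble(
    subject_id = subject_id,
    erd_pct_lh = erd_l$scalar_percent, ers_pct_lh = ers_l$scalar_percent,
    erd_pct_rh = erd_r$scalar_percent, ers_pct_rh = ers_r$scalar_percent,
    rel_erd_power_lh = relpow(erd_l), rel_ers_power_lh = relpow(ers_l),
    rel_erd_power_rh = relpow(erd_r), rel_ers_power_rh = relpow(ers_r),
    classdis = classdis,
    missing_peak_flags = paste(flags, collapse = ";"))
  if (out$erd_pct_lh > 0 || out$erd_pct_rh > 0)
    rlang::inform(paste0("subject ", subject_id,
                         ": positive ERD% from a contralateral component"))
  out
}

.feature_cols <- c("erd_pct_lh", "ers_pct_lh", "erd_pct_rh", "ers_pct_rh",
                   "rel_erd_power_lh", "rel_ers_power_lh",
                   "rel_erd_power_rh", "rel_ers_power_rh")

#' Explanatory regression of ClassDis on the eight features
#'
#' Ordinary least squares of the performance score on the eight
#' neurophysiological indicators, with per-coefficient t tests, the
#' overall F test, adjusted R-squared, and standardized coefficients
#' (from z-scored predictors and response). Use [generics::tidy()] /
#' [generics::glance()] on the result.
#'
#' @param features Tibble with the eight feature columns and the
#'   response.
#' @param response Response column name (default `"classdis"`).
#' @return Object of class `erdica_regression`.
#' @export
fit_regression <- function(features, response = "classdis") {
  X <- as.matrix(features[, .feature_cols])
  y <- features[[response]]
  if (length(y) <= ncol(X) + 1)
    stop("need more subjects than coefficients (n > 9)")
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    bad <- .feature_cols[qrX$pivot[seq(qrX$rank + 1, ncol(X) + 1)] - 1]
    stop("collinear feature columns: ", paste(bad, collapse = ", "))
  }
  df <- as.data.frame(cbind(y = y, X))
  fit <- stats::lm(y ~ ., data = df)
  zs <- function(v) (v - mean(v)) / stats::sd(v)
  dfz <- as.data.frame(cbind(y = zs(y), apply(X, 2, zs)))
  fitz <- stats::lm(y ~ ., data = dfz)
  structure(list(fit = fit, std_fit = fitz, n = length(y),
                 response = response),
            class = "erdica_regression")
}

#' @export
print.erdica_regression <- function(x, ...) {
  g <- generics::glance(x)
  cat(sprintf("<erdica_regression> n=%d, F(%d,%d)=%.3f (p=%.3g), adj R2=%.3f\n",
              x$n, g$df, g$df_residual, g$statistic, g$p_value,
              g$adj_r_squared))
  invisible(x)
}

#' @rdname fit_regression
#' @param x An `erdica_regression`.
#' @param ... Unused.
#' @method tidy erdica_regression
#' @export
tidy.erdica_regression <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  sz <- summary(x$std_fit)$coefficients
  tibble::tibble(term = rownames(s),
                 estimate = unname(s[, 1]), std_error = unname(s[, 2]),
                 statistic = unname(s[, 3]), p_value = unname(s[, 4]),
                 std_beta = c(NA_real_, unname(sz[-1, 1])))
}

#' @rdname fit_regression
#' @method glance erdica_regression
#' @export
glance.erdica_regression <- function(x, ...) {
  s <- summary(x$fit)
  f <- s$fstatistic
  tibble::tibble(r_squared = s$r.squared,
                 adj_r_squared = s$adj.r.squared,
                 statistic = unname(f[1]), df = unname(f[2]),
                 df_residual = unname(f[3]),
                 p_value = stats::pf(f[1], f[2], f[3], lower.tail = FALSE),
                 n = x$n)
}

#' k-fold cross-validation of the feature regression
#'
#' Deterministic fold assignment under `seed`; within each fold the
#' regression is refitted on the training subjects and evaluated on the
#' held-out subjects; MAE and RMSE are pooled over all held-out
#' predictions.
#'
#' @param features Feature tibble as in [fit_regression()].
#' @param k Number of folds.
#' @param seed Fold-assignment seed.
#' @param response Response column.
#' @return One-row tibble with `mae`, `rmse`, `k`.
#' @export
cross_validate <- function(features, k = 10, seed = 1,
                           response = "classdis") {
  n <- nrow(features)
  if (k > n) stop("k (", k, ") exceeds the number of subjects (", n, ")")
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  X <- as.matrix(features[, .feature_cols])
  y <- features[[response]]
  resid <- numeric(n)
  for (f in seq_len(k)) {
    tr <- fold != f
    df <- as.data.frame(cbind(y = y[tr], X[tr, , drop = FALSE]))
    fit <- stats::lm(y ~ ., data = df)
    newd <- as.data.frame(X[!tr, , drop = FALSE])
    resid[!tr] <- y[!tr] - stats::predict(fit, newdata = newd)
  }
  tibble::tibble(mae = mean(abs(resid)), rmse = sqrt(mean(resid^2)), k = k)
}

#' Cluster one hand's performance into good/poor
#'
#' k-means (k = 2, multiple restarts) on the z-scored triplet
#' {ERD%, relative ERS power, ClassDis} for one imagery side; the
#' cluster with the higher mean ClassDis is labeled `"good"`.
#'
#' @param features Feature tibble.
#' @param side `"left"` or `"right"`: which hand's imagery features to
#'   use.
#' @param seed k-means seed.
#' @param nstart Random restarts.
#' @return Character vector of `"good"` / `"poor"` per subject.
#' @export
cluster_one_hand <- function(features, side = c("left", "right"), seed = 1,
                             nstart = 20) {
  side <- match.arg(side)
  cols <- if (side == "left") c("erd_pct_lh", "rel_ers_power_lh", "classdis")
          else c("erd_pct_rh", "rel_ers_power_rh", "classdis")
  if (nrow(features) < 4) stop("need at least 4 subjects to cluster")
  M <- as.matrix(features[, cols])
  sds <- apply(M, 2, stats::sd)
  if (all(sds == 0)) {
    warning("degenerate identical features; assigning all subjects one cluster")
    return(rep("poor", nrow(M)))
  }
  Z <- sweep(sweep(M, 2, colMeans(M)), 2, pmax(sds, .Machine$double.eps), "/")
  set.seed(seed)
  km <- stats::kmeans(Z, centers = 2, nstart = nstart)
  cd_means <- tapply(features$classdis, km$cluster, mean)
  good_cluster <- as.integer(names(which.max(cd_means)))
  ifelse(km$cluster == good_cluster, "good", "poor")
}

#' Combine per-hand labels into the four proficiency groups
#'
#' @param left_labels,right_labels `"good"`/`"poor"` vectors from
#'   [cluster_one_hand()] for the left- and right-hand tasks.
#' @param subject_id Optional identifiers.
#' @return Tibble with `subject_id`, `left_label`, `right_label`,
#'   `group` (good / LgoodRpoor / LpoorRgood / poor).
#' @export
assign_groups <- function(left_labels, right_labels,
                          subject_id = sprintf("S%03d", seq_along(left_labels))) {
  stopifnot(length(left_labels) == length(right_labels))
  group <- dplyr::case_when(
    left_labels == "good" & right_labels == "good" ~ "good",
    left_labels == "good" & right_labels == "poor" ~ "LgoodRpoor",
    left_labels == "poor" & right_labels == "good" ~ "LpoorRgood",
    TRUE ~ "poor")
  tibble::tibble(subject_id = subject_id, left_label = left_labels,
                 right_label = right_labels, group = group)
}

#' Tukey-Kramer HSD post hoc comparisons
#'
#' Studentized-range test on all group pairs with the Tukey-Kramer
#' unequal-n standard error `sqrt(MSE/2 (1/ni + 1/nj))`.
#'
#' @param values Numeric response.
#' @param groups Group factor.
#' @return Tibble with `comparison`, `diff`, `se`, `q`, `p_value`.
#' @export
tukey_kramer <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  n <- tapply(values, groups, length)
  m <- tapply(values, groups, mean)
  df <- length(values) - k
  mse <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2))) / df
  pairs <- utils::combn(levels(groups), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt(mse / 2 * (1 / n[[a]] + 1 / n[[b]]))
    q <- abs(m[[a]] - m[[b]]) / se
    tibble::tibble(comparison = paste(a, "vs", b),
                   diff = m[[a]] - m[[b]], se = se, q = q,
                   p_value = stats::ptukey(q, k, df, lower.tail = FALSE))
  })
}

#' Games-Howell post hoc comparisons
#'
#' Studentized-range test for unequal variances: per-pair standard
#' error `sqrt(si^2/ni + sj^2/nj)`, `q = |diff| sqrt(2) / se`, with
#' Welch-Satterthwaite degrees of freedom.
#'
#' @inheritParams tukey_kramer
#' @return Tibble with `comparison`, `diff`, `se`, `q`, `df`,
#'   `p_value`.
#' @export
games_howell <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  n <- tapply(values, groups, length)
  m <- tapply(values, groups, mean)
  v <- tapply(values, groups, stats::var)
  pairs <- utils::combn(levels(groups), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    va <- v[[a]] / n[[a]]; vb <- v[[b]] / n[[b]]
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (n[[a]] - 1) + vb^2 / (n[[b]] - 1))
    q <- abs(m[[a]] - m[[b]]) * sqrt(2) / se
    tibble::tibble(comparison = paste(a, "vs", b),
                   diff = m[[a]] - m[[b]], se = se, q = q, df = df,
                   p_value = stats::ptukey(q, k, df, lower.tail = FALSE))
  })
}

#' Group-comparison statistics for the stratified cohort
#'
#' For each of the four headline features (ERD% and relative ERS power,
#' both sides), homogeneity of variances is assessed with Levene's test
#' (alpha 0.05): homogeneous features get a classic one-way ANOVA with
#' Tukey-Kramer post hocs, heterogeneous ones Welch's ANOVA with
#' Games-Howell post hocs. Within-group paired t tests compare left-
#' vs right-hand ERD% and relative ERS power. Groups with fewer than 2
#' subjects are excluded with a warning.
#'
#' @param features Feature tibble including a `group` column.
#' @param feature_cols Features to test.
#' @return List of class `erdica_group_stats`: `omnibus` (per-feature
#'   test tibble), `posthoc` (per-feature pairwise tibble), `paired`
#'   (within-group LH-vs-RH tibble).
#' @export
group_statistics <- function(features,
                             feature_cols = c("erd_pct_lh", "erd_pct_rh",
                                              "rel_ers_power_lh",
                                              "rel_ers_power_rh")) {
  stopifnot("group" %in% names(features))
  cnt <- table(features$group)
  small <- names(cnt)[cnt < 2]
  if (length(small)) {
    warning("excluding group(s) with n < 2: ", paste(small, collapse = ", "))
    features <- features[!features$group %in% small, ]
  }
  if (length(unique(features$group)) < 2)
    stop("need at least 2 groups with at least 2 subjects")
  g <- factor(features$group)
  omnibus <- purrr::map_dfr(feature_cols, function(fc) {
    v <- features[[fc]]
    lev <- car::leveneTest(v ~ g)
    homogeneous <- lev[1, "Pr(>F)"] > 0.05
    if (homogeneous) {
      a <- stats::anova(stats::aov(v ~ g))
      tibble::tibble(feature = fc, test = "anova",
                     levene_p = lev[1, "Pr(>F)"],
                     statistic = a$`F value`[1],
                     df1 = a$Df[1], df2 = a$Df[2],
                     p_value = a$`Pr(>F)`[1])
    } else {
      w <- stats::oneway.test(v ~ g, var.equal = FALSE)
      tibble::tibble(feature = fc, test = "welch",
                     levene_p = lev[1, "Pr(>F)"],
                     statistic = unname(w$statistic),
                     df1 = unname(w$parameter[1]), df2 = unname(w$parameter[2]),
                     p_value = w$p.value)
    }
  })
  posthoc <- purrr::map_dfr(feature_cols, function(fc) {
    v <- features[[fc]]
    use_tukey <- omnibus$test[omnibus$feature == fc] == "anova"
    ph <- if (use_tukey) tukey_kramer(v, g) else games_howell(v, g)
    dplyr::mutate(ph, feature = fc,
                  method = if (use_tukey) "tukey-kramer" else "games-howell",
                  .before = 1)
  })
  paired_specs <- list(c("erd_pct_lh", "erd_pct_rh", "erd_pct"),
                       c("rel_ers_power_lh", "rel_ers_power_rh",
                         "rel_ers_power"))
  paired <- purrr::map_dfr(levels(g), function(grp) {
    sub <- features[features$group == grp, ]
    purrr::map_dfr(paired_specs, function(sp) {
      lh <- sub[[sp[1]]]; rh <- sub[[sp[2]]]
      tt <- tryCatch(stats::t.test(lh, rh, paired = TRUE),
                     error = function(e) NULL)
      tibble::tibble(group = grp, metric = sp[3], n = nrow(sub),
                     mean_lh = mean(lh), mean_rh = mean(rh),
                     statistic = if (is.null(tt)) NA_real_
                                 else unname(tt$statistic),
                     p_value = if (is.null(tt)) NA_real_ else tt$p.value)
    })
  })
  structure(list(omnibus = omnibus, posthoc = posthoc, paired = paired),
            class = "erdica_group_stats")
}

#' @export
print.erdica_group_stats <- function(x, ...) {
  cat("<erdica_group_stats>\n")
  print(x$omnibus)
  invisible(x)
}
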