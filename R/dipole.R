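#' Fit a single equivalent current dipole to a component topography
#'
#' Finds the dipole position minimizing residual variance of the
#' average-referenced topography under the concentric-sphere forward
#' model: at each candidate position the moment is solved linearly by
#' least squares, so the search is over position only. A coarse pass over
#' the model's source grid seeds a Nelder-Mead refinement constrained to
#' the innermost shell.
#'
#' @param topography Numeric vector of channel weights (one per model
#'   electrode), any scale.
#' @param hm A [head_model()].
#' @param refine Logical; run local refinement after the grid pass.
#' @return Object of class `dipole_fit`: list with `position` (mm),
#'   `moment`, `residual_variance` in `[0, 1]`, and `hemisphere`
#'   (`"left"`, `"right"` or `"midline"`, by the sign of x with a 5 mm
#'   midline band).
#' @export
fit_dipole <- function(topography, hm, refine = TRUE) {
  topography <- as.numeric(topography)
  if (length(topography) != nrow(hm$electrodes))
    stop("topography length (", length(topography),
         ") does not match electrode count (", nrow(hm$electrodes), ")")
  if (all(abs(topography) < .Machine$double.eps))
    stop("degenerate all-zero topography")
  t0 <- topography - mean(topography)
  tt <- sum(t0^2)
  rv_at <- function(p) {
    if (sqrt(sum(p^2)) >= 0.97 * hm$radii[1]) return(list(rv = 2, m = c(0, 0, 0)))
    Lf <- leadfield(hm, p)
    m <- qr.coef(qr(Lf), t0)
    m[is.na(m)] <- 0
    list(rv = max(0, 1 - sum((Lf %*% m)^2) / tt), m = m)
  }
  grid <- as.matrix(hm$source_space[, c("x", "y", "z")])
  G <- .grid_basis(hm)                     # (3 * npoints) x channels
  s <- (G %*% t0)^2
  ss <- colSums(matrix(s, nrow = 3))
  best <- grid[which.max(ss), ]
  if (refine) {
    opt <- stats::optim(best, function(p) rv_at(p)$rv, method = "Nelder-Mead",
                        control = list(maxit = 200, reltol = 1e-9))
    best <- opt$par
  }
  res <- rv_at(best)
  structure(list(
    position = unname(best),
    moment = unname(res$m),
    residual_variance = res$rv,
    hemisphere = if (abs(best[1]) < 5) "midline"
                 else if (best[1] < 0) "left" else "right"
  ), class = "dipole_fit")
}

# Orthonormal lead-field bases at the source-grid points, stacked into a
# (3 * npoints) x channels matrix and cached on the head model.
.grid_basis <- function(hm) {
  if (!is.null(hm$cache$grid_basis)) return(hm$cache$grid_basis)
  grid <- as.matrix(hm$source_space[, c("x", "y", "z")])
  G <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    t(qr.Q(qr(leadfield(hm, grid[i, ]))))
  }))
  if (!is.null(hm$cache)) hm$cache$grid_basis <- G
  G
}

#' Residual-variance screen for dipole fits
#'
#' Keeps a component only when a single dipole explains its topography
#' well: residual variance at or below `threshold` (default 15%).
#'
#' @param fit A `dipole_fit`.
#' @param threshold Maximum acceptable residual variance fraction.
#' @return `TRUE` to keep, `FALSE` to exclude.
#' @export
screen_rv <- function(fit, threshold = 0.15) {
  fit$residual_variance <= threshold
}

#' @export
print.dipole_fit <- function(x, ...) {
  cat(sprintf("<dipole_fit> pos [%.1f, %.1f, %.1f] mm (%s), rv %.3f\n",
              x$position[1], x$position[2], x$position[3],
              x$hemisphere, x$residual_variance))
  invisible(x)
}
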