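#' Infomax independent component analysis of an epoch set
#'
#' Natural-gradient Infomax with the logistic nonlinearity on the
#' concatenated kept trials: the data are centered and sphered by PCA to
#' full rank (30 channels in, 30 components out), the unmixing matrix is
#' learned in randomized blocks with learning-rate annealing driven by
#' the angle between successive updates, and components are returned in
#' descending order of mean projected variance. Topographies (columns of
#' the mixing matrix) are normalized to unit norm with the largest
#' absolute weight positive, activations rescaled accordingly.
#'
#' @param es An [epoch_set()] (kept trials are used).
#' @param seed Integer seed; fixed seed gives a reproducible unmixing
#'   matrix.
#' @param max_iter Maximum training passes over the data.
#' @param tol Stop when the per-weight RMS change of the unmixing matrix
#'   falls below this.
#' @param lrate Initial learning rate.
#' @param anneal_after,anneal After `anneal_after` passes the rate is
#'   additionally cooled geometrically by `anneal` per pass, so the
#'   block-stochastic updates settle.
#' @return Object of class `ica_decomposition`: `W` (components x
#'   channels unmixing, sphering included), `A` (mixing, `solve(W)`),
#'   `activations` (trials x components x time), `converged`,
#'   `n_iterations`, plus the epoch metadata.
#' @export
infomax <- function(es, seed = 1, max_iter = 200, tol = 1e-6, lrate = 0.1,
                    anneal_after = 100, anneal = 0.96) {
  x <- kept_epochs(es)
  nt <- dim(x)[1]; nc <- dim(x)[2]; ns <- dim(x)[3]
  X <- matrix(aperm(x, c(2, 3, 1)), nc, ns * nt)   # channels x samples
  if (ncol(X) < 20 * nc^2)
    warning("fewer than 20 * channels^2 samples; ICA may be unstable")
  ctr <- rowMeans(X)
  X <- X - ctr
  eg <- eigen(tcrossprod(X) / ncol(X), symmetric = TRUE)
  ev <- pmax(eg$values, max(eg$values) * 1e-12)
  sphere <- eg$vectors %*% diag(1 / sqrt(ev)) %*% t(eg$vectors)
  Xw <- sphere %*% X

  set.seed(seed)
  n <- ncol(Xw)
  block <- min(n, 1024L)
  core <- .infomax_core(Xw, as.integer(max_iter), lrate, tol,
                        as.integer(block), as.integer(anneal_after), anneal)
  W <- core$W
  converged <- core$converged
  it <- core$iterations

  Wfull <- W %*% sphere
  A <- solve(Wfull)
  # order by mean projected variance
  U <- Wfull %*% X
  pv <- colSums(A^2) * apply(U, 1, stats::var)
  ord <- order(pv, decreasing = TRUE)
  Wfull <- Wfull[ord, , drop = FALSE]
  A <- A[, ord, drop = FALSE]
  U <- U[ord, , drop = FALSE]
  # unit-norm topographies, positive max weight
  nrm <- sqrt(colSums(A^2))
  sgn <- vapply(seq_len(nc), function(k) sign(A[which.max(abs(A[, k])), k]),
                numeric(1))
  A <- sweep(A, 2, nrm * sgn, "/")
  Wfull <- sweep(Wfull, 1, nrm * sgn, "*")
  U <- sweep(U, 1, nrm * sgn, "*")

  acts <- aperm(array(U, c(nc, ns, nt)), c(3, 1, 2))
  structure(list(W = Wfull, A = A, activations = acts,
                 topographies = A, converged = converged, n_iterations = it,
                 seed = seed, fs = es$fs, window = es$window,
                 task_label = es$task_label, channel_names = es$channel_names,
                 center = ctr),
            class = "ica_decomposition")
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf("<ica_decomposition> '%s': %d comps, %d trials, %s in %d iters\n",
              x$task_label, nrow(x$W), dim(x$activations)[1],
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  invisible(x)
}

#' Reject trials by their IC activation time series
#'
#' Applies the same four rejection criteria to the component activations
#' that [reject_epochs()] applies to channel data; a trial rejected in
#' any component is removed from every component.
#'
#' @param dec An [infomax()] decomposition.
#' @param crit A [rejection_criteria()].
#' @return The decomposition with offending trials removed from
#'   `activations`; indices of removed trials in `$rejected_trials`, the
#'   criteria in `$rejection_log`.
#' @export
reject_ic_epochs <- function(dec, crit = rejection_criteria()) {
  nt <- dim(dec$activations)[1]
  # screen in sensor-referred units: an IC's activation times its largest
  # topography weight is the biggest contribution any electrode sees, so
  # the microvolt amplitude threshold keeps its meaning
  wmax <- apply(abs(dec$topographies), 2, max)
  screened <- sweep(dec$activations, 2, wmax, "*")
  es <- epoch_set(screened, dec$window, dec$fs, dec$task_label,
                  paste0("IC", seq_len(dim(dec$activations)[2])))
  es <- reject_epochs(es, crit)
  drop_idx <- which(!es$kept_mask)
  dec$activations <- dec$activations[es$kept_mask, , , drop = FALSE]
  dec$rejected_trials <- drop_idx
  dec$rejection_log <- es$rejection_log
  dec
}

#' Screen focal (single-electrode) components
#'
#' Components whose topography is dominated by a single electrode are
#' unlikely to be neural (typically muscle artifacts). A component is
#' flagged when `max |w| / sum |w| > focality_threshold`.
#'
#' @param dec An [infomax()] decomposition.
#' @param focality_threshold Dominance ratio above which a component is
#'   removed.
#' @return Logical vector, `TRUE` for components that PASS the screen
#'   (i.e. are kept).
#' @export
screen_focal_components <- function(dec, focality_threshold = 0.6) {
  A <- dec$topographies
  ratio <- apply(A, 2, function(w) max(abs(w)) / sum(abs(w)))
  ratio <= focality_threshold
}
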