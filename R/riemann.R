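#' Per-trial covariance matrices of an epoch set
#'
#' Sample covariance of each kept trial over the task window, shrunk
#' toward the scaled identity `(tr(C)/p) I` by weight `shrinkage` to
#' guarantee positive definiteness.
#'
#' @param es An [epoch_set()].
#' @param task_window Seconds relative to the prompt, default `c(0, 4)`.
#' @param shrinkage Convex weight on the scaled-identity target.
#' @return Object of class `covariance_set`: list with `mats` (list of
#'   SPD matrices), `shrinkage`, `task_window`.
#' @export
trial_covariances <- function(es, task_window = c(0, 4), shrinkage = 0.05) {
  x <- kept_epochs(es)
  if (dim(x)[1] < 2) stop("need at least 2 kept trials")
  tt <- epoch_times(es)
  cols <- which(tt >= task_window[1] & tt < task_window[2])
  p <- dim(x)[2]
  if (length(cols) <= p && shrinkage <= 0)
    stop("fewer time samples than channels: use shrinkage > 0")
  mats <- lapply(seq_len(dim(x)[1]), function(i) {
    m <- x[i, , cols]
    m <- m - rowMeans(m)
    C <- tcrossprod(m) / (length(cols) - 1)
    (1 - shrinkage) * C + shrinkage * (sum(diag(C)) / p) * diag(p)
  })
  structure(list(mats = mats, shrinkage = shrinkage,
                 task_window = task_window),
            class = "covariance_set")
}

# symmetric eigen helpers
.spd_eig_fun <- function(P, fun) {
  e <- eigen((P + t(P)) / 2, symmetric = TRUE)
  if (any(e$values <= 0)) stop("matrix is not positive definite")
  e$vectors %*% (fun(e$values) * t(e$vectors))
}
.spd_sqrt <- function(P) .spd_eig_fun(P, sqrt)
.spd_isqrt <- function(P) .spd_eig_fun(P, function(v) 1 / sqrt(v))
.spd_log <- function(P) .spd_eig_fun(P, log)
.spd_exp <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  e$vectors %*% (exp(e$values) * t(e$vectors))
}

#' Affine-invariant Riemannian distance between SPD matrices
#'
#' `delta(P, Q) = || logm(P^-1/2 Q P^-1/2) ||_F`, invariant under any
#' common invertible congruence transform of both arguments.
#'
#' @param P,Q Symmetric positive-definite matrices of equal size.
#' @return Nonnegative scalar distance.
#' @export
riemannian_distance <- function(P, Q) {
  is <- .spd_isqrt(P)
  M <- .spd_log(is %*% Q %*% is)
  sqrt(sum(M^2))
}

#' Riemannian (Frechet) mean of SPD matrices
#'
#' Iterated tangent-space averaging under the affine-invariant metric:
#' at each step the matrices are mapped to the tangent space at the
#' current estimate, averaged, and the estimate moved along the
#' exponential map until the gradient norm falls below `tol`.
#'
#' @param mats A [trial_covariances()] set or plain list of SPD
#'   matrices.
#' @param tol Convergence tolerance on the tangent-mean Frobenius norm.
#' @param max_iter Maximum iterations.
#' @return The SPD mean, with attribute `converged`.
#' @export
riemannian_mean <- function(mats, tol = 1e-9, max_iter = 100) {
  if (inherits(mats, "covariance_set")) mats <- mats$mats
  if (!length(mats)) stop("need at least one matrix")
  if (length(mats) == 1) return(structure(mats[[1]], converged = TRUE))
  M <- Reduce(`+`, mats) / length(mats)     # arithmetic mean start
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    Ms <- .spd_sqrt(M); Mi <- .spd_isqrt(M)
    S <- Reduce(`+`, lapply(mats, function(P) .spd_log(Mi %*% P %*% Mi))) /
      length(mats)
    if (sqrt(sum(S^2)) < tol) { converged <- TRUE; break }
    M <- Ms %*% .spd_exp(S) %*% Ms
    M <- (M + t(M)) / 2
  }
  structure(M, converged = converged)
}

#' Riemannian class distinctiveness of two covariance sets
#'
#' Fisher-style separability on the SPD manifold: the Riemannian
#' distance between the class Frechet means divided by the average
#' within-class dispersion, where each class dispersion is the mean
#' Riemannian distance of its trial covariances to the class mean.
#' Higher values mean better separated classes.
#'
#' @param A,B [trial_covariances()] sets (or lists of SPD matrices).
#' @return Object of class `classdis_result`: `mean_A`, `mean_B`,
#'   `sigma_A`, `sigma_B`, `delta`, `classdis`. When both classes are
#'   degenerate (all matrices identical) `classdis` is 0; when only the
#'   dispersions vanish it is `Inf` with a warning.
#' @export
class_distinctiveness <- function(A, B) {
  if (inherits(A, "covariance_set")) A <- A$mats
  if (inherits(B, "covariance_set")) B <- B$mats
  if (!length(A) || !length(B)) stop("both classes need at least one trial")
  mA <- riemannian_mean(A); mB <- riemannian_mean(B)
  sA <- mean(vapply(A, riemannian_distance, numeric(1), Q = mA))
  sB <- mean(vapply(B, riemannian_distance, numeric(1), Q = mB))
  delta <- riemannian_distance(mA, mB)
  denom <- 0.5 * (sA + sB)
  tol0 <- 1e-10 * max(1, delta)           # numerically-zero dispersion
  cd <- if (denom > tol0) delta / denom
        else if (delta <= tol0) 0
        else { warning("zero within-class dispersion with separated means");
               Inf }
  structure(list(mean_A = unclass(mA), mean_B = unclass(mB),
                 sigma_A = sA, sigma_B = sB, delta = delta, classdis = cd),
            class = "classdis_result")
}

#' @export
print.classdis_result <- function(x, ...) {
  cat(sprintf("<classdis_result> delta %.4f, sigma (%.4f, %.4f), ClassDis %.4f\n",
              x$delta, x$sigma_A, x$sigma_B, x$classdis))
  invisible(x)
}
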