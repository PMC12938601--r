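#' Concentric-sphere head model
#'
#' Four-shell (brain / CSF / skull / scalp) concentric spherical volume
#' conductor with an idealized electrode montage on the outer shell and a
#' regular source grid inside the innermost shell. The quasi-static
#' forward problem is solved per spherical-harmonic degree: within each
#' shell the radial part of the potential is `A r^n + B r^-(n+1)`, the
#' dipole contributes the free-space singular term in the innermost shell,
#' and continuity of potential and radial current density across shell
#' boundaries plus a no-outflow condition at the scalp give a small linear
#' system per degree. Degree-wise gains are precomputed at construction.
#'
#' @param radii Shell outer radii in mm, innermost first.
#' @param conductivities Shell conductivities in S/m, same order.
#' @param labels Electrode labels placed by [electrode_positions()].
#' @param n_degrees Number of spherical-harmonic degrees retained.
#' @param grid_spacing_mm Source-grid spacing in mm.
#' @return An object of class `head_model`: list with `radii`, `cond`,
#'   `electrodes` (channels x 3, mm), `gains` (per-degree transfer gains),
#'   and `source_space` (tibble: x, y, z, hemisphere, region).
#' @export
head_model <- function(radii = c(71, 72, 79, 85),
                       conductivities = c(0.33, 1.0, 0.0042, 0.33),
                       labels = motor_montage(),
                       n_degrees = 80,
                       grid_spacing_mm = 12) {
  stopifnot(length(radii) == length(conductivities),
            all(diff(radii) > 0), all(conductivities > 0))
  elec <- electrode_positions(labels, radius = radii[length(radii)])
  hm <- structure(list(
    radii = radii, cond = conductivities, electrodes = elec,
    gains = .shell_gains(radii, conductivities, n_degrees),
    n_degrees = n_degrees,
    cache = new.env(parent = emptyenv())
  ), class = "head_model")
  hm$source_space <- .make_source_space(hm, grid_spacing_mm)
  hm
}

# Per-degree radial transfer gain: potential at the outer surface produced
# by a unit-strength singular term (rho^-(n+1), radii normalized by the
# outer radius) originating in the innermost shell.
.shell_gains <- function(radii, cond, n_degrees) {
  N <- length(radii)
  R <- radii[N]
  rho <- radii / R
  if (N == 1) {  # homogeneous bounded sphere: A1 n = (n + 1)
    n <- seq_len(n_degrees)
    return((2 * n + 1) / n)
  }
  vapply(seq_len(n_degrees), function(n) {
    # unknowns: A1, A2, B2, ..., AN, BN  (2N - 1 of them)
    nu <- 2 * N - 1
    M <- matrix(0, nu, nu)
    rhs <- numeric(nu)
    idxA <- function(j) if (j == 1) 1L else as.integer(2 * j - 2)
    idxB <- function(j) as.integer(2 * j - 1)  # j >= 2
    row <- 0L
    for (j in seq_len(N - 1)) {
      r <- rho[j]
      up <- r^n; dn <- r^-(n + 1)
      dup <- n * r^(n - 1); ddn <- -(n + 1) * r^-(n + 2)
      # potential continuity
      row <- row + 1L
      M[row, idxA(j)] <- up
      if (j > 1) M[row, idxB(j)] <- dn
      M[row, idxA(j + 1)] <- -up
      M[row, idxB(j + 1)] <- -dn
      if (j == 1) rhs[row] <- -dn            # primary term, strength 1
      # radial current continuity
      row <- row + 1L
      M[row, idxA(j)] <- cond[j] * dup
      if (j > 1) M[row, idxB(j)] <- cond[j] * ddn
      M[row, idxA(j + 1)] <- -cond[j + 1] * dup
      M[row, idxB(j + 1)] <- -cond[j + 1] * ddn
      if (j == 1) rhs[row] <- -cond[1] * ddn
    }
    # no current outflow at the scalp (rho = 1)
    row <- row + 1L
    M[row, idxA(N)] <- n
    M[row, idxB(N)] <- -(n + 1)
    sol <- solve(M, rhs)
    sol[idxA(N)] + sol[idxB(N)]   # potential at rho = 1
  }, numeric(1))
}

.make_source_space <- function(hm, spacing) {
  rmax <- 0.88 * hm$radii[1]
  ax <- seq(-rmax, rmax, by = spacing)
  g <- expand.grid(x = ax, y = ax, z = ax)
  g <- g[sqrt(g$x^2 + g$y^2 + g$z^2) <= rmax & g$z > -20, ]
  atlas <- default_motor_atlas()
  sm <- atlas[atlas$ba %in% c("BA1-3", "BA4"), ]
  in_motor <- vapply(seq_len(nrow(g)), function(i) {
    p <- as.numeric(g[i, ])
    any(p[1] >= sm$xmin & p[1] <= sm$xmax &
        p[2] >= sm$ymin & p[2] <= sm$ymax &
        p[3] >= sm$zmin & p[3] <= sm$zmax)
  }, logical(1))
  tibble::tibble(
    x = g$x, y = g$y, z = g$z,
    hemisphere = ifelse(abs(g$x) < 5, "midline",
                        ifelse(g$x < 0, "left", "right")),
    region = ifelse(in_motor, "motor", "non-motor")
  )
}

# Legendre polynomials P_n(u) and derivatives P_n'(u) for n = 1..L,
# vectorized over u. Returns list(P = L x length(u), dP = L x length(u)).
.legendre_terms <- function(u, L) {
  nu <- length(u)
  P <- matrix(0, L, nu); dP <- matrix(0, L, nu)
  Pm1 <- rep(1, nu); dPm1 <- rep(0, nu)    # P_0, P_0'
  Pc <- u; dPc <- rep(1, nu)               # P_1, P_1'
  P[1, ] <- Pc; dP[1, ] <- dPc
  if (L >= 2) for (n in 2:L) {
    Pn <- ((2 * n - 1) * u * Pc - (n - 1) * Pm1) / n
    dPn <- n * Pc + u * dPc                # P_n' = n P_{n-1} + u P_{n-1}'
    Pm1 <- Pc; Pc <- Pn; dPc <- dPn
    P[n, ] <- Pn; dP[n, ] <- dPn
  }
  list(P = P, dP = dP)
}

#' Forward potential of a current dipole
#'
#' Average-referenced scalp potentials at the model's electrodes for a
#' dipole at `pos` (mm) with moment `moment` (arbitrary units). Linear in
#' the moment; use [leadfield()] for the 3-column basis.
#'
#' @param hm A [head_model()].
#' @param pos Numeric length-3 dipole position in mm (inside shell 1).
#' @param moment Numeric length-3 dipole moment.
#' @return Numeric vector of potentials, one per electrode.
#' @export
forward_dipole <- function(hm, pos, moment) {
  drop(leadfield(hm, pos) %*% as.numeric(moment))
}

#' Dipole lead field at a position
#'
#' @param hm A [head_model()].
#' @param pos Numeric length-3 position in mm.
#' @return Electrodes x 3 matrix mapping moment to average-referenced
#'   potentials.
#' @export
leadfield <- function(hm, pos) {
  pos <- as.numeric(pos)
  b <- sqrt(sum(pos^2))
  R <- hm$radii[length(hm$radii)]
  if (b >= hm$radii[1]) stop("dipole position outside the innermost shell")
  L <- hm$n_degrees
  E <- hm$electrodes / R                  # unit-sphere electrode directions
  ne <- nrow(E)
  if (b < 1e-9) {
    # central dipole: only the n = 1 term survives
    phat <- c(0, 0, 0); u <- rep(0, ne)
  } else {
    phat <- pos / b
    u <- drop(E %*% phat)
  }
  u <- pmin(1, pmax(-1, u))
  lt <- .legendre_terms(u, L)
  scale <- hm$gains * (max(b, 1e-9) / R)^(seq_len(L) - 1) /
    (4 * pi * hm$cond[1] * R^2)
  # radial part: sum_n scale_n * n * P_n(u)  (coefficient of m_r)
  nvec <- seq_len(L)
  rad <- drop(crossprod(lt$P, scale * nvec))        # length ne
  # tangential part: sum_n scale_n * P_n'(u), multiplies m.(ehat - u phat)
  tang <- drop(crossprod(lt$dP, scale))
  # assemble lead field: V = rad * (m.phat) + tang * (m.(ehat - u phat))
  Lf <- matrix(0, ne, 3)
  for (k in 1:3) {
    ek <- E[, k]
    Lf[, k] <- rad * phat[k] + tang * (ek - u * phat[k])
  }
  Lf <- sweep(Lf, 2, colMeans(Lf))        # common average reference
  rownames(Lf) <- rownames(hm$electrodes)
  Lf
}

# Exact free-space dipole potential (used as an independent oracle for the
# multipole expansion in the test suite).
.freespace_potential <- function(pos, moment, points, sigma = 0.33) {
  d <- sweep(points, 2, pos)
  r3 <- rowSums(d^2)^1.5
  drop(d %*% moment) / (4 * pi * sigma * r3)
}
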