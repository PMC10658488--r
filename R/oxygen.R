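# Steady-state reaction-diffusion oxygen oracle on the mask's pixel grid.
#
# Model: div(D(x) grad c) - k(x) c = 0, with per-pixel diffusivity and
# first-order consumption set by mask class (vessel lumen vs tissue gel),
# Dirichlet c = c0 on the configured media-channel edges and zero flux on
# the others. Five-point stencil with harmonic-mean interface diffusivities;
# the resulting symmetric positive-definite system is solved directly
# (sparse Cholesky). First-order kinetics are used so a closed-form slab
# solution exists as an independent oracle.

#' Oxygen transport parameters
#'
#' Defaults make vessels low-resistance conduits from the media boundaries
#' (`D_vessel >> D_tissue`, `k_vessel < k_tissue`), so dense, spanning
#' networks oxygenate tissue better. These are model constants of this
#' package, normalized so the source concentration is 1.
#'
#' @param c0 Source concentration at Dirichlet edges; fixed at 1 (normalized).
#' @param D_tissue Diffusivity in the gel, um^2/s.
#' @param D_vessel Diffusivity in vessel lumen, um^2/s; must be `>= D_tissue`.
#' @param k_tissue First-order consumption in tissue, 1/s.
#' @param k_vessel First-order endothelial consumption in vessel pixels, 1/s.
#' @param boundary Character subset of `c("left", "right", "top", "bottom")`
#'   naming the Dirichlet media-channel edges; default lateral edges.
#' @param solver_tol Relative residual tolerance of the linear solve.
#' @return An object of class `transport_params`.
#' @export
transport_params <- function(c0 = 1, D_tissue = 1e3, D_vessel = 1e5,
                             k_tissue = 1e-2, k_vessel = 1e-3,
                             boundary = c("left", "right"),
                             solver_tol = 1e-8) {
  if (c0 != 1) stopf("c0 is normalized and must equal 1")
  if (!(D_vessel >= D_tissue && D_tissue > 0))
    stopf("need D_vessel >= D_tissue > 0")
  if (k_tissue < 0 || k_vessel < 0) stopf("consumption rates must be >= 0")
  boundary <- match.arg(boundary, c("left", "right", "top", "bottom"),
                        several.ok = TRUE)
  structure(list(c0 = c0, D_tissue = D_tissue, D_vessel = D_vessel,
                 k_tissue = k_tissue, k_vessel = k_vessel,
                 boundary = boundary, solver_tol = solver_tol),
            class = "transport_params")
}

#' Solve the steady-state oxygen field over a vessel mask
#'
#' Finite-difference discretization on the pixel grid (spacing = pixel
#' pitch): for each non-Dirichlet pixel i,
#' `sum_j w_ij (c_j - c_i) - k_i h^2 c_i = 0` with
#' `w_ij = 2 D_i D_j / (D_i + D_j)` over the 4-neighbours; missing
#' neighbours give zero flux. Dirichlet pixels (whole configured edges) are
#' eliminated into the right-hand side, keeping the system symmetric
#' positive definite. The discrete maximum principle bounds the solution in
#' `[0, c0]`; values are clamped to that interval to absorb round-off.
#'
#' @param mask A [vessel_mask()].
#' @param params A [transport_params()].
#' @return Object of class `oxygen_field`: list with `values` (matrix, same
#'   shape as the mask, in `[0, c0]`) and `residual` (relative residual of
#'   the solve).
#' @export
solve_oxygen <- function(mask, params = transport_params()) {
  stopifnot(inherits(mask, "vessel_mask"), inherits(params, "transport_params"))
  pix <- mask$pixels
  nr <- nrow(pix); nc <- ncol(pix)
  h <- mask$pixel_pitch
  v <- pix == 1L
  D <- matrix(params$D_tissue, nr, nc); D[v] <- params$D_vessel
  k <- matrix(params$k_tissue, nr, nc); k[v] <- params$k_vessel

  if (params$k_tissue == 0 && params$k_vessel == 0) {
    # no consumption: uniform field c0 satisfies the PDE and both BC types
    return(structure(list(values = matrix(params$c0, nr, nc), residual = 0),
                     class = "oxygen_field"))
  }

  dir_mask <- matrix(FALSE, nr, nc)
  if ("left" %in% params$boundary) dir_mask[, 1] <- TRUE
  if ("right" %in% params$boundary) dir_mask[, nc] <- TRUE
  if ("top" %in% params$boundary) dir_mask[1, ] <- TRUE
  if ("bottom" %in% params$boundary) dir_mask[nr, ] <- TRUE

  idx <- matrix(seq_len(nr * nc), nr, nc)
  free <- !dir_mask
  fid <- matrix(0L, nr, nc)          # pixel -> free-unknown index
  fid[free] <- seq_len(sum(free))
  nfree <- sum(free)

  # harmonic-mean conductances on pixel interfaces
  ia <- integer(0); ib <- integer(0); w <- numeric(0)
  if (nc > 1) {
    ia <- c(ia, as.vector(idx[, 1:(nc - 1)]))
    ib <- c(ib, as.vector(idx[, 2:nc]))
  }
  if (nr > 1) {
    ia <- c(ia, as.vector(idx[1:(nr - 1), ]))
    ib <- c(ib, as.vector(idx[2:nr, ]))
  }
  w <- 2 * D[ia] * D[ib] / (D[ia] + D[ib])

  # diagonal: sum of incident conductances + consumption
  wsum <- numeric(nr * nc)
  wacc <- rowsum(c(w, w), c(ia, ib))
  wsum[as.integer(rownames(wacc))] <- wacc[, 1]
  diag_acc <- wsum[free] + k[free] * h * h

  # off-diagonals between free-free interfaces; Dirichlet neighbours move
  # w * c0 to the right-hand side
  fa <- fid[ia]; fb <- fid[ib]
  both <- fa > 0 & fb > 0
  b <- numeric(nfree)
  da <- fa > 0 & fb == 0
  db <- fb > 0 & fa == 0
  if (any(da)) {
    acc <- rowsum(w[da], fa[da])
    b[as.integer(rownames(acc))] <- b[as.integer(rownames(acc))] +
      acc[, 1] * params$c0
  }
  if (any(db)) {
    acc <- rowsum(w[db], fb[db])
    b[as.integer(rownames(acc))] <- b[as.integer(rownames(acc))] +
      acc[, 1] * params$c0
  }

  A <- Matrix::sparseMatrix(
    i = c(fa[both], fb[both], seq_len(nfree)),
    j = c(fb[both], fa[both], seq_len(nfree)),
    x = c(-w[both], -w[both], diag_acc),
    dims = c(nfree, nfree)
  )
  A <- Matrix::forceSymmetric(A)
  x <- as.numeric(Matrix::solve(A, b))
  resid <- sqrt(sum((as.numeric(A %*% x) - b)^2))
  bnorm <- sqrt(sum(b^2))
  rel <- if (bnorm > 0) resid / bnorm else resid
  if (!is.finite(rel) || rel > max(params$solver_tol, 1e-8) * 100)
    stopf("oxygen solve did not converge (relative residual %.3g)", rel)

  values <- matrix(params$c0, nr, nc)
  values[free] <- x
  values <- pmin(pmax(values, 0), params$c0)  # absorb round-off only
  structure(list(values = values, residual = rel), class = "oxygen_field")
}

#' Area-average oxygen over vessel and tissue pixels
#'
#' @param field An `oxygen_field` from [solve_oxygen()] (or a bare matrix).
#' @param mask The [vessel_mask()] the field was solved on.
#' @param c0 Normalizing source concentration.
#' @return Data frame with `oxy_v` (mean over vessel pixels) and `oxy_t`
#'   (mean over tissue pixels), both in `[0, 1]`; an empty pixel class
#'   yields 0 by convention.
#' @export
summarize_oxygen <- function(field, mask, c0 = 1) {
  vals <- if (is.list(field)) field$values else field
  if (!all(dim(vals) == dim(mask$pixels))) stopf("field/mask shape mismatch")
  v <- mask$pixels == 1L
  oxy_v <- if (any(v)) mean(vals[v]) / c0 else 0
  oxy_t <- if (any(!v)) mean(vals[!v]) / c0 else 0
  data.frame(oxy_v = oxy_v, oxy_t = oxy_t)
}

#' Closed-form slab solution for homogeneous tissue
#'
#' For an avascular slab of width `length` with both lateral faces held at
#' `c0` and uniform first-order consumption, the steady profile is
#' `c(x) = c0 cosh(lambda (x - L/2)) / cosh(lambda L / 2)` with
#' `lambda = sqrt(k_tissue / D_tissue)`. Used as the independent oracle for
#' the numeric solver.
#'
#' @param params A [transport_params()]; only the tissue coefficients are
#'   used.
#' @param length Slab width L, micrometres.
#' @param x Position(s) in `[0, L]`, micrometres.
#' @return Concentration value(s); `k_tissue = 0` returns `c0` everywhere.
#' @export
analytic_slab <- function(params, length, x) {
  if (params$k_tissue == 0) return(rep(params$c0, length(x)))
  lam <- sqrt(params$k_tissue / params$D_tissue)
  params$c0 * cosh(lam * (x - length / 2)) / cosh(lam * length / 2)
}
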