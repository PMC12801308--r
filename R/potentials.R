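#' Analytic model potentials built from Gaussian wells
#'
#' Constructs a model free-energy landscape \eqn{F(s) = -\sum_i A_i
#' \exp(-\|s - c_i\|^2 / (2 w_i^2)) + \frac{k}{2}\|s - c_0\|^2} from a set of
#' Gaussian wells plus an optional confining harmonic term.  These potentials
#' play the role of a known ground truth: their minima are refined to
#' stationary points at construction and their saddle points (with analytic
#' barrier heights) are located by a dense-grid search followed by local
#' refinement, so downstream free-energy estimates can be checked against
#' exact values.
#'
#' @param centers numeric matrix (one well per row) or vector (single well /
#'   1D) of well centres, nm.
#' @param depths well depths \eqn{A_i > 0}, kJ/mol.
#' @param widths well widths \eqn{w_i > 0}, nm (recycled).
#' @param conf_k spring constant of the confining quadratic term,
#'   kJ/mol/nm^2; 0 disables confinement.
#' @param conf_center centre of the confinement (defaults to the mean of the
#'   well centres).
#' @param locate_saddles logical; search for saddle points at construction.
#' @param grid_n nodes per axis of the saddle-search grid.
#' @return An object of class `model_potential` with elements `centers`,
#'   `depths`, `widths`, `conf_center`, `conf_k`, `dimensionality`,
#'   `known_minima` (matrix of refined stationary minima), `known_saddles`
#'   (matrix, possibly 0-row) and `saddle_energies` (kJ/mol).
#' @examples
#' pot <- make_double_well(rbind(c(-1, 0), c(1, 0)), depths = c(10, 10),
#'                         widths = 0.5)
#' potential_energy(pot, pot$known_minima)
#' pot$known_saddles
#' @export
make_gaussian_wells <- function(centers, depths, widths, conf_k = 0,
                                conf_center = NULL, locate_saddles = TRUE,
                                grid_n = 400) {
  if (is.null(dim(centers))) centers <- matrix(centers, ncol = length(centers))
  centers <- as.matrix(centers)
  storage.mode(centers) <- "double"
  n <- nrow(centers)
  d <- ncol(centers)
  if (!d %in% c(1L, 2L)) stop("only 1D and 2D potentials are supported")
  if (any(depths <= 0)) stop("well depths must be positive")
  if (any(widths <= 0)) stop("well widths must be positive")
  depths <- rep_len(as.numeric(depths), n)
  widths <- rep_len(as.numeric(widths), n)
  if (n > 1) {
    dd <- as.matrix(dist(centers))
    diag(dd) <- Inf
    if (min(dd) < 1e-8)
      stop("invalid geometry: coincident well centers")
  }
  if (is.null(conf_center)) conf_center <- colMeans(centers)
  conf_center <- as.numeric(conf_center)
  if (conf_k < 0) stop("confinement spring constant must be >= 0")

  pot <- structure(
    list(centers = centers, depths = depths, widths = widths,
         conf_center = conf_center, conf_k = conf_k, dimensionality = d),
    class = "model_potential")

  # refine each well centre to a true stationary point of the composed F
  minima <- t(apply(centers, 1, function(x0) .refine_minimum(pot, x0)))
  if (d == 1) minima <- matrix(minima, ncol = 1)
  gn <- apply(minima, 1, function(x) sqrt(sum(potential_gradient(pot, x)^2)))
  pot$known_minima <- minima[gn < 1e-6, , drop = FALSE]

  if (locate_saddles && n > 1) {
    sdl <- .locate_saddles(pot, grid_n = grid_n)
    pot$known_saddles <- sdl$coords
    pot$saddle_energies <- sdl$energies
  } else {
    pot$known_saddles <- matrix(numeric(0), ncol = d)
    pot$saddle_energies <- numeric(0)
  }
  pot
}

#' Two-well model potential
#'
#' Convenience wrapper around [make_gaussian_wells()] for the canonical
#' double-well fixture: two distinct Gaussian wells plus optional harmonic
#' confinement.
#'
#' @param minima 2-row matrix (or length-2 vector in 1D) of well centres, nm.
#' @inheritParams make_gaussian_wells
#' @export
make_double_well <- function(minima, depths, widths, conf_k = 0,
                             conf_center = NULL) {
  if (is.null(dim(minima)) && length(minima) == 2)
    minima <- matrix(minima, ncol = 1)
  minima <- as.matrix(minima)
  if (nrow(minima) != 2) stop("a double well needs exactly two minima")
  make_gaussian_wells(minima, depths, widths, conf_k = conf_k,
                      conf_center = conf_center)
}

#' Evaluate a model potential
#'
#' @param potential a `model_potential`.
#' @param x point (vector) or matrix of points (one per row), nm.
#' @return energies in kJ/mol (one per point).
#' @export
potential_energy <- function(potential, x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = potential$dimensionality)
  apply(x, 1, function(p) .pot_eg(potential, p)$energy)
}

#' Analytic gradient of a model potential
#'
#' @inheritParams potential_energy
#' @return gradient vector (single point) or matrix, kJ/mol/nm.
#' @export
potential_gradient <- function(potential, x) {
  if (is.null(dim(x)))
    return(.pot_eg(potential, x)$gradient)
  t(apply(x, 1, function(p) .pot_eg(potential, p)$gradient))
}

.pot_eg <- function(pot, x) {
  d <- pot$dimensionality
  stopifnot(length(x) == d)
  dx <- sweep(pot$centers, 2, x, function(c, x) x - c) # rows: x - c_i
  r2 <- rowSums(dx^2)
  e <- pot$depths * exp(-r2 / (2 * pot$widths^2))
  energy <- -sum(e)
  grad <- colSums(dx * e / pot$widths^2)
  if (pot$conf_k > 0) {
    dc <- x - pot$conf_center
    energy <- energy + 0.5 * pot$conf_k * sum(dc^2)
    grad <- grad + pot$conf_k * dc
  }
  if (!all(is.finite(energy)) || !all(is.finite(grad)))
    stop("non-finite potential energy/gradient")
  list(energy = energy, gradient = as.numeric(grad))
}

.refine_minimum <- function(pot, x0) {
  res <- optim(x0, fn = function(p) .pot_eg(pot, p)$energy,
               gr = function(p) .pot_eg(pot, p)$gradient,
               method = "BFGS", control = list(reltol = 1e-16, maxit = 500))
  res$par
}

# |grad F|^2 evaluated vectorized over a matrix of points (rows)
.grad_sq_grid <- function(pot, pts) {
  d <- pot$dimensionality
  G <- matrix(0, nrow(pts), d)
  for (i in seq_len(nrow(pot$centers))) {
    dx <- sweep(pts, 2, pot$centers[i, ])       # pts - c_i
    e <- pot$depths[i] * exp(-rowSums(dx^2) / (2 * pot$widths[i]^2))
    G <- G + dx * (e / pot$widths[i]^2)
  }
  if (pot$conf_k > 0)
    G <- G + pot$conf_k * sweep(pts, 2, pot$conf_center)
  rowSums(G^2)
}

# numerical Hessian from the analytic gradient
.num_hessian <- function(pot, x, h = 1e-5) {
  d <- length(x)
  H <- matrix(0, d, d)
  for (j in seq_len(d)) {
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    H[, j] <- (.pot_eg(pot, xp)$gradient - .pot_eg(pot, xm)$gradient) / (2 * h)
  }
  (H + t(H)) / 2
}

# dense-grid search for index-1 saddles: local minima of |grad|^2 on the grid,
# Nelder-Mead refinement, Hessian classification, de-duplication.
.locate_saddles <- function(pot, grid_n = 400, pad = NULL) {
  d <- pot$dimensionality
  if (is.null(pad)) pad <- 3 * max(pot$widths)
  lo <- apply(pot$centers, 2, min) - pad
  hi <- apply(pot$centers, 2, max) + pad
  gsq <- function(p) sum(.pot_eg(pot, p)$gradient^2)

  if (d == 1) {
    ax <- seq(lo, hi, length.out = max(grid_n, 1000))
    g <- .grad_sq_grid(pot, matrix(ax, ncol = 1))
    cand <- which(diff(sign(diff(g))) >= 1) + 1L
    starts <- lapply(cand, function(i) ax[i])
  } else {
    ax <- seq(lo[1], hi[1], length.out = grid_n)
    ay <- seq(lo[2], hi[2], length.out = grid_n)
    pts <- cbind(rep(ax, times = length(ay)), rep(ay, each = length(ax)))
    G <- matrix(.grad_sq_grid(pot, pts), nrow = length(ax))
    cand <- which(.local_min_mask(G), arr.ind = TRUE)
    if (nrow(cand) > 200) {
      gv <- G[cand]
      cand <- cand[order(gv)[1:200], , drop = FALSE]
    }
    starts <- lapply(seq_len(nrow(cand)),
                     function(k) c(ax[cand[k, 1]], ay[cand[k, 2]]))
  }

  coords <- matrix(numeric(0), ncol = d)
  energies <- numeric(0)
  for (x0 in starts) {
    res <- optim(x0, gsq, method = "Nelder-Mead",
                 control = list(reltol = 1e-16, maxit = 2000, warn.1d.NelderMead = FALSE))
    if (sqrt(res$value) > 1e-6) next
    p <- res$par
    # skip points that refined onto a known minimum
    if (nrow(pot$known_minima) &&
        min(sqrt(rowSums(sweep(pot$known_minima, 2, p)^2))) < 1e-3) next
    ev <- eigen(.num_hessian(pot, p), symmetric = TRUE,
                only.values = TRUE)$values
    if (d == 1) {
      if (ev[1] >= 0) next          # want a 1D maximum
    } else {
      if (!(ev[1] > 0 && ev[2] < 0)) next  # exactly one negative direction
    }
    if (nrow(coords) &&
        min(sqrt(rowSums(sweep(coords, 2, p)^2))) < 1e-3) next
    coords <- rbind(coords, p)
    energies <- c(energies, .pot_eg(pot, p)$energy)
  }
  rownames(coords) <- NULL
  list(coords = coords, energies = energies)
}

# interior local minima of a matrix under the 8-neighbourhood; non-strict so
# that symmetric ties (a saddle falling exactly between two nodes) still
# yield candidates -- duplicates are merged after refinement
.local_min_mask <- function(G) {
  nr <- nrow(G); nc <- ncol(G)
  M <- matrix(FALSE, nr, nc)
  if (nr < 3 || nc < 3) return(M)
  i <- 2:(nr - 1); j <- 2:(nc - 1)
  C <- G[i, j]
  ok <- C <= G[i - 1, j] & C <= G[i + 1, j] & C <= G[i, j - 1] &
        C <= G[i, j + 1] & C <= G[i - 1, j - 1] & C <= G[i - 1, j + 1] &
        C <= G[i + 1, j - 1] & C <= G[i + 1, j + 1]
  M[i, j] <- ok
  M
}

#' Analytic barrier between two wells of a model potential
#'
#' Barrier from the given minimum to the lowest saddle, in kJ/mol.
#'
#' @param potential a `model_potential` with located saddles.
#' @param from index of the minimum in `known_minima`.
#' @export
analytic_barrier <- function(potential, from = 1) {
  if (!nrow(potential$known_saddles)) stop("potential has no located saddle")
  fmin <- potential_energy(potential,
                           potential$known_minima[from, , drop = FALSE])
  min(potential$saddle_energies) - fmin
}

#' @export
print.model_potential <- function(x, ...) {
  cat(sprintf("Model potential: %d Gaussian well(s) in %dD\n",
              nrow(x$centers), x$dimensionality))
  cat(sprintf("  depths (kJ/mol): %s\n", paste(signif(x$depths, 4), collapse = ", ")))
  cat(sprintf("  widths (nm):     %s\n", paste(signif(x$widths, 4), collapse = ", ")))
  if (x$conf_k > 0)
    cat(sprintf("  confinement: k = %g kJ/mol/nm^2 at (%s)\n", x$conf_k,
                paste(signif(x$conf_center, 4), collapse = ", ")))
  cat(sprintf("  %d refined minimum/minima, %d saddle(s)\n",
              nrow(x$known_minima), nrow(x$known_saddles)))
  invisible(x)
}
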