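#' Free-energy surface container
#'
#' A rectilinear CV grid with free-energy values in kJ/mol.  1D surfaces
#' store a numeric vector, 2D surfaces a matrix (rows follow axis 1).
#' `normalized` records whether the minimum has been shifted to exactly 0.
#'
#' @param values numeric vector (1D) or matrix (2D), kJ/mol.
#' @param axes named list of grid axis vectors, nm.
#' @param temperature K (used by [marginalize_1d()]).
#' @param biasfactor bias factor of the generating run (NA when not from
#'   hills).
#' @param normalized logical.
#' @export
new_fes <- function(values, axes, temperature = 310.15, biasfactor = NA_real_,
                    normalized = FALSE) {
  stopifnot(is.list(axes), length(axes) %in% c(1L, 2L))
  if (length(axes) == 2) {
    values <- as.matrix(values)
    stopifnot(nrow(values) == length(axes[[1]]),
              ncol(values) == length(axes[[2]]))
  } else {
    values <- as.numeric(values)
    stopifnot(length(values) == length(axes[[1]]))
  }
  if (!all(is.finite(values))) stop("invalid surface: non-finite values")
  if (is.null(names(axes))) names(axes) <- paste0("d", seq_along(axes))
  structure(list(values = values, axes = axes,
                 cv_names = names(axes), temperature = temperature,
                 biasfactor = biasfactor, normalized = isTRUE(normalized)),
            class = "fes")
}

.fes_dim <- function(fes) length(fes$axes)

#' Shift a surface so its minimum is exactly zero
#' @param fes a `fes`.
#' @export
normalize_fes <- function(fes) {
  fes$values <- fes$values - min(fes$values)
  fes$normalized <- TRUE
  fes
}

#' @export
print.fes <- function(x, ...) {
  dims <- vapply(x$axes, length, 0L)
  cat(sprintf("Free-energy surface: %s grid on (%s)\n",
              paste(dims, collapse = " x "),
              paste(x$cv_names, collapse = ", ")))
  for (j in seq_along(x$axes))
    cat(sprintf("  %s: %.4g..%.4g nm\n", x$cv_names[j], min(x$axes[[j]]),
                max(x$axes[[j]])))
  cat(sprintf("  range %.4g..%.4g kJ/mol%s, T = %g K\n", min(x$values),
              max(x$values), if (x$normalized) " (min at 0)" else "",
              x$temperature))
  invisible(x)
}

#' @export
summary.fes <- function(object, min_depth = 1, ...) {
  print(object)
  m <- find_minima(normalize_fes(object), min_depth = min_depth)
  cat(sprintf("  %d basin(s) at min_depth = %g kJ/mol:\n", nrow(m), min_depth))
  print(as.data.frame(m), row.names = FALSE)
  invisible(m)
}

#' @export
plot.fes <- function(x, n_levels = 12, ...) {
  if (.fes_dim(x) == 1) {
    plot(x$axes[[1]], x$values, type = "l", xlab = paste(x$cv_names[1], "(nm)"),
         ylab = "free energy (kJ/mol)", ...)
  } else {
    image(x$axes[[1]], x$axes[[2]], x$values,
          col = hcl.colors(64, "viridis", rev = TRUE),
          xlab = paste(x$cv_names[1], "(nm)"),
          ylab = paste(x$cv_names[2], "(nm)"), ...)
    contour(x$axes[[1]], x$axes[[2]], x$values, nlevels = n_levels,
            add = TRUE, drawlabels = FALSE, col = "grey30")
  }
  invisible(x)
}

#' Free-energy surface by bias summation over hills
#'
#' Sums every deposited Gaussian onto each grid node to obtain the
#' accumulated bias \eqn{V}; the free-energy estimate is \eqn{F = -V},
#' multiplied by \eqn{\gamma/(\gamma-1)} when `wt_correction` is on (the
#' hills store post-scaling heights, so the well-tempered limit satisfies
#' \eqn{V \to -(1 - 1/\gamma) F}), then min-shifted to zero.
#'
#' @param hills a `hills` object.
#' @param grid optional named list of axis vectors; by default a
#'   `npoints`-per-axis grid spanning the hills' bounding box padded by
#'   `pad` (3 times the maximum width when NULL).
#' @param npoints nodes per axis for the default grid.
#' @param pad padding of the default grid, nm.
#' @param wt_correction apply the \eqn{\gamma/(\gamma-1)} factor (default
#'   TRUE).
#' @param temperature stored on the surface for downstream marginalization.
#' @return a normalized `fes`.
#' @export
bias_sum_fes <- function(hills, grid = NULL, npoints = 256L, pad = NULL,
                         wt_correction = TRUE, temperature = 310.15) {
  cvn <- attr(hills, "cv_names")
  d <- length(cvn)
  C <- .hills_centers(hills)
  S <- .hills_sigmas(hills)
  gamma <- NA_real_
  if (wt_correction && nrow(hills)) {
    gamma <- unique(hills$biasf)
    if (!length(gamma) || anyNA(gamma))
      stop("parameter error: wt_correction requires a bias factor in the hills")
    if (length(gamma) > 1) {
      warning("multiple bias factors found; using the first")
      gamma <- gamma[1]
    }
    if (gamma <= 1) stop("parameter error: bias factor must exceed 1")
  }
  if (is.null(grid)) {
    if (!nrow(hills)) stop("cannot build a default grid from an empty series")
    if (is.null(pad)) pad <- 3 * max(S)
    grid <- lapply(seq_len(d), function(j)
      seq(min(C[, j]) - pad, max(C[, j]) + pad, length.out = npoints))
    names(grid) <- cvn
  }
  stopifnot(length(grid) == d)
  if (nrow(hills)) {
    for (j in seq_len(d))
      if (min(C[, j]) < min(grid[[j]]) || max(C[, j]) > max(grid[[j]]))
        stop("grid does not cover the hills' centers")
  }
  V <- cpp_bias_sum_grid(C, S, hills$height, unname(grid))
  if (d == 2) V <- matrix(V, nrow = length(grid[[1]]))
  Fv <- -V
  if (wt_correction && nrow(hills)) Fv <- Fv * gamma / (gamma - 1)
  normalize_fes(new_fes(Fv, grid, temperature = temperature,
                        biasfactor = if (wt_correction) gamma else
                          unique(hills$biasf)[1]))
}

#' Evaluate a model potential on a grid as a `fes`
#'
#' Ground-truth surface for validating reconstructions and path methods.
#'
#' @param potential a `model_potential`.
#' @param grid named list of axis vectors; default spans the well centres
#'   padded by 3 max widths.
#' @param npoints nodes per axis for the default grid.
#' @param temperature K.
#' @param normalize min-shift to zero (default TRUE).
#' @export
potential_to_fes <- function(potential, grid = NULL, npoints = 256L,
                             temperature = 310.15, normalize = TRUE) {
  d <- potential$dimensionality
  if (is.null(grid)) {
    pad <- 3 * max(potential$widths)
    grid <- lapply(seq_len(d), function(j)
      seq(min(potential$centers[, j]) - pad,
          max(potential$centers[, j]) + pad, length.out = npoints))
    names(grid) <- paste0("d", seq_len(d))
  }
  if (d == 1) {
    v <- potential_energy(potential, matrix(grid[[1]], ncol = 1))
  } else {
    pts <- as.matrix(expand.grid(grid[[1]], grid[[2]]))
    v <- matrix(potential_energy(potential, pts), nrow = length(grid[[1]]))
  }
  out <- new_fes(v, grid, temperature = temperature)
  if (normalize) out <- normalize_fes(out) else out
}

# ---- basin detection --------------------------------------------------------

# neighbour index matrix (NA out of bounds): 2-neighbourhood in 1D,
# 8-neighbourhood in 2D; built vectorized so the sweep loop stays cheap
.neighbor_matrix <- function(dims) {
  if (length(dims) == 1) {
    n <- dims[1]
    i <- seq_len(n)
    m <- cbind(i - 1L, i + 1L)
    m[m < 1L | m > n] <- NA_integer_
    return(m)
  }
  nx <- dims[1]; ny <- dims[2]
  n <- nx * ny
  i <- seq_len(n)
  ix <- ((i - 1L) %% nx) + 1L
  iy <- ((i - 1L) %/% nx) + 1L
  offs <- expand.grid(dx = -1:1, dy = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0), ]
  m <- matrix(NA_integer_, n, nrow(offs))
  for (k in seq_len(nrow(offs))) {
    jx <- ix + offs$dx[k]; jy <- iy + offs$dy[k]
    ok <- jx >= 1L & jx <= nx & jy >= 1L & jy <= ny
    m[ok, k] <- (jy[ok] - 1L) * nx + jx[ok]
  }
  m
}

#' Local minima (basins) of a free-energy surface
#'
#' Strict local minima of the grid under the 8-neighbourhood (2D) or
#' 2-neighbourhood (1D), filtered by topographic prominence: a minimum is
#' kept only if the lowest saddle connecting it to any deeper basin lies at
#' least `min_depth` kJ/mol above it (computed exactly on the grid by a
#' union-find sweep over nodes in ascending free energy).  Basins are
#' labelled A, B, C, ... by ascending free energy; on a normalized surface
#' the global minimum (label A) sits at 0.00 kJ/mol.
#'
#' @param fes a normalized `fes`.
#' @param min_depth prominence threshold, kJ/mol; the default 1 kJ/mol
#'   discards sub-thermal grid noise (thermal energy at 310 K is about
#'   2.6 kJ/mol).
#' @return data.frame of class `fes_minima`: `label`, one coordinate column
#'   per CV (nm), `free_energy` (kJ/mol), `node` (grid index).
#' @export
find_minima <- function(fes, min_depth = 1) {
  stopifnot(inherits(fes, "fes"))
  if (!all(is.finite(fes$values))) stop("invalid surface: non-finite values")
  if (!fes$normalized) fes <- normalize_fes(fes)
  v <- as.numeric(fes$values)
  dims <- vapply(fes$axes, length, 0L)
  nbmat <- .neighbor_matrix(dims)
  ord <- order(v, seq_along(v))     # ascending F, ties by index
  parent <- integer(length(v))      # 0 = unprocessed
  comp_min <- integer(0)            # representative minimum node per root
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  min_nodes <- integer(0)
  prominence <- numeric(0)
  min_of_root <- new.env(parent = emptyenv())
  for (vtx in ord) {
    nbr <- nbmat[vtx, ]
    nbr <- nbr[!is.na(nbr)]
    done <- nbr[parent[nbr] != 0L]
    if (!length(done)) {
      parent[vtx] <- vtx
      assign(as.character(vtx), vtx, envir = min_of_root)
      min_nodes <- c(min_nodes, vtx)
      prominence <- c(prominence, Inf)
      next
    }
    roots <- unique(vapply(done, find, 0L))
    rmins <- vapply(roots, function(r) get(as.character(r),
                                           envir = min_of_root), 0L)
    deepest <- roots[which.min(v[rmins])]
    parent[vtx] <- deepest
    if (length(roots) > 1) {
      for (r in roots[roots != deepest]) {
        mn <- get(as.character(r), envir = min_of_root)
        prominence[match(mn, min_nodes)] <- v[vtx] - v[mn]
        parent[r] <- deepest
      }
    }
  }
  keep <- prominence >= min_depth
  nodes <- min_nodes[keep]
  o <- order(v[nodes], nodes)
  nodes <- nodes[o]
  coords <- .node_coords(fes, nodes)
  out <- data.frame(label = .basin_labels(length(nodes)),
                    stringsAsFactors = FALSE)
  for (j in seq_along(fes$axes)) out[[fes$cv_names[j]]] <- coords[, j]
  out$free_energy <- v[nodes]
  out$node <- nodes
  attr(out, "min_depth") <- min_depth
  attr(out, "fes") <- fes
  class(out) <- c("fes_minima", "data.frame")
  out
}

.node_coords <- function(fes, nodes) {
  dims <- vapply(fes$axes, length, 0L)
  if (length(dims) == 1)
    return(matrix(fes$axes[[1]][nodes], ncol = 1))
  nx <- dims[1]
  ix <- ((nodes - 1L) %% nx) + 1L
  iy <- ((nodes - 1L) %/% nx) + 1L
  cbind(fes$axes[[1]][ix], fes$axes[[2]][iy])
}

.basin_labels <- function(n) {
  if (n <= 26) return(LETTERS[seq_len(n)])
  c(LETTERS, paste0(rep(LETTERS, each = 26), LETTERS))[seq_len(n)]
}

#' @export
print.fes_minima <- function(x, ...) {
  cat(sprintf("Basins (min_depth = %g kJ/mol):\n", attr(x, "min_depth")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

# ---- 1D marginals -----------------------------------------------------------

.logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

.trap_weights <- function(ax) {
  n <- length(ax)
  h <- diff(ax)
  w <- numeric(n)
  w[1] <- h[1] / 2
  w[n] <- h[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (h[-1] + h[-(n - 1)]) / 2
  w
}

#' Thermal 1D marginal of a 2D free-energy surface
#'
#' Integrates the Boltzmann factor over the discarded CV:
#' \deqn{F(d_1) = -\beta^{-1} \ln\left[\frac{\int e^{-\beta F(d_1, d_2)}
#'   \mathrm{d}d_2}{\int e^{-\beta F}\,\mathrm{d}d_1 \mathrm{d}d_2}\right]}
#' with \eqn{\beta = 1/(k_B T)}, by trapezoidal quadrature on the grid
#' (log-sum-exp for stability); the result is re-normalized so its minimum
#' is zero.
#'
#' @param fes a 2D `fes` (normalized or not; temperature is taken from the
#'   surface unless overridden).
#' @param keep_axis which CV to keep (index or name).
#' @param temperature optional override, K.
#' @return a normalized 1D `fes`.
#' @export
marginalize_1d <- function(fes, keep_axis = 1, temperature = NULL) {
  stopifnot(inherits(fes, "fes"))
  if (.fes_dim(fes) != 2)
    stop("dimensionality error: marginalization needs a 2D surface")
  if (is.character(keep_axis)) keep_axis <- match(keep_axis, fes$cv_names)
  stopifnot(keep_axis %in% c(1, 2))
  temperature <- temperature %||% fes$temperature
  beta <- 1 / (.kB * temperature)
  Fm <- if (keep_axis == 1) fes$values else t(fes$values)
  kept <- fes$axes[[keep_axis]]
  other <- fes$axes[[3 - keep_axis]]
  wo <- .trap_weights(other)
  wk <- .trap_weights(kept)
  li <- vapply(seq_along(kept), function(i)
    .logsumexp(-beta * Fm[i, ] + log(wo)), 0)
  denom <- .logsumexp(li + log(wk))
  prof <- -(li - denom) / beta
  normalize_fes(new_fes(prof, fes$axes[keep_axis],
                        temperature = temperature,
                        biasfactor = fes$biasfactor))
}

# ---- convergence diagnostics ------------------------------------------------

#' Block-convergence diagnostics of a metadynamics run
#'
#' Splits the hills series by time into `n_blocks` cumulative prefixes,
#' reconstructs the surface from each prefix, and reports the RMS
#' difference (over the grid, after min-shift) between successive
#' estimates: a converging run shows decreasing successive differences.
#'
#' @param hills a `hills` object.
#' @param n_blocks number of cumulative blocks (>= 1).
#' @param grid optional grid passed to [bias_sum_fes()]; by default the
#'   full-series default grid is reused for every prefix so surfaces are
#'   comparable.
#' @param ... further arguments to [bias_sum_fes()].
#' @return list of class `fes_convergence`: `fes` (list of per-block
#'   surfaces), `n_hills` (prefix sizes), `rms_diff` (length
#'   `n_blocks - 1`).
#' @export
block_convergence <- function(hills, n_blocks, grid = NULL, ...) {
  n <- nrow(hills)
  if (n_blocks < 1) stop("invalid blocks: n_blocks must be >= 1")
  if (n_blocks > n)
    stop(sprintf("invalid blocks: %d blocks requested for %d hills",
                 n_blocks, n))
  full <- bias_sum_fes(hills, grid = grid, ...)
  if (is.null(grid)) grid <- full$axes
  sizes <- floor(n * seq_len(n_blocks) / n_blocks)
  fl <- lapply(sizes, function(b)
    bias_sum_fes(hills[seq_len(b), , drop = FALSE], grid = grid, ...))
  rms <- if (n_blocks > 1)
    vapply(seq_len(n_blocks - 1), function(b)
      sqrt(mean((fl[[b + 1]]$values - fl[[b]]$values)^2)), 0)
  else numeric(0)
  structure(list(fes = fl, n_hills = sizes, rms_diff = rms),
            class = "fes_convergence")
}

#' @export
print.fes_convergence <- function(x, ...) {
  cat(sprintf("Block convergence: %d cumulative blocks (%s hills)\n",
              length(x$fes), paste(x$n_hills, collapse = ", ")))
  if (length(x$rms_diff))
    cat("  successive RMS differences (kJ/mol):",
        paste(signif(x$rms_diff, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Export a free-energy surface as plain text
#'
#' Column-major grid table (axis values then free energy) plus a JSON
#' metadata side-car (`<path>.json`).
#'
#' @param fes a `fes`.
#' @param path output table file.
#' @export
write_fes <- function(fes, path) {
  if (.fes_dim(fes) == 1) {
    df <- data.frame(fes$axes[[1]], fes$values)
  } else {
    g <- expand.grid(fes$axes[[1]], fes$axes[[2]])
    df <- data.frame(g[[1]], g[[2]], as.numeric(fes$values))
  }
  names(df) <- c(fes$cv_names, "free_energy")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#", paste(names(df), collapse = " ")), con)
  write.table(format(df, digits = 10, trim = TRUE), con, quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(cv_names = fes$cv_names, temperature = fes$temperature,
         biasfactor = fes$biasfactor, normalized = fes$normalized,
         grid = lapply(fes$axes, function(a)
           list(min = min(a), max = max(a), n = length(a)))),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
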