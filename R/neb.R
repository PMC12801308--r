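# bilinear interpolation of a 2D fes at points P (n x 2); clamps to the grid
.fes_interp <- function(fes, P) {
  ax <- fes$axes[[1]]; ay <- fes$axes[[2]]
  x <- pmin(pmax(P[, 1], ax[1]), ax[length(ax)])
  y <- pmin(pmax(P[, 2], ay[1]), ay[length(ay)])
  i <- pmin(findInterval(x, ax), length(ax) - 1L)
  j <- pmin(findInterval(y, ay), length(ay) - 1L)
  tx <- (x - ax[i]) / (ax[i + 1] - ax[i])
  ty <- (y - ay[j]) / (ay[j + 1] - ay[j])
  V <- fes$values
  v00 <- V[cbind(i, j)];     v10 <- V[cbind(i + 1L, j)]
  v01 <- V[cbind(i, j + 1L)]; v11 <- V[cbind(i + 1L, j + 1L)]
  (1 - tx) * (1 - ty) * v00 + tx * (1 - ty) * v10 +
    (1 - tx) * ty * v01 + tx * ty * v11
}

# central-difference gradient of the bilinear interpolant
.fes_grad <- function(fes, P, h = NULL) {
  if (is.null(h))
    h <- 0.5 * min(vapply(fes$axes, function(a) min(diff(a)), 0))
  gx <- (.fes_interp(fes, cbind(P[, 1] + h, P[, 2])) -
         .fes_interp(fes, cbind(P[, 1] - h, P[, 2]))) / (2 * h)
  gy <- (.fes_interp(fes, cbind(P[, 1], P[, 2] + h)) -
         .fes_interp(fes, cbind(P[, 1], P[, 2] - h))) / (2 * h)
  cbind(gx, gy)
}

.resolve_basin <- function(x, minima, fes) {
  if (is.character(x)) {
    if (is.null(minima)) stop("basin labels need a `minima` table")
    i <- match(x, minima$label)
    if (is.na(i)) stop(sprintf("lookup error: unknown basin label '%s'", x))
    return(list(coords = as.numeric(minima[i, fes$cv_names]), label = x))
  }
  list(coords = as.numeric(x), label = NA_character_)
}

#' Minimum free-energy path between two basins (nudged elastic band)
#'
#' A chain of images is relaxed on the (bilinearly interpolated) surface
#' under the projected NEB force: the component of the surface gradient
#' perpendicular to the path tangent, plus a tangential spring force keeping
#' images spread; endpoints stay fixed.  No climbing image is used.  The
#' transition state is the profile maximum, refined by a parabola through
#' the three bracketing images (arc-length coordinate) and re-evaluated on
#' the surface, which recovers saddle locations below the image spacing.
#'
#' @param fes a 2D `fes`.
#' @param a,b endpoints: basin labels (with `minima`) or CV coordinate
#'   vectors, nm.
#' @param minima optional [find_minima()] table for label lookup.
#' @param n_images number of images (>= 3).
#' @param spring_k spring constant, kJ/mol/nm^2.
#' @param step gradient-descent step, nm per (kJ/mol/nm).
#' @param tol convergence threshold on the maximum perpendicular force,
#'   kJ/mol/nm.
#' @param max_iter iteration cap; non-convergence returns the path with
#'   `converged = FALSE` and a warning.
#' @return object of class `neb_path`: `images` (n x 2), `profile`
#'   (kJ/mol), `ts_index`, `ts_coords`, `ts_energy`, `dF_forward`,
#'   `dF_backward` (kJ/mol), `converged`, `from`, `to`.
#' @export
neb_path <- function(fes, a, b, minima = NULL, n_images = 32L,
                     spring_k = 100, step = 1e-4, tol = 0.5,
                     max_iter = 5000L) {
  stopifnot(inherits(fes, "fes"))
  if (.fes_dim(fes) != 2) stop("NEB needs a 2D surface")
  if (n_images < 3) stop("n_images must be >= 3")
  A <- .resolve_basin(a, minima, fes)
  B <- .resolve_basin(b, minima, fes)
  frac <- seq(0, 1, length.out = n_images)
  P <- cbind(A$coords[1] + frac * (B$coords[1] - A$coords[1]),
             A$coords[2] + frac * (B$coords[2] - A$coords[2]))
  lo <- vapply(fes$axes, min, 0); hi <- vapply(fes$axes, max, 0)
  ii <- 2:(n_images - 1)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    G <- .fes_grad(fes, P[ii, , drop = FALSE])
    tau <- P[ii + 1L, , drop = FALSE] - P[ii - 1L, , drop = FALSE]
    tau <- tau / sqrt(rowSums(tau^2))
    gpar <- rowSums(G * tau)
    gperp <- G - gpar * tau
    dfwd <- sqrt(rowSums((P[ii + 1L, , drop = FALSE] -
                          P[ii, , drop = FALSE])^2))
    dbwd <- sqrt(rowSums((P[ii, , drop = FALSE] -
                          P[ii - 1L, , drop = FALSE])^2))
    fspring <- spring_k * (dfwd - dbwd) * tau
    P[ii, ] <- P[ii, , drop = FALSE] + step * (-gperp + fspring)
    P[ii, 1] <- pmin(pmax(P[ii, 1], lo[1]), hi[1])
    P[ii, 2] <- pmin(pmax(P[ii, 2], lo[2]), hi[2])
    if (max(sqrt(rowSums(gperp^2))) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning(sprintf("NEB did not reach tol = %g in %d iterations", tol,
                    max_iter))
  profile <- .fes_interp(fes, P)
  ts_index <- which.max(profile)
  ts_coords <- P[ts_index, ]
  ts_energy <- profile[ts_index]
  if (ts_index > 1 && ts_index < n_images) {
    # parabolic refinement along arc length through the bracketing images
    s <- c(0, cumsum(sqrt(rowSums(diff(P)^2))))
    s3 <- s[(ts_index - 1):(ts_index + 1)]
    f3 <- profile[(ts_index - 1):(ts_index + 1)]
    dd <- (f3[3] - 2 * f3[2] + f3[1])
    if (is.finite(dd) && dd < 0) {
      num <- (f3[3] - f3[1]) / 2
      ss <- s3[2] - num / dd * (s3[3] - s3[1]) / 2
      ss <- min(max(ss, s3[1]), s3[3])
      k <- if (ss <= s3[2]) ts_index - 1L else ts_index
      t <- (ss - s[k]) / (s[k + 1] - s[k])
      cand <- (1 - t) * P[k, ] + t * P[k + 1L, ]
      fc <- .fes_interp(fes, matrix(cand, ncol = 2))
      if (fc >= ts_energy) {
        ts_coords <- cand
        ts_energy <- fc
      }
    }
  }
  structure(list(images = P, profile = profile, ts_index = ts_index,
                 ts_coords = ts_coords, ts_energy = ts_energy,
                 dF_forward = ts_energy - profile[1],
                 dF_backward = ts_energy - profile[n_images],
                 converged = converged, iterations = it,
                 from = A$label, to = B$label),
            class = "neb_path")
}

#' @export
print.neb_path <- function(x, ...) {
  cat(sprintf(
    "NEB path %s -> %s: %d images, dF_fwd = %.3f, dF_bwd = %.3f kJ/mol%s\n",
    x$from %||% "a", x$to %||% "b", nrow(x$images), x$dF_forward,
    x$dF_backward, if (x$converged) "" else " (NOT converged)"))
  cat(sprintf("  transition state at (%s) nm, %.3f kJ/mol (image %d)\n",
              paste(signif(x$ts_coords, 4), collapse = ", "), x$ts_energy,
              x$ts_index))
  invisible(x)
}

#' @export
plot.neb_path <- function(x, ...) {
  s <- c(0, cumsum(sqrt(rowSums(diff(x$images)^2))))
  plot(s, x$profile, type = "b", xlab = "arc length (nm)",
       ylab = "free energy (kJ/mol)", ...)
  invisible(x)
}

#' Eyring-Polanyi transition half-life
#'
#' Classical transition-state kinetics: rate
#' \eqn{k = \kappa \frac{k_B T}{h} e^{-\Delta F / (R T)}} and half-life
#' \eqn{t_{1/2} = \ln 2 / k}, reported in ps.  Strictly increasing in
#' \eqn{\Delta F}.
#'
#' @param deltaF free-energy barrier, kJ/mol (>= 0); vectorized.
#' @param temperature K (default 300).
#' @param transmission transmission coefficient \eqn{\kappa} (default 1).
#' @export
eyring_half_life <- function(deltaF, temperature = 300, transmission = 1) {
  if (any(deltaF < 0)) stop("domain error: deltaF must be >= 0")
  if (temperature <= 0) stop("temperature must be > 0")
  rate <- transmission * (.kB_SI * temperature / .h_SI) *
    exp(-deltaF * 1000 / (.R_gas * temperature))   # 1/s
  log(2) / rate * 1e12
}

#' Barriers and half-lives for a set of basin transitions
#'
#' Runs [neb_path()] for each requested ordered basin pair (one relaxation
#' per unordered pair; the reverse direction reuses the same path), then
#' fills forward/backward barriers and Eyring-Polanyi half-lives.  Rows
#' with a half-life below 1 ps are flagged transient: such states are
#' typically not captured at ordinary trajectory-saving strides.
#'
#' @param fes a 2D `fes`.
#' @param minima a [find_minima()] table.
#' @param pairs 2-column matrix or data.frame of basin labels (from, to);
#'   default: all ordered pairs of adjacent-rank basins.
#' @param temperature kinetics temperature, K (default 300).
#' @param transmission transmission coefficient (default 1).
#' @param ... passed to [neb_path()].
#' @return data.frame of class `transition_table`: `from`, `to`,
#'   `dF` (kJ/mol), `half_life_ps`, `transient`; the relaxed paths are kept
#'   in the `paths` attribute.
#' @export
transition_table <- function(fes, minima, pairs = NULL, temperature = 300,
                             transmission = 1, ...) {
  if (is.null(pairs)) {
    if (nrow(minima) < 2) {
      pairs <- matrix(character(0), ncol = 2)
    } else {
      lab <- minima$label
      pairs <- cbind(lab[-length(lab)], lab[-1])
      pairs <- rbind(pairs, pairs[, 2:1, drop = FALSE])
    }
  }
  pairs <- as.matrix(pairs)
  out <- data.frame(from = character(0), to = character(0), dF = numeric(0),
                    half_life_ps = numeric(0), transient = logical(0))
  paths <- list()
  if (nrow(pairs)) {
    for (lab in unique(as.character(pairs)))
      .resolve_basin(lab, minima, fes)   # validate labels up front
    for (r in seq_len(nrow(pairs))) {
      fr <- pairs[r, 1]; to <- pairs[r, 2]
      key <- paste(sort(c(fr, to)), collapse = "|")
      if (is.null(paths[[key]]))
        paths[[key]] <- neb_path(fes, sort(c(fr, to))[1], sort(c(fr, to))[2],
                                 minima = minima, ...)
      p <- paths[[key]]
      dF <- if (p$from == fr) p$dF_forward else p$dF_backward
      hl <- eyring_half_life(max(dF, 0), temperature, transmission)
      out[nrow(out) + 1L, ] <- list(fr, to, dF, hl, hl < 1)
    }
  }
  attr(out, "paths") <- paths
  attr(out, "temperature") <- temperature
  class(out) <- c("transition_table", "data.frame")
  out
}

#' @export
print.transition_table <- function(x, ...) {
  cat(sprintf("Transitions (Eyring-Polanyi at %g K; transient = t1/2 < 1 ps):\n",
              attr(x, "temperature")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Export a transition table (and its paths) as plain text
#'
#' @param table a `transition_table`.
#' @param path output CSV; each relaxed path goes to
#'   `<path>_<from><to>_path.dat`.
#' @export
write_transition_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE)
  paths <- attr(table, "paths")
  stem <- sub("\\.csv$", "", path)
  for (key in names(paths)) {
    p <- paths[[key]]
    df <- data.frame(p$images[, 1], p$images[, 2], p$profile)
    names(df) <- c("cv1", "cv2", "free_energy")
    utils::write.table(df, sprintf("%s_%s_path.dat", stem,
                                   gsub("\\|", "", key)),
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
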