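#' Hills series: the record of deposited Gaussian bias
#'
#' A `hills` object is a data.frame with one deposited Gaussian per row --
#' `time` (ps), one centre column per CV (nm), one `sigma_<cv>` width column
#' per CV (nm), `height` (kJ/mol, as deposited, i.e. after well-tempered
#' scaling) and `biasf` (the bias factor \eqn{\gamma}) -- plus a `cv_names`
#' attribute.  It is the exchange format between the sampling engine and the
#' free-energy reconstruction.
#'
#' @param time deposition times, ps.
#' @param centers matrix of hill centres (one row per hill), nm.
#' @param sigmas widths per CV (vector recycled to all hills, or matrix), nm.
#' @param heights deposited heights, kJ/mol.
#' @param biasf bias factor \eqn{\gamma} (scalar or per hill).
#' @param cv_names CV names (default `d1`, `d2`, ... up to dimension).
#' @export
hills_series <- function(time, centers, sigmas, heights, biasf,
                         cv_names = NULL) {
  if (is.null(dim(centers))) centers <- matrix(centers, ncol = 1)
  d <- ncol(centers)
  if (is.null(cv_names)) cv_names <- paste0("d", seq_len(d))
  stopifnot(length(cv_names) == d, nrow(centers) == length(time),
            length(heights) == length(time))
  if (is.null(dim(sigmas))) {
    sigmas <- if (length(time))
      matrix(rep(sigmas, length.out = d), nrow = length(time), ncol = d,
             byrow = TRUE)
    else matrix(numeric(0), ncol = d)
  }
  if (length(time)) {
    if (any(heights <= 0)) stop("hill heights must be > 0")
    if (any(sigmas <= 0)) stop("hill widths must be > 0")
  }
  df <- data.frame(time = as.numeric(time))
  for (j in seq_len(d)) df[[cv_names[j]]] <- centers[, j]
  for (j in seq_len(d)) df[[paste0("sigma_", cv_names[j])]] <- sigmas[, j]
  df$height <- as.numeric(heights)
  df$biasf <- rep_len(as.numeric(biasf), length(time))
  structure(df, cv_names = cv_names, class = c("hills", "data.frame"))
}

#' @export
print.hills <- function(x, ...) {
  cvn <- attr(x, "cv_names")
  cat(sprintf("Hills series: %d hills on (%s)", nrow(x),
              paste(cvn, collapse = ", ")))
  if (nrow(x))
    cat(sprintf(", t = %g..%g ps, heights %.3g..%.3g kJ/mol, biasf %g",
                min(x$time), max(x$time), min(x$height), max(x$height),
                x$biasf[1]))
  cat("\n")
  invisible(x)
}

#' @export
`[.hills` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "cv_names") <- attr(x, "cv_names")
    class(out) <- c("hills", "data.frame")
  }
  out
}

.hills_centers <- function(h) as.matrix(h[, attr(h, "cv_names"), drop = FALSE])
.hills_sigmas <- function(h)
  as.matrix(h[, paste0("sigma_", attr(h, "cv_names")), drop = FALSE])

#' Metadynamics bias potential from a hills series
#'
#' Evaluates \eqn{V(s) = \sum_k W_k \exp\{-\sum_i (s_i - c_{k,i})^2 /
#' (2\sigma_{k,i}^2)\}} over all deposited hills; the history-dependent
#' bias that fills free-energy wells.  Returns 0 for an empty series.
#'
#' @param s CV point (vector) or matrix of points, nm.
#' @param hills a `hills` object.
#' @return bias in kJ/mol (>= 0), one value per point.
#' @export
bias_potential <- function(s, hills) {
  cvn <- attr(hills, "cv_names")
  d <- length(cvn)
  if (is.null(dim(s))) s <- matrix(s, ncol = length(s))
  if (ncol(s) != d)
    stop(sprintf("shape error: points have %d dims but hills have %d CVs",
                 ncol(s), d))
  if (!nrow(hills)) return(rep(0, nrow(s)))
  C <- .hills_centers(hills)
  S <- .hills_sigmas(hills)
  H <- hills$height
  apply(s, 1, function(p) {
    arg <- rowSums(sweep(C, 2, p)^2 / (2 * S^2))
    sum(H * exp(-arg))
  })
}

#' Write a hills series in the standard hills-file dialect
#'
#' Header `#! FIELDS time <cvs> sigma_<cvs> height biasf` followed by
#' whitespace-separated numeric rows; values at 17 significant digits so the
#' round trip through [read_hills()] is bit-exact.
#'
#' @param hills a `hills` object.
#' @param path output file.
#' @export
write_hills <- function(hills, path) {
  cvn <- attr(hills, "cv_names")
  cols <- c("time", cvn, paste0("sigma_", cvn), "height", "biasf")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(cols, collapse = " ")), con)
  if (nrow(hills)) {
    m <- vapply(cols, function(cl) sprintf("%.17g", hills[[cl]]),
                character(nrow(hills)))
    if (nrow(hills) == 1) m <- matrix(m, nrow = 1)
    writeLines(apply(m, 1, paste, collapse = " "), con)
  }
  invisible(path)
}

#' Read a hills file
#'
#' Parses the dialect written by [write_hills()] (and the common
#' `#! FIELDS` convention of metadynamics engines): the header names the
#' columns; `#`-prefixed lines elsewhere are ignored; row order is
#' preserved.
#'
#' @param path hills file.
#' @return a `hills` object.
#' @export
read_hills <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  ln <- readLines(path)
  if (!length(ln) || !grepl("^#!\\s*FIELDS\\s+", ln[1]))
    stop("format error: missing '#! FIELDS' header line")
  fields <- strsplit(sub("^#!\\s*FIELDS\\s+", "", ln[1]), "\\s+")[[1]]
  if (!"time" %in% fields || !"height" %in% fields)
    stop("format error: FIELDS header must name 'time' and 'height' columns")
  sig <- grep("^sigma_", fields, value = TRUE)
  cvn <- setdiff(fields, c("time", "height", "biasf", sig))
  if (!length(cvn) || !setequal(paste0("sigma_", cvn), sig))
    stop("format error: FIELDS header must pair each CV with a sigma_ column")
  body_idx <- which(!grepl("^\\s*(#|$)", ln))
  body_idx <- body_idx[body_idx > 1]
  rows <- strsplit(trimws(ln[body_idx]), "\\s+")
  vals <- matrix(NA_real_, nrow = length(rows), ncol = length(fields))
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) != length(fields))
      stop(sprintf("parse error at line %d: expected %d fields, got %d",
                   body_idx[i], length(fields), length(rows[[i]])))
    v <- suppressWarnings(as.numeric(rows[[i]]))
    if (anyNA(v))
      stop(sprintf("parse error at line %d: non-numeric value", body_idx[i]))
    vals[i, ] <- v
  }
  colnames(vals) <- fields
  hills_series(time = vals[, "time"],
               centers = vals[, cvn, drop = FALSE],
               sigmas = vals[, sig, drop = FALSE],
               heights = vals[, "height"],
               biasf = if ("biasf" %in% fields) vals[, "biasf"] else NA_real_,
               cv_names = cvn)
}
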