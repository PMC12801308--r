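#' Collective variables d1 and d2 of a frame
#'
#' The two collective variables used to bias and map the landscape:
#' `d1` is the distance between the mass-weighted centres of the backbone
#' atoms (N, CA, C, O) of residues 202-204 (group 1) and of residues 282-284
#' (group 2); `d2` is the distance between the CA atoms of residues 218 and
#' 250.  Both are in nm and invariant under rigid motion of the frame.
#'
#' @param x a `trajectory` or a single `traj_frame`.
#' @return for a frame, a named vector `c(d1, d2)`; for a trajectory, a
#'   data.frame (`frame_time`, `d1`, `d2`) with one row per frame.
#' @export
compute_cvs <- function(x) {
  if (inherits(x, "trajectory")) {
    cv <- t(vapply(seq_len(n_frames(x)),
                   function(i) compute_cvs(get_frame(x, i)), numeric(2)))
    return(data.frame(frame_time = x$times, d1 = cv[, 1], d2 = cv[, 2]))
  }
  fr <- .as_frame(x)
  atoms <- fr$atoms
  g1 <- which(atoms$residue_id %in% 202:204 &
              atoms$atom_name %in% c("N", "CA", "C", "O"))
  g2 <- which(atoms$residue_id %in% 282:284 &
              atoms$atom_name %in% c("N", "CA", "C", "O"))
  for (r in 202:204) for (nm in c("N", "CA", "C", "O")) .atom_index(atoms, r, nm)
  for (r in 282:284) for (nm in c("N", "CA", "C", "O")) .atom_index(atoms, r, nm)
  com <- function(idx) {
    m <- atoms$mass[idx]
    colSums(fr$xyz[idx, , drop = FALSE] * m) / sum(m)
  }
  d1 <- sqrt(sum((com(g1) - com(g2))^2))
  ca218 <- fr$xyz[.atom_index(atoms, 218, "CA"), ]
  ca250 <- fr$xyz[.atom_index(atoms, 250, "CA"), ]
  d2 <- sqrt(sum((ca218 - ca250)^2))
  c(d1 = d1, d2 = d2)
}

#' Interhelical angle of a frame
#'
#' Angle (degrees, in \[0, 180\]) between the helix-1 direction, taken as the
#' CA(210) to CA(221) vector, and the helix-2 direction, CA(249) to CA(267).
#'
#' @param x a `trajectory` (returns one angle per frame) or a `traj_frame`.
#' @export
interhelical_angle <- function(x) {
  if (inherits(x, "trajectory"))
    return(vapply(seq_len(n_frames(x)),
                  function(i) interhelical_angle(get_frame(x, i)), 0))
  fr <- .as_frame(x)
  a <- fr$atoms
  v1 <- fr$xyz[.atom_index(a, 221, "CA"), ] - fr$xyz[.atom_index(a, 210, "CA"), ]
  v2 <- fr$xyz[.atom_index(a, 267, "CA"), ] - fr$xyz[.atom_index(a, 249, "CA"), ]
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-12 || n2 < 1e-12)
    stop("degenerate geometry: zero-length helix vector")
  acos(max(-1, min(1, sum(v1 * v2) / (n1 * n2)))) * 180 / pi
}

# optimal proper rotation (det +1) aligning X onto Y after centring (Kabsch)
.kabsch <- function(X, Y) {
  S <- svd(crossprod(X, Y))          # t(X) %*% Y
  s <- sign(det(S$u %*% t(S$v)))
  D <- diag(c(1, 1, s))
  S$u %*% D %*% t(S$v)
}

#' RMSD profile of a trajectory against a reference frame
#'
#' Per frame, the backbone atoms are optimally superposed onto the reference
#' by the Kabsch rotation (translation + proper rotation, reflection
#' forbidden, no scaling, unweighted), then the root-mean-square deviation is
#' taken over the superposed coordinates.
#'
#' @param trajectory a `trajectory`.
#' @param reference a `traj_frame`, or a frame index into `trajectory`
#'   (default: first frame).
#' @return data.frame (`frame_time`, `rmsd`) in nm.
#' @export
rmsd_profile <- function(trajectory, reference = 1L) {
  ref <- if (is.numeric(reference)) get_frame(trajectory, reference) else
    .as_frame(reference)
  if (!identical(trajectory$atoms$residue_id, ref$atoms$residue_id) ||
      !identical(trajectory$atoms$atom_name, ref$atoms$atom_name))
    stop("alignment error: atom rosters differ between trajectory and reference")
  Y <- scale(ref$xyz, scale = FALSE)
  r <- vapply(seq_len(n_frames(trajectory)), function(i) {
    X <- scale(trajectory$coords[, , i, drop = TRUE], scale = FALSE)
    R <- .kabsch(X, Y)
    sqrt(mean(rowSums((X %*% R - Y)^2)))
  }, 0)
  data.frame(frame_time = trajectory$times, rmsd = r)
}

#' Pairwise-distance descriptor matrix
#'
#' One row per frame of all pairwise distances (nm) between the selected
#' atoms; rotation/translation invariant by construction, so no alignment
#' convention is needed.  By default CA atoms are selected and, when more
#' than 50 would be selected, every other residue is kept.
#'
#' @param trajectory a `trajectory`.
#' @param atom_names atom names to select (default `"CA"`).
#' @param residues optional residue ids to restrict the selection.
#' @param thin_over if the selection exceeds this count, keep every other
#'   selected residue (set `Inf` to disable).
#' @return matrix with `choose(n, 2)` columns labelled
#'   `r<res>.<name>-r<res>.<name>`.
#' @export
build_descriptors <- function(trajectory, atom_names = "CA", residues = NULL,
                              thin_over = 50L) {
  a <- trajectory$atoms
  sel <- which(a$atom_name %in% atom_names &
               (if (is.null(residues)) TRUE else a$residue_id %in% residues))
  if (!length(sel)) stop("empty selection: no atoms match")
  if (length(sel) > thin_over) {
    keep_res <- sort(unique(a$residue_id[sel]))
    keep_res <- keep_res[seq(1, length(keep_res), by = 2)]
    sel <- sel[a$residue_id[sel] %in% keep_res]
  }
  if (length(sel) < 2) stop("need at least two selected atoms")
  lbl <- sprintf("r%d.%s", a$residue_id[sel], a$atom_name[sel])
  pairs <- combn(length(sel), 2)
  D <- t(vapply(seq_len(n_frames(trajectory)), function(f) {
    as.numeric(dist(trajectory$coords[sel, , f, drop = TRUE]))
  }, numeric(ncol(pairs))))
  colnames(D) <- paste(lbl[pairs[1, ]], lbl[pairs[2, ]], sep = "-")
  rownames(D) <- NULL
  D
}

#' Write a CV or RMSD series as headered CSV
#'
#' @param series data.frame as returned by [compute_cvs()] or
#'   [rmsd_profile()].
#' @param path output CSV.
#' @export
write_series_csv <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
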