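#' Trajectory container
#'
#' A trajectory is an ordered set of frames sharing one atom roster.  Atoms
#' carry a residue id (a contiguous subset of 202..284, the numbering of the
#' bHLHLZ construct modelled here), a backbone atom name (N, CA, C or O) and
#' a mass in amu; coordinates are stored in nm as an
#' `n_atoms x 3 x n_frames` array.
#'
#' @param atoms data.frame with columns `residue_id`, `atom_name`, `mass`.
#' @param coords numeric array `n_atoms x 3 x n_frames`, nm.
#' @param times frame times, ps.
#' @return object of class `trajectory`.
#' @export
new_trajectory <- function(atoms, coords, times) {
  stopifnot(is.data.frame(atoms),
            all(c("residue_id", "atom_name", "mass") %in% names(atoms)))
  if (length(dim(coords)) == 2) coords <- array(coords, c(dim(coords), 1))
  stopifnot(length(dim(coords)) == 3, dim(coords)[1] == nrow(atoms),
            dim(coords)[2] == 3, dim(coords)[3] == length(times))
  if (!all(atoms$atom_name %in% names(.atom_masses)))
    stop("atom names must be backbone names: N, CA, C, O")
  rid <- sort(unique(atoms$residue_id))
  if (any(rid < 202L) || any(rid > 284L) ||
      !identical(rid, seq(min(rid), max(rid))))
    stop("residue ids must be a contiguous subset of 202..284")
  structure(list(atoms = atoms, coords = coords, times = as.numeric(times)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames, %d atoms, residues %d-%d, %s-%s ps\n",
              n_frames(x), nrow(x$atoms), min(x$atoms$residue_id),
              max(x$atoms$residue_id), format(min(x$times)),
              format(max(x$times))))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory a `trajectory`.
#' @export
n_frames <- function(trajectory) dim(trajectory$coords)[3]

#' Extract one frame of a trajectory
#'
#' @param trajectory a `trajectory`.
#' @param i frame index.
#' @return object of class `traj_frame`: list with `atoms` (roster
#'   data.frame), `xyz` (n_atoms x 3 matrix, nm) and `time` (ps).
#' @export
get_frame <- function(trajectory, i) {
  stopifnot(i >= 1, i <= n_frames(trajectory))
  structure(list(atoms = trajectory$atoms,
                 xyz = trajectory$coords[, , i, drop = TRUE],
                 time = trajectory$times[i]),
            class = "traj_frame")
}

.as_frame <- function(x, i = 1L) {
  if (inherits(x, "traj_frame")) return(x)
  if (inherits(x, "trajectory")) return(get_frame(x, i))
  stop("expected a trajectory or a traj_frame")
}

# index of one atom in a roster; descriptive error when absent
.atom_index <- function(atoms, residue, name) {
  i <- which(atoms$residue_id == residue & atoms$atom_name == name)
  if (length(i) != 1)
    stop(sprintf("missing atom: %s of residue %d", name, residue))
  i
}

# ---- ideal two-helix geometry -----------------------------------------------

# canonical alpha-helix parameters (nm): rise/residue, residues/turn, CA radius
.HELIX_RISE <- 0.15
.HELIX_RPT <- 3.6
.HELIX_RADIUS <- 0.23

# backbone atom placement in the local helix frame: radius, phase offset (rad),
# axial offset (nm) relative to the CA helix
.BB_GEOM <- list(N  = c(r = 0.157, dphi = -0.52, dz = -0.120),
                 CA = c(r = 0.230, dphi =  0.00, dz =  0.000),
                 C  = c(r = 0.168, dphi =  0.46, dz =  0.100),
                 O  = c(r = 0.190, dphi =  0.38, dz =  0.230))

.HELIX1_RES <- 202:228
.LOOP_RES <- 229:238
.HELIX2_RES <- 239:281
.TAIL_RES <- 282:284   # C-terminal extension continuing helix 2

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("degenerate geometry: zero-length vector")
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# backbone atoms of an ideal helix segment along axis u from `origin`;
# e1, e2 span the perpendicular plane
.helix_atoms <- function(res_ids, origin, u, e1, e2, phase0 = 0) {
  omega <- 2 * pi / .HELIX_RPT
  out <- matrix(0, nrow = 4 * length(res_ids), ncol = 3)
  k <- 1L
  for (j in seq_along(res_ids)) {
    for (nm in c("N", "CA", "C", "O")) {
      g <- .BB_GEOM[[nm]]
      z <- (j - 1) * .HELIX_RISE + g["dz"]
      phi <- phase0 + (j - 1) * omega + g["dphi"]
      out[k, ] <- origin + u * z +
        g["r"] * (cos(phi) * e1 + sin(phi) * e2)
      k <- k + 1L
    }
  }
  out
}

# one noiseless two-helix conformation at interhelical angle theta (degrees):
# helix 1 (202-228) along +z, helix 2 (239-284) along an axis chosen so that
# the CA(249)->CA(267) chord makes exactly theta with the CA(210)->CA(221)
# chord; the 229-238 loop interpolates between the helix ends.
.two_helix_frame <- function(theta_deg) {
  theta <- theta_deg * pi / 180
  u <- c(0, 0, 1); e1 <- c(1, 0, 0); e2 <- c(0, 1, 0)
  h1 <- .helix_atoms(.HELIX1_RES, c(0, 0, 0), u, e1, e2)

  roster1 <- expand.grid(atom_name = c("N", "CA", "C", "O"),
                         residue_id = .HELIX1_RES,
                         stringsAsFactors = FALSE)[, 2:1]
  ca210 <- h1[which(roster1$residue_id == 210 & roster1$atom_name == "CA"), ]
  ca221 <- h1[which(roster1$residue_id == 221 & roster1$atom_name == "CA"), ]
  u1 <- .unit(ca221 - ca210)                    # measured helix-1 direction
  ex <- c(1, 0, 0)
  e <- .unit(ex - sum(ex * u1) * u1)            # in-plane perpendicular
  w <- .unit(.cross3(u1, e))                    # lateral offset direction

  axis2 <- cos(theta) * u1 + sin(theta) * e
  # 249->267 spans 18 residues = 5 full turns, so its chord is exactly axis2
  e21 <- w
  e22 <- .unit(.cross3(axis2, e21))

  hinge <- h1[nrow(h1) - 2, ]                   # CA of residue 228
  origin2 <- hinge + 0.35 * axis2 + 0.55 * w
  res2 <- c(.HELIX2_RES, .TAIL_RES)
  h2 <- .helix_atoms(res2, origin2, axis2, e21, e22)
  roster2 <- expand.grid(atom_name = c("N", "CA", "C", "O"),
                         residue_id = res2,
                         stringsAsFactors = FALSE)[, 2:1]

  # loop CA positions interpolate hinge -> helix-2 start; N/C/O hang off CA
  ca239 <- h2[which(roster2$residue_id == 239 & roster2$atom_name == "CA"), ]
  nl <- length(.LOOP_RES)
  loop <- matrix(0, nrow = 4 * nl, ncol = 3)
  offs <- list(N = c(-0.06, 0.03, 0), CA = c(0, 0, 0),
               C = c(0.06, 0.03, 0), O = c(0.08, 0.10, 0))
  k <- 1L
  for (j in seq_len(nl)) {
    ca <- hinge + (j / (nl + 1)) * (ca239 - hinge)
    for (nm in c("N", "CA", "C", "O")) {
      loop[k, ] <- ca + offs[[nm]]
      k <- k + 1L
    }
  }
  rosterL <- expand.grid(atom_name = c("N", "CA", "C", "O"),
                         residue_id = .LOOP_RES,
                         stringsAsFactors = FALSE)[, 2:1]

  roster <- rbind(roster1, rosterL, roster2)
  xyz <- rbind(h1, loop, h2)
  ord <- order(roster$residue_id, match(roster$atom_name, c("N", "CA", "C", "O")))
  roster <- roster[ord, ]
  xyz <- xyz[ord, , drop = FALSE]
  roster$mass <- unname(.atom_masses[roster$atom_name])
  rownames(roster) <- NULL
  list(atoms = roster, xyz = xyz)
}

#' Synthetic two-helix trajectory
#'
#' Generates backbone (N, CA, C, O) trajectories of an ideal two-helix
#' protein model with residues 202-284: helix 1 spans residues 202-228,
#' helix 2 residues 239-281 (continued to 284), joined by a flexible loop
#' (229-238) hinged so that the interhelical angle -- measured between the
#' CA(210)->CA(221) and CA(249)->CA(267) chords, as in
#' [interhelical_angle()] -- equals the requested schedule value exactly
#' before noise.  Isotropic Gaussian coordinate noise emulates thermal
#' fluctuation of the backbone.
#'
#' @param angle_schedule interhelical angle per frame, degrees in \[0, 180\].
#' @param noise_sd standard deviation of the additive coordinate noise, nm.
#' @param seed RNG seed; the same seed reproduces the trajectory exactly.
#' @param frame_dt time between frames, ps.
#' @return a [new_trajectory()] object with one frame per schedule entry.
#' @examples
#' traj <- generate_helix_pair_trajectory(c(90, 60, 30), noise_sd = 0)
#' interhelical_angle(traj)
#' @export
generate_helix_pair_trajectory <- function(angle_schedule, noise_sd = 0.03,
                                           seed = 1L, frame_dt = 1) {
  if (length(angle_schedule) == 0) stop("empty input: angle schedule has no frames")
  if (any(angle_schedule < 0 | angle_schedule > 180))
    stop("angles must lie in [0, 180] degrees")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  f1 <- .two_helix_frame(angle_schedule[1])
  na <- nrow(f1$atoms)
  coords <- array(0, c(na, 3, length(angle_schedule)))
  for (i in seq_along(angle_schedule)) {
    fr <- if (i == 1) f1 else .two_helix_frame(angle_schedule[i])
    xyz <- fr$xyz
    if (noise_sd > 0) xyz <- xyz + rnorm(length(xyz), sd = noise_sd)
    coords[, , i] <- xyz
  }
  new_trajectory(f1$atoms, coords,
                 times = (seq_along(angle_schedule) - 1) * frame_dt)
}

# ---- PDB / XYZ I/O ----------------------------------------------------------

#' Write a trajectory as a minimal multi-model PDB file
#'
#' One `MODEL`/`ENDMDL` block per frame; fixed-width `ATOM` records
#' (columns: record 1-6, serial 7-11, name 13-16, resName 18-20, chain 22,
#' resSeq 23-26, x/y/z 31-54 in Angstrom at 0.001 precision, occupancy
#' 55-60, B 61-66, element 77-78).  Coordinates are converted from nm.
#'
#' @param trajectory a `trajectory`.
#' @param path output file.
#' @export
write_pdb <- function(trajectory, path) {
  atoms <- trajectory$atoms
  elem <- substr(atoms$atom_name, 1, 1)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(trajectory))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- trajectory$coords[, , f, drop = TRUE] * 10  # nm -> Angstrom
    lines <- sprintf(
      "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(atoms)), sprintf(" %-3s", atoms$atom_name), "", "ALA", "A",
      atoms$residue_id, "", xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, elem)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a minimal multi-model PDB file written by [write_pdb()]
#'
#' @param path PDB file.
#' @param frame_dt time between models, ps.
#' @return a `trajectory` (coordinates in nm).
#' @export
read_pdb <- function(path, frame_dt = 1) {
  ln <- readLines(path)
  model_starts <- grep("^MODEL", ln)
  if (!length(model_starts)) model_starts <- 0L
  atom_ln <- ln[startsWith(ln, "ATOM")]
  if (!length(atom_ln)) stop("no ATOM records found")
  n_models <- max(length(model_starts), 1L)
  per <- length(atom_ln) / n_models
  if (per != round(per)) stop("models have differing atom counts")
  first <- atom_ln[seq_len(per)]
  atoms <- data.frame(
    residue_id = as.integer(substr(first, 23, 26)),
    atom_name = trimws(substr(first, 13, 16)),
    stringsAsFactors = FALSE)
  atoms$mass <- unname(.atom_masses[atoms$atom_name])
  xyz <- cbind(as.numeric(substr(atom_ln, 31, 38)),
               as.numeric(substr(atom_ln, 39, 46)),
               as.numeric(substr(atom_ln, 47, 54))) / 10
  coords <- array(0, c(per, 3, n_models))
  for (f in seq_len(n_models))
    coords[, , f] <- xyz[((f - 1) * per + 1):(f * per), ]
  new_trajectory(atoms, coords, times = (seq_len(n_models) - 1) * frame_dt)
}

#' Write a trajectory in XYZ format (coordinates in nm)
#'
#' Plain XYZ with the atom count line, a comment line per frame
#' (`frame <i> time <t> ps`), and `name x y z` rows.  Residue identities are
#' not representable in XYZ; use [write_pdb()] for a lossless roster.
#'
#' @inheritParams write_pdb
#' @export
write_xyz <- function(trajectory, path) {
  con <- file(path, "w")
  on.exit(close(con))
  na <- nrow(trajectory$atoms)
  for (f in seq_len(n_frames(trajectory))) {
    writeLines(as.character(na), con)
    writeLines(sprintf("frame %d time %.6f ps", f, trajectory$times[f]), con)
    xyz <- trajectory$coords[, , f, drop = TRUE]
    writeLines(sprintf("%-3s %17.9f %17.9f %17.9f",
                       trajectory$atoms$atom_name,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}

#' Read an XYZ file written by [write_xyz()]
#'
#' @param path XYZ file.
#' @param atoms optional roster data.frame restoring residue ids; by default
#'   atom names are kept and residue ids are filled sequentially from 202.
#' @export
read_xyz <- function(path, atoms = NULL) {
  ln <- readLines(path)
  na <- as.integer(ln[1])
  block <- na + 2L
  n_fr <- length(ln) %/% block
  times <- numeric(n_fr)
  coords <- array(0, c(na, 3, n_fr))
  names1 <- character(na)
  for (f in seq_len(n_fr)) {
    off <- (f - 1L) * block
    times[f] <- as.numeric(sub(".*time ([0-9.eE+-]+) ps.*", "\\1",
                               ln[off + 2L]))
    rows <- strsplit(trimws(ln[(off + 3L):(off + block)]), "[[:space:]]+")
    m <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    coords[, , f] <- m
    if (f == 1L) names1 <- vapply(rows, `[`, "", 1L)
  }
  if (is.null(atoms)) {
    n_res <- na %/% 4L
    atoms <- data.frame(residue_id = rep(202:(201 + n_res), each = 4L),
                        atom_name = names1,
                        mass = unname(.atom_masses[names1]),
                        stringsAsFactors = FALSE)
  }
  new_trajectory(atoms, coords, times)
}
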