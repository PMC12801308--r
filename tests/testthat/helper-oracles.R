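# Independent brute-force oracles and small fixtures shared by the tests.
# These deliberately avoid the package's own code paths.

# canonical two-well fixture: analytic barrier ~15 kJ/mol, wells on realistic
# CV coordinates (nm scale)
two_well_fixture <- function() {
  make_double_well(rbind(c(0.6, 1.0), c(2.0, 1.0)), depths = c(18.7, 18.7),
                   widths = 0.3, conf_k = 5)
}

# explicit mass-weighted CV computation (nested sums, no matrix shortcuts)
brute_cvs <- function(frame) {
  a <- frame$atoms
  com <- function(res_range) {
    sx <- sy <- sz <- sm <- 0
    for (i in seq_len(nrow(a))) {
      if (a$residue_id[i] %in% res_range &&
          a$atom_name[i] %in% c("N", "CA", "C", "O")) {
        m <- a$mass[i]
        sx <- sx + m * frame$xyz[i, 1]
        sy <- sy + m * frame$xyz[i, 2]
        sz <- sz + m * frame$xyz[i, 3]
        sm <- sm + m
      }
    }
    c(sx, sy, sz) / sm
  }
  c1 <- com(202:204); c2 <- com(282:284)
  d1 <- sqrt(sum((c1 - c2)^2))
  i218 <- which(a$residue_id == 218 & a$atom_name == "CA")
  i250 <- which(a$residue_id == 250 & a$atom_name == "CA")
  d2 <- sqrt(sum((frame$xyz[i218, ] - frame$xyz[i250, ])^2))
  c(d1, d2)
}

# nested-loop pairwise distances for one frame and a selection index vector
brute_pairdists <- function(xyz, sel) {
  out <- numeric(0)
  for (i in seq_along(sel)) {
    for (j in seq_along(sel)) {
      if (j > i)
        out <- c(out, sqrt(sum((xyz[sel[i], ] - xyz[sel[j], ])^2)))
    }
  }
  out
}

# naive double-loop bias summation over hills at arbitrary points
brute_bias <- function(pts, hills_df, cv_names) {
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1)
  out <- numeric(nrow(pts))
  for (p in seq_len(nrow(pts))) {
    v <- 0
    for (h in seq_len(nrow(hills_df))) {
      arg <- 0
      for (j in seq_along(cv_names)) {
        dx <- pts[p, j] - hills_df[[cv_names[j]]][h]
        s <- hills_df[[paste0("sigma_", cv_names[j])]][h]
        arg <- arg + dx^2 / (2 * s^2)
      }
      v <- v + hills_df$height[h] * exp(-arg)
    }
    out[p] <- v
  }
  out
}

# orthogonal-Procrustes RMSD oracle: centred SVD superposition (det +1)
brute_rmsd <- function(X, Y) {
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  S <- svd(t(Xc) %*% Yc)
  R <- S$u %*% diag(c(1, 1, sign(det(S$u %*% t(S$v))))) %*% t(S$v)
  sqrt(mean(rowSums((Xc %*% R - Yc)^2)))
}

# adjusted Rand index between two labelings
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sij <- sum(choose2(tab))
  si <- sum(choose2(rowSums(tab)))
  sj <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  exp_idx <- si * sj / n2
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

# random rigid transform (proper rotation + translation) applied to a frame
apply_random_rigid <- function(frame, seed) {
  set.seed(seed)
  A <- matrix(rnorm(9), 3)
  qr_d <- qr(A)
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  tr <- rnorm(3, sd = 2)
  frame$xyz <- frame$xyz %*% R + matrix(tr, nrow(frame$xyz), 3, byrow = TRUE)
  frame
}

# direct (non-logsumexp) trapezoidal marginalization oracle
brute_marginal <- function(values, ax1, ax2, temperature, keep = 1) {
  kB <- 0.0083144626
  beta <- 1 / (kB * temperature)
  tw <- function(ax) {
    n <- length(ax); h <- diff(ax); w <- numeric(n)
    w[1] <- h[1] / 2; w[n] <- h[n - 1] / 2
    if (n > 2) w[2:(n - 1)] <- (h[-1] + h[-(n - 1)]) / 2
    w
  }
  Fm <- if (keep == 1) values else t(values)
  kept <- if (keep == 1) ax1 else ax2
  other <- if (keep == 1) ax2 else ax1
  wo <- tw(other); wk <- tw(kept)
  num <- vapply(seq_along(kept),
                function(i) sum(exp(-beta * Fm[i, ]) * wo), 0)
  den <- sum(num * wk)
  prof <- -log(num / den) / beta
  prof - min(prof)
}
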