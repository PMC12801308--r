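#' Langevin dynamics parameters
#'
#' Parameters of the overdamped (position-space) Langevin integrator used to
#' sample model potentials.  One-step Euler-Maruyama:
#' \deqn{x \leftarrow x - \frac{\Delta t}{\zeta}\nabla(F + V_{bias})
#'   + \sqrt{2 k_B T \Delta t/\zeta}\,\xi}
#' which preserves the Boltzmann distribution of the potential for small
#' \eqn{\Delta t}; the friction \eqn{\zeta} only sets the diffusive time
#' scale.
#'
#' @param friction friction coefficient, 1/ps (default 1.0).
#' @param temperature K (default 310.15).
#' @param timestep ps.
#' @param n_steps number of integration steps.
#' @param seed RNG seed.
#' @export
langevin_params <- function(friction = 1.0, temperature = 310.15,
                            timestep = 5e-4, n_steps = 1e5L, seed = 1L) {
  if (friction <= 0) stop("friction must be > 0")
  if (temperature <= 0) stop("temperature must be > 0")
  if (timestep <= 0) stop("timestep must be > 0")
  if (n_steps < 0) stop("n_steps must be >= 0")
  structure(list(friction = friction, temperature = temperature,
                 timestep = timestep, n_steps = as.integer(n_steps),
                 seed = as.integer(seed)),
            class = "langevin_params")
}

#' Sample a model potential with overdamped Langevin dynamics
#'
#' @param potential a `model_potential`.
#' @param params a [langevin_params()] object.
#' @param bias optional external bias: a `hills` object (static Gaussian
#'   bias, fast path) or an R function `f(x)` returning
#'   `list(energy, gradient)` (slow path, intended for small tests).  The
#'   total force is \eqn{-\nabla(F + V_{bias})}.
#' @param x0 start position (default: first known minimum, or the
#'   confinement centre).
#' @param save_stride store every `save_stride`-th step.
#' @param reflect reflect at `wall_lo` (for distance-like CVs that cannot go
#'   negative).
#' @param wall_lo location of the reflecting lower wall, nm.
#' @return data.frame with `time` (ps) and one column per CV dimension
#'   (`x1`, `x2`, ...).  Identical seeds give identical series.
#' @export
langevin_sample <- function(potential, params, bias = NULL, x0 = NULL,
                            save_stride = 1L, reflect = FALSE, wall_lo = 0) {
  stopifnot(inherits(potential, "model_potential"),
            inherits(params, "langevin_params"))
  d <- potential$dimensionality
  if (is.null(x0))
    x0 <- if (nrow(potential$known_minima)) potential$known_minima[1, ]
          else potential$conf_center
  stopifnot(length(x0) == d)
  set.seed(params$seed)

  if (is.function(bias)) {
    return(.langevin_r(potential, params, bias, x0, save_stride, reflect,
                       wall_lo))
  }
  hc <- matrix(numeric(0), ncol = d)
  hh <- numeric(0)
  hsig <- rep(1, d)
  if (inherits(bias, "hills") && nrow(bias)) {
    cvn <- attr(bias, "cv_names")
    hc <- as.matrix(bias[, cvn, drop = FALSE])
    hh <- bias$height
    hsig <- as.numeric(bias[1, paste0("sigma_", cvn)])
  }
  res <- .run_engine(potential, x0, params, W0 = 0, sigma = rep(0.1, d),
                     stride_steps = 0L, biasfactor = 0,
                     save_stride = save_stride, reflect = reflect,
                     wall_lo = wall_lo, static_hills = list(centers = hc,
                                                            heights = hh,
                                                            sigma = hsig))
  out <- data.frame(time = res$times)
  for (j in seq_len(d)) out[[paste0("x", j)]] <- res$positions[, j]
  out
}

# R-loop integrator used only when the bias is an arbitrary R callable
.langevin_r <- function(pot, params, bias, x0, save_stride, reflect, wall_lo) {
  d <- length(x0)
  dt <- params$timestep
  mob <- dt / params$friction
  noise <- sqrt(2 * .kB * params$temperature * dt / params$friction)
  x <- as.numeric(x0)
  n_save <- params$n_steps %/% save_stride
  pos <- matrix(0, n_save, d)
  tm <- numeric(n_save)
  isave <- 0L
  for (step in seq_len(params$n_steps)) {
    g <- .pot_eg(pot, x)$gradient + bias(x)$gradient
    if (!all(is.finite(g)))
      stop(sprintf("non-finite force at step %d", step))
    x <- x - mob * g + noise * rnorm(d)
    if (reflect) x <- ifelse(x < wall_lo, 2 * wall_lo - x, x)
    if (step %% save_stride == 0) {
      isave <- isave + 1L
      pos[isave, ] <- x
      tm[isave] <- step * dt
    }
  }
  out <- data.frame(time = tm)
  for (j in seq_len(d)) out[[paste0("x", j)]] <- pos[, j]
  out
}

# shared call into the compiled engine; static hills are passed by running
# the metadynamics path with deposition disabled and pre-loaded hills
.run_engine <- function(pot, x0, lp, W0, sigma, stride_steps, biasfactor,
                        save_stride, reflect, wall_lo,
                        static_hills = NULL) {
  d <- pot$dimensionality
  if (!is.null(static_hills) && length(static_hills$heights)) {
    # fold a static Gaussian bias into the potential as negative-depth wells
    pot <- within_static_bias(pot, static_hills)
  }
  cpp_langevin_metad(pot$centers, pot$depths, pot$widths,
                     pot$conf_center, pot$conf_k, as.numeric(x0),
                     lp$friction, lp$temperature, lp$timestep, lp$n_steps,
                     as.integer(save_stride), W0, sigma,
                     as.integer(stride_steps), biasfactor, reflect, wall_lo)
}

# a static hills bias is itself a sum of Gaussians: represent V_bias as
# negative-depth isotropic wells appended to the model potential (requires
# isotropic hill widths, which is how hills are deposited here)
within_static_bias <- function(pot, sh) {
  if (length(unique(round(sh$sigma, 12))) != 1)
    stop("static hills bias requires isotropic widths")
  pot$centers <- rbind(pot$centers, sh$centers)
  pot$depths <- c(pot$depths, -sh$heights)
  pot$widths <- c(pot$widths, rep(sh$sigma[1], length(sh$heights)))
  pot
}
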