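#' Well-tempered metadynamics parameters
#'
#' Defaults follow the production setup used for the two-CV landscape:
#' Gaussian width 0.2 nm per CV, initial hill height 1.2 kJ/mol, deposition
#' stride 1 ps, bias factor 8, temperature 310.15 K.
#'
#' @param height initial Gaussian height \eqn{W_0}, kJ/mol.
#' @param sigma Gaussian width per CV, nm (recycled to the dimensionality).
#' @param stride deposition stride \eqn{\tau}, ps.
#' @param biasfactor \eqn{\gamma > 1}; heights are attenuated by
#'   \eqn{\exp(-V/(k_B \Delta T))} with \eqn{\Delta T = (\gamma - 1) T}.
#' @param temperature K.
#' @param seed RNG seed for the coupled sampler.
#' @export
wtmetad_params <- function(height = 1.2, sigma = 0.2, stride = 1,
                           biasfactor = 8, temperature = 310.15, seed = 1L) {
  if (height <= 0) stop("initial hill height must be > 0")
  if (any(sigma <= 0)) stop("Gaussian widths must be > 0")
  if (stride <= 0) stop("deposition stride must be > 0")
  if (biasfactor <= 1)
    stop("invalid parameter: biasfactor must exceed 1 (well-tempered regime)")
  if (temperature <= 0) stop("temperature must be > 0")
  structure(list(height = height, sigma = sigma, stride = stride,
                 biasfactor = biasfactor, temperature = temperature,
                 seed = as.integer(seed)),
            class = "wtmetad_params")
}

#' Well-tempered height of the next hill
#'
#' \eqn{W = W_0 \exp\{-V(s, t)/(k_B \Delta T)\}} with
#' \eqn{\Delta T = (\gamma - 1) T}: the deposited height decays
#' exponentially with the bias already accumulated at the current CV
#' position, which is what makes the bias converge.  Always in
#' \eqn{(0, W_0]}.
#'
#' @param params a [wtmetad_params()] object.
#' @param current_bias_at_s accumulated bias \eqn{V(s, t)} at the deposition
#'   point, kJ/mol (>= 0).
#' @export
next_hill_height <- function(params, current_bias_at_s) {
  stopifnot(inherits(params, "wtmetad_params"))
  if (any(current_bias_at_s < 0)) stop("accumulated bias must be >= 0")
  dT <- (params$biasfactor - 1) * params$temperature
  params$height * exp(-current_bias_at_s / (.kB * dT))
}

#' Run well-tempered metadynamics on a model potential
#'
#' Couples the overdamped Langevin sampler to history-dependent Gaussian
#' deposition: every stride \eqn{\tau} a hill of well-tempered height is
#' added at the current CV position and immediately contributes to the bias
#' force \eqn{-\nabla(F + V)}.  Hills are recorded as deposited
#' (post-scaling heights), matching the convention of standard hills files;
#' the reconstruction in [bias_sum_fes()] therefore applies the
#' \eqn{\gamma/(\gamma-1)} correction.  CVs are treated as non-periodic
#' distances with a reflecting wall at 0 nm.
#'
#' @param potential a `model_potential` standing in for the molecular free
#'   energy along the CVs.
#' @param params a [wtmetad_params()] object.
#' @param langevin a [langevin_params()] object (its temperature is taken
#'   from `params` to keep sampling and tempering consistent).
#' @param x0 start position (default: first known minimum).
#' @param save_stride store the CV series every this many steps (default:
#'   one record per deposition stride).
#' @param reflect reflecting lower wall at 0 nm (default TRUE).
#' @return list of class `wtmetad_run` with `hills` (a `hills` object) and
#'   `cv` (data.frame: `time` plus one column per CV).  Identical seeds and
#'   parameters give identical output.
#' @export
run_wtmetad <- function(potential, params = wtmetad_params(),
                        langevin = langevin_params(), x0 = NULL,
                        save_stride = NULL, reflect = TRUE) {
  stopifnot(inherits(potential, "model_potential"),
            inherits(params, "wtmetad_params"),
            inherits(langevin, "langevin_params"))
  d <- potential$dimensionality
  sigma <- rep(params$sigma, length.out = d)
  stride_steps <- round(params$stride / langevin$timestep)
  if (stride_steps < 1)
    stop("deposition stride is shorter than the integration timestep")
  if (is.null(x0))
    x0 <- if (nrow(potential$known_minima)) potential$known_minima[1, ]
          else potential$conf_center
  if (is.null(save_stride)) save_stride <- stride_steps
  lp <- langevin
  lp$temperature <- params$temperature
  set.seed(params$seed)
  res <- .run_engine(potential, x0, lp, W0 = params$height, sigma = sigma,
                     stride_steps = stride_steps,
                     biasfactor = params$biasfactor,
                     save_stride = save_stride, reflect = reflect,
                     wall_lo = 0)
  cvn <- paste0("d", seq_len(d))
  h <- hills_series(time = res$hill_times, centers = res$hill_centers,
                    sigmas = sigma, heights = res$hill_heights,
                    biasf = params$biasfactor, cv_names = cvn)
  cv <- data.frame(time = res$times)
  for (j in seq_len(d)) cv[[cvn[j]]] <- res$positions[, j]
  structure(list(hills = h, cv = cv, params = params, langevin = lp),
            class = "wtmetad_run")
}

#' @export
print.wtmetad_run <- function(x, ...) {
  cat(sprintf(
    "WT-MetaD run: %d hills (W0 = %g kJ/mol, sigma = %s nm, gamma = %g), %d CV records\n",
    nrow(x$hills), x$params$height,
    paste(x$params$sigma, collapse = "/"), x$params$biasfactor, nrow(x$cv)))
  invisible(x)
}
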