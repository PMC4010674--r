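# Run expr with a private RNG stream, restoring the caller's state.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Cholesky factor (lower) of a Hermitian positive semidefinite matrix.
.chol_herm <- function(G, jitter = 0) {
  s <- nrow(G)
  L <- matrix(0 + 0i, s, s)
  for (j in seq_len(s)) {
    d <- Re(G[j, j]) + jitter - sum(Mod(L[j, seq_len(j - 1L)])^2)
    if (d < 0) {
      if (d > -1e-10 * max(Re(diag(G)), 1e-300)) d <- 0
      else stop("matrix is not positive semidefinite")
    }
    L[j, j] <- sqrt(d)
    if (j < s) {
      for (i in (j + 1L):s) {
        acc <- G[i, j]
        if (j > 1L) acc <- acc -
            sum(L[i, seq_len(j - 1L)] * Conj(L[j, seq_len(j - 1L)]))
        L[i, j] <- if (Re(L[j, j]) > 0) acc / L[j, j] else 0
      }
    }
  }
  L
}

#' Finite-epoch sampling noise for cross-spectral estimates
#'
#' Draws a sampled cross-spectral dataset from the complex-Wishart
#' distribution implied by averaging `n_epochs` independent periodograms of
#' a Gaussian process with the given true spectra: per condition and
#' frequency, \eqn{S = \tfrac{1}{n}\sum_{i=1}^{n} z_i z_i^H} with
#' \eqn{z_i \sim CN(0, G)}.  The draw is Hermitian positive semidefinite by
#' construction and converges to the analytic spectra as
#' \eqn{O(1/\sqrt{n})}.
#'
#' @param x A [csd()] of analytic (true) spectra.
#' @param n_epochs Degrees of freedom (epochs averaged), at least 2.
#' @param seed Integer seed; draws are reproducible bit-for-bit.
#' @return A [csd()] of sampled spectra with `n_epochs` recorded.
#' @export
sample_wishart_csd <- function(x, n_epochs, seed = 1L) {
  validate_csd(x)
  n_epochs <- as.integer(n_epochs)
  if (n_epochs < 2L) stop("'n_epochs' must be at least 2")
  d <- dim(x$values)
  s <- d[3L]
  out <- x$values
  .with_seed(seed, {
    for (cd in seq_len(d[1L])) for (fi in seq_len(d[2L])) {
      G <- matrix(x$values[cd, fi, , ], s, s)
      L <- .chol_herm(G)
      W <- matrix(complex(real = rnorm(s * n_epochs),
                          imaginary = rnorm(s * n_epochs)) / sqrt(2),
                  s, n_epochs)
      Z <- L %*% W
      S <- Z %*% Conj(t(Z)) / n_epochs
      S <- (S + Conj(t(S))) / 2
      diag(S) <- Re(diag(S))
      out[cd, fi, , ] <- S
    }
  })
  csd(out, x$freqs, x$conditions, x$sites, n_epochs = n_epochs)
}

#' Default generating parameters for synthetic contrast experiments
#'
#' The ground truth used by [simulate_csd_dataset()]: a full
#' condition-effect model (gain, coupling and extent factors all active)
#' whose deviations and sensitivities were chosen to reproduce the
#' phenomenology of contrast experiments in visual cortex — gamma-band
#' spectral peaks at every contrast whose frequency increases monotonically
#' (by roughly 10 Hz) from the lowest to the highest contrast.  The gain of
#' the superficial pyramidal population is disinhibited with contrast
#' (negative sensitivity on its self-inhibition `alpha_a44`), the couplings
#' to and from the superficial pyramidal cells strengthen, excitatory
#' horizontal extents shrink (decay rates increase) and inhibitory extents
#' grow.
#'
#' @return A list with named numeric `dev` (log-scale deviations from the
#'   prior means) and `beta` (condition sensitivities, named by the
#'   parameters they modulate).
#' @export
cmc_truth <- function() {
  dev <- c(alpha_a14 = -0.4, alpha_a41 = -0.4, alpha_a44 = -0.3,
           kappa1 = -0.2, kappa4 = -0.2)
  beta <- c(alpha_a44 = -0.5, alpha_a33 = -0.2,
            alpha_a14 = 0.7, alpha_a41 = 0.7,
            alpha_a12 = 0.2, alpha_a21 = 0.2, alpha_a23 = 0.2,
            alpha_a32 = 0.2,
            c_a11 = 0.2, c_a33 = 0.2, c_a44 = 0.2,
            c_a14 = 0.3, c_a21 = 0.3, c_a23 = 0.3, c_a41 = 0.3,
            c_a12 = -0.3, c_a22 = -0.3, c_a32 = -0.3)
  list(dev = dev, beta = beta)
}

#' Generate a synthetic multi-condition cross-spectral dataset
#'
#' Computes the analytic cross-spectra of the generating model for every
#' condition of the design (applying the condition-specific effects of the
#' generating truth) and then draws finite-epoch estimation noise from the
#' complex-Wishart distribution via [sample_wishart_csd()].
#'
#' @param truth List with `dev` and `beta` as from [cmc_truth()]; `beta`
#'   must only name parameters modulated by `model`.
#' @param model The generating [cmc_model()].
#' @param design A [condition_design()].
#' @param freqs Frequency grid (Hz).
#' @param priors A [default_priors()] object supplying prior means and
#'   structure.
#' @param n_epochs Epochs per condition (`Inf` for noiseless analytic
#'   spectra).
#' @param n_k Spatial truncation order.
#' @param seed Integer seed.
#' @return An object of class `"cmc_dataset"`: list with the sampled `csd`,
#'   the noiseless `analytic` spectra, the packed generating vector
#'   `truth_packed`, and the generating context.
#' @export
simulate_csd_dataset <- function(truth = cmc_truth(),
                                 model = model_space()[[7L]],
                                 design = condition_design(),
                                 freqs = seq(4, 90, length.out = 24L),
                                 priors = default_priors(variant = model$variant),
                                 n_epochs = 256L, n_k = 32L, seed = 1L) {
  grid <- spectral_grid(freqs, n_k = n_k,
                        patch_length = attr(priors, "conn")$patch_length)
  dv <- truth$dev
  if (length(truth$beta))
    dv <- c(dv, setNames(truth$beta, paste0("beta_", names(truth$beta))))
  packed <- pack_params(dv, priors, model)
  n_cond <- length(design$covariate)
  ns <- attr(priors, "n_sites")
  vals <- array(0 + 0i, c(n_cond, length(freqs), ns, ns))
  for (cd in seq_len(n_cond)) {
    p <- apply_condition_effects(packed, model, design, cd, priors)
    g <- .predict_csd_core(grid, p$sensors, p$noise, p$syn, p$conn,
                           model$variant)
    if (!all(is.finite(g)))
      stop("unstable generating parameters: non-finite spectra in condition ",
           cd)
    vals[cd, , , ] <- g
  }
  analytic <- csd(vals, freqs, conditions = design$labels)
  sampled <- if (is.finite(n_epochs))
    sample_wishart_csd(analytic, n_epochs = n_epochs, seed = seed)
  else analytic
  structure(list(csd = sampled, analytic = analytic, truth = truth,
                 truth_packed = packed, model = model, design = design,
                 n_epochs = n_epochs, seed = seed),
            class = "cmc_dataset")
}

#' @export
print.cmc_dataset <- function(x, ...) {
  cat(sprintf("Synthetic dataset: model '%s', %d conditions, seed %d, %s epochs\n",
              x$model$name, length(x$design$covariate), x$seed,
              format(x$n_epochs)))
  print(x$csd)
  invisible(x)
}

#' Simulate the stochastic delayed neural field on a ring
#'
#' Direct time-domain integration of the four-population field equations on
#' a periodic lattice: second-order synaptic dynamics per population
#' (integrated exactly between steps by an exponential scheme), horizontal
#' coupling through the exponentially decaying kernels with axonal
#' conduction delays (rounded to integration steps), and spatially and
#' temporally white noise driving the spiny stellate population.  In
#' linearised mode the firing-rate nonlinearity is replaced by its slope at
#' the zero expansion point, making the simulation an independent
#' Monte-Carlo check of the analytic transfer functions; in nonlinear mode
#' the full sigmoid (centred at its fixed-point value) is used.
#'
#' Electrode signals are obtained by integrating the population mixture
#' against each electrode's periodic Gaussian lead field; sites are bipolar
#' differences per the montage.
#'
#' @param n_epochs Number of contiguous epochs to record (after burn-in).
#' @param epoch_length Epoch duration (s).
#' @param fs Output sampling rate (Hz); must divide `1/dt`.
#' @param dt Integration step (s).
#' @param n_x Number of lattice points on the ring.
#' @param burn_in Initial duration discarded (s).
#' @param input_amp Spectral density \eqn{g_u} of the white input.
#' @param linearised Use the linearised transmission nonlinearity.
#' @param init_sd Standard deviation of random initial depolarisations
#'   (zero starts from rest).
#' @param seed Integer seed.
#' @inheritParams predict_csd
#' @return An object of class `"cmc_epochs"`: list with `series` (array
#'   sites x samples x epochs), `fs`, `sites`, and the simulation settings.
#' @export
simulate_field <- function(n_epochs = 8L, epoch_length = 0.5, fs = 1000,
                           dt = 1e-4, n_x = 128L, burn_in = 1,
                           input_amp = 1, linearised = TRUE, init_sd = 0,
                           seed = 1L,
                           syn = synaptic_params(),
                           conn = connectivity_params(),
                           sensors = sensor_model()) {
  if (dt <= 0) stop("'dt' must be positive")
  rec_every <- round(1 / (fs * dt))
  if (abs(rec_every * fs * dt - 1) > 1e-8)
    stop("'fs' must be an integer divisor of 1/dt")
  n_x <- as.integer(n_x)
  ell <- conn$patch_length
  dx <- ell / n_x
  spe <- round(epoch_length * fs)
  n_rec <- round(burn_in * fs) + n_epochs * spe
  n_steps <- n_rec * rec_every
  # ring distances, conduction lags and per-edge kernel weights
  jmax <- n_x %/% 2L
  dist <- dx * (0:jmax)
  lags <- as.integer(round(conn$inv_speed * dist / dt))
  e <- .cmc_edge_table
  groups <- paste(e$from, signif(conn$c_decay[e$edge], 12))
  ug <- unique(groups)
  wmat <- sapply(ug, function(g) {
    cval <- conn$c_decay[e$edge][match(g, groups)]
    exp(-cval * dist)
  })                                     # (jmax+1) x n groups
  edge_group <- match(groups, ug) - 1L
  group_pop <- e$from[match(ug, groups)] - 1L
  edge_wt <- e$sign * conn$alpha[e$edge] / 2 * dx
  # exponential-integrator coefficients per population
  gam <- sigmoid_gain(syn)
  prop <- matrix(0, 4L, 6L)
  for (a in 1:4) {
    kp <- syn$kappa[a]
    ek <- exp(-kp * dt)
    prop[a, 1:4] <- c((1 + kp * dt) * ek, dt * ek,
                      -kp^2 * dt * ek, (1 - kp * dt) * ek)
    prop[a, 5:6] <- c((1 - (1 + kp * dt) * ek) / kp^2, dt * ek)
  }
  # exact covariance of the stochastic increment for the driven population
  kp <- syn$kappa[1L]
  xq <- 2 * kp * dt
  eq <- exp(-xq)
  I2 <- (1 - eq) / (2 * kp)
  Iu <- 1 / (4 * kp^2) - eq * (dt / (2 * kp) + 1 / (4 * kp^2))
  Iuu <- 1 / (4 * kp^3) - eq * (dt^2 / (2 * kp) + dt / (2 * kp^2) +
                                  1 / (4 * kp^3))
  Q11 <- Iuu
  Q12 <- Iu - kp * Iuu
  Q22 <- I2 - 2 * kp * Iu + kp^2 * Iuu
  scl <- kp^2 * input_amp * n_x          # kappa1^2 * var density of input
  L11 <- sqrt(Q11 * scl)
  L21 <- if (L11 > 0) Q12 * scl / L11 else 0
  L22 <- sqrt(max(Q22 * scl - L21^2, 0))
  # electrode lead-field weights on the lattice (unit-mass periodic Gaussian)
  xg <- dx * (0:(n_x - 1L))
  wch <- t(sapply(seq_along(sensors$centres), function(q) {
    y <- xg - sensors$centres[q]
    w <- 0
    for (im in -3:3) w <- w + stats::dnorm(y + im * ell, 0, sensors$dispersions[q])
    w * dx
  }))
  wsite <- (sensors$montage %*% wch) * sensors$gains
  sim <- .with_seed(seed, field_sim_cpp(
    kappa = syn$kappa, prop = prop,
    edge_to = e$to - 1L, edge_group = edge_group, edge_wt = edge_wt,
    group_pop = group_pop, wmat = as.matrix(wmat), lags = lags,
    gamma = gam, r = syn$r, eta = syn$eta, linearised = linearised,
    wsite = wsite, mix = sensors$mix,
    n_x = n_x, n_steps = n_steps, rec_every = rec_every,
    noiseL = c(L11, L21, L22), dt = dt, init_sd = init_sd))
  keep <- sim[, round(burn_in * fs) + seq_len(n_epochs * spe), drop = FALSE]
  series <- array(keep, c(nrow(keep), spe, n_epochs))
  structure(list(series = series, fs = fs,
                 sites = paste0("site", seq_len(nrow(keep))),
                 dt = dt, n_x = n_x, seed = seed,
                 linearised = linearised, input_amp = input_amp),
            class = "cmc_epochs")
}

#' Welch cross-spectral density estimate from epoched time series
#'
#' Averaged cross-periodograms over non-overlapping Hann-tapered segments:
#' the estimator of the two-sided cross-spectral density (per Hz) whose
#' expectation matches the analytic predictions of [predict_csd()].
#'
#' @param x A `"cmc_epochs"` object, an array channels x samples x epochs,
#'   or a channels x samples matrix (split into epochs internally).
#' @param fs Sampling rate (Hz); taken from the object when available.
#' @param window Segment length (s); each epoch is cut into non-overlapping
#'   segments of this length.  An epoch shorter than the window is an
#'   error.
#' @param condition Condition label for the output.
#' @return A [csd()] with one condition and the number of averaged segments
#'   as `n_epochs`.
#' @export
estimate_csd <- function(x, fs = NULL, window = 0.5, condition = "cond1") {
  if (inherits(x, "cmc_epochs")) {
    fs <- x$fs
    arr <- x$series
  } else if (is.matrix(x)) {
    if (is.null(fs)) stop("supply 'fs' for a plain matrix")
    arr <- array(x, c(nrow(x), ncol(x), 1L))
  } else arr <- x
  if (is.null(fs)) stop("supply 'fs'")
  nc <- dim(arr)[1L]
  nsamp <- dim(arr)[2L]
  nep <- dim(arr)[3L]
  nw <- round(window * fs)
  if (nw > nsamp) stop("epoch shorter than the analysis window")
  nseg_per <- nsamp %/% nw
  if (nep * nseg_per < 2L) stop("need at least 2 segments")
  w <- 0.5 * (1 - cos(2 * pi * (0:(nw - 1L)) / nw))   # periodic Hann
  norm <- sum(w^2) * fs                                # dt / sum(w^2) scaling
  nf <- nw %/% 2L - 1L
  freqs <- (1:nf) * fs / nw
  acc <- array(0 + 0i, c(nf, nc, nc))
  nseg <- 0L
  for (ep in seq_len(nep)) for (sg in seq_len(nseg_per)) {
    seg <- arr[, (sg - 1L) * nw + seq_len(nw), ep, drop = FALSE]
    X <- t(apply(matrix(seg, nc, nw), 1L, function(v) fft(v * w)))
    X <- matrix(X, nc, nw)[, 2:(nf + 1L), drop = FALSE]
    for (l in seq_len(nc)) for (m in seq_len(nc))
      acc[, l, m] <- acc[, l, m] + X[l, ] * Conj(X[m, ]) / norm
    nseg <- nseg + 1L
  }
  acc <- acc / nseg
  for (l in seq_len(nc)) acc[, l, l] <- Re(acc[, l, l])
  csd(array(acc, c(1L, dim(acc))), freqs, conditions = condition,
      sites = if (inherits(x, "cmc_epochs")) x$sites else NULL,
      n_epochs = nseg)
}

#' Gamma-band peak frequency of an auto-spectrum
#'
#' Frequency of the maximum of an auto-spectrum within a band (default the
#' gamma band, 30-80 Hz).  When the band maximum sits on a band edge the
#' spectrum is searched for interior local maxima; if none exists the peak
#' is reported as absent (`NA`), mirroring featureless spectra in which no
#' gamma peak is detectable.
#'
#' @param x A [csd()] object or a numeric spectrum.
#' @param band Frequency band `c(lo, hi)` in Hz.
#' @param freqs Frequency grid (required when `x` is numeric).
#' @param site,condition Which auto-spectrum of a `csd` to use.
#' @return Peak frequency in Hz, or `NA_real_` when no interior peak
#'   exists.
#' @export
gamma_peak <- function(x, band = c(30, 80), freqs = NULL, site = 1L,
                       condition = 1L) {
  if (inherits(x, "csd")) {
    freqs <- x$freqs
    spec <- Re(x$values[condition, , site, site])
  } else {
    spec <- as.numeric(x)
    if (is.null(freqs) || length(freqs) != length(spec))
      stop("supply 'freqs' matching the spectrum")
  }
  sel <- which(freqs >= band[1L] & freqs <= band[2L])
  if (length(sel) == 0L) stop("empty frequency band")
  sb <- spec[sel]
  imax <- which.max(sb)
  interior <- function(i) i > 1L && i < length(sb)
  if (interior(imax)) return(freqs[sel[imax]])
  loc <- which(diff(sign(diff(sb))) < 0) + 1L         # interior local maxima
  if (!length(loc)) return(NA_real_)
  freqs[sel[loc[which.max(sb[loc])]]]
}
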