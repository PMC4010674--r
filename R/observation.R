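#' Sensor model for a bipolar ECoG montage over the patch
#'
#' Each electrode sees the patch through a Gaussian lead field centred at
#' `centres[q]` with spatial dispersion `dispersions[q]`; recording sites are
#' bipolar differences of electrode pairs defined by the montage matrix.  The
#' measured signal mixes the four populations with weights `mix`.
#'
#' The defaults place 8 electrodes a distance \eqn{\ell/8} apart, centred on
#' the middle of a 25 mm patch, with dispersion \eqn{\ell/16}, paired into 4
#' bipolar sites that share no electrode, and mixing weights that let the
#' pyramidal populations dominate the signal with no interneuron
#' contribution.
#'
#' @param centres Electrode positions on the patch, mm, in `[0, patch_length)`.
#' @param dispersions Gaussian lead-field widths, mm, positive.
#' @param montage Integer matrix (sites x electrodes); every row must contain
#'   exactly one `+1` and one `-1` and sum to zero.
#' @param mix Length-4 non-negative population contribution weights.
#' @param gains Per-site amplitude gains (used by the neural-mass variant,
#'   where the spatial lead-field structure collapses; unity by default).
#' @param patch_length Patch length, mm.
#' @return An object of class `"sensor_model"`.
#' @export
sensor_model <- function(centres = NULL, dispersions = NULL, montage = NULL,
                         mix = c(0.2, 0, 0.2, 0.6), gains = NULL,
                         patch_length = 25) {
  if (is.null(centres))
    centres <- patch_length / 2 + patch_length / 8 * seq(-3.5, 3.5, by = 1)
  n_e <- length(centres)
  if (is.null(dispersions)) dispersions <- rep(patch_length / 16, n_e)
  if (is.null(montage)) {
    if (n_e %% 2L != 0L)
      stop("default montage needs an even number of electrodes")
    montage <- matrix(0L, n_e %/% 2L, n_e)
    for (l in seq_len(nrow(montage))) {
      montage[l, 2L * l - 1L] <- -1L
      montage[l, 2L * l] <- 1L
    }
  }
  montage <- as.matrix(montage)
  if (is.null(gains)) gains <- rep(1, nrow(montage))
  if (any(centres < 0) || any(centres > patch_length))
    stop("electrode centres must lie within [0, patch_length]")
  if (length(dispersions) != n_e || any(dispersions <= 0))
    stop("'dispersions' must be positive, one per electrode")
  ok <- apply(montage, 1L, function(r)
    sum(r == 1L) == 1L && sum(r == -1L) == 1L && sum(r) == 0L &&
      all(r %in% c(-1L, 0L, 1L)))
  if (ncol(montage) != n_e || !all(ok))
    stop("each montage row must contain exactly one +1 and one -1 and sum to 0")
  if (length(mix) != 4L || any(mix < 0))
    stop("'mix' must be 4 non-negative weights")
  if (length(gains) != nrow(montage) || any(gains <= 0))
    stop("'gains' must be positive, one per site")
  structure(list(centres = as.numeric(centres),
                 dispersions = as.numeric(dispersions),
                 montage = montage, mix = as.numeric(mix),
                 gains = as.numeric(gains), patch_length = patch_length),
            class = "sensor_model")
}

#' Input and channel noise spectra
#'
#' Both the neuronal input fluctuations and the channel noise are mixtures of
#' a white component and a coloured (pink) component,
#' \eqn{g(\omega) = \alpha + \beta (f_{ref}/f)^{\gamma_{exp}}} with
#' \eqn{f_{ref} = 1} Hz.  Input noise is spatially white (wavenumber
#' independent).  Channel noise has a site-specific part added to the
#' auto-spectra and an optional common part shared by every site pair.
#'
#' @param alpha_u,beta_u White and coloured input amplitudes.
#' @param alpha_n,beta_n White and coloured site-noise amplitudes (scalar,
#'   shared across sites, or one value per site).
#' @param alpha_c,beta_c Common channel-noise amplitudes (shared across all
#'   site pairs); set to zero to disable.
#' @param exponent Spectral exponent of the coloured components.
#' @return An object of class `"noise_params"`.
#' @export
noise_params <- function(alpha_u = 1, beta_u = 1,
                         alpha_n = 1e-8, beta_n = 5e-8,
                         alpha_c = 2e-9, beta_c = 1e-8,
                         exponent = 1) {
  vals <- c(alpha_u, beta_u, alpha_n, beta_n, alpha_c, beta_c)
  if (any(vals < 0)) stop("noise amplitudes must be non-negative")
  structure(list(alpha_u = alpha_u, beta_u = beta_u,
                 alpha_n = alpha_n, beta_n = beta_n,
                 alpha_c = alpha_c, beta_c = beta_c, exponent = exponent),
            class = "noise_params")
}

#' Gaussian lead-field Fourier factor
#'
#' Fourier transform of a unit-mass Gaussian lead field of spatial width
#' `phi`, evaluated at angular wavenumber `k` (rad/mm):
#' \eqn{E(\phi, k) = e^{-\phi^2 k^2 / 2}}.  Expressed in spatial-cycle units
#' \eqn{\xi = k/2\pi} this is the conventional \eqn{e^{-2\pi^2\phi^2\xi^2}}.
#' Values lie in (0, 1], are even in `k`, and decrease in both `|k|` and
#' `phi` (the lead field is a spatial low-pass filter).
#'
#' @param phi Dispersion (mm), positive.
#' @param k Angular wavenumber(s) (rad/mm).
#' @export
lead_field_ft <- function(phi, k) {
  if (any(phi <= 0)) stop("'phi' must be positive")
  exp(-0.5 * phi^2 * k^2)
}

#' Input spectrum and channel-noise spectrum
#'
#' @param omega Angular frequency(ies), rad/s, positive.
#' @param noise A [noise_params()] object.
#' @return Non-negative spectral density values.
#' @export
input_spectrum <- function(omega, noise = noise_params()) {
  .mixture_spectrum(omega, noise$alpha_u, noise$beta_u, noise$exponent)
}

#' @rdname input_spectrum
#' @export
channel_noise_spectrum <- function(omega, noise = noise_params()) {
  .mixture_spectrum(omega, noise$alpha_n, noise$beta_n, noise$exponent)
}

.mixture_spectrum <- function(omega, alpha, beta, exponent) {
  f <- omega / (2 * pi)
  alpha + beta * (1 / f)^exponent
}

#' Complex cross-spectral density container
#'
#' A `csd` holds complex Hermitian site-by-site spectral matrices over
#' frequencies and experimental conditions: `values[cond, freq, i, j]`.
#' Diagonals are real and non-negative.
#'
#' @param values Complex array `[n conditions, n frequencies, s, s]` (an
#'   `[n freq, s, s]` array is promoted to a single condition).
#' @param freqs Frequencies in Hz.
#' @param conditions Condition labels.
#' @param sites Site labels.
#' @param n_epochs Optional epoch count per condition (degrees of freedom of
#'   the estimate).
#' @return An object of class `"csd"`.
#' @export
csd <- function(values, freqs, conditions = NULL, sites = NULL,
                n_epochs = NULL) {
  if (length(dim(values)) == 3L)
    values <- array(values, c(1L, dim(values)))
  d <- dim(values)
  if (length(d) != 4L || d[3L] != d[4L])
    stop("'values' must be a [condition, frequency, site, site] array")
  if (length(freqs) != d[2L]) stop("'freqs' length must match dim 2")
  if (is.null(conditions)) conditions <- paste0("cond", seq_len(d[1L]))
  if (is.null(sites)) sites <- paste0("site", seq_len(d[3L]))
  if (!is.null(n_epochs)) n_epochs <- rep_len(n_epochs, d[1L])
  obj <- structure(list(values = values, freqs = as.numeric(freqs),
                        conditions = as.character(conditions),
                        sites = as.character(sites), n_epochs = n_epochs),
                   class = "csd")
  validate_csd(obj)
  obj
}

#' @rdname csd
#' @param x A `csd` object.
#' @param tol Tolerance for the Hermitian-symmetry check, relative to the
#'   largest magnitude entry.
#' @export
validate_csd <- function(x, tol = 1e-8) {
  v <- x$values
  vc <- Conj(aperm(v, c(1L, 2L, 4L, 3L)))
  sc <- max(abs(v), 1e-300)
  if (max(abs(v - vc)) > tol * sc)
    stop("cross-spectral matrices are not Hermitian")
  s <- dim(v)[3L]
  for (l in seq_len(s)) {
    if (min(Re(v[, , l, l])) < -tol * sc)
      stop("auto-spectra must be non-negative")
  }
  invisible(x)
}

#' @export
print.csd <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Cross-spectral densities: %d condition(s) x %d frequencies x %d sites\n",
              d[1L], d[2L], d[3L]))
  cat(sprintf("  frequencies: %.3g - %.3g Hz\n", min(x$freqs), max(x$freqs)))
  cat("  conditions: ", paste(x$conditions, collapse = ", "), "\n", sep = "")
  if (!is.null(x$n_epochs))
    cat("  epochs/condition: ", paste(x$n_epochs, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
plot.csd <- function(x, condition = 1L, what = c("auto", "cross"), ...) {
  what <- match.arg(what)
  s <- dim(x$values)[3L]
  if (what == "auto") {
    sp <- sapply(seq_len(s), function(l) Re(x$values[condition, , l, l]))
    graphics::matplot(x$freqs, sp, type = "l", lty = 1,
                      xlab = "frequency (Hz)", ylab = "power density",
                      main = paste("auto-spectra,", x$conditions[condition]), ...)
    graphics::legend("topright", legend = x$sites, col = seq_len(s), lty = 1,
                     bty = "n", cex = 0.8)
  } else {
    pr <- utils::combn(s, 2L)
    sp <- apply(pr, 2L, function(ij) Mod(x$values[condition, , ij[1], ij[2]]))
    graphics::matplot(x$freqs, sp, type = "l", lty = 1,
                      xlab = "frequency (Hz)", ylab = "|cross-spectrum|",
                      main = paste("cross-spectra,", x$conditions[condition]), ...)
  }
  invisible(x)
}

#' Bipolar site transfer function
#'
#' The spatiotemporal filter from input fluctuations at wavenumber `k` to the
#' signal of one bipolar site: the difference of the two electrodes'
#' phase-shifted lead-field factors times the mixed population transfer,
#' \deqn{\tilde T_l(k,\omega) = \big(e^{-i a_{l^+} k} E(\phi_{l^+},k)
#'   - e^{-i a_{l^-} k} E(\phi_{l^-},k)\big)\, Q \cdot T(k,\omega).}
#'
#' @param site Site (montage row) index.
#' @param k Wavenumber (rad/mm).
#' @param omega Angular frequency (rad/s).
#' @param sensors A [sensor_model()].
#' @inheritParams jacobian_J
#' @return Complex scalar.
#' @export
site_transfer <- function(site, k, omega, sensors = sensor_model(),
                          syn = synaptic_params(),
                          conn = connectivity_params()) {
  site <- as.integer(site)
  if (length(site) != 1L || is.na(site) || site < 1L ||
      site > nrow(sensors$montage))
    stop("invalid site index")
  Tk <- transfer_matrix(k, omega, syn, conn)
  row <- sensors$montage[site, ]
  b <- sum(row * exp(-1i * sensors$centres * k) *
             lead_field_ft(sensors$dispersions, k))
  sensors$gains[site] * b * sum(sensors$mix * Tk)
}

# Electrode-to-site spatial factors over a wavenumber grid: rows = sites.
.site_factors <- function(sensors, kv) {
  ph <- exp(-1i * outer(sensors$centres, kv)) *
    t(sapply(sensors$dispersions, lead_field_ft, k = kv))
  (sensors$montage %*% ph) * sensors$gains
}

#' Predict cross-spectral densities for one condition
#'
#' Evaluates the analytic forward model: population transfer functions over
#' the (wavenumber, frequency) grid, bipolar lead-field projection, summation
#' over wavenumbers against the spatially white input spectrum, and addition
#' of channel noise,
#' \deqn{\hat g_{lm}(\omega) = \sum_k \tilde T_l(k,\omega)\, g_u(\omega)\,
#'   \tilde T_m(k,\omega)^* + g_n(\omega)\,\delta_{lm} + g_c(\omega).}
#' Site-specific channel noise enters the auto-spectra only; the common
#' component is added to every site pair.  The result is Hermitian with
#' real non-negative diagonal by construction.
#'
#' For the neural-mass variant (`variant = "mass"`), the patch collapses to a
#' point: only the `k = 0` mode contributes and the bipolar lead-field
#' structure (which cancels exactly at `k = 0`) is replaced by the per-site
#' amplitude gains of the sensor model.
#'
#' @param grid A [spectral_grid()].
#' @param sensors A [sensor_model()].
#' @param noise A [noise_params()].
#' @inheritParams jacobian_J
#' @param variant `"field"` (full spatial model) or `"mass"` (point source).
#' @param condition Condition label for the output.
#' @return A [csd()] with one condition.
#' @export
predict_csd <- function(grid, sensors = sensor_model(),
                        noise = noise_params(),
                        syn = synaptic_params(),
                        conn = connectivity_params(),
                        variant = c("field", "mass"),
                        condition = "cond1") {
  variant <- match.arg(variant)
  G <- .predict_csd_core(grid, sensors, noise, syn, conn, variant)
  csd(array(G, c(1L, dim(G))), grid$freqs, conditions = condition)
}

.predict_csd_core <- function(grid, sensors, noise, syn, conn, variant) {
  wv <- grid$omega
  nw <- length(wv)
  ns <- nrow(sensors$montage)
  if (variant == "mass") {
    g0 <- spectral_grid(grid$freqs, n_k = 0L, patch_length = grid$patch_length)
    tf <- transfer_grid(g0, syn, conn)                 # [4, 1, nw]
    qt <- colSums(matrix(tf, 4L, nw) * sensors$mix)    # length nw
    St <- outer(sensors$gains, qt)                     # ns x nw
    sig <- array(0 + 0i, c(nw, ns, ns))
    gu <- input_spectrum(wv, noise)
    for (l in seq_len(ns)) for (m in seq_len(ns))
      sig[, l, m] <- St[l, ] * Conj(St[m, ]) * gu
  } else {
    tf <- transfer_grid(grid, syn, conn)               # [4, nk, nw]
    kv <- grid$wavenumbers
    nk <- length(kv)
    qt <- sensors$mix[1L] * tf[1L, , ] + sensors$mix[2L] * tf[2L, , ] +
      sensors$mix[3L] * tf[3L, , ] + sensors$mix[4L] * tf[4L, , ]
    qt <- matrix(qt, nk, nw)
    B <- .site_factors(sensors, kv)                    # ns x nk
    gu <- input_spectrum(wv, noise)
    Tt <- vector("list", ns)
    for (l in seq_len(ns)) Tt[[l]] <- B[l, ] * qt      # nk x nw
    sig <- array(0 + 0i, c(nw, ns, ns))
    for (l in seq_len(ns)) for (m in l:ns) {
      x <- colSums(Tt[[l]] * Conj(Tt[[m]])) * gu
      sig[, l, m] <- x
      if (m > l) sig[, m, l] <- Conj(x)
    }
  }
  gc_ <- .mixture_spectrum(wv, noise$alpha_c, noise$beta_c, noise$exponent)
  for (l in seq_len(ns)) {
    nl <- .mixture_spectrum(wv,
                            rep_len(noise$alpha_n, ns)[l],
                            rep_len(noise$beta_n, ns)[l], noise$exponent)
    sig[, l, l] <- Re(sig[, l, l]) + nl + gc_
    for (m in seq_len(ns)) if (m != l) sig[, l, m] <- sig[, l, m] + gc_
  }
  sig
}

#' Convergence-based choice of the wavenumber truncation
#'
#' Doubles the spatial truncation order until doubling it again changes every
#' predicted cross-spectrum by less than `tol` in relative terms, starting
#' from `start`.
#'
#' @param freqs Frequencies (Hz) at which predictions are compared.
#' @inheritParams predict_csd
#' @param start,max_n Starting and maximal truncation order.
#' @param tol Relative change below which the truncation is accepted.
#' @return The selected truncation order `N`.
#' @export
adaptive_n_k <- function(freqs, sensors = sensor_model(),
                         noise = noise_params(), syn = synaptic_params(),
                         conn = connectivity_params(),
                         start = 32L, max_n = 512L, tol = 1e-6) {
  n <- as.integer(start)
  g <- spectral_grid(freqs, n_k = n, patch_length = conn$patch_length)
  cur <- .predict_csd_core(g, sensors, noise, syn, conn, "field")
  while (n < max_n) {
    g2 <- spectral_grid(freqs, n_k = 2L * n, patch_length = conn$patch_length)
    nxt <- .predict_csd_core(g2, sensors, noise, syn, conn, "field")
    if (max(abs(nxt - cur)) <= tol * max(abs(nxt))) return(n)
    n <- 2L * n
    cur <- nxt
  }
  n
}
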