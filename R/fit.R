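#' Vectorise cross-spectral data for Gaussian inversion
#'
#' Real and imaginary parts of the Hermitian site-by-site matrices are
#' treated as real Gaussian observations.  For every condition the stacked
#' layout is: real parts of the upper triangle including the diagonal
#' (column-major), then imaginary parts of the strict upper triangle
#' (column-major), each block running over frequencies; conditions are
#' concatenated.  `devectorise_csd()` inverts the mapping onto a template.
#'
#' @param x A [csd()] object.
#' @return Numeric vector of length
#'   `n conditions * n frequencies * n sites^2`.
#' @export
vectorise_csd <- function(x) {
  validate_csd(x)
  .vectorise_values(x$values)
}

.vectorise_values <- function(v) {
  d <- dim(v)
  s <- d[3L]
  iu <- which(upper.tri(diag(s), diag = TRUE))
  is <- which(upper.tri(diag(s)))
  out <- vector("list", d[1L])
  for (cd in seq_len(d[1L])) {
    flat <- matrix(v[cd, , , ], d[2L], s * s)
    out[[cd]] <- c(Re(flat[, iu]), Im(flat[, is]))
  }
  unlist(out, use.names = FALSE)
}

#' @rdname vectorise_csd
#' @param vec Numeric vector as produced by `vectorise_csd()`.
#' @param template A `csd` supplying dimensions and labels.
#' @export
devectorise_csd <- function(vec, template) {
  d <- dim(template$values)
  s <- d[3L]
  iu <- which(upper.tri(diag(s), diag = TRUE))
  is <- which(upper.tri(diag(s)))
  per <- d[2L] * s * s
  if (length(vec) != d[1L] * per)
    stop("vector length does not match the template dimensions")
  v <- array(0 + 0i, d)
  for (cd in seq_len(d[1L])) {
    blk <- vec[(cd - 1L) * per + seq_len(per)]
    re <- matrix(blk[seq_len(d[2L] * length(iu))], d[2L])
    im <- matrix(blk[-seq_len(d[2L] * length(iu))], d[2L])
    flat <- matrix(0 + 0i, d[2L], s * s)
    flat[, iu] <- re
    flat[, is] <- flat[, is] + 1i * im
    m <- array(flat, c(d[2L], s, s))
    mh <- Conj(aperm(m, c(1L, 3L, 2L)))
    diag_ix <- (seq_len(s) - 1L) * s + seq_len(s)
    fl2 <- matrix(m + mh, d[2L], s * s)
    fl2[, diag_ix] <- fl2[, diag_ix] / 2
    v[cd, , , ] <- array(fl2, c(d[2L], s, s))
  }
  csd(v, template$freqs, template$conditions, template$sites,
      template$n_epochs)
}

#' Inversion control settings
#'
#' @param max_iter Maximum outer (Gauss-Newton) iterations.
#' @param tol Free-energy improvement below which an iteration counts
#'   towards convergence.
#' @param tol_streak Consecutive small improvements required to stop.
#' @param fd_step Central finite-difference step on the packed vector.
#' @param init_damping Initial Levenberg-Marquardt damping.
#' @param lambda_hyper_var Variance of the Gaussian hyperprior on the
#'   log-precision of the observation noise (its mean is matched to the
#'   sample variance of the data).
#' @param n_k Spatial truncation order used for predictions during fitting.
#' @param weighting Residual weighting: `"level"` (default) scales the
#'   residual of every site pair by \eqn{\sqrt{g_{ll} g_{mm}}} of the
#'   observed auto-spectra, matching the level-proportional variance of
#'   averaged-periodogram estimates; `"none"` uses unweighted residuals.
#'   The weights are a fixed function of the data, so free energies remain
#'   comparable across models fitted to the same data.
#' @param warm_start Initialise condition-effect models from a preliminary
#'   null-model fit (see [fit_csd()]).
#' @param lambda_step Maximum increase of the noise log-precision per
#'   outer iteration (graduated precision annealing).
#' @param lambda_fixed Optional fixed value for the noise log-precision;
#'   when given, no precision updates (and no hyperprior term) are applied.
#' @param lambda_per_condition Estimate one noise log-precision per
#'   experimental condition instead of a single shared one.
#' @param verbose Print per-iteration free energies.
#' @return A list of class `"fit_control"`.
#' @export
fit_control <- function(max_iter = 128L, tol = 0.01, tol_streak = 4L,
                        fd_step = 1e-3, init_damping = 1,
                        lambda_hyper_var = 16, n_k = 32L,
                        weighting = c("level", "none"), warm_start = TRUE,
                        lambda_step = Inf, lambda_fixed = NULL,
                        lambda_per_condition = FALSE, verbose = FALSE) {
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 tol_streak = as.integer(tol_streak), fd_step = fd_step,
                 init_damping = init_damping,
                 lambda_hyper_var = lambda_hyper_var,
                 n_k = as.integer(n_k), weighting = match.arg(weighting),
                 warm_start = isTRUE(warm_start), lambda_step = lambda_step,
                 lambda_fixed = lambda_fixed,
                 lambda_per_condition = isTRUE(lambda_per_condition),
                 verbose = isTRUE(verbose)),
            class = "fit_control")
}

# Per-observation weights sqrt(g_ll * g_mm) from the observed auto-spectra,
# in vectorised layout (identical for the real and imaginary components of
# a pair).
.level_weights <- function(data) {
  v <- data$values
  d <- dim(v)
  W <- array(0, d)
  for (cd in seq_len(d[1L])) for (l in seq_len(d[3L])) for (m in seq_len(d[4L]))
    W[cd, , l, m] <- sqrt(Re(v[cd, , l, l]) * Re(v[cd, , m, m]))
  W <- pmax(W, 1e-12 * max(W))
  .vectorise_values(W * (1 + 1i))
}

# Prediction stack h(theta): vectorised predicted CSD over all conditions.
# The per-condition spectra come from the compiled closed-form predictor;
# only the coupling strengths and spatial decays can be condition specific,
# so sensor factors and noise spectra are assembled once per evaluation.
.make_predictor <- function(model, priors, design, grid) {
  n_cond <- length(design$covariate)
  u <- design$covariate
  en <- .cmc_edge_table$edge
  sgn <- .cmc_edge_table$sign
  nm_all <- priors$name
  mean_all <- setNames(priors$mean, nm_all)
  free_ix <- which(priors$free)
  n_free <- length(free_ix)
  ix <- function(x) match(x, nm_all)
  ix_kappa <- ix(paste0("kappa", 1:4)); ix_r <- ix("r")
  ix_alpha <- ix(paste0("alpha_", en)); ix_c <- ix(paste0("c_", en))
  ix_ups <- ix("inv_speed")
  n_e <- attr(priors, "n_electrodes"); n_s <- attr(priors, "n_sites")
  ix_cen <- ix(paste0("centre_", seq_len(n_e)))
  ix_phi <- ix(paste0("phi_", seq_len(n_e)))
  ix_gain <- ix(paste0("gain_", seq_len(n_s)))
  ix_noise <- ix(c("alpha_u", "beta_u", "alpha_n", "beta_n",
                   "alpha_c", "beta_c"))
  sens0 <- attr(priors, "sensors")
  eta <- attr(priors, "syn")$eta
  expo <- attr(priors, "noise")$exponent
  ell <- attr(priors, "conn")$patch_length
  mass <- model$variant == "mass"
  kpos <- grid$wavenumbers[grid$wavenumbers >= 0]
  if (mass) kpos <- 0
  kw <- ifelse(kpos == 0, 1, 2)
  wv <- grid$omega
  finv <- (2 * pi / wv)^expo
  nw <- length(wv)
  # sensitivity bookkeeping: position of each modulated parameter
  mod_ix <- match(model$modulated, nm_all)
  mod_alpha <- match(ix_alpha, mod_ix)    # NA where not modulated
  mod_c <- match(ix_c, mod_ix)
  iu <- which(upper.tri(diag(n_s), diag = TRUE))
  is <- which(upper.tri(diag(n_s)))
  vec1 <- function(g) {
    flat <- matrix(g, nw, n_s * n_s)
    c(Re(flat[, iu]), Im(flat[, is]))
  }
  function(packed) {
    dev <- numeric(length(nm_all))
    dev[free_ix] <- packed[seq_len(n_free)]
    beta <- packed[-seq_len(n_free)]
    th <- mean_all * exp(dev)
    r <- th[ix_r]; er <- exp(r * eta)
    gam <- r * er / (1 + er)^2
    if (mass) {
      B <- matrix(complex(real = th[ix_gain]), n_s, 1L)
    } else {
      E <- exp(-0.5 * outer(th[ix_phi]^2, kpos^2))
      ph <- exp(-1i * outer(th[ix_cen] %% ell, kpos)) * E
      B <- (sens0$montage %*% ph) * th[ix_gain]
    }
    gu <- th[ix_noise[1L]] + th[ix_noise[2L]] * finv
    gn <- th[ix_noise[3L]] + th[ix_noise[4L]] * finv
    gc_ <- th[ix_noise[5L]] + th[ix_noise[6L]] * finv
    alpha0 <- th[ix_alpha] * sgn
    c0 <- th[ix_c]
    if (!length(beta)) {
      g <- csd_predict_cpp(th[ix_kappa], alpha0, c0, th[ix_ups], gam,
                           kpos, kw, wv, sens0$mix, B, gu, gn, gc_)
      return(rep.int(vec1(g), n_cond))
    }
    ba <- ifelse(is.na(mod_alpha), 0, beta[mod_alpha])
    bc <- ifelse(is.na(mod_c), 0, beta[mod_c])
    out <- vector("list", n_cond)
    for (cd in seq_len(n_cond)) {
      g <- csd_predict_cpp(th[ix_kappa], alpha0 * exp(ba * u[cd]),
                           c0 * exp(bc * u[cd]), th[ix_ups], gam,
                           kpos, kw, wv, sens0$mix, B, gu, gn, gc_)
      out[[cd]] <- vec1(g)
    }
    unlist(out, use.names = FALSE)
  }
}

.fd_jacobian <- function(fn, x, f0, step) {
  p <- length(x)
  J <- matrix(0, length(f0), p)
  for (j in seq_len(p)) {
    d <- step
    for (attempt in 1:3) {
      xp <- x; xp[j] <- xp[j] + d
      xm <- x; xm[j] <- xm[j] - d
      fp <- fn(xp); fm <- fn(xm)
      if (all(is.finite(fp)) && all(is.finite(fm))) {
        J[, j] <- (fp - fm) / (2 * d)
        break
      }
      d <- d / 10
    }
  }
  J
}

#' Laplace free energy of a Gaussian approximate posterior
#'
#' The evidence bound used both as the objective of [fit_csd()] and as the
#' model-comparison score:
#' \deqn{F = \underbrace{-\tfrac{n}{2}\log 2\pi + \tfrac{n}{2}\lambda
#'  - \tfrac{e^{\lambda}}{2}\big(e^\top e + \mathrm{tr}(J^\top J C)\big)}_{
#'  \mathrm{E}_q[\log p(y|\theta)]}
#'  - \mathrm{KL}\big(N(\mu, C)\,\|\,N(0, \Sigma_p)\big)
#'  - \tfrac{\pi_h}{2}(\lambda - \bar\lambda)^2}
#' with residuals \eqn{e = y - h(\mu)}, observation precision
#' \eqn{e^{\lambda} I}, and prediction Jacobian `J`.  For a linear-Gaussian
#' model evaluated at the exact posterior this equals the log marginal
#' likelihood (plus the hyperprior term).
#'
#' @param y Observation vector.
#' @param pred Prediction vector at `mu`.
#' @param J Jacobian of the predictions (n x p); may be `NULL` to drop the
#'   posterior-uncertainty correction.
#' @param mu Posterior mean deviation from the prior mean.
#' @param C Posterior covariance (p x p).
#' @param lambda Log precision of the observation noise.
#' @param prior_var Prior variances (length p) of the packed parameters.
#' @param lambda_mean,lambda_var Hyperprior on `lambda`; `lambda_var = Inf`
#'   (or `NULL` mean) drops the term.
#' @param groups Optional integer vector assigning each observation to a
#'   noise-precision group when `lambda` is a vector (one log-precision per
#'   group); by default all observations share `lambda[1]`.
#' @return Scalar free energy.
#' @export
laplace_free_energy <- function(y, pred, J, mu, C, lambda, prior_var,
                                lambda_mean = NULL, lambda_var = Inf,
                                groups = NULL) {
  e <- y - pred
  n <- length(y)
  p <- length(mu)
  if (is.null(groups)) groups <- rep(1L, n)
  G <- length(lambda)
  lik <- -n / 2 * log(2 * pi)
  for (g in seq_len(G)) {
    sel <- groups == g
    tr_g <- if (is.null(J)) 0 else
      sum(crossprod(J[sel, , drop = FALSE]) * C)
    lik <- lik + sum(sel) / 2 * lambda[g] -
      exp(lambda[g]) / 2 * (sum(e[sel]^2) + tr_g)
  }
  ldC <- determinant(C, logarithm = TRUE)$modulus
  kl <- 0.5 * (sum(diag(C) / prior_var) + sum(mu^2 / prior_var) - p +
                 sum(log(prior_var)) - ldC)
  hyp <- if (is.null(lambda_mean) || !is.finite(lambda_var) || lambda_var <= 0)
    0 else -0.5 * sum((lambda - lambda_mean)^2) / lambda_var
  as.numeric(lik - kl + hyp)
}

#' Fit a canonical-microcircuit field model to cross-spectral data
#'
#' Inverts the generative model by variational Laplace: a Gaussian posterior
#' over the packed log-scale parameters (deviations and condition
#' sensitivities) is optimised by Gauss-Newton ascent on the Laplace free
#' energy, with Levenberg-Marquardt step control (damping increased on
#' rejected steps), central finite-difference prediction Jacobians, and a
#' single observation-noise log-precision hyperparameter updated by Newton
#' steps under a Gaussian hyperprior.  All experimental conditions are
#' fitted simultaneously: the likelihood factorises over conditions while
#' the model couples them through the condition-specific effects.
#'
#' Accepted iterations never decrease the free energy; convergence is
#' declared after `tol_streak` consecutive accepted improvements below
#' `tol`.
#'
#' @param data A [csd()] object or a dataset from [simulate_csd_dataset()].
#' @param model A [cmc_model()] describing condition-specific effects and
#'   the field/mass variant.
#' @param priors A [default_priors()] object; defaults to the standard
#'   priors for the model's variant.
#' @param design A [condition_design()]; defaults to the standard 9-level
#'   contrast design when the data have 9 conditions.
#' @param control A [fit_control()] list.  With `warm_start = TRUE`
#'   (default), models with condition-specific effects are initialised from
#'   a preliminary fit of the matching null model, which makes the ascent
#'   from the prior means much more reliable on multimodal objectives.
#' @param init Optional named initial deviations (defaults to the prior
#'   means, i.e. zero; overrides the warm start).
#' @return An object of class `"cmcfit"` with elements `mu` (posterior mean
#'   deviations), `C` (posterior covariance), `lambda`, `F` (free energy),
#'   `F_trace`, `converged`, `iterations`, and the model/prior/design/grid
#'   context.  Methods: [print.cmcfit()], [summary.cmcfit()],
#'   [coef.cmcfit()], `vcov`, [predict.cmcfit()], [residuals.cmcfit()],
#'   [plot.cmcfit()], [simulate.cmcfit()].
#' @seealso [compare_models()] for Bayesian model comparison across fits.
#' @export
fit_csd <- function(data, model = cmc_model(), priors = NULL, design = NULL,
                    control = fit_control(), init = NULL) {
  if (inherits(data, "cmc_dataset")) data <- data$csd
  validate_csd(data)
  n_cond <- length(data$conditions)
  if (is.null(design)) {
    if (n_cond == 9L) design <- condition_design()
    else stop("supply a 'design' matching the ", n_cond, " data conditions")
  }
  if (length(design$covariate) != n_cond)
    stop("design has ", length(design$covariate), " conditions, data have ",
         n_cond)
  if (is.null(priors))
    priors <- default_priors(variant = model$variant)
  if (model$variant != attr(priors, "variant"))
    stop("priors were built for the '", attr(priors, "variant"),
         "' variant but the model is '", model$variant, "'")
  grid <- spectral_grid(data$freqs, n_k = control$n_k,
                        patch_length = attr(priors, "conn")$patch_length)

  y <- vectorise_csd(data)
  w <- if (control$weighting == "level") .level_weights(data) else
    rep(1, length(y))
  y <- y / w
  n <- length(y)
  nm <- packed_names(priors, model)
  p <- length(nm)
  pv <- c(priors$var[priors$free],
          rep(model$beta_var, length(model$modulated)))
  names(pv) <- nm
  Pp <- diag(1 / pv, p)
  predictor_raw <- .make_predictor(model, priors, design, grid)
  predictor <- function(x) predictor_raw(x) / w

  if (is.null(init) && control$warm_start && length(model$modulated)) {
    ctl0 <- control
    ctl0$warm_start <- FALSE
    ctl0$max_iter <- min(control$max_iter, 64L)
    null_model <- cmc_model(variant = model$variant,
                            beta_var = model$beta_var)
    stage1 <- fit_csd(data, model = null_model, priors = priors,
                      design = design, control = ctl0)
    init <- stage1$mu
  }
  mu <- if (is.null(init)) setNames(numeric(p), nm) else
    pack_params(init, priors, model)
  # noise-precision groups: one shared log-precision, or one per condition
  grp <- if (control$lambda_per_condition)
    rep(seq_len(n_cond), each = n %/% n_cond) else rep(1L, n)
  G <- max(grp)
  n_g <- tabulate(grp, G)
  lam_bar <- -log(max(var(y), 1e-300))
  lam_var <- control$lambda_hyper_var
  lambda <- rep(lam_bar, G)
  if (!is.null(control$lambda_fixed)) {
    lam_bar <- control$lambda_fixed
    lambda <- rep(lam_bar, G)
    lam_var <- Inf                        # drop the hyperprior term
  }
  pred <- predictor(mu)
  if (!all(is.finite(pred)))
    stop("non-finite prediction at the initial parameters")

  F_trace <- numeric(0)
  tau <- control$init_damping
  streak <- 0L
  converged <- FALSE
  iter <- 0L
  F_cur <- -Inf
  while (iter < control$max_iter) {
    iter <- iter + 1L
    J <- .fd_jacobian(predictor, mu, pred, control$fd_step)
    JtJ_g <- lapply(seq_len(G), function(g)
      crossprod(J[grp == g, , drop = FALSE]))
    JtJ <- Reduce(`+`, JtJ_g)
    e <- y - pred
    Hfun <- function(lam) {
      H <- Pp
      for (g in seq_len(G)) H <- H + exp(lam[g]) * JtJ_g[[g]]
      H
    }
    # Newton updates of the noise log-precisions at fixed mu.  The total
    # increase per outer iteration is capped so the effective likelihood
    # sharpens gradually (graduated precision) when requested.
    lam0 <- lambda
    n_lam_it <- if (is.null(control$lambda_fixed)) 8L else 0L
    for (it in seq_len(n_lam_it)) {
      C <- .safe_solve(Hfun(lambda))
      mx <- 0
      for (g in seq_len(G)) {
        S <- sum(e[grp == g]^2) + sum(JtJ_g[[g]] * C)
        g1 <- n_g[g] / 2 - exp(lambda[g]) / 2 * S -
          (lambda[g] - lam_bar) / lam_var
        h1 <- -exp(lambda[g]) / 2 * S - 1 / lam_var
        step <- max(min(-g1 / h1, 4), -4)
        lambda[g] <- min(lambda[g] + step, lam0[g] + control$lambda_step)
        mx <- max(mx, abs(step))
      }
      if (mx < 1e-6) break
    }
    H <- Hfun(lambda)
    C <- .safe_solve(H)
    F_cur <- laplace_free_energy(y, pred, J, mu, C, lambda, pv,
                                 lam_bar, lam_var, groups = grp)
    if (control$verbose)
      message(sprintf("iter %3d  F = %.4f  tau = %.2g", iter, F_cur, tau))
    gvec <- crossprod(J, exp(lambda)[grp] * e) - mu / pv
    accepted <- FALSE
    dF <- 0
    for (inner in 1:8) {
      Hd <- H + tau * diag(diag(H), p)
      dmu <- drop(.safe_solve(Hd) %*% gvec)
      mu_new <- mu + dmu
      pred_new <- predictor(mu_new)
      if (all(is.finite(pred_new))) {
        F_new <- laplace_free_energy(y, pred_new, J, mu_new, C, lambda, pv,
                                     lam_bar, lam_var, groups = grp)
        if (is.finite(F_new) && F_new > F_cur) {
          dF <- F_new - F_cur
          mu <- mu_new
          pred <- pred_new
          F_cur <- F_new
          tau <- max(tau / 2, 1e-8)
          accepted <- TRUE
          break
        }
        if (is.finite(F_new) &&
            F_new >= F_cur - 1e-8 * max(1, abs(F_cur))) {
          # flat step at a stationary point: converging, do not move
          dF <- 0
          tau <- max(tau / 2, 1e-8)
          accepted <- TRUE
          break
        }
      }
      tau <- tau * 4
      if (tau > 1e10) break
    }
    F_trace <- c(F_trace, F_cur)
    if (accepted) streak <- if (dF < control$tol) streak + 1L else 0L
    if (streak >= control$tol_streak) {
      converged <- TRUE
      break
    }
    if (!accepted && tau > 1e10) break
  }
  Jf <- .fd_jacobian(predictor, mu, pred, control$fd_step)
  H <- Pp
  for (g in seq_len(G))
    H <- H + exp(lambda[g]) * crossprod(Jf[grp == g, , drop = FALSE])
  C <- .safe_solve(H)
  names(mu) <- nm
  dimnames(C) <- list(nm, nm)
  structure(list(mu = mu, C = C, lambda = lambda, F = F_cur,
                 F_trace = F_trace, converged = converged,
                 iterations = iter, model = model, priors = priors,
                 design = design, grid = grid, control = control,
                 data = data, prior_var = pv, weights = w, groups = grp,
                 lambda_prior = c(mean = lam_bar, var = lam_var)),
            class = "cmcfit")
}

.safe_solve <- function(H) {
  out <- tryCatch(chol2inv(chol(H)), error = function(e) NULL)
  if (is.null(out)) {
    jit <- 1e-8 * mean(diag(H))
    for (i in 1:8) {
      out <- tryCatch(chol2inv(chol(H + jit * diag(nrow(H)))),
                      error = function(e) NULL)
      if (!is.null(out)) break
      jit <- jit * 10
    }
    if (is.null(out)) stop("posterior precision is numerically singular")
  }
  (out + t(out)) / 2
}

#' @export
print.cmcfit <- function(x, ...) {
  cat(sprintf("Canonical-microcircuit %s model '%s'\n",
              x$model$variant, x$model$name))
  cat(sprintf("  free energy F = %.3f after %d iterations (%s)\n",
              x$F, x$iterations,
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("  %d free parameters, %d data points, log-precision %.2f\n",
              length(x$mu), length(vectorise_csd(x$data)), mean(x$lambda)))
  invisible(x)
}

#' @export
#' @describeIn fit_csd Posterior summary table (log-scale deviations with
#'   90% credible intervals and natural-unit values).
summary.cmcfit <- function(object, level = 0.90, ...) {
  sd <- sqrt(pmax(diag(object$C), 0))
  z <- qnorm(1 - (1 - level) / 2)
  pm <- setNames(object$priors$mean, object$priors$name)
  nat <- ifelse(grepl("^beta_", names(object$mu)), NA_real_,
                pm[names(object$mu)] * exp(object$mu))
  tab <- data.frame(parameter = names(object$mu), mean = unname(object$mu),
                    sd = unname(sd),
                    lower = unname(object$mu - z * sd),
                    upper = unname(object$mu + z * sd),
                    natural = unname(nat))
  out <- list(table = tab, F = object$F, model = object$model,
              converged = object$converged, level = level)
  class(out) <- "summary.cmcfit"
  out
}

#' @export
print.summary.cmcfit <- function(x, ...) {
  cat(sprintf("Model '%s': F = %.3f (%s)\n", x$model$name, x$F,
              if (x$converged) "converged" else "not converged"))
  tab <- x$table
  tab[, -1L] <- lapply(tab[, -1L], signif, digits = 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.cmcfit <- function(object, type = c("deviation", "natural"), ...) {
  type <- match.arg(type)
  if (type == "deviation") return(object$mu)
  pm <- setNames(object$priors$mean, object$priors$name)
  is_beta <- grepl("^beta_", names(object$mu))
  out <- object$mu
  out[!is_beta] <- pm[names(object$mu)[!is_beta]] * exp(object$mu[!is_beta])
  out
}

#' @export
vcov.cmcfit <- function(object, ...) object$C

#' @export
#' @describeIn fit_csd Predicted cross-spectra at the posterior mean.
predict.cmcfit <- function(object, ...) {
  pred <- .make_predictor(object$model, object$priors, object$design,
                          object$grid)(object$mu)
  devectorise_csd(pred, object$data)
}

#' @export
#' @describeIn fit_csd Observed minus predicted cross-spectra (complex
#'   array).
residuals.cmcfit <- function(object, ...) {
  object$data$values - predict(object)$values
}

#' @export
#' @describeIn fit_csd Overlay of observed (points) and predicted (lines)
#'   auto-spectra for one condition.
plot.cmcfit <- function(x, condition = 1L, ...) {
  obs <- x$data
  prd <- predict(x)
  s <- length(obs$sites)
  so <- sapply(seq_len(s), function(l) Re(obs$values[condition, , l, l]))
  sp <- sapply(seq_len(s), function(l) Re(prd$values[condition, , l, l]))
  graphics::matplot(obs$freqs, so, pch = 1, col = seq_len(s), log = "y",
                    xlab = "frequency (Hz)", ylab = "power density",
                    main = sprintf("model '%s', %s", x$model$name,
                                   obs$conditions[condition]), ...)
  graphics::matlines(prd$freqs, sp, lty = 1, col = seq_len(s))
  invisible(x)
}

#' @export
#' @describeIn fit_csd Draw finite-epoch datasets from the fitted model at
#'   the posterior mean.
simulate.cmcfit <- function(object, nsim = 1, seed = NULL,
                            n_epochs = NULL, ...) {
  if (is.null(n_epochs))
    n_epochs <- if (!is.null(object$data$n_epochs))
      object$data$n_epochs[1L] else 256L
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  pred <- predict(object)
  lapply(seq_len(nsim), function(i)
    sample_wishart_csd(pred, n_epochs = n_epochs, seed = seed + i - 1L))
}

#' Free energy of a fitted model
#'
#' Recomputes the Laplace free energy of a [fit_csd()] result from its
#' stored posterior, or returns components evaluated at supplied values.
#'
#' @param fit A `"cmcfit"` object.
#' @param mu,C,lambda Optional values overriding the stored posterior.
#' @return Scalar free energy.
#' @export
free_energy <- function(fit, mu = fit$mu, C = fit$C, lambda = fit$lambda) {
  raw <- .make_predictor(fit$model, fit$priors, fit$design, fit$grid)
  predictor <- function(x) raw(x) / fit$weights
  y <- vectorise_csd(fit$data) / fit$weights
  pred <- predictor(mu)
  J <- .fd_jacobian(predictor, mu, pred, fit$control$fd_step)
  laplace_free_energy(y, pred, J, mu, C, lambda, fit$prior_var,
                      fit$lambda_prior["mean"], fit$lambda_prior["var"],
                      groups = fit$groups)
}
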