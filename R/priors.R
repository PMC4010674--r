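#' Experimental condition design
#'
#' The contrast covariate entering condition-specific parameter modulation.
#' With linear coding the covariate is the printed contrast percentage
#' divided by 100; with log coding (each non-zero contrast step roughly
#' doubling the light intensity) it is a log-intensity score rescaled to
#' `[0, 1]`.
#'
#' @param contrasts Contrast levels as printed percentages.
#' @param coding `"linear"` (default) or `"log"`.
#' @return An object of class `"condition_design"` with `contrasts`,
#'   `covariate` `u`, and condition labels.
#' @export
condition_design <- function(contrasts = c(0, 5, 10, 16, 23, 32, 44, 60, 82),
                             coding = c("linear", "log")) {
  coding <- match.arg(coding)
  if (any(!is.finite(contrasts)) || any(contrasts < 0))
    stop("'contrasts' must be non-negative percentages")
  if (coding == "linear") {
    u <- contrasts / 100
  } else {
    lg <- log2(pmax(contrasts, min(contrasts[contrasts > 0]) / 2))
    u <- (lg - min(lg)) / diff(range(lg))
  }
  structure(list(contrasts = contrasts, covariate = u,
                 labels = paste0(contrasts, "%"), coding = coding),
            class = "condition_design")
}

# Names of the log-scale parameters, in packing order.
.param_names <- function(n_electrodes = 8L, n_sites = 4L) {
  c(paste0("kappa", 1:4), "r",
    paste0("alpha_", .cmc_edge_table$edge),
    paste0("c_", .cmc_edge_table$edge),
    "inv_speed",
    paste0("centre_", seq_len(n_electrodes)),
    paste0("phi_", seq_len(n_electrodes)),
    paste0("gain_", seq_len(n_sites)),
    "alpha_u", "beta_u", "alpha_n", "beta_n", "alpha_c", "beta_c")
}

#' Prior specification for all model parameters
#'
#' Every scale parameter \eqn{\theta_j} consumed by the neuronal and
#' observation models is parameterised as \eqn{\theta_j = \bar\theta_j
#' e^{\vartheta_j}} with a Gaussian prior \eqn{\vartheta_j \sim N(0, v_j)} on
#' the log-scale factor.  Prior means follow the conventional tabulated
#' values (see [synaptic_params()], [default_alpha()], [default_c_decay()]);
#' log-scale variances default to 1/16 for coupling strengths, spatial
#' decays, lead-field dispersions and noise amplitudes, and 1/64 for the rate
#' constants, the conduction speed and the electrode centres.
#'
#' In the `"mass"` variant the spatial machinery collapses: spatial decays,
#' conduction speed, electrode centres and dispersions are fixed (with the
#' inverse conduction speed pinned to zero, shrinking the patch to a point)
#' and the per-site gains become free.
#'
#' @param syn,conn,sensors,noise Template parameter objects supplying prior
#'   means and structural information (montage, mixing weights, patch
#'   length).
#' @param variant `"field"` or `"mass"`.
#' @param free_sensors Logical; set `FALSE` to fix electrode centres and
#'   dispersions at their prior means (e.g. when the sensor geometry is
#'   known by design).
#' @return An object of class `"cmc_priors"`: a data frame with columns
#'   `name`, `mean`, `var`, `free`, carrying the template objects as
#'   attributes.
#' @export
default_priors <- function(syn = synaptic_params(),
                           conn = connectivity_params(),
                           sensors = sensor_model(),
                           noise = noise_params(),
                           variant = c("field", "mass"),
                           free_sensors = TRUE) {
  variant <- match.arg(variant)
  n_e <- length(sensors$centres)
  n_s <- nrow(sensors$montage)
  nm <- .param_names(n_e, n_s)
  mean <- c(syn$kappa, syn$r, conn$alpha, conn$c_decay, conn$inv_speed,
            sensors$centres, sensors$dispersions, sensors$gains,
            noise$alpha_u, noise$beta_u, noise$alpha_n, noise$beta_n,
            noise$alpha_c, noise$beta_c)
  v16 <- 1 / 16; v64 <- 1 / 64
  var <- c(rep(v64, 4L), v16, rep(v16, 10L), rep(v16, 10L), v64,
           rep(v64, n_e), rep(v16, n_e), rep(v16, n_s), rep(v16, 6L))
  free <- rep(TRUE, length(nm))
  names(mean) <- names(var) <- names(free) <- nm
  free["r"] <- FALSE                      # gain is redundant with couplings
  free[paste0("gain_", seq_len(n_s))] <- FALSE
  if (!free_sensors)
    free[c(paste0("centre_", seq_len(n_e)), paste0("phi_", seq_len(n_e)))] <- FALSE
  if (variant == "mass") {
    mean["inv_speed"] <- 0
    free[c(paste0("c_", .cmc_edge_table$edge), "inv_speed",
           paste0("centre_", seq_len(n_e)),
           paste0("phi_", seq_len(n_e)))] <- FALSE
    free[paste0("gain_", seq_len(n_s))] <- TRUE
  }
  tab <- data.frame(name = nm, mean = unname(mean), var = unname(var),
                    free = unname(free), stringsAsFactors = FALSE)
  structure(tab, class = c("cmc_priors", "data.frame"),
            variant = variant, sensors = sensors, noise = noise,
            syn = syn, conn = conn,
            n_electrodes = n_e, n_sites = n_s)
}

#' Candidate models of condition-specific effects
#'
#' A model is defined by which parameter subsets are allowed to change
#' (log-linearly) with the condition covariate: `G` — the recurrent gain of
#' the pyramidal populations (alpha_a33, alpha_a44); `L` — the strengths of
#' the six between-population couplings; `E` — the spatial extents (all ten
#' decay parameters).  Each modulated parameter `j` gains a free sensitivity
#' \eqn{\beta_j} (zero-mean prior) so that
#' \eqn{\theta_j(c) = \bar\theta_j \exp(\vartheta_j + \beta_j u_c)}.
#'
#' @param G,L,E Logical factor switches.
#' @param variant `"field"` or `"mass"` (see [mass_restriction()]).
#' @param id Optional model number.
#' @param beta_var Prior variance of the sensitivities.
#' @return An object of class `"cmc_model"`.
#' @export
cmc_model <- function(G = FALSE, L = FALSE, E = FALSE,
                      variant = c("field", "mass"), id = NULL,
                      beta_var = 1 / 16) {
  variant <- match.arg(variant)
  mod <- character(0)
  if (G) mod <- c(mod, paste0("alpha_", c("a33", "a44")))
  if (L) mod <- c(mod, paste0("alpha_", c("a14", "a12", "a21", "a23",
                                          "a41", "a32")))
  if (E) mod <- c(mod, paste0("c_", .cmc_edge_table$edge))
  structure(list(G = G, L = L, E = E, modulated = mod,
                 null = !any(G, L, E), variant = variant, id = id,
                 beta_var = beta_var,
                 name = paste0(if (G) "G", if (L) "L", if (E) "E",
                               if (!any(G, L, E)) "null",
                               if (variant == "mass") "-mass")),
            class = "cmc_model")
}

#' @export
print.cmc_model <- function(x, ...) {
  cat(sprintf("CMC %s model '%s'%s: %d modulated parameter(s)\n",
              x$variant, x$name,
              if (!is.null(x$id)) paste0(" (model ", x$id, ")") else "",
              length(x$modulated)))
  if (length(x$modulated))
    cat("  ", paste(x$modulated, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Factorial model space over condition-specific effects
#'
#' The \eqn{2^3} factorial over the G, L and E factors: models 1-3 are the
#' single factors, 4 combines gain and extent, 5 couplings and extent, 6
#' gain and couplings, 7 all three, and 8 is the null model with no
#' condition-specific effects (flagged `null`).
#'
#' @param variant `"field"` or `"mass"` applied to every model.
#' @return A list of 8 [cmc_model()] objects.
#' @export
model_space <- function(variant = "field") {
  fac <- list(c(TRUE, FALSE, FALSE), c(FALSE, TRUE, FALSE),
              c(FALSE, FALSE, TRUE), c(TRUE, FALSE, TRUE),
              c(FALSE, TRUE, TRUE), c(TRUE, TRUE, FALSE),
              c(TRUE, TRUE, TRUE), c(FALSE, FALSE, FALSE))
  lapply(seq_along(fac), function(i)
    cmc_model(fac[[i]][1L], fac[[i]][2L], fac[[i]][3L],
              variant = variant, id = i))
}

#' Neural-mass restriction of a model
#'
#' Returns the same condition-effect model evaluated as a point source: only
#' the zero-wavenumber mode contributes, the conduction delay is removed and
#' the spatial parameters are fixed rather than free (see [default_priors()]
#' and [predict_csd()]).
#'
#' @param model A [cmc_model()].
#' @return The model with `variant = "mass"`.
#' @export
mass_restriction <- function(model) {
  cmc_model(model$G, model$L, model$E, variant = "mass", id = model$id,
            beta_var = model$beta_var)
}

#' Pack and unpack log-scale parameter deviations
#'
#' `pack_params()` flattens named deviations (and, when a model with
#' condition effects is supplied, sensitivities named `beta_<parameter>`)
#' into the packed vector over free parameters used by the inversion;
#' missing entries are zero.  `unpack_params()` inverts the packing and
#' materialises the natural-unit parameter objects
#' \eqn{\theta = \bar\theta e^{\vartheta}}.
#'
#' @param dev Named numeric vector of log-scale deviations (and
#'   `beta_<name>` sensitivities).
#' @param priors A [default_priors()] object.
#' @param model A [cmc_model()]; its modulated set determines which
#'   sensitivity entries exist.
#' @return `pack_params()`: a named numeric vector. `unpack_params()`: a
#'   list with `syn`, `conn`, `sensors`, `noise`, `dev` (full named
#'   deviation vector) and `beta`.
#' @export
pack_params <- function(dev = numeric(0), priors, model = cmc_model()) {
  nm <- packed_names(priors, model)
  out <- setNames(numeric(length(nm)), nm)
  if (length(dev)) {
    bad <- setdiff(names(dev), c(priors$name, .beta_names(model)))
    if (length(bad))
      stop("unknown parameter name(s): ", paste(bad, collapse = ", "))
    keep <- intersect(names(dev), nm)
    out[keep] <- dev[keep]
    dropped <- setdiff(names(dev), nm)
    dropped <- dropped[dev[dropped] != 0]
    if (length(dropped))
      stop("deviation supplied for fixed parameter(s): ",
           paste(dropped, collapse = ", "))
  }
  out
}

#' @rdname pack_params
#' @export
packed_names <- function(priors, model = cmc_model()) {
  c(priors$name[priors$free], .beta_names(model))
}

.beta_names <- function(model) {
  if (length(model$modulated)) paste0("beta_", model$modulated)
  else character(0)
}

#' @rdname pack_params
#' @param packed Packed numeric vector as produced by `pack_params()`.
#' @export
unpack_params <- function(packed, priors, model = cmc_model()) {
  nm <- packed_names(priors, model)
  if (length(packed) != length(nm))
    stop("packed vector has length ", length(packed), ", expected ",
         length(nm))
  names(packed) <- nm
  dev <- setNames(numeric(nrow(priors)), priors$name)
  free_nm <- priors$name[priors$free]
  dev[free_nm] <- packed[free_nm]
  beta <- packed[setdiff(nm, free_nm)]
  names(beta) <- sub("^beta_", "", names(beta))
  c(.materialise(dev, priors), list(dev = dev, beta = beta))
}

# Build natural-unit parameter objects from a full deviation vector.
.materialise <- function(dev, priors) {
  mean <- setNames(priors$mean, priors$name)
  th <- mean * exp(dev)
  sens0 <- attr(priors, "sensors")
  noise0 <- attr(priors, "noise")
  n_e <- attr(priors, "n_electrodes")
  n_s <- attr(priors, "n_sites")
  en <- .cmc_edge_table$edge
  syn <- structure(list(kappa = unname(th[paste0("kappa", 1:4)]),
                        r = unname(th[["r"]]),
                        eta = attr(priors, "syn")$eta),
                   class = "synaptic_params")
  conn <- structure(list(alpha = setNames(unname(th[paste0("alpha_", en)]), en),
                         c_decay = setNames(unname(th[paste0("c_", en)]), en),
                         inv_speed = unname(th[["inv_speed"]]),
                         patch_length = attr(priors, "conn")$patch_length),
                    class = "connectivity_params")
  pl <- conn$patch_length
  sensors <- structure(list(
    centres = unname(th[paste0("centre_", seq_len(n_e))]) %% pl,
    dispersions = unname(th[paste0("phi_", seq_len(n_e))]),
    montage = sens0$montage, mix = sens0$mix,
    gains = unname(th[paste0("gain_", seq_len(n_s))]),
    patch_length = pl), class = "sensor_model")
  noise <- structure(list(alpha_u = unname(th[["alpha_u"]]),
                          beta_u = unname(th[["beta_u"]]),
                          alpha_n = unname(th[["alpha_n"]]),
                          beta_n = unname(th[["beta_n"]]),
                          alpha_c = unname(th[["alpha_c"]]),
                          beta_c = unname(th[["beta_c"]]),
                          exponent = noise0$exponent),
                     class = "noise_params")
  list(syn = syn, conn = conn, sensors = sensors, noise = noise)
}

#' Condition-specific parameters under a model of contrast effects
#'
#' For every parameter `j` in the model's modulated set, the log-scale factor
#' is shifted by \eqn{\beta_j u_c} for condition `c`; unmodulated parameters
#' are identical across conditions.
#'
#' @param packed Packed parameter vector (deviations and sensitivities).
#' @param model A [cmc_model()].
#' @param design A [condition_design()].
#' @param condition Condition index into the design.
#' @param priors A [default_priors()] object.
#' @return As [unpack_params()]: natural-unit parameter objects for the
#'   requested condition.
#' @export
apply_condition_effects <- function(packed, model, design, condition,
                                    priors) {
  condition <- as.integer(condition)
  if (condition < 1L || condition > length(design$covariate))
    stop("condition ", condition, " not in the design")
  up <- unpack_params(packed, priors, model)
  if (!length(up$beta) || design$covariate[condition] == 0)
    return(up)
  dev <- up$dev
  dev[names(up$beta)] <- dev[names(up$beta)] +
    up$beta * design$covariate[condition]
  c(.materialise(dev, priors), list(dev = dev, beta = up$beta))
}
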