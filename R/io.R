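#' Read and write the cross-spectral container
#'
#' Cross-spectral data are stored in a single versioned JSON document
#' holding the frequency grid, condition and site labels, optional epoch
#' counts and the real and imaginary value arrays at full precision.  The
#' same layout is used everywhere (synthetic datasets, estimates, model
#' predictions).
#'
#' @param x A [csd()] object.
#' @param path File path (`.json`).
#' @return `read_csd()` returns a [csd()]; `write_csd()` returns `path`
#'   invisibly.
#' @export
write_csd <- function(x, path) {
  validate_csd(x)
  doc <- list(format = "cmcfield-csd", version = 1L,
              freqs = x$freqs, conditions = x$conditions, sites = x$sites,
              n_epochs = x$n_epochs, dim = dim(x$values),
              re = as.numeric(Re(x$values)), im = as.numeric(Im(x$values)))
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = FALSE,
                       null = "null")
  invisible(path)
}

#' @rdname write_csd
#' @export
read_csd <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "cmcfield-csd"))
    stop("not a cmcfield cross-spectral container: ", path)
  v <- array(complex(real = doc$re, imaginary = doc$im), doc$dim)
  csd(v, doc$freqs, doc$conditions, doc$sites,
      n_epochs = if (length(doc$n_epochs)) doc$n_epochs else NULL)
}

#' Export cross-spectra as a long-format CSV table
#'
#' One row per (condition, frequency, site pair) with real and imaginary
#' parts — a plain-text view for inspection in other tools.
#'
#' @inheritParams write_csd
#' @export
csd_to_csv <- function(x, path) {
  validate_csd(x)
  d <- dim(x$values)
  g <- expand.grid(site_j = x$sites, site_i = x$sites,
                   freq = x$freqs, condition = x$conditions,
                   stringsAsFactors = FALSE)
  vv <- aperm(x$values, c(4L, 3L, 2L, 1L))
  out <- data.frame(condition = g$condition, freq = g$freq,
                    site_i = g$site_i, site_j = g$site_j,
                    re = as.numeric(Re(vv)), im = as.numeric(Im(vv)))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

# ---- run configuration ----------------------------------------------------

.config_schema <- list(
  seed = "integer", outdir = "character",
  grid = list(fmin = "numeric", fmax = "numeric", n_freq = "integer",
              n_k = "integer"),
  conditions = "numeric", n_epochs = "integer",
  model = list(id = "integer", variant = "character"),
  inversion = list(max_iter = "integer", tol = "numeric",
                   tol_streak = "integer", lambda_hyper_var = "numeric"),
  truth = list(dev = "named", beta = "named"),
  priors = list(alpha = "named", c_decay = "named", free_sensors = "logical")
)

#' Load and validate a run configuration
#'
#' Configurations are YAML documents; unknown keys are rejected so typos
#' fail loudly.  See the packaged example under
#' `system.file("extdata", "example_config.yaml", package = "cmcfield")`.
#'
#' @param path Path to a YAML file, or a list.
#' @return The validated configuration list with defaults filled in.
#' @export
run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (!is.list(cfg)) stop("configuration must be a mapping")
  .check_keys(cfg, .config_schema, "config")
  defaults <- list(seed = 1L, outdir = "cmcfield-run",
                   grid = list(fmin = 4, fmax = 90, n_freq = 24L, n_k = 32L),
                   conditions = c(0, 5, 10, 16, 23, 32, 44, 60, 82),
                   n_epochs = 256L,
                   model = list(id = 7L, variant = "field"),
                   inversion = list())
  cfg <- modifyList(defaults, cfg)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

.check_keys <- function(x, schema, where) {
  unknown <- setdiff(names(x), names(schema))
  if (length(unknown))
    stop("unknown configuration key(s) under '", where, "': ",
         paste(unknown, collapse = ", "))
  for (nm in names(x)) {
    sc <- schema[[nm]]
    if (is.list(sc) && !identical(sc, "named"))
      .check_keys(x[[nm]], sc, paste(where, nm, sep = "."))
  }
  invisible(TRUE)
}

# Resolve config pieces into package objects.
.config_objects <- function(cfg) {
  freqs <- seq(cfg$grid$fmin, cfg$grid$fmax, length.out = cfg$grid$n_freq)
  design <- condition_design(cfg$conditions)
  conn <- connectivity_params(
    alpha = .merge_named(default_alpha(), cfg$priors$alpha),
    c_decay = .merge_named(default_c_decay(), cfg$priors$c_decay))
  variant <- cfg$model$variant
  priors <- default_priors(conn = conn, variant = variant,
                           free_sensors = !isFALSE(cfg$priors$free_sensors))
  model <- model_space(variant = variant)[[cfg$model$id]]
  truth <- cmc_truth()
  if (!is.null(cfg$truth$dev)) truth$dev <- unlist(cfg$truth$dev)
  if (!is.null(cfg$truth$beta)) truth$beta <- unlist(cfg$truth$beta)
  # the generating truth may only modulate what the generating model allows
  truth$beta <- truth$beta[names(truth$beta) %in% model$modulated]
  control <- do.call(fit_control,
                     c(cfg$inversion, list(n_k = cfg$grid$n_k)))
  list(freqs = freqs, design = design, priors = priors, model = model,
       truth = truth, control = control)
}

.merge_named <- function(base, override) {
  if (is.null(override)) return(base)
  override <- unlist(override)
  bad <- setdiff(names(override), names(base))
  if (length(bad)) stop("unknown parameter override: ",
                        paste(bad, collapse = ", "))
  base[names(override)] <- override
  base
}

# Archive the fully resolved configuration (and the coupling-strength
# mapping, which is ambiguous in the published table) with every run.
.archive_run <- function(cfg, obj, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  resolved <- cfg
  resolved$resolved_alpha_mapping <- as.list(attr(obj$priors, "conn")$alpha)
  jsonlite::write_json(resolved, file.path(outdir, "config_resolved.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  msg <- sprintf(
    "[%s] seed=%d model=%s variant=%s alpha=[%s]",
    format(Sys.time(), "%Y-%m-%d %H:%M:%S"), cfg$seed, obj$model$name,
    obj$model$variant,
    paste(sprintf("%s=%g", names(attr(obj$priors, "conn")$alpha),
                  attr(obj$priors, "conn")$alpha), collapse = " "))
  cat(msg, "\n", file = file.path(outdir, "run.log"), append = TRUE)
  invisible(outdir)
}
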