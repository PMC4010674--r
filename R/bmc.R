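#' Fixed-effects Bayesian model comparison
#'
#' Compares fitted models by their variational free energies (approximate
#' log evidences).  Because every model is fitted jointly to all conditions,
#' the joint likelihood factorises over conditions and a single free energy
#' per model plays the role of the summed per-condition log evidence.
#' Posterior model probabilities assume a uniform prior over the models
#' compared: \eqn{p(m|y) \propto e^{F_m}}.  A log-evidence difference of 3
#' corresponds to a likelihood ratio of about 20:1.
#'
#' @param fits A list of [fit_csd()] results fitted to the same data.
#' @param names Optional model labels (default: each model's name).
#' @return An object of class `"cmcbmc"`: a data frame with columns
#'   `model`, `F`, `rel_logev` (free energy relative to the best model) and
#'   `posterior` (posterior model probability).
#' @export
compare_models <- function(fits, names = NULL) {
  if (!length(fits)) stop("no fitted models to compare")
  if (inherits(fits, "cmcfit")) fits <- list(fits)
  ok <- vapply(fits, inherits, logical(1L), what = "cmcfit")
  if (!all(ok)) stop("'fits' must be a list of cmcfit objects")
  if (length(fits) > 1L) {
    y0 <- vectorise_csd(fits[[1L]]$data)
    same <- vapply(fits[-1L], function(f)
      isTRUE(all.equal(vectorise_csd(f$data), y0)), logical(1L))
    if (!all(same))
      stop("models were not fitted to the same data")
  }
  if (is.null(names))
    names <- vapply(fits, function(f) f$model$name, character(1L))
  Fv <- vapply(fits, function(f) f$F, numeric(1L))
  rel <- Fv - max(Fv)
  post <- exp(rel) / sum(exp(rel))
  out <- data.frame(model = names, F = Fv, rel_logev = rel,
                    posterior = post, stringsAsFactors = FALSE)
  structure(out, class = c("cmcbmc", "data.frame"))
}

#' @export
print.cmcbmc <- function(x, ...) {
  cat("Fixed-effects Bayesian model comparison\n")
  tab <- as.data.frame(x)
  tab$F <- round(tab$F, 2)
  tab$rel_logev <- round(tab$rel_logev, 2)
  tab$posterior <- signif(tab$posterior, 3)
  print(tab, row.names = FALSE)
  best <- tab$model[which.max(x$F)]
  cat(sprintf("Best model: '%s'", best))
  srt <- sort(x$F, decreasing = TRUE)
  if (length(srt) > 1L) {
    d <- srt[1L] - srt[2L]
    cat(sprintf(" (log-evidence margin %.2f, likelihood ratio %.3g:1)",
                d, exp(d)))
  }
  cat("\n")
  invisible(x)
}

#' @export
plot.cmcbmc <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(x$rel_logev - min(x$rel_logev), names.arg = x$model,
                    ylab = "relative log evidence", las = 2, ...)
  graphics::barplot(x$posterior, names.arg = x$model,
                    ylab = "posterior probability", ylim = c(0, 1),
                    las = 2, ...)
  invisible(x)
}
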