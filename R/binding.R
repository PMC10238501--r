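# One-site, ligand-depletion-corrected fluorescence-anisotropy binding
# model: titration simulator and dissociation-constant fitter.

#' Bound fraction under the one-site binding model
#'
#' Exact solution of the single-site mass balance for probe (labeled DNA)
#' at total concentration `T` titrated with protein at total concentration
#' `P`:
#' `b = ((P + T + Kd) - sqrt((P + T + Kd)^2 - 4 P T)) / (2 T)`.
#' Because the probe (2 nM) is comparable to the dissociation constant
#' (~6 nM) in this assay, the depletion-corrected quadratic is the
#' default; the hyperbolic limit `P / (P + Kd)` is available via
#' `model = "hyperbola"` and is recovered exactly as `T/Kd -> 0`.
#'
#' @param P Titrant (protein) concentration(s), nM, >= 0.
#' @param T Probe concentration, nM, > 0 (default 2, the assay's probe).
#' @param Kd Dissociation constant, nM, > 0.
#' @param model `"depletion"` (exact quadratic) or `"hyperbola"`.
#' @return Bound fraction(s) in `[0, min(1, P/T)]`.
#' @examples
#' boundFraction(6.2, T = 2, Kd = 6.4)  # ~0.45
#' @export
boundFraction <- function(P, T = 2, Kd, model = c("depletion", "hyperbola")) {
  model <- match.arg(model)
  stopifnot(all(P >= 0), T > 0, all(Kd > 0))
  if (model == "hyperbola") return(P / (P + Kd))
  s <- P + T + Kd
  disc <- pmax(s^2 - 4 * P * T, 0)  # numerical guard; >= 0 analytically
  (s - sqrt(disc)) / (2 * T)
}

#' Model anisotropy of a titration point
#'
#' `r = rFree + (rBound - rFree) * boundFraction(P, T, Kd)`: the measured
#' anisotropy interpolates between the free-probe and bound-probe values
#' with the bound fraction.
#'
#' @inheritParams boundFraction
#' @param rFree Anisotropy of the free probe.
#' @param rBound Anisotropy of the fully bound probe.
#' @return Model anisotropy value(s).
#' @export
modelAnisotropy <- function(P, Kd, rFree, rBound, T = 2,
                            model = c("depletion", "hyperbola")) {
  rFree + (rBound - rFree) * boundFraction(P, T, Kd, match.arg(model))
}

#' Default titration concentration grid
#'
#' Doubling series starting at 6.2 nM (the assay's first titration point)
#' continued until the bound fraction exceeds `saturation` (the titration
#' was carried on "until the anisotropy values are saturated"), preceded
#' by the probe-only baseline point P = 0 that every titration measures
#' before protein is added.
#'
#' @param Kd Assumed dissociation constant (nM) used to locate saturation.
#' @param T Probe concentration (nM).
#' @param start First titrant concentration (nM).
#' @param saturation Bound fraction at which the series stops.
#' @param includeBlank Include the probe-only P = 0 point.
#' @return Ascending numeric vector of concentrations (nM).
#' @examples
#' titrationGrid(6.4)
#' @export
titrationGrid <- function(Kd, T = 2, start = 6.2, saturation = 0.98,
                          includeBlank = TRUE) {
  P <- start
  while (boundFraction(P[length(P)], T, Kd) <= saturation)
    P <- c(P, 2 * P[length(P)])
  if (includeBlank) P <- c(0, P)
  P
}

#' @describeIn TitrationCurve-class Constructor.
#' @param P_nM Titrant concentrations (nM).
#' @param anisotropy Measured anisotropy, one per concentration.
#' @param replicate Replicate labels (default 1).
#' @param probe_nM Probe concentration T (nM, default 2).
#' @param condition,variant Pass-through labels.
#' @export
TitrationCurve <- function(P_nM, anisotropy, replicate = 1L, probe_nM = 2,
                           condition = "dark", variant = "") {
  new("TitrationCurve",
      data = data.frame(P_nM = P_nM, anisotropy = anisotropy,
                        replicate = rep(replicate, length.out = length(P_nM))),
      probe_nM = probe_nM, condition = condition, variant = variant)
}

#' Simulate a noisy anisotropy titration
#'
#' Model anisotropies on a concentration grid plus i.i.d. Gaussian noise;
#' the synthetic stand-in for the fluorimeter.
#'
#' @param Kd Ground-truth dissociation constant (nM).
#' @param rFree,rBound Free/bound anisotropies (defaults 0.10 / 0.25,
#'   typical for a rhodamine-labeled 27-bp probe).
#' @param T Probe concentration (nM, default 2).
#' @param P Concentration grid (default [titrationGrid()] at the true
#'   `Kd`).
#' @param noiseSd Gaussian noise s.d. on anisotropy (default 0.005).
#' @param nReplicates Technical replicates (default 2, as measured per
#'   condition).
#' @param seed Optional integer seed.
#' @param condition,variant Pass-through labels.
#' @return A [TitrationCurve-class].
#' @examples
#' simulateTitration(6.4, seed = 1)
#' @export
simulateTitration <- function(Kd, rFree = 0.10, rBound = 0.25, T = 2,
                              P = titrationGrid(Kd, T), noiseSd = 0.005,
                              nReplicates = 2, seed = NULL,
                              condition = "dark", variant = "") {
  stopifnot(noiseSd >= 0, nReplicates >= 1)
  mu <- modelAnisotropy(P, Kd, rFree, rBound, T)
  .withSeed(seed, {
    r <- rep(mu, nReplicates) +
      stats::rnorm(length(P) * nReplicates, 0, noiseSd)
    TitrationCurve(rep(P, nReplicates), r,
                   replicate = rep(seq_len(nReplicates), each = length(P)),
                   probe_nM = T, condition = condition, variant = variant)
  })
}

#' Fit a titration curve to the one-site binding model
#'
#' Nonlinear least squares over `(Kd, rFree, rBound)` with positivity of
#' `Kd` enforced by fitting `log(Kd)`. Replicates are pooled. Starting
#' values are data-driven: `rFree`/`rBound` from the curve endpoints and
#' `Kd` from the half-rise concentration, so the fit is insensitive to
#' initial guesses. Standard errors come from the curvature at the optimum
#' (the `Kd` error by the delta method). Non-convergence or a boundary
#' `Kd` is flagged in the `converged` slot, not silently returned.
#'
#' @param curve A [TitrationCurve-class] (>= 4 distinct concentrations
#'   spanning the half-saturation point for identifiability).
#' @param model `"depletion"` (default) or `"hyperbola"`.
#' @return A [BindingFit-class].
#' @examples
#' fit <- fitTitration(simulateTitration(6.4, seed = 1))
#' bindingKd(fit)
#' @export
fitTitration <- function(curve, model = c("depletion", "hyperbola")) {
  model <- match.arg(model)
  stopifnot(is(curve, "TitrationCurve"))
  d <- curve@data
  if (length(unique(d$P_nM)) < 4)
    stop("need >= 4 distinct concentrations to fit 3 parameters")
  Tprobe <- curve@probe_nM
  agg <- tapply(d$anisotropy, d$P_nM, mean)
  Pu <- as.numeric(names(agg))
  rf0 <- agg[[which.min(Pu)]]
  rb0 <- agg[[which.max(Pu)]]
  half <- (rf0 + rb0) / 2
  kd0 <- Pu[which.min(abs(agg - half))]
  if (kd0 <= 0) kd0 <- Pu[Pu > 0][1]
  fit <- minpack.lm::nlsLM(
    anisotropy ~ rFree + (rBound - rFree) *
      boundFraction(P_nM, Tprobe, exp(logKd), model),
    data = d,
    start = list(logKd = log(kd0), rFree = rf0, rBound = rb0),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  kd <- exp(cf[["logKd"]])
  interior <- kd > 1e-4 && kd < 1e6
  conv <- isTRUE(fit$convInfo$isConv) && interior
  new("BindingFit",
      estimates = c(Kd = kd, rFree = cf[["rFree"]],
                    rBound = cf[["rBound"]]),
      se = c(Kd = kd * se[["logKd"]], rFree = se[["rFree"]],
             rBound = se[["rBound"]]),
      converged = conv, model = model,
      residSd = sqrt(sum(stats::residuals(fit)^2) /
                       max(1, nrow(d) - 3)),
      nObs = nrow(d))
}

#' @describeIn BindingFit-class Dissociation-constant accessor (nM).
#' @param x,object A `BindingFit`.
#' @export
setGeneric("bindingKd", function(x) standardGeneric("bindingKd"))

#' @rdname BindingFit-class
#' @export
setMethod("bindingKd", "BindingFit", function(x) x@estimates[["Kd"]])

setMethod("show", "BindingFit", function(object) {
  e <- object@estimates; s <- object@se
  cat(sprintf(
    "One-site binding fit (%s model, n = %d): Kd = %.3g +/- %.2g nM, rFree = %.4g, rBound = %.4g%s\n",
    object@model, object@nObs, e[["Kd"]], s[["Kd"]], e[["rFree"]],
    e[["rBound"]],
    if (object@converged) "" else "  [NOT CONVERGED]"))
})

setMethod("show", "TitrationCurve", function(object) {
  d <- object@data
  cat("TitrationCurve (", object@condition,
      if (nzchar(object@variant)) paste0(", ", object@variant), "): probe ",
      object@probe_nM, " nM, ", length(unique(d$P_nM)),
      " concentrations x ", length(unique(d$replicate)),
      " replicate(s)\n", sep = "")
})

#' Write / read a titration as tabular text
#'
#' TSV with columns `P_nM`, `anisotropy`, `replicate` and `#` metadata
#' header lines.
#'
#' @param curve A [TitrationCurve-class].
#' @param path File path.
#' @return `path` invisibly (`writeTitration`); a `TitrationCurve`
#'   (`readTitration`).
#' @export
writeTitration <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# probe_nM=", curve@probe_nM),
               paste0("# condition=", curve@condition),
               paste0("# variant=", curve@variant)), con)
  utils::write.table(curve@data, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeTitration
#' @export
readTitration <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- function(key, default) {
    m <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (length(m)) sub(paste0("^# ", key, "="), "", m[1]) else default
  }
  df <- utils::read.delim(text = lines[!grepl("^#", lines)], sep = "\t")
  new("TitrationCurve", data = df[, c("P_nM", "anisotropy", "replicate")],
      probe_nM = as.numeric(meta("probe_nM", "2")),
      condition = meta("condition", ""), variant = meta("variant", ""))
}
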