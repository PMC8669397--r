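# EMSA analysis: equilibrium bound fraction with ligand depletion, rate
# equation relaxation to steady state, and the (kd, baseline, asymptote)
# fit parametrisation with ka an arbitrary constant and Kd = kd/ka.

#' TitrationSeries: an EMSA titration
#'
#' @slot protein_concs Protein (MatP dimer) concentrations in nM.
#' @slot dna_total Total labelled DNA concentration in nM.
#' @slot responses Measured responses (bound fraction or intensity
#'   fraction), same length as `protein_concs`.
#' @exportClass TitrationSeries
setClass("TitrationSeries",
  representation(protein_concs = "numeric", dna_total = "numeric",
                 responses = "numeric"))

setValidity("TitrationSeries", function(object) {
  msgs <- character()
  if (length(object@protein_concs) != length(object@responses))
    msgs <- c(msgs, "'protein_concs' and 'responses' must have equal length")
  if (any(object@protein_concs < 0))
    msgs <- c(msgs, "concentrations must be >= 0")
  if (length(object@dna_total) != 1L || object@dna_total <= 0)
    msgs <- c(msgs, "'dna_total' must be a single positive concentration")
  if (!all(is.finite(object@responses)))
    msgs <- c(msgs, "responses must be finite")
  if (length(msgs)) msgs else TRUE
})

#' @param protein_concs,dna_total,responses See the class slots.
#' @rdname TitrationSeries-class
#' @export
TitrationSeries <- function(protein_concs, dna_total, responses) {
  new("TitrationSeries", protein_concs = as.numeric(protein_concs),
      dna_total = as.numeric(dna_total), responses = as.numeric(responses))
}

#' @export
setMethod("length", "TitrationSeries", function(x) length(x@protein_concs))

#' @export
setMethod("show", "TitrationSeries", function(object) {
  cat(sprintf("TitrationSeries: %d points, [DNA] = %g nM, [P] %g-%g nM\n",
              length(object@protein_concs), object@dna_total,
              min(object@protein_concs), max(object@protein_concs)))
})

#' @rdname TitrationSeries-class
#' @param x A `TitrationSeries`.
#' @export
titrationConcs <- function(x) x@protein_concs

#' @rdname TitrationSeries-class
#' @export
titrationResponses <- function(x) x@responses

#' Read a titration series from TSV
#'
#' Expects columns `conc_nM` and `response` (header row required).
#'
#' @param path TSV file path.
#' @param dnaTotal Total DNA concentration in nM.
#' @return A [TitrationSeries-class].
#' @export
readTitrationTSV <- function(path, dnaTotal) {
  if (!file.exists(path)) .stopf("titration file not found: %s", path)
  df <- utils::read.delim(path)
  if (!all(c("conc_nM", "response") %in% names(df)))
    .stopf("'%s' must have columns conc_nM and response", path)
  TitrationSeries(df$conc_nM, dnaTotal, df$response)
}

#' BindingFit: fitted EMSA binding parameters
#'
#' The fit is parametrised by the dissociation rate `k_d`, `baseline` and
#' `asymptote`, with the association rate `k_a` an arbitrary model constant;
#' the equilibrium dissociation constant is `K_d = k_d / k_a`, which is
#' independent of the arbitrary time domain.
#'
#' @slot k_d Dissociation rate (1/time, arbitrary time unit).
#' @slot k_a Association rate constant (1/(nM time), held fixed).
#' @slot K_d Equilibrium dissociation constant in nM (`k_d / k_a`).
#' @slot baseline,asymptote Affine response mapping of the bound fraction.
#' @slot rss Residual sum of squares of the fit.
#' @slot inverted `TRUE` when the fitted asymptote lies below the baseline.
#' @exportClass BindingFit
setClass("BindingFit",
  representation(k_d = "numeric", k_a = "numeric", K_d = "numeric",
                 baseline = "numeric", asymptote = "numeric", rss = "numeric",
                 inverted = "logical"))

setValidity("BindingFit", function(object) {
  if (object@K_d <= 0) return("'K_d' must be positive")
  if (abs(object@K_d - object@k_d / object@k_a) >
      1e-9 * max(1, object@K_d)) return("K_d must equal k_d / k_a")
  TRUE
})

#' @export
setMethod("show", "BindingFit", function(object) {
  cat(sprintf("BindingFit: K_d = %.4g nM (k_d = %.4g, k_a = %.4g)\n",
              object@K_d, object@k_d, object@k_a))
  cat(sprintf("  baseline %.4g, asymptote %.4g, rss %.4g%s\n",
              object@baseline, object@asymptote, object@rss,
              if (object@inverted) " [inverted response]" else ""))
})

#' @rdname BindingFit-class
#' @param x A `BindingFit`.
#' @export
fittedKd <- function(x) x@K_d

#' Equilibrium bound fraction with ligand depletion
#'
#' Solves the single-site binding equilibrium exactly: the bound complex
#' concentration `PD` is the root of
#' \deqn{PD^2 - (P_t + D_t + K_d) PD + P_t D_t = 0}
#' in `[0, min(P_t, D_t)]`, and the bound fraction is `PD / D_t`. At 2 nM
#' labelled DNA, depletion of free protein is not negligible relative to
#' candidate `K_d` values, so the quadratic (not the hyperbola) is the
#' default model.
#'
#' @param pTot Total protein concentration in nM (vectorised).
#' @param dTot Total DNA concentration in nM (> 0).
#' @param Kd Equilibrium dissociation constant in nM (> 0).
#' @param depletion If `FALSE`, use the no-depletion hyperbola
#'   `pTot / (pTot + Kd)` instead.
#' @return Bound fraction(s) in `[0, 1]`.
#' @examples
#' equilibriumBoundFraction(10, 2, 5) # ~0.636
#' @export
equilibriumBoundFraction <- function(pTot, dTot, Kd, depletion = TRUE) {
  if (any(pTot < 0)) .stopf("'pTot' must be >= 0")
  .assert_scalar_num(dTot, "dTot")
  .assert_scalar_num(Kd, "Kd")
  if (dTot <= 0) .stopf("'dTot' must be positive")
  if (Kd <= 0) .stopf("'Kd' must be positive")
  if (!depletion) return(pTot / (pTot + Kd))
  b <- pTot + dTot + Kd
  disc <- pmax(b^2 - 4 * pTot * dTot, 0)
  # smaller quadratic root, written in the numerically stable form
  pd <- ifelse(pTot == 0, 0, 2 * pTot * dTot / (b + sqrt(disc)))
  pmin(pmax(pd / dTot, 0), 1)
}

#' Relax the binding rate equation to steady state
#'
#' Integrates \eqn{d[PD]/dt = k_a (P_t - PD)(D_t - PD) - k_d PD} from
#' `PD(0) = 0` in an arbitrary time domain and returns the bound fraction at
#' `tEnd`. Convergence (relative change per unit time below `1e-8` at
#' `tEnd`) is checked and non-convergence is an error suggesting a larger
#' `tEnd`. At convergence the result equals [equilibriumBoundFraction()]
#' with `Kd = k_d / k_a`.
#'
#' @param pTot,dTot Total concentrations in nM.
#' @param kA,kD Association and dissociation rates (> 0), arbitrary time
#'   unit.
#' @param tEnd Integration end time; choose `kD * tEnd >> 1`.
#' @param steps Number of reported integration steps (default 400).
#' @return Bound fraction at `tEnd`.
#' @export
simulateRateEquation <- function(pTot, dTot, kA, kD, tEnd = NULL,
                                 steps = 400L) {
  for (v in c(pTot, dTot, kA, kD)) .assert_scalar_num(v, "rate arguments")
  if (kA <= 0 || kD <= 0) .stopf("rates must be positive")
  if (dTot <= 0) .stopf("'dTot' must be positive")
  if (is.null(tEnd)) {
    # the slowest relaxation rate is bounded below by kD, so kD * tEnd = 100
    # guarantees steady state in the arbitrary time domain
    tEnd <- 100 / kD
  }
  times <- seq(0, tEnd, length.out = max(2L, as.integer(steps)))
  deriv <- function(t, y, parms) {
    pd <- y[1L]
    list(kA * (pTot - pd) * (dTot - pd) - kD * pd)
  }
  sol <- deSolve::ode(y = c(PD = 0), times = times, func = deriv,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  pd_end <- sol[nrow(sol), "PD"]
  rate_end <- abs(kA * (pTot - pd_end) * (dTot - pd_end) - kD * pd_end)
  step <- tEnd / (length(times) - 1L)
  # relative change per reported step at tEnd must be negligible
  if (rate_end * step > 1e-8 * max(pd_end, dTot * 1e-3))
    .stopf("rate equation not converged at tEnd = %g (residual rate %.3g); increase tEnd", tEnd, rate_end)
  unname(pd_end / dTot)
}

#' Fit an EMSA titration with the rate-equation equilibrium model
#'
#' Least-squares fit of
#' `response = baseline + (asymptote - baseline) * f_eq(p; K_d)`, with
#' `f_eq` the depletion-aware equilibrium bound fraction and
#' `K_d = k_d / kaConst`. The association rate `kaConst` is an arbitrary
#' constant: rescaling it rescales the fitted `k_d` but leaves `K_d`
#' invariant. Optimisation is Nelder-Mead on `(log k_d, baseline,
#' asymptote)` with multi-start over `K_d` decades spanning the
#' concentration range.
#'
#' @param series A [TitrationSeries-class] with >= 5 points spanning at
#'   least a 10-fold concentration range.
#' @param kaConst Arbitrary association rate constant (> 0, default 1).
#' @param depletion Use the depletion-aware quadratic (default `TRUE`).
#' @return A [BindingFit-class].
#' @export
fitTitration <- function(series, kaConst = 1, depletion = TRUE) {
  stopifnot(is(series, "TitrationSeries"))
  .assert_scalar_num(kaConst, "kaConst")
  if (kaConst <= 0) .stopf("'kaConst' must be positive")
  p <- series@protein_concs
  y <- series@responses
  d <- series@dna_total
  if (length(p) < 5L) .stopf("at least 5 titration points are required")
  pos <- p[p > 0]
  if (length(pos) < 2L || max(pos) / min(pos) < 10)
    .stopf("titration must span at least a 10-fold concentration range")
  if (stats::var(y) < 1e-12 * max(1, mean(y)^2))
    .stopf("flat response: nothing to fit")

  rss_fun <- function(par) {
    kd <- exp(par[1L])
    f <- equilibriumBoundFraction(p, d, kd / kaConst, depletion = depletion)
    sum((y - (par[2L] + (par[3L] - par[2L]) * f))^2)
  }
  # multi-start over Kd decades covering the titrated range
  decades <- seq(floor(log10(min(pos) / 10)), ceiling(log10(max(pos) * 10)))
  best <- NULL
  for (kd0 in 10^decades * kaConst) {
    fit <- stats::optim(c(log(kd0), min(y), max(y)), rss_fun,
                        method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-12))
    # polish once from the incumbent to tighten convergence
    fit <- stats::optim(fit$par, rss_fun, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (best$convergence != 0 && best$value > 1e-10)
    .stopf("fit did not converge (optim code %d, rss %.4g)",
           best$convergence, best$value)
  kd <- exp(best$par[1L])
  new("BindingFit", k_d = kd, k_a = kaConst, K_d = kd / kaConst,
      baseline = best$par[2L], asymptote = best$par[3L], rss = best$value,
      inverted = best$par[3L] < best$par[2L])
}
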