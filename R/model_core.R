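#' Parameter set for the biphasic CICR activity model
#'
#' The activity of a ryanodine receptor channel as a function of free
#' cytoplasmic Ca2+ is modelled as the product of occupancy of a
#' high-affinity activating Ca2+ site (A-site) and vacancy of a
#' low-affinity inactivating Ca2+ site (I-site):
#' \deqn{A = A_{max} \, f_A \, (1 - f_I)}
#' where each site occupancy follows a Hill isotherm
#' \eqn{f = [Ca]^n / ([Ca]^n + K^n)}.
#'
#' All concentrations and dissociation constants are stored in mol/L;
#' pCa (\eqn{-\log_{10}} molar) is a derived view used at the interfaces.
#'
#' @param Amax Dimensionless gain on the B/Bmax scale (> 0).
#' @param KA Dissociation constant of the activating site, mol/L (> 0).
#' @param KI Dissociation constant of the inactivating site, mol/L (> 0).
#' @param nA Hill coefficient of the activating site (> 0).
#' @param nI Hill coefficient of the inactivating site (> 0).
#' @return An object of class `binding_params`.
#' @examples
#' p <- binding_params(Amax = 0.4, KA = 10^-4.79, KI = 1e-3, nA = 2, nI = 1)
#' pca50(p)
#' @export
binding_params <- function(Amax, KA, KI, nA = 2, nI = 1) {
  vals <- c(Amax = Amax, KA = KA, KI = KI, nA = nA, nI = nI)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all binding model parameters (Amax, KA, KI, nA, nI) must be finite and > 0",
         call. = FALSE)
  }
  structure(as.list(vals), class = "binding_params")
}

#' @export
print.binding_params <- function(x, ...) {
  cat(sprintf(
    "CICR binding model: Amax = %.4g, pKA = %.3f, pKI = %.3f, nA = %.2g, nI = %.2g\n",
    x$Amax, -log10(x$KA), -log10(x$KI), x$nA, x$nI))
  invisible(x)
}

#' Free Ca2+ concentration with a consistent pCa view
#'
#' @param value Free Ca2+ concentration in mol/L (> 0), or `NULL` if
#'   `pCa` is given.
#' @param pCa \eqn{-\log_{10}}(molar Ca2+); used when `value` is absent.
#' @return A `ca_conc` object holding both representations.
#' @examples
#' ca_conc(pCa = 7)$value  # 1e-7 M
#' @export
ca_conc <- function(value = NULL, pCa = NULL) {
  if (is.null(value) && is.null(pCa)) stop("give either value (mol/L) or pCa", call. = FALSE)
  if (is.null(value)) value <- 10^(-pCa)
  if (any(!is.finite(value)) || any(value <= 0)) {
    stop("free Ca2+ concentration must be finite and > 0", call. = FALSE)
  }
  structure(list(value = value, pCa = -log10(value)), class = "ca_conc")
}

.ca_value <- function(ca) {
  if (inherits(ca, "ca_conc")) ca$value else ca
}

#' Hill site-occupancy fraction
#'
#' Occupied fraction of a Ca2+ site, \eqn{[Ca]^n/([Ca]^n + K^n)}.
#' Evaluated in log space (`plogis`) so extreme pCa values neither
#' overflow nor underflow.
#'
#' @param ca Free Ca2+ in mol/L (numeric, vectorized) or a [ca_conc()].
#' @param K Dissociation constant, mol/L (> 0).
#' @param n Hill coefficient (> 0).
#' @return Fraction in \[0, 1\].
#' @examples
#' hill_fraction(1e-5, K = 1e-5, n = 2)  # 0.5 at half-saturation
#' @export
hill_fraction <- function(ca, K, n) {
  ca <- .ca_value(ca)
  if (!is.finite(K) || K <= 0) stop("K must be finite and > 0", call. = FALSE)
  if (!is.finite(n) || n <= 0) stop("n must be finite and > 0", call. = FALSE)
  if (any(!is.finite(ca)) || any(ca <= 0)) stop("ca must be finite and > 0", call. = FALSE)
  # [Ca]^n/([Ca]^n + K^n) = 1/(1 + exp(-n (ln ca - ln K)))
  stats::plogis(n * (log(ca) - log(K)))
}

#' Biphasic CICR activity
#'
#' Evaluates \eqn{A = A_{max} f_A (1 - f_I)} at one or more free Ca2+
#' concentrations. Rises with A-site occupancy at submicromolar to
#' micromolar Ca2+ and falls again as the inactivating site fills,
#' giving the bell-shaped Ca2+ dependence seen in [3H]ryanodine binding.
#'
#' @param params A [binding_params()] object.
#' @param ca Free Ca2+ in mol/L (vectorized) or a [ca_conc()].
#' @return Activity on the B/Bmax scale, in \[0, Amax\].
#' @examples
#' p <- binding_params(0.4, 10^-4.79, 1e-3)
#' cicr_activity(p, ca_conc(pCa = 5))
#' @export
cicr_activity <- function(params, ca) {
  stopifnot(inherits(params, "binding_params"))
  ca <- .ca_value(ca)
  fA <- hill_fraction(ca, params$KA, params$nA)
  fI <- hill_fraction(ca, params$KI, params$nI)
  params$Amax * fA * (1 - fI)
}

#' pCa for half-maximal activation
#'
#' By default pCa50 is the half-point of the activating fraction
#' \eqn{f_A}, i.e. \eqn{-\log_{10} K_A}. With `method = "composite"` it
#' is instead read from the ascending limb of the full biphasic curve
#' \eqn{A(Ca)}: the pCa where A first reaches half of its maximum.
#'
#' @param params A [binding_params()] object.
#' @param method `"KA"` (default) or `"composite"`.
#' @return pCa50, dimensionless.
#' @export
pca50 <- function(params, method = c("KA", "composite")) {
  stopifnot(inherits(params, "binding_params"))
  method <- match.arg(method)
  if (method == "KA") return(-log10(params$KA))
  # composite: locate the maximum of A on a fine pCa grid, then solve
  # A = Amax_observed/2 on the ascending (low-Ca) side
  grid <- seq(12, 1, by = -0.001)
  a <- cicr_activity(params, 10^(-grid))
  imax <- which.max(a)
  half <- a[imax] / 2
  f <- function(pca) cicr_activity(params, 10^(-pca)) - half
  stats::uniroot(f, lower = grid[imax], upper = 12, tol = 1e-10)$root
}

#' Modelled resting channel activity
#'
#' Evaluates the biphasic activity at resting cytoplasmic Ca2+
#' (pCa 7, i.e. 100 nM, by default), the extrapolation used to judge how
#' leaky a channel variant is in an unstimulated cell.
#'
#' @param params A [binding_params()] object.
#' @param pCa Resting pCa (default 7).
#' @return Activity on the B/Bmax scale.
#' @export
resting_activity <- function(params, pCa = 7) {
  cicr_activity(params, 10^(-pCa))
}

#' Fold-change in resting activity of a variant relative to wild type
#'
#' Ratio of modelled activities at resting Ca2+. For a variant whose
#' activating-site affinity is increased r-fold with all other
#' parameters shared, the ratio approaches \eqn{r^{n_A}} in the low-Ca
#' limit.
#'
#' @param wt,mut [binding_params()] for the reference and the variant.
#' @param pCa Resting pCa (default 7).
#' @return Dimensionless fold-change mut/wt.
#' @export
fold_change_at_rest <- function(wt, mut, pCa = 7) {
  a_wt <- resting_activity(wt, pCa)
  a_mut <- resting_activity(mut, pCa)
  if (a_wt <= 0 || !is.finite(a_wt)) {
    stop("reference resting activity is zero; fold-change undefined", call. = FALSE)
  }
  a_mut / a_wt
}

#' Serialize model parameters to a flat JSON record
#'
#' Files use pK notation (`pKA = -log10(KA)`); mol/L is used internally.
#'
#' @param params A [binding_params()] object.
#' @param path File to write; if `NULL`, the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
params_to_json <- function(params, path = NULL) {
  stopifnot(inherits(params, "binding_params"))
  rec <- list(Amax = params$Amax, pKA = -log10(params$KA),
              pKI = -log10(params$KI), nA = params$nA, nI = params$nI)
  txt <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read model parameters from a flat JSON record
#'
#' @param path File, JSON string, or connection accepted by
#'   [jsonlite::fromJSON()].
#' @return A [binding_params()] object.
#' @export
params_from_json <- function(path) {
  rec <- jsonlite::fromJSON(path)
  need <- c("Amax", "pKA", "pKI", "nA", "nI")
  if (!all(need %in% names(rec))) {
    stop("parameter record must contain fields: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  binding_params(Amax = rec$Amax, KA = 10^(-rec$pKA), KI = 10^(-rec$pKI),
                 nA = rec$nA, nI = rec$nI)
}
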