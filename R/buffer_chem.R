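#' Chelator specification
#'
#' Describes one Ca2+ chelator (EGTA, BAPTA, ...) by its total
#' concentration and binding constants. Two modes are supported:
#' apparent constants measured at the assay pH/ionic conditions (the
#' default working mode — the constants file is the boundary of this
#' package), or absolute constants plus stepwise proton pKa values from
#' which an apparent Kd is computed at a given pH via [apparent_kd()].
#'
#' @param name Label ("EGTA", "BAPTA", or custom).
#' @param total Total chelator, mol/L (>= 0).
#' @param Kd_Ca Ca2+ dissociation constant, mol/L (> 0). Interpreted as
#'   apparent or absolute depending on `mode` of the enclosing system.
#' @param Kd_Mg Optional Mg2+ dissociation constant, mol/L.
#' @param pKa Optional numeric vector of stepwise proton pKa values
#'   (highest first), required to convert absolute to apparent.
#' @return A `chelator_spec` object.
#' @export
chelator_spec <- function(name, total, Kd_Ca, Kd_Mg = NULL, pKa = NULL) {
  if (!is.finite(total) || total < 0) stop("total must be >= 0", call. = FALSE)
  if (!is.finite(Kd_Ca) || Kd_Ca <= 0) stop("Kd_Ca must be > 0", call. = FALSE)
  if (!is.null(Kd_Mg) && (!is.finite(Kd_Mg) || Kd_Mg <= 0)) {
    stop("Kd_Mg must be > 0 when given", call. = FALSE)
  }
  structure(list(name = name, total = total, Kd_Ca = Kd_Ca,
                 Kd_Mg = Kd_Mg, pKa = pKa),
            class = "chelator_spec")
}

#' Apparent Ca2+ dissociation constant at a given pH
#'
#' Protons compete with Ca2+ for the chelator, so the effective
#' (apparent) Kd rises as pH falls:
#' \deqn{K_{app} = K_{abs} (1 + \sum_i 10^{\sum_{j \le i} (pKa_j - pH)})}
#' i.e. the cumulative proton-binding polynomial evaluated at
#' \eqn{[H^+] = 10^{-pH}}. An empty pKa list returns the absolute Kd.
#'
#' @param chelator A [chelator_spec()] whose `Kd_Ca` is absolute.
#' @param pH Assay pH.
#' @return Apparent Kd, mol/L.
#' @export
apparent_kd <- function(chelator, pH) {
  stopifnot(inherits(chelator, "chelator_spec"))
  pKa <- chelator$pKa
  if (is.null(pKa) || length(pKa) == 0) return(chelator$Kd_Ca)
  terms <- 10^cumsum(pKa - pH)
  chelator$Kd_Ca * (1 + sum(terms))
}

#' Buffer system for free-ion speciation
#'
#' @param chelators List of [chelator_spec()] objects.
#' @param total_Ca Total Ca2+, mol/L (>= 0).
#' @param total_Mg Total Mg2+, mol/L (>= 0).
#' @param pH Assay pH (used only in absolute-constants mode).
#' @param mode `"apparent"`: `Kd_Ca`/`Kd_Mg` are used as given;
#'   `"absolute"`: apparent Ca constants are derived via [apparent_kd()]
#'   (each chelator must then carry a pKa list).
#' @return A `buffer_system` object.
#' @export
buffer_system <- function(chelators = list(), total_Ca = 0, total_Mg = 0,
                          pH = 7.0, mode = c("apparent", "absolute")) {
  mode <- match.arg(mode)
  if (inherits(chelators, "chelator_spec")) chelators <- list(chelators)
  stopifnot(all(vapply(chelators, inherits, logical(1), "chelator_spec")))
  if (total_Ca < 0 || total_Mg < 0) stop("totals must be >= 0", call. = FALSE)
  if (mode == "absolute") {
    if (pH < 4 || pH > 10) stop("pH must be in [4, 10] for proton correction",
                                call. = FALSE)
    missing_pka <- vapply(chelators, function(ch) is.null(ch$pKa), logical(1))
    if (any(missing_pka)) {
      stop("absolute-constants mode requires a pKa list on every chelator",
           call. = FALSE)
    }
  }
  structure(list(chelators = chelators, total_Ca = total_Ca,
                 total_Mg = total_Mg, pH = pH, mode = mode),
            class = "buffer_system")
}

.effective_kds <- function(system) {
  lapply(system$chelators, function(ch) {
    kd_ca <- if (system$mode == "absolute") apparent_kd(ch, system$pH) else ch$Kd_Ca
    list(total = ch$total, Kd_Ca = kd_ca, Kd_Mg = ch$Kd_Mg)
  })
}

# chelator-bound Ca at given free ion levels (competitive 1:1 binding)
.bound_ca <- function(kds, ca, mg) {
  sum(vapply(kds, function(k) {
    denom <- 1 + ca / k$Kd_Ca + if (is.null(k$Kd_Mg)) 0 else mg / k$Kd_Mg
    k$total * (ca / k$Kd_Ca) / denom
  }, numeric(1)))
}

.bound_mg <- function(kds, ca, mg) {
  sum(vapply(kds, function(k) {
    if (is.null(k$Kd_Mg)) return(0)
    denom <- 1 + ca / k$Kd_Ca + mg / k$Kd_Mg
    k$total * (mg / k$Kd_Mg) / denom
  }, numeric(1)))
}

# free Mg at a given free Ca, from the Mg mass balance (monotone root)
.free_mg_given_ca <- function(kds, total_Mg, ca) {
  if (total_Mg == 0) return(0)
  f <- function(mg) mg + .bound_mg(kds, ca, mg) - total_Mg
  stats::uniroot(f, lower = 0, upper = total_Mg, tol = 1e-18)$root
}

#' Free ion concentrations of a chelator-buffered system
#'
#' Solves the coupled Ca2+/Mg2+ mass-balance equations
#' (total = free + sum of chelator-bound, with competitive binding) by
#' bracketed root finding on free Ca2+, with free Mg2+ resolved by a
#' nested monotone root at each Ca2+ trial. The mass-balance function
#' is monotone in each free concentration, so the bracket always
#' converges.
#'
#' @param system A [buffer_system()].
#' @return List with `free_Ca` (a [ca_conc()], or 0 with
#'   `below_resolution = TRUE` when total Ca is 0), `free_Mg` (mol/L),
#'   and the relative mass-balance `residual`.
#' @examples
#' sys <- buffer_system(chelator_spec("EGTA", 10e-3, Kd_Ca = 1e-7),
#'                      total_Ca = 5e-3)
#' free_ca(sys)$free_Ca$pCa   # ~7: half-saturated chelator
#' @export
free_ca <- function(system) {
  stopifnot(inherits(system, "buffer_system"))
  kds <- .effective_kds(system)
  Tca <- system$total_Ca
  if (Tca == 0) {
    mg <- .free_mg_given_ca(kds, system$total_Mg, 0)
    return(list(free_Ca = 0, free_Mg = mg, residual = 0,
                below_resolution = TRUE))
  }
  resid <- function(ca) {
    mg <- .free_mg_given_ca(kds, system$total_Mg, ca)
    ca + .bound_ca(kds, ca, mg) - Tca
  }
  # bracket in log space: at ca = Tca the residual is >= 0 (bound >= 0)
  lo <- Tca * 1e-15
  if (resid(lo) > 0) stop("solver error: no bracket below total Ca", call. = FALSE)
  root <- stats::uniroot(resid, lower = lo, upper = Tca, tol = 1e-18)$root
  # Newton polish to drive the relative residual below 1e-12
  for (it in 1:50) {
    r <- resid(root)
    if (abs(r) <= 1e-14 * Tca) break
    h <- root * 1e-7
    dr <- (resid(root + h) - resid(root - h)) / (2 * h)
    step <- r / dr
    cand <- root - step
    if (!is.finite(cand) || cand <= 0) break
    root <- cand
  }
  mg <- .free_mg_given_ca(kds, system$total_Mg, root)
  rel <- abs(root + .bound_ca(kds, root, mg) - Tca) / Tca
  list(free_Ca = ca_conc(value = root), free_Mg = mg, residual = rel,
       below_resolution = FALSE)
}

#' Total Ca2+ needed to reach a target free concentration
#'
#' Closed-form inverse of the mass balance: with free Ca2+ fixed, the
#' bound amount on every chelator is explicit, so
#' \eqn{total = free + \sum L_i \, free / (free + K_{d,i})}
#' (Mg2+ competition is folded into an effective Kd at the free Mg2+
#' implied by the target).
#'
#' @param system A [buffer_system()]; its `total_Ca` is ignored.
#' @param target_free Target free Ca2+ (mol/L) or a [ca_conc()].
#' @return Total Ca2+ in mol/L.
#' @export
total_ca_for_target <- function(system, target_free) {
  stopifnot(inherits(system, "buffer_system"))
  ca <- .ca_value(target_free)
  if (!is.finite(ca) || ca <= 0) stop("target free Ca must be > 0", call. = FALSE)
  kds <- .effective_kds(system)
  mg <- .free_mg_given_ca(kds, system$total_Mg, ca)
  ca + .bound_ca(kds, ca, mg)
}

#' Design a pCa ladder
#'
#' Batch inverse over a set of target pCa values: one row per pCa with
#' the total Ca2+ to add. Lower pCa (more free Ca2+) always needs at
#' least as much total Ca2+.
#'
#' @param system A [buffer_system()] template (totals of Ca ignored).
#' @param pCa_values Numeric target pCa values.
#' @return Data frame with columns `pCa`, `total_Ca_M`, `status`.
#' @export
pca_ladder <- function(system, pCa_values) {
  rows <- lapply(pCa_values, function(p) {
    tot <- tryCatch(total_ca_for_target(system, ca_conc(pCa = p)),
                    error = function(e) NA_real_)
    data.frame(pCa = p, total_Ca_M = tot,
               status = if (is.na(tot)) "failed" else "ok")
  })
  do.call(rbind, rows)
}

#' Read a buffer system from a JSON config
#'
#' Schema: `{chelators: [{name, total_M, Kd_Ca_M, Kd_Mg_M?, pKa?}],
#' total_Ca_M, total_Mg_M, pH, mode?}`.
#'
#' @param path JSON file or string.
#' @return A [buffer_system()].
#' @export
buffer_from_json <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  chs <- lapply(cfg$chelators, function(ch) {
    chelator_spec(ch$name, ch$total_M, ch$Kd_Ca_M,
                  Kd_Mg = ch$Kd_Mg_M, pKa = unlist(ch$pKa))
  })
  buffer_system(chs, total_Ca = cfg$total_Ca_M %||% 0,
                total_Mg = cfg$total_Mg_M %||% 0,
                pH = cfg$pH %||% 7.0, mode = cfg$mode %||% "apparent")
}
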