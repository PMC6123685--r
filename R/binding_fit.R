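#' Construct a [3H]ryanodine binding curve
#'
#' A binding curve is a long-format table of replicate bound values over
#' a pCa grid for one genotype in one condition, on the normalized
#' B/Bmax ("averaged activity") scale.
#'
#' @param pCa Numeric vector of pCa values, one per row.
#' @param B Bound values (B/Bmax units), same length, all >= 0.
#' @param replicate Integer replicate id per row.
#' @param genotype,condition,medium Labels attached to the curve.
#' @return A `binding_curve` data frame.
#' @export
binding_curve <- function(pCa, B, replicate = 1L,
                          genotype = "WT", condition = "control",
                          medium = "0.17M-NaCl-Mg") {
  df <- data.frame(pCa = pCa, replicate = as.integer(replicate), B = B)
  if (any(!is.finite(df$pCa)) || any(!is.finite(df$B))) {
    stop("pCa and B must be finite", call. = FALSE)
  }
  if (any(df$B < 0)) stop("bound values must be >= 0", call. = FALSE)
  if (length(unique(df$pCa)) < 5) {
    stop("a binding curve needs >= 5 distinct pCa points", call. = FALSE)
  }
  structure(df, class = c("binding_curve", "data.frame"),
            genotype = genotype, condition = condition, medium = medium)
}

#' Scatchard analysis of a ryanodine saturation series
#'
#' Determines the maximal binding (Bmax, the number of functional
#' channels) and the dissociation constant from a saturation series by
#' ordinary least squares on the Scatchard transform: bound/free (y)
#' against bound (x) is linear with slope -1/Kd and x-intercept Bmax.
#'
#' @param free Free ryanodine concentrations, nM (>= 3 distinct values).
#' @param bound Bound values (> 0), same units as the desired Bmax.
#' @return List with `Bmax`, `Kd` (nM), their standard errors
#'   (delta-method from the OLS covariance), and the underlying `lm` fit.
#' @examples
#' f <- c(3, 5, 10, 20)
#' b <- 10 * f / (f + 5)           # Bmax 10, Kd 5 nM
#' scatchard_bmax(f, b)$Bmax
#' @export
scatchard_bmax <- function(free, bound) {
  if (length(free) != length(bound)) stop("free and bound must match", call. = FALSE)
  if (length(unique(free)) < 3) stop("need >= 3 distinct free concentrations", call. = FALSE)
  if (any(bound <= 0) || any(free <= 0)) stop("free and bound must be > 0", call. = FALSE)
  fit <- stats::lm(I(bound / free) ~ bound)
  co <- stats::coef(fit)
  slope <- co[[2]]; intercept <- co[[1]]
  if (slope >= 0) {
    stop("non-negative Scatchard slope: no saturable binding in the series",
         call. = FALSE)
  }
  V <- suppressWarnings(stats::vcov(fit))  # noiseless series fit exactly
  Kd <- -1 / slope
  Bmax <- -intercept / slope
  # delta method: Kd = -1/s  -> dKd/ds = 1/s^2 ; Bmax = -i/s
  se_Kd <- sqrt(V[2, 2]) / slope^2
  g <- c(-1 / slope, intercept / slope^2)   # d(Bmax)/d(i), d(Bmax)/d(s)
  se_Bmax <- sqrt(drop(t(g) %*% V %*% g))
  list(Bmax = Bmax, Kd = Kd, se_Bmax = se_Bmax, se_Kd = se_Kd, fit = fit)
}

#' Normalize raw bound values by Bmax
#'
#' Elementwise division onto the B/Bmax scale; the result represents the
#' averaged activity of the channel population.
#'
#' @param raw_B Raw bound values.
#' @param Bmax Maximal binding from [scatchard_bmax()] (> 0).
#' @return B/Bmax values.
#' @export
normalize_to_bmax <- function(raw_B, Bmax) {
  if (!is.finite(Bmax) || Bmax <= 0) {
    stop("invalid normalization: Bmax must be finite and > 0", call. = FALSE)
  }
  raw_B / Bmax
}

# model prediction used inside nls formulas; pK parametrization keeps the
# optimizer on a well-scaled, unconstrained-ish scale
.cicr_predict <- function(pCa, Amax, pKA, pKI, nA, nI) {
  lca <- -pCa * log(10)
  fA <- stats::plogis(nA * (lca + pKA * log(10)))
  fI <- stats::plogis(nI * (lca + pKI * log(10)))
  Amax * fA * (1 - fI)
}

.cicr_predict_mono <- function(pCa, Amax, pKA, nA) {
  Amax * stats::plogis(nA * log(10) * (pKA - pCa))
}

#' Fit the biphasic CICR model to a binding curve
#'
#' Weighted (equal-weight) nonlinear least squares of
#' \eqn{A = A_{max} f_A (1 - f_I)} over the free parameters Amax, KA and
#' (when inactivation is on) KI, with the Hill coefficients held fixed.
#' Initialization is multi-start: KA is started at every observed pCa
#' grid point, Amax at the maximum observed mean B/Bmax, KI at 10 KA,
#' and the best start by residual sum of squares wins. All replicate
#' points are fitted (not the means) unless `use_means = TRUE`.
#'
#' Curves with essentially no binding are not fitted: if the largest
#' per-point mean B/Bmax is below `lost_threshold` or below three times
#' the replicate noise estimate (median within-point SD), the result is
#' flagged `"not_determined"`, mirroring how null mutants are reported.
#'
#' @param curve A [binding_curve()] (or data frame with pCa, replicate, B).
#' @param nA,nI Fixed Hill coefficients (defaults 2 and 1).
#' @param inactivation If `FALSE`, fit a monophasic curve with fI = 0
#'   (used for high-salt, Mg2+-free media that remove inactivation).
#' @param use_means Fit the per-point means instead of the replicates.
#' @param lost_threshold Mean-activity floor for the lost-binding rule.
#' @return A `binding_fit` list: `params` ([binding_params()] or NULL),
#'   `pCa50`, `se` (per free parameter, on the Amax/pKA/pKI scale),
#'   `se_pCa50`, `r_squared`, `converged`, `status` ("ok" |
#'   "not_determined" | "failed"), `n_points`, and the data fitted.
#' @export
fit_binding_curve <- function(curve, nA = 2, nI = 1, inactivation = TRUE,
                              use_means = FALSE, lost_threshold = 0.01) {
  df <- as.data.frame(curve)[, c("pCa", "replicate", "B")]
  df <- df[order(df$pCa, df$replicate), , drop = FALSE]
  means <- tapply(df$B, df$pCa, mean)
  sds <- tapply(df$B, df$pCa, stats::sd)
  noise <- stats::median(sds, na.rm = TRUE)
  if (!is.finite(noise)) noise <- 0
  res <- list(params = NULL, pCa50 = NA_real_, se = NULL, se_pCa50 = NA_real_,
              r_squared = NA_real_, converged = FALSE, status = "failed",
              n_points = nrow(df), nA = nA, nI = nI,
              genotype = attr(curve, "genotype"),
              condition = attr(curve, "condition"))
  class(res) <- "binding_fit"
  if (max(means) < max(lost_threshold, 3 * noise)) {
    res$status <- "not_determined"
    return(res)
  }
  dat <- if (use_means) {
    data.frame(pCa = as.numeric(names(means)), B = as.numeric(means))
  } else df
  starts_pKA <- sort(unique(dat$pCa))
  A0 <- max(means)
  best <- NULL
  for (pKA0 in starts_pKA) {
    fit <- tryCatch({
      if (inactivation) {
        minpack.lm::nlsLM(
          B ~ .cicr_predict(pCa, Amax, pKA, pKI, nA, nI),
          data = dat,
          start = list(Amax = A0, pKA = pKA0, pKI = pKA0 - 1),
          lower = c(Amax = 1e-8, pKA = 0, pKI = -2),
          upper = c(Amax = 100, pKA = 12, pKI = 12),
          control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12))
      } else {
        minpack.lm::nlsLM(
          B ~ .cicr_predict_mono(pCa, Amax, pKA, nA),
          data = dat,
          start = list(Amax = A0, pKA = pKA0),
          lower = c(Amax = 1e-8, pKA = 0),
          upper = c(Amax = 100, pKA = 12),
          control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12))
      }
    }, error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse - 1e-14) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) return(res)
  fit <- best$fit
  co <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(co)))
  sst <- sum((dat$B - mean(dat$B))^2)
  res$params <- binding_params(
    Amax = co[["Amax"]], KA = 10^(-co[["pKA"]]),
    KI = if (inactivation) 10^(-co[["pKI"]]) else 1e6,
    nA = nA, nI = nI)
  res$pCa50 <- co[["pKA"]]
  res$se <- se
  res$se_pCa50 <- unname(se["pKA"])
  res$r_squared <- 1 - best$sse / sst
  res$converged <- TRUE
  res$status <- "ok"
  res
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("binding fit [%s/%s]: status=%s", x$genotype %||% "?",
              x$condition %||% "?", x$status))
  if (x$status == "ok") {
    cat(sprintf(", pCa50=%.3f (SE %.3f), R2=%.4f", x$pCa50, x$se_pCa50,
                x$r_squared))
  }
  cat("\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select shared Hill coefficients by maximizing summed R-squared
#'
#' Fits every curve of a panel at every candidate (nA, nI) pair and
#' returns the pair with the largest sum of R-squared values across
#' curves — one shared pair for the whole panel. Ties are broken toward
#' the smaller coefficients (the grid is scanned in increasing order).
#'
#' @param curves List of [binding_curve()] objects.
#' @param grid_nA,grid_nI Candidate Hill coefficients.
#' @param inactivation Passed through to [fit_binding_curve()].
#' @return List with `nA`, `nI`, the `sum_r2` matrix
#'   (rows = nA, cols = nI), and `fits` at the selected pair.
#' @export
select_hill_coefficients <- function(curves,
                                     grid_nA = c(1, 1.5, 2, 2.5, 3),
                                     grid_nI = c(0.5, 1, 1.5, 2),
                                     inactivation = TRUE) {
  if (length(curves) == 0) stop("need at least one curve", call. = FALSE)
  grid_nA <- sort(grid_nA); grid_nI <- sort(grid_nI)
  sum_r2 <- matrix(NA_real_, length(grid_nA), length(grid_nI),
                   dimnames = list(nA = grid_nA, nI = grid_nI))
  any_ok <- FALSE
  for (i in seq_along(grid_nA)) {
    for (j in seq_along(grid_nI)) {
      r2 <- vapply(curves, function(cv) {
        f <- fit_binding_curve(cv, nA = grid_nA[i], nI = grid_nI[j],
                               inactivation = inactivation)
        if (f$status == "ok") f$r_squared else 0
      }, numeric(1))
      sum_r2[i, j] <- sum(r2)
      if (any(r2 > 0)) any_ok <- TRUE
    }
  }
  if (!any_ok) stop("all fits failed at every grid point", call. = FALSE)
  k <- which.max(sum_r2)  # column-major: scans smaller nA first within each nI
  idx <- arrayInd(k, dim(sum_r2))
  nA <- grid_nA[idx[1]]; nI <- grid_nI[idx[2]]
  fits <- lapply(curves, fit_binding_curve, nA = nA, nI = nI,
                 inactivation = inactivation)
  list(nA = nA, nI = nI, sum_r2 = sum_r2, fits = fits)
}

#' Per-genotype caffeine-sensitization summary
#'
#' Builds the summary table behind pCa50 bar panels: for every genotype,
#' the control and caffeine pCa50, their difference (delta_pCa50, the
#' caffeine sensitization), and the modelled resting-activity
#' fold-change versus wild type at pCa 7. Rows whose fits did not
#' converge or were flagged not-determined carry `NA` numeric fields and
#' the propagated status, never a silent zero.
#'
#' @param fits List of `binding_fit` objects with genotype/condition set.
#' @param wt_label Genotype label of the reference (default "WT").
#' @param conditions Character pair naming the control and the
#'   sensitized condition.
#' @return Data frame with one row per genotype.
#' @export
sensitization_table <- function(fits, wt_label = "WT",
                                conditions = c("control", "caffeine-10mM")) {
  geno <- vapply(fits, function(f) f$genotype %||% NA_character_, character(1))
  cond <- vapply(fits, function(f) f$condition %||% NA_character_, character(1))
  pick <- function(g, cn) {
    i <- which(geno == g & cond == cn)
    if (length(i) == 0) NULL else fits[[i[1]]]
  }
  wt <- pick(wt_label, conditions[1])
  if (is.null(wt) || wt$status != "ok") {
    stop("wild-type control fit is missing or did not converge", call. = FALSE)
  }
  rows <- lapply(unique(geno), function(g) {
    fc <- pick(g, conditions[1]); fk <- pick(g, conditions[2])
    p50c <- if (!is.null(fc) && fc$status == "ok") fc$pCa50 else NA_real_
    p50k <- if (!is.null(fk) && fk$status == "ok") fk$pCa50 else NA_real_
    fold <- if (!is.null(fc) && fc$status == "ok") {
      fold_change_at_rest(wt$params, fc$params)
    } else NA_real_
    status <- paste(
      if (is.null(fc)) "control:absent" else paste0("control:", fc$status),
      if (is.null(fk)) "caffeine:absent" else paste0("caffeine:", fk$status),
      sep = ";")
    data.frame(genotype = g, pCa50_control = p50c, pCa50_caffeine = p50k,
               delta_pCa50 = p50k - p50c, resting_fold_vs_wt = fold,
               status = status, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
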