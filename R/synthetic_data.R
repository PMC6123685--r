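# run code under a local RNG state so generators never disturb the
# caller's random stream
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a replicate [3H]ryanodine binding curve
#'
#' Runs the biphasic CICR model forward on a pCa grid and adds
#' independent Gaussian replicate noise (truncated at zero, since bound
#' counts cannot be negative). With the default noise SD of 0.02 on the
#' B/Bmax scale and n = 4 replicates the curves have the error-bar
#' magnitude typical of equilibrium binding panels.
#'
#' @param truth A [binding_params()] object (the generating truth).
#' @param grid pCa grid (default 12 points, 8 to 3).
#' @param noise_sd Gaussian noise SD on the B/Bmax scale.
#' @param replicates Replicates per pCa point (default 4).
#' @param seed Integer seed; identical seeds give identical tables.
#' @param ... Labels passed to [binding_curve()].
#' @return A [binding_curve()].
#' @export
gen_binding_curve <- function(truth, grid = seq(8, 3, length.out = 12),
                              noise_sd = 0.02, replicates = 4L,
                              seed = NULL, ...) {
  stopifnot(inherits(truth, "binding_params"), replicates >= 1)
  mu <- cicr_activity(truth, 10^(-grid))
  .with_seed(seed, {
    pCa <- rep(grid, each = replicates)
    rep_id <- rep(seq_len(replicates), times = length(grid))
    B <- rep(mu, each = replicates) + stats::rnorm(length(pCa), 0, noise_sd)
    binding_curve(pCa, pmax(B, 0), replicate = rep_id, ...)
  })
}

#' Simulate a ryanodine saturation series
#'
#' Single-site isotherm \eqn{B = B_{max} F / (F + K_d)} over a free
#' ryanodine grid (3-20 nM by default) with optional Gaussian noise.
#'
#' @param Bmax,Kd Truth values (Kd in nM).
#' @param grid Free concentrations, nM.
#' @param noise_sd Gaussian noise SD in B units.
#' @param seed Integer seed.
#' @return Data frame with columns `free_nM`, `bound`.
#' @export
gen_saturation <- function(Bmax, Kd, grid = c(3, 5, 8, 12, 16, 20),
                           noise_sd = 0, seed = NULL) {
  stopifnot(Bmax > 0, Kd > 0)
  mu <- Bmax * grid / (grid + Kd)
  .with_seed(seed, {
    data.frame(free_nM = grid,
               bound = pmax(mu + stats::rnorm(length(grid), 0, noise_sd), 1e-12))
  })
}

#' Simulate an antiphase cytoplasmic/ER Ca2+ trace pair
#'
#' Emulates the dual-indicator phenotype of spontaneously oscillating
#' cells: cytoplasmic Ca2+ spikes with a concomitant sawtooth drop and
#' refill of ER luminal Ca2+. An optional caffeine window either evokes
#' massive ER release (cytoplasmic surge with ER depletion) or nothing,
#' emulating caffeine-sensitive and -insensitive channels. Calibration
#' segments realizing Fmin and Fmax are appended at the end of each
#' trace; the ER floor defaults to 7.655% of Fmax.
#'
#' @param duration_s Recording length before calibration (default 120).
#' @param dt Sampling interval, s (default 0.1).
#' @param osc_freq_per_min Spontaneous spike frequency (0 = quiescent).
#' @param cyto_amp Spike amplitude, normalized units.
#' @param cyto_baseline Cytoplasmic baseline, normalized units.
#' @param er_upper,er_lower ER sawtooth envelope, normalized units.
#' @param caffeine_window Optional `c(start, end)` seconds.
#' @param caffeine_response If `TRUE`, caffeine evokes release.
#' @param Fmax_cyto,Fmax_er Raw-scale calibration ceilings.
#' @param er_floor_frac ER Fmin as a fraction of Fmax.
#' @param noise_sd Gaussian noise SD, normalized units.
#' @param seed Integer seed.
#' @return List with `cyto` and `er` [ca_trace()] objects plus `truth`
#'   (spike times and counts).
#' @export
gen_dual_trace <- function(duration_s = 120, dt = 0.1, osc_freq_per_min = 5,
                           cyto_amp = 0.8, cyto_baseline = 0.05,
                           er_upper = 0.9, er_lower = 0.5,
                           caffeine_window = NULL, caffeine_response = TRUE,
                           Fmax_cyto = 1000, Fmax_er = 800,
                           er_floor_frac = 0.07655,
                           noise_sd = 0.01, seed = NULL) {
  stopifnot(er_upper > er_lower)
  t <- seq(0, duration_s, by = dt)
  spikes <- if (osc_freq_per_min > 0) {
    spacing <- 60 / osc_freq_per_min
    sp <- seq(spacing / 2, duration_s, by = spacing)
    if (!is.null(caffeine_window)) {
      sp <- sp[sp < caffeine_window[1] | sp > caffeine_window[2]]
    }
    sp
  } else numeric(0)
  cyto <- rep(cyto_baseline, length(t))
  er <- rep(er_upper, length(t))
  # ER refill time is 80% of the inter-spike interval so consecutive
  # sawtooth teeth never overlap
  rec <- 0.8 * (if (length(spikes) > 1) spikes[2] - spikes[1] else 10)
  for (s in spikes) {
    cyto <- cyto + cyto_amp * exp(-((t - s) / 0.4)^2)
    er <- er - (er_upper - er_lower) *
      ifelse(t >= s, pmax(0, 1 - (t - s) / rec), 0)
  }
  er <- pmin(pmax(er, er_lower - 0.05), er_upper)
  if (!is.null(caffeine_window) && caffeine_response) {
    inwin <- t >= caffeine_window[1] & t <= caffeine_window[2]
    cyto[inwin] <- pmax(cyto[inwin],
                        cyto_baseline + 0.95 * exp(-(t[inwin] - caffeine_window[1]) / 5))
    er[inwin] <- 0.2
    after <- t > caffeine_window[2]
    er[after] <- pmin(er[after], 0.2 + (er_upper - 0.2) *
                        (1 - exp(-(t[after] - caffeine_window[2]) / 20)))
  }
  .with_seed(seed, {
    cyto <- cyto + stats::rnorm(length(t), 0, noise_sd)
    er <- er + stats::rnorm(length(t), 0, noise_sd)
    # calibration segments: 5 s at Fmin then 5 s at Fmax (noiseless anchors)
    tcal <- seq(duration_s + dt, duration_s + 10, by = dt)
    ncal <- length(tcal)
    half <- seq_len(ncal) <= ncal / 2
    cal_norm <- ifelse(half, 0, 1)
    to_raw <- function(norm, Fmin, Fmax) Fmin + norm * (Fmax - Fmin)
    Fmin_er <- er_floor_frac * Fmax_er
    events <- c(
      if (!is.null(caffeine_window)) list(caffeine = caffeine_window),
      list(calibration = c(duration_s + dt, duration_s + 10)))
    list(
      cyto = ca_trace(c(t, tcal),
                      to_raw(c(cyto, cal_norm), 0, Fmax_cyto),
                      channel = "cyto", Fmin = 0, Fmax = Fmax_cyto,
                      events = events),
      er = ca_trace(c(t, tcal),
                    to_raw(c(er, cal_norm), Fmin_er, Fmax_er),
                    channel = "er", Fmin = Fmin_er, Fmax = Fmax_er,
                    events = events),
      truth = list(spike_times = spikes, spike_count = length(spikes),
                   freq_per_min = length(spikes) / (duration_s / 60)))
  })
}

#' Simulate caffeine dose-response peak data
#'
#' Peak responses from a Hill dose-response (floor, ceiling, EC50, hill)
#' with Gaussian noise, several cells per dose.
#'
#' @param EC50 Truth EC50, mM (default 1, the wild-type-like value).
#' @param hill Truth Hill slope (default 1.5).
#' @param floor,ceiling Response bounds.
#' @param doses Dose grid, mM.
#' @param cells_per_dose Replicate cells per dose.
#' @param noise_sd Gaussian noise SD on the response scale.
#' @param seed Integer seed.
#' @return Data frame `dose_mM`, `cell`, `response`.
#' @export
gen_dose_response <- function(EC50 = 1, hill = 1.5, floor = 0, ceiling = 1,
                              doses = c(0.03, 0.1, 0.3, 1, 3, 10),
                              cells_per_dose = 6L, noise_sd = 0.05,
                              seed = NULL) {
  mu <- floor + (ceiling - floor) * doses^hill / (doses^hill + EC50^hill)
  .with_seed(seed, {
    d <- rep(doses, each = cells_per_dose)
    m <- rep(mu, each = cells_per_dose)
    data.frame(dose_mM = d,
               cell = rep(seq_len(cells_per_dose), times = length(doses)),
               response = m + stats::rnorm(length(d), 0, noise_sd))
  })
}

# fixed-width PDB ATOM record writer (columns per the v3.3 format)
.write_pdb <- function(at, path) {
  name4 <- ifelse(nchar(at$elety) < 4,
                  sprintf(" %-3s", at$elety), at$elety)
  lines <- sprintf(
    "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(at)), name4, at$resid, at$chain, at$resno,
    at$x, at$y, at$z, 1, 0, substr(at$elety, 1, 1))
  writeLines(c(lines, "END"), path)
}

.write_cif <- function(at, path, name = "synthetic") {
  hdr <- c(paste0("data_", name), "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "auth_seq_id", "auth_comp_id",
                    "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num")))
  rows <- sprintf(
    "ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 %d %s %s %s 1",
    seq_len(nrow(at)), substr(at$elety, 1, 1), at$elety, at$resid, at$chain,
    at$resno, at$x, at$y, at$z, at$resno, at$resid, at$chain, at$elety)
  writeLines(c(hdr, rows, "#"), path)
}

#' Generate a synthetic two-domain fixture pair
#'
#' Builds a toy protein of two Calpha "domains" (A and B), writes a
#' reference state and a second state in which domain B is rigidly
#' shifted by a known vector while domain A is untouched, in both PDB
#' and mmCIF renderings. The files are labelled synthetic; they exist
#' so displacement measurements can be validated against an exact
#' ground truth.
#'
#' @param shift Length-3 displacement of domain B, angstrom.
#' @param n_per_domain Calpha atoms per domain (default 20).
#' @param dir Output directory (default a fresh tempdir).
#' @param seed Integer seed for the atom placement.
#' @return List: paths (`stateA_pdb`, `stateA_cif`, `stateB_pdb`,
#'   `stateB_cif`), `domains` (residue ranges), and the truth `shift`.
#' @export
gen_two_domain_fixture <- function(shift = c(2, 0, 0), n_per_domain = 20L,
                                   dir = tempfile("fixture"), seed = NULL) {
  stopifnot(length(shift) == 3, all(is.finite(shift)))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .with_seed(seed, {
    mk <- function(n, origin) {
      # compact random blob around the origin
      data.frame(chain = "A",
                 resno = integer(n), resid = "ALA", elety = "CA",
                 x = origin[1] + stats::rnorm(n, 0, 4),
                 y = origin[2] + stats::rnorm(n, 0, 4),
                 z = origin[3] + stats::rnorm(n, 0, 4),
                 stringsAsFactors = FALSE)
    }
    A <- mk(n_per_domain, c(0, 0, 0));   A$resno <- seq_len(n_per_domain)
    B <- mk(n_per_domain, c(20, 0, 0));  B$resno <- 100 + seq_len(n_per_domain)
    stateA <- rbind(A, B)
    B2 <- B; B2$x <- B2$x + shift[1]; B2$y <- B2$y + shift[2]; B2$z <- B2$z + shift[3]
    stateB <- rbind(A, B2)
    paths <- list(stateA_pdb = file.path(dir, "synthetic_stateA.pdb"),
                  stateA_cif = file.path(dir, "synthetic_stateA.cif"),
                  stateB_pdb = file.path(dir, "synthetic_stateB.pdb"),
                  stateB_cif = file.path(dir, "synthetic_stateB.cif"))
    .write_pdb(stateA, paths$stateA_pdb); .write_cif(stateA, paths$stateA_cif)
    .write_pdb(stateB, paths$stateB_pdb); .write_cif(stateB, paths$stateB_cif)
    c(paths, list(domains = list(A = seq_len(n_per_domain),
                                 B = 100 + seq_len(n_per_domain)),
                  shift = shift))
  })
}

#' Generate the full synthetic study panel
#'
#' A genotype truth table emulating the phenotype classes of the study
#' system — wild type, a caffeine-insensitive tryptophan mutant, a
#' constitutively sensitized isoleucine mutant, and a disease-class
#' mutant with eightfold higher Ca2+ sensitivity — together with
#' replicate binding curves for every genotype x condition and a dual
#' trace per genotype. The WT activating-site pCa50 (4.79) and the
#' eightfold KA shift of the disease mutant are literature-anchored
#' truths; every other parameter is illustrative, and each manifest row
#' is tagged `"anchored"` or `"illustrative"` accordingly.
#'
#' @param seed Integer master seed; per-genotype seeds are derived.
#' @param noise_sd Binding-curve noise SD.
#' @param replicates Replicates per pCa point.
#' @return List: `truth` (manifest data frame), `curves` (named list of
#'   [binding_curve()]), `traces` (named list from [gen_dual_trace()]).
#' @export
gen_paper_panel <- function(seed = 1L, noise_sd = 0.02, replicates = 4L) {
  pKA_wt <- 4.79
  truth <- data.frame(
    genotype = c("WT", "WT", "W-mut", "W-mut", "I-mut", "I-mut",
                 "C-mut", "C-mut"),
    condition = rep(c("control", "caffeine-10mM"), 4),
    Amax = c(0.40, 0.40, 0.35, 0.35, 0.45, 0.45, 0.40, 0.40),
    pKA = c(pKA_wt, pKA_wt + 0.5,          # WT: caffeine sensitizes
            5.10, 5.10,                    # W-mut: caffeine-insensitive
            5.50, 6.00,                    # I-mut: sensitized, still responsive
            pKA_wt + log10(8), pKA_wt + log10(8) + 0.5),  # eightfold KA
    pKI = rep(3, 8),
    nA = 2, nI = 1,
    provenance = c("anchored", "illustrative", "illustrative", "illustrative",
                   "illustrative", "illustrative", "anchored", "illustrative"),
    stringsAsFactors = FALSE)
  curves <- vector("list", nrow(truth))
  names(curves) <- paste(truth$genotype, truth$condition, sep = "|")
  for (i in seq_len(nrow(truth))) {
    p <- binding_params(truth$Amax[i], 10^(-truth$pKA[i]), 10^(-truth$pKI[i]),
                        truth$nA[i], truth$nI[i])
    curves[[i]] <- gen_binding_curve(
      p, noise_sd = noise_sd, replicates = replicates,
      seed = seed * 1000L + i, genotype = truth$genotype[i],
      condition = truth$condition[i])
  }
  genos <- unique(truth$genotype)
  traces <- lapply(seq_along(genos), function(i) {
    sensitized <- genos[i] %in% c("I-mut", "C-mut")
    gen_dual_trace(
      osc_freq_per_min = if (sensitized) 8 else 4,
      er_upper = if (sensitized) 0.6 else 0.9,
      caffeine_window = c(90, 100),
      caffeine_response = !identical(genos[i], "W-mut"),
      seed = seed * 1000L + 100L + i)
  })
  names(traces) <- genos
  list(truth = truth, curves = curves, traces = traces)
}
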