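#' Default RyR1 domain dictionary
#'
#' Named residue ranges of the RyR1 protomer used for displacement
#' measurements: the cytoplasmic shell, the core solenoid (CSol), the
#' transmembrane region with the cytoplasmic S6 extension (TM+S6c), and
#' the C-terminal domain (CTD). Override per structure as needed.
#'
#' @return Named list of integer ranges.
#' @export
ryr1_domains <- function() {
  list(shell = 1:3666, csol = 3667:4253, tm_s6c = 4540:4956, ctd = 4957:5037)
}

#' Residue correspondence between rabbit RyR1 and mouse RyR2
#'
#' One-to-one mapping of the analyzed sites at the Ca2+/caffeine-binding
#' interface, plus two disease-associated positions. The RyR1 isoleucine
#' is stored as I4996; the alternative printed numbering I4966 appearing
#' in some figure panels is flagged in the `note` column.
#'
#' @return Data frame with columns ryr1, ryr2, aa, note.
#' @export
ryr1_ryr2_sites <- function() {
  data.frame(
    ryr1 = c(4716L, 4996L, 3753L, 3893L, 3967L, 3970L, 5001L, 4238L, 4678L),
    ryr2 = c(4644L, 4925L, 3713L, 3847L, 3921L, 3924L, NA,    4192L, 4606L),
    aa   = c("W", "I", "F", "E", "E", "Q", "T", "C", "A"),
    note = c("", "also printed as I4966 in one panel; 4996 is used here",
             "", "", "", "", "RyR2 equivalent not printed", "", ""),
    stringsAsFactors = FALSE)
}

#' Load a coordinate model from PDB or mmCIF
#'
#' Parses the file with bio3d, keeps one protomer chain (the first
#' alphabetically unless given — a documented convention for
#' homotetramers), resolves alternate locations to the highest-occupancy
#' conformer, and records residue-number gaps.
#'
#' @param path PDB (`.pdb`, `.ent`) or mmCIF (`.cif`, `.mmcif`) file.
#' @param chain Chain identifier; default first alphabetically.
#' @return A `structure_model`: data frame of atoms (chain, resno,
#'   insert, resid, elety, x, y, z, o) with attributes `source`,
#'   `chain`, `gaps`.
#' @export
load_structure <- function(path, chain = NULL) {
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext %in% c("cif", "mmcif")) {
    suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE))
  } else if (ext %in% c("pdb", "ent")) {
    bio3d::read.pdb(path, rm.alt = FALSE)
  } else {
    stop("unknown structure format: .", ext, " (expected pdb/ent/cif/mmcif)",
         call. = FALSE)
  }
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  chains <- sort(unique(at$chain))
  if (is.null(chain)) chain <- chains[1]
  if (!chain %in% chains) {
    stop("chain '", chain, "' not present (available: ",
         paste(chains, collapse = ", "), ")", call. = FALSE)
  }
  at <- at[at$chain == chain, , drop = FALSE]
  if (is.null(at$insert)) at$insert <- ""
  at$insert[is.na(at$insert)] <- ""
  if (is.null(at$o) || all(is.na(at$o))) at$o <- 1
  # altloc: keep the highest-occupancy conformer per (resno, insert, atom)
  key <- paste(at$resno, at$insert, at$elety, sep = "|")
  at <- at[order(key, -at$o), , drop = FALSE]
  at <- at[!duplicated(paste(at$resno, at$insert, at$elety, sep = "|")), ,
           drop = FALSE]
  at <- at[order(at$resno, at$insert), , drop = FALSE]
  res <- sort(unique(at$resno))
  gaps <- res[c(FALSE, diff(res) > 1)]
  out <- at[, c("chain", "resno", "insert", "resid", "elety", "x", "y", "z", "o")]
  rownames(out) <- NULL
  structure(out, class = c("structure_model", "data.frame"),
            source = path, chain = chain, gaps = gaps)
}

# Calpha coordinate matrix keyed by residue number
.ca_matrix <- function(model, resnos = NULL) {
  at <- as.data.frame(model)
  at <- at[at$elety == "CA", , drop = FALSE]
  if (!is.null(resnos)) at <- at[at$resno %in% resnos, , drop = FALSE]
  m <- as.matrix(at[, c("x", "y", "z")])
  rownames(m) <- at$resno
  m
}

# Kabsch least-squares rotation: returns R such that P %*% R best matches Q
# (both centred). det(R) is forced to +1 (proper rotation).
.kabsch <- function(P, Q) {
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$v %*% t(s$u)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Rigid-body superposition of two coordinate models
#'
#' Least-squares (Kabsch) superposition of the mobile model onto the
#' reference over the Calpha atoms of a residue selection. Residues
#' missing from either model are dropped pairwise.
#'
#' @param mobile,reference `structure_model` objects.
#' @param selection Integer residue numbers; default all shared.
#' @return List: `R` (3x3 rotation), `t` (translation so that
#'   `x %*% R + t` maps mobile onto reference), `rmsd` (angstrom) over
#'   the selection, `n` atoms used.
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  Pm <- .ca_matrix(mobile, selection)
  Qm <- .ca_matrix(reference, selection)
  common <- intersect(rownames(Pm), rownames(Qm))
  if (length(common) < 3) stop("need >= 3 common Calpha atoms", call. = FALSE)
  P <- Pm[common, , drop = FALSE]; Q <- Qm[common, , drop = FALSE]
  cp <- colMeans(P); cq <- colMeans(Q)
  R <- .kabsch(sweep(P, 2, cp), sweep(Q, 2, cq))
  tvec <- unname(cq - drop(cp %*% R))
  moved <- sweep(sweep(P, 2, cp) %*% R, 2, cq, "+")
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  list(R = R, t = tvec, rmsd = rmsd, n = length(common))
}

#' Apply a superposition transform to a model
#'
#' @param model A `structure_model`.
#' @param xf Transform list from [superpose()].
#' @return The transformed `structure_model`.
#' @export
apply_transform <- function(model, xf) {
  xyz <- as.matrix(as.data.frame(model)[, c("x", "y", "z")])
  moved <- sweep(xyz %*% xf$R, 2, xf$t, "+")
  model$x <- moved[, 1]; model$y <- moved[, 2]; model$z <- moved[, 3]
  model
}

#' Domain displacement between two conformational states
#'
#' Superposes state B onto state A over a reference selection (for RyR
#' the least-mobile frame is the TM+S6c region), then reports how far a
#' target domain has moved: the mean per-Calpha displacement and the
#' centroid shift vector, both in angstrom.
#'
#' @param stateA,stateB `structure_model` objects (A is the frame).
#' @param reference_selection Residues defining the superposition frame.
#' @param target_domain Residues of the domain whose motion is measured.
#' @return List: `mean_displacement`, `centroid_shift` (length-3
#'   vector, frame of stateA), `centroid_shift_norm`, `per_residue`
#'   (named vector), `frame_rmsd`, `n`.
#' @export
domain_displacement <- function(stateA, stateB, reference_selection,
                                target_domain) {
  xf <- superpose(stateB, stateA, reference_selection)
  B2 <- apply_transform(stateB, xf)
  A <- .ca_matrix(stateA, target_domain)
  B <- .ca_matrix(B2, target_domain)
  common <- intersect(rownames(A), rownames(B))
  if (length(common) == 0) stop("no shared Calpha atoms in the target domain",
                                call. = FALSE)
  A <- A[common, , drop = FALSE]; B <- B[common, , drop = FALSE]
  d <- sqrt(rowSums((B - A)^2))
  shift <- unname(colMeans(B) - colMeans(A))
  list(mean_displacement = mean(d), centroid_shift = shift,
       centroid_shift_norm = sqrt(sum(shift^2)),
       per_residue = stats::setNames(d, common),
       frame_rmsd = xf$rmsd, n = length(common))
}

.backbone <- c("N", "CA", "C", "O", "OXT")

#' Distance between two residues
#'
#' Minimum heavy-atom distance (default) or distance between side-chain
#' centroids. Hydrogens are excluded; for centroid mode backbone atoms
#' are excluded too (falling back to all atoms for glycine).
#'
#' @param model A `structure_model`.
#' @param resA,resB Residue numbers.
#' @param mode `"min"` or `"centroid"`.
#' @return Distance in angstrom.
#' @export
residue_pair_distance <- function(model, resA, resB,
                                  mode = c("min", "centroid")) {
  mode <- match.arg(mode)
  at <- as.data.frame(model)
  at <- at[!grepl("^H", at$elety), , drop = FALSE]
  a <- at[at$resno == resA, , drop = FALSE]
  b <- at[at$resno == resB, , drop = FALSE]
  if (nrow(a) == 0 || nrow(b) == 0) {
    miss <- c(if (nrow(a) == 0) resA, if (nrow(b) == 0) resB)
    stop("residue(s) absent from model: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (mode == "centroid") {
    sa <- a[!a$elety %in% .backbone, , drop = FALSE]; if (nrow(sa) == 0) sa <- a
    sb <- b[!b$elety %in% .backbone, , drop = FALSE]; if (nrow(sb) == 0) sb <- b
    ca <- colMeans(sa[, c("x", "y", "z")]); cb <- colMeans(sb[, c("x", "y", "z")])
    return(sqrt(sum((ca - cb)^2)))
  }
  A <- as.matrix(a[, c("x", "y", "z")]); B <- as.matrix(b[, c("x", "y", "z")])
  min(sqrt(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)))
}

#' Planar-polygon gauge of a binding-pocket mouth
#'
#' A size proxy for a pocket framed by a set of coordinating residues:
#' the designated gauge atoms (side-chain oxygens by default) are
#' projected onto their best-fit plane, ordered by angle about their
#' centroid, and the area of the resulting polygon is returned together
#' with all pairwise atom distances. This is a proxy measure of pocket
#' mouth size, not a cavity-volume computation.
#'
#' @param model A `structure_model`.
#' @param residues Residue numbers framing the pocket.
#' @param atoms Optional atom-name vector selecting the gauge atoms;
#'   default side-chain oxygens (OD1, OE1, OG1, ... — names starting
#'   with O other than backbone O).
#' @return List: `area` (squared angstrom), `distances` (matrix,
#'   angstrom), `points` (the gauge coordinates used).
#' @export
pocket_gauge <- function(model, residues, atoms = NULL) {
  at <- as.data.frame(model)
  at <- at[at$resno %in% residues, , drop = FALSE]
  sel <- if (is.null(atoms)) {
    grepl("^O", at$elety) & !at$elety %in% c("O", "OXT")
  } else {
    at$elety %in% atoms
  }
  g <- at[sel, , drop = FALSE]
  if (nrow(g) < 3) stop("need >= 3 gauge atoms", call. = FALSE)
  P <- as.matrix(g[, c("x", "y", "z")])
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  sv <- svd(Pc)
  uv <- Pc %*% sv$v[, 1:2]          # in-plane coordinates
  ord <- order(atan2(uv[, 2], uv[, 1]))
  u <- uv[ord, 1]; v <- uv[ord, 2]
  area <- abs(sum(u * c(v[-1], v[1]) - c(u[-1], u[1]) * v)) / 2
  D <- as.matrix(stats::dist(P))
  dimnames(D) <- list(paste(g$resno, g$elety, sep = ":"),
                      paste(g$resno, g$elety, sep = ":"))
  list(area = area, distances = D, points = P)
}
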