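#' Read a long-format binding CSV
#'
#' Expected columns: `genotype`, `condition`, `pCa` (or `ca_M` with
#' `ca_unit = "M"`), `replicate_id`, `B`. Malformed rows are reported
#' with their file line numbers.
#'
#' @param path CSV file.
#' @param ca_unit `"pCa"` (default) or `"M"` — how the Ca column is
#'   declared.
#' @return Named list of [binding_curve()] objects, one per
#'   genotype x condition, names `"genotype|condition"`. A header-only
#'   file returns an empty list with a warning.
#' @export
read_binding_csv <- function(path, ca_unit = c("pCa", "M")) {
  ca_unit <- match.arg(ca_unit)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ca_col <- if (ca_unit == "pCa") "pCa" else "ca_M"
  need <- c("genotype", "condition", ca_col, "replicate_id", "B")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("binding CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) {
    warning("header-only binding CSV: no data rows")
    return(list())
  }
  bad <- which(!is.finite(df[[ca_col]]) | !is.finite(df$B) | df$B < 0)
  if (length(bad)) {
    stop("malformed binding rows at file line(s): ",
         paste(bad + 1, collapse = ", "),
         " (non-finite ", ca_col, "/B or negative B)", call. = FALSE)
  }
  df$pCa_val <- if (ca_unit == "M") -log10(df[[ca_col]]) else df[[ca_col]]
  keys <- unique(df[, c("genotype", "condition")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$genotype == keys$genotype[i] & df$condition == keys$condition[i], ]
    binding_curve(sub$pCa_val, sub$B, replicate = sub$replicate_id,
                  genotype = keys$genotype[i], condition = keys$condition[i])
  })
  names(out) <- paste(keys$genotype, keys$condition, sep = "|")
  out
}

#' Write a binding curve list to a long-format CSV
#'
#' @param curves Named list of [binding_curve()] objects.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_binding_csv <- function(curves, path) {
  rows <- lapply(curves, function(cv) {
    data.frame(genotype = attr(cv, "genotype"),
               condition = attr(cv, "condition"),
               pCa = cv$pCa, replicate_id = cv$replicate, B = cv$B,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write the sensitization summary as TSV
#'
#' Numbers are written with 6 significant digits; use the JSON manifest
#' for full precision.
#'
#' @param rows Data frame from [sensitization_table()].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_summary_tsv <- function(rows, path) {
  out <- rows
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a pipeline configuration
#'
#' @param config Named list; unknown keys are rejected and all problems
#'   are reported at once.
#' @return The validated config with defaults filled in.
#' @export
validate_config <- function(config) {
  known <- c("seed", "out_dir", "stages", "wt_label", "noise_sd",
             "replicates", "nA", "nI", "select_hill", "grid_nA", "grid_nI")
  defaults <- list(seed = 1L, out_dir = tempfile("cicr_run"),
                   stages = c("simulate", "fit", "summarize"),
                   wt_label = "WT", noise_sd = 0.02, replicates = 4L,
                   nA = 2, nI = 1, select_hill = FALSE,
                   grid_nA = c(1, 1.5, 2, 2.5, 3), grid_nI = c(0.5, 1, 1.5, 2))
  problems <- character(0)
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    problems <- c(problems, paste0("unknown config key(s): ",
                                   paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, config[intersect(names(config), known)])
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) {
    problems <- c(problems, "seed must be a single integer")
  }
  bad_stage <- setdiff(cfg$stages, c("simulate", "fit", "summarize"))
  if (length(bad_stage)) {
    problems <- c(problems, paste0("unknown stage(s): ",
                                   paste(bad_stage, collapse = ", ")))
  }
  if (length(problems)) {
    stop("invalid pipeline config:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  cfg
}

#' Run the simulate -> fit -> summarize pipeline
#'
#' Executes the enabled stages in dependency order on the synthetic
#' study panel, writing the binding CSV, per-fit JSON records, the
#' summary TSV and a run manifest. All randomness flows from the single
#' config seed through per-stage derived seeds, so re-running an
#' identical config reproduces byte-identical numeric tables. On a
#' stage failure, downstream stages are skipped with a recorded status.
#'
#' @param config Named list, see [validate_config()].
#' @return The run manifest (list), invisibly written to
#'   `manifest.json` in the output directory.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = cfg, package_version =
                     as.character(utils::packageVersion("cicrfit")),
                   stages = list(), outputs = list())
  curves <- NULL
  if ("simulate" %in% cfg$stages) {
    panel <- gen_paper_panel(seed = as.integer(cfg$seed),
                             noise_sd = cfg$noise_sd,
                             replicates = cfg$replicates)
    curves <- panel$curves
    csv <- file.path(cfg$out_dir, "binding.csv")
    write_binding_csv(curves, csv)
    utils::write.csv(panel$truth, file.path(cfg$out_dir, "truth_manifest.csv"),
                     row.names = FALSE)
    manifest$stages$simulate <- "ok"
    manifest$outputs$binding_csv <- "binding.csv"
  }
  fits <- NULL
  if ("fit" %in% cfg$stages) {
    if (is.null(curves)) {
      manifest$stages$fit <- "skipped: no curves (simulate disabled?)"
    } else {
      if (isTRUE(cfg$select_hill)) {
        sel <- select_hill_coefficients(curves, cfg$grid_nA, cfg$grid_nI)
        fits <- sel$fits
        manifest$stages$fit <- sprintf("ok (selected nA=%g nI=%g)",
                                       sel$nA, sel$nI)
      } else {
        fits <- lapply(curves, fit_binding_curve, nA = cfg$nA, nI = cfg$nI)
        manifest$stages$fit <- "ok"
      }
      recs <- lapply(fits, function(f) {
        list(genotype = f$genotype, condition = f$condition,
             status = f$status, pCa50 = f$pCa50, se_pCa50 = f$se_pCa50,
             r_squared = f$r_squared)
      })
      jsonlite::write_json(recs, file.path(cfg$out_dir, "fits.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      manifest$outputs$fits_json <- "fits.json"
    }
  }
  if ("summarize" %in% cfg$stages) {
    if (is.null(fits)) {
      manifest$stages$summarize <- "skipped: no fits"
    } else {
      summ <- sensitization_table(fits, wt_label = cfg$wt_label)
      write_summary_tsv(summ, file.path(cfg$out_dir, "summary.tsv"))
      manifest$stages$summarize <- "ok"
      manifest$outputs$summary_tsv <- "summary.tsv"
    }
  }
  files <- file.path(cfg$out_dir, unlist(manifest$outputs))
  manifest$md5 <- as.list(tools::md5sum(files))
  names(manifest$md5) <- basename(files)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}
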