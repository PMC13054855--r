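FRACTION_LABELS <- c("C", "M", "N", "PT")

#' Read and validate a sample sheet
#'
#' A sample sheet maps PRM runs to the experimental design: one row per
#' run with its fraction label (C = cytosolic, M = mitochondrial,
#' N = nuclear, PT = total proteome), replicate id, and replicate kind.
#'
#' @param path Path to a TSV or CSV file with columns `path`, `fraction`,
#'   `replicate` and optionally `kind` (`biological`/`technical`,
#'   defaults to biological).
#' @return A validated tibble.
#' @export
read_sample_sheet <- function(path) {
  reader <- if (grepl("\\.csv$", path)) readr::read_csv else readr::read_tsv
  sheet <- reader(path, show_col_types = FALSE, progress = FALSE)
  if (!"kind" %in% names(sheet)) sheet$kind <- "biological"
  validate_sample_sheet(sheet)
  sheet
}

#' @rdname read_sample_sheet
#' @param sheet A sample-sheet tibble to validate in place.
#' @export
validate_sample_sheet <- function(sheet) {
  required <- c("path", "fraction", "replicate")
  missing_cols <- setdiff(required, names(sheet))
  if (length(missing_cols)) {
    abort(paste0("Sample sheet lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- setdiff(unique(sheet$fraction), FRACTION_LABELS)
  if (length(bad)) {
    abort(sprintf("Unknown fraction label(s): %s (allowed: %s).",
                  paste(bad, collapse = ", "),
                  paste(FRACTION_LABELS, collapse = ", ")))
  }
  dup <- duplicated(sheet[, c("fraction", "replicate")])
  if (any(dup)) {
    abort(sprintf("Duplicate (fraction, replicate) pair: (%s, %s).",
                  sheet$fraction[dup][1], sheet$replicate[dup][1]))
  }
  if ("kind" %in% names(sheet)) {
    badk <- setdiff(unique(sheet$kind), c("biological", "technical"))
    if (length(badk)) {
      abort(paste0("Replicate kind must be biological or technical, got: ",
                   paste(badk, collapse = ", ")))
    }
  }
  invisible(sheet)
}

provenance_header <- function(panel, params) {
  panel_file <- tempfile(fileext = ".tsv")
  on.exit(unlink(panel_file))
  readr::write_tsv(as_tibble(panel)[, setdiff(names(panel), "transitions")],
                   panel_file, progress = FALSE)
  checksum <- unname(tools::md5sum(panel_file))
  c(
    sprintf("# prmfrac %s", as.character(utils::packageVersion("prmfrac"))),
    sprintf("# panel_md5 %s", checksum),
    sprintf("# parameters %s",
            paste(names(params), unlist(params), sep = "=", collapse = " "))
  )
}

write_tsv_with_header <- function(x, path, header_lines) {
  writeLines(header_lines, path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Read a TSV written with provenance header lines
#'
#' @param path File written by [run_pipeline()] (leading `#` comment
#'   lines carry tool version, panel checksum and parameters).
#' @return A tibble; the header lines are attached as attribute
#'   `provenance`.
#' @export
read_pipeline_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  attr(out, "provenance") <- hdr
  out
}

#' Run the full quantification and QC pipeline
#'
#' Ties the stages together: validates the sample sheet, quantifies every
#' run against the panel (XIC extraction, interference screen, peak
#' integration, peptide-level summation), and scores fraction enrichment
#' (ERs, CV%, ANOVA, Tukey, verdicts). Outputs are deterministic for
#' fixed inputs; every written table carries a provenance header with the
#' tool version, the panel checksum and the parameters used. No stage
#' mutates its inputs.
#'
#' @param sample_sheet A sample-sheet tibble or path.
#' @param panel A panel tibble or path (default: packaged marker panel).
#' @param out_dir Optional output directory; when given, writes
#'   `quant.tsv` (per-transition areas), `totals.tsv`, `report_*.tsv`
#'   (ratios, cv, anova, tukey, verdicts).
#' @param ppm_tol XIC tolerance in ppm (default 10).
#' @param rt_window Optional retention-time window in seconds.
#' @param alpha Verdict significance level (default 0.05).
#' @param fractions Fractions entering ANOVA/verdicts (default C/M/N;
#'   a PT channel is kept as reference only).
#' @return A list: `quant` (per-transition tibble), `totals`, `report`
#'   (an [enrichment_report()]).
#' @export
run_pipeline <- function(sample_sheet, panel = NULL, out_dir = NULL,
                         ppm_tol = 10, rt_window = NULL, alpha = 0.05,
                         fractions = c("C", "M", "N")) {
  if (is.character(sample_sheet)) sample_sheet <- read_sample_sheet(sample_sheet)
  validate_sample_sheet(sample_sheet)
  if (is.null(panel)) {
    panel <- load_panel()
  } else if (is.character(panel)) {
    panel <- load_panel(panel)
  }
  missing_runs <- sample_sheet$path[!file.exists(sample_sheet$path)]
  if (length(missing_runs)) {
    abort(paste0("Stage quant: run file(s) not found: ",
                 paste(missing_runs, collapse = ", ")))
  }
  quant <- tryCatch(
    quantify_runs(sample_sheet, panel, ppm_tol = ppm_tol,
                  rt_window = rt_window),
    error = function(e) abort(paste0("Stage quant failed: ",
                                     conditionMessage(e)))
  )
  totals <- peptide_totals(quant)
  report <- tryCatch(
    enrichment_report(totals, alpha = alpha, fractions = fractions),
    error = function(e) abort(paste0("Stage report failed: ",
                                     conditionMessage(e)))
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    hdr <- provenance_header(panel, list(ppm_tol = ppm_tol, alpha = alpha,
                                         fractions = paste(fractions,
                                                           collapse = "/")))
    write_tsv_with_header(quant, file.path(out_dir, "quant.tsv"), hdr)
    write_tsv_with_header(totals, file.path(out_dir, "totals.tsv"), hdr)
    for (nm in c("ratios", "cv", "anova", "tukey", "verdicts")) {
      write_tsv_with_header(report[[nm]],
                            file.path(out_dir, paste0("report_", nm, ".tsv")),
                            hdr)
    }
  }
  list(quant = quant, totals = totals, report = report)
}
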