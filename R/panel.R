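#' Load and validate a transition panel
#'
#' Reads a tab-separated panel configuration (one row per peptide ion,
#' transitions as a comma-separated list like `"y7+,y6+,b3+"`) and
#' validates it: peptide lengths must lie in `[8, 25]`, every entry needs
#' at least 3 transitions, and each printed precursor m/z is recomputed
#' from the sequence and charge — a deviation beyond `mz_tol` fails the
#' load, naming the offending entry.
#'
#' With `path = NULL` the packaged subcellular-marker panel is loaded:
#' 8 marker proteins (2 nuclear, 3 mitochondrial, 3 cytosolic) monitored
#' through 16 peptide ions and 76 transitions.
#'
#' @param path Path to a panel TSV, or `NULL` for the packaged marker
#'   panel.
#' @param mz_tol Maximum allowed |printed - recomputed| precursor m/z
#'   (default 0.005; printed tables are rounded to 3 decimals so small
#'   deviations up to 0.001 are expected and reported in `mz_delta`).
#' @return A tibble of class `transition_panel` with one row per peptide
#'   ion: `protein`, `gene`, `accession_human`, `accession_mouse`,
#'   `compartment`, `peptide`, `precursor_mz` (as printed),
#'   `precursor_charge`, `transitions` (list-column of fragment labels)
#'   and `mz_delta`.
#' @export
#' @examples
#' panel <- load_panel()
#' nrow(panel)                      # 16 peptide ions
#' dplyr::n_distinct(panel$gene)    # 8 marker proteins
load_panel <- function(path = NULL, mz_tol = 0.005) {
  if (is.null(path)) {
    path <- system.file("extdata", "marker_panel.tsv", package = "prmfrac")
  }
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("protein", "gene", "compartment", "peptide",
                "precursor_mz", "precursor_charge", "transitions")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    abort(paste0("Panel file lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad_comp <- setdiff(unique(raw$compartment),
                      c("nuclear", "mitochondrial", "cytosolic"))
  if (length(bad_comp)) {
    abort(paste0("Unknown compartment label(s): ",
                 paste(bad_comp, collapse = ", ")))
  }
  panel <- raw |>
    dplyr::mutate(
      transitions = strsplit(gsub("\\s", "", .data$transitions), ",", fixed = FALSE),
      precursor_charge = as.integer(.data$precursor_charge)
    )
  len <- nchar(panel$peptide)
  if (any(len < 8 | len > 25)) {
    bad <- panel$peptide[len < 8 | len > 25][1]
    abort(sprintf("Peptide '%s' has length %d; panel peptides must be 8-25 residues.",
                  bad, nchar(bad)))
  }
  ntr <- lengths(panel$transitions)
  if (any(ntr < 3)) {
    abort(sprintf("Peptide '%s' lists %d transitions; at least 3 are required.",
                  panel$peptide[ntr < 3][1], min(ntr)))
  }
  recomputed <- precursor_mz(panel$peptide, panel$precursor_charge)
  delta <- panel$precursor_mz - recomputed
  if (any(abs(delta) > mz_tol)) {
    i <- which.max(abs(delta))
    abort(sprintf(
      "Printed precursor m/z %.3f for %s (%d+) deviates from recomputed %.4f by %.4f (tolerance %.3f).",
      panel$precursor_mz[i], panel$peptide[i], panel$precursor_charge[i],
      recomputed[i], delta[i], mz_tol
    ))
  }
  parsed <- parse_fragment_label(unlist(panel$transitions))
  if (anyNA(parsed$series)) {
    abort(sprintf("Unparseable transition label '%s'.",
                  unlist(panel$transitions)[which(is.na(parsed$series))[1]]))
  }
  panel$mz_delta <- delta
  class(panel) <- c("transition_panel", class(panel))
  panel
}

parse_fragment_label <- function(label) {
  m <- stringr::str_match(label, "^([by])(\\d+)(?:\\+{1}|\\^?(\\d+)\\+?)?$")
  charge <- ifelse(is.na(m[, 4]), 1L, suppressWarnings(as.integer(m[, 4])))
  tibble(
    label = label,
    series = m[, 2],
    ordinal = suppressWarnings(as.integer(m[, 3])),
    product_charge = charge
  )
}

#' Expand a panel into its transition table
#'
#' One row per monitored (peptide ion, fragment ion) pair, with product
#' m/z computed from the b/y fragment mass rules.
#'
#' @param panel A [load_panel()] tibble.
#' @return A tibble with columns `protein`, `gene`, `compartment`,
#'   `peptide`, `precursor_mz`, `precursor_charge`, `fragment`, `series`,
#'   `ordinal`, `product_charge`, `product_mz`.
#' @export
#' @examples
#' transition_table(load_panel())
transition_table <- function(panel) {
  long <- panel |>
    as_tibble() |>
    dplyr::select("protein", "gene", "compartment", "peptide",
                  "precursor_mz", "precursor_charge", "transitions") |>
    tidyr::unnest_longer("transitions", values_to = "fragment")
  if (nrow(long) == 0) {
    return(dplyr::mutate(long, series = character(), ordinal = integer(),
                         product_charge = integer(), product_mz = numeric()))
  }
  parsed <- parse_fragment_label(long$fragment)
  long |>
    dplyr::mutate(
      series = parsed$series,
      ordinal = parsed$ordinal,
      product_charge = parsed$product_charge,
      product_mz = fragment_mz(.data$peptide, parsed$series, parsed$ordinal,
                               parsed$product_charge)
    )
}

#' Export a transition list
#'
#' Writes the panel as a flat comma-separated transition list (one row per
#' transition) in the column layout common to targeted-MS method editors.
#'
#' @param panel A [load_panel()] tibble.
#' @param path Output CSV path.
#' @return The exported tibble, invisibly.
#' @export
export_transition_list <- function(panel, path) {
  out <- transition_table(panel) |>
    dplyr::transmute(
      protein = .data$protein,
      gene = .data$gene,
      peptide = .data$peptide,
      precursor_mz = .data$precursor_mz,
      precursor_charge = .data$precursor_charge,
      product_mz = .data$product_mz,
      product_charge = .data$product_charge,
      fragment = .data$fragment,
      compartment = .data$compartment
    )
  readr::write_csv(out, path, progress = FALSE)
  invisible(out)
}

#' Re-import an exported transition list as a panel
#'
#' Inverse of [export_transition_list()]: collapses the per-transition rows
#' back to one row per peptide ion and revalidates the result, so an
#' export/import round trip reproduces the panel.
#'
#' @param path Path to a CSV written by [export_transition_list()].
#' @param mz_tol Passed to the precursor m/z validation.
#' @return A `transition_panel` tibble.
#' @export
read_transition_list <- function(path, mz_tol = 0.005) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  raw |>
    dplyr::group_by(.data$protein, .data$gene, .data$compartment,
                    .data$peptide, .data$precursor_mz, .data$precursor_charge) |>
    dplyr::summarise(transitions = paste(.data$fragment, collapse = ","),
                     .groups = "drop") |>
    dplyr::mutate(accession_human = NA_character_,
                  accession_mouse = NA_character_) |>
    readr::write_tsv(tmp, progress = FALSE)
  load_panel(tmp, mz_tol = mz_tol)
}

#' @export
print.transition_panel <- function(x, ...) {
  cat(sprintf("<transition_panel> %d peptide ions, %d proteins, %d transitions\n",
              nrow(x), dplyr::n_distinct(x$gene), sum(lengths(x$transitions))))
  NextMethod()
}
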