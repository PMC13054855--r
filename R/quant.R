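#' Read a PRM run from mzML
#'
#' Loads the centroided MS2 scans of a PRM acquisition in retention-time
#' order. Each scan carries its isolation-window target and half-widths;
#' files whose MS2 scans lack isolation information are rejected, as are
#' profile-mode spectra (the extraction model assumes centroid peaks).
#'
#' @param path Path to an mzML file.
#' @param default_half_width Isolation half-width (m/z) assumed when the
#'   file does not state one (default 0.85).
#' @return A tibble of class `prm_run` with one row per MS2 scan:
#'   `scan`, `rt` (seconds), `iso_target`, `iso_lower`, `iso_upper`
#'   (window bounds in m/z) and `peaks` (list-column of two-column
#'   matrices `mz`, `intensity`). Run metadata is attached as attributes
#'   `path` and `n_spectra`.
#' @export
read_prm_run <- function(path, default_half_width = 0.85) {
  if (!file.exists(path)) abort(sprintf("mzML file not found: %s", path))
  handle <- tryCatch(
    mzR::openMSfile(path),
    error = function(e) abort(sprintf("Failed to parse '%s': %s", path,
                                      conditionMessage(e)))
  )
  on.exit(mzR::close(handle))
  hdr <- mzR::header(handle)
  ms2 <- which(hdr$msLevel == 2L)
  if (length(ms2) == 0) {
    warn(sprintf("No MS2 scans in '%s'; returning an empty run.", path))
    run <- tibble(scan = integer(), rt = numeric(), iso_target = numeric(),
                  iso_lower = numeric(), iso_upper = numeric(), peaks = list())
    attr(run, "path") <- path
    attr(run, "n_spectra") <- 0L
    class(run) <- c("prm_run", class(run))
    return(run)
  }
  h2 <- hdr[ms2, ]
  if (any(!is.na(h2$centroided) & !h2$centroided)) {
    abort(sprintf("'%s' contains profile-mode MS2 spectra; only centroided PRM data are supported.", path))
  }
  target <- h2$isolationWindowTargetMZ
  if (all(is.na(target))) target <- h2$precursorMZ
  if (any(is.na(target))) {
    abort(sprintf("MS2 scans in '%s' lack isolation-window information.", path))
  }
  lower <- ifelse(is.na(h2$isolationWindowLowerOffset), default_half_width,
                  h2$isolationWindowLowerOffset)
  upper <- ifelse(is.na(h2$isolationWindowUpperOffset), default_half_width,
                  h2$isolationWindowUpperOffset)
  pk <- mzR::peaks(handle, ms2)
  if (is.matrix(pk)) pk <- list(pk)
  pk <- lapply(pk, function(m) {
    colnames(m) <- c("mz", "intensity")
    m
  })
  ord <- order(h2$retentionTime)
  run <- tibble(
    scan = h2$acquisitionNum[ord],
    rt = h2$retentionTime[ord],
    iso_target = target[ord],
    iso_lower = target[ord] - lower[ord],
    iso_upper = target[ord] + upper[ord],
    peaks = pk[ord]
  )
  attr(run, "path") <- path
  attr(run, "n_spectra") <- nrow(hdr)
  class(run) <- c("prm_run", class(run))
  run
}

#' Extract an ion chromatogram for one transition
#'
#' For every scan whose isolation window contains the precursor m/z (and
#' whose retention time falls inside `rt_window`, when given), sums the
#' intensities of centroid peaks within `ppm_tol` of the product m/z. A
#' scan with no matching peak contributes a zero point, so the trace has
#' one point per qualifying scan.
#'
#' @param run A [read_prm_run()] tibble.
#' @param precursor_mz Precursor m/z of the transition.
#' @param product_mz Product (fragment) m/z to extract.
#' @param ppm_tol Mass tolerance in parts per million (default 10).
#' @param rt_window Optional numeric length-2 retention-time window in
#'   seconds; default spans the whole run.
#' @return A tibble of class `chromatogram` with columns `rt` and
#'   `intensity` (strictly increasing `rt`); the transition coordinates
#'   are attached as attributes.
#' @export
extract_xic <- function(run, precursor_mz, product_mz, ppm_tol = 10,
                        rt_window = NULL) {
  if (ppm_tol <= 0) abort("`ppm_tol` must be > 0.")
  keep <- run$iso_lower <= precursor_mz & precursor_mz <= run$iso_upper
  if (!is.null(rt_window)) {
    keep <- keep & run$rt >= rt_window[1] & run$rt <= rt_window[2]
  }
  sel <- run[keep, ]
  tol <- product_mz * ppm_tol * 1e-6
  intensity <- vapply(sel$peaks, function(m) {
    hits <- abs(m[, "mz"] - product_mz) <= tol
    sum(m[hits, "intensity"])
  }, numeric(1))
  chrom <- tibble(rt = sel$rt, intensity = intensity)
  if (nrow(chrom) == 0) {
    attr(chrom, "empty") <- TRUE
  }
  attr(chrom, "precursor_mz") <- precursor_mz
  attr(chrom, "product_mz") <- product_mz
  attr(chrom, "ppm_tol") <- ppm_tol
  class(chrom) <- c("chromatogram", class(chrom))
  chrom
}

#' Integrate a chromatographic peak
#'
#' Locates the global apex, extends the integration boundaries outward
#' until the trace falls below `min_frac` of the apex intensity (or a
#' persistent local minimum marks the start of a neighbouring feature),
#' and integrates by the trapezoidal rule. Areas are in
#' intensity·seconds.
#'
#' @param chrom A [extract_xic()] chromatogram (needs >= 3 points unless
#'   it is entirely empty/zero).
#' @param min_frac Boundary threshold as a fraction of apex intensity
#'   (default 0.01).
#' @return A one-row tibble: `area`, `apex_rt`, `rt_min`, `rt_max`,
#'   `below_detection`.
#' @export
integrate_peak <- function(chrom, min_frac = 0.01) {
  n <- nrow(chrom)
  if (n == 0 || all(chrom$intensity <= 0)) {
    return(tibble(area = 0, apex_rt = NA_real_, rt_min = NA_real_,
                  rt_max = NA_real_, below_detection = TRUE))
  }
  if (n < 3) abort("Chromatogram must have at least 3 points to integrate.")
  y <- chrom$intensity
  x <- chrom$rt
  apex <- which.max(y)
  thr <- min_frac * y[apex]
  # walk outward; stop below threshold or at a local minimum followed by a rise
  left <- apex
  while (left > 1) {
    if (y[left - 1] < thr) { left <- left - 1; break }
    if (left >= 2 && left < apex && y[left] <= y[left + 1] &&
        left > 1 && y[left - 1] > y[left]) break
    left <- left - 1
  }
  right <- apex
  while (right < n) {
    if (y[right + 1] < thr) { right <- right + 1; break }
    if (right > apex && y[right] <= y[right - 1] &&
        right < n && y[right + 1] > y[right]) break
    right <- right + 1
  }
  idx <- left:right
  area <- trapz(x[idx], y[idx])
  tibble(area = area, apex_rt = x[apex], rt_min = x[left], rt_max = x[right],
         below_detection = FALSE)
}

trapz <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Peptide-level total area
#'
#' Arithmetic sum of a peptide's transition areas, excluding flagged
#' transitions. With every transition flagged (or none supplied) the total
#' is missing, with the reason attached.
#'
#' @param areas Numeric vector of per-transition areas.
#' @param flagged Logical vector marking transitions to exclude
#'   (interference, below detection); default none.
#' @return Total area (scalar), or `NA` with attribute `reason` when no
#'   unflagged transition remains.
#' @export
#' @examples
#' peptide_total_area(c(100, 200, 300))
#' peptide_total_area(c(100, 200, 300), flagged = c(TRUE, FALSE, FALSE))
peptide_total_area <- function(areas, flagged = rep(FALSE, length(areas))) {
  stopifnot(length(areas) == length(flagged))
  keep <- !flagged & !is.na(areas)
  if (!any(keep)) {
    reason <- if (length(areas) == 0) "no transitions" else "all transitions flagged"
    return(structure(NA_real_, reason = reason))
  }
  sum(areas[keep])
}

#' Automated interference screen for one peptide's transitions
#'
#' Proxy for manual curation of co-elution: transitions of one peptide
#' must share an elution profile. All-zero traces are flagged
#' `below_detection` and excluded. The screen then runs in two passes:
#' apexes deviating from the consensus (median) apex by more than half the
#' consensus peak width are flagged `apex_shift`, and each trace's median
#' Pearson correlation with the apex-consistent traces must reach
#' `cor_threshold` (`low_correlation` otherwise). Restricting the
#' correlation reference to apex-consistent traces keeps one shifted
#' interferent from dragging down the good transitions. Flags are
#' reported, never silently applied.
#'
#' @param chroms Named list of chromatograms (one per transition of the
#'   same peptide, on a common scan grid).
#' @param cor_threshold Minimum median pairwise correlation (default 0.8).
#' @return A tibble with columns `transition`, `flagged`, `reason`.
#' @export
interference_check <- function(chroms, cor_threshold = 0.8) {
  if (is.null(names(chroms))) names(chroms) <- paste0("transition", seq_along(chroms))
  res <- tibble(transition = names(chroms), flagged = FALSE, reason = NA_character_)
  zero <- vapply(chroms, function(ch) nrow(ch) == 0 || all(ch$intensity <= 0),
                 logical(1))
  res$flagged[zero] <- TRUE
  res$reason[zero] <- "below_detection"
  live <- which(!zero)
  if (length(live) < 2) {
    if (length(live) < length(chroms)) {
      warn("Fewer than two detectable transitions; co-elution screen skipped.")
    }
    return(res)
  }
  npts <- vapply(chroms[live], nrow, integer(1))
  if (length(unique(npts)) > 1) {
    warn("Transitions sampled on different grids; co-elution screen skipped.")
    return(res)
  }
  mat <- vapply(chroms[live], function(ch) ch$intensity, numeric(npts[1]))
  rts <- chroms[[live[1]]]$rt
  # pass 1: apex consistency against the consensus (median) apex, with the
  # FWHM of the summed trace as the peak-width yardstick
  apexes <- rts[apply(mat, 2, which.max)]
  consensus <- stats::median(apexes)
  total <- rowSums(mat)
  half <- max(total) / 2
  above <- which(total >= half)
  width <- if (length(above) >= 2) rts[max(above)] - rts[min(above)] else
    diff(range(rts))
  apex_ok <- abs(apexes - consensus) <= width / 2
  for (j in which(!apex_ok)) {
    res$flagged[live[j]] <- TRUE
    res$reason[live[j]] <- "apex_shift"
  }
  # pass 2: co-elution correlation among the apex-consistent traces, so a
  # single shifted interferent cannot drag the good transitions down
  ref <- which(apex_ok)
  if (length(ref) >= 2) {
    cc <- suppressWarnings(stats::cor(mat))
    cc[!is.finite(cc)] <- 0
    for (j in seq_along(live)) {
      others <- setdiff(ref, j)
      if (length(others) == 0) next
      med_cor <- stats::median(cc[others, j])
      if (med_cor < cor_threshold) {
        res$flagged[live[j]] <- TRUE
        res$reason[live[j]] <- if (is.na(res$reason[live[j]])) {
          "low_correlation"
        } else {
          paste(res$reason[live[j]], "low_correlation", sep = "+")
        }
      }
    }
  }
  res
}

#' Quantify a panel in one PRM run
#'
#' Extracts, screens and integrates every panel transition in one run and
#' sums unflagged transition areas to peptide level.
#'
#' @param run A [read_prm_run()] tibble (or a path to an mzML file).
#' @param panel A [load_panel()] tibble.
#' @param ppm_tol XIC mass tolerance in ppm (default 10).
#' @param rt_window Optional retention-time window (seconds) applied to
#'   all extractions.
#' @param screen Apply [interference_check()] and exclude flagged
#'   transitions from totals (default TRUE).
#' @return A tibble with one row per transition: `protein`, `gene`,
#'   `compartment`, `peptide`, `precursor_charge`, `fragment`, `area`,
#'   `flagged`, `flag_reason`, `total_area` (peptide-level sum, repeated
#'   across the peptide's rows; `NA` when all transitions are flagged).
#' @export
quantify_run <- function(run, panel, ppm_tol = 10, rt_window = NULL,
                         screen = TRUE) {
  if (is.character(run)) run <- read_prm_run(run)
  tt <- transition_table(panel)
  tt |>
    dplyr::group_by(.data$protein, .data$gene, .data$compartment,
                    .data$peptide, .data$precursor_charge) |>
    dplyr::group_modify(function(d, key) {
      chroms <- purrr::map(seq_len(nrow(d)), function(i) {
        extract_xic(run, d$precursor_mz[i], d$product_mz[i],
                    ppm_tol = ppm_tol, rt_window = rt_window)
      })
      names(chroms) <- d$fragment
      peaks <- purrr::map_dfr(chroms, integrate_peak)
      if (screen && nrow(d) >= 2) {
        flags <- interference_check(chroms)
      } else {
        flags <- tibble(transition = d$fragment,
                        flagged = peaks$below_detection,
                        reason = ifelse(peaks$below_detection,
                                        "below_detection", NA_character_))
      }
      total <- peptide_total_area(peaks$area, flags$flagged)
      tibble(
        fragment = d$fragment,
        product_mz = d$product_mz,
        area = peaks$area,
        apex_rt = peaks$apex_rt,
        flagged = flags$flagged,
        flag_reason = flags$reason,
        total_area = as.numeric(total)
      )
    }) |>
    dplyr::ungroup()
}

#' Quantify a set of runs described by a sample sheet
#'
#' @param sample_sheet A tibble with columns `path`, `fraction`
#'   (C/M/N/PT), `replicate` (see [read_sample_sheet()]).
#' @param panel A [load_panel()] tibble.
#' @inheritParams quantify_run
#' @return Per-transition quantification table across runs, with `run`,
#'   `fraction` and `replicate` columns prepended.
#' @export
quantify_runs <- function(sample_sheet, panel, ppm_tol = 10,
                          rt_window = NULL, screen = TRUE) {
  validate_sample_sheet(sample_sheet)
  purrr::pmap_dfr(
    sample_sheet[, c("path", "fraction", "replicate")],
    function(path, fraction, replicate) {
      quantify_run(path, panel, ppm_tol = ppm_tol, rt_window = rt_window,
                   screen = screen) |>
        dplyr::mutate(run = basename(path), fraction = fraction,
                      replicate = replicate, .before = 1)
    }
  )
}

#' Collapse a transition-level quant table to peptide totals
#'
#' @param quant Output of [quantify_runs()].
#' @return One row per (run, peptide): total area and number of unflagged
#'   transitions used.
#' @export
peptide_totals <- function(quant) {
  quant |>
    dplyr::group_by(dplyr::across(dplyr::any_of(c(
      "run", "fraction", "replicate", "protein", "gene", "compartment",
      "peptide", "precursor_charge"
    )))) |>
    dplyr::summarise(
      total_area = .data$total_area[1],
      n_transitions_used = sum(!.data$flagged),
      .groups = "drop"
    )
}
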