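#' Describe a synthetic fractionation experiment
#'
#' Defines the generative model behind the package's synthetic PRM data:
#' each panel peptide gets a ground-truth mean total area per fraction
#' (its home fraction, from the marker's compartment, elevated
#' `fold_enrichment`-fold over the others), replicate areas scatter
#' log-normally with coefficient of variation `cv`, and each transition
#' elutes as a Gaussian peak whose integrated area is the peptide total
#' area times the transition's relative weight. Defaults mirror the
#' standard fraction-purity study design: 3 fractions (C/M/N) times 3
#' biological replicates with a 10-fold home-fraction enrichment.
#'
#' @param panel A [load_panel()] tibble.
#' @param fractions Fraction labels to simulate (subset of C/M/N/PT). A
#'   PT channel, when requested, gets the mean of the three fraction
#'   means (a whole-lysate reference).
#' @param replicates Replicates per fraction (default 3).
#' @param fold_enrichment Home-fraction fold change over the two other
#'   fractions (default 10).
#' @param base_area Mean total area in non-home fractions (arbitrary
#'   intensity·seconds, default 1e5).
#' @param cv Replicate coefficient of variation of the log-normal area
#'   noise (default 0.15; 0 disables noise).
#' @param peak_sigma Gaussian elution peak sigma in seconds (default 4).
#' @param scan_interval Time between consecutive scans of one precursor
#'   (default 1.5 s).
#' @param rt_spacing Spacing between consecutive peptide apexes (default
#'   30 s, i.e. >= 6 sigma, so peptides cannot interfere unless asked to).
#' @param baseline Additive baseline intensity per matched centroid
#'   (default 0).
#' @param interference Optional list(`peptide`, `fragment`, `ppm_offset`,
#'   `rel_intensity`, `rt_shift`) injecting a contaminating peak near one
#'   product m/z.
#' @return A list of class `simulation_design`.
#' @export
simulation_design <- function(panel, fractions = c("C", "M", "N"),
                              replicates = 3, fold_enrichment = 10,
                              base_area = 1e5, cv = 0.15, peak_sigma = 4,
                              scan_interval = 1.5, rt_spacing = 30,
                              baseline = 0, interference = NULL) {
  stopifnot(fold_enrichment > 0, peak_sigma > 0, scan_interval > 0,
            replicates >= 1)
  bad <- setdiff(fractions, c("C", "M", "N", "PT"))
  if (length(bad)) abort(paste0("Unknown fraction label(s): ",
                                paste(bad, collapse = ", ")))
  home_map <- c(nuclear = "N", mitochondrial = "M", cytosolic = "C")
  tt <- transition_table(panel)
  # per-peptide transition weights: linearly decreasing, normalised to 1
  weights <- tt |>
    dplyr::group_by(.data$peptide) |>
    dplyr::mutate(weight = rev(seq_len(dplyr::n())) / sum(seq_len(dplyr::n()))) |>
    dplyr::ungroup()
  peptides <- panel |>
    as_tibble() |>
    dplyr::mutate(
      home = unname(home_map[.data$compartment]),
      apex_rt = 60 + (dplyr::row_number() - 1) * rt_spacing
    )
  truth <- tidyr::crossing(
    peptides[, c("gene", "peptide", "compartment", "home")],
    fraction = fractions
  ) |>
    dplyr::mutate(mean_area = dplyr::case_when(
      .data$fraction == "PT" ~ base_area * (fold_enrichment + 2) / 3,
      .data$fraction == .data$home ~ base_area * fold_enrichment,
      TRUE ~ base_area
    ))
  structure(
    list(panel = panel, transitions = weights, peptides = peptides,
         ground_truth = truth, fractions = fractions,
         replicates = replicates, fold_enrichment = fold_enrichment,
         base_area = base_area, cv = cv, peak_sigma = peak_sigma,
         scan_interval = scan_interval, rt_spacing = rt_spacing,
         baseline = baseline, interference = interference),
    class = "simulation_design"
  )
}

lognormal_areas <- function(mean_area, cv) {
  if (cv == 0) return(mean_area)
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean_area) - sdlog^2 / 2
  stats::rlnorm(length(mean_area), meanlog = meanlog, sdlog = sdlog)
}

#' Draw a replicate area table from a simulation design
#'
#' Samples per-replicate peptide total areas around the design's
#' ground-truth fraction means using a multiplicative log-normal noise
#' model calibrated so that the expected value equals the mean and the
#' coefficient of variation equals `design$cv`. With `cv = 0` the areas
#' equal the means exactly. A fixed seed reproduces the table exactly.
#'
#' @param design A [simulation_design()].
#' @param seed Integer random seed (default 1).
#' @return A list with `areas` (tibble: `fraction`, `replicate`, `gene`,
#'   `compartment`, `peptide`, `total_area`) and `ground_truth` (the
#'   design's mean-area table).
#' @export
simulate_area_table <- function(design, seed = 1L) {
  stopifnot(inherits(design, "simulation_design"))
  tab <- tidyr::crossing(design$ground_truth,
                         replicate = seq_len(design$replicates))
  set.seed(seed)
  tab$total_area <- lognormal_areas(tab$mean_area, design$cv)
  areas <- tab |>
    dplyr::select("fraction", "replicate", "gene", "compartment",
                  "peptide", "total_area") |>
    dplyr::arrange(.data$fraction, .data$replicate, .data$peptide)
  list(areas = areas, ground_truth = design$ground_truth)
}

#' Write one simulated PRM run to mzML
#'
#' Emits a centroided MS2 scan stream: each panel peptide is scheduled
#' around its apex (apex +/- 5 sigma at the design's scan interval), the
#' isolation window targets the printed precursor m/z with +/- 0.85 m/z
#' half-width, and every transition contributes a centroid peak at its
#' exact product m/z whose Gaussian elution profile integrates to
#' `total_area x transition weight`. Optional baseline and interference
#' peaks are added per the design.
#'
#' @param design A [simulation_design()].
#' @param areas Peptide total areas for this run: tibble with columns
#'   `peptide`, `total_area` (e.g. one fraction/replicate slice of
#'   [simulate_area_table()]).
#' @param path Output mzML path.
#' @return `path`, invisibly.
#' @export
simulate_prm_run <- function(design, areas, path) {
  stopifnot(inherits(design, "simulation_design"))
  tt <- design$transitions
  peps <- design$peptides
  scans <- list(); meta <- list()
  for (i in seq_len(nrow(peps))) {
    pep <- peps$peptide[i]
    total <- areas$total_area[match(pep, areas$peptide)]
    if (is.na(total)) next
    tr <- tt[tt$peptide == pep, ]
    times <- seq(peps$apex_rt[i] - 5 * design$peak_sigma,
                 peps$apex_rt[i] + 5 * design$peak_sigma,
                 by = design$scan_interval)
    for (t in times) {
      mzs <- tr$product_mz
      ints <- total * tr$weight *
        stats::dnorm(t, peps$apex_rt[i], design$peak_sigma) + design$baseline
      intf <- design$interference
      if (!is.null(intf) && identical(intf$peptide, pep)) {
        jtr <- match(intf$fragment, tr$fragment)
        if (!is.na(jtr)) {
          shift <- if (is.null(intf$rt_shift)) 0 else intf$rt_shift
          rel <- if (is.null(intf$rel_intensity)) 1 else intf$rel_intensity
          mz_off <- tr$product_mz[jtr] * (1 + intf$ppm_offset * 1e-6)
          mzs <- c(mzs, mz_off)
          ints <- c(ints, rel * total * tr$weight[jtr] *
                      stats::dnorm(t, peps$apex_rt[i] + shift, design$peak_sigma))
        }
      }
      keep <- ints > 0
      ord <- order(mzs[keep])
      scans[[length(scans) + 1]] <-
        cbind(mz = mzs[keep][ord], intensity = ints[keep][ord])
      meta[[length(meta) + 1]] <-
        c(rt = t, target = peps$precursor_mz[i], charge = peps$precursor_charge[i])
    }
  }
  write_mzml(scans, meta, path)
  invisible(path)
}

write_mzml <- function(scans, meta, path) {
  n <- length(scans)
  if (n == 0) {
    # header-only file: one empty MS1 placeholder is not written; emit a
    # minimal valid mzML with zero spectra via mzR
    mzR::writeMSData(list(), file = path,
                     header = empty_mzml_header())
    return(invisible(path))
  }
  rt <- vapply(meta, `[[`, numeric(1), "rt")
  ord <- order(rt)
  scans <- scans[ord]; meta <- meta[ord]
  hdr <- empty_mzml_header()[rep(1, n), ]
  for (i in seq_len(n)) {
    hdr$seqNum[i] <- i
    hdr$acquisitionNum[i] <- i
    hdr$spectrumId[i] <- paste0("scan=", i)
    hdr$retentionTime[i] <- meta[[i]][["rt"]]
    hdr$precursorMZ[i] <- meta[[i]][["target"]]
    hdr$precursorCharge[i] <- as.integer(meta[[i]][["charge"]])
    hdr$isolationWindowTargetMZ[i] <- meta[[i]][["target"]]
    hdr$peaksCount[i] <- nrow(scans[[i]])
    hdr$totIonCurrent[i] <- sum(scans[[i]][, "intensity"])
    if (nrow(scans[[i]])) {
      bp <- which.max(scans[[i]][, "intensity"])
      hdr$basePeakMZ[i] <- scans[[i]][bp, "mz"]
      hdr$basePeakIntensity[i] <- scans[[i]][bp, "intensity"]
      hdr$lowMZ[i] <- min(scans[[i]][, "mz"])
      hdr$highMZ[i] <- max(scans[[i]][, "mz"])
    }
  }
  rownames(hdr) <- NULL
  mzR::writeMSData(scans, file = path, header = hdr, outformat = "mzml")
  invisible(path)
}

empty_mzml_header <- function() {
  data.frame(
    seqNum = 1L, acquisitionNum = 1L, msLevel = 2L, polarity = 1L,
    peaksCount = 0L, totIonCurrent = 0, retentionTime = 0,
    basePeakMZ = 0, basePeakIntensity = 0, collisionEnergy = 27,
    ionisationEnergy = 0, lowMZ = 0, highMZ = 0, precursorScanNum = 0L,
    precursorMZ = 0, precursorCharge = 0L, precursorIntensity = 0,
    mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_, spectrumId = "scan=1",
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = 0, isolationWindowLowerOffset = 0.85,
    isolationWindowUpperOffset = 0.85, scanWindowLowerLimit = 50,
    scanWindowUpperLimit = 2000, stringsAsFactors = FALSE
  )
}

#' Simulate a complete fractionation experiment to disk
#'
#' Draws one replicate area table and writes one mzML PRM run per
#' (fraction, replicate), returning the sample sheet and the ground
#' truth needed to score recovery.
#'
#' @param design A [simulation_design()].
#' @param out_dir Output directory (created if needed).
#' @param seed Integer random seed.
#' @return A list: `sample_sheet` (tibble `path`, `fraction`,
#'   `replicate`, `kind`), `areas`, `ground_truth`.
#' @export
simulate_experiment <- function(design, out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_area_table(design, seed = seed)
  sheet <- sim$areas |>
    dplyr::distinct(.data$fraction, .data$replicate) |>
    dplyr::mutate(
      path = file.path(out_dir, sprintf("%s_rep%d.mzML", .data$fraction,
                                        .data$replicate)),
      kind = "biological"
    )
  for (i in seq_len(nrow(sheet))) {
    slice <- sim$areas |>
      dplyr::filter(.data$fraction == sheet$fraction[i],
                    .data$replicate == sheet$replicate[i])
    simulate_prm_run(design, slice, sheet$path[i])
  }
  list(sample_sheet = sheet[, c("path", "fraction", "replicate", "kind")],
       areas = sim$areas, ground_truth = sim$ground_truth)
}
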