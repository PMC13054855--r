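#' In-silico tryptic digestion
#'
#' Cleaves after K or R except when the next residue is proline (classic
#' trypsin rule), then emits every concatenation of at most
#' `max_missed + 1` adjacent fully-tryptic fragments, ordered from the
#' N-terminus.
#'
#' @param sequence A single protein sequence, or a named character vector /
#'   data frame with columns `protein` and `sequence` for several proteins.
#' @param max_missed Maximum number of internal missed cleavage sites
#'   (default 0).
#' @return A tibble with columns `protein`, `peptide`, `start`, `end` and
#'   `missed_cleavages`, ordered N- to C-terminal (then by missed-cleavage
#'   count at equal start).
#' @export
#' @examples
#' digest_trypsin("AAAKGGGRCCC")
#' digest_trypsin("AKRLK", max_missed = 1)
digest_trypsin <- function(sequence, max_missed = 0L) {
  if (max_missed < 0) abort("`max_missed` must be >= 0.")
  if (is.data.frame(sequence)) {
    stopifnot(all(c("protein", "sequence") %in% names(sequence)))
    prot <- sequence$protein
    seqs <- sequence$sequence
  } else {
    seqs <- unname(sequence)
    prot <- if (is.null(names(sequence))) {
      if (length(sequence) == 1) "protein" else paste0("protein", seq_along(sequence))
    } else {
      names(sequence)
    }
  }
  purrr::map2_dfr(prot, seqs, digest_one, max_missed = max_missed)
}

digest_one <- function(protein, sequence, max_missed) {
  chars <- check_sequence(sequence)[[1]]
  n <- length(chars)
  # cleave after position i when residue i is K/R and i+1 is not P
  cut_after <- which(chars %in% c("K", "R"))
  cut_after <- cut_after[cut_after == n | chars[pmin(cut_after + 1, n)] != "P"]
  bounds <- c(0L, cut_after, if (length(cut_after) == 0 || max(cut_after) < n) n)
  bounds <- unique(bounds)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  k <- length(starts)
  out <- vector("list", k)
  for (i in seq_len(k)) {
    jmax <- min(k, i + max_missed)
    js <- i:jmax
    out[[i]] <- tibble(
      protein = protein,
      peptide = vapply(js, function(j) substr(sequence, starts[i], ends[j]), character(1)),
      start = starts[i],
      end = ends[js],
      missed_cleavages = js - i
    )
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$start, .data$missed_cleavages)
}

#' Proteotypic-candidate selection rules
#'
#' The peptide-selection criteria of the assay: length between 8 and 25
#' residues, no missed cleavages, and soft avoidance of chemically labile
#' methionine and tryptophan (avoided peptides are kept only when a protein
#' offers fewer than `min_clean` clean candidates).
#'
#' @param min_len,max_len Allowed peptide length range (residues).
#' @param max_missed Maximum missed cleavages retained (default 0).
#' @param avoid_residues Residues to avoid when alternatives exist.
#' @param min_clean Minimum number of clean candidates a protein must have
#'   before avoided-residue peptides are dropped (default 2).
#' @return A list of class `selection_rules`.
#' @export
selection_rules <- function(min_len = 8L, max_len = 25L, max_missed = 0L,
                            avoid_residues = c("M", "W"), min_clean = 2L) {
  if (min_len > max_len) abort("`min_len` must be <= `max_len`.")
  if (max_missed < 0) abort("`max_missed` must be >= 0.")
  structure(
    list(min_len = min_len, max_len = max_len, max_missed = max_missed,
         avoid_residues = avoid_residues, min_clean = min_clean),
    class = "selection_rules"
  )
}

#' Filter and rank proteotypic peptide candidates
#'
#' Applies [selection_rules()] to a digest table: drops peptides outside
#' the length window or with more than the allowed missed cleavages,
#' partitions the rest into clean peptides and fallbacks carrying avoided
#' residues, and keeps fallbacks only for proteins with fewer than
#' `min_clean` clean candidates. Ordering is deterministic: clean first,
#' then ascending length, then lexicographic.
#'
#' @param peptides A tibble as returned by [digest_trypsin()] (columns
#'   `protein`, `peptide`, `missed_cleavages`).
#' @param rules A [selection_rules()] object.
#' @param evidence Optional character vector of peptide sequences with
#'   prior experimental evidence (e.g. shotgun identifications); when
#'   supplied, candidates are restricted to it.
#' @return A tibble with columns `protein`, `peptide`, `length`, `clean`
#'   and `rank` (per protein).
#' @export
filter_candidates <- function(peptides, rules = selection_rules(),
                              evidence = NULL) {
  if (nrow(peptides) == 0) {
    return(tibble(protein = character(), peptide = character(),
                  length = integer(), clean = logical(), rank = integer()))
  }
  avoid_re <- paste0("[", paste(rules$avoid_residues, collapse = ""), "]")
  out <- peptides |>
    dplyr::mutate(length = nchar(.data$peptide)) |>
    dplyr::filter(
      .data$length >= rules$min_len, .data$length <= rules$max_len,
      .data$missed_cleavages <= rules$max_missed
    ) |>
    dplyr::mutate(
      clean = if (length(rules$avoid_residues)) {
        !stringr::str_detect(.data$peptide, avoid_re)
      } else {
        TRUE
      }
    )
  if (!is.null(evidence)) {
    out <- dplyr::filter(out, .data$peptide %in% evidence)
  }
  out |>
    dplyr::group_by(.data$protein) |>
    dplyr::filter(.data$clean | sum(.data$clean) < rules$min_clean) |>
    dplyr::arrange(dplyr::desc(.data$clean), .data$length, .data$peptide,
                   .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::distinct(.data$protein, .data$peptide, .keep_all = TRUE) |>
    dplyr::select("protein", "peptide", "length", "clean", "rank")
}

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper around `Biostrings::readAAStringSet()` returning the tidy
#' two-column layout the digestion functions accept.
#'
#' @param path Path to an (uncompressed) amino-acid FASTA file.
#' @return A tibble with columns `protein` (first word of the header) and
#'   `sequence`.
#' @export
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("Package 'Biostrings' is required to read FASTA files.")
  }
  aa <- Biostrings::readAAStringSet(path)
  tibble(
    protein = vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1),
    sequence = as.character(aa)
  )
}
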