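test_that("tryptic digestion follows the KR-not-before-P rule", {
  expect_equal(digest_trypsin("AAAKGGGRCCC")$peptide, c("AAAK", "GGGR", "CCC"))
  expect_equal(digest_trypsin("AAAKPGGG")$peptide, "AAAKPGGG")
  expect_setequal(digest_trypsin("AKRLK", max_missed = 1)$peptide,
                  c("AK", "R", "LK", "AKR", "RLK"))
  expect_error(digest_trypsin("AB1K"), "Unknown residue")
})

test_that("digestion equals the brute-force oracle on random proteins", {
  set.seed(42)
  for (i in 1:200) {
    s <- random_protein(150)
    for (mm in 0:1) {
      got <- digest_trypsin(s, max_missed = mm)
      want <- oracle_digest(s, max_missed = mm)
      expect_equal(sort(paste(got$peptide, got$missed_cleavages)),
                   sort(paste(want$peptide, want$missed_cleavages)),
                   info = paste("seq", i, "mm", mm))
    }
  }
})

test_that("candidate filtering applies length, cleavage and soft-avoidance rules", {
  peps <- tibble::tibble(
    protein = c("P1", "P1", "P1", "P1"),
    peptide = c("SHORTK", "AGELVSDLKK", "TGQVESALR", "DLSVGETANR"),
    missed_cleavages = c(0, 1, 0, 0)
  )
  out <- filter_candidates(peps)
  # 6-mer too short, missed-cleavage peptide dropped
  expect_setequal(out$peptide, c("TGQVESALR", "DLSVGETANR"))

  # protein whose only in-range peptides carry Met: all retained as fallback
  met_only <- tibble::tibble(
    protein = "P2",
    peptide = c("IMQEYQLEQK", "TQVTVQYMQDR", "AMSELTGQLK"),
    missed_cleavages = 0
  )
  out2 <- filter_candidates(met_only)
  expect_equal(nrow(out2), 3)
  expect_true(all(!out2$clean))

  # with >= 2 clean alternatives the Met peptides are dropped
  mixed <- dplyr::bind_rows(met_only, tibble::tibble(
    protein = "P2", peptide = c("TGQVESALR", "DLSVGETANR"),
    missed_cleavages = 0
  ))
  out3 <- filter_candidates(mixed)
  expect_setequal(out3$peptide, c("TGQVESALR", "DLSVGETANR"))

  # deterministic ordering: clean first, then length, then lexicographic
  expect_equal(out3$rank, seq_len(nrow(out3)))
  expect_equal(out3$peptide, c("TGQVESALR", "DLSVGETANR"))

  # empty input is not an error
  expect_equal(nrow(filter_candidates(peps[0, ])), 0)

  # evidence list restricts candidates
  out4 <- filter_candidates(mixed, evidence = "TGQVESALR")
  expect_equal(out4$peptide, "TGQVESALR")
})

test_that("the packaged marker panel loads and validates", {
  panel <- load_panel()
  expect_equal(nrow(panel), 16)
  expect_equal(dplyr::n_distinct(panel$gene), 8)
  expect_equal(sum(lengths(panel$transitions)), 76)
  expect_setequal(unique(panel$compartment),
                  c("nuclear", "mitochondrial", "cytosolic"))
  expect_true(all(abs(panel$mz_delta) <= 0.001))
  expect_true(all(nchar(panel$peptide) >= 8 & nchar(panel$peptide) <= 25))
  expect_true(all(lengths(panel$transitions) >= 3))
})

test_that("panel validation rejects malformed configurations", {
  base <- readr::read_tsv(panel_path(), show_col_types = FALSE)
  tmp <- tempfile(fileext = ".tsv")

  bad_len <- base
  bad_len$peptide[1] <- strrep("A", 26)
  readr::write_tsv(bad_len, tmp)
  expect_error(load_panel(tmp), "8-25 residues")

  bad_mz <- base
  bad_mz$precursor_mz[bad_mz$peptide == "EGDLIAAQAR"] <- 523.278
  readr::write_tsv(bad_mz, tmp)
  expect_error(load_panel(tmp), "EGDLIAAQAR")

  bad_tr <- base
  bad_tr$transitions[1] <- "y7+,y6+"
  readr::write_tsv(bad_tr, tmp)
  expect_error(load_panel(tmp), "at least 3")

  bad_comp <- base
  bad_comp$compartment[1] <- "membrane"
  readr::write_tsv(bad_comp, tmp)
  expect_error(load_panel(tmp), "compartment")
})

test_that("every panel peptide is fully tryptic in its parent scaffold", {
  panel <- load_panel()
  parents <- read_fasta(synthetic_parents_path())
  dig <- digest_trypsin(parents, max_missed = 0)
  expect_true(all(panel$peptide %in% dig$peptide))
  # soft avoidance: clean panel peptides always pass; Met-containing ones
  # pass when their protein lacks 2 clean alternatives (NDUFAF4, HSP90AB1)
  pool <- dplyr::semi_join(dig, tibble::tibble(peptide = panel$peptide),
                           by = "peptide")
  kept <- filter_candidates(pool)
  clean <- panel$peptide[!grepl("[MW]", panel$peptide)]
  expect_true(all(clean %in% kept$peptide))
  expect_true(all(c("IMQEYQLEQK", "YHTSQSGDEMTSLSEYVSR") %in% kept$peptide))
  # MAT2A offers two clean candidates, so its Met peptide is dropped under
  # the default threshold and retained once the per-protein requirement
  # asks for three candidates (the published assay keeps it on
  # prior-evidence grounds)
  expect_false("TQVTVQYMQDR" %in% kept$peptide)
  relaxed <- filter_candidates(pool, selection_rules(min_clean = 3))
  expect_true(all(panel$peptide %in% relaxed$peptide))
})

test_that("transition-list export round-trips losslessly", {
  panel <- load_panel()
  tmp <- tempfile(fileext = ".csv")
  exported <- export_transition_list(panel, tmp)
  expect_equal(nrow(exported), 76)
  back <- read_transition_list(tmp)
  a <- dplyr::arrange(as.data.frame(panel)[, c("gene", "peptide", "precursor_mz",
                                               "precursor_charge")], peptide)
  b <- dplyr::arrange(as.data.frame(back)[, c("gene", "peptide", "precursor_mz",
                                              "precursor_charge")], peptide)
  expect_equal(a, b)
  tr_a <- lapply(panel$transitions[order(panel$peptide)], sort)
  tr_b <- lapply(back$transitions[order(back$peptide)], sort)
  expect_equal(tr_a, tr_b)

  # empty panel exports a header-only file
  tmp2 <- tempfile(fileext = ".csv")
  export_transition_list(panel[0, ], tmp2)
  expect_equal(length(readLines(tmp2)), 1)
})

test_that("product m/z in the export matches the fragment mass rules", {
  tt <- transition_table(load_panel())
  y7 <- tt[tt$peptide == "EGDLIAAQAR" & tt$fragment == "y7+", ]
  expect_equal(y7$product_mz, 742.456999, tolerance = 1e-5)
  b3 <- tt[tt$peptide == "EGDLIAAQAR" & tt$fragment == "b3+", ]
  expect_equal(b3$product_mz, 302.098276, tolerance = 1e-5)
})
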