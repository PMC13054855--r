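# Independent oracles and fixture builders shared across tests.

# Brute-force tryptic digestion: scan for cleavage sites, then enumerate
# all concatenations of <= max_missed + 1 adjacent fully-tryptic fragments.
oracle_digest <- function(sequence, max_missed = 0) {
  ch <- strsplit(sequence, "")[[1]]
  n <- length(ch)
  cuts <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] %in% c("K", "R") && (i == n || ch[i + 1] != "P")) {
      cuts <- c(cuts, i)
    }
  }
  bounds <- unique(c(0, cuts, n))
  starts <- bounds[-length(bounds)] + 1
  ends <- bounds[-1]
  out <- character(0)
  mc <- integer(0)
  for (i in seq_along(starts)) {
    for (m in 0:max_missed) {
      j <- i + m
      if (j > length(ends)) break
      out <- c(out, substr(sequence, starts[i], ends[j]))
      mc <- c(mc, m)
    }
  }
  data.frame(peptide = out, missed_cleavages = mc, stringsAsFactors = FALSE)
}

random_protein <- function(max_len = 200) {
  len <- sample(10:max_len, 1)
  paste(sample(c("G","A","S","P","V","T","C","L","I","N","D","Q","K","E",
                 "M","H","F","R","Y","W"), len, replace = TRUE),
        collapse = "")
}

# Upper-tail studentized-range probability by direct numeric integration:
# Q = R / S with R the range of k iid standard normals and S an independent
# chi/sqrt(df) scale. Inner integral gives P(R <= r); the outer integrates
# over the density of S.
oracle_ptukey_upper <- function(q, k, df) {
  p_range <- function(r) {
    if (r <= 0) return(0)
    f <- function(z) {
      k * stats::dnorm(z) * (stats::pnorm(z) - stats::pnorm(z - r))^(k - 1)
    }
    stats::integrate(f, -Inf, Inf, rel.tol = 1e-10)$value
  }
  dS <- function(s) {
    exp((df / 2) * log(df) - lgamma(df / 2) - (df / 2 - 1) * log(2) +
          (df - 1) * log(s) - df * s^2 / 2)
  }
  outer <- stats::integrate(
    Vectorize(function(s) dS(s) * p_range(q * s)),
    0, Inf, rel.tol = 1e-8
  )$value
  1 - outer
}

# Brute-force one-way ANOVA from sums of squares.
oracle_anova_f <- function(groups) {
  y <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  grand <- mean(y)
  means <- tapply(y, g, mean)
  ssb <- sum(lengths(groups) * (means - grand)^2)
  ssw <- sum((y - means[g])^2)
  k <- length(groups)
  n <- length(y)
  (ssb / (k - 1)) / (ssw / (n - k))
}

panel_path <- function() {
  system.file("extdata", "marker_panel.tsv", package = "prmfrac")
}

synthetic_parents_path <- function() {
  system.file("extdata", "synthetic_parent_proteins.fasta",
              package = "prmfrac")
}

# In-memory PRM scan stream for XIC tests: one isolation window, peaks
# given as list of mz/intensity matrices.
make_run <- function(rts, peaks, iso_target = 500, half_width = 0.85) {
  run <- tibble::tibble(
    scan = seq_along(rts),
    rt = rts,
    iso_target = iso_target,
    iso_lower = iso_target - half_width,
    iso_upper = iso_target + half_width,
    peaks = peaks
  )
  class(run) <- c("prm_run", class(run))
  run
}

gaussian_chrom <- function(area, apex, sigma, rts) {
  tibble::tibble(rt = rts, intensity = area * stats::dnorm(rts, apex, sigma))
}

# Replicate area table for the statistics layer, bypassing quantification.
make_totals <- function(means, n = 3, cv = 0, gene = "LMNA",
                        peptide = "EGDLIAAQAR", compartment = "nuclear",
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tidyr::crossing(fraction = names(means), replicate = seq_len(n)) |>
    dplyr::mutate(
      gene = gene, peptide = peptide, compartment = compartment,
      total_area = if (cv == 0) means[fraction] else {
        sdlog <- sqrt(log(1 + cv^2))
        stats::rlnorm(dplyr::n(), log(means[fraction]) - sdlog^2 / 2, sdlog)
      }
    )
}
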