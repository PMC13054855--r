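test_that("CV% uses the sample standard deviation over the mean", {
  expect_equal(cv_percent(c(5, 5, 5)), 0)
  expect_equal(cv_percent(c(1, 2, 3)), 50)
  single <- cv_percent(10)
  expect_true(is.na(single))
  expect_match(attr(single, "reason"), "fewer than 2")
  zero_mean <- cv_percent(c(-1, 1))
  expect_match(attr(zero_mean, "reason"), "mean")
  expect_equal(cv_percent(c(1, 2, NA, 3)), 50)
})

test_that("enrichment ratios divide fraction means and are antisymmetric", {
  expect_equal(enrichment_ratio(c(3, 3), c(3, 3)), 1)
  expect_equal(enrichment_ratio(c(20, 20, 20), c(2, 2, 2)), 10)
  set.seed(11)
  a <- runif(5, 1, 100); b <- runif(5, 1, 100)
  expect_equal(enrichment_ratio(a, b), 1 / enrichment_ratio(b, a),
               tolerance = 1e-12)
  inf <- enrichment_ratio(c(1, 2), c(0, 0))
  expect_true(is.infinite(inf))
  expect_equal(attr(inf, "flag"), "zero denominator")
})

test_that("one-way ANOVA matches hand and brute-force computations", {
  d <- data.frame(
    area = c(1, 2, 3, 2, 3, 4, 3, 4, 5),
    fraction = rep(c("C", "M", "N"), each = 3)
  )
  fit <- anova_oneway(d, area, fraction)
  # hand computation: between SS = 3[(2-3)^2 + 0 + (4-3)^2] = 6 on 2 df,
  # within SS = 3 x 2 = 6 on 6 df, F = (6/2)/(6/6) = 3
  expect_equal(fit$statistic, 3, tolerance = 1e-10)
  expect_equal(fit$statistic, oracle_anova_f(list(c(1, 2, 3), c(2, 3, 4),
                                                  c(3, 4, 5))),
               tolerance = 1e-12)
  expect_equal(unname(fit$df), c(2, 6))

  # identical groups: F = 0, p = 1
  same <- data.frame(area = rep(7, 9), fraction = rep(c("C", "M", "N"), 3))
  fit0 <- anova_oneway(same, area, fraction)
  expect_equal(fit0$statistic, 0)
  expect_equal(fit0$p.value, 1)

  # zero within-group variance, non-zero between: p -> 0 sentinel
  sep <- data.frame(area = rep(c(1, 2), each = 3),
                    fraction = rep(c("C", "M"), each = 3))
  fits <- anova_oneway(sep, area, fraction)
  expect_true(is.infinite(fits$statistic))
  expect_equal(fits$p.value, 0)

  # two groups: F equals the squared pooled-variance t statistic
  two <- data.frame(area = c(1.2, 3.1, 2.4, 4.0, 5.2, 3.9),
                    fraction = rep(c("C", "M"), each = 3))
  fit2 <- anova_oneway(two, area, fraction)
  tt <- t.test(area ~ fraction, data = two, var.equal = TRUE)
  expect_equal(fit2$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(fit2$p.value, tt$p.value, tolerance = 1e-10)

  # random fixtures against the sums-of-squares oracle
  set.seed(99)
  for (i in 1:25) {
    groups <- lapply(seq_len(sample(2:5, 1)),
                     function(g) rnorm(sample(3:8, 1), mean = g))
    dd <- data.frame(area = unlist(groups),
                     fraction = rep(seq_along(groups), lengths(groups)))
    expect_equal(anova_oneway(dd, area, fraction)$statistic,
                 oracle_anova_f(groups), tolerance = 1e-10)
  }

  expect_error(anova_oneway(d[1:3, ], area, fraction), "two groups")
})

test_that("tidy and glance expose the ANOVA fit as tibbles", {
  d <- data.frame(area = c(1, 2, 3, 2, 3, 4, 3, 4, 5),
                  fraction = rep(c("C", "M", "N"), each = 3))
  fit <- anova_oneway(d, area, fraction)
  g <- glance(fit)
  expect_equal(g$statistic, 3, tolerance = 1e-10)
  td <- tidy(fit)
  expect_equal(td$mean, c(2, 3, 4))
  expect_equal(td$n, rep(3L, 3))
})

test_that("Tukey-Kramer q and adjusted p behave as the theory requires", {
  d <- data.frame(area = c(1, 2, 3, 2, 3, 4, 3, 4, 5),
                  fraction = rep(c("C", "M", "N"), each = 3))
  tk <- tukey_hsd(d, area, fraction)
  expect_equal(nrow(tk), 3)
  # cross-check against stats::TukeyHSD on the same layout
  ref <- TukeyHSD(aov(area ~ fraction, data = d))$fraction
  expect_equal(sort(tk$adj.p.value), sort(unname(ref[, "p adj"])),
               tolerance = 1e-9)

  # identical groups: all adjusted p = 1
  same <- data.frame(area = rep(7, 9), fraction = rep(c("C", "M", "N"), 3))
  expect_true(all(tukey_hsd(same, area, fraction)$adj.p.value == 1))

  # adjusted p >= unadjusted pairwise p for k > 2 (conservativeness)
  set.seed(5)
  dd <- data.frame(area = rnorm(12), fraction = rep(c("A", "B", "C", "D"), 3))
  tk2 <- tukey_hsd(dd, area, fraction)
  for (j in seq_len(nrow(tk2))) {
    sub <- dd[dd$fraction %in% c(tk2$group1[j], tk2$group2[j]), ]
    p_raw <- t.test(area ~ fraction, data = sub, var.equal = TRUE)$p.value
    expect_gte(tk2$adj.p.value[j], p_raw - 1e-12)
  }

  # permutation invariance in group order
  perm <- dd[sample(nrow(dd)), ]
  tk3 <- tukey_hsd(perm, area, fraction)
  key <- function(x) x[order(x$group1, x$group2), c("q", "adj.p.value")]
  expect_equal(key(as.data.frame(tk2)), key(as.data.frame(tk3)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("studentized-range p matches an independent quadrature oracle", {
  d <- data.frame(area = c(1, 2, 3, 2, 3, 4, 3, 4, 5),
                  fraction = rep(c("C", "M", "N"), each = 3))
  tk <- tukey_hsd(d, area, fraction)
  for (j in seq_len(nrow(tk))) {
    expect_equal(tk$adj.p.value[j],
                 oracle_ptukey_upper(tk$q[j], k = 3, df = 6),
                 tolerance = 1e-4)
  }
  # and at another design point (k = 4, unequal-ish q values)
  expect_equal(stats::ptukey(3.2, 4, 10, lower.tail = FALSE),
               oracle_ptukey_upper(3.2, 4, 10), tolerance = 1e-4)
})

test_that("enrichment verdicts follow direction and significance", {
  # home fraction 10x with tiny variance: enriched
  strong <- make_totals(c(C = 1e5, M = 1e5, N = 1e6), cv = 0.02, seed = 1)
  expect_equal(classify_enrichment(strong)$verdict, "enriched")

  # direction right but noisy: indeterminate
  weak <- make_totals(c(C = 9e5, M = 9.5e5, N = 1e6), cv = 0.4, seed = 8)
  v <- classify_enrichment(weak)$verdict
  expect_true(v %in% c("indeterminate", "failed"))

  # home fraction lowest: failed
  wrong <- make_totals(c(C = 1e6, M = 1e6, N = 1e5), cv = 0.02, seed = 2)
  expect_equal(classify_enrichment(wrong)$verdict, "failed")

  # missing fraction: indeterminate with reason
  partial <- make_totals(c(C = 1e5, N = 1e6), cv = 0.02, seed = 3)
  out <- classify_enrichment(partial)
  expect_equal(out$verdict, "indeterminate")
  expect_match(out$reason, "missing")
})

test_that("the enrichment report assembles ratios, CVs and tests coherently", {
  totals <- dplyr::bind_rows(
    make_totals(c(C = 1e5, M = 1e5, N = 1e6, PT = 4e5), cv = 0.05,
                gene = "LMNA", peptide = "EGDLIAAQAR",
                compartment = "nuclear", seed = 21),
    make_totals(c(C = 1e6, M = 1e5, N = 1e5, PT = 4e5), cv = 0.05,
                gene = "AHCY", peptide = "IILLAEGR",
                compartment = "cytosolic", seed = 22)
  )
  rep <- enrichment_report(totals)
  # ER(A/B) * ER(B/A) = 1
  r <- rep$ratios
  for (i in seq_len(nrow(r))) {
    inv <- r[r$peptide == r$peptide[i] & r$numerator == r$denominator[i] &
               r$denominator == r$numerator[i], ]
    expect_equal(r$er[i] * inv$er, 1, tolerance = 1e-9)
  }
  # nuclear marker: N/C ratio near 10
  nc <- r[r$peptide == "EGDLIAAQAR" & r$numerator == "N" & r$denominator == "C", ]
  expect_equal(nc$er, 10, tolerance = 0.3)
  # CV table covers every fraction including the PT reference
  expect_setequal(unique(rep$cv$fraction), c("C", "M", "N", "PT"))
  expect_true(all(rep$cv$cv_percent < 20, na.rm = TRUE))
  # p-values live in [0, 1]; verdicts enriched for both markers
  expect_true(all(rep$tukey$adj.p.value >= 0 & rep$tukey$adj.p.value <= 1))
  expect_true(all(rep$verdicts$verdict == "enriched"))
  expect_equal(glance(rep)$n_enriched, 2)
})
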