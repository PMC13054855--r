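#' Coefficient of variation (%)
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation; missing
#' values are dropped. Undefined (with a reason attribute) for fewer than
#' two observations or a non-positive mean.
#'
#' @param x Numeric vector of replicate measurements.
#' @return CV in percent, or `NA` with attribute `reason`.
#' @export
#' @examples
#' cv_percent(c(1, 2, 3))  # 50
cv_percent <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(structure(NA_real_, reason = "fewer than 2 values"))
  m <- mean(x)
  if (m <= 0) return(structure(NA_real_, reason = "non-positive mean"))
  100 * stats::sd(x) / m
}

#' Enrichment ratio between two fractions
#'
#' Ratio of mean total areas, `mean(a) / mean(b)`, missing values
#' dropped. A zero denominator yields `Inf` with a flag attribute.
#'
#' @param a,b Numeric vectors of replicate total areas for the numerator
#'   and denominator fraction.
#' @return The enrichment ratio (scalar).
#' @export
#' @examples
#' enrichment_ratio(c(20, 20, 20), c(2, 2, 2))  # 10
enrichment_ratio <- function(a, b) {
  ma <- mean(a, na.rm = TRUE)
  mb <- mean(b, na.rm = TRUE)
  if (is.nan(ma) || is.nan(mb)) return(structure(NA_real_, flag = "missing fraction"))
  if (mb == 0) return(structure(Inf, flag = "zero denominator"))
  ma / mb
}

#' One-way ANOVA on replicate areas
#'
#' Classical fixed-effects one-way analysis of variance (between/within
#' mean squares, F on `k - 1` and `N - k` degrees of freedom), fitted via
#' `stats::lm()`. Degenerate layouts are resolved explicitly: identical
#' data in all groups give `F = 0, p = 1`; zero within-group variance with
#' non-zero between-group variance gives an infinite F with `p = 0`.
#'
#' @param data A data frame of replicate measurements.
#' @param value,group Column names (tidy-eval) holding the measurement and
#'   the grouping factor.
#' @param log_transform Analyse `log(value)` instead of raw areas
#'   (default FALSE; raw total areas are the conventional scale here).
#' @return An object of class `prm_anova` with elements `statistic`
#'   (F), `p.value`, `df` (c(between, within)), `ms_within`, `group_means`,
#'   `group_n`, `degenerate`. Has [tidy()] and [glance()] methods.
#' @export
#' @examples
#' d <- data.frame(area = c(1, 2, 3, 2, 3, 4, 3, 4, 5),
#'                 fraction = rep(c("C", "M", "N"), each = 3))
#' glance(anova_oneway(d, area, fraction))
anova_oneway <- function(data, value, group, log_transform = FALSE) {
  y <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- factor(rlang::eval_tidy(rlang::enquo(group), data))
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]; g <- droplevels(g[keep])
  if (log_transform) y <- log(y)
  k <- nlevels(g)
  n <- length(y)
  if (k < 2) abort("At least two groups are required.")
  if (n <= k) abort("Total observations must exceed the number of groups.")
  means <- tapply(y, g, mean)
  ns <- tapply(y, g, length)
  ss_within <- sum((y - means[g])^2)
  ss_between <- sum(ns * (means - mean(y))^2)
  df <- c(between = k - 1, within = n - k)
  degenerate <- NA_character_
  if (ss_within <= .Machine$double.eps * sum(y^2)) {
    if (ss_between <= .Machine$double.eps * max(1, sum(y^2))) {
      f <- 0; p <- 1; degenerate <- "no variance"
    } else {
      f <- Inf; p <- 0; degenerate <- "zero within-group variance"
    }
    ms_within <- 0
  } else {
    fit <- stats::anova(stats::lm(y ~ g))
    f <- fit$`F value`[1]
    p <- fit$`Pr(>F)`[1]
    ms_within <- fit$`Mean Sq`[2]
  }
  structure(
    list(statistic = f, p.value = p, df = df, ms_within = ms_within,
         group_means = means, group_n = ns, degenerate = degenerate,
         log_transform = log_transform),
    class = "prm_anova"
  )
}

#' Tukey's HSD (Tukey-Kramer) pairwise comparisons
#'
#' For each pair of groups computes the studentized-range statistic
#' `q = |mean_i - mean_j| / sqrt(MSwithin / 2 * (1/n_i + 1/n_j))`
#' (the Tukey-Kramer form, valid for unequal group sizes) and the
#' family-wise adjusted p-value from the studentized-range distribution
#' with `k` groups and `N - k` degrees of freedom.
#'
#' @inheritParams anova_oneway
#' @return An object of class `prm_tukey`: a tibble with columns
#'   `group1`, `group2`, `estimate` (mean difference), `q`, `adj.p.value`,
#'   plus attributes `k` and `df`. `MSwithin = 0` yields a degenerate
#'   flag (`q = Inf` or 0, p 0 or 1).
#' @export
#' @examples
#' d <- data.frame(area = c(1, 2, 3, 2, 3, 4, 3, 4, 5),
#'                 fraction = rep(c("C", "M", "N"), each = 3))
#' tukey_hsd(d, area, fraction)
tukey_hsd <- function(data, value, group, log_transform = FALSE) {
  fit <- anova_oneway(data, {{ value }}, {{ group }},
                      log_transform = log_transform)
  means <- fit$group_means
  ns <- fit$group_n
  k <- length(means)
  df <- unname(fit$df["within"])
  pairs <- utils::combn(names(means), 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    diff <- means[[g1]] - means[[g2]]
    se <- sqrt(fit$ms_within / 2 * (1 / ns[[g1]] + 1 / ns[[g2]]))
    if (se == 0) {
      q <- if (abs(diff) == 0) 0 else Inf
      p <- if (abs(diff) == 0) 1 else 0
    } else {
      q <- abs(diff) / se
      p <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    }
    tibble(group1 = g1, group2 = g2, estimate = diff, q = q, adj.p.value = p)
  })
  structure(res, k = k, df = df, degenerate = fit$ms_within == 0,
            class = c("prm_tukey", class(res)))
}

#' @export
print.prm_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df["between"], x$df["within"], x$statistic, x$p.value))
  if (!is.na(x$degenerate)) cat("  degenerate case:", x$degenerate, "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.prm_anova <- function(x, ...) {
  tibble(
    group = names(x$group_means),
    n = as.integer(x$group_n),
    mean = as.numeric(x$group_means)
  )
}

#' @exportS3Method generics::glance
glance.prm_anova <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p.value,
         df_between = x$df[["between"]], df_within = x$df[["within"]],
         ms_within = x$ms_within, degenerate = x$degenerate)
}

#' @exportS3Method generics::tidy
tidy.prm_tukey <- function(x, ...) {
  as_tibble(x)
}

#' Compartment enrichment verdict for each marker
#'
#' A marker passes ("enriched") when its home-fraction mean total area
#' exceeds both other fractions and both Tukey comparisons against them
#' are significant at `alpha`; "indeterminate" when the direction is
#' right but significance fails (or data are incomplete); "failed" when
#' another fraction has the highest mean.
#'
#' @param totals Peptide-level totals ([peptide_totals()] output) with
#'   columns `fraction`, `replicate`, `gene`, `peptide`, `compartment`,
#'   `total_area`.
#' @param alpha Significance level (default 0.05).
#' @param fractions Fractions participating in the comparison (default
#'   C, M, N; the total-proteome channel PT is a reference channel and is
#'   excluded by default).
#' @return One row per peptide: `gene`, `peptide`, `compartment`,
#'   `home_fraction`, `verdict`, `reason`.
#' @export
classify_enrichment <- function(totals, alpha = 0.05,
                                fractions = c("C", "M", "N")) {
  home_map <- c(nuclear = "N", mitochondrial = "M", cytosolic = "C")
  totals |>
    dplyr::filter(.data$fraction %in% fractions) |>
    dplyr::group_by(dplyr::across(dplyr::any_of(c("protein", "gene", "compartment", "peptide")))) |>
    dplyr::group_modify(function(d, key) {
      home <- unname(home_map[key$compartment])
      verdict_one(d, home, alpha, fractions)
    }) |>
    dplyr::ungroup() |>
    dplyr::rename(home_fraction = "home")
}

verdict_one <- function(d, home, alpha, fractions) {
  d <- dplyr::filter(d, !is.na(.data$total_area))
  present <- unique(d$fraction)
  if (is.na(home) || !all(fractions %in% present)) {
    return(tibble(home = home, verdict = "indeterminate",
                  reason = "missing fraction(s)"))
  }
  counts <- table(d$fraction)
  if (any(counts < 2)) {
    return(tibble(home = home, verdict = "indeterminate",
                  reason = "fewer than 2 replicates in a fraction"))
  }
  means <- tapply(d$total_area, d$fraction, mean)
  others <- setdiff(fractions, home)
  if (!all(means[home] > means[others])) {
    return(tibble(home = home, verdict = "failed",
                  reason = "home fraction not highest"))
  }
  tk <- tukey_hsd(d, .data$total_area, .data$fraction)
  sig <- vapply(others, function(o) {
    row <- tk[(tk$group1 == home & tk$group2 == o) |
                (tk$group1 == o & tk$group2 == home), ]
    row$adj.p.value[1] < alpha
  }, logical(1))
  if (all(sig)) {
    tibble(home = home, verdict = "enriched", reason = NA_character_)
  } else {
    tibble(home = home, verdict = "indeterminate",
           reason = "direction correct but not significant")
  }
}

#' Full enrichment report for a quantified experiment
#'
#' Assembles the fraction-purity QC summary: per-peptide enrichment
#' ratios for every ordered fraction pair, replicate CV% per fraction,
#' one-way ANOVA across fractions, Tukey pairwise adjusted p-values, and
#' the per-marker enrichment verdict.
#'
#' @param totals Peptide-level totals (see [peptide_totals()]).
#' @param alpha Verdict significance level (default 0.05).
#' @param fractions Fractions entering the ANOVA/verdicts (default
#'   C, M, N). Enrichment ratios and CVs are reported for every fraction
#'   present, including a PT reference channel.
#' @param log_transform Run the ANOVA/Tukey on log areas (default FALSE).
#' @return An object of class `enrichment_report`: a list of tibbles
#'   `ratios`, `cv`, `anova`, `tukey`, `verdicts`, with [tidy()],
#'   [glance()] and [ggplot2::autoplot()] methods.
#' @export
enrichment_report <- function(totals, alpha = 0.05,
                              fractions = c("C", "M", "N"),
                              log_transform = FALSE) {
  key_cols <- intersect(c("protein", "gene", "compartment", "peptide",
                          "precursor_charge"), names(totals))
  by_pep <- dplyr::group_by(totals, dplyr::across(dplyr::all_of(key_cols)))

  ratios <- by_pep |>
    dplyr::group_modify(function(d, key) {
      fr <- sort(unique(d$fraction))
      grid <- expand.grid(numerator = fr, denominator = fr,
                          stringsAsFactors = FALSE)
      grid <- grid[grid$numerator != grid$denominator, ]
      grid$er <- vapply(seq_len(nrow(grid)), function(i) {
        as.numeric(enrichment_ratio(
          d$total_area[d$fraction == grid$numerator[i]],
          d$total_area[d$fraction == grid$denominator[i]]
        ))
      }, numeric(1))
      as_tibble(grid)
    }) |>
    dplyr::ungroup()

  cv <- by_pep |>
    dplyr::group_modify(function(d, key) {
      d |>
        dplyr::group_by(.data$fraction) |>
        dplyr::summarise(
          n = sum(!is.na(.data$total_area)),
          mean_area = mean(.data$total_area, na.rm = TRUE),
          cv_percent = as.numeric(cv_percent(.data$total_area)),
          .groups = "drop"
        )
    }) |>
    dplyr::ungroup()

  anova_tab <- by_pep |>
    dplyr::group_modify(function(d, key) {
      d <- dplyr::filter(d, .data$fraction %in% fractions,
                         !is.na(.data$total_area))
      if (dplyr::n_distinct(d$fraction) < 2 ||
          nrow(d) <= dplyr::n_distinct(d$fraction)) {
        return(tibble(statistic = NA_real_, p.value = NA_real_,
                      df_between = NA_real_, df_within = NA_real_,
                      ms_within = NA_real_, degenerate = "insufficient data"))
      }
      glance(anova_oneway(d, .data$total_area, .data$fraction,
                          log_transform = log_transform))
    }) |>
    dplyr::ungroup()

  tukey_tab <- by_pep |>
    dplyr::group_modify(function(d, key) {
      d <- dplyr::filter(d, .data$fraction %in% fractions,
                         !is.na(.data$total_area))
      if (dplyr::n_distinct(d$fraction) < 2 ||
          nrow(d) <= dplyr::n_distinct(d$fraction)) {
        return(tibble(group1 = character(), group2 = character(),
                      estimate = numeric(), q = numeric(),
                      adj.p.value = numeric()))
      }
      tidy(tukey_hsd(d, .data$total_area, .data$fraction,
                     log_transform = log_transform))
    }) |>
    dplyr::ungroup()

  verdicts <- classify_enrichment(totals, alpha = alpha, fractions = fractions)

  structure(
    list(ratios = ratios, cv = cv, anova = anova_tab, tukey = tukey_tab,
         verdicts = verdicts, alpha = alpha, fractions = fractions,
         totals = totals),
    class = "enrichment_report"
  )
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat(sprintf("<enrichment_report> %d peptides, fractions: %s, alpha = %g\n",
              nrow(x$verdicts), paste(x$fractions, collapse = "/"), x$alpha))
  print(x$verdicts, ...)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.enrichment_report <- function(x, ...) {
  x$verdicts |>
    dplyr::left_join(x$anova,
                     by = intersect(names(x$verdicts), names(x$anova)))
}

#' @exportS3Method generics::glance
glance.enrichment_report <- function(x, ...) {
  tibble(
    n_peptides = nrow(x$verdicts),
    n_enriched = sum(x$verdicts$verdict == "enriched"),
    n_indeterminate = sum(x$verdicts$verdict == "indeterminate"),
    n_failed = sum(x$verdicts$verdict == "failed"),
    alpha = x$alpha
  )
}
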