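# The inferential toolkit of classical diagnostic morphometry: one-way
# fixed-effects ANOVA, pooled two-sample t, Mann-Whitney U with the
# tie-corrected normal approximation, and Kruskal-Wallis. ANOVA, t and
# Kruskal-Wallis delegate to the standard stats machinery; the Mann-Whitney
# normal approximation is computed directly because base R does not expose
# the Z statistic (it is cross-checked against wilcox.test and exact
# enumeration in the test suite).

as_group_list <- function(x, g = NULL) {
  if (is.list(x) && !is.data.frame(x)) return(x)
  if (is.null(g)) bm_config_error("supply a list of groups or values plus labels")
  split(x, g)
}

#' One-way fixed-effects analysis of variance
#'
#' Decomposes the total sum of squares into between- and within-group
#' components; the F ratio is the between mean square over the within mean
#' square with an upper-tail F p-value.
#'
#' @param x Named list of numeric vectors (one per group), or a numeric
#'   vector combined with `g`.
#' @param g Group labels when `x` is a vector.
#' @return An object of class `morph_anova`: `between_ss`, `within_ss`,
#'   `total_ss`, `df_between`, `df_within`, `df_total`, `ms_between`,
#'   `ms_within`, `f_ratio`, `p_value`.
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))
#' @export
one_way_anova <- function(x, g = NULL) {
  groups <- as_group_list(x, g)
  if (length(groups) < 2L) bm_config_error("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    bm_data_error("every group needs at least 2 observations")
  }
  if (sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1))) <= 0) {
    bm_data_error("degenerate data: zero within-group variance")
  }
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  tab <- stats::anova(stats::lm(values ~ fac))
  within_ss <- tab$`Sum Sq`[2]
  structure(list(
    between_ss = tab$`Sum Sq`[1], within_ss = within_ss,
    total_ss = tab$`Sum Sq`[1] + within_ss,
    df_between = tab$Df[1], df_within = tab$Df[2],
    df_total = tab$Df[1] + tab$Df[2],
    ms_between = tab$`Mean Sq`[1], ms_within = tab$`Mean Sq`[2],
    f_ratio = tab$`F value`[1], p_value = tab$`Pr(>F)`[1]),
    class = "morph_anova")
}

#' @export
print.morph_anova <- function(x, ...) {
  cat(sprintf(
    "One-way ANOVA: F(%d, %d) = %.3f, P = %s\n  SS between %.3f + within %.3f = total %.3f\n",
    x$df_between, x$df_within, x$f_ratio, format_p(x$p_value),
    x$between_ss, x$within_ss, x$total_ss))
  invisible(x)
}

morph_test <- function(test, comparison, statistic, df, p_value, extra = NULL) {
  structure(c(list(test = test, comparison = comparison,
                   statistic = statistic, df = df, p_value = p_value,
                   alternative = "two.sided"), extra),
            class = "morph_test")
}

#' @export
print.morph_test <- function(x, ...) {
  cat(sprintf("%s (%s): statistic = %.4f%s, P = %s\n", x$test,
              if (is.null(x$comparison)) "two groups" else x$comparison,
              x$statistic,
              if (!is.null(x$df) && !is.na(x$df)) sprintf(", df = %g", x$df) else "",
              format_p(x$p_value)))
  invisible(x)
}

#' Pooled-variance two-sample Student's t test
#'
#' Two-sided independent-samples t test with the pooled variance estimate
#' and `n1 + n2 - 2` degrees of freedom; the statistic is reported as a
#' magnitude.
#'
#' @param a,b Numeric samples (each at least 2 values).
#' @param comparison Optional label describing the pair.
#' @return A `morph_test` with `statistic` = |t|, `df`, `p_value`.
#' @export
t_test_pooled <- function(a, b, comparison = NULL) {
  if (length(a) < 2L || length(b) < 2L) {
    bm_data_error("each sample needs at least 2 observations")
  }
  if (stats::var(a) + stats::var(b) == 0) {
    bm_data_error("degenerate data: zero pooled variance")
  }
  r <- stats::t.test(a, b, var.equal = TRUE)
  morph_test("pooled t", comparison, abs(unname(r$statistic)),
             unname(r$parameter), r$p.value)
}

#' Mann-Whitney U test (normal approximation)
#'
#' Rank-sum test for two independent samples. `U` is computed for the
#' first sample; the Z statistic uses the normal approximation with the
#' tie-corrected variance
#' `n1 n2 / 12 * (N + 1 - sum(t^3 - t) / (N (N - 1)))`. No continuity
#' correction is applied by default (the closed forms used as test oracles
#' assume none); set `continuity = TRUE` for the corrected variant.
#'
#' @param a,b Numeric samples (each at least 1 value).
#' @param comparison Optional label describing the pair.
#' @param continuity Apply the 0.5 continuity correction to Z.
#' @return A `morph_test` with `statistic` = U (first sample), `z` (signed),
#'   `df = NA`, and the two-sided normal p-value.
#' @export
mann_whitney <- function(a, b, comparison = NULL, continuity = FALSE) {
  if (length(a) < 1L || length(b) < 1L) bm_data_error("empty sample")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) {
    bm_data_error("degenerate data: all values tied across both samples")
  }
  num <- u - n1 * n2 / 2
  if (continuity && num != 0) num <- num - sign(num) * 0.5
  z <- num / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  morph_test("Mann-Whitney U", comparison, u, NA_real_, p, extra = list(z = z))
}

#' Kruskal-Wallis rank test for k independent groups
#'
#' H statistic with the standard tie correction (division by
#' `1 - sum(t^3 - t) / (N^3 - N)`), referred to the chi-squared
#' distribution with k - 1 degrees of freedom.
#'
#' @inheritParams one_way_anova
#' @return A `morph_test` with `statistic` = H (chi-squared), `df = k - 1`.
#' @export
kruskal_wallis <- function(x, g = NULL) {
  groups <- as_group_list(x, g)
  if (length(groups) < 2L) bm_config_error("need at least 2 groups")
  values <- unlist(groups, use.names = FALSE)
  if (length(values) < length(groups) + 1L) {
    bm_data_error("need at least k + 1 observations in total")
  }
  if (length(unique(values)) == 1L) {
    bm_data_error("degenerate data: all values identical")
  }
  fac <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  r <- stats::kruskal.test(values, fac)
  morph_test("Kruskal-Wallis", paste(names(groups), collapse = " / "),
             unname(r$statistic), unname(r$parameter), r$p.value)
}

format_p <- function(p, digits = 4) {
  ifelse(p < 1e-4, "<0.0001", sprintf("%.*f", digits, p))
}

report_variables <- c("nuclear_area", "cell_area",
                      "nuclear_form_pe", "cellular_form_pe",
                      "nuclear_ci", "cellular_ci", "nc_ratio")

group_pairs <- list(c("leukoplakia", "normal"),
                    c("scc", "normal"),
                    c("leukoplakia", "scc"))

#' Run the full group comparison over all morphometric variables
#'
#' For each variable (nuclear and cell area, nuclear and cellular form
#' perimeter and contour index, N:C ratio) computes: per-group descriptive
#' summaries, the one-way ANOVA over the three groups, the three pairwise
#' pooled t tests, the three pairwise Mann-Whitney tests, and the
#' Kruskal-Wallis test, flagging significance at `alpha`.
#'
#' @param records Measurement data frame (descriptors are derived when
#'   absent).
#' @param variables Variables to analyze (default: all seven).
#' @param alpha Significance threshold (default 0.05).
#' @param circle Circle constant choice for derived descriptors.
#' @return An object of class `morph_report`: data frames `summaries`,
#'   `anova`, `t_tests`, `mann_whitney`, `kruskal_wallis`, plus `alpha`.
#' @examples
#' rep <- run_full_comparison(table2_fixture())
#' subset(rep$anova, variable == "nuclear_area")
#' @export
run_full_comparison <- function(records, variables = report_variables,
                                alpha = 0.05,
                                circle = getOption("basalmorph.circle", "pi")) {
  records <- validate_measurements(records)
  present <- levels(droplevels(records$group))
  if (length(present) < 2L) {
    bm_config_error(sprintf(
      "need at least 2 diagnostic groups, found: %s",
      paste(present, collapse = ", ")))
  }
  if (!all(GROUP_LEVELS %in% present)) {
    bm_config_error(sprintf(
      "missing group(s) %s; present: %s",
      paste(setdiff(GROUP_LEVELS, present), collapse = ", "),
      paste(present, collapse = ", ")))
  }
  d <- suppressWarnings(derive_descriptors(records, circle))
  summaries <- list(); anova_rows <- list(); t_rows <- list()
  mw_rows <- list(); kw_rows <- list()
  for (v in variables) {
    if (!v %in% names(d)) bm_config_error(sprintf("unknown variable '%s'", v))
    groups <- split(d[[v]], d$group)
    summaries[[v]] <- summarize_groups(d, v)
    a <- one_way_anova(groups)
    anova_rows[[v]] <- data.frame(
      variable = v, between_ss = a$between_ss, within_ss = a$within_ss,
      total_ss = a$total_ss, df_between = a$df_between,
      df_within = a$df_within, df_total = a$df_total,
      ms_between = a$ms_between, ms_within = a$ms_within,
      f_ratio = a$f_ratio, p_value = a$p_value,
      significant = a$p_value <= alpha)
    for (pr in group_pairs) {
      lbl <- paste(pr, collapse = " vs ")
      tt <- t_test_pooled(groups[[pr[1]]], groups[[pr[2]]], lbl)
      t_rows[[paste(v, lbl)]] <- data.frame(
        variable = v, comparison = lbl, t = tt$statistic, df = tt$df,
        p_value = tt$p_value, significant = tt$p_value <= alpha)
      mw <- mann_whitney(groups[[pr[1]]], groups[[pr[2]]], lbl)
      mw_rows[[paste(v, lbl)]] <- data.frame(
        variable = v, comparison = lbl, u = mw$statistic,
        z = abs(mw$z), p_value = mw$p_value,
        significant = mw$p_value <= alpha)
    }
    kw <- kruskal_wallis(groups)
    kw_rows[[v]] <- data.frame(
      variable = v, chisq = kw$statistic, df = kw$df, p_value = kw$p_value,
      significant = kw$p_value <= alpha)
  }
  structure(list(
    summaries = do.call(rbind, c(summaries, list(make.row.names = FALSE))),
    anova = do.call(rbind, c(anova_rows, list(make.row.names = FALSE))),
    t_tests = do.call(rbind, c(t_rows, list(make.row.names = FALSE))),
    mann_whitney = do.call(rbind, c(mw_rows, list(make.row.names = FALSE))),
    kruskal_wallis = do.call(rbind, c(kw_rows, list(make.row.names = FALSE))),
    alpha = alpha, n = nrow(d)),
    class = "morph_report")
}

#' @export
print.morph_report <- function(x, ...) {
  cat(sprintf("Morphometric group comparison (%d cases, alpha = %g)\n",
              x$n, x$alpha))
  cat("\nANOVA F ratios:\n")
  a <- x$anova
  for (i in seq_len(nrow(a))) {
    cat(sprintf("  %-18s F(%d,%d) = %8.3f  P = %s%s\n", a$variable[i],
                a$df_between[i], a$df_within[i], a$f_ratio[i],
                format_p(a$p_value[i]), if (a$significant[i]) " *" else ""))
  }
  cat("\nKruskal-Wallis:\n")
  k <- x$kruskal_wallis
  for (i in seq_len(nrow(k))) {
    cat(sprintf("  %-18s chi2(%d) = %7.3f  P = %s%s\n", k$variable[i],
                k$df[i], k$chisq[i], format_p(k$p_value[i]),
                if (k$significant[i]) " *" else ""))
  }
  invisible(x)
}

#' Serialize a comparison report to CSV tables and JSON
#'
#' Writes one CSV per result family -- `summaries.csv`,
#' `anova_size.csv` (areas), `anova_form_pe.csv`, `anova_ci.csv`,
#' `anova_nc_ratio.csv`, `t_tests.csv`, `mann_whitney.csv`,
#' `kruskal_wallis.csv` -- mirroring the classical table layouts (source
#' of variation, sum of squares, df, mean square, F ratio, P value), plus
#' the complete report as `report.json` with full float precision.
#' P-value columns carry a display form where values below 1e-4 print as
#' `<0.0001`.
#'
#' @param report A `morph_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!inherits(report, "morph_report")) bm_config_error("not a morph_report")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  anova_long <- function(rows) {
    do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
      r <- rows[i, ]
      data.frame(
        variable = r$variable,
        source_of_variation = c("Between groups", "Within groups", "Total"),
        sum_of_squares = c(r$between_ss, r$within_ss, r$total_ss),
        df = c(r$df_between, r$df_within, r$df_total),
        mean_square = c(r$ms_between, r$ms_within, NA),
        f_ratio = c(r$f_ratio, NA, NA),
        p_value = c(r$p_value, NA, NA),
        p_display = c(format_p(r$p_value), "", ""))
    }))
  }
  a <- report$anova
  groups_of <- list(
    anova_size = c("nuclear_area", "cell_area"),
    anova_form_pe = c("nuclear_form_pe", "cellular_form_pe"),
    anova_ci = c("nuclear_ci", "cellular_ci"),
    anova_nc_ratio = "nc_ratio")
  for (nm in names(groups_of)) {
    rows <- a[a$variable %in% groups_of[[nm]], , drop = FALSE]
    if (nrow(rows)) {
      utils::write.csv(anova_long(rows), file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE, na = "")
    }
  }
  tt <- report$t_tests
  tt$p_display <- format_p(tt$p_value)
  utils::write.csv(tt, file.path(dir, "t_tests.csv"), row.names = FALSE)
  mw <- report$mann_whitney
  mw$p_display <- format_p(mw$p_value)
  utils::write.csv(mw, file.path(dir, "mann_whitney.csv"), row.names = FALSE)
  kw <- report$kruskal_wallis
  kw$p_display <- format_p(kw$p_value)
  utils::write.csv(kw, file.path(dir, "kruskal_wallis.csv"), row.names = FALSE)
  utils::write.csv(report$summaries, file.path(dir, "summaries.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(alpha = report$alpha, n = report$n,
         summaries = report$summaries, anova = report$anova,
         t_tests = report$t_tests, mann_whitney = report$mann_whitney,
         kruskal_wallis = report$kruskal_wallis),
    file.path(dir, "report.json"), dataframe = "rows", digits = NA,
    auto_unbox = TRUE)
  invisible(dir)
}
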