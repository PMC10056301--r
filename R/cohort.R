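#' Shapiro-Wilk normality screen
#'
#' @param values Numeric vector, 3 <= n <= 50, non-constant.
#' @return One-row tibble with `statistic` (W) and `p_value`.
#' @export
normality_screen <- function(values) {
  n <- length(values)
  if (n < 3 || n > 50) abort("Shapiro-Wilk screen requires 3 <= n <= 50.")
  if (var(values) == 0) abort("Constant input: zero variance.")
  sw <- shapiro.test(values)
  tibble::tibble(statistic = unname(sw$statistic),
                 p_value = unname(sw$p.value))
}

significance_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "")
}

#' Paired comparison of two conditions
#'
#' Compares paired per-subject values with a paired t-test when the
#' differences pass the Shapiro-Wilk screen (at `normality_alpha`),
#' otherwise a paired Wilcoxon signed-rank test. The 95% confidence
#' interval of the mean paired difference (t-based) is always reported.
#'
#' @param a,b Equal-length per-subject vectors, paired by position.
#' @param component Label carried into the output row.
#' @param normality_alpha Screen level for switching to Wilcoxon.
#' @return One-row tibble: `component`, `mean_a`, `se_a`, `mean_b`,
#'   `se_b`, `diff_ci_lo`, `diff_ci_hi`, `statistic`, `p_value`,
#'   `test_used`, `stars`.
#' @export
paired_compare <- function(a, b, component = "value",
                           normality_alpha = 0.05) {
  if (length(a) != length(b)) abort("`a` and `b` must be paired (equal length).")
  n <- length(a)
  if (n < 3) abort("Paired comparison requires n >= 3.")
  d <- a - b
  se <- function(x) sd(x) / sqrt(length(x))
  if (all(d == 0)) {
    return(tibble::tibble(component = component,
                          mean_a = mean(a), se_a = se(a),
                          mean_b = mean(b), se_b = se(b),
                          diff_ci_lo = 0, diff_ci_hi = 0,
                          statistic = 0, p_value = 1,
                          test_used = "degenerate", stars = ""))
  }
  ci <- mean(d) + c(-1, 1) * qt(0.975, n - 1) * se(d)
  use_t <- var(d) > 0 && length(unique(d)) >= 3 &&
    normality_screen(d)$p_value > normality_alpha
  if (use_t) {
    tt <- t.test(a, b, paired = TRUE)
    stat <- unname(tt$statistic); p <- tt$p.value; test <- "paired t"
  } else {
    wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE))
    stat <- unname(wt$statistic); p <- wt$p.value
    test <- "wilcoxon signed-rank"
  }
  tibble::tibble(component = component, mean_a = mean(a), se_a = se(a),
                 mean_b = mean(b), se_b = se(b),
                 diff_ci_lo = ci[1], diff_ci_hi = ci[2],
                 statistic = stat, p_value = p, test_used = test,
                 stars = significance_stars(p))
}

#' Compare two fitting conditions across a cohort
#'
#' Runs [paired_compare()] per component on a tidy cohort table, for a
#' chosen measured variable (concentration or CRLB).
#'
#' @param table Tidy cohort tibble with columns `subject`, `component`,
#'   `condition` and the value column.
#' @param value Name of the value column (default `"conc_mM"`).
#' @param conditions Length-2 character: the two condition labels, in the
#'   order a - b.
#' @return Tibble with one [paired_compare()] row per component.
#' @export
compare_conditions <- function(table, value = "conc_mM",
                               conditions = NULL) {
  stopifnot(is.data.frame(table))
  if (is.null(conditions)) conditions <- unique(table$condition)[1:2]
  wide <- tidyr::pivot_wider(
    table[, c("subject", "component", "condition", value)],
    names_from = "condition", values_from = dplyr::all_of(value))
  purrr::map_dfr(unique(wide$component), function(cmp) {
    w <- wide[wide$component == cmp, ]
    paired_compare(w[[conditions[1]]], w[[conditions[2]]], component = cmp)
  })
}

#' Significance-masked correlation matrix
#'
#' Pearson correlations between all component pairs of one condition;
#' entries whose test p-value is at or above `alpha` are masked to `NA`
#' (displayed blank). The diagonal is 1; zero-variance components are
#' masked entirely with a warning.
#'
#' @param table Tidy cohort tibble (`subject`, `component`, `condition`,
#'   value column).
#' @param condition Condition label to use.
#' @param alpha Significance level for masking (default 0.1).
#' @param value Value column name.
#' @return Square matrix with dimnames = components; masked entries `NA`.
#' @export
correlation_matrix <- function(table, condition = table$condition[1],
                               alpha = 0.1, value = "conc_mM") {
  sub <- table[table$condition == condition, ]
  wide <- tidyr::pivot_wider(sub[, c("subject", "component", value)],
                             names_from = "component",
                             values_from = dplyr::all_of(value))
  M <- as.matrix(wide[, -1, drop = FALSE])
  if (nrow(M) < 4) abort("Correlation matrix requires n >= 4 subjects.")
  comps <- colnames(M)
  k <- length(comps)
  out <- matrix(NA_real_, k, k, dimnames = list(comps, comps))
  degenerate <- apply(M, 2, function(x) var(x) == 0)
  if (any(degenerate)) {
    warn(sprintf("Zero-variance component(s) masked: %s",
                 paste(comps[degenerate], collapse = ", ")))
  }
  for (i in seq_len(k)) {
    out[i, i] <- 1
    if (degenerate[i]) { out[i, i] <- NA_real_; next }
    for (j in seq_len(k)) {
      if (j <= i || degenerate[j]) next
      ct <- cor.test(M[, i], M[, j], method = "pearson")
      if (ct$p.value < alpha) out[i, j] <- out[j, i] <- unname(ct$estimate)
    }
  }
  out
}

#' Coefficient of variation in percent
#'
#' `100 * SD / mean`, sample SD (n - 1 denominator).
#'
#' @param values Numeric vector with positive mean.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(values) {
  m <- mean(values)
  if (!is.finite(m) || m <= 0) abort("CV requires a positive mean.")
  100 * sd(values) / m
}

#' Classify components by between-subject CV versus mean CRLB
#'
#' For each component and condition, compares the between-subject
#' coefficient of variation of the concentration with the mean relative
#' CRLB (%SD). A component is CV-dominant when CV strictly exceeds the
#' mean CRLB - between-subject (biological) variability exceeds the
#' measurement error, so between-subject comparisons are meaningful;
#' otherwise it is CRLB-dominant (ties count as CRLB-dominant).
#' Components are also binned by mean CRLB: `<15%`, `<35%`, `>=35%`.
#'
#' @param table Tidy cohort tibble with `conc_mM` and `crlb_rel` columns.
#' @return Tibble: `component`, `condition`, `cv_pct`, `mean_crlb_rel`,
#'   `dominance`, `crlb_band`.
#' @export
cv_vs_crlb <- function(table) {
  stopifnot(is.data.frame(table))
  if (!"crlb_rel" %in% names(table)) abort("`crlb_rel` column is required.")
  grp <- dplyr::group_by(table, .data$component, .data$condition)
  out <- dplyr::summarise(
    grp,
    cv_pct = if (mean(.data$conc_mM) > 0) coefficient_of_variation(.data$conc_mM)
             else NA_real_,
    mean_crlb_rel = mean(.data$crlb_rel, na.rm = TRUE),
    .groups = "drop")
  missing <- is.na(out$mean_crlb_rel) | is.nan(out$mean_crlb_rel)
  if (any(missing)) {
    warn(sprintf("Missing CRLB for: %s; skipped.",
                 paste(unique(out$component[missing]), collapse = ", ")))
    out <- out[!missing, ]
  }
  dplyr::mutate(
    out,
    dominance = ifelse(.data$cv_pct > .data$mean_crlb_rel,
                       "CV-dominant", "CRLB-dominant"),
    crlb_band = dplyr::case_when(.data$mean_crlb_rel < 15 ~ "<15%",
                                 .data$mean_crlb_rel < 35 ~ "<35%",
                                 TRUE ~ ">=35%"))
}

#' Plot CV against mean CRLB
#'
#' One point per component and condition with the identity line;
#' components above the line are CV-dominant.
#'
#' @param classification Output of [cv_vs_crlb()].
#' @return A ggplot object.
#' @export
plot_cv_crlb <- function(classification) {
  ggplot2::ggplot(classification,
                  ggplot2::aes(x = .data$mean_crlb_rel, y = .data$cv_pct,
                               shape = .data$condition)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Mean CRLB (%SD)", y = "Between-subject CV (%)")
}

#' Plot a significance-masked correlation matrix
#'
#' @param mat Matrix from [correlation_matrix()].
#' @return A ggplot object; masked entries are blank.
#' @export
plot_correlation_matrix <- function(mat) {
  d <- tibble::as_tibble(as.data.frame(as.table(mat), stringsAsFactors = FALSE))
  names(d) <- c("row", "col", "r")
  ggplot2::ggplot(d[!is.na(d$r), ],
                  ggplot2::aes(x = .data$col, y = .data$row,
                               fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "red", mid = "white", high = "blue",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1))
}
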