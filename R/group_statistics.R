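# Nonparametric group comparison machinery: Shapiro-Wilk normality gate,
# Kruskal-Wallis omnibus, Dunn's post hoc z tests with Bonferroni
# adjustment, and median (IQR) comparison tables per feature and stage.

#' Shapiro-Wilk normality assessment per group
#'
#' Records per-group normality p-values. The downstream pipeline proceeds
#' nonparametrically regardless of the outcome; the gate is descriptive.
#'
#' @param values_by_group named list of numeric vectors (>= 3 values each).
#' @return data.frame with `group`, `n`, `p_value`, `degenerate` (all
#'   values identical, test inapplicable).
#' @export
normality_gate <- function(values_by_group) {
  rows <- lapply(names(values_by_group), function(g) {
    v <- values_by_group[[g]][is.finite(values_by_group[[g]])]
    if (length(v) < 3) stop("group ", g, " has fewer than 3 values")
    degen <- length(unique(v)) == 1L
    p <- if (degen || length(v) > 5000) NA_real_ else stats::shapiro.test(v)$p.value
    data.frame(group = g, n = length(v), p_value = p, degenerate = degen)
  })
  do.call(rbind, rows)
}

#' Dunn's post hoc pairwise z tests with Bonferroni adjustment
#'
#' Mean-rank z statistics with tie correction:
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))` with
#' `T = sum(t^3 - t) / (12 (N - 1))` over tie groups; two-sided p-values
#' multiplied by the number of comparisons, capped at 1.
#'
#' @param values_by_group named list of numeric vectors.
#' @return data.frame with `comparison`, `z`, `p_unadjusted`, `p_adjusted`.
#' @export
dunn_test <- function(values_by_group) {
  groups <- names(values_by_group)
  x <- unlist(values_by_group, use.names = FALSE)
  g <- rep(groups, vapply(values_by_group, length, integer(1)))
  ok <- is.finite(x)
  x <- x[ok]; g <- g[ok]
  N <- length(x)
  r <- rank(x)
  ties <- table(x)
  Tcorr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  combs <- utils::combn(groups, 2)
  k <- ncol(combs)
  rows <- lapply(seq_len(k), function(i) {
    a <- combs[1, i]; b <- combs[2, i]
    se <- sqrt((N * (N + 1) / 12 - Tcorr) * (1 / n[[a]] + 1 / n[[b]]))
    z <- if (se > 0) (rbar[[a]] - rbar[[b]]) / se else 0
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(comparison = paste0(a, "-", b), z = z,
               p_unadjusted = p, p_adjusted = min(1, p * k))
  })
  do.call(rbind, rows)
}

#' Three-group omnibus and post hoc comparison
#'
#' Kruskal-Wallis rank test (tie-corrected H) followed by Dunn-Bonferroni
#' pairwise z tests. Pairwise p-values are always computed; when the
#' omnibus test does not reject at `alpha` they are flagged as not
#' licensed rather than suppressed, so complete tables can be printed.
#'
#' @param values_by_group named list of >= 2 numeric vectors (>= 3 values
#'   each for the omnibus test).
#' @param alpha omnibus significance level (default 0.05).
#' @return list with `omnibus_p`, `H`, `pairwise` (data.frame from
#'   [dunn_test()] plus `posthoc_licensed`).
#' @export
compare_groups <- function(values_by_group, alpha = 0.05) {
  x <- unlist(values_by_group, use.names = FALSE)
  g <- factor(rep(names(values_by_group),
                  vapply(values_by_group, length, integer(1))))
  ok <- is.finite(x)
  if (length(unique(x[ok])) == 1L) {
    pw <- dunn_test(values_by_group)
    pw$posthoc_licensed <- FALSE
    return(list(omnibus_p = 1, H = 0, pairwise = pw))
  }
  kw <- stats::kruskal.test(x[ok], g[ok])
  pw <- dunn_test(values_by_group)
  pw$posthoc_licensed <- kw$p.value < alpha
  list(omnibus_p = kw$p.value, H = unname(kw$statistic), pairwise = pw)
}

iqr_linear <- function(v) {
  q <- stats::quantile(v, c(0.25, 0.75), na.rm = TRUE, type = 7, names = FALSE)
  q[2] - q[1]
}

#' Build median (IQR) comparison tables per feature and stage
#'
#' Emits the standard comparison layout: one row per (feature, stage) with
#' per-group `median (IQR)` summaries, the omnibus p-value, and the three
#' pairwise Dunn-Bonferroni p-values. Quantiles use linear interpolation;
#' IQR is Q3 - Q1.
#'
#' @param feature_table data.frame with columns `subject_id`, `group`,
#'   `stage`, plus one column per feature.
#' @param features feature columns to tabulate (default: all non-id).
#' @param alpha significance level for the significance flags.
#' @return data.frame of class `GroupComparisonTable`.
#' @export
build_comparison_tables <- function(feature_table,
                                    features = NULL, alpha = 0.05) {
  ids <- c("subject_id", "group", "stage")
  if (is.null(features)) features <- setdiff(names(feature_table), ids)
  groups <- unique(feature_table$group)
  single <- length(groups) < 2
  rows <- list()
  for (f in features) {
    for (st in sort(unique(feature_table$stage))) {
      sub <- feature_table[feature_table$stage == st, ]
      vals <- lapply(groups, function(g) sub[sub$group == g, f])
      names(vals) <- groups
      row <- data.frame(feature = f, stage = st)
      for (g in groups) {
        v <- vals[[g]][is.finite(vals[[g]])]
        med <- if (length(v)) stats::median(v) else NA_real_
        iq <- if (length(v)) iqr_linear(v) else NA_real_
        row[[paste0("median_", g)]] <- med
        row[[paste0("iqr_", g)]] <- iq
        row[[paste0("summary_", g)]] <- sprintf("%.1f (%.1f)", med, iq)
      }
      if (!single && all(vapply(vals, function(v) sum(is.finite(v)) >= 3, logical(1)))) {
        cmp <- compare_groups(vals, alpha)
        row$omnibus_p <- cmp$omnibus_p
        for (i in seq_len(nrow(cmp$pairwise))) {
          row[[paste0("p_", cmp$pairwise$comparison[i])]] <-
            cmp$pairwise$p_adjusted[i]
        }
        row$significant <- cmp$omnibus_p < alpha
      } else {
        row$omnibus_p <- NA_real_
        row$significant <- NA
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  nm <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) { r[setdiff(nm, names(r))] <- NA; r[nm] })
  out <- do.call(rbind, rows)
  class(out) <- c("GroupComparisonTable", "data.frame")
  out
}
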