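# Group contrasts (pooled t-test + Cohen's d) and clinical-score
# correlations over visit-level feature tables.

#' Cohen's d from group summary statistics
#'
#' Standardized mean difference using the pooled (n-1 weighted) standard
#' deviation:
#' `d = (mean_a - mean_b) / sqrt(((n_a-1) sd_a^2 + (n_b-1) sd_b^2) / (n_a+n_b-2))`.
#' Antisymmetric under swapping the groups; `NA` when the pooled SD is zero.
#'
#' @param meanA,sdA,nA summary statistics of group A (nA >= 2).
#' @param meanB,sdB,nB summary statistics of group B (nB >= 2).
#' @return numeric effect size.
#' @examples
#' cohensD(0.92, 0.51, 18, 1.91, 0.46, 11)  # about -2
#' @export
cohensD <- function(meanA, sdA, nA, meanB, sdB, nB) {
  stopifnot(nA >= 2, nB >= 2, sdA >= 0, sdB >= 0)
  sp <- sqrt(((nA - 1) * sdA^2 + (nB - 1) * sdB^2) / (nA + nB - 2))
  if (sp == 0) return(NA_real_)
  (meanA - meanB) / sp
}

# pooled two-sample t-test + d from raw values; returns NA row if degenerate
.contrastRow <- function(xa, xb, feature, ga, gb) {
  xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
  out <- data.frame(feature = feature, group_a = ga, group_b = gb,
                    mean_a = NA_real_, sd_a = NA_real_, n_a = length(xa),
                    mean_b = NA_real_, sd_b = NA_real_, n_b = length(xb),
                    d = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  if (length(xa) < 2 || length(xb) < 2) return(out)
  out$mean_a <- mean(xa); out$sd_a <- sd(xa)
  out$mean_b <- mean(xb); out$sd_b <- sd(xb)
  out$d <- cohensD(out$mean_a, out$sd_a, length(xa),
                   out$mean_b, out$sd_b, length(xb))
  if (sd(c(xa, xb)) > 0)
    out$p <- t.test(xa, xb, var.equal = TRUE)$p.value
  out
}

#' Pairwise group contrasts for a feature table
#'
#' For every feature and every pair of groups, computes the two-sided
#' independent two-sample t-test with pooled variance and Cohen's d from the
#' pooled SD. No multiple-testing adjustment is applied by default, matching
#' an exploratory-analysis policy; set `adjust = "BH"` for
#' Benjamini-Hochberg-adjusted p-values in an extra column.
#'
#' @param visits data.frame with a `group` column and feature columns, one
#'   row per visit.
#' @param features character vector of feature column names.
#' @param groups character vector of group labels defining the pairs
#'   (order fixes the sign convention: each pair is (earlier, later)).
#' @param adjust `"none"` (default) or a method for [stats::p.adjust()].
#' @return data.frame, one row per (feature, group pair): summary stats per
#'   group, `d`, `p` (and `p_adj` when `adjust != "none"`).
#' @export
pairwiseGroupTable <- function(visits, features,
                               groups = c("HD", "pHD", "CTR"),
                               adjust = "none") {
  stopifnot(is.data.frame(visits), "group" %in% names(visits))
  missingF <- setdiff(features, names(visits))
  if (length(missingF))
    stop("unknown feature column(s): ", paste(missingF, collapse = ", "))
  pairs <- utils::combn(groups, 2)
  rows <- list()
  for (f in features) {
    for (k in seq_len(ncol(pairs))) {
      ga <- pairs[1, k]; gb <- pairs[2, k]
      rows[[length(rows) + 1L]] <-
        .contrastRow(visits[visits$group == ga, f],
                     visits[visits$group == gb, f], f, ga, gb)
    }
  }
  out <- do.call(rbind, rows)
  if (!identical(adjust, "none")) out$p_adj <- p.adjust(out$p, method = adjust)
  out
}

#' Correlations between features and clinical scores
#'
#' Pearson correlation for the continuous scales (MoCA, UHDRS functional and
#' motor) and Spearman rank correlation for the discrete five-level
#' dysarthria score, with two-sided p-values, using pairwise-complete
#' observations.
#'
#' @param visits data.frame with clinical-score columns (`moca`,
#'   `uhdrs_functional`, `uhdrs_motor`, `dysarthria`) and feature columns.
#' @param features character vector of feature column names.
#' @param scores character vector of clinical-score column names present in
#'   `visits`.
#' @return data.frame with columns `feature`, `clinical_score`, `method`,
#'   `coefficient`, `p`, `n`.
#' @export
correlationTable <- function(visits, features,
                             scores = c("moca", "uhdrs_functional",
                                        "uhdrs_motor", "dysarthria")) {
  stopifnot(is.data.frame(visits))
  missingC <- setdiff(c(features, scores), names(visits))
  if (length(missingC))
    stop("missing column(s): ", paste(missingC, collapse = ", "))
  rows <- list()
  for (f in features) {
    for (s in scores) {
      method <- if (s == "dysarthria") "spearman" else "pearson"
      ok <- complete.cases(visits[[f]], visits[[s]])
      x <- visits[[f]][ok]; y <- visits[[s]][ok]
      coefv <- NA_real_; pv <- NA_real_
      if (sum(ok) >= 3 && sd(x) > 0 && sd(y) > 0) {
        ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
        coefv <- unname(ct$estimate); pv <- ct$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, clinical_score = s, method = method,
        coefficient = coefv, p = pv, n = sum(ok), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
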