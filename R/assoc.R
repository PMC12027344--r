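#' Correlate IDR1 sensitivity (log2FC) with continuous pri-miRNA features
#'
#' Pearson correlation (with two-sided p) between each named continuous
#' feature and the per-miRNA log2 fold change; rows with missing values are
#' dropped pairwise. Constant features are reported as not-available with a
#' reason instead of a statistic.
#'
#' @param de data.frame with `feature` and `log2FC` columns (one row per
#'   miRNA, names matching the feature table's `name`).
#' @param features feature table (e.g. [simulate_feature_table()]).
#' @param feature_names continuous feature columns to test.
#' @return data.frame: feature, kind, statistic (Pearson r), p, n, note.
#' @export
correlate_features <- function(de, features, feature_names) {
  stopifnot(all(feature_names %in% names(features)))
  merged <- merge(de[, c("feature", "log2FC")], features,
                  by.x = "feature", by.y = "name")
  rows <- lapply(feature_names, function(f) {
    x <- merged[[f]]; y <- merged$log2FC
    ok <- complete.cases(x, y)
    x <- as.numeric(x[ok]); y <- y[ok]
    if (length(x) < 3)
      stop("fewer than 3 paired observations for feature ", f)
    if (sd(x) == 0 || sd(y) == 0)
      return(data.frame(feature = f, kind = "continuous",
                        statistic = NA_real_, p = NA_real_, n = length(x),
                        note = "constant variable", stringsAsFactors = FALSE))
    ct <- cor.test(x, y)
    data.frame(feature = f, kind = "continuous",
               statistic = unname(ct$estimate), p = ct$p.value,
               n = length(x), note = "", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare log2FC between two feature-defined miRNA groups
#'
#' Welch two-sample t-test (two-sided) on log2FC between the two levels of a
#' categorical feature, matching the group comparisons of the association
#' analysis.
#'
#' @param de data.frame with `feature` and `log2FC`.
#' @param features feature table.
#' @param categorical_name name of a logical/two-level feature column.
#' @return data.frame: feature, kind, statistic (Welch t), p, n.
#' @export
group_compare <- function(de, features, categorical_name) {
  stopifnot(categorical_name %in% names(features))
  merged <- merge(de[, c("feature", "log2FC")], features,
                  by.x = "feature", by.y = "name")
  g <- merged[[categorical_name]]
  ok <- complete.cases(g, merged$log2FC)
  g <- g[ok]; y <- merged$log2FC[ok]
  lv <- sort(unique(g))  # deterministic group order (FALSE/TRUE, alphabetic)
  if (length(lv) != 2) stop("feature ", categorical_name,
                            " does not split miRNAs into two groups")
  y1 <- y[g == lv[1]]; y2 <- y[g == lv[2]]
  if (length(y1) < 2 || length(y2) < 2)
    stop("both groups need at least 2 members")
  tt <- t.test(y1, y2)
  data.frame(feature = categorical_name, kind = "categorical",
             statistic = unname(tt$statistic), p = tt$p.value,
             n = length(y), stringsAsFactors = FALSE)
}

#' Overlap of two downregulated miRNA sets with a hypergeometric tail test
#'
#' The overlap percent uses the smaller set as denominator; the p-value is
#' the one-sided hypergeometric enrichment tail P(X >= n_overlap) for
#' drawing |B| features from a universe containing |A| marked features.
#'
#' @param down_a,down_b character vectors of feature names (subsets of the
#'   universe).
#' @param universe_size number of detected features the sets were drawn
#'   from; must be at least |A union B|.
#' @return list: n_overlap, percent (of the smaller set), p.
#' @export
set_overlap <- function(down_a, down_b, universe_size) {
  a <- unique(down_a); b <- unique(down_b)
  if (!length(a) || !length(b)) stop("overlap percent undefined for empty set")
  if (universe_size < length(union(a, b)))
    stop("universe smaller than the union of the sets")
  k <- length(intersect(a, b))
  p <- phyper(k - 1, length(a), universe_size - length(a), length(b),
              lower.tail = FALSE)
  list(n_overlap = k, percent = 100 * k / min(length(a), length(b)), p = p)
}
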