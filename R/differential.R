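#' @importFrom stats median pnorm p.adjust setNames var lm coef
#' @importFrom SummarizedExperiment assay colData
NULL

.as_count_matrix <- function(counts) {
  if (is(counts, "SummarizedExperiment")) counts <- assay(counts)
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  counts
}

#' Median-of-ratios size factors
#'
#' The standard library-size normalization for count matrices: each
#' feature's geometric mean across samples defines a pseudo-reference, and a
#' sample's size factor is the median of its count-to-reference ratios over
#' features whose counts are positive in every sample.
#'
#' @param counts features x samples matrix of non-negative integers (or a
#'   `SummarizedExperiment`).
#' @return positive numeric vector of per-sample size factors.
#' @export
sizeFactorsMedianOfRatios <- function(counts) {
  counts <- .as_count_matrix(counts)
  if (ncol(counts) < 2L) stop("need >= 2 samples")
  log_gm <- rowMeans(log(counts))
  use <- is.finite(log_gm)
  if (!any(use)) {
    stop("no feature has all-positive counts; consider adding a pseudocount ",
         "before normalization")
  }
  sf <- apply(counts[use, , drop = FALSE], 2L, function(k) {
    exp(median(log(k) - log_gm[use]))
  })
  setNames(sf, colnames(counts))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement; a validated front
#' end over `stats::p.adjust(method = "BH")`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order as `p`.
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

# Method-of-moments NB dispersion, pooled across groups:
# within-group variance in normalized counts = mu/s_eff + alpha*mu^2;
# solve for alpha per feature, then shrink toward a 1/mu trend fit.
.mom_dispersion <- function(norm, groups, size_factors) {
  n_feat <- nrow(norm)
  num <- rep(0, n_feat); den <- rep(0, n_feat)
  for (g in unique(groups)) {
    j <- which(groups == g)
    if (length(j) < 2L) next
    mu <- rowMeans(norm[, j, drop = FALSE])
    v <- apply(norm[, j, drop = FALSE], 1L, var)
    shot <- mu * mean(1 / size_factors[j]) # Poisson part on normalized scale
    num <- num + (v - shot)
    den <- den + mu^2
  }
  raw <- ifelse(den > 0, num / den, NA_real_)
  raw <- pmax(raw, 1e-8)
  mu_all <- rowMeans(norm)
  ok <- !is.na(raw) & mu_all > 0 & raw > 1e-8
  trend <- rep(median(raw, na.rm = TRUE), n_feat)
  if (sum(ok) >= 10L) {
    # parametric trend alpha(mu) = a0 + a1/mu, coefficients floored at 0
    fit <- try(lm(raw[ok] ~ I(1 / mu_all[ok])), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      a <- pmax(coef(fit), 0)
      trend <- a[1L] + a[2L] / pmax(mu_all, 1e-8)
    }
  }
  shrunk <- 0.5 * ifelse(is.na(raw), trend, raw) + 0.5 * trend
  pmax(shrunk, 1e-8)
}

#' Simplified negative-binomial differential test
#'
#' Tests each feature for a log2 fold change exceeding `lfc_threshold`
#' between two sample groups, on median-of-ratios normalized counts. The
#' model is deliberately lightweight: group means on the normalized scale
#' (pseudocount 0.5), method-of-moments NB dispersion pooled across groups,
#' floored at 1e-8 and shrunk halfway toward a fitted `a0 + a1/mu` trend, a
#' delta-method standard error on the log2 ratio, and a two-sided normal
#' p-value for the composite hypothesis `|LFC| > lfc_threshold`
#' (statistic `max(0, |LFC| - lfc_threshold) / SE`). Multiple testing is
#' controlled by Benjamini-Hochberg. Accessibility analyses conventionally
#' run at `fdr = 0.1`, expression analyses at `fdr = 0.05`, both with
#' `lfc_threshold = 1`.
#'
#' @param counts features x samples non-negative integer matrix (or
#'   `SummarizedExperiment`; group labels then default to `colData$group`).
#' @param group_a,group_b column names/indices (or label values) of the two
#'   groups; the fold change is A over B.
#' @param groups optional vector of group labels parallel to columns, used
#'   when `group_a`/`group_b` are label values.
#' @param lfc_threshold log2 fold-change threshold entering the test.
#' @param fdr q-value cutoff for the three-way call.
#' @param pseudocount added to normalized group means before the log ratio.
#' @param size_factors optional precomputed size factors.
#' @return data.frame with one row per feature: `feature`, `base_mean`,
#'   `log2_fold_change`, `standard_error`, `p_value`, `q_value`, `call`
#'   (factor `A_up`/`B_up`/`ns`).
#' @export
nbDiffTest <- function(counts, group_a, group_b, groups = NULL,
                       lfc_threshold = 1, fdr = 0.1, pseudocount = 0.5,
                       size_factors = NULL) {
  if (is(counts, "SummarizedExperiment") && is.null(groups)) {
    groups <- as.character(colData(counts)$group)
  }
  counts <- .as_count_matrix(counts)
  if (is.null(groups)) groups <- colnames(counts)
  ja <- which(groups %in% group_a)
  jb <- which(groups %in% group_b)
  if (!length(ja) || !length(jb)) stop("empty group selection")
  if (length(ja) < 2L || length(jb) < 2L) {
    warning("fewer than 2 replicates in a group; dispersion is pooled and ",
            "poorly estimated")
  }
  sub <- counts[, c(ja, jb), drop = FALSE]
  grp <- rep(c("A", "B"), c(length(ja), length(jb)))
  sf <- if (is.null(size_factors)) sizeFactorsMedianOfRatios(sub) else
    size_factors[c(ja, jb)]
  norm <- sweep(sub, 2L, sf, "/")
  mu_a <- rowMeans(norm[, grp == "A", drop = FALSE])
  mu_b <- rowMeans(norm[, grp == "B", drop = FALSE])
  lfc <- log2((mu_a + pseudocount) / (mu_b + pseudocount))
  alpha <- .mom_dispersion(norm, grp, sf)

  # Var(mean of normalized counts) = (1/n^2) sum_j (mu/s_j + alpha mu^2);
  # delta method on log2(mean + pseudocount)
  ja2 <- which(grp == "A"); jb2 <- which(grp == "B")
  v_a <- (mu_a * sum(1 / sf[ja2]) + length(ja2) * alpha * mu_a^2) /
    length(ja2)^2
  v_b <- (mu_b * sum(1 / sf[jb2]) + length(jb2) * alpha * mu_b^2) /
    length(jb2)^2
  ln2sq <- log(2)^2
  se <- sqrt(v_a / (mu_a + pseudocount)^2 / ln2sq +
               v_b / (mu_b + pseudocount)^2 / ln2sq)
  se[se == 0 | !is.finite(se)] <- NA_real_

  stat <- pmax(abs(lfc) - lfc_threshold, 0) / se
  p <- 2 * pnorm(-stat)
  all_zero <- mu_a == 0 & mu_b == 0
  p[all_zero] <- 1
  lfc[all_zero] <- 0
  p[is.na(p)] <- 1
  q <- bhAdjust(p)
  call <- rep("ns", length(p))
  sig <- q < fdr & abs(lfc) > lfc_threshold
  call[sig & lfc > 0] <- "A_up"
  call[sig & lfc < 0] <- "B_up"
  feat <- rownames(counts)
  if (is.null(feat)) feat <- as.character(seq_len(nrow(counts)))
  data.frame(feature = feat, base_mean = (mu_a + mu_b) / 2,
             log2_fold_change = lfc, standard_error = se,
             p_value = p, q_value = q,
             call = factor(call, levels = c("A_up", "B_up", "ns")),
             row.names = NULL, stringsAsFactors = FALSE)
}
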