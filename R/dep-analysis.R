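#' @title Pairwise differential expression between histotype groups
#' @description Per-protein two-sample tests on observed (never imputed)
#'   log2 abundances, Benjamini-Hochberg adjustment across proteins, and the
#'   panel-discovery threshold "fold change > 4 and adjusted P < 0.01"
#'   (fold change on the linear scale, i.e. `|log2 FC| > 2`), plus one-way
#'   ANOVA across multiple groups.
#' @name dep_analysis
NULL

# vectorized Welch t-test per protein on observed values only;
# proteins with < min_obs observations in either group are excluded
welch_by_protein <- function(matrix, idxA, idxB, min_obs = 3) {
  A <- as_plain_matrix(unclass(matrix))[idxA, , drop = FALSE]
  B <- as_plain_matrix(unclass(matrix))[idxB, , drop = FALSE]
  nA <- colSums(!is.na(A)); nB <- colSums(!is.na(B))
  mA <- colMeans(A, na.rm = TRUE); mB <- colMeans(B, na.rm = TRUE)
  vA <- apply(A, 2, stats::var, na.rm = TRUE)
  vB <- apply(B, 2, stats::var, na.rm = TRUE)
  ok <- nA >= min_obs & nB >= min_obs & !is.na(vA) & !is.na(vB) &
    (vA + vB) > 0
  se2 <- vA[ok] / nA[ok] + vB[ok] / nB[ok]
  tstat <- (mA[ok] - mB[ok]) / sqrt(se2)
  df <- se2^2 / ((vA[ok] / nA[ok])^2 / (nA[ok] - 1) +
                   (vB[ok] / nB[ok])^2 / (nB[ok] - 1))
  data.frame(protein = colnames(matrix)[ok],
             log2fc = mA[ok] - mB[ok],
             p = 2 * stats::pt(-abs(tstat), df),
             n_a = nA[ok], n_b = nB[ok],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Differentially expressed proteins between two groups
#'
#' Welch's t-test per protein on observed log2 values (proteins with fewer
#' than `min_obs` observations in either group are excluded), BH adjustment
#' across tested proteins, then the filter
#' `|log2 FC| > log2(fc_threshold)` AND `adjusted p < alpha`. Fold change is
#' group A relative to group B; `direction` is `"up"`/`"down"` in A.
#'
#' @param matrix abundance matrix (log2, `NA` = missing, *not* imputed).
#' @param group_a,group_b sample id vectors (or row indices), each of size
#'   >= 2.
#' @param fc_threshold linear-scale fold-change threshold (default 4).
#' @param alpha adjusted-p threshold (default 0.01).
#' @param min_obs minimum observed values per group per protein.
#' @param all_results return the full test table instead of only the
#'   passing proteins.
#' @return data frame with `protein`, `log2fc`, `p`, `p_adj`, `direction`.
#' @export
pairwise_dep <- function(matrix, group_a, group_b, fc_threshold = 4,
                         alpha = 0.01, min_obs = 3, all_results = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 samples")
  tab <- welch_by_protein(matrix, group_a, group_b, min_obs)
  tab$p_adj <- stats::p.adjust(tab$p, method = "BH")
  tab$direction <- ifelse(tab$log2fc > 0, "up", "down")
  tab$significant <- abs(tab$log2fc) > log2(fc_threshold) & tab$p_adj < alpha
  if (all_results) tab else
    tab[tab$significant, setdiff(names(tab), "significant"), drop = FALSE]
}

#' Pairwise DEP counts over all group pairs
#'
#' For every ordered pair of groups, the number of up- and down-regulated
#' proteins passing the thresholds. Antisymmetric by construction:
#' `up(A, B) == down(B, A)`.
#'
#' @param matrix abundance matrix.
#' @param groups named list group -> sample ids, or a vector of group labels
#'   aligned with the matrix rows.
#' @inheritParams pairwise_dep
#' @return data frame with `group_a`, `group_b`, `up`, `down`, `total`.
#' @export
dep_count_matrix <- function(matrix, groups, fc_threshold = 4, alpha = 0.01,
                             min_obs = 3) {
  if (!is.list(groups)) {
    stopifnot(length(groups) == nrow(matrix))
    groups <- split(rownames(matrix), groups)
  }
  if (length(groups) < 2) stop("need at least 2 groups")
  gn <- names(groups)
  out <- list()
  for (i in seq_along(gn)) for (j in seq_along(gn)) {
    if (i >= j) next
    dep <- pairwise_dep(matrix, groups[[i]], groups[[j]],
                        fc_threshold, alpha, min_obs)
    up <- sum(dep$direction == "up"); dn <- sum(dep$direction == "down")
    out[[length(out) + 1]] <- data.frame(
      group_a = c(gn[i], gn[j]), group_b = c(gn[j], gn[i]),
      up = c(up, dn), down = c(dn, up), total = up + dn,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' One-way ANOVA per protein across groups
#'
#' Classical (equal-variance) one-way ANOVA F-test on observed log2 values.
#' Groups contributing fewer than `min_obs` observed values to a protein are
#' dropped for that protein; proteins retaining fewer than two groups get
#' `NA`.
#'
#' @param matrix abundance matrix.
#' @param groups group labels aligned with rows, or named list as in
#'   [dep_count_matrix()].
#' @param min_obs minimum observations per group per protein (default 2).
#' @return named numeric vector of p-values per protein.
#' @export
anova_across_groups <- function(matrix, groups, min_obs = 2) {
  m <- as_plain_matrix(unclass(matrix))
  if (is.list(groups)) {
    lab <- rep(NA_character_, nrow(m))
    for (g in names(groups)) lab[rownames(m) %in% groups[[g]]] <- g
    groups <- lab
  }
  stopifnot(length(groups) == nrow(m))
  if (length(unique(stats::na.omit(groups))) < 2)
    stop("need at least 2 groups")
  apply(m, 2, function(x) {
    ok <- !is.na(x) & !is.na(groups)
    x <- x[ok]; g <- groups[ok]
    keep <- names(which(table(g) >= min_obs))
    sel <- g %in% keep
    x <- x[sel]; g <- factor(g[sel])
    if (nlevels(g) < 2) return(NA_real_)
    gm <- tapply(x, g, mean); n <- tapply(x, g, length)
    ssb <- sum(n * (gm - mean(x))^2)
    ssw <- sum((x - gm[g])^2)
    df1 <- nlevels(g) - 1; df2 <- length(x) - nlevels(g)
    if (df2 < 1 || ssw == 0) return(NA_real_)
    stats::pf(ssb / df1 / (ssw / df2), df1, df2, lower.tail = FALSE)
  })
}
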