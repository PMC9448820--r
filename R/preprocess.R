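#' @title Detection-limit imputation and discovery-anchored normalization
#' @description Missing entries in label-free DIA matrices mostly arise when
#'   protein content falls below the detection limit, so all missing values
#'   are imputed with the ceiling of the global observed minimum of the
#'   *discovery* matrix, `ceiling(D_min)`. Each feature is then z-transformed
#'   with the discovery-set mean and standard deviation, `(D - mu) / sigma`,
#'   and the same constants are applied unchanged to any test cohort.
#' @name preprocess
NULL

#' Per-feature missing rate
#' @param matrix an [abundance_matrix()] or plain numeric matrix with `NA`s.
#' @return named numeric vector of missing fractions per protein.
#' @export
missing_rate <- function(matrix) colMeans(is.na(matrix))

#' Drop features with high missingness
#'
#' The global-profile retention rule: keep proteins quantified with missing
#' rate strictly below `cutoff` (default 0.90).
#'
#' @param matrix abundance matrix.
#' @param cutoff maximum tolerated missing fraction, in `(0, 1]`.
#' @return the filtered abundance matrix.
#' @export
filter_missing_rate <- function(matrix, cutoff = 0.90) {
  stopifnot(cutoff > 0, cutoff <= 1)
  keep <- missing_rate(matrix) < cutoff
  abundance_matrix(as_plain_matrix(unclass(matrix))[, keep, drop = FALSE])
}

#' Average technical replicates per nodule
#'
#' Cell-wise arithmetic mean of observed log2 values across the replicates of
#' each nodule; a cell missing in every replicate stays missing. Averaging is
#' done *before* imputation so the imputation constant cannot bias replicate
#' means.
#'
#' @param matrix abundance matrix (rows = replicate samples).
#' @param groups named list mapping nodule id -> character vector of sample
#'   ids, or a vector of nodule ids aligned with the matrix rows.
#' @return abundance matrix with one row per nodule.
#' @export
aggregate_replicates <- function(matrix, groups) {
  if (!is.list(groups)) {
    stopifnot(length(groups) == nrow(matrix))
    groups <- split(rownames(matrix), groups)
  }
  out <- t(vapply(groups, function(ids) {
    sub <- matrix[ids, , drop = FALSE]
    colMeans(sub, na.rm = TRUE)
  }, numeric(ncol(matrix))))
  out[is.nan(out)] <- NA_real_
  abundance_matrix(out, sample_ids = names(groups),
                   protein_ids = colnames(matrix))
}

#' Fit the discovery-anchored normalization model
#'
#' Computes the imputation constant `ceiling(D_min)` (ceiling of the minimum
#' over all observed values of the discovery matrix), imputes, and estimates
#' per-feature mean and standard deviation (unbiased, n-1 denominator) on the
#' imputed discovery matrix. Features whose missing rate is not below
#' `missing_cutoff` are dropped first; features with zero variance after
#' imputation are excluded with a warning (or an error when
#' `zero_variance = "error"`).
#'
#' @param discovery abundance matrix of the discovery cohort.
#' @param missing_cutoff feature retention cutoff, see [filter_missing_rate()].
#' @param zero_variance `"exclude"` (default) or `"error"`.
#' @return object of class `normalization_model` with fields `impute_value`,
#'   `mu`, `sigma`, `feature_ids`, `dropped_zero_variance`.
#' @export
fit_normalizer <- function(discovery, missing_cutoff = 0.90,
                           zero_variance = c("exclude", "error")) {
  zero_variance <- match.arg(zero_variance)
  if (nrow(discovery) < 2) stop("need at least 2 discovery samples")
  m <- filter_missing_rate(discovery, missing_cutoff)
  obs <- m[!is.na(m)]
  if (!length(obs)) stop("discovery matrix has no observed values")
  impute_value <- ceiling(min(obs))
  filled <- as_plain_matrix(unclass(m))
  filled[is.na(filled)] <- impute_value
  mu <- colMeans(filled)
  sigma <- apply(filled, 2, stats::sd)
  bad <- sigma <= 0
  if (any(bad)) {
    msg <- sprintf("%d feature(s) with zero variance after imputation: %s",
                   sum(bad), paste(utils::head(colnames(filled)[bad], 5),
                                   collapse = ", "))
    if (zero_variance == "error") stop(msg)
    warning(msg, "; excluded from the model")
  }
  structure(list(impute_value = impute_value,
                 mu = mu[!bad], sigma = sigma[!bad],
                 feature_ids = colnames(filled)[!bad],
                 dropped_zero_variance = colnames(filled)[bad]),
            class = "normalization_model")
}

#' @export
print.normalization_model <- function(x, ...) {
  cat(sprintf("normalization_model: %d features, impute_value = %d\n",
              length(x$feature_ids), as.integer(x$impute_value)))
  invisible(x)
}

#' Apply a normalization model to a matrix
#'
#' Missing cells are set to the model's `impute_value`, then each feature is
#' z-transformed with the *discovery-derived* mean and standard deviation.
#' The output contains no missing cells. All matrix features must be known to
#' the model.
#'
#' @param model a `normalization_model`.
#' @param matrix abundance matrix whose features are a subset of the model's.
#' @return abundance matrix of z-scores, no `NA`s.
#' @export
apply_normalizer <- function(model, matrix) {
  stopifnot(inherits(model, "normalization_model"))
  unknown <- setdiff(colnames(matrix), model$feature_ids)
  if (length(unknown))
    stop("feature(s) not in the normalization model: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  v <- as_plain_matrix(unclass(matrix))
  if (any(!is.finite(v[!is.na(v)]))) stop("non-finite input values")
  v[is.na(v)] <- model$impute_value
  ids <- colnames(v)
  v <- sweep(v, 2, model$mu[ids], "-")
  v <- sweep(v, 2, model$sigma[ids], "/")
  abundance_matrix(v, sample_ids = rownames(matrix), protein_ids = ids)
}

#' Replicate quality control
#'
#' Per replicate group: the per-protein coefficient of variation (sd/mean of
#' the log2 values, computed on cells observed in at least two replicates)
#' and all pairwise Spearman correlations on commonly observed proteins.
#' Groups with fewer than two samples are skipped with a warning.
#'
#' @param matrix abundance matrix.
#' @param replicate_groups named list nodule -> sample ids.
#' @return object of class `qc_report`: `cv` (per-group median CV),
#'   `spearman` (per-pair correlations), `median_cv`, `median_spearman`.
#' @export
replicate_qc <- function(matrix, replicate_groups) {
  sizes <- lengths(replicate_groups)
  if (any(sizes < 2)) {
    warning(sum(sizes < 2), " replicate group(s) with < 2 samples skipped")
    replicate_groups <- replicate_groups[sizes >= 2]
  }
  if (!length(replicate_groups)) stop("no replicate groups of size >= 2")
  cvs <- vapply(replicate_groups, function(ids) {
    sub <- matrix[ids, , drop = FALSE]
    n_obs <- colSums(!is.na(sub))
    sub <- sub[, n_obs >= 2, drop = FALSE]
    cv <- apply(sub, 2, function(x) {
      x <- x[!is.na(x)]
      stats::sd(x) / mean(x)
    })
    stats::median(cv, na.rm = TRUE)
  }, numeric(1))
  rho <- unlist(lapply(replicate_groups, function(ids) {
    pairs <- utils::combn(ids, 2, simplify = FALSE)
    vapply(pairs, function(pr) {
      x <- matrix[pr[1], ]; y <- matrix[pr[2], ]
      ok <- !is.na(x) & !is.na(y)
      stats::cor(x[ok], y[ok], method = "spearman")
    }, numeric(1))
  }))
  structure(list(cv = cvs, spearman = rho,
                 median_cv = stats::median(cvs, na.rm = TRUE),
                 median_spearman = stats::median(rho, na.rm = TRUE)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: median CV = %.4f, median Spearman = %.3f (%d groups)\n",
              x$median_cv, x$median_spearman, length(x$cv)))
  invisible(x)
}

#' Serialize / load a normalization model as JSON
#' @param model a `normalization_model`.
#' @param path file path.
#' @export
write_normalizer_json <- function(model, path) {
  jsonlite::write_json(
    list(impute_value = model$impute_value,
         feature_ids = model$feature_ids,
         mu = unname(model$mu), sigma = unname(model$sigma)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_normalizer_json
#' @export
read_normalizer_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(impute_value = as.numeric(j$impute_value),
                 mu = stats::setNames(j$mu, j$feature_ids),
                 sigma = stats::setNames(j$sigma, j$feature_ids),
                 feature_ids = j$feature_ids,
                 dropped_zero_variance = character(0)),
            class = "normalization_model")
}
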