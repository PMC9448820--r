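#' @title Synthetic DIA-style thyroid cohort simulator
#' @description Generates sample-by-protein log2 abundance matrices with the
#'   statistical structure the downstream pipeline assumes: a right-skewed
#'   pooled abundance distribution summarized by its quartiles, missingness
#'   concentrated below a detection threshold (missing-not-at-random),
#'   benign/malignant group structure carried by a planted subset of
#'   informative proteins, a multi-histotype composition, and optional
#'   technical replicates per nodule.
#' @name synthetic_cohort
NULL

# histotype -> benign/malignant dictionary; total and deterministic
.HISTOTYPE_CLASS <- c(
  N = "benign", MNG = "benign", FA = "benign", L = "benign", HCA = "benign",
  FTC = "malignant", PTC = "malignant", HCC = "malignant", fvPTC = "malignant"
)

#' Map histotypes to benign/malignant class
#'
#' Benign: N, MNG, FA, L, HCA. Malignant: FTC, PTC, HCC, fvPTC.
#'
#' @param histotype character vector of histotype codes.
#' @return character vector in `{"benign","malignant"}`.
#' @export
histotype_class <- function(histotype) {
  cls <- .HISTOTYPE_CLASS[as.character(histotype)]
  if (anyNA(cls))
    stop("unknown histotype(s): ",
         paste(unique(histotype[is.na(cls)]), collapse = ", "))
  unname(cls)
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults restate the discovery-cohort conditions the simulator emulates:
#' 579 tissue samples over five histotypes (40 N, 203 MNG, 137 FA, 75 FTC,
#' 124 PTC), pooled observed-abundance quartiles 18.0 / 19.0 / 20.3 on the
#' log2 scale, and an overall missing fraction of 0.51 produced by logistic
#' censoring below a detection threshold.
#'
#' @param n_per_histotype named integer vector, nodules per histotype.
#' @param n_proteins number of proteins.
#' @param n_informative number of planted discriminative proteins.
#' @param effect_size log2-units mean shift between benign and malignant
#'   nodules for informative proteins.
#' @param effect_direction `"up"` (default): informative proteins are
#'   up-shifted in malignant samples; `"mixed"`: alternating signs.
#' @param base_quartiles numeric length-3: target Q1/median/Q3 of the pooled
#'   observed log2 intensities.
#' @param missing_fraction_target overall missing fraction in `[0, 0.95]`.
#' @param detection_steepness slope (per log2 unit) of the logistic
#'   missingness-vs-abundance curve.
#' @param replicate_count technical replicates per nodule.
#' @param noise_sd log2-units standard deviation of both the inter-nodule
#'   biological scatter and the per-replicate measurement noise.
#' @param seed integer RNG seed; identical config + seed gives bit-identical
#'   output.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_histotype = c(N = 40, MNG = 203, FA = 137,
                                              FTC = 75, PTC = 124),
                          n_proteins = 1000,
                          n_informative = 19,
                          effect_size = 2,
                          effect_direction = c("up", "mixed"),
                          base_quartiles = c(18.0, 19.0, 20.3),
                          missing_fraction_target = 0.51,
                          detection_steepness = 2,
                          replicate_count = 1,
                          noise_sd = 1,
                          seed = 1L) {
  effect_direction <- match.arg(effect_direction)
  if (is.null(names(n_per_histotype)) || any(names(n_per_histotype) == ""))
    stop("`n_per_histotype` must be a named vector")
  histotype_class(names(n_per_histotype))  # validates codes
  if (any(n_per_histotype < 0) || n_proteins < 1 || n_informative < 0)
    stop("counts must be non-negative (and n_proteins >= 1)")
  if (n_informative > n_proteins) stop("n_informative exceeds n_proteins")
  if (missing_fraction_target < 0 || missing_fraction_target > 0.95)
    stop("missing_fraction_target must lie in [0, 0.95]")
  if (length(base_quartiles) != 3 || is.unsorted(base_quartiles))
    stop("base_quartiles must be three non-decreasing log2 intensities")
  if (detection_steepness <= 0) stop("detection_steepness must be positive")
  if (replicate_count < 1) stop("replicate_count must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(n_per_histotype = n_per_histotype,
                 n_proteins = as.integer(n_proteins),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size,
                 effect_direction = effect_direction,
                 base_quartiles = base_quartiles,
                 missing_fraction_target = missing_fraction_target,
                 detection_steepness = detection_steepness,
                 replicate_count = as.integer(replicate_count),
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# run `expr` under seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# quantile function of the two-half-normal protein-mean distribution fitted
# through three quartile anchors
half_normal_q <- function(u, anchors) {
  s_lo <- (anchors[2] - anchors[1]) / stats::qnorm(0.75)
  s_hi <- (anchors[3] - anchors[2]) / stats::qnorm(0.75)
  s <- ifelse(u < 0.5, s_lo, s_hi)
  anchors[2] + s * stats::qnorm(u)
}

# threshold t such that mean(plogis(s * (t - x))) == target
calibrate_threshold <- function(x, steepness, target) {
  f <- function(t) mean(stats::plogis(steepness * (t - x))) - target
  lo <- min(x) - 60
  hi <- max(x) + 60
  if (f(lo) > 0 || f(hi) < 0)
    stop("calibration failure: missing_fraction_target unreachable")
  stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
}

weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which.max(cw >= p)], numeric(1))
}

#' Generate a synthetic cohort
#'
#' Draws per-protein latent mean abundances from a two-half-normal
#' distribution anchored at the target quartiles, adds planted
#' benign-vs-malignant shifts for the informative proteins, inter-nodule
#' biological scatter, and per-replicate measurement noise, then censors
#' entries to missing with probability `plogis(steepness * (threshold - x))`.
#' The detection threshold is calibrated so the overall expected missing
#' fraction equals `missing_fraction_target`, and the latent anchors are
#' iteratively adjusted so the quartiles of the *observed* (surviving) values
#' match `base_quartiles`. Informative proteins are drawn from the upper
#' abundance range (quantiles 0.70-0.995 of the mean distribution), matching
#' the observation that panel-grade features sit above the median abundance
#' and carry little missingness.
#'
#' @param config a [cohort_config()].
#' @return an object of class `synthetic_cohort`: a list with elements
#'   `matrix` ([abundance_matrix()]), `annotation` (data frame with
#'   `sample_id`, `nodule_id`, `replicate`, `histotype`, `class`),
#'   `truth_informative` (character), and `truth_detection_threshold`
#'   (log2 intensity, `NA` when censoring is disabled).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    nh <- config$n_per_histotype[config$n_per_histotype > 0]
    n_nod <- sum(nh)
    if (n_nod < 1) stop("cohort has no nodules")
    p <- config$n_proteins
    protein_ids <- sprintf("PROT%04d", seq_len(p))
    informative <- if (config$n_informative > 0)
      protein_ids[seq_len(config$n_informative)] else character(0)
    is_inf <- protein_ids %in% informative

    # nodule-level annotation
    histotype <- rep(names(nh), times = nh)
    nodule_id <- sprintf("NOD%04d", seq_len(n_nod))
    cls <- histotype_class(histotype)
    malignant <- cls == "malignant"

    # per-protein mean quantile positions (informative drawn high-abundance)
    u <- stats::runif(p)
    u[is_inf] <- stats::runif(sum(is_inf), 0.70, 0.995)

    # planted shifts (log2 units), applied to malignant nodules
    delta <- numeric(p)
    if (any(is_inf)) {
      sgn <- if (config$effect_direction == "up") 1
             else rep_len(c(1, -1), sum(is_inf))
      delta[is_inf] <- sgn * config$effect_size
    }

    # structural (seed-fixed) random components, reused across calibration
    bio <- matrix(stats::rnorm(n_nod * p, sd = config$noise_sd), n_nod, p)
    r <- config$replicate_count
    n_samp <- n_nod * r
    tech <- matrix(stats::rnorm(n_samp * p, sd = config$noise_sd), n_samp, p)
    nod_of_sample <- rep(seq_len(n_nod), each = r)

    build_latent <- function(anchors) {
      m <- half_normal_q(u, anchors)
      nodule_val <- sweep(bio, 2, m, "+") +
        outer(malignant, delta)               # n_nod x p
      nodule_val[nod_of_sample, , drop = FALSE] + tech
    }

    anchors <- config$base_quartiles
    target <- config$missing_fraction_target
    steep <- config$detection_steepness
    thr <- NA_real_
    if (target > 0) {
      # calibrate anchors so post-censoring observed quartiles hit targets,
      # using expected survival weights (deterministic given the draws)
      for (it in seq_len(12)) {
        lat <- build_latent(anchors)
        thr <- calibrate_threshold(lat, steep, target)
        w <- 1 - stats::plogis(steep * (thr - lat))
        qobs <- weighted_quantile(as.vector(lat), as.vector(w),
                                  c(0.25, 0.5, 0.75))
        resid <- config$base_quartiles - qobs
        if (max(abs(resid)) < 1e-3) break
        anchors <- anchors + resid
        anchors <- cummax(anchors)            # keep anchors ordered
      }
      lat <- build_latent(anchors)
      thr <- calibrate_threshold(lat, steep, target)
      pmiss <- stats::plogis(steep * (thr - lat))
      mask <- matrix(stats::runif(length(lat)) < pmiss, nrow(lat), ncol(lat))
      lat[mask] <- NA_real_
    } else {
      lat <- build_latent(anchors)
    }

    sample_id <- if (r > 1)
      sprintf("%s_r%d", rep(nodule_id, each = r), rep(seq_len(r), n_nod))
    else rep(nodule_id, each = r)
    annotation <- data.frame(
      sample_id = sample_id,
      nodule_id = rep(nodule_id, each = r),
      replicate = rep(seq_len(r), n_nod),
      histotype = rep(histotype, each = r),
      class = rep(cls, each = r),
      stringsAsFactors = FALSE)

    structure(list(
      matrix = abundance_matrix(lat, sample_ids = sample_id,
                                protein_ids = protein_ids),
      annotation = annotation,
      truth_informative = informative,
      truth_detection_threshold = thr,
      config = config), class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic_cohort: %d samples (%d nodules), %d proteins, %.1f%% missing\n",
    nrow(x$matrix), length(unique(x$annotation$nodule_id)), ncol(x$matrix),
    100 * mean(is.na(x$matrix))))
  cat("histotypes:", paste(sprintf("%s=%d", names(table(x$annotation$histotype)),
                                   table(x$annotation$histotype)),
                           collapse = ", "), "\n")
  invisible(x)
}

# subset a cohort to a set of sample ids (keeps truth fields)
subset_cohort <- function(cohort, sample_ids) {
  keep <- cohort$annotation$sample_id %in% sample_ids
  structure(list(
    matrix = abundance_matrix(
      as_plain_matrix(unclass(cohort$matrix))[cohort$annotation$sample_id %in%
                                                sample_ids, , drop = FALSE]),
    annotation = cohort$annotation[keep, , drop = FALSE],
    truth_informative = cohort$truth_informative,
    truth_detection_threshold = cohort$truth_detection_threshold,
    config = cohort$config), class = "synthetic_cohort")
}

# largest-remainder allocation of n items over `fractions`
allocate_counts <- function(n, fractions) {
  exact <- n * fractions
  base <- floor(exact)
  extra <- n - sum(base)
  if (extra > 0) {
    o <- order(exact - base, decreasing = TRUE)[seq_len(extra)]
    base[o] <- base[o] + 1
  }
  as.integer(base)
}

#' Split a cohort into stratified partitions
#'
#' Partitions the cohort at the *nodule* level (replicates of one nodule
#' never straddle splits), stratified on an annotation key, with per-stratum
#' sizes allocated by the largest-remainder rule so totals match the
#' requested fractions exactly (e.g. 579 samples at 2/3 : 1/3 give 386 and
#' 193; at 0.8 : 0.2 give 463 and 116).
#'
#' @param cohort a `synthetic_cohort`.
#' @param fractions positive fractions summing to 1.
#' @param stratify_by annotation column to stratify on (default `"class"`).
#' @param seed integer seed for the shuffle.
#' @return list of `synthetic_cohort` partitions.
#' @export
split_cohort <- function(cohort, fractions, stratify_by = "class",
                         seed = 1L) {
  if (any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be positive and sum to 1")
  ann <- cohort$annotation
  if (!stratify_by %in% names(ann)) stop("unknown annotation key: ", stratify_by)
  nod <- unique(ann[, c("nodule_id", stratify_by)])
  k <- length(fractions)
  with_seed(seed, {
    assign_split <- integer(nrow(nod))
    names(assign_split) <- nod$nodule_id
    for (s in unique(nod[[stratify_by]])) {
      ids <- nod$nodule_id[nod[[stratify_by]] == s]
      if (length(ids) < k)
        stop(sprintf("stratum '%s' smaller than number of splits", s))
      counts <- allocate_counts(length(ids), fractions)
      ids <- sample(ids)
      assign_split[ids] <- rep(seq_len(k), times = counts)
    }
    lapply(seq_len(k), function(i) {
      keep_nod <- names(assign_split)[assign_split == i]
      subset_cohort(cohort, ann$sample_id[ann$nodule_id %in% keep_nod])
    })
  })
}

#' Write a synthetic cohort to a directory
#'
#' Writes `matrix.tsv` (the abundance TSV dialect), `annotation.tsv`, and
#' `truth.json` (informative protein ids and detection threshold).
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory, created if needed.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_abundance_tsv(cohort$matrix, file.path(dir, "matrix.tsv"))
  write_annotation_tsv(cohort$annotation, file.path(dir, "annotation.tsv"))
  jsonlite::write_json(
    list(truth_informative = cohort$truth_informative,
         truth_detection_threshold = cohort$truth_detection_threshold),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
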