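test_that("imputation constant is the ceiling of the observed minimum", {
  m <- abundance_matrix(matrix(c(11.2, 13, 15, NA, 14.5, 16), 3, 2,
                               dimnames = list(paste0("s", 1:3), c("a", "b"))))
  expect_identical(fit_normalizer(m, missing_cutoff = 1)$impute_value, 12)
  m2 <- abundance_matrix(matrix(c(12.0, 13, 15, 14, 14.5, 16), 3, 2,
                                dimnames = list(paste0("s", 1:3), c("a", "b"))))
  expect_identical(fit_normalizer(m2)$impute_value, 12)
})

test_that("mu/sigma match hand arithmetic on a 3x2 toy with one missing cell", {
  # observed: a = (11.2, 13, 15), b = (NA, 14.5, 16); impute = ceiling(11.2) = 12
  m <- abundance_matrix(matrix(c(11.2, 13, 15, NA, 14.5, 16), 3, 2,
                               dimnames = list(paste0("s", 1:3), c("a", "b"))))
  nm <- fit_normalizer(m, missing_cutoff = 1)
  filled_b <- c(12, 14.5, 16)
  expect_equal(unname(nm$mu), c(mean(c(11.2, 13, 15)), mean(filled_b)))
  expect_equal(unname(nm$sigma), c(sd(c(11.2, 13, 15)), sd(filled_b)))
})

test_that("self-normalization yields mean 0 and sd 1 per feature", {
  set.seed(2)
  v <- matrix(rnorm(200, 19, 2), 20, 10,
              dimnames = list(paste0("s", 1:20), paste0("p", 1:10)))
  v[sample(length(v), 30)] <- NA
  m <- abundance_matrix(v)
  nm <- fit_normalizer(m, missing_cutoff = 1)
  z <- apply_normalizer(nm, m)
  expect_false(anyNA(z))
  expect_lt(max(abs(colMeans(z))), 1e-9)
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-9)
  # identical test matrix -> identical output
  expect_equal(unclass(apply_normalizer(nm, m)), unclass(z))
})

test_that("normalization is anchored to the discovery model only", {
  set.seed(3)
  disc <- abundance_matrix(matrix(rnorm(100, 19), 10, 10,
                                  dimnames = list(paste0("s", 1:10),
                                                  paste0("p", 1:10))))
  nm <- fit_normalizer(disc)
  test1 <- abundance_matrix(matrix(rnorm(50, 25), 5, 10,
                                   dimnames = list(paste0("t", 1:5),
                                                   paste0("p", 1:10))))
  z1 <- apply_normalizer(nm, test1)
  nm2 <- fit_normalizer(disc)  # refit after seeing different test data
  expect_identical(nm$mu, nm2$mu)
  expect_identical(nm$impute_value, nm2$impute_value)
  # all-missing sample: closed form (impute - mu) / sigma
  all_na <- abundance_matrix(matrix(NA_real_, 1, 10,
                                    dimnames = list("x", paste0("p", 1:10))))
  z <- apply_normalizer(nm, all_na)
  expect_equal(as.numeric(z), unname((nm$impute_value - nm$mu) / nm$sigma))
})

test_that("imputation is idempotent through apply_normalizer", {
  set.seed(4)
  v <- matrix(rnorm(60, 19), 6, 10,
              dimnames = list(paste0("s", 1:6), paste0("p", 1:10)))
  v[c(3, 17, 40)] <- NA
  m <- abundance_matrix(v)
  nm <- fit_normalizer(m, missing_cutoff = 1)
  z1 <- apply_normalizer(nm, m)
  # applying to the already-complete matrix on the original scale:
  filled <- v; filled[is.na(filled)] <- nm$impute_value
  z2 <- apply_normalizer(nm, abundance_matrix(filled))
  expect_equal(unclass(z1), unclass(z2))
})

test_that("unknown features and zero-variance features are handled", {
  m <- abundance_matrix(matrix(c(1, 2, 3, 5, 5, 5), 3, 2,
                               dimnames = list(paste0("s", 1:3), c("a", "b"))))
  expect_warning(nm <- fit_normalizer(m), "zero variance")
  expect_identical(nm$feature_ids, "a")
  expect_error(fit_normalizer(m, zero_variance = "error"), "zero variance")
  expect_error(apply_normalizer(nm, m), "not in the normalization model")
})

test_that("missing-rate filter applies the < cutoff rule", {
  v <- matrix(rnorm(100, 19), 10, 10,
              dimnames = list(paste0("s", 1:10), paste0("p", 1:10)))
  v[1:4, 1] <- NA   # 40% missing
  v[1:3, 2] <- NA   # 30% missing
  m <- abundance_matrix(v)
  kept <- colnames(filter_missing_rate(m, 0.35))
  expect_false("p1" %in% kept)
  expect_true("p2" %in% kept)
})

test_that("replicate aggregation averages observed values before imputation", {
  v <- matrix(c(10, 12, NA, NA, 14, 16), 2, 3, byrow = FALSE,
              dimnames = list(c("r1", "r2"), c("a", "b", "c")))
  m <- abundance_matrix(v)
  ag <- aggregate_replicates(m, list(n1 = c("r1", "r2")))
  expect_equal(as.numeric(ag), c(11, NA, 15))
  # nodule order does not change values
  v2 <- rbind(v, r3 = c(20, 21, 22), r4 = c(22, 23, 24))
  m2 <- abundance_matrix(v2)
  g12 <- aggregate_replicates(m2, list(n1 = c("r1", "r2"), n2 = c("r3", "r4")))
  g21 <- aggregate_replicates(m2, list(n2 = c("r3", "r4"), n1 = c("r1", "r2")))
  expect_equal(g12["n1", ], g21["n1", ])
  expect_equal(g12["n2", ], g21["n2", ])
})

test_that("replicate QC: identical replicates give CV 0 and Spearman 1", {
  v <- matrix(rep(c(15, 17, 19, 21), each = 2), 2, 4,
              dimnames = list(c("r1", "r2"), paste0("p", 1:4)))
  qc <- replicate_qc(abundance_matrix(v), list(n1 = c("r1", "r2")))
  expect_equal(qc$median_cv, 0)
  expect_equal(qc$median_spearman, 1)
})

test_that("noise-free synthetic replicates give median CV 0", {
  ch <- generate_cohort(small_cohort_config(
    noise_sd = 0, replicate_count = 2, missing_fraction_target = 0))
  groups <- split(ch$annotation$sample_id, ch$annotation$nodule_id)
  qc <- replicate_qc(ch$matrix, groups)
  expect_equal(qc$median_cv, 0)
})

test_that("Spearman matches the brute-force rank formula on a permuted toy", {
  # 4 proteins, ranks hand-permuted: x ranks 1234, y ranks 2143
  x <- c(10, 11, 12, 13)
  y <- c(20.5, 20.1, 22.9, 22.3)
  v <- rbind(r1 = x, r2 = y)
  colnames(v) <- paste0("p", 1:4)
  qc <- suppressWarnings(replicate_qc(abundance_matrix(v),
                                      list(n = c("r1", "r2"))))
  rho_hand <- 1 - 6 * sum((rank(x) - rank(y))^2) / (4 * (4^2 - 1))
  expect_equal(unname(qc$spearman), rho_hand)
})

test_that("groups of size < 2 are skipped with a warning", {
  v <- matrix(rnorm(12, 19), 3, 4,
              dimnames = list(c("r1", "r2", "r3"), paste0("p", 1:4)))
  expect_warning(
    qc <- replicate_qc(abundance_matrix(v),
                       list(n1 = c("r1", "r2"), n2 = "r3")),
    "skipped")
  expect_length(qc$cv, 1)
})

test_that("normalizer JSON round trip preserves the model", {
  set.seed(5)
  m <- abundance_matrix(matrix(rnorm(60, 19), 6, 10,
                               dimnames = list(paste0("s", 1:6),
                                               paste0("p", 1:10))))
  nm <- fit_normalizer(m)
  path <- withr::local_tempfile(fileext = ".json")
  write_normalizer_json(nm, path)
  nm2 <- read_normalizer_json(path)
  expect_equal(nm2$mu, nm$mu)
  expect_equal(nm2$sigma, nm$sigma)
  expect_identical(nm2$impute_value, nm$impute_value)
  expect_equal(unclass(apply_normalizer(nm2, m)),
               unclass(apply_normalizer(nm, m)))
})
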