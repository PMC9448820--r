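# shared in-code fixtures; everything is generated, nothing read from disk

# small labelled gaussian classification matrix with planted column shifts
make_labelled_matrix <- function(n_per_class = 30, p = 10, shifted = 1:3,
                                 shift = 2, sd = 1, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  X <- matrix(rnorm(n * p, sd = sd), n, p,
              dimnames = list(paste0("s", seq_len(n)),
                              sprintf("P%02d", seq_len(p))))
  y <- rep(c("benign", "malignant"), each = n_per_class)
  X[y == "malignant", shifted] <- X[y == "malignant", shifted] + shift
  list(X = X, y = y)
}

# tiny default cohort for structural tests
small_cohort_config <- function(...) {
  args <- list(...)
  defaults <- list(
    n_per_histotype = c(N = 8, MNG = 20, FA = 14, FTC = 10, PTC = 14),
    n_proteins = 60, n_informative = 5, effect_size = 2,
    missing_fraction_target = 0.4, noise_sd = 1, seed = 42)
  do.call(cohort_config, utils::modifyList(defaults, args))
}

# independent log-gamma oracle for the t-density kernel
t_kernel_oracle <- function(d, nu) {
  exp(lgamma((nu + 1) / 2) - lgamma(nu / 2) - 0.5 * log(nu * pi) -
        (nu + 1) / 2 * log1p(d^2 / nu))
}

# scalar Bernoulli KL oracle for the two-way divergence
bern_kl <- function(p, q) p * log(p / q) + (1 - p) * log((1 - p) / (1 - q))

# Wilson interval by direct inversion of the score statistic (uniroot),
# independent of the closed form used by the package
wilson_oracle <- function(k, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  phat <- k / n
  score <- function(p) (phat - p)^2 - z^2 * p * (1 - p) / n
  # score(phat) < 0 and score() > 0 outside the interval; at k = 0 (k = n)
  # the lower (upper) endpoint is exactly 0 (1), so bracket away from phat
  lo <- if (k == 0) 0 else
    uniroot(score, c(1e-14, phat * (1 - 1e-9)), tol = 1e-14)$root
  hi <- if (k == n) 1 else
    uniroot(score, c(phat + (1 - phat) * 1e-9, 1 - 1e-14), tol = 1e-14)$root
  c(lower = lo, upper = hi)
}

# O(n^2) pairwise-comparison AUC oracle with tie correction
auc_oracle <- function(scores, truth01) {
  pos <- scores[truth01 == 1]; neg <- scores[truth01 == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}
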