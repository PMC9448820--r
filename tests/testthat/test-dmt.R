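test_that("t_kernel matches the Student-t density (log-gamma oracle)", {
  expect_equal(t_kernel(0, 1), 1 / pi, tolerance = 1e-12)
  expect_equal(t_kernel(2, 100), t_kernel_oracle(2, 100), tolerance = 1e-12)
  for (nu in c(0.5, 1, 10, 100)) {
    d <- seq(0, 5, by = 0.25)
    expect_equal(t_kernel(d, nu), t_kernel_oracle(d, nu), tolerance = 1e-12)
    expect_true(all(diff(t_kernel(d, nu)) < 0))  # strictly decreasing in D
  }
  expect_error(t_kernel(matrix(c(0, NA), 1), 1), "non-finite")
})

test_that("symmetrize matches its algebra and a double-loop oracle", {
  a <- matrix(0.3, 2, 2)
  expect_equal(symmetrize(a)[1, 2], 2 * 0.3 * (1 - 0.3))
  expect_equal(symmetrize(matrix(1, 3, 3)), matrix(0, 3, 3))
  set.seed(8)
  A <- matrix(runif(16, 0.05, 0.95), 4, 4)
  S <- symmetrize(A)
  oracle <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4)
    oracle[i, j] <- A[i, j] + A[j, i] - 2 * A[i, j] * A[j, i]
  expect_equal(S, oracle, tolerance = 1e-15)
  expect_equal(S, t(S))
  expect_true(all(S >= 0 & S <= 1))
})

test_that("pairwise similarities are bounded in (0, 1) pre-clamp", {
  # coincident points: 2*pi*kappa(0, nu)^2, via the log-gamma oracle
  expect_equal(2 * pi * t_kernel_oracle(0, 1)^2, 2 / pi, tolerance = 1e-12)
  x2 <- rbind(c(1, 2), c(1, 2))
  P1 <- pairwise_similarities(x2, nu = 1)
  expect_equal(P1[1, 2], {
    a <- 2 / pi; a + a - 2 * a * a  # symmetrization of equal entries
  }, tolerance = 1e-10)
  s100 <- 2 * pi * t_kernel_oracle(0, 100)^2
  expect_gt(s100, 0.99); expect_lt(s100, 1)
  # density bound: similarity of coincident points < 1 for every nu
  for (nu in c(0.5, 1, 10, 100)) {
    pre <- 2 * pi * t_kernel_oracle(seq(0, 10, 0.5), nu)^2
    expect_true(all(pre > 0 & pre < 1))
  }
  expect_error(pairwise_similarities(matrix(1, 1, 3), 1), "at least 2")
})

test_that("dmt_loss equals the scalar Bernoulli-KL oracle and is >= 0", {
  P <- matrix(c(1, 0.8, 0.8, 1), 2, 2)
  Q <- matrix(c(1, 0.2, 0.2, 1), 2, 2)
  expect_equal(dmt_loss(P, Q), 2 * bern_kl(0.8, 0.2), tolerance = 1e-12)
  expect_equal(dmt_loss(P, P), 0)
  set.seed(10)
  for (r in 1:50) {
    n <- sample(3:6, 1)
    P <- matrix(runif(n * n, 0.01, 0.99), n, n); diag(P) <- 1
    Q <- matrix(runif(n * n, 0.01, 0.99), n, n); diag(Q) <- 1
    l <- dmt_loss(P, Q)
    expect_gte(l, 0)
    # oracle: double loop over ordered pairs
    lo <- 0
    for (i in 1:n) for (j in 1:n) if (i != j) lo <- lo + bern_kl(P[i, j], Q[i, j])
    expect_equal(l, lo, tolerance = 1e-10)
    # invariant to simultaneous permutation
    pr <- sample(n)
    expect_equal(dmt_loss(P[pr, pr], Q[pr, pr]), l, tolerance = 1e-10)
  }
  expect_error(dmt_loss(matrix(c(1, 0, 0, 1), 2), matrix(0.5, 2, 2)),
               "clamp")
})

test_that("weighted cross-entropy: direct substitution and beta = 1 identity", {
  expect_equal(weighted_cross_entropy(1, 0.5, beta = 1.6), 1.6 * log(2),
               tolerance = 1e-12)
  set.seed(12)
  y <- rbinom(40, 1, 0.5); p <- runif(40, 0.01, 0.99)
  expect_equal(weighted_cross_entropy(y, p, beta = 1),
               -sum(y * log(p) + (1 - y) * log(1 - p)), tolerance = 1e-12)
  # label-swap symmetry at beta = 1
  expect_equal(weighted_cross_entropy(y, p, beta = 1),
               weighted_cross_entropy(1 - y, 1 - p, beta = 1),
               tolerance = 1e-12)
  # clamped perfect predictions: loss -> 0 as eps -> 0
  eps <- 10^-(4:8)
  losses <- vapply(eps, function(e)
    weighted_cross_entropy(c(1, 0), c(1 - e, e), beta = 1.6), numeric(1))
  expect_true(all(diff(losses) < 0))
  expect_lt(losses[length(losses)], 1e-6)
  expect_error(weighted_cross_entropy(1, 1, beta = 1.6), "clamp")
})

test_that("total_loss composes its components", {
  set.seed(13)
  X <- matrix(rnorm(12), 4, 3)
  y <- c(1, 0, 1, 0)
  cfg0 <- net_config(input_dim = 3, hidden = c(4, 3), latent_dim = 2,
                     alpha1 = 0, alpha2 = 0, seed = 1)
  params <- thyropanel:::init_params(cfg0)
  l0 <- total_loss(X, y, params, cfg0)
  expect_equal(l0$total, l0$dmt)
  # all-zero weights -> L_r = 0
  pz <- params
  pz$W <- lapply(pz$W, function(w) w * 0)
  expect_equal(total_loss(X, y, pz, cfg0)$l2, 0)
  # component-wise oracle at the stated weights
  cfg <- net_config(input_dim = 3, hidden = c(4, 3), latent_dim = 2, seed = 1)
  l <- total_loss(X, y, params, cfg)
  P <- pairwise_similarities(X, cfg$nu_X, cfg$eps_clamp)
  V <- thyropanel:::net_forward(params, X)$V
  Q <- pairwise_similarities(V, cfg$nu_Z, cfg$eps_clamp)
  dmt_o <- 0
  for (i in 1:4) for (j in 1:4) if (i != j)
    dmt_o <- dmt_o + bern_kl(P[i, j], Q[i, j])
  probs <- thyropanel:::net_forward(params, X)$probs
  ce_o <- weighted_cross_entropy(y, probs[, 2], beta = cfg$beta)
  l2_o <- sum(unlist(lapply(params$W, function(w) w^2)))
  expect_equal(l$dmt, dmt_o, tolerance = 1e-10)
  expect_equal(l$ce, ce_o, tolerance = 1e-10)
  expect_equal(l$l2, l2_o, tolerance = 1e-12)
  expect_equal(l$total, dmt_o + cfg$alpha1 * ce_o + cfg$alpha2 * l2_o,
               tolerance = 1e-10)
})

test_that("analytic gradient matches central finite differences", {
  cfg <- net_config(input_dim = 4, hidden = c(6, 5), latent_dim = 3, seed = 2)
  for (s in c(31, 32, 33)) {
    set.seed(s)
    X <- matrix(rnorm(20), 5, 4)
    y <- rbinom(5, 1, 0.5)
    if (length(unique(y)) < 2) y <- c(1, 0, y[-(1:2)])
    params <- thyropanel:::init_params(cfg)
    gc <- gradient_check(X, y, params, cfg)
    expect_lt(gc$max_rel_err, 1e-4)
  }
})

test_that("training separates a planted signal and is reproducible", {
  d <- make_labelled_matrix(n_per_class = 60, p = 6, shifted = 1:6,
                            shift = 2.4, seed = 21)
  cfg <- net_config(input_dim = 6, hidden = c(16, 8), latent_dim = 4,
                    batch_size = 64, epochs = 25, cv_folds = 3, seed = 4)
  cl <- train_dmt(scale(d$X), d$y, cfg)
  expect_gte(max(cl$fold_auc), 0.95)
  expect_length(cl$fold_auc, 3)
  # bit-for-bit reproducibility under the same seed
  cl2 <- train_dmt(scale(d$X), d$y, cfg)
  expect_identical(cl$params, cl2$params)
  expect_identical(cl$fold_auc, cl2$fold_auc)
})

test_that("label-permuted training yields chance-level validation AUC", {
  d <- make_labelled_matrix(n_per_class = 60, p = 6, shifted = 1:6,
                            shift = 2.4, seed = 22)
  set.seed(23)
  yperm <- sample(d$y)
  cfg <- net_config(input_dim = 6, hidden = c(16, 8), latent_dim = 4,
                    batch_size = 64, epochs = 25, cv_folds = 3, seed = 5)
  cl <- train_dmt(scale(d$X), yperm, cfg)
  expect_gte(mean(cl$fold_auc), 0.35)
  expect_lte(mean(cl$fold_auc), 0.65)
})

test_that("prediction follows the malignant-tie class rule", {
  # force known probabilities through a degenerate head: all-zero weights
  cfg <- net_config(input_dim = 2, hidden = c(3, 3), latent_dim = 2, seed = 6)
  params <- thyropanel:::init_params(cfg)
  params$W <- lapply(params$W, function(w) w * 0)
  params$b <- lapply(params$b, function(b) b * 0)
  cl <- structure(list(params = params, config = cfg, panel = c("a", "b")),
                  class = "dmt_classifier")
  X <- matrix(rnorm(6), 3, 2, dimnames = list(NULL, c("a", "b")))
  pr <- predict(cl, X)
  # zero weights give the exact tie y0 = y1 = 0.5 -> malignant (P = 0)
  expect_equal(pr$y0_hat, rep(0.5, 3))
  expect_identical(pr$P_label, rep(0L, 3))
  expect_equal(pr$y0_hat + pr$y1_hat, rep(1, 3))
  # biased head: benign logit larger -> P = 1 and score > 0.5
  params$b[[length(params$b)]] <- c(0, 2)
  cl$params <- params
  pr2 <- predict(cl, X)
  expect_identical(pr2$P_label, rep(1L, 3))
  expect_true(all(pr2$score > 0.5))
  expect_equal(pr2$score, pr2$y1_hat)
})

test_that("latent embedding is deterministic with the configured dimension", {
  d <- make_labelled_matrix(n_per_class = 40, p = 5, shifted = 1:5,
                            shift = 2.5, seed = 24)
  cfg <- net_config(input_dim = 5, hidden = c(12, 8), latent_dim = 3,
                    batch_size = 64, epochs = 20, cv_folds = 2, seed = 7)
  cl <- train_dmt(scale(d$X), d$y, cfg)
  V1 <- latent_embedding(cl, scale(d$X))
  V2 <- latent_embedding(cl, scale(d$X))
  expect_identical(V1, V2)
  expect_identical(ncol(V1), 3L)
  # inter-class latent separation exceeds intra-class spread
  ben <- V1[d$y == "benign", , drop = FALSE]
  mal <- V1[d$y == "malignant", , drop = FALSE]
  inter <- sqrt(sum((colMeans(ben) - colMeans(mal))^2))
  intra <- mean(c(apply(ben, 2, sd), apply(mal, 2, sd)))
  expect_gt(inter, intra)
})

test_that("held-out AUC increases with planted effect size", {
  aucs <- vapply(c(0.5, 1, 2, 3), function(es) {
    mean(vapply(1:3, function(r) {
      d <- make_labelled_matrix(n_per_class = 50, p = 5, shifted = 1:5,
                                shift = es, seed = 500 + 10 * r + es * 100)
      cfg <- net_config(input_dim = 5, hidden = c(12, 8), latent_dim = 3,
                        batch_size = 64, epochs = 15, cv_folds = 3,
                        seed = 600 + r)
      mean(train_dmt(scale(d$X), d$y, cfg)$fold_auc)
    }, numeric(1)))
  }, numeric(1))
  # monotone recovery; strictness only before the AUC ceiling is reached
  expect_true(all(diff(aucs) >= 0))
  below_ceiling <- which(aucs[-length(aucs)] < 0.99)
  expect_true(all(diff(aucs)[below_ceiling] > 0))
  expect_gt(aucs[4], aucs[1])
})

test_that("classifier JSON round trip reproduces predictions", {
  d <- make_labelled_matrix(n_per_class = 30, p = 4, shifted = 1:4,
                            shift = 2.5, seed = 26)
  cfg <- net_config(input_dim = 4, hidden = c(8, 6), latent_dim = 3,
                    batch_size = 32, epochs = 10, cv_folds = 2, seed = 9)
  cl <- train_dmt(scale(d$X), d$y, cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_classifier_json(cl, path)
  cl2 <- read_classifier_json(path)
  expect_equal(predict(cl2, scale(d$X))$y0_hat, predict(cl, scale(d$X))$y0_hat,
               tolerance = 1e-12)
})
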