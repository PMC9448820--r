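#' @title Manifold-regularized neural classifier (DMT loss)
#' @description A two-part multilayer perceptron — a feature-extraction
#'   sub-model mapping each sample's panel vector to a latent feature vector,
#'   and a classification sub-model assigning benign/malignant probabilities —
#'   trained end-to-end with a composite loss
#'   `L = L_DMT + alpha1 * L_e + alpha2 * L_r`. `L_DMT` is a cross-layer
#'   two-way divergence: pairwise similarities are built in the input space
#'   (`P`) and the latent space (`Q`) from a Student-t kernel of Euclidean
#'   distances followed by a symmetrization map, and each off-diagonal pair
#'   contributes the KL divergence between the Bernoulli distributions with
#'   parameters `P_ij` and `Q_ij`, in both directions. `L_e` is a weighted
#'   cross-entropy with penalty `beta` on the benign class to handle class
#'   imbalance, and `L_r` is the squared L2 norm of the weights.
#' @name dmt_net
NULL

#' Network configuration
#'
#' Defaults are the stated training regime: `alpha1 = 1e3`, `alpha2 = 50`,
#' `beta = 1.6`, `nu_X = 100` (near-Gaussian kernel in input space),
#' `nu_Z = 1` (standard t kernel in latent space), learning rate `2e-2`,
#' batch size 256, 100 epochs, 5-fold cross-validated model selection.
#'
#' @param input_dim number of panel features.
#' @param hidden integer vector of hidden-layer widths of the
#'   feature-extraction sub-model.
#' @param latent_dim latent feature dimension.
#' @param alpha1,alpha2 non-negative loss weights on cross-entropy and L2.
#' @param beta class-imbalance penalty in `(0, 2)`; the benign term is
#'   weighted `beta`, the malignant term `2 - beta`.
#' @param nu_X,nu_Z t-kernel degrees of freedom for input / latent space.
#' @param learning_rate,batch_size,epochs optimizer settings (Adam).
#' @param eps_clamp probability floor applied to similarities and predicted
#'   probabilities, in `(0, 0.5)`; the two-way divergence and the log loss
#'   diverge at exact 0/1.
#' @param cv_folds folds for model selection by validation AUC.
#' @param seed integer seed.
#' @return object of class `net_config`.
#' @export
net_config <- function(input_dim, hidden = c(64, 32), latent_dim = 8,
                       alpha1 = 1e3, alpha2 = 50, beta = 1.6,
                       nu_X = 100, nu_Z = 1,
                       learning_rate = 2e-2, batch_size = 256, epochs = 100,
                       eps_clamp = 1e-6, cv_folds = 5, seed = 1L) {
  stopifnot(input_dim >= 1, latent_dim >= 1, all(hidden >= 1),
            alpha1 >= 0, alpha2 >= 0, beta > 0, beta < 2,
            nu_X > 0, nu_Z > 0, learning_rate > 0, batch_size >= 2,
            epochs >= 1, eps_clamp > 0, eps_clamp < 0.5, cv_folds >= 2)
  structure(list(input_dim = as.integer(input_dim),
                 hidden = as.integer(hidden),
                 latent_dim = as.integer(latent_dim),
                 alpha1 = alpha1, alpha2 = alpha2, beta = beta,
                 nu_X = nu_X, nu_Z = nu_Z,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 eps_clamp = eps_clamp,
                 cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed)),
            class = "net_config")
}

## ---- similarity kernel ----------------------------------------------------

# log of the t-density normalizing constant Gamma((nu+1)/2)/(sqrt(nu*pi)Gamma(nu/2))
t_kernel_const <- function(nu) {
  exp(lgamma((nu + 1) / 2) - lgamma(nu / 2) - 0.5 * log(nu * pi))
}

#' Student-t kernel of a distance matrix
#'
#' `A = c(nu) * (1 + D^2 / nu)^(-(nu + 1) / 2)` elementwise, with
#' `c(nu) = Gamma((nu+1)/2) / (sqrt(nu * pi) * Gamma(nu/2))` — the Student-t
#' density evaluated at each distance.
#'
#' @param D non-negative distance matrix (or vector).
#' @param nu degrees of freedom, `> 0`.
#' @return matrix of kernel values in `(0, c(nu)]`.
#' @export
t_kernel <- function(D, nu) {
  if (any(!is.finite(D))) stop("non-finite distances")
  if (any(D < 0)) stop("distances must be non-negative")
  stopifnot(nu > 0)
  t_kernel_const(nu) * (1 + D * D / nu)^(-(nu + 1) / 2)
}

#' Symmetrize a similarity matrix
#'
#' `S(A) = A + t(A) - 2 * A * t(A)` (elementwise product) — the fuzzy-set
#' union of the two directed similarities.
#'
#' @param A matrix with entries in `[0, 1]`.
#' @return symmetric matrix.
#' @export
symmetrize <- function(A) {
  if (any(A < 0 | A > 1)) stop("entries must lie in [0, 1]")
  A + t(A) - 2 * A * t(A)
}

# squared pairwise Euclidean distances, exact zero diagonal
pairwise_sqdist <- function(X) {
  rs <- rowSums(X * X)
  E <- outer(rs, rs, "+") - 2 * tcrossprod(X)
  E[E < 0] <- 0
  diag(E) <- 0
  E
}

# pre-symmetrization similarity 2*pi*kappa(D, nu)^2 from squared distances
t_similarity <- function(E, nu) {
  2 * pi * t_kernel_const(nu)^2 * (1 + E / nu)^(-(nu + 1))
}

#' Pairwise similarity matrix of a batch
#'
#' Euclidean distances between the row vectors are passed through the
#' Student-t kernel, squared and scaled by `2 * pi` (so that the similarity
#' of coincident points stays below 1 for every `nu`), symmetrized, and
#' clamped off-diagonal to `[eps_clamp, 1 - eps_clamp]`. The diagonal is set
#' to 1 and is excluded from all downstream sums.
#'
#' @param X numeric matrix, one row per sample (at least two rows).
#' @param nu t-kernel degrees of freedom.
#' @param eps_clamp off-diagonal clamp, see [net_config()].
#' @return symmetric similarity matrix.
#' @export
pairwise_similarities <- function(X, nu, eps_clamp = 1e-6) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 vectors")
  S <- symmetrize(t_similarity(pairwise_sqdist(X), nu))
  S <- pmin(pmax(S, eps_clamp), 1 - eps_clamp)
  diag(S) <- 1
  S
}

#' Cross-layer two-way divergence
#'
#' `sum_{i != j} P log(P / Q) + (1 - P) log((1 - P) / (1 - Q))` — the sum
#' over ordered off-diagonal pairs of the KL divergence between Bernoulli
#' distributions with success probabilities `P_ij` and `Q_ij` (natural log).
#' Non-negative, and zero iff `P = Q` off-diagonal.
#'
#' @param P,Q similarity matrices with off-diagonal entries in `(0, 1)`.
#' @return non-negative scalar.
#' @export
dmt_loss <- function(P, Q) {
  stopifnot(all(dim(P) == dim(Q)))
  off <- row(P) != col(P)
  p <- P[off]; q <- Q[off]
  if (any(p <= 0 | p >= 1 | q <= 0 | q >= 1))
    stop("off-diagonal entries must lie strictly in (0, 1); clamp first")
  sum(p * log(p / q) + (1 - p) * log((1 - p) / (1 - q)))
}

#' Class-weighted binary cross-entropy
#'
#' `-sum(beta * Y * log(yhat) + (2 - beta) * (1 - Y) * log(1 - yhat))`, where
#' `Y = 1` denotes benign and `yhat` is the predicted benign probability. At
#' `beta = 1` this is the standard (unweighted) binary cross-entropy.
#'
#' @param y 0/1 labels (1 = benign).
#' @param y_hat predicted benign probabilities, strictly in `(0, 1)`.
#' @param beta penalty in `(0, 2)`.
#' @return non-negative scalar.
#' @export
weighted_cross_entropy <- function(y, y_hat, beta = 1.6) {
  stopifnot(length(y) == length(y_hat), all(y %in% c(0, 1)))
  if (any(y_hat <= 0 | y_hat >= 1))
    stop("predicted probabilities at 0 or 1; clamp before the log loss")
  -sum(beta * y * log(y_hat) + (2 - beta) * (1 - y) * log(1 - y_hat))
}

## ---- parameters, forward, loss, backward ----------------------------------

# parameter list: extractor (W,b) per layer (ReLU hidden, linear latent),
# then a linear 2-class softmax head
init_params <- function(config) {
  dims <- c(config$input_dim, config$hidden, config$latent_dim)
  params <- list(W = list(), b = list())
  for (l in seq_len(length(dims) - 1)) {
    fan_in <- dims[l]
    params$W[[l]] <- matrix(stats::rnorm(fan_in * dims[l + 1],
                                         sd = sqrt(2 / fan_in)),
                            fan_in, dims[l + 1])
    params$b[[l]] <- numeric(dims[l + 1])
  }
  hd <- length(dims)  # head index = last + 1
  params$W[[hd]] <- matrix(stats::rnorm(config$latent_dim * 2,
                                        sd = sqrt(1 / config$latent_dim)),
                           config$latent_dim, 2)
  params$b[[hd]] <- numeric(2)
  params
}

# forward pass; returns activations needed for backprop
net_forward <- function(params, X) {
  nl <- length(params$W)          # last is the head
  A <- list(X)
  Z <- vector("list", nl)
  for (l in seq_len(nl - 2)) {    # ReLU hidden layers
    Z[[l]] <- sweep(A[[l]] %*% params$W[[l]], 2, params$b[[l]], "+")
    A[[l + 1]] <- pmax(Z[[l]], 0)
  }
  lv <- nl - 1                    # linear latent layer
  V <- sweep(A[[lv]] %*% params$W[[lv]], 2, params$b[[lv]], "+")
  logits <- sweep(V %*% params$W[[nl]], 2, params$b[[nl]], "+")
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  probs <- e / rowSums(e)         # col 1 = malignant y0, col 2 = benign y1
  list(A = A, Z = Z, V = V, logits = logits, probs = probs)
}

# clamp helper returning values and an in-range mask (for gradient masking)
clamp01 <- function(x, eps) {
  ok <- x > eps & x < 1 - eps
  list(v = pmin(pmax(x, eps), 1 - eps), ok = ok)
}

#' Total training loss of the DMT network
#'
#' `L = L_DMT + alpha1 * L_e + alpha2 * L_r` on one batch: the two-way
#' divergence between input-space similarities `P` and latent-space
#' similarities `Q`, the weighted cross-entropy of the softmax head, and the
#' squared L2 norm of all weight matrices (biases excluded).
#'
#' @param X normalized batch matrix (rows = samples).
#' @param y 0/1 labels, 1 = benign.
#' @param params network parameter list (see [train_dmt()] internals).
#' @param config a [net_config()].
#' @return list with `total`, `dmt`, `ce`, `l2` components.
#' @export
total_loss <- function(X, y, params, config) {
  fw <- net_forward(params, X)
  P <- pairwise_similarities(X, config$nu_X, config$eps_clamp)
  Q <- pairwise_similarities(fw$V, config$nu_Z, config$eps_clamp)
  l_dmt <- dmt_loss(P, Q)
  y1 <- clamp01(fw$probs[, 2], config$eps_clamp)$v
  y0 <- clamp01(fw$probs[, 1], config$eps_clamp)$v
  l_ce <- -sum(config$beta * y * log(y1) +
                 (2 - config$beta) * (1 - y) * log(y0))
  l_l2 <- sum(vapply(params$W, function(w) sum(w * w), numeric(1)))
  list(total = l_dmt + config$alpha1 * l_ce + config$alpha2 * l_l2,
       dmt = l_dmt, ce = l_ce, l2 = l_l2)
}

# analytic gradient of total_loss wrt every parameter
net_gradient <- function(X, y, params, config) {
  nl <- length(params$W)
  fw <- net_forward(params, X)
  N <- nrow(X)
  eps <- config$eps_clamp

  # --- dL_DMT / dV ---
  P <- pairwise_similarities(X, config$nu_X, eps)
  E <- pairwise_sqdist(fw$V)
  B <- t_similarity(E, config$nu_Z)       # pre-symmetrization, symmetric
  S <- symmetrize(B)
  cq <- clamp01(S, eps)
  Q <- cq$v; diag(Q) <- 1
  G <- matrix(0, N, N)                    # dL/dQ, off-diagonal, clamp-masked
  off <- row(G) != col(G)
  act <- off & cq$ok
  G[act] <- -P[act] / Q[act] + (1 - P[act]) / (1 - Q[act])
  # S_ij = B_ij + B_ji - 2 B_ij B_ji  =>  dL/dB = G*(1-2B') + G'*(1-2B)
  dB <- G * (1 - 2 * t(B)) + t(G) * (1 - 2 * B)
  # dB/dE = -2*pi*c^2*(nu+1)/nu * (1+E/nu)^(-(nu+2))
  nu <- config$nu_Z
  dE <- dB * (-2 * pi * t_kernel_const(nu)^2 * (nu + 1) / nu *
                (1 + E / nu)^(-(nu + 2)))
  diag(dE) <- 0
  U <- dE + t(dE)
  gV_dmt <- 2 * (rowSums(U) * fw$V - U %*% fw$V)

  # --- alpha1 * dL_e / dlogits ---
  p0 <- clamp01(fw$probs[, 1], eps)
  p1 <- clamp01(fw$probs[, 2], eps)
  dP <- cbind(ifelse(p0$ok, -(2 - config$beta) * (1 - y) / p0$v, 0),
              ifelse(p1$ok, -config$beta * y / p1$v, 0)) * config$alpha1
  pr <- fw$probs
  dlogits <- pr * (dP - rowSums(dP * pr))

  # --- backward ---
  gW <- vector("list", nl); gb <- vector("list", nl)
  gW[[nl]] <- crossprod(fw$V, dlogits) + 2 * config$alpha2 * params$W[[nl]]
  gb[[nl]] <- colSums(dlogits)
  dV <- gV_dmt + dlogits %*% t(params$W[[nl]])
  lv <- nl - 1
  gW[[lv]] <- crossprod(fw$A[[lv]], dV) + 2 * config$alpha2 * params$W[[lv]]
  gb[[lv]] <- colSums(dV)
  dA <- dV %*% t(params$W[[lv]])
  for (l in rev(seq_len(nl - 2))) {
    dZ <- dA * (fw$Z[[l]] > 0)
    gW[[l]] <- crossprod(fw$A[[l]], dZ) + 2 * config$alpha2 * params$W[[l]]
    gb[[l]] <- colSums(dZ)
    dA <- dZ %*% t(params$W[[l]])
  }
  list(W = gW, b = gb)
}

# flatten / unflatten for the finite-difference oracle and Adam state
flatten_params <- function(params)
  c(unlist(lapply(params$W, as.vector)), unlist(params$b))

unflatten_params <- function(theta, template) {
  out <- template
  pos <- 1L
  for (l in seq_along(template$W)) {
    n <- length(template$W[[l]])
    out$W[[l]] <- matrix(theta[pos:(pos + n - 1)], nrow(template$W[[l]]))
    pos <- pos + n
  }
  for (l in seq_along(template$b)) {
    n <- length(template$b[[l]])
    out$b[[l]] <- theta[pos:(pos + n - 1)]
    pos <- pos + n
  }
  out
}

## ---- training -------------------------------------------------------------

as_benign01 <- function(y) {
  if (is.numeric(y)) {
    stopifnot(all(y %in% c(0, 1)))
    return(as.numeric(y))
  }
  y <- as.character(y)
  stopifnot(all(y %in% c("benign", "malignant")))
  as.numeric(y == "benign")
}

# stratified fold assignment (1..k per sample)
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# one SGD/Adam fit on (X, y); returns the parameter list
fit_dmt_once <- function(X, y, config) {
  params <- init_params(config)
  theta <- flatten_params(params)
  m <- v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  step <- 0L
  n <- nrow(X)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = config$batch_size)
    batches <- lapply(starts, function(s)
      ord[s:min(s + config$batch_size - 1, n)])
    nb <- length(batches)
    if (nb > 1 && length(batches[[nb]]) < 2) {
      batches[[nb - 1]] <- c(batches[[nb - 1]], batches[[nb]])
      batches <- batches[-nb]
    }
    for (idx in batches) {
      g <- net_gradient(X[idx, , drop = FALSE], y[idx], params, config)
      gth <- flatten_params(g)
      if (any(!is.finite(gth)))
        stop("divergent loss: non-finite gradient during training")
      step <- step + 1L
      m <- b1 * m + (1 - b1) * gth
      v <- b2 * v + (1 - b2) * gth * gth
      mh <- m / (1 - b1^step)
      vh <- v / (1 - b2^step)
      theta <- theta - config$learning_rate * mh / (sqrt(vh) + adam_eps)
      params <- unflatten_params(theta, params)
    }
  }
  params
}

#' Train the DMT classifier with cross-validated model selection
#'
#' Runs stratified `cv_folds`-fold cross-validation: for each fold a network
#' is trained on the remaining folds for `epochs` epochs (Adam, the
#' configured learning rate and batch size; input-space similarities `P` are
#' recomputed per minibatch from the inputs, latent similarities `Q` from
#' the current latent vectors) and scored by AUC on the held-out fold, using
#' the malignant probability as the ranking score. The fold model with the
#' highest validation AUC is returned together with all fold AUCs.
#'
#' @param X normalized panel matrix (no missing values), samples in rows.
#' @param y labels: `"benign"`/`"malignant"`, or 0/1 with 1 = benign.
#' @param config a [net_config()]; `input_dim` must equal `ncol(X)`.
#' @param normalizer optional [fit_normalizer()] model stored for provenance.
#' @return object of class `dmt_classifier` with fields `params`, `config`,
#'   `panel`, `fold_auc`, `best_fold`, `normalizer`.
#' @export
train_dmt <- function(X, y, config, normalizer = NULL) {
  stopifnot(inherits(config, "net_config"))
  X <- as_plain_matrix(unclass(X))
  if (anyNA(X)) stop("training matrix contains missing values; normalize first")
  if (ncol(X) != config$input_dim)
    stop("config$input_dim does not match ncol(X)")
  y <- as_benign01(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  with_seed(config$seed, {
    fold <- stratified_folds(y, config$cv_folds)
    fits <- vector("list", config$cv_folds)
    aucs <- numeric(config$cv_folds)
    for (k in seq_len(config$cv_folds)) {
      tr <- fold != k
      if (length(unique(y[!tr])) < 2 || length(unique(y[tr])) < 2)
        stop("a fold lost one of the classes; reduce cv_folds")
      fits[[k]] <- fit_dmt_once(X[tr, , drop = FALSE], y[tr], config)
      fw <- net_forward(fits[[k]], X[!tr, , drop = FALSE])
      # malignancy score = y0_hat; positive class = malignant (y == 0)
      aucs[k] <- roc_auc(fw$probs[, 1], 1 - y[!tr])$auc
    }
    best <- which.max(aucs)
    structure(list(params = fits[[best]], config = config,
                   panel = colnames(X), fold_auc = aucs,
                   best_fold = best, normalizer = normalizer),
              class = "dmt_classifier")
  })
}

#' @export
print.dmt_classifier <- function(x, ...) {
  cat(sprintf("dmt_classifier: %d-protein panel, latent dim %d\n",
              length(x$panel), x$config$latent_dim))
  cat(sprintf("fold validation AUCs: %s (best fold %d)\n",
              paste(sprintf("%.3f", x$fold_auc), collapse = ", "),
              x$best_fold))
  invisible(x)
}

# align newdata columns with the classifier's panel
align_panel <- function(object, newdata) {
  newdata <- as_plain_matrix(unclass(newdata))
  if (!is.null(object$panel)) {
    if (!all(object$panel %in% colnames(newdata)))
      stop("input lacks panel feature(s): ",
           paste(setdiff(object$panel, colnames(newdata)), collapse = ", "))
    newdata <- newdata[, object$panel, drop = FALSE]
  }
  if (anyNA(newdata)) stop("input contains missing values; normalize first")
  newdata
}

#' Predict class probabilities and labels
#'
#' Returns the malignant probability `y0_hat`, the benign probability
#' `y1_hat`, `score = y1_hat` (a score above 0.5 reads benign), and the
#' class prediction `P_label`: 1 (benign) when `y0_hat < y1_hat`, else 0
#' (malignant) — ties go to malignant, the clinically conservative side.
#'
#' @param object a `dmt_classifier`.
#' @param newdata normalized matrix restricted (or restrictable) to the panel.
#' @param ... unused.
#' @return data frame with `sample_id`, `y0_hat`, `y1_hat`, `score`,
#'   `P_label`.
#' @export
predict.dmt_classifier <- function(object, newdata, ...) {
  newdata <- align_panel(object, newdata)
  fw <- net_forward(object$params, newdata)
  y0 <- fw$probs[, 1]; y1 <- fw$probs[, 2]
  data.frame(sample_id = rownames(newdata) %||% seq_len(nrow(newdata)),
             y0_hat = y0, y1_hat = y1, score = y1,
             P_label = ifelse(y0 < y1, 1L, 0L),
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Latent feature vectors of samples
#'
#' Deterministic coordinates from the feature-extraction sub-model, one row
#' per sample, `latent_dim` columns.
#'
#' @param object a `dmt_classifier`.
#' @param newdata normalized matrix restricted to the panel.
#' @return numeric matrix of latent vectors.
#' @export
latent_embedding <- function(object, newdata) {
  newdata <- align_panel(object, newdata)
  V <- net_forward(object$params, newdata)$V
  rownames(V) <- rownames(newdata)
  V
}

#' Finite-difference check of the analytic gradient
#'
#' Compares the analytic gradient of [total_loss()] against central finite
#' differences at the current parameters. Returns the maximum relative error
#' over all parameters (relative to the gradient's infinity norm).
#'
#' @param X,y,params,config as in [total_loss()].
#' @param h finite-difference step.
#' @return list with `max_rel_err`, `analytic`, `numeric` vectors.
#' @export
gradient_check <- function(X, y, params, config, h = 1e-5) {
  ana <- flatten_params(net_gradient(X, y, params, config))
  theta <- flatten_params(params)
  num <- vapply(seq_along(theta), function(i) {
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    (total_loss(X, y, unflatten_params(tp, params), config)$total -
       total_loss(X, y, unflatten_params(tm, params), config)$total) / (2 * h)
  }, numeric(1))
  scale <- max(abs(ana), abs(num), 1e-8)
  list(max_rel_err = max(abs(ana - num)) / scale, analytic = ana,
       numeric = num)
}

#' Serialize / load a trained classifier as JSON
#'
#' JSON header (panel, config, fold AUCs) plus the flattened weight vector.
#'
#' @param object a `dmt_classifier`.
#' @param path file path.
#' @export
write_classifier_json <- function(object, path) {
  jsonlite::write_json(
    list(panel = object$panel,
         config = unclass(object$config),
         fold_auc = object$fold_auc,
         best_fold = object$best_fold,
         theta = flatten_params(object$params)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_classifier_json
#' @export
read_classifier_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(net_config, j$config[setdiff(names(j$config), NULL)])
  template <- with_seed(1L, init_params(cfg))
  structure(list(params = unflatten_params(j$theta, template),
                 config = cfg, panel = j$panel, fold_auc = j$fold_auc,
                 best_fold = j$best_fold, normalizer = NULL),
            class = "dmt_classifier")
}
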