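#' @title Feature screening and genetic-algorithm panel selection
#' @description The two-step feature selection ladder: (1) an initial screen
#'   keeping proteins that are differentially expressed between benign and
#'   malignant samples (union an externally curated whitelist) and have a
#'   missing rate below a cutoff; (2) a genetic algorithm over fixed-size
#'   protein combinations, with fitness `F^C = mean of 3-fold cross-validated
#'   accuracies` of a compact neural classifier on dataset A, and final
#'   ranking of the top candidates by accuracy on the held-out dataset B.
#' @name panel_select
NULL

#' Screening configuration
#'
#' @param fc_threshold linear fold-change threshold of the differential
#'   screen (default 2; the panel-discovery DEP threshold of 4 is stricter
#'   than needed at this stage).
#' @param alpha adjusted-p threshold of the screen (default 0.05).
#' @param whitelist protein ids always admitted to the screen result (stands
#'   in for literature/TCGA/OMIM curation), still subject to the
#'   missing-rate filter.
#' @param missing_rate_cutoff features must have missing rate strictly below
#'   this fraction (default 0.35).
#' @return object of class `screen_config`.
#' @export
screen_config <- function(fc_threshold = 2, alpha = 0.05,
                          whitelist = character(0),
                          missing_rate_cutoff = 0.35) {
  stopifnot(fc_threshold >= 1, alpha > 0, alpha <= 1,
            missing_rate_cutoff > 0, missing_rate_cutoff <= 1)
  structure(list(fc_threshold = fc_threshold, alpha = alpha,
                 whitelist = as.character(whitelist),
                 missing_rate_cutoff = missing_rate_cutoff),
            class = "screen_config")
}

#' Screen features for the genetic algorithm
#'
#' Returns the union of (proteins differentially expressed between benign
#' and malignant at the screen thresholds, tested on observed values) and
#' the whitelist, filtered to proteins with missing rate below the cutoff,
#' sorted by id.
#'
#' @param matrix abundance matrix (log2, `NA` = missing).
#' @param labels benign/malignant labels aligned with rows.
#' @param config a [screen_config()].
#' @return character vector of protein ids.
#' @export
screen_features <- function(matrix, labels, config = screen_config()) {
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(matrix),
            all(labels %in% c("benign", "malignant")))
  if (length(unique(labels)) < 2) stop("both classes must be present")
  dep <- pairwise_dep(matrix,
                      which(labels == "malignant"),
                      which(labels == "benign"),
                      fc_threshold = config$fc_threshold,
                      alpha = config$alpha)
  ids <- union(dep$protein, intersect(config$whitelist, colnames(matrix)))
  mr <- missing_rate(matrix)[ids]
  ids <- ids[mr < config$missing_rate_cutoff]
  if (!length(ids))
    stop("screen returned no features; relax fc_threshold/alpha or the ",
         "missing-rate cutoff")
  sort(ids)
}

## ---- compact fitness classifier (plain cross-entropy MLP) -----------------

# small two-hidden-layer perceptron with sigmoid output, full-batch Adam;
# deliberately lighter than the DMT network: it is called thousands of times
# inside the genetic algorithm, so bias addition and the optimizer state are
# kept allocation-lean
mlp_fit <- function(X, y, hidden = c(16, 8), epochs = 150, lr = 0.05) {
  dims <- c(ncol(X), hidden, 1)
  nl <- length(dims) - 1
  n <- nrow(X)
  W <- lapply(seq_len(nl), function(l)
    matrix(stats::rnorm(dims[l] * dims[l + 1], sd = sqrt(2 / dims[l])),
           dims[l], dims[l + 1]))
  b <- lapply(dims[-1], numeric)
  mW <- vW <- lapply(W, function(w) w * 0)
  mb <- vb <- lapply(b, function(x) x * 0)
  beta1 <- 0.9; beta2 <- 0.999; aeps <- 1e-8
  A <- vector("list", nl); Z <- vector("list", nl - 1)
  for (it in seq_len(epochs)) {
    A[[1]] <- X
    for (l in seq_len(nl - 1)) {
      Z[[l]] <- A[[l]] %*% W[[l]] + rep(b[[l]], each = n)
      A[[l + 1]] <- Z[[l]] * (Z[[l]] > 0)
    }
    z_out <- drop(A[[nl]] %*% W[[nl]]) + b[[nl]]
    p <- 1 / (1 + exp(-z_out))
    dZl <- matrix(p - y, ncol = 1) / n
    c1 <- 1 / (1 - beta1^it); c2 <- 1 / (1 - beta2^it)
    for (l in nl:1) {
      gW <- crossprod(A[[l]], dZl)
      gb <- colSums(dZl)
      if (l > 1) {
        dA <- dZl %*% t(W[[l]])
        dZl <- dA * (Z[[l - 1]] > 0)
      }
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW * gW
      W[[l]] <- W[[l]] - lr * (mW[[l]] * c1) / (sqrt(vW[[l]] * c2) + aeps)
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb * gb
      b[[l]] <- b[[l]] - lr * (mb[[l]] * c1) / (sqrt(vb[[l]] * c2) + aeps)
    }
  }
  list(W = W, b = b)
}

mlp_predict <- function(fit, X) {
  nl <- length(fit$W)
  A <- X
  for (l in seq_len(nl - 1)) {
    Z <- A %*% fit$W[[l]] + rep(fit$b[[l]], each = nrow(X))
    A <- Z * (Z > 0)
  }
  drop(1 / (1 + exp(-(A %*% fit$W[[nl]] + fit$b[[nl]]))))
}

#' Cross-validated fitness of a candidate panel
#'
#' `F^C = (1/k) * sum(A_k^C)`: the mean held-out accuracy of a compact
#' neural classifier over a stratified k-fold split of dataset A, trained on
#' the candidate's columns only.
#'
#' @param features candidate protein ids (all present in `X`).
#' @param X normalized dataset-A matrix.
#' @param y benign/malignant labels (or 0/1 with 1 = benign).
#' @param folds number of folds (default 3).
#' @param seed seed controlling fold assignment and classifier init.
#' @param epochs,hidden fitness-classifier budget.
#' @return object of class `panel_candidate`: list with `C` (ids), `F`
#'   (fitness), `A_k` (per-fold accuracies).
#' @export
evaluate_fitness <- function(features, X, y, folds = 3, seed = 1L,
                             epochs = 150, hidden = c(16, 8)) {
  X <- as_plain_matrix(unclass(X))
  missing <- setdiff(features, colnames(X))
  if (length(missing))
    stop("candidate feature(s) absent from dataset A: ",
         paste(missing, collapse = ", "))
  y <- as_benign01(y)
  Xc <- X[, features, drop = FALSE]
  with_seed(seed, {
    fold <- stratified_folds(y, folds)
    acc <- vapply(seq_len(folds), function(k) {
      tr <- fold != k
      if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2)
        stop("a fold lost one of the classes")
      fit <- mlp_fit(Xc[tr, , drop = FALSE], y[tr], hidden, epochs)
      mean((mlp_predict(fit, Xc[!tr, , drop = FALSE]) > 0.5) == y[!tr])
    }, numeric(1))
    structure(list(C = features, F = mean(acc), A_k = acc),
              class = "panel_candidate")
  })
}

#' Genetic-algorithm configuration
#'
#' @param panel_size K, the fixed combination size (default 19).
#' @param population_size,generations,crossover_rate,mutation_rate,elitism_count
#'   evolutionary budget and operator rates.
#' @param cv_folds folds of the fitness evaluation (default 3).
#' @param top_candidates how many distinct best-fitness candidates from the
#'   final population are ranked on dataset B.
#' @param fitness_epochs,fitness_hidden budget of the compact fitness
#'   classifier.
#' @param seed integer seed.
#' @return object of class `ga_config`.
#' @export
ga_config <- function(panel_size = 19, population_size = 60,
                      generations = 40, crossover_rate = 0.7,
                      mutation_rate = 0.2, elitism_count = 2,
                      cv_folds = 3, top_candidates = 10,
                      fitness_epochs = 150, fitness_hidden = c(16, 8),
                      seed = 1L) {
  stopifnot(panel_size >= 1, population_size >= 2,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            elitism_count >= 0, elitism_count < population_size,
            generations >= 1, cv_folds >= 2, top_candidates >= 1)
  structure(list(panel_size = as.integer(panel_size),
                 population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 elitism_count = as.integer(elitism_count),
                 cv_folds = as.integer(cv_folds),
                 top_candidates = as.integer(top_candidates),
                 fitness_epochs = as.integer(fitness_epochs),
                 fitness_hidden = as.integer(fitness_hidden),
                 seed = as.integer(seed)),
            class = "ga_config")
}

# uniform set recombination: keep the intersection, fill to size K from the
# symmetric difference
ga_crossover <- function(a, b, k) {
  common <- intersect(a, b)
  pool <- setdiff(union(a, b), common)
  need <- k - length(common)
  sort(c(common, if (need > 0) sample(pool, need)))
}

# replace one random member with a random non-member
ga_mutate <- function(ind, universe) {
  out <- setdiff(ind, sample(ind, 1))
  sort(c(out, sample(setdiff(universe, ind), 1)))
}

#' Genetic-algorithm panel selection
#'
#' Evolves a population of fixed-size protein combinations. Fitness (mean
#' 3-fold cross-validated accuracy, [evaluate_fitness()]) is computed on
#' dataset A only; dataset B is touched exactly once per finalist, to rank
#' the distinct top-fitness candidates of the final population, and the
#' panel with the best dataset-B accuracy is reported. Selection is by
#' tournament (size 3) with elitism; crossover is uniform set-recombination
#' with duplicate repair; mutation swaps one member for a non-member. Every
#' individual carries exactly K distinct features at every generation, so a
#' hard panel-size cap holds by construction. Fitness values are cached, and
#' all fitness evaluations share one fold split (derived from the seed), so
#' the best-fitness trajectory is monotone non-decreasing whenever
#' `elitism_count >= 1`.
#'
#' @param a_matrix,a_labels normalized dataset A and its labels (fitness).
#' @param b_matrix,b_labels normalized dataset B and its labels (final
#'   ranking only).
#' @param screened_features candidate pool from [screen_features()].
#' @param config a [ga_config()].
#' @return object of class `panel_selection`: `best` (a `panel_candidate`),
#'   `b_accuracy`, `trajectory` (per-generation best fitness),
#'   `finalists` (data frame of B evaluations), `n_fitness_evaluations`.
#' @export
ga_select <- function(a_matrix, a_labels, b_matrix, b_labels,
                      screened_features, config = ga_config()) {
  stopifnot(inherits(config, "ga_config"))
  k <- config$panel_size
  universe <- sort(unique(as.character(screened_features)))
  if (length(universe) < k)
    stop("fewer screened features than panel_size")
  fit_seed <- config$seed + 10000L
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  fitness_of <- function(ind) {
    key <- paste(ind, collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    n_eval <<- n_eval + 1L
    cand <- evaluate_fitness(ind, a_matrix, a_labels,
                             folds = config$cv_folds, seed = fit_seed,
                             epochs = config$fitness_epochs,
                             hidden = config$fitness_hidden)
    cache[[key]] <- cand
    cand
  }
  b_rank <- function(cands) {
    y_b <- as_benign01(b_labels)
    Xb <- as_plain_matrix(unclass(b_matrix))
    Xa <- as_plain_matrix(unclass(a_matrix))
    y_a <- as_benign01(a_labels)
    vapply(cands, function(cand) {
      with_seed(fit_seed, {
        fit <- mlp_fit(Xa[, cand$C, drop = FALSE], y_a,
                       config$fitness_hidden, config$fitness_epochs)
        mean((mlp_predict(fit, Xb[, cand$C, drop = FALSE]) > 0.5) == y_b)
      })
    }, numeric(1))
  }

  if (k == length(universe)) {
    # no search needed: the panel is the full screened set
    best <- fitness_of(universe)
    bacc <- b_rank(list(best))
    return(structure(list(best = best, b_accuracy = bacc,
                          trajectory = best$F,
                          finalists = data.frame(
                            panel = paste(universe, collapse = "|"),
                            fitness = best$F, b_accuracy = bacc),
                          n_fitness_evaluations = n_eval, config = config),
                     class = "panel_selection"))
  }

  with_seed(config$seed, {
    pop <- replicate(config$population_size,
                     sort(sample(universe, k)), simplify = FALSE)
    trajectory <- numeric(config$generations)
    for (gen in seq_len(config$generations)) {
      cands <- lapply(pop, fitness_of)
      fits <- vapply(cands, `[[`, numeric(1), "F")
      trajectory[gen] <- max(fits)
      if (gen == config$generations) break
      if (length(unique(vapply(pop, paste, "", collapse = "|"))) == 1 &&
          config$mutation_rate == 0) {
        warning("population degenerate with mutation_rate 0; stopping early")
        trajectory <- trajectory[seq_len(gen)]
        break
      }
      ord <- order(fits, decreasing = TRUE)
      new_pop <- pop[ord[seq_len(config$elitism_count)]]
      tournament <- function() {
        ids <- sample.int(length(pop), 3)
        pop[[ids[which.max(fits[ids])]]]
      }
      while (length(new_pop) < config$population_size) {
        p1 <- tournament()
        child <- if (stats::runif(1) < config$crossover_rate)
          ga_crossover(p1, tournament(), k) else p1
        if (stats::runif(1) < config$mutation_rate)
          child <- ga_mutate(child, universe)
        new_pop[[length(new_pop) + 1]] <- child
      }
      pop <- new_pop
    }
    # distinct top-fitness candidates of the final population -> dataset B
    cands <- lapply(pop, fitness_of)
    fits <- vapply(cands, `[[`, numeric(1), "F")
    keys <- vapply(pop, paste, "", collapse = "|")
    ord <- order(fits, decreasing = TRUE)
    ord <- ord[!duplicated(keys[ord])]
    finalists <- cands[ord[seq_len(min(config$top_candidates, length(ord)))]]
    bacc <- b_rank(finalists)
    pick <- which.max(bacc)  # tie -> earlier, i.e. higher fitness
    structure(list(best = finalists[[pick]], b_accuracy = bacc[pick],
                   trajectory = trajectory,
                   finalists = data.frame(
                     panel = vapply(finalists, function(cd)
                       paste(cd$C, collapse = "|"), ""),
                     fitness = vapply(finalists, `[[`, numeric(1), "F"),
                     b_accuracy = bacc),
                   n_fitness_evaluations = n_eval, config = config),
              class = "panel_selection")
  })
}

#' @export
print.panel_selection <- function(x, ...) {
  cat(sprintf("panel_selection: K = %d, fitness F = %.3f, dataset-B accuracy = %.3f\n",
              length(x$best$C), x$best$F, x$b_accuracy))
  cat("panel:", paste(x$best$C, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.panel_candidate <- function(x, ...) {
  cat(sprintf("panel_candidate: |C| = %d, F = %.3f (folds: %s)\n",
              length(x$C), x$F, paste(sprintf("%.3f", x$A_k), collapse = ", ")))
  invisible(x)
}
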