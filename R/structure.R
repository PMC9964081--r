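#' Admixture-style ancestry estimation
#'
#' Estimates individual ancestry proportions for `K` ancestral clusters
#' from the genotype matrix, in the spirit of sNMF/ADMIXTURE: each
#' sample's per-locus genotype distribution is modelled as a convex
#' mixture `P(g_il = j) = sum_k Q[i,k] * G[k,j,l]` of cluster-specific
#' genotype-state frequencies. The fit maximizes the masked (missing
#' calls ignored) log-likelihood with a symmetric Dirichlet(1 + alpha)
#' prior on the rows of `Q` by expectation-maximization, so the
#' penalized loss is non-increasing across iterations, `Q` rows live on
#' the simplex by construction, and the per-cluster genotype factors
#' are proper frequencies. Clusters are relabelled by the first sample
#' index attaining maximum membership, for stable plotting.
#'
#' @param gm A [genotype_matrix()].
#' @param K Number of ancestral clusters (1 <= K <= n_samples).
#' @param seed RNG seed for the random initialization.
#' @param alpha Regularization (Dirichlet pseudocount) on `Q` rows,
#'   >= 0; the default 10 mildly shrinks memberships toward uniform and
#'   keeps them strictly positive.
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Relative change in penalized loss declaring convergence
#'   (default 1e-6).
#' @return A list of class `ancestry_result`: `Q` (n x K, rows sum to
#'   1), `G_freq` (K x 3 x loci array of genotype-state frequencies),
#'   `K`, `cross_entropy` (final masked training cross-entropy,
#'   nats/call), `loss_trace` (penalized loss per iteration), `n_iter`,
#'   `converged`, `seed`.
#' @export
estimate_ancestry <- function(gm, K, seed, alpha = 10, max_iter = 500,
                              tol = 1e-6) {
  stopifnot(inherits(gm, "genotype_matrix"), K >= 1, alpha >= 0)
  if (K > n_samples(gm)) stop("K exceeds the number of samples")
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  set.seed(seed)

  X <- gm$calls
  n <- nrow(X); m <- ncol(X)
  obs <- !is.na(X)
  n_obs_i <- rowSums(obs)
  if (any(n_obs_i == 0L)) stop("sample(s) with no called locus")
  idx_state <- as.vector(X) + 1L            # 1..3, NA where missing
  idx_state[is.na(idx_state)] <- 1L         # placeholder, masked later
  idx_locus <- rep(seq_len(m), each = n)
  flat <- cbind(idx_state, idx_locus)

  # init: Q rows ~ normalized uniforms; G from pooled state frequencies
  # perturbed per cluster
  Q <- matrix(stats::runif(n * K, 0.1, 1), n, K)
  Q <- Q / rowSums(Q)
  pool <- vapply(seq_len(m), function(l) {
    tab <- tabulate(X[, l] + 1L, nbins = 3L)
    (tab + 0.5) / sum(tab + 0.5)
  }, numeric(3))                            # 3 x m
  G <- array(NA_real_, c(K, 3L, m))
  for (k in seq_len(K)) {
    gk <- pool * matrix(stats::runif(3L * m, 0.5, 1.5), 3L, m)
    G[k, , ] <- sweep(gk, 2L, colSums(gk), "/")
  }

  P <- vector("list", K)                    # P[[k]][i, l] = G[k, x_il, l]
  loss_trace <- numeric(0)
  prev <- Inf
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    D <- matrix(0, n, m)
    for (k in seq_len(K)) {
      Pk <- matrix(G[k, , ][flat], n, m)
      Pk[!obs] <- 0
      P[[k]] <- Pk
      D <- D + Q[, k] * Pk
    }
    ll <- sum(log(pmax(D[obs], 1e-300)))
    pen <- if (alpha > 0) alpha * sum(log(pmax(Q, 1e-300))) else 0
    loss <- -(ll + pen)
    loss_trace <- c(loss_trace, loss)

    Dsafe <- pmax(D, 1e-300)
    Qnew <- matrix(0, n, K)
    Gnew <- array(0, c(K, 3L, m))
    for (k in seq_len(K)) {
      W <- Q[, k] * P[[k]] / Dsafe          # responsibilities x mask
      W[!obs] <- 0
      Qnew[, k] <- (rowSums(W) + alpha) / (n_obs_i + K * alpha)
      for (j in 1:3) {
        Gnew[k, j, ] <- colSums(W * (obs & X == (j - 1L)))
      }
      tot <- Gnew[k, 1L, ] + Gnew[k, 2L, ] + Gnew[k, 3L, ]
      for (j in 1:3) Gnew[k, j, ] <- Gnew[k, j, ] / pmax(tot, 1e-300)
    }
    Q <- Qnew; G <- Gnew
    if (is.finite(prev) && abs(prev - loss) <= tol * abs(prev)) {
      converged <- TRUE
      break
    }
    prev <- loss
  }

  # final loss and cross-entropy under the converged parameters
  D <- matrix(0, n, m)
  for (k in seq_len(K)) {
    Pk <- matrix(G[k, , ][flat], n, m)
    Pk[!obs] <- 0
    D <- D + Q[, k] * Pk
  }
  ce <- -mean(log(pmax(D[obs], 1e-300)))

  # relabel clusters by first sample attaining max membership
  top <- max.col(Q, ties.method = "first")
  first_idx <- vapply(seq_len(K), function(k) {
    w <- which(top == k)
    if (length(w)) min(w) else n + k
  }, numeric(1))
  ord <- order(first_idx)
  Q <- Q[, ord, drop = FALSE]
  G <- G[ord, , , drop = FALSE]

  dimnames(Q) <- list(gm$sample_ids, paste0("cluster", seq_len(K)))
  dimnames(G) <- list(paste0("cluster", seq_len(K)),
                      c("homref", "het", "homalt"), gm$locus_ids)
  structure(list(Q = Q, G_freq = G, K = K, cross_entropy = ce,
                 loss_trace = loss_trace, n_iter = iter,
                 converged = converged, seed = seed),
            class = "ancestry_result")
}

#' @export
print.ancestry_result <- function(x, ...) {
  cat(sprintf("ancestry_result: K = %d, %d samples, cross-entropy %.4f (%d EM iterations%s)\n",
              x$K, nrow(x$Q), x$cross_entropy, x$n_iter,
              if (x$converged) ", converged" else ""))
  invisible(x)
}

#' Select the number of ancestral clusters by masked prediction
#'
#' For each candidate `K`, a fraction of the observed calls is masked,
#' the model is fitted on the remainder, and the masked entries are
#' scored by cross-entropy (mean negative log probability of the held
#' out genotype state). The procedure is repeated `n_rep` times with
#' fresh masks and initializations, cross-entropies are averaged, and
#' the `K` minimizing the average is returned (ties go to the smaller
#' `K`).
#'
#' @param gm A [genotype_matrix()].
#' @param k_range Integer vector of candidate `K` values.
#' @param seed RNG seed.
#' @param holdout_fraction Fraction of observed calls masked per
#'   replicate (default 0.05).
#' @param n_rep Replicates averaged per `K` (default 5).
#' @param ... Passed to [estimate_ancestry()] (e.g. `alpha`,
#'   `max_iter`).
#' @return A list with `best_k` and `cross_entropy` (data frame:
#'   `K`, `mean_ce` plus one column per replicate).
#' @export
select_k <- function(gm, k_range, seed, holdout_fraction = 0.05,
                     n_rep = 5, ...) {
  stopifnot(length(k_range) >= 1, all(k_range >= 1),
            holdout_fraction > 0, holdout_fraction < 1)
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  k_range <- sort(unique(as.integer(k_range)))
  X <- gm$calls
  obs_idx <- which(!is.na(X))
  ce <- matrix(NA_real_, length(k_range), n_rep,
               dimnames = list(paste0("K", k_range), NULL))
  for (rep_i in seq_len(n_rep)) {
    set.seed(seed + 7919L * rep_i)
    mask <- draw_mask(X, obs_idx, holdout_fraction)
    Xtrain <- X
    Xtrain[mask] <- NA_integer_
    gm_train <- genotype_matrix(Xtrain, gm$sample_ids, gm$locus_ids)
    truth_state <- X[mask] + 1L
    i_vec <- ((mask - 1L) %% nrow(X)) + 1L
    l_vec <- ((mask - 1L) %/% nrow(X)) + 1L
    for (ki in seq_along(k_range)) {
      fit <- estimate_ancestry(gm_train, k_range[ki],
                               seed = seed + 100003L * rep_i + k_range[ki],
                               ...)
      p <- numeric(length(mask))
      for (k in seq_len(k_range[ki])) {
        p <- p + fit$Q[cbind(i_vec, k)] *
          fit$G_freq[k, , ][cbind(truth_state, l_vec)]
      }
      ce[ki, rep_i] <- -mean(log(pmax(p, 1e-9)))
    }
  }
  mean_ce <- rowMeans(ce)
  best <- k_range[which.min(mean_ce)]  # which.min takes the first: smallest K
  list(best_k = best,
       cross_entropy = data.frame(K = k_range, mean_ce = unname(mean_ce),
                                  ce, row.names = NULL))
}

# internal: mask a fraction of observed calls, re-drawing (bounded) if a
# locus would lose all its observations
draw_mask <- function(X, obs_idx, fraction, max_retry = 20L) {
  n <- nrow(X)
  n_mask <- max(1L, round(fraction * length(obs_idx)))
  obs_per_locus <- colSums(!is.na(X))
  for (try in seq_len(max_retry)) {
    mask <- sample(obs_idx, n_mask)
    lost <- tabulate(((mask - 1L) %/% n) + 1L, nbins = ncol(X))
    if (all(obs_per_locus - lost >= 1L)) return(mask)
  }
  stop("could not draw a holdout mask keeping every locus observed")
}

#' Discriminant analysis of principal components (DAPC)
#'
#' Centers the genotype matrix (missing calls mean-imputed), reduces it
#' to `n_pcs` principal components, then runs linear discriminant
#' analysis on the population labels. Axis signs are fixed so the
#' largest-magnitude loading of each axis is positive, making scores
#' invariant to locus order.
#'
#' @param gm A [genotype_matrix()].
#' @param popmap Data frame with columns `sample`, `population`; every
#'   population needs at least 2 samples.
#' @param n_pcs Number of principal components retained (< n_samples).
#' @param n_axes Number of discriminant axes reported (default: all,
#'   i.e. `min(n_pops - 1, n_pcs)`).
#' @return A list of class `dapc_result`: `n_pcs`, `discriminants`
#'   (sample scores), `axis_variance` (per-axis share of discriminable
#'   variance), `group_centroids`, `populations`, `assignments`
#'   (in-sample nearest-centroid classification in discriminant space).
#' @export
dapc_fit <- function(gm, popmap, n_pcs, n_axes = NULL) {
  pop <- match_populations(gm, popmap)
  sizes <- table(pop)
  if (any(sizes < 2L)) {
    stop("population(s) with a single sample (within-group scatter undefined): ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  }
  if (length(sizes) < 2L) stop("DAPC needs at least two populations")
  if (n_pcs >= n_samples(gm)) stop("n_pcs must be smaller than the sample count")
  max_axes <- min(length(sizes) - 1L, n_pcs)
  if (is.null(n_axes)) n_axes <- max_axes
  n_axes <- min(n_axes, max_axes)

  X <- impute_center(gm$calls)
  pca <- stats::prcomp(X, center = FALSE, rank. = n_pcs)
  rot <- fix_signs(pca$rotation)
  scores <- X %*% rot
  ld <- linear_discriminants(scores, pop)
  disc <- scores %*% ld$axes[, seq_len(n_axes), drop = FALSE]
  av <- ld$eigenvalues / sum(ld$eigenvalues)
  centroids <- apply(disc, 2L, function(x) tapply(x, pop, mean))
  if (n_axes == 1L) centroids <- matrix(centroids, ncol = 1L,
                                        dimnames = list(names(sizes), NULL))
  assigned <- nearest_centroid(disc, centroids)
  structure(list(n_pcs = n_pcs,
                 discriminants = disc,
                 axis_variance = av[seq_len(n_axes)],
                 group_centroids = centroids,
                 populations = pop,
                 assignments = assigned),
            class = "dapc_result")
}

# internal: Fisher linear discriminant axes via the ridge-regularized
# generalized eigenproblem W^{-1} B (robust to zero within-group scatter,
# e.g. populations fixed for different alleles)
linear_discriminants <- function(scores, grp) {
  grp <- as.character(grp)
  groups <- unique(grp)
  p <- ncol(scores)
  mu <- colMeans(scores)
  W <- matrix(0, p, p)
  B <- matrix(0, p, p)
  for (g in groups) {
    sg <- scores[grp == g, , drop = FALSE]
    mg <- colMeans(sg)
    cg <- sweep(sg, 2L, mg, "-")
    W <- W + crossprod(cg)
    B <- B + nrow(sg) * tcrossprod(mg - mu)
  }
  n_axes <- min(length(groups) - 1L, p)
  ridge <- 1e-9 * sum(diag(W)) / p
  if (ridge <= 0) ridge <- 1e-12 * max(sum(diag(B)) / p, 1)
  R <- chol(W + ridge * diag(p))
  Ri <- backsolve(R, diag(p))
  K <- t(Ri) %*% B %*% Ri
  eig <- eigen((K + t(K)) / 2, symmetric = TRUE)
  axes <- fix_signs(Ri %*% eig$vectors[, seq_len(n_axes), drop = FALSE])
  list(axes = axes, eigenvalues = pmax(eig$values[seq_len(n_axes)], 0))
}

# internal: assign each row to the closest group centroid
nearest_centroid <- function(disc, centroids) {
  d2 <- outer(rowSums(disc^2), rep(1, nrow(centroids))) -
    2 * disc %*% t(centroids) +
    outer(rep(1, nrow(disc)), rowSums(centroids^2))
  rownames(centroids)[max.col(-d2, ties.method = "first")]
}

# internal: mean-impute missing calls and center columns
impute_center <- function(X) {
  mode(X) <- "double"
  mu <- colMeans(X, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  for (j in which(colSums(is.na(X)) > 0L)) {
    X[is.na(X[, j]), j] <- mu[j]
  }
  sweep(X, 2L, colMeans(X), "-")
}

# internal: flip each column so its largest-|.| element is positive
fix_signs <- function(M) {
  for (j in seq_len(ncol(M))) {
    i <- which.max(abs(M[, j]))
    if (M[i, j] < 0) M[, j] <- -M[, j]
  }
  M
}

#' Cross-validate the number of retained principal components
#'
#' Stratified holdout validation of the DAPC pre-processing: per
#' replicate, a fraction of each population is held out (populations
#' too small to stratify stay whole in training, with a message), the
#' PCA and LDA are fitted on the training samples, and held-out samples
#' are assigned to populations. The candidate maximizing mean correct
#' reassignment wins; ties go to the smallest candidate.
#'
#' @param gm A [genotype_matrix()].
#' @param popmap Data frame with columns `sample`, `population`.
#' @param candidate_n_pcs Integer vector of candidate PC counts.
#' @param n_rep Holdout replicates (default 30).
#' @param test_fraction Held-out share per population (default 0.1).
#' @param seed RNG seed.
#' @return A list with `optimal_n_pcs` and `scores` (data frame:
#'   `n_pcs`, `mean_correct`).
#' @export
crossvalidate_pcs <- function(gm, popmap, candidate_n_pcs, n_rep = 30,
                              test_fraction = 0.1, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  pop <- match_populations(gm, popmap)
  candidate_n_pcs <- sort(unique(as.integer(candidate_n_pcs)))
  n <- n_samples(gm)
  if (any(candidate_n_pcs >= floor(n * (1 - test_fraction)))) {
    stop("candidate PC counts must be below the training-set size")
  }
  set.seed(seed)
  X <- impute_center(gm$calls)
  acc <- matrix(NA_real_, length(candidate_n_pcs), n_rep)
  whole_logged <- character(0)
  for (r in seq_len(n_rep)) {
    test <- integer(0)
    for (p in unique(pop)) {
      idx <- which(pop == p)
      n_test <- max(1L, floor(test_fraction * length(idx)))
      if (length(idx) - n_test < 2L) {
        whole_logged <- union(whole_logged, p)
        next  # too small to stratify: keep whole population in training
      }
      test <- c(test, sample(idx, n_test))
    }
    if (length(test) == 0L) stop("no population is large enough to hold out")
    train <- setdiff(seq_len(n), test)
    mu <- colMeans(X[train, , drop = FALSE])
    Xtr <- sweep(X[train, , drop = FALSE], 2L, mu, "-")
    Xte <- sweep(X[test, , drop = FALSE], 2L, mu, "-")
    pca <- stats::prcomp(Xtr, center = FALSE, rank. = max(candidate_n_pcs))
    str_tr <- Xtr %*% pca$rotation
    str_te <- Xte %*% pca$rotation
    for (ci in seq_along(candidate_n_pcs)) {
      cpc <- candidate_n_pcs[ci]
      ld <- linear_discriminants(str_tr[, seq_len(cpc), drop = FALSE],
                                 pop[train])
      dtr <- str_tr[, seq_len(cpc), drop = FALSE] %*% ld$axes
      dte <- str_te[, seq_len(cpc), drop = FALSE] %*% ld$axes
      ctr <- apply(dtr, 2L, function(x) tapply(x, pop[train], mean))
      if (ncol(ld$axes) == 1L) {
        ctr <- matrix(ctr, ncol = 1L,
                      dimnames = list(sort(unique(pop[train])), NULL))
      }
      acc[ci, r] <- mean(nearest_centroid(dte, ctr) == pop[test])
    }
  }
  if (length(whole_logged)) {
    message("population(s) too small to stratify, kept whole in training: ",
            paste(whole_logged, collapse = ", "))
  }
  mean_acc <- rowMeans(acc)
  best <- candidate_n_pcs[which.max(mean_acc)]  # first max: smallest candidate
  list(optimal_n_pcs = best,
       scores = data.frame(n_pcs = candidate_n_pcs,
                           mean_correct = unname(mean_acc)))
}
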