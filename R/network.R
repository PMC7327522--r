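# Regularized partial correlation network ------------------------------------
#
# Sparse Gaussian graphical model on the sample *correlation* matrix
# (variables standardized, so edge weights are scale-free), estimated by
# L1-penalized maximum likelihood (graphical lasso, block coordinate
# descent) over a penalty grid, with the penalty selected by the extended
# BIC: EBIC = -2 loglik + E log(n) + 4 gamma E log(p), E = number of
# nonzero off-diagonal pairs. Edge weights are the partial correlations of
# the selected precision matrix.

#' Network-estimation configuration
#'
#' @param gamma EBIC hyperparameter controlling network complexity
#'   (default 0.5).
#' @param rho_grid Positive penalty values, ascending (default 100
#'   log-spaced over \[0.01, 1\] of the maximum absolute correlation).
#' @param min_abs_edge Edges with |partial correlation| below this are not
#'   reported (default 0).
#' @return A `network_config` list.
#' @export
network_config <- function(gamma = 0.5, rho_grid = NULL, min_abs_edge = 0) {
  if (gamma < 0) abort("`gamma` must be >= 0")
  if (!is.null(rho_grid)) {
    if (any(rho_grid <= 0) || is.unsorted(rho_grid))
      abort("`rho_grid` must be positive and ascending")
  }
  structure(list(gamma = gamma, rho_grid = rho_grid,
                 min_abs_edge = min_abs_edge),
            class = "network_config")
}

#' Partial correlations from a precision matrix
#'
#' `rho_ij = -K_ij / sqrt(K_ii * K_jj)`, diagonal set to 0.
#'
#' @param K Symmetric positive-definite precision matrix.
#' @return Matrix of partial correlations.
#' @export
partial_corr_from_precision <- function(K) {
  if (!isSymmetric(unname(K), tol = 1e-8)) abort("precision must be symmetric")
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) abort("precision matrix is not positive definite")
  d <- 1 / sqrt(diag(K))
  P <- -K * outer(d, d)
  diag(P) <- 0
  P
}

# one lasso subproblem by coordinate descent:
# min_b 0.5 b' W11 b - s12' b + rho ||b||_1
lasso_cd <- function(W11, s12, rho, beta0, tol = 1e-7, max_iter = 500) {
  beta <- beta0
  p1 <- length(s12)
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(p1)) {
      resid <- s12[j] - sum(W11[j, -j] * beta[-j])
      bj <- sign(resid) * max(abs(resid) - rho, 0) / W11[j, j]
      delta <- max(delta, abs(bj - beta[j]))
      beta[j] <- bj
    }
    if (delta < tol) break
  }
  beta
}

# Constrained MLE with a fixed zero pattern (support-restricted refit used
# for EBIC scoring): same block algorithm with the lasso step replaced by a
# least-squares solve on the column's allowed entries.
glasso_refit <- function(S, support, tol = 1e-7, max_iter = 200) {
  p <- nrow(S)
  W <- S
  B <- matrix(0, p - 1, p)
  for (it in seq_len(max_iter)) {
    W_old <- W
    for (j in seq_len(p)) {
      idx <- setdiff(seq_len(p), j)
      allowed <- which(support[idx, j])
      beta <- numeric(p - 1)
      if (length(allowed) > 0) {
        beta[allowed] <- solve(W[idx[allowed], idx[allowed], drop = FALSE],
                               S[idx[allowed], j])
      }
      B[, j] <- beta
      w12 <- W[idx, idx, drop = FALSE] %*% beta
      W[idx, j] <- w12
      W[j, idx] <- w12
    }
    if (max(abs(W - W_old)) < tol) break
  }
  Theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- setdiff(seq_len(p), j)
    t_jj <- 1 / (W[j, j] - sum(W[idx, j] * B[, j]))
    Theta[j, j] <- t_jj
    Theta[idx, j] <- -B[, j] * t_jj
  }
  (Theta + t(Theta)) / 2
}

# Friedman block-coordinate graphical lasso on a correlation matrix S.
# Returns the estimated covariance W and precision Theta at penalty rho.
glasso_fit <- function(S, rho, W_init = NULL, tol = 1e-5, max_iter = 100) {
  p <- nrow(S)
  W <- W_init %||% (S + rho * diag(p))
  diag(W) <- diag(S) + rho
  B <- matrix(0, p - 1, p) # lasso coefficients per column, warm-started
  for (it in seq_len(max_iter)) {
    W_old <- W
    for (j in seq_len(p)) {
      idx <- setdiff(seq_len(p), j)
      beta <- lasso_cd(W[idx, idx, drop = FALSE], S[idx, j], rho, B[, j])
      B[, j] <- beta
      w12 <- W[idx, idx, drop = FALSE] %*% beta
      W[idx, j] <- w12
      W[j, idx] <- w12
    }
    if (max(abs(W - W_old)) < tol * mean(abs(diag(S)))) break
  }
  # recover precision: theta_jj = 1/(w_jj - w12' beta); theta_12 = -beta*theta_jj
  Theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- setdiff(seq_len(p), j)
    beta <- B[, j]
    t_jj <- 1 / (W[j, j] - sum(W[idx, j] * beta))
    Theta[j, j] <- t_jj
    Theta[idx, j] <- -beta * t_jj
  }
  Theta <- (Theta + t(Theta)) / 2
  list(W = W, Theta = Theta)
}

#' EBIC-selected graphical lasso partial-correlation network
#'
#' Standardizes the variables, estimates a sparse precision matrix along a
#' penalty path, selects the penalty minimizing the EBIC with hyperparameter
#' `gamma`, and returns the partial correlations of the selected precision
#' together with node centralities. Among equal-EBIC penalties the largest
#' (sparsest) wins.
#'
#' @param data Samples x compounds matrix or data frame.
#' @param cfg A [network_config()].
#' @return A `partial_corr_network` list: `weights` (partial-correlation
#'   matrix), `precision`, `rho`, `path` (tibble rho/edges/ebic),
#'   `centrality` tibble, `n`, `gamma`.
#' @export
ebic_glasso <- function(data, cfg = network_config()) {
  X <- as.matrix(data)
  n <- nrow(X); p <- ncol(X)
  if (n < 3) abort("need at least 3 samples")
  nodes <- colnames(X) %||% sprintf("V%d", seq_len(p))
  S <- stats::cor(X)
  max_abs <- max(abs(S[upper.tri(S)]))
  rho_grid <- cfg$rho_grid %||%
    exp(seq(log(0.01 * max_abs), log(max_abs), length.out = 100))
  # descend from the sparsest end with warm starts
  rho_desc <- sort(rho_grid, decreasing = TRUE)
  fits <- vector("list", length(rho_desc))
  W_prev <- NULL
  for (i in seq_along(rho_desc)) {
    fits[[i]] <- tryCatch(glasso_fit(S, rho_desc[i], W_init = W_prev),
                          error = function(e) NULL)
    if (!is.null(fits[[i]])) W_prev <- fits[[i]]$W
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok))
    abort(paste0("graphical lasso failed to converge at every penalty: ",
                 paste(signif(rho_desc, 3), collapse = ", ")))
  # EBIC scored on the support-restricted unpenalized refit, so shrinkage
  # does not masquerade as lack of fit; identical supports share a score
  refit_cache <- new.env(parent = emptyenv())
  path <- purrr::map2_dfr(fits[ok], rho_desc[ok], function(f, rho) {
    Th <- f$Theta
    supp <- abs(Th) > 1e-8
    E <- sum(supp[upper.tri(supp)])
    key <- paste0("s", paste(which(supp[upper.tri(supp)]), collapse = ","))
    if (!exists(key, envir = refit_cache)) {
      Th_ref <- glasso_refit(S, supp)
      ll <- (n / 2) * (as.numeric(determinant(Th_ref, TRUE)$modulus) -
                         sum(S * Th_ref))
      assign(key, -2 * ll + E * log(n) + 4 * cfg$gamma * E * log(p),
             envir = refit_cache)
    }
    tibble(rho = rho, edges = E, ebic = get(key, envir = refit_cache))
  })
  # ties -> largest rho; rho_desc order means the first minimum is sparsest
  best <- which.min(path$ebic)
  Theta <- fits[ok][[best]]$Theta
  weights <- partial_corr_from_precision(Theta)
  weights[abs(weights) < cfg$min_abs_edge] <- 0
  dimnames(weights) <- list(nodes, nodes)
  net <- structure(list(weights = weights, precision = Theta,
                        rho = path$rho[best], path = path, n = n,
                        gamma = cfg$gamma),
                   class = "partial_corr_network")
  net$centrality <- centralities(net)
  net
}

#' Node centralities of a partial-correlation network
#'
#' Strength = sum of absolute incident edge weights; shortest paths use edge
#' length 1/|weight| on nonzero edges; closeness = 1 / (sum of distances to
#' all other nodes), set to 0 for nodes that cannot reach every other node;
#' betweenness = standard shortest-path betweenness.
#'
#' @param net A `partial_corr_network` (or a bare weight matrix).
#' @return Tibble: `node`, `strength`, `closeness`, `betweenness`.
#' @export
centralities <- function(net) {
  W <- if (inherits(net, "partial_corr_network")) net$weights else net
  if (nrow(W) < 2) abort("need at least 2 nodes")
  nodes <- rownames(W) %||% sprintf("V%d", seq_len(nrow(W)))
  A <- abs(W)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  strength <- rowSums(A)
  if (igraph::ecount(g) > 0) {
    len <- 1 / igraph::E(g)$weight
    D <- igraph::distances(g, weights = len)
    btw <- igraph::betweenness(g, weights = len, directed = FALSE)
  } else {
    D <- matrix(Inf, nrow(W), nrow(W)); diag(D) <- 0
    btw <- rep(0, nrow(W))
  }
  closeness <- vapply(seq_len(nrow(D)), function(i) {
    d <- D[i, -i]
    if (any(!is.finite(d)) || sum(d) == 0) 0 else 1 / sum(d)
  }, numeric(1))
  tibble(node = nodes, strength = strength,
         closeness = as.numeric(closeness),
         betweenness = as.numeric(btw))
}

#' Edge list of a partial-correlation network
#'
#' @param x A `partial_corr_network`.
#' @param ... Unused.
#' @return Tibble: `node_a`, `node_b`, `partial_corr` (nonzero edges only).
#' @exportS3Method generics::tidy
tidy.partial_corr_network <- function(x, ...) {
  W <- x$weights
  ut <- which(upper.tri(W) & abs(W) > 0, arr.ind = TRUE)
  tibble(node_a = rownames(W)[ut[, 1]], node_b = colnames(W)[ut[, 2]],
         partial_corr = W[ut])
}

#' @exportS3Method generics::glance
glance.partial_corr_network <- function(x, ...) {
  tibble(rho = x$rho, n_edges = sum(abs(x$weights[upper.tri(x$weights)]) > 0),
         n_nodes = nrow(x$weights), gamma = x$gamma, n = x$n)
}
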