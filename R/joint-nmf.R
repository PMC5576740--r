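#' Configuration for the joint factorization
#'
#' Collects the tunable parameters of the joint non-negative factorization.
#' `lambda` and `mu` weight the consensus penalties tying the topology and
#' attribute embeddings to the shared consensus embedding; both default to 1
#' (neutral weighting) and setting both to 0 recovers two independent
#' classical multiplicative-update factorizations.
#'
#' @param k Latent dimension. `NULL` (default) picks `floor(n/2)` in
#'   topology-only mode and `floor((n+m)/4)` in attribute mode at fit time,
#'   clamped to `k < n` and, in attribute mode, to the compression condition
#'   `(n+m)*k < n*m`.
#' @param lambda Consensus weight for the topology embedding, `>= 0`.
#' @param mu Consensus weight for the attribute embedding, `>= 0`.
#' @param eps Absolute stopping threshold on the squared Frobenius
#'   reconstruction error of the adjacency matrix. `NULL` (default) resolves
#'   to `1e-4 * ||A||_F^2` at fit time, making the criterion scale-free.
#' @param max_iter Iteration cap, `>= 1`.
#' @param seed Integer seed; all random initialization flows from it.
#' @param delta Small positive guard added to every update denominator so a
#'   dead row/column cannot cause division by zero.
#' @param rel_tol Secondary stopping rule: stop when the relative change of
#'   the objective between iterations falls below this value.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(k = NULL, lambda = 1, mu = 1, eps = NULL,
                       max_iter = 500, seed = 1, delta = 1e-12,
                       rel_tol = 1e-6) {
  if (!is.null(k)) {
    k <- as.integer(k)
    if (length(k) != 1 || is.na(k) || k < 1) {
      stop("`k` must be a positive integer.", call. = FALSE)
    }
  }
  if (lambda < 0 || mu < 0) {
    stop("`lambda` and `mu` must be non-negative.", call. = FALSE)
  }
  if (!is.null(eps) && eps <= 0) {
    stop("`eps` must be positive.", call. = FALSE)
  }
  max_iter <- as.integer(max_iter)
  if (max_iter < 1) stop("`max_iter` must be at least 1.", call. = FALSE)
  if (delta <= 0) stop("`delta` must be positive.", call. = FALSE)
  structure(
    list(k = k, lambda = lambda, mu = mu, eps = eps, max_iter = max_iter,
         seed = as.integer(seed), delta = delta, rel_tol = rel_tol),
    class = "fit_config"
  )
}

#' @export
print.fit_config <- function(x, ...) {
  cat("<fit_config> k=", if (is.null(x$k)) "auto" else x$k,
      " lambda=", x$lambda, " mu=", x$mu,
      " eps=", if (is.null(x$eps)) "auto" else x$eps,
      " max_iter=", x$max_iter, " seed=", x$seed, "\n", sep = "")
  invisible(x)
}

# Default latent dimension: half the node count without attributes,
# a quarter of (nodes + attributes) with them; always k < n and, with
# attributes, (n+m)k < nm so the factors compress the input.
default_latent_dim <- function(n, m = NULL) {
  if (is.null(m)) {
    k <- floor(n / 2)
  } else {
    k <- floor((n + m) / 4)
    bound <- ceiling(n * m / (n + m)) - 1L
    k <- min(k, bound)
  }
  max(1L, min(as.integer(k), n - 1L))
}

resolve_config <- function(config, n, m = NULL, normA2 = NULL) {
  if (is.null(config$k)) {
    config$k <- default_latent_dim(n, m)
  } else {
    if (config$k >= n) {
      stop("Latent dimension k = ", config$k, " must be smaller than the ",
           "node count n = ", n, ".", call. = FALSE)
    }
    if (!is.null(m) && (n + m) * config$k >= n * m) {
      warning("k = ", config$k, " violates the compression condition ",
              "(n+m)k < nm; clamping.", call. = FALSE)
      config$k <- default_latent_dim(n, m)
    }
  }
  if (is.null(config$eps) && !is.null(normA2)) {
    config$eps <- 1e-4 * normA2
  }
  config
}

#' Initialize the factor matrices
#'
#' Fills every factor matrix with independent draws from the uniform
#' distribution on (0, 1], reproducibly from `config$seed`, and computes the
#' diagonal normalizers from the drawn base matrices. Strictly positive
#' initialization guarantees the multiplicative updates can move every entry.
#'
#' @param graph An `lp_graph`, or a symmetric non-negative numeric matrix.
#' @param attrs Optional `lp_attributes` (attributes x nodes); `NULL` for
#'   topology-only mode.
#' @param config A [fit_config()]; `config$k` must be set (use
#'   [fit_config()] with an explicit `k`, or let [nmf_lp()] resolve it).
#' @return A list of class `nmf_lp_factors` with elements `U` (n x k), `V`
#'   (k x n), `Vstar` (k x n), `q` (length-k column sums of `U`), and, in
#'   attribute mode, `UB` (m x k), `VB` (k x n), `qb`.
#' @export
init_factors <- function(graph, attrs = NULL, config = fit_config()) {
  A <- as_adjacency(graph)
  n <- ncol(A)
  m <- if (is.null(attrs)) NULL else nrow(attrs)
  config <- resolve_config(config, n, m)
  k <- config$k
  # 1 - runif() has support (0, 1]: every entry strictly positive
  model <- withr::with_seed(config$seed, {
    fac <- list(
      U = matrix(1 - stats::runif(n * k), n, k),
      V = matrix(1 - stats::runif(k * n), k, n)
    )
    if (!is.null(attrs)) {
      fac$UB <- matrix(1 - stats::runif(m * k), m, k)
      fac$VB <- matrix(1 - stats::runif(k * n), k, n)
    }
    fac$Vstar <- matrix(1 - stats::runif(k * n), k, n)
    fac
  })
  model$q <- colSums(model$U)
  if (!is.null(attrs)) model$qb <- colSums(model$UB)
  model$k <- k
  model$mode <- if (is.null(attrs)) "topology" else "attributes"
  structure(model, class = "nmf_lp_factors")
}

as_adjacency <- function(x) {
  if (inherits(x, "lp_graph")) return(x$A)
  x <- as.matrix(x)
  if (nrow(x) != ncol(x) || any(x < 0)) {
    stop("Expected an `lp_graph` or a square non-negative matrix.",
         call. = FALSE)
  }
  if (max(abs(x - t(x))) > 1e-8) {
    stop("Adjacency matrix must be symmetric.", call. = FALSE)
  }
  x
}

#' Multiplicative update of the topology base matrix U
#'
#' Rescales each entry of `U` by the ratio of the positive and negative parts
#' of the gradient of `||A - UV||_F^2 + lambda ||QV - Vstar||_F^2`, then
#' recomputes the diagonal normalizer `q` from the new `U`. All other factors
#' are untouched.
#'
#' @param model An `nmf_lp_factors` list.
#' @param A Symmetric non-negative adjacency matrix.
#' @param config A [fit_config()] (uses `lambda` and `delta`).
#' @return The model with updated `U` and `q`.
#' @export
update_u <- function(model, A, config = fit_config()) {
  lam <- config$lambda
  n <- nrow(model$U)
  num <- A %*% t(model$V) +
    lam * rep(rowSums(model$Vstar * model$V), each = n)
  den <- model$U %*% (model$V %*% t(model$V)) +
    lam * rep(rowSums(model$V^2) * colSums(model$U), each = n) +
    config$delta
  model$U <- model$U * num / den
  model$q <- colSums(model$U)
  model
}

#' Multiplicative update of the attribute base matrix
#'
#' Structural analogue of [update_u()] for the attribute factorization:
#' minimizes `||B - UB VB||_F^2 + mu ||QB VB - Vstar||_F^2` in `UB`, then
#' recomputes `qb`.
#'
#' @inheritParams update_u
#' @param B Non-negative attribute matrix (attributes x nodes).
#' @return The model with updated `UB` and `qb`.
#' @export
update_ub <- function(model, B, config = fit_config()) {
  mu <- config$mu
  m <- nrow(model$UB)
  num <- B %*% t(model$VB) +
    mu * rep(rowSums(model$Vstar * model$VB), each = m)
  den <- model$UB %*% (model$VB %*% t(model$VB)) +
    mu * rep(rowSums(model$VB^2) * colSums(model$UB), each = m) +
    config$delta
  model$UB <- model$UB * num / den
  model$qb <- colSums(model$UB)
  model
}

#' Multiplicative update of the topology coefficient matrix V
#'
#' Minimizes `||A - UV||_F^2 + lambda ||V - Vstar||_F^2` in `V`:
#' each entry is rescaled by
#' `((U'A)[l,m] + lambda Vstar[l,m]) / ((U'UV)[l,m] + lambda V[l,m] + delta)`.
#'
#' @inheritParams update_u
#' @return The model with updated `V`.
#' @export
update_v <- function(model, A, config = fit_config()) {
  lam <- config$lambda
  num <- t(model$U) %*% A + lam * model$Vstar
  den <- crossprod(model$U) %*% model$V + lam * model$V + config$delta
  model$V <- model$V * num / den
  model
}

#' Multiplicative update of the attribute coefficient matrix
#'
#' Analogue of [update_v()] for the attribute factorization: minimizes
#' `||B - UB VB||_F^2 + mu ||VB - Vstar||_F^2` in `VB`.
#'
#' @inheritParams update_ub
#' @return The model with updated `VB`.
#' @export
update_vb <- function(model, B, config = fit_config()) {
  mu <- config$mu
  num <- t(model$UB) %*% B + mu * model$Vstar
  den <- crossprod(model$UB) %*% model$VB + mu * model$VB + config$delta
  model$VB <- model$VB * num / den
  model
}

#' Closed-form update of the consensus embedding
#'
#' Sets `Vstar[l,m] = (q[l] V[l,m] + qb[l] VB[l,m]) / 2`, the exact minimizer
#' of `||QV - Vstar||_F^2 + ||QB VB - Vstar||_F^2`. In topology-only mode the
#' consensus is `Vstar = QV`, the normalized node embedding used for scoring.
#'
#' @param model An `nmf_lp_factors` list with current `q` (and `qb`).
#' @return The model with updated `Vstar`.
#' @export
update_vstar <- function(model) {
  if (model$mode == "attributes") {
    model$Vstar <- 0.5 * (model$q * model$V + model$qb * model$VB)
  } else {
    model$Vstar <- model$q * model$V
  }
  model
}

#' Joint factorization objective
#'
#' The sum of four squared Frobenius terms: the two reconstruction errors and
#' the two consensus penalties,
#' `||A - UV||^2 + ||B - UB VB||^2 + lambda ||QV - Vstar||^2 +
#'  mu ||QB VB - Vstar||^2`.
#' In topology-only mode the attribute and `mu` terms vanish.
#'
#' @inheritParams update_u
#' @param B Attribute matrix or `NULL`.
#' @return A non-negative scalar.
#' @export
objective_j <- function(model, A, B = NULL, config = fit_config()) {
  if (ncol(model$U) != nrow(model$V) || nrow(model$U) != nrow(A) ||
      ncol(model$V) != ncol(A)) {
    stop("Factor shapes are inconsistent with A.", call. = FALSE)
  }
  val <- sum((A - model$U %*% model$V)^2) +
    config$lambda * sum((model$q * model$V - model$Vstar)^2)
  if (!is.null(B)) {
    if (nrow(model$UB) != nrow(B) || ncol(model$VB) != ncol(B)) {
      stop("Factor shapes are inconsistent with B.", call. = FALSE)
    }
    val <- val + sum((B - model$UB %*% model$VB)^2) +
      config$mu * sum((model$qb * model$VB - model$Vstar)^2)
  }
  val
}

#' Fit the joint non-negative factorization link-prediction model
#'
#' Factorizes the adjacency matrix `A` (and, when `attrs` is supplied, the
#' node-attribute matrix `B`) into non-negative factors sharing a consensus
#' node embedding, by cycling multiplicative updates: update `U` (recompute
#' `Q`), update `UB` (recompute `QB`), update `V`, update `VB`, then set the
#' consensus `Vstar` in closed form. Iteration stops when the reconstruction
#' error `||A - UV||_F^2` drops to `eps`, when the relative change of the
#' objective falls below `rel_tol`, or at `max_iter` (the returned model is
#' then flagged as not converged rather than erroring).
#'
#' @param x An `lp_graph`, or a symmetric non-negative matrix to factorize
#'   directly (useful for factorization-recovery experiments).
#' @param attrs Optional `lp_attributes` aligned to the nodes of `x`.
#' @param config A [fit_config()].
#' @param init Optional explicit initial factors (a list with `U`, `V`,
#'   `Vstar` and, in attribute mode, `UB`, `VB`), overriding the random
#'   initialization. Used e.g. for permutation-equivariance checks.
#' @param verbose Print one line per iteration (iteration, objective,
#'   reconstruction error) to stderr.
#' @return An object of class `nmf_lp_fit`: the final factors plus
#'   `history` (a tibble with `iteration`, `objective`, `recon_error`),
#'   `converged`, `stopped_by` (`"eps"`, `"rel_change"` or `"max_iter"`),
#'   the resolved `config`, and `node_ids`.
#' @examples
#' g <- generate_sbm(planted_spec(n = 30, seed = 1))
#' fit <- nmf_lp(g$graph, g$attributes, fit_config(k = 4, seed = 1))
#' glance(fit)
#' @export
nmf_lp <- function(x, attrs = NULL, config = fit_config(), init = NULL,
                   verbose = FALSE) {
  A <- as_adjacency(x)
  n <- ncol(A)
  node_ids <- if (inherits(x, "lp_graph")) x$node_ids else
    (colnames(A) %||% paste0("node_", seq_len(n)))
  B <- NULL
  if (!is.null(attrs)) {
    if (ncol(attrs) != n) {
      stop("`attrs` has ", ncol(attrs), " node columns but the graph has ",
           n, " nodes.", call. = FALSE)
    }
    B <- unclass(as.matrix(attrs))
  }
  normA2 <- sum(A^2)
  config <- resolve_config(config, n, if (is.null(B)) NULL else nrow(B),
                           normA2 = normA2)
  model <- init_factors(A, attrs = if (is.null(B)) NULL else attrs,
                        config = config)
  if (!is.null(init)) {
    for (nm in intersect(names(init), c("U", "V", "UB", "VB", "Vstar"))) {
      stopifnot(all(dim(model[[nm]]) == dim(init[[nm]])))
      model[[nm]] <- init[[nm]]
    }
    model$q <- colSums(model$U)
    if (!is.null(B)) model$qb <- colSums(model$UB)
  }

  hist_obj <- numeric(config$max_iter)
  hist_rec <- numeric(config$max_iter)
  j_prev <- Inf
  stopped_by <- "max_iter"
  iters <- config$max_iter
  for (t in seq_len(config$max_iter)) {
    model <- update_u(model, A, config)
    if (!is.null(B)) model <- update_ub(model, B, config)
    model <- update_v(model, A, config)
    if (!is.null(B)) model <- update_vb(model, B, config)
    model <- update_vstar(model)
    rec <- sum((A - model$U %*% model$V)^2)
    j <- objective_j(model, A, B, config)
    hist_obj[t] <- j
    hist_rec[t] <- rec
    if (verbose) {
      message(sprintf("iter %4d  J = %.6g  ||A-UV||^2 = %.6g", t, j, rec))
    }
    if (rec <= config$eps) {
      stopped_by <- "eps"
      iters <- t
      break
    }
    if (is.finite(j_prev) && abs(j_prev - j) < config$rel_tol * j_prev) {
      stopped_by <- "rel_change"
      iters <- t
      break
    }
    j_prev <- j
  }

  structure(
    c(unclass(model), list(
      history = tibble::tibble(
        iteration = seq_len(iters),
        objective = hist_obj[seq_len(iters)],
        recon_error = hist_rec[seq_len(iters)]
      ),
      converged = stopped_by != "max_iter",
      stopped_by = stopped_by,
      config = config,
      node_ids = node_ids
    )),
    class = "nmf_lp_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
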