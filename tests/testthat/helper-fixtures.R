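# Small graphs built in code ------------------------------------------------

triangle_graph <- function() {
  lp_graph(rbind(c("1", "2"), c("2", "3"), c("3", "1")))
}

path_graph <- function(n = 3) {
  ids <- as.character(seq_len(n))
  lp_graph(cbind(ids[-n], ids[-1]))
}

star_graph <- function(leaves = 3) {
  lp_graph(cbind("c", paste0("l", seq_len(leaves))))
}

random_lp_graph <- function(n, p, seed) {
  el <- withr::with_seed(seed, {
    ig <- igraph::sample_gnp(n, p)
    igraph::as_edgelist(ig, names = FALSE)
  })
  if (nrow(el) == 0) stop("random graph came out empty; raise p")
  new_graph_from_indices(n, el)
}

new_graph_from_indices <- function(n, el) {
  ids <- paste0("v", seq_len(n))
  lp_graph(cbind(ids[el[, 1]], ids[el[, 2]]), nodes = ids)
}

# Random factor models ------------------------------------------------------

random_model <- function(n, k, m = NULL, seed = 1, scale = 1) {
  withr::with_seed(seed, {
    mod <- list(
      U = matrix(runif(n * k), n, k) * scale,
      V = matrix(runif(k * n), k, n) * scale,
      Vstar = matrix(runif(k * n), k, n) * scale,
      k = k,
      mode = if (is.null(m)) "topology" else "attributes"
    )
    if (!is.null(m)) {
      mod$UB <- matrix(runif(m * k), m, k) * scale
      mod$VB <- matrix(runif(k * n), k, n) * scale
    }
    mod$q <- colSums(mod$U)
    if (!is.null(m)) mod$qb <- colSums(mod$UB)
    structure(mod, class = "nmf_lp_factors")
  })
}

random_symmetric <- function(n, seed) {
  withr::with_seed(seed, {
    x <- matrix(runif(n * n), n, n)
    (x + t(x)) / 2
  })
}

# Sub-objectives the update rules minimize ----------------------------------

f_of_u <- function(model, A, lambda) {
  q <- colSums(model$U)
  sum((A - model$U %*% model$V)^2) +
    lambda * sum((q * model$V - model$Vstar)^2)
}

f_of_ub <- function(model, B, mu) {
  qb <- colSums(model$UB)
  sum((B - model$UB %*% model$VB)^2) +
    mu * sum((qb * model$VB - model$Vstar)^2)
}

g_of_v <- function(model, A, lambda) {
  sum((A - model$U %*% model$V)^2) +
    lambda * sum((model$V - model$Vstar)^2)
}

g_of_vb <- function(model, B, mu) {
  sum((B - model$UB %*% model$VB)^2) +
    mu * sum((model$VB - model$Vstar)^2)
}

h_of_vstar <- function(model, vstar) {
  out <- sum((model$q * model$V - vstar)^2)
  if (model$mode == "attributes") {
    out <- out + sum((model$qb * model$VB - vstar)^2)
  }
  out
}

# Brute-force oracles -------------------------------------------------------

brute_baseline <- function(A, x, y, index) {
  gx <- which(A[x, ] == 1)
  gy <- which(A[y, ] == 1)
  cc <- length(intersect(gx, gy))
  kx <- length(gx)
  ky <- length(gy)
  div0 <- function(num, den) if (den == 0) 0 else num / den
  switch(index,
    cn = cc,
    salton = div0(cc, sqrt(kx * ky)),
    jaccard = div0(cc, length(union(gx, gy))),
    sorensen = div0(2 * cc, kx + ky),
    hpi = div0(cc, min(kx, ky)),
    hdi = div0(cc, max(kx, ky)),
    lhn_i = div0(cc, kx * ky),
    pa = kx * ky
  )
}

brute_objective <- function(model, A, B, lambda, mu) {
  total <- 0
  n <- nrow(A)
  k <- model$k
  for (i in seq_len(n)) for (j in seq_len(n)) {
    pred <- 0
    for (l in seq_len(k)) pred <- pred + model$U[i, l] * model$V[l, j]
    total <- total + (A[i, j] - pred)^2
  }
  for (l in seq_len(k)) for (j in seq_len(n)) {
    total <- total +
      lambda * (model$q[l] * model$V[l, j] - model$Vstar[l, j])^2
  }
  if (!is.null(B)) {
    m <- nrow(B)
    for (i in seq_len(m)) for (j in seq_len(n)) {
      pred <- 0
      for (l in seq_len(k)) pred <- pred + model$UB[i, l] * model$VB[l, j]
      total <- total + (B[i, j] - pred)^2
    }
    for (l in seq_len(k)) for (j in seq_len(n)) {
      total <- total +
        mu * (model$qb[l] * model$VB[l, j] - model$Vstar[l, j])^2
    }
  }
  total
}

# Central-difference gradient of fn at positive entries of mat
numeric_gradient <- function(fn, mat, h = 1e-6) {
  g <- matrix(0, nrow(mat), ncol(mat))
  for (i in seq_len(nrow(mat))) for (j in seq_len(ncol(mat))) {
    up <- mat; up[i, j] <- mat[i, j] + h
    dn <- mat; dn[i, j] <- mat[i, j] - h
    g[i, j] <- (fn(up) - fn(dn)) / (2 * h)
  }
  g
}

# Reference predictors for the benchmark harness ----------------------------

perfect_scorer <- function(train_g, split) {
  S <- matrix(0, train_g$n, train_g$n)
  pr <- split$probe
  S[pr] <- 1
  S[pr[, c(2, 1), drop = FALSE]] <- 1
  S
}

random_scorer_factory <- function(seed) {
  force(seed)
  function(train_g, split) {
    n <- train_g$n
    withr::with_seed(seed + split$fold, {
      S <- matrix(runif(n * n), n, n)
      (S + t(S)) / 2
    })
  }
}
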