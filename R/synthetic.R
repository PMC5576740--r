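#' Specification of a planted-structure benchmark instance
#'
#' Describes a stochastic block model with block-informative binary node
#' attributes: nodes are assigned to `blocks` near-equal communities, edges
#' appear within a community with probability `p_in` and between communities
#' with `p_out`, and each community owns `m / blocks` characteristic
#' attributes that its members carry with probability `attr_signal` while
#' all other nodes carry them at the background rate.
#'
#' @param n Node count.
#' @param blocks Number of communities.
#' @param p_in,p_out Within/between-community edge probabilities,
#'   `0 <= p_out <= p_in <= 1`.
#' @param m Attribute count; defaults to `n / 2`.
#' @param attr_signal Probability a community's characteristic attribute is
#'   present in its members.
#' @param attr_background Background presence probability elsewhere.
#' @param seed Integer seed.
#' @return An object of class `planted_spec`.
#' @export
planted_spec <- function(n = 100, blocks = 2, p_in = 0.3, p_out = 0.05,
                         m = ceiling(n / 2), attr_signal = 0.9,
                         attr_background = 0.05, seed = 1) {
  n <- as.integer(n)
  blocks <- as.integer(blocks)
  m <- as.integer(m)
  if (n < 2 || blocks < 1 || blocks > n) {
    stop("Need 1 <= blocks <= n and n >= 2.", call. = FALSE)
  }
  if (p_in < 0 || p_in > 1 || p_out < 0 || p_out > p_in) {
    stop("Edge probabilities must satisfy 0 <= p_out <= p_in <= 1.",
         call. = FALSE)
  }
  if (attr_signal < 0 || attr_signal > 1 ||
      attr_background < 0 || attr_background > 1) {
    stop("Attribute probabilities must lie in [0, 1].", call. = FALSE)
  }
  if (m < blocks) {
    stop("Need at least one attribute per block (m >= blocks).",
         call. = FALSE)
  }
  structure(
    list(n = n, blocks = blocks, p_in = p_in, p_out = p_out, m = m,
         attr_signal = attr_signal, attr_background = attr_background,
         seed = as.integer(seed)),
    class = "planted_spec"
  )
}

#' Generate a stochastic block model graph with planted attributes
#'
#' Draws an undirected simple graph from the stochastic block model of a
#' [planted_spec()] (via `igraph::sample_sbm()`), together with a binary
#' attribute incidence matrix whose attributes are split evenly across
#' communities: a community's attributes are present in its members with
#' probability `attr_signal` and elsewhere at the background rate. The
#' returned ground-truth community assignment is for test use only.
#'
#' @param spec A [planted_spec()].
#' @return A list with `graph` (an `lp_graph`), `attributes` (an
#'   `lp_attributes`, L1-normalized per node), `incidence` (the raw binary
#'   attribute x node matrix), and `blocks` (integer community assignment).
#' @examples
#' g <- generate_sbm(planted_spec(n = 20, seed = 1))
#' g$graph
#' @export
generate_sbm <- function(spec) {
  stopifnot(inherits(spec, "planted_spec"))
  sizes <- block_sizes(spec$n, spec$blocks)
  assignment <- rep(seq_len(spec$blocks), times = sizes)
  pm <- matrix(spec$p_out, spec$blocks, spec$blocks)
  diag(pm) <- spec$p_in
  node_ids <- paste0("n", seq_len(spec$n))
  out <- withr::with_seed(spec$seed, {
    ig <- igraph::sample_sbm(spec$n, pref.matrix = pm, block.sizes = sizes)
    el <- igraph::as_edgelist(ig, names = FALSE)
    owner <- rep(seq_len(spec$blocks), times = block_sizes(spec$m,
                                                           spec$blocks))
    prob <- ifelse(outer(owner, assignment, "=="),
                   spec$attr_signal, spec$attr_background)
    inc <- matrix(stats::rbinom(spec$m * spec$n, 1, prob), spec$m, spec$n)
    list(el = el, inc = inc)
  })
  graph <- if (nrow(out$el) > 0) {
    new_lp_graph(node_ids, cbind(pmin(out$el[, 1], out$el[, 2]),
                                 pmax(out$el[, 1], out$el[, 2])))
  } else {
    new_lp_graph(node_ids, matrix(integer(), 0, 2))
  }
  dimnames(out$inc) <- list(paste0("a", seq_len(spec$m)), node_ids)
  list(
    graph = graph,
    attributes = lp_attributes(out$inc, normalize = TRUE),
    incidence = out$inc,
    blocks = assignment
  )
}

block_sizes <- function(n, blocks) {
  base <- n %/% blocks
  sizes <- rep(base, blocks)
  extra <- n - base * blocks
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

#' Generate a graph with a planted low-rank structure
#'
#' Draws a non-negative factor `W` (n x k) and forms the symmetric, exactly
#' rank-`k` planted product `P = W W'`. The adjacency matrix keeps the
#' highest-valued off-diagonal pairs of `P`: `density_scale` is the fraction
#' of all pairs turned into edges, so `density_scale = 1` yields the
#' complete graph. The real-valued planted product is returned for
#' factorization-recovery experiments: refitting it at the planted rank
#' should drive the relative reconstruction error toward zero.
#'
#' @param n Node count.
#' @param k Planted rank, `k < n`.
#' @param density_scale Target edge density in (0, 1\].
#' @param seed Integer seed.
#' @return A list with `graph` (an `lp_graph`), `planted` (the n x n
#'   rank-`k` product), and `W` (the planted factor).
#' @export
generate_low_rank <- function(n, k, density_scale = 0.2, seed = 1) {
  n <- as.integer(n)
  k <- as.integer(k)
  if (k >= n) stop("Need k < n.", call. = FALSE)
  if (density_scale <= 0 || density_scale > 1) {
    stop("`density_scale` must lie in (0, 1].", call. = FALSE)
  }
  W <- withr::with_seed(seed, matrix(stats::runif(n * k), n, k))
  P <- W %*% t(W)
  up <- which(upper.tri(P), arr.ind = TRUE)
  vals <- P[up]
  n_edges <- max(1L, round(density_scale * length(vals)))
  keep <- up[order(-vals)[seq_len(n_edges)], , drop = FALSE]
  graph <- new_lp_graph(paste0("n", seq_len(n)), keep)
  list(graph = graph, planted = P, W = W)
}
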