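#' Neighborhood similarity indices for link prediction
#'
#' The eight classical local indices, computed from the (training) graph's
#' neighbor sets. With `c` the number of common neighbors of the pair and
#' `k_x`, `k_y` the endpoint degrees:
#'
#' * `cn`        — common neighbors, `c`
#' * `salton`    — `c / sqrt(k_x k_y)`
#' * `jaccard`   — `c / |union of neighborhoods|`
#' * `sorensen`  — `2c / (k_x + k_y)`
#' * `hpi`       — hub promoted, `c / min(k_x, k_y)`
#' * `hdi`       — hub depressed, `c / max(k_x, k_y)`
#' * `lhn_i`     — Leicht-Holme-Newman, `c / (k_x k_y)`
#' * `pa`        — preferential attachment, `k_x k_y`
#'
#' Any 0/0 is defined as 0, so pairs sharing nothing (or touching isolated
#' nodes) rank last rather than producing NaN. During evaluation the indices
#' must be computed on the training graph only, never on a graph containing
#' probe edges.
#'
#' @param graph An `lp_graph`.
#' @param index One of `"cn"`, `"salton"`, `"jaccard"`, `"sorensen"`,
#'   `"hpi"`, `"hdi"`, `"lhn_i"`, `"pa"`.
#' @return An `lp_scores` object with the symmetric score matrix.
#' @examples
#' g <- lp_graph(rbind(c("1", "2"), c("2", "3")))
#' baseline_scores(g, "cn")$S["1", "3"]
#' @export
baseline_scores <- function(graph,
                            index = c("cn", "salton", "jaccard", "sorensen",
                                      "hpi", "hdi", "lhn_i", "pa")) {
  index <- match.arg(index)
  stopifnot(inherits(graph, "lp_graph"))
  A <- graph$A
  C <- A %*% A            # C[x, y] = number of common neighbors
  deg <- rowSums(A)
  S <- switch(index,
    cn = C,
    salton = safe_div(C, sqrt(outer(deg, deg))),
    jaccard = safe_div(C, outer(deg, deg, "+") - C),
    sorensen = safe_div(2 * C, outer(deg, deg, "+")),
    hpi = safe_div(C, outer(deg, deg, pmin)),
    hdi = safe_div(C, outer(deg, deg, pmax)),
    lhn_i = safe_div(C, outer(deg, deg)),
    pa = outer(deg, deg)
  )
  diag(S) <- 0
  lp_scores(S, graph$node_ids, index)
}

safe_div <- function(num, den) {
  out <- num / den
  out[den == 0] <- 0
  out
}
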