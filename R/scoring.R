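#' Score all node pairs from the consensus embedding
#'
#' Turns a fitted model into a symmetric matrix of pair scores by comparing
#' the column vectors of the consensus embedding `Vstar`. Cosine similarity
#' is the default: it is bounded and invariant to positive rescaling of the
#' embeddings, so only the direction of a node's latent coordinates matters.
#' The cosine of two zero vectors is defined as 0.
#'
#' @param model An `nmf_lp_fit` (or any list carrying a k x n `Vstar` and
#'   `node_ids`).
#' @param similarity One of `"cosine"`, `"dot"`, `"neg_euclidean"`.
#' @return An object of class `lp_scores`: list with the n x n symmetric
#'   score matrix `S`, `node_ids`, and the `similarity` used. Diagonal
#'   entries carry no ranking meaning.
#' @export
score_from_embeddings <- function(model,
                                  similarity = c("cosine", "dot",
                                                 "neg_euclidean")) {
  similarity <- match.arg(similarity)
  V <- model$Vstar
  S <- switch(similarity,
    cosine = {
      nrm <- sqrt(colSums(V^2))
      nz <- nrm > 0
      X <- V
      X[, nz] <- sweep(V[, nz, drop = FALSE], 2, nrm[nz], "/")
      X[, !nz] <- 0
      crossprod(X)
    },
    dot = crossprod(V),
    neg_euclidean = -as.matrix(stats::dist(t(V)))
  )
  S <- (S + t(S)) / 2  # exact symmetry against floating-point drift
  lp_scores(S, model$node_ids, similarity)
}

#' Wrap a score matrix as an `lp_scores` object
#'
#' Lets externally computed pair scores (e.g. a reference predictor) flow
#' through the ranking and evaluation functions.
#'
#' @param S Symmetric n x n numeric score matrix.
#' @param node_ids Character vector of node identifiers, length n.
#' @param similarity Label recorded on the object.
#' @return An `lp_scores` object.
#' @export
lp_scores <- function(S, node_ids, similarity = "custom") {
  dimnames(S) <- list(node_ids, node_ids)
  structure(list(S = S, node_ids = node_ids, similarity = similarity),
            class = "lp_scores")
}

#' @export
print.lp_scores <- function(x, ...) {
  cat("<lp_scores> ", length(x$node_ids), " nodes (", x$similarity, ")\n",
      sep = "")
  invisible(x)
}

#' Rank non-observed node pairs by score
#'
#' Lists candidate links — off-diagonal pairs that are not training edges —
#' in descending score order. Ties are broken by lexicographic node-index
#' order, so rankings are deterministic across runs.
#'
#' @param scores An `lp_scores` object.
#' @param train An `lp_graph` whose edges are excluded from the candidate
#'   list, or an M x 2 integer matrix of node-index pairs.
#' @param top_l Optional positive integer: keep only the best `top_l`
#'   candidates. If it exceeds the number of candidates the full list is
#'   returned with a warning.
#' @return A tibble with columns `node_a`, `node_b` (identifiers) and
#'   `score`, sorted by decreasing score.
#' @export
rank_candidates <- function(scores, train, top_l = NULL) {
  stopifnot(inherits(scores, "lp_scores"))
  n <- length(scores$node_ids)
  idx <- candidate_pairs(n, edge_index(train))
  if (nrow(idx) == 0) {
    return(tibble::tibble(node_a = character(), node_b = character(),
                          score = numeric()))
  }
  sc <- scores$S[idx]
  ord <- order(-sc, idx[, 1], idx[, 2])
  if (!is.null(top_l)) {
    if (top_l > length(ord)) {
      warning("top_l = ", top_l, " exceeds the ", length(ord),
              " candidate pairs; returning all of them.", call. = FALSE)
      top_l <- length(ord)
    }
    ord <- ord[seq_len(top_l)]
  }
  tibble::tibble(
    node_a = scores$node_ids[idx[ord, 1]],
    node_b = scores$node_ids[idx[ord, 2]],
    score = sc[ord]
  )
}

edge_index <- function(x) {
  if (inherits(x, "lp_graph")) return(x$edges)
  x <- as.matrix(x)
  if (nrow(x) == 0) return(matrix(integer(), 0, 2))
  cbind(pmin(x[, 1], x[, 2]), pmax(x[, 1], x[, 2]))
}

# All off-diagonal unordered pairs (i < j) not present in `exclude`.
candidate_pairs <- function(n, exclude) {
  keep <- upper.tri(matrix(FALSE, n, n))
  if (nrow(exclude) > 0) keep[exclude] <- FALSE
  which(keep, arr.ind = TRUE)
}

#' Write a ranked candidate list as TSV
#'
#' @param ranked Tibble from [rank_candidates()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranked_tsv <- function(ranked, path) {
  utils::write.table(ranked, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
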