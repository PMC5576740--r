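#' Randomly partition the observed edges into cross-validation folds
#'
#' The observed edge set is split into `folds` near-equal random groups;
#' split `i` uses group `i` as the probe set and the remaining edges for
#' training. Probe sets partition the edge set: every observed edge appears
#' in exactly one probe set.
#'
#' @param graph An `lp_graph`.
#' @param folds Number of folds, `>= 2`.
#' @param seed Integer seed making the partition reproducible.
#' @return A list of `eval_split` objects, each a list with `train` and
#'   `probe` (integer edge-index matrices), `fold`, and `n` (node count).
#' @export
kfold_edge_splits <- function(graph, folds = 10, seed = 1) {
  stopifnot(inherits(graph, "lp_graph"))
  folds <- as.integer(folds)
  M <- nrow(graph$edges)
  if (folds < 2) stop("`folds` must be at least 2.", call. = FALSE)
  if (M < folds) {
    stop("Graph has ", M, " edges; cannot make ", folds, " folds.",
         call. = FALSE)
  }
  assignment <- withr::with_seed(seed,
    sample(rep(seq_len(folds), length.out = M)))
  lapply(seq_len(folds), function(i) {
    structure(
      list(train = graph$edges[assignment != i, , drop = FALSE],
           probe = graph$edges[assignment == i, , drop = FALSE],
           fold = i,
           n = graph$n),
      class = "eval_split"
    )
  })
}

#' Training graph of a fold
#'
#' Rebuilds the graph on the same node set using only the fold's training
#' edges, so downstream fitting and baseline indices can never see probe
#' edges.
#'
#' @param graph The full `lp_graph`.
#' @param split An `eval_split`.
#' @return An `lp_graph` with identical `node_ids` and only training edges.
#' @export
train_graph <- function(graph, split) {
  stopifnot(inherits(graph, "lp_graph"), inherits(split, "eval_split"))
  new_lp_graph(graph$node_ids, split$train)
}

# Upper-triangle index matrix of pairs that are not observed edges at all
# (neither train nor probe): the "nonexistent" links.
nonexistent_pairs <- function(split) {
  candidate_pairs(split$n, rbind(split$train, split$probe))
}

#' Exact AUC by exhaustive comparison
#'
#' Compares every (probe edge, nonexistent pair) combination: the AUC is the
#' fraction of comparisons the probe edge wins, counting exact score ties as
#' half. This is the deterministic expectation that sampling-based AUC
#' estimates.
#'
#' @param scores An `lp_scores` object (scored on the training graph).
#' @param split An `eval_split`; together its train and probe sets define
#'   which pairs are nonexistent.
#' @return A scalar in \[0, 1\].
#' @export
auc_exact <- function(scores, split) {
  stopifnot(inherits(scores, "lp_scores"), inherits(split, "eval_split"))
  if (nrow(split$probe) == 0) {
    stop("Probe set is empty; nothing to evaluate.", call. = FALSE)
  }
  nonex <- nonexistent_pairs(split)
  if (nrow(nonex) == 0) {
    stop("No nonexistent pairs: the observed graph is complete.",
         call. = FALSE)
  }
  p <- scores$S[edge_index(split$probe)]
  q <- scores$S[nonex]
  np <- length(p)
  r <- rank(c(p, q))[seq_len(np)]  # midranks count ties as half
  (sum(r) - np * (np + 1) / 2) / (np * length(q))
}

#' Sampling-based AUC
#'
#' Draws `n_samples` independent (probe edge, nonexistent pair) comparisons
#' uniformly at random and applies the counting rule: `n_higher` comparisons
#' where the probe edge scores strictly higher, `n_equal` exact score ties,
#' AUC `= (n_higher + 0.5 n_equal) / n_samples`. Tie detection uses exact
#' floating-point equality, matching the discrete tie count of the
#' definition.
#'
#' @inheritParams auc_exact
#' @param n_samples Number of sampled comparisons.
#' @param seed Integer seed for the draws.
#' @return An object of class `auc_result`: list with `n`, `n_higher`,
#'   `n_equal`, and `auc`.
#' @export
auc_sampling <- function(scores, split, n_samples = 10000, seed = 1) {
  stopifnot(inherits(scores, "lp_scores"), inherits(split, "eval_split"))
  if (nrow(split$probe) == 0) {
    stop("Probe set is empty; nothing to evaluate.", call. = FALSE)
  }
  nonex <- nonexistent_pairs(split)
  if (nrow(nonex) == 0) {
    stop("No nonexistent pairs: the observed graph is complete.",
         call. = FALSE)
  }
  p <- scores$S[edge_index(split$probe)]
  q <- scores$S[nonex]
  draws <- withr::with_seed(seed, {
    cbind(sample.int(length(p), n_samples, replace = TRUE),
          sample.int(length(q), n_samples, replace = TRUE))
  })
  ps <- p[draws[, 1]]
  qs <- q[draws[, 2]]
  n_higher <- sum(ps > qs)
  n_equal <- sum(ps == qs)
  structure(
    list(n = n_samples, n_higher = n_higher, n_equal = n_equal,
         auc = (n_higher + 0.5 * n_equal) / n_samples),
    class = "auc_result"
  )
}

#' @export
print.auc_result <- function(x, ...) {
  cat("<auc_result> AUC = ", format(x$auc, digits = 4), "  (n' = ",
      x$n_higher, ", n'' = ", x$n_equal, ", n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Precision at L
#'
#' Ranks all non-observed pairs (everything except training edges and the
#' diagonal) by score, descending, with the deterministic lexicographic
#' tie-break, and returns the fraction of the top `L` that are probe edges.
#'
#' @inheritParams auc_exact
#' @param l The list length L, `>= 1`. If it exceeds the number of candidate
#'   pairs, precision is computed over all candidates with a warning.
#' @return A scalar in \[0, 1\].
#' @export
precision_at_l <- function(scores, split, l) {
  stopifnot(inherits(scores, "lp_scores"), inherits(split, "eval_split"))
  l <- as.integer(l)
  if (l < 1) stop("`l` must be at least 1.", call. = FALSE)
  idx <- candidate_pairs(split$n, split$train)
  if (l > nrow(idx)) {
    warning("l = ", l, " exceeds the ", nrow(idx),
            " candidate pairs; using all of them.", call. = FALSE)
    l <- nrow(idx)
  }
  sc <- scores$S[idx]
  ord <- order(-sc, idx[, 1], idx[, 2])[seq_len(l)]
  top <- idx[ord, , drop = FALSE]
  probe_keys <- pair_key(split$probe, split$n)
  mean(pair_key(top, split$n) %in% probe_keys)
}

pair_key <- function(idx, n) {
  (as.numeric(idx[, 1]) - 1) * n + as.numeric(idx[, 2])
}

#' Cross-validated benchmark of link predictors
#'
#' Runs the full evaluation protocol: for each fold, every method is fitted
#' (or its index computed) on the training graph only and evaluated on the
#' fold's probe set with exact AUC and precision at L. The factorization
#' model is refitted per fold with a fold-derived seed.
#'
#' @param graph The full `lp_graph`.
#' @param attrs Optional `lp_attributes`, used by the factorization method.
#' @param methods Character vector drawn from `"nmf_lp"` and the baseline
#'   index names, and/or a named list whose elements are either such names
#'   or functions `function(train_graph, split)` returning an `lp_scores`
#'   (or bare score matrix) — the hook used to inject reference predictors.
#' @param folds Number of cross-validation folds.
#' @param config [fit_config()] for the factorization method; its seed is
#'   offset by the fold number so folds get independent initializations.
#' @param seed Seed for the fold partition.
#' @param top_l L for precision; `NULL` (default) uses each fold's probe
#'   count.
#' @return A tibble of class `lp_benchmark` with columns `method`, `fold`,
#'   `auc`, `precision`.
#' @export
run_benchmark <- function(graph, attrs = NULL,
                          methods = c("nmf_lp", "cn", "salton", "jaccard",
                                      "sorensen", "hpi", "hdi", "lhn_i",
                                      "pa"),
                          folds = 10, config = fit_config(), seed = 1,
                          top_l = NULL) {
  stopifnot(inherits(graph, "lp_graph"))
  if (!is.list(methods)) methods <- as.list(methods)
  nms <- names(methods) %||% rep("", length(methods))
  names(methods) <- ifelse(nzchar(nms), nms,
                           vapply(methods, function(m)
                             if (is.character(m)) m else "custom", ""))
  splits <- kfold_edge_splits(graph, folds = folds, seed = seed)
  rows <- purrr::map_dfr(splits, function(split) {
    tg <- train_graph(graph, split)
    # probe edges must not leak into training
    stopifnot(all(tg$A[edge_index(split$probe)] == 0))
    purrr::map_dfr(names(methods), function(nm) {
      method <- methods[[nm]]
      sc <- if (is.function(method)) {
        out <- method(tg, split)
        if (inherits(out, "lp_scores")) out else lp_scores(out, tg$node_ids)
      } else if (identical(method, "nmf_lp")) {
        cfg <- config
        cfg$seed <- (config$seed + split$fold) %% .Machine$integer.max
        score_from_embeddings(nmf_lp(tg, attrs = attrs, config = cfg))
      } else {
        baseline_scores(tg, method)
      }
      l <- top_l %||% nrow(split$probe)
      tibble::tibble(
        method = nm,
        fold = split$fold,
        auc = auc_exact(sc, split),
        precision = precision_at_l(sc, split, l)
      )
    })
  })
  structure(rows, class = c("lp_benchmark", class(rows)))
}

#' Per-method summary of a benchmark run
#'
#' @param bench An `lp_benchmark` tibble.
#' @return A tibble with one row per method: mean and standard deviation of
#'   the fold AUCs and the mean precision, sorted by decreasing mean AUC.
#' @export
summarize_benchmark <- function(bench) {
  bench |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      mean_auc = mean(.data$auc),
      sd_auc = stats::sd(.data$auc),
      mean_precision = mean(.data$precision),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$mean_auc))
}
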