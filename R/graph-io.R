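#' Build an undirected simple graph from an edge table
#'
#' Constructs the package's graph container from a two-column table of node
#' identifiers. The graph is undirected and simple: both orderings of a pair
#' denote the same edge, duplicate edges are collapsed, and self-loops are
#' dropped with a warning. Node order is first appearance in the input
#' (scanning each row left to right) unless `nodes` supplies an explicit
#' ordering.
#'
#' @param edges A two-column matrix or data frame; each row is one edge given
#'   by its two endpoint identifiers (coerced to character).
#' @param nodes Optional character vector fixing the node ordering. Must
#'   contain every identifier appearing in `edges`; may contain extra
#'   (isolated) nodes.
#' @return An object of class `lp_graph`: a list with `node_ids` (character),
#'   `n` (node count), `edges` (an M x 2 integer matrix of node indices with
#'   `i < j`), and `A` (the dense symmetric 0/1 adjacency matrix with zero
#'   diagonal).
#' @examples
#' g <- lp_graph(rbind(c("a", "b"), c("b", "c"), c("c", "a")))
#' g$n
#' @export
lp_graph <- function(edges, nodes = NULL) {
  edges <- as.matrix(edges)
  if (ncol(edges) < 2) {
    stop("`edges` must have two columns of node identifiers.", call. = FALSE)
  }
  a <- as.character(edges[, 1])
  b <- as.character(edges[, 2])
  seen <- unique(as.vector(t(cbind(a, b))))
  if (is.null(nodes)) {
    node_ids <- seen
  } else {
    node_ids <- as.character(nodes)
    missing <- setdiff(seen, node_ids)
    if (length(missing) > 0) {
      stop("`nodes` is missing identifiers present in `edges`: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
  }
  i <- match(a, node_ids)
  j <- match(b, node_ids)
  loops <- i == j
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped.", call. = FALSE)
    i <- i[!loops]
    j <- j[!loops]
  }
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  keep <- !duplicated(lo * (length(node_ids) + 1) + hi)
  new_lp_graph(node_ids, cbind(lo[keep], hi[keep]))
}

# edge_idx: M x 2 integer matrix, i < j, unique
new_lp_graph <- function(node_ids, edge_idx) {
  n <- length(node_ids)
  edge_idx <- matrix(as.integer(edge_idx), ncol = 2)
  A <- matrix(0, n, n, dimnames = list(node_ids, node_ids))
  if (nrow(edge_idx) > 0) {
    A[edge_idx] <- 1
    A[edge_idx[, c(2, 1), drop = FALSE]] <- 1
  }
  structure(
    list(node_ids = node_ids, n = n, edges = edge_idx, A = A),
    class = "lp_graph"
  )
}

#' @export
print.lp_graph <- function(x, ...) {
  cat("<lp_graph> ", x$n, " nodes, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' @method as_tibble lp_graph
#' @export
as_tibble.lp_graph <- function(x, ...) {
  tibble::tibble(
    node_a = x$node_ids[x$edges[, 1]],
    node_b = x$node_ids[x$edges[, 2]]
  )
}

#' Adjacency matrix of a graph
#'
#' @param graph An `lp_graph`.
#' @return The dense symmetric 0/1 adjacency matrix with node identifiers as
#'   dimnames.
#' @export
adjacency_matrix <- function(graph) {
  stopifnot(inherits(graph, "lp_graph"))
  graph$A
}

#' Read an undirected edge list from a plain-text file
#'
#' One edge per line: two whitespace-separated node identifiers (extra tokens
#' on a line are ignored). Lines whose first non-blank character is the
#' comment prefix, and blank lines, are skipped. Duplicate edges are
#' collapsed and self-loops dropped with a warning.
#'
#' @param path Path to the edge-list file.
#' @param comment Comment prefix; lines starting with it are ignored.
#' @return An [lp_graph()] with nodes in first-appearance order.
#' @export
read_edge_list <- function(path, comment = "#") {
  if (!file.exists(path)) {
    stop("Cannot read edge list: file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  trimmed <- trimws(lines)
  active <- which(nzchar(trimmed) & !startsWith(trimmed, comment))
  if (length(active) == 0) {
    stop("Edge list contains no edges: ", path, call. = FALSE)
  }
  toks <- strsplit(trimmed[active], "\\s+")
  bad <- which(lengths(toks) < 2)
  if (length(bad) > 0) {
    stop("Parse error in ", path, " at line ", active[bad[1]],
         ": expected at least two node identifiers.", call. = FALSE)
  }
  lp_graph(cbind(
    vapply(toks, `[[`, "", 1L),
    vapply(toks, `[[`, "", 2L)
  ))
}

#' Write a graph as a plain-text edge list
#'
#' @param graph An `lp_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "lp_graph"))
  lines <- paste(graph$node_ids[graph$edges[, 1]],
                 graph$node_ids[graph$edges[, 2]])
  writeLines(lines, path)
  invisible(path)
}

#' Node-attribute matrix container
#'
#' Stores node attributes as an m x n non-negative matrix with attributes in
#' rows and nodes in columns, column `j` aligned with `node_ids[j]` of the
#' companion graph. This orientation makes the attribute factorization
#' shape-compatible with the topology factorization: both coefficient
#' matrices, and the consensus embedding, are k x n with node embeddings in
#' columns.
#'
#' @param mat Non-negative numeric matrix, attributes x nodes.
#' @param attribute_names Character vector of length `nrow(mat)`.
#' @param node_ids Character vector of length `ncol(mat)`.
#' @param normalize If `TRUE` (default), each node's attribute vector is
#'   scaled to unit L1 sum via [normalize_attributes()].
#' @return An object of class `lp_attributes` (a matrix with dimnames).
#' @export
lp_attributes <- function(mat, attribute_names = rownames(mat),
                          node_ids = colnames(mat), normalize = TRUE) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) {
    stop("Attribute values must be non-negative.", call. = FALSE)
  }
  if (is.null(attribute_names)) {
    attribute_names <- paste0("attr_", seq_len(nrow(mat)))
  }
  if (is.null(node_ids)) {
    node_ids <- paste0("node_", seq_len(ncol(mat)))
  }
  dimnames(mat) <- list(attribute_names, node_ids)
  out <- structure(mat, class = c("lp_attributes", "matrix", "array"))
  if (normalize) normalize_attributes(out) else out
}

#' Normalize node attribute vectors to unit L1 sum
#'
#' Each node's attribute vector (a column of the attributes x nodes matrix)
#' is divided by its sum when that sum is positive; all-zero vectors are left
#' all-zero. After normalization every entry lies in \[0, 1\]. The operation
#' is idempotent.
#'
#' @param raw Non-negative matrix (attributes in rows, nodes in columns) or
#'   an `lp_attributes` object.
#' @return An `lp_attributes` object with unit-sum (or all-zero) columns.
#' @export
normalize_attributes <- function(raw) {
  mat <- unclass(as.matrix(raw))
  if (any(mat < 0)) {
    stop("Attribute values must be non-negative.", call. = FALSE)
  }
  s <- colSums(mat)
  s[s == 0] <- 1
  mat <- sweep(mat, 2, s, "/")
  structure(mat, class = c("lp_attributes", "matrix", "array"))
}

#' @export
print.lp_attributes <- function(x, ...) {
  cat("<lp_attributes> ", nrow(x), " attributes x ", ncol(x), " nodes\n",
      sep = "")
  invisible(x)
}

#' Read a node-attribute file
#'
#' Two formats are supported. In `"bag"` mode each line names a node followed
#' by the whitespace-separated names of its present attributes (suited to
#' binary keyword-style annotations); the result is a binary incidence matrix
#' before normalization. In `"dense"` mode the first non-comment line is a
#' header of attribute names and each following line is a node identifier
#' followed by that many non-negative numeric values.
#'
#' @param path Path to the attribute file.
#' @param graph The companion [lp_graph()]; every node identifier in the file
#'   must be one of its nodes. Nodes absent from the file get all-zero
#'   attribute vectors.
#' @param mode `"bag"` or `"dense"`.
#' @param comment Comment prefix.
#' @param normalize Normalize per-node vectors to unit L1 sum (default).
#' @return An `lp_attributes` object with columns aligned to
#'   `graph$node_ids`.
#' @export
read_attributes <- function(path, graph, mode = c("bag", "dense"),
                            comment = "#", normalize = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(graph, "lp_graph"))
  if (!file.exists(path)) {
    stop("Cannot read attributes: file not found: ", path, call. = FALSE)
  }
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, comment)]
  toks <- strsplit(lines, "\\s+")
  if (mode == "bag") {
    node_of <- vapply(toks, `[[`, "", 1L)
    unknown <- setdiff(node_of, graph$node_ids)
    if (length(unknown) > 0) {
      stop("Attribute file names unknown node(s): ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    }
    attr_names <- unique(unlist(lapply(toks, `[`, -1L)))
    mat <- matrix(0, length(attr_names), graph$n,
                  dimnames = list(attr_names, graph$node_ids))
    for (t in toks) {
      present <- t[-1L]
      if (length(present) > 0) mat[present, t[[1L]]] <- 1
    }
  } else {
    header <- toks[[1]]
    m <- length(header)
    body <- toks[-1]
    node_of <- vapply(body, `[[`, "", 1L)
    unknown <- setdiff(node_of, graph$node_ids)
    if (length(unknown) > 0) {
      stop("Attribute file names unknown node(s): ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    }
    bad <- which(lengths(body) != m + 1L)
    if (length(bad) > 0) {
      stop("Parse error in ", path, ": line for node '", node_of[bad[1]],
           "' does not have ", m, " values.", call. = FALSE)
    }
    mat <- matrix(0, m, graph$n, dimnames = list(header, graph$node_ids))
    for (t in body) {
      v <- suppressWarnings(as.numeric(t[-1L]))
      if (anyNA(v)) {
        stop("Non-numeric attribute value for node '", t[[1L]], "'.",
             call. = FALSE)
      }
      if (any(v < 0)) {
        stop("Negative attribute value for node '", t[[1L]],
             "'; inputs must be non-negative.", call. = FALSE)
      }
      mat[, t[[1L]]] <- v
    }
  }
  lp_attributes(mat, normalize = normalize)
}

#' Write a node-attribute table
#'
#' Inverse of [read_attributes()]. In `"bag"` mode attributes with a strictly
#' positive value are written as present; use it only for binary incidence
#' data.
#'
#' @param attrs An `lp_attributes` object.
#' @param path Output file path.
#' @param mode `"bag"` or `"dense"`.
#' @return `path`, invisibly.
#' @export
write_attributes <- function(attrs, path, mode = c("bag", "dense")) {
  mode <- match.arg(mode)
  stopifnot(inherits(attrs, "lp_attributes"))
  nodes <- colnames(attrs)
  if (mode == "bag") {
    lines <- vapply(seq_along(nodes), function(j) {
      present <- rownames(attrs)[attrs[, j] > 0]
      paste(c(nodes[j], present), collapse = " ")
    }, "")
  } else {
    header <- paste(rownames(attrs), collapse = " ")
    body <- vapply(seq_along(nodes), function(j) {
      paste(c(nodes[j], format(attrs[, j], trim = TRUE, digits = 15)),
            collapse = " ")
    }, "")
    lines <- c(header, body)
  }
  writeLines(lines, path)
  invisible(path)
}
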