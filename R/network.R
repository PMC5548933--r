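#' Validate a weighted network
#'
#' Checks that a graph is a valid analysis substrate: undirected, simple
#' (no self-loops, no multi-edges) and with strictly positive edge weights.
#' Unweighted graphs are promoted to unit weights so that topological
#' (binary) analysis goes through the same code path.
#'
#' @param net an \code{igraph} object.
#' @param require_connected if \code{TRUE}, error on disconnected input.
#' @return the validated \code{igraph} object, with a \code{weight} edge
#'   attribute guaranteed to exist.
#' @export
as_weighted_network <- function(net, require_connected = FALSE) {
  if (!igraph::is_igraph(net)) {
    stop("`net` must be an igraph object")
  }
  if (igraph::is_directed(net)) {
    stop("`net` must be undirected")
  }
  if (any(igraph::which_loop(net))) {
    stop("`net` must not contain self-loops")
  }
  if (any(igraph::which_multiple(net))) {
    stop("`net` must not contain multi-edges")
  }
  if (is.null(igraph::E(net)$weight)) {
    igraph::E(net)$weight <- 1
  }
  w <- igraph::E(net)$weight
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("edge weights must be finite and strictly positive")
  }
  if (require_connected && igraph::ecount(net) > 0 && !igraph::is_connected(net)) {
    comp <- igraph::components(net)
    a <- which(comp$membership == 1)[1]
    b <- which(comp$membership == 2)[1]
    stop(sprintf(
      "network is disconnected: no path between nodes '%s' and '%s'",
      node_label(net, a), node_label(net, b)
    ))
  }
  net
}

node_label <- function(net, idx) {
  nm <- igraph::V(net)$name
  if (is.null(nm)) as.character(idx) else nm[idx]
}

#' Strip link weights from a network
#'
#' Returns the same topology with every edge weight set to 1, i.e. the
#' binary (unweighted) version of the network. Idempotent. Removing the
#' weights redefines the metric space as pure hop distance, which is how
#' the small-world versus fractal scaling comparison is set up.
#'
#' @param net a weighted network (\code{igraph}).
#' @return an \code{igraph} with identical nodes/edges and unit weights.
#' @export
binarize <- function(net) {
  net <- as_weighted_network(net)
  igraph::E(net)$weight <- 1
  net
}

#' Build a co-authorship network from paper memberships
#'
#' Two authors are linked iff they share at least one paper; the link
#' weight is the sum over shared papers k of 1/n_k, where n_k is the
#' number of authors of paper k. Note the denominator is n_k, not the
#' n_k - 1 variant sometimes used for collaboration networks.
#'
#' @param memberships a list; each element is a character vector of the
#'   authors of one paper.
#' @return a weighted \code{igraph} network.
#' @export
coauthorship_network <- function(memberships) {
  if (!is.list(memberships) || length(memberships) == 0) {
    stop("`memberships` must be a non-empty list of author vectors")
  }
  pair_w <- new.env(parent = emptyenv())
  authors <- character(0)
  for (k in seq_along(memberships)) {
    a <- unique(as.character(memberships[[k]]))
    if (length(a) == 0) {
      stop(sprintf("paper %d has an empty author list", k))
    }
    authors <- union(authors, a)
    if (length(a) < 2) next
    nk <- length(a)
    a <- sort(a)
    for (i in 1:(nk - 1)) {
      for (j in (i + 1):nk) {
        key <- paste(a[i], a[j], sep = "\r")
        prev <- if (is.null(pair_w[[key]])) 0 else pair_w[[key]]
        pair_w[[key]] <- prev + 1 / nk
      }
    }
  }
  keys <- ls(pair_w)
  if (length(keys) == 0) {
    g <- igraph::make_empty_graph(n = length(authors), directed = FALSE)
    igraph::V(g)$name <- authors
    igraph::E(g)$weight <- numeric(0)
    return(g)
  }
  ends <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  el <- data.frame(
    from = ends[, 1], to = ends[, 2],
    weight = vapply(keys, function(k) pair_w[[k]], numeric(1)),
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                     vertices = data.frame(name = sort(authors)))
  as_weighted_network(g)
}

#' Read a weighted edge list
#'
#' Canonical format: one edge per line, `node_a<TAB>node_b<TAB>weight`.
#' Node identifiers are arbitrary strings. Lines starting with `#` are
#' skipped. GraphML is supported read-only through igraph.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"tsv"` or `"graphml"`.
#' @return a validated weighted \code{igraph} network.
#' @export
read_network <- function(path, format = c("auto", "tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml" else "tsv"
  }
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
    return(as_weighted_network(g))
  }
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0) stop("no edges found in ", path)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0) {
    stop(sprintf("line %d: expected `node\\tnode\\tweight`", keep[bad[1]]))
  }
  from <- vapply(parts, `[[`, character(1), 1)
  to <- vapply(parts, `[[`, character(1), 2)
  w <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 3)))
  if (anyNA(w)) {
    stop(sprintf("line %d: weight is not a number", keep[which(is.na(w))[1]]))
  }
  nonpos <- which(w <= 0)
  if (length(nonpos) > 0) {
    stop(sprintf("line %d: weight must be > 0", keep[nonpos[1]]))
  }
  self <- which(from == to)
  if (length(self) > 0) {
    stop(sprintf("line %d: self-loop not allowed", keep[self[1]]))
  }
  key <- ifelse(from < to, paste(from, to, sep = "\r"), paste(to, from, sep = "\r"))
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    idx <- which(key == dup)
    if (length(unique(w[idx])) > 1) {
      stop(sprintf("line %d: duplicate edge with conflicting weights", keep[idx[2]]))
    }
    stop(sprintf("line %d: duplicate edge", keep[idx[2]]))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = w, stringsAsFactors = FALSE),
    directed = FALSE
  )
  as_weighted_network(g)
}

#' Write a weighted edge list
#'
#' One edge per line, tab-separated, weights printed at 12 significant
#' digits so that a read/write round trip preserves the metric.
#'
#' @param net a weighted network.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  net <- as_weighted_network(net)
  el <- igraph::as_edgelist(net, names = TRUE)
  w <- igraph::E(net)$weight
  writeLines(sprintf("%s\t%s\t%.12g", el[, 1], el[, 2], w), path)
  invisible(path)
}
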