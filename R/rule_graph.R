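#' Trait association graph
#'
#' The mined rules are summarized as an undirected weighted graph: vertices
#' are trait-level items, and each rule contributes one count to the edge
#' weight of every unordered pair of items within its body-plus-head
#' (clique expansion). Edge attribute `max_lift` records the strongest lift
#' among contributing rules; vertex attribute `degree` is cached for
#' size-proportional rendering.
#'
#' @param rules a non-empty `rule_set`.
#' @param collapse_traits if TRUE, merge all levels of a trait ("TG1".."TG5")
#'   into a single trait vertex by stripping the trailing level digits.
#' @return a `trait_graph` (an igraph object with the attributes above).
#' @export
build_trait_graph <- function(rules, collapse_traits = FALSE) {
  stopifnot(inherits(rules, "rule_set"))
  if (!nrow(rules)) stop2("cannot build a graph from an empty rule set")
  pair_rows <- lapply(seq_len(nrow(rules)), function(i) {
    items <- sort(unique(c(strsplit(rules$body[i], ";", fixed = TRUE)[[1L]],
                           rules$head[i])))
    if (collapse_traits) items <- sort(unique(sub("[0-9]+$", "", items)))
    if (length(items) < 2L) return(NULL)
    pr <- t(utils::combn(items, 2L))
    data.frame(u = pr[, 1L], v = pr[, 2L], lift = rules$lift[i],
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, pair_rows)
  if (is.null(pairs)) stop2("no item pairs: all rules collapse to one vertex")
  key <- paste(pairs$u, pairs$v, sep = "\t")
  agg <- data.frame(
    u = tapply(pairs$u, key, `[`, 1L),
    v = tapply(pairs$v, key, `[`, 1L),
    weight = as.integer(tapply(key, key, length)),
    max_lift = as.numeric(tapply(pairs$lift, key, max)),
    stringsAsFactors = FALSE
  )
  agg <- agg[order(agg$u, agg$v), , drop = FALSE]
  g <- igraph::graph_from_data_frame(agg, directed = FALSE)
  igraph::V(g)$degree <- igraph::degree(g)
  class(g) <- c("trait_graph", class(g))
  g
}

#' Neighbors of an item, strongest association first
#'
#' @param graph a `trait_graph`.
#' @param item vertex name.
#' @return character vector of neighboring items ordered by edge weight
#'   (descending), ties broken lexicographically.
#' @export
trait_neighbors <- function(graph, item) {
  stopifnot(inherits(graph, "trait_graph"))
  if (!(item %in% igraph::V(graph)$name)) stop2("unknown item: ", item)
  es <- igraph::incident(graph, item)
  if (!length(es)) return(character())
  ends <- igraph::ends(graph, es)
  other <- ifelse(ends[, 1L] == item, ends[, 2L], ends[, 1L])
  w <- igraph::edge_attr(graph, "weight", es)
  other[order(-w, other)]
}

#' Export / import a trait graph
#'
#' GraphML keeps the weight, max_lift and degree attributes; the edge-list
#' dialect is "u<TAB>v<TAB>weight". Re-importing either reproduces the
#' graph structure and weights.
#'
#' @param graph a `trait_graph`.
#' @param path output file.
#' @param format "graphml" or "edgelist".
#' @name graph_io
#' @export
export_graph <- function(graph, path, format = c("graphml", "edgelist")) {
  stopifnot(inherits(graph, "trait_graph"))
  format <- match.arg(format)
  if (igraph::ecount(graph) == 0L) stop2("refusing to export an empty graph")
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    ends <- igraph::ends(graph, igraph::E(graph))
    lines <- sprintf("%s\t%s\t%d", ends[, 1L], ends[, 2L],
                     igraph::E(graph)$weight)
    writeLines(lines[order(lines)], path)
  }
  invisible(path)
}

#' @rdname graph_io
#' @export
import_graph <- function(path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  g <- if (format == "graphml") {
    igraph::read_graph(path, format = "graphml")
  } else {
    df <- utils::read.delim(path, header = FALSE,
                            col.names = c("u", "v", "weight"))
    igraph::graph_from_data_frame(df, directed = FALSE)
  }
  igraph::V(g)$degree <- igraph::degree(g)
  class(g) <- c("trait_graph", class(g))
  g
}

#' Render the trait graph to PNG
#'
#' Vertex size is proportional to degree; layout uses a fixed seed so runs
#' are reproducible.
#'
#' @param graph a `trait_graph`.
#' @param path PNG output path.
#' @param seed layout seed.
#' @export
plot_trait_graph <- function(graph, path, seed = 1L) {
  stopifnot(inherits(graph, "trait_graph"))
  grDevices::png(path, width = 900, height = 900)
  on.exit(grDevices::dev.off())
  set.seed(seed)
  deg <- igraph::V(graph)$degree
  plot(graph, vertex.size = 5 + 20 * deg / max(deg),
       edge.width = igraph::E(graph)$weight /
         max(igraph::E(graph)$weight) * 4)
  invisible(path)
}
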