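#' Interaction graphs from edge lists
#'
#' Builds a deduplicated undirected interaction graph. Edges are unordered
#' pairs; duplicates (in either order) collapse to one edge; self-pairs
#' are routed to a separate self-loop set (homodimerization is reported
#' but never counted as a partner).
#'
#' @param a,b Character vectors of interactor ids (equal length).
#' @param subunit_ids Character vector of node ids flagged as Mediator
#'   subunits (used by [classify_hubs()]).
#' @return Object of class `interaction_graph`: list with `nodes`,
#'   `edges` (two-column data frame), `self_loops`, `subunit_ids`.
#' @export
interaction_graph <- function(a, b, subunit_ids = character(0)) {
  stopifnot(length(a) == length(b))
  a <- as.character(a); b <- as.character(b)
  self <- a == b
  self_loops <- unique(a[self])
  a2 <- pmin(a[!self], b[!self])
  b2 <- pmax(a[!self], b[!self])
  key <- paste(a2, b2, sep = "\r")
  keep <- !duplicated(key)
  edges <- data.frame(a = a2[keep], b = b2[keep], stringsAsFactors = FALSE)
  nodes <- unique(c(a, b, subunit_ids))
  structure(list(nodes = nodes, edges = edges, self_loops = self_loops,
                 subunit_ids = unique(subunit_ids)),
            class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf("<interaction_graph> %d nodes, %d edges, %d self-loops, %d subunits\n",
              length(x$nodes), nrow(x$edges), length(x$self_loops),
              length(x$subunit_ids)))
  invisible(x)
}

#' Read a two-column interaction edge list
#'
#' TSV/whitespace edge list, two interactor ids per line (extra columns
#' ignored), `#` comments skipped. Malformed lines raise a format error
#' naming the line number.
#'
#' @param path Edge list path.
#' @inheritParams interaction_graph
#' @return An [interaction_graph()].
#' @export
read_edges <- function(path, subunit_ids = character(0)) {
  if (!file.exists(path))
    stop(sprintf("edge list not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(fields) < 2L)
  if (length(bad) > 0L)
    stop(sprintf("malformed edge at line %d of %s (need two ids)",
                 idx[bad[1L]], path), call. = FALSE)
  ## drop a header line if present
  if (length(fields) > 0L &&
      identical(tolower(fields[[1L]][1:2]), c("a", "b")))
    fields <- fields[-1L]
  if (length(fields) == 0L)
    return(interaction_graph(character(0), character(0), subunit_ids))
  interaction_graph(vapply(fields, `[[`, "", 1L),
                    vapply(fields, `[[`, "", 2L), subunit_ids)
}

#' Number of distinct interaction partners of a node
#'
#' Self-loops are excluded: a protein is not its own partner.
#'
#' @param graph An [interaction_graph()].
#' @param node Node id.
#' @return Non-negative integer.
#' @export
partner_count <- function(graph, node) {
  stopifnot(inherits(graph, "interaction_graph"))
  if (!node %in% graph$nodes)
    stop(sprintf("unknown node: %s", node), call. = FALSE)
  partners <- c(graph$edges$b[graph$edges$a == node],
                graph$edges$a[graph$edges$b == node])
  length(unique(partners))
}

#' Classify interaction hubs
#'
#' A node is a *hub* when it has at least `hub_threshold` (default 10)
#' distinct direct partners; it is a *subunit-subunit hub* when at least
#' `subunit_threshold` (default 5) of its partners are themselves Mediator
#' subunits.
#'
#' @param graph An [interaction_graph()] with `subunit_ids` set (possibly
#'   empty).
#' @param hub_threshold,subunit_threshold Partner-count thresholds
#'   (each >= 1).
#' @return Data frame with one row per node: `node`, `is_subunit`,
#'   `partner_count`, `subunit_partner_count`, `is_hub`,
#'   `is_subunit_hub`, `has_self_loop`.
#' @export
classify_hubs <- function(graph, hub_threshold = 10L, subunit_threshold = 5L) {
  stopifnot(inherits(graph, "interaction_graph"),
            hub_threshold >= 1L, subunit_threshold >= 1L)
  nodes <- graph$nodes
  subs <- graph$subunit_ids
  adj <- split(c(graph$edges$b, graph$edges$a),
               c(graph$edges$a, graph$edges$b))
  pc <- vapply(nodes, function(nd) length(unique(adj[[nd]])), 0L)
  spc <- vapply(nodes, function(nd)
    length(unique(intersect(adj[[nd]], subs))), 0L)
  data.frame(node = nodes,
             is_subunit = nodes %in% subs,
             partner_count = pc,
             subunit_partner_count = spc,
             is_hub = pc >= hub_threshold,
             is_subunit_hub = spc >= subunit_threshold,
             has_self_loop = nodes %in% graph$self_loops,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write an interaction graph back to a TSV edge list
#'
#' Self-loops are written as `id id` lines so the file round-trips.
#'
#' @param graph An [interaction_graph()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_edges <- function(graph, path) {
  df <- rbind(graph$edges,
              data.frame(a = graph$self_loops, b = graph$self_loops,
                         stringsAsFactors = FALSE))
  write_tsv(df, path)
}
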