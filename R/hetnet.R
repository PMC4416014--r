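#' Construct a two-class heterogeneous network (2-HN)
#'
#' A 2-HN has two node classes, `A` and `B`, and three undirected weighted
#' edge channels: `AA` (both endpoints class A), `AB` (one endpoint of each
#' class, a bipartite channel), and `BB` (both endpoints class B). The channel
#' of an edge is fully determined by the classes of its endpoints; in
#' applications the three channels are typically built from different data
#' sources (e.g. chemical similarity, chemical-target interaction, gene
#' interaction) so their densities and weight scales are not comparable.
#'
#' @param nodes data.frame with columns `node_id` (character, unique) and
#'   `class` (`"A"` or `"B"`); an optional integer `module` column carries
#'   ground-truth module labels.
#' @param edges data.frame with columns `u`, `v` (node ids) and optionally
#'   `weight` (positive, default 1).
#' @param allow_selfloops logical; self-loops are rejected in input networks
#'   but arise internally when modules are aggregated into supernodes.
#' @return An object of class `hetnet`: a list with elements `nodes` (as
#'   given, plus canonical ordering) and `edges` (with a derived `channel`
#'   column, one of `"AA"`, `"AB"`, `"BB"`).
#' @export
hetnet <- function(nodes, edges, allow_selfloops = FALSE) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  if (!all(c("node_id", "class") %in% names(nodes)))
    stop("node table must have columns 'node_id' and 'class'")
  nodes$node_id <- as.character(nodes$node_id)
  nodes$class <- as.character(nodes$class)
  if (anyDuplicated(nodes$node_id))
    stop("duplicate node_id in node table")
  if (!all(nodes$class %in% c("A", "B")))
    stop("node class must be 'A' or 'B'")

  if (nrow(edges) == 0) {
    edges <- data.frame(u = character(), v = character(),
                        weight = numeric(), channel = character(),
                        stringsAsFactors = FALSE)
  } else {
    if (!all(c("u", "v") %in% names(edges)))
      stop("edge table must have columns 'u' and 'v'")
    edges$u <- as.character(edges$u)
    edges$v <- as.character(edges$v)
    if (is.null(edges$weight)) edges$weight <- 1
    edges$weight <- as.numeric(edges$weight)
    if (anyNA(edges$weight) || any(edges$weight <= 0))
      stop("edge weights must be positive")
    unknown <- setdiff(c(edges$u, edges$v), nodes$node_id)
    if (length(unknown))
      stop("edge table references unknown node(s): ",
           paste(utils::head(unknown, 5), collapse = ", "))
    if (!allow_selfloops && any(edges$u == edges$v))
      stop("self-loops are not allowed in input networks")
    cls <- stats::setNames(nodes$class, nodes$node_id)
    edges$channel <- edge_channel(cls[edges$u], cls[edges$v])
    # canonical orientation: u <= v lexicographically, A endpoint first for AB
    swap <- ifelse(edges$channel == "AB",
                   cls[edges$u] == "B",
                   edges$u > edges$v)
    tmp <- edges$u[swap]; edges$u[swap] <- edges$v[swap]; edges$v[swap] <- tmp
    if (anyDuplicated(edges[, c("u", "v")]))
      stop("duplicate edge for an unordered node pair")
    edges <- edges[, c("u", "v", "weight", "channel")]
  }
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "hetnet")
}

edge_channel <- function(cu, cv) {
  ifelse(cu == cv, ifelse(cu == "A", "AA", "BB"), "AB")
}

#' @export
print.hetnet <- function(x, ...) {
  tab <- table(factor(x$edges$channel, levels = c("AA", "AB", "BB")))
  cat(sprintf(
    "<hetnet> %d nodes (%d A, %d B); edges AA=%d AB=%d BB=%d\n",
    nrow(x$nodes), sum(x$nodes$class == "A"), sum(x$nodes$class == "B"),
    tab["AA"], tab["AB"], tab["BB"]))
  invisible(x)
}

#' Read a 2-HN from node and edge tables
#'
#' @param node_table_path TSV with header columns `node_id`, `class`, and
#'   optionally `module` (integer ground-truth label).
#' @param edge_table_path TSV with header columns `u`, `v`, and optionally
#'   `weight` (defaults to 1).
#' @return A `hetnet`; if the node table has a `module` column the labels are
#'   kept in `net$nodes$module`.
#' @export
read_hetnet <- function(node_table_path, edge_table_path) {
  nodes <- utils::read.delim(node_table_path, colClasses = "character",
                             check.names = FALSE)
  if (!is.null(nodes$module)) nodes$module <- as.integer(nodes$module)
  edges <- utils::read.delim(edge_table_path, colClasses = "character",
                             check.names = FALSE)
  if (!is.null(edges$weight)) edges$weight <- as.numeric(edges$weight)
  hetnet(nodes, edges)
}

#' Write a 2-HN to node and edge tables
#'
#' Inverse of [read_hetnet()]: `read_hetnet()` on the written files
#' reproduces the network exactly.
#'
#' @param net a `hetnet`.
#' @inheritParams read_hetnet
#' @export
write_hetnet <- function(net, node_table_path, edge_table_path) {
  stopifnot(inherits(net, "hetnet"))
  utils::write.table(net$nodes, node_table_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(net$edges[, c("u", "v", "weight")], edge_table_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Per-channel totals and degrees of a 2-HN
#'
#' Decomposes the network into its three subnetworks and computes, per
#' channel, the total weight and the weighted degree (strength) of every
#' node. Degrees are strictly per-channel: the AA degree of a node counts
#' only AA edges, the bipartite degree only AB edges, and so on. A self-loop
#' of weight w contributes w to the channel total and 2w to its node's
#' degree.
#'
#' @param net a `hetnet`.
#' @return A list of class `subnetwork_stats` with elements `mA`, `mPi`,
#'   `mB` (channel totals) and named numeric vectors `dA`, `kPi`, `dPi`,
#'   `dB` over all nodes (`kPi` is the bipartite degree of A nodes, `dPi`
#'   of B nodes; entries for the other class are zero).
#' @export
subnetwork_stats <- function(net) {
  stopifnot(inherits(net, "hetnet"))
  ids <- net$nodes$node_id
  zero <- stats::setNames(numeric(length(ids)), ids)
  deg_in <- function(ed) {
    d <- zero
    if (nrow(ed)) {
      s <- rowsum(c(ed$weight, ed$weight), c(ed$u, ed$v))
      d[rownames(s)] <- s[, 1]
    }
    d
  }
  e <- net$edges
  aa <- e[e$channel == "AA", ]; ab <- e[e$channel == "AB", ]
  bb <- e[e$channel == "BB", ]
  dPi_all <- deg_in(ab)
  isA <- stats::setNames(net$nodes$class == "A", ids)
  structure(list(
    mA  = sum(aa$weight), mPi = sum(ab$weight), mB = sum(bb$weight),
    dA  = deg_in(aa),
    kPi = ifelse(isA, dPi_all, 0),
    dPi = ifelse(isA, 0, dPi_all),
    dB  = deg_in(bb)
  ), class = "subnetwork_stats")
}

#' Export the module-level (coarse) network of a partition
#'
#' Each module is represented by up to two supernodes: the submodule of its
#' class-A members and the submodule of its class-B members. Supernode
#' self-loop weight is the total internal weight of that submodule; edges
#' between supernodes carry the aggregated weight between the corresponding
#' submodules and are flagged as intra-module (the two supernodes belong to
#' the same module) or inter-module.
#'
#' Two TSVs are written: `<out_prefix>_supernodes.tsv` with columns
#' `supernode_id`, `module_id`, `class`, `size`, `self_loop_weight`, and
#' `<out_prefix>_edges.tsv` with columns `src`, `dst`, `weight`, `intra`.
#'
#' @param net a `hetnet`.
#' @param partition named integer vector mapping every node to a module id.
#' @param out_prefix path prefix for the two output files.
#' @return Invisibly, the list of the two written data frames.
#' @export
export_module_network <- function(net, partition, out_prefix) {
  agg <- aggregate_modules(net, partition)
  sn <- agg$coarse$nodes
  ed <- agg$coarse$edges
  self_w <- stats::setNames(numeric(nrow(sn)), sn$node_id)
  loops <- ed[ed$u == ed$v, ]
  if (nrow(loops)) self_w[loops$u] <- loops$weight
  supernodes <- data.frame(
    supernode_id = sn$node_id,
    module_id = agg$lineage[sn$node_id],
    class = sn$class,
    size = sn$size,
    self_loop_weight = self_w,
    stringsAsFactors = FALSE)
  ed <- ed[ed$u != ed$v, c("u", "v", "weight")]
  names(ed) <- c("src", "dst", "weight")
  ed$intra <- as.integer(agg$lineage[ed$src] == agg$lineage[ed$dst])
  utils::write.table(supernodes, paste0(out_prefix, "_supernodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ed, paste0(out_prefix, "_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(supernodes = supernodes, edges = ed))
}
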