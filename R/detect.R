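#' Configuration for mixed-modularity module detection
#'
#' @param seed integer; seeds the per-sweep node shuffles, making detection
#'   fully reproducible.
#' @param max_levels maximum number of Louvain levels (local moving +
#'   aggregation rounds).
#' @param min_gain minimum total mixed-modularity improvement a level must
#'   deliver for optimization to continue.
#' @param node_order `"shuffled"` (reshuffle sweep order each sweep, seeded)
#'   or `"input"` (node-table order).
#' @export
detect_config <- function(seed = 1L, max_levels = 20L, min_gain = 1e-9,
                          node_order = c("shuffled", "input")) {
  node_order <- match.arg(node_order)
  stopifnot(max_levels >= 1, min_gain >= 0)
  structure(list(seed = as.integer(seed), max_levels = as.integer(max_levels),
                 min_gain = min_gain, node_order = node_order),
            class = "detect_config")
}

# integer-indexed view of a hetnet for the C++ engine
net_index <- function(net) {
  ids <- net$nodes$node_id
  idx <- stats::setNames(seq_along(ids), ids)
  list(
    n = length(ids),
    ids = ids,
    cls = as.integer(net$nodes$class == "B"),
    eu = unname(idx[net$edges$u]) - 1L,
    ev = unname(idx[net$edges$v]) - 1L,
    ew = net$edges$weight,
    ech = match(net$edges$channel, c("AA", "AB", "BB")) - 1L
  )
}

#' One local-moving phase over a 2-HN
#'
#' Sweeps all nodes repeatedly; each node is reassigned to the neighboring
#' module (reachable through any channel) with the largest strictly positive
#' mixed-modularity gain, or stays put. Sweeping stops when a full sweep
#' makes no move, so the returned partition is a local optimum under
#' single-node moves.
#'
#' @param net a `hetnet` (self-loops permitted, as in aggregated networks).
#' @param partition starting partition; defaults to singletons.
#' @param config a [detect_config()].
#' @return List with `partition` (named integer vector), `gain` (total
#'   mixed-modularity improvement, >= 0) and `sweeps`.
#' @export
local_moving_pass <- function(net, partition = NULL, config = detect_config()) {
  if (is.null(partition)) partition <- singleton_partition(net)
  partition <- canonicalize_partition(as_partition(partition, net))
  ix <- net_index(net)
  res <- cpp_local_moving(ix$n, ix$cls, ix$eu, ix$ev, ix$ew, ix$ech,
                          unname(partition) - 1L,
                          config$seed, config$node_order == "shuffled")
  list(partition = stats::setNames(res$membership + 1L, ix$ids),
       gain = res$gain, sweeps = res$sweeps)
}

#' Aggregate a partitioned 2-HN into its module-level network
#'
#' Every module is collapsed into up to two class-pure supernodes (its A-side
#' and B-side submodules), so the coarse network is again a valid 2-HN and
#' mixed modularity applies to it unchanged. Submodule-internal weight
#' becomes a supernode self-loop; weights between submodules are summed.
#' Under the lineage-induced partition (the two supernodes of a module
#' co-assigned), the coarse network has exactly the same mixed modularity as
#' the original under `partition`.
#'
#' @param net a `hetnet`.
#' @param partition named integer vector covering `net`.
#' @return List with `coarse` (a `hetnet` whose node table carries a `size`
#'   column of original node counts), `lineage` (named integer vector:
#'   supernode id -> module id) and `node_map` (original node -> supernode).
#' @export
aggregate_modules <- function(net, partition) {
  partition <- as_partition(partition, net)
  sizes <- if (is.null(net$nodes$size)) rep(1L, nrow(net$nodes)) else net$nodes$size
  super_of <- paste0("M", partition[net$nodes$node_id], "_", net$nodes$class)
  node_map <- stats::setNames(super_of, net$nodes$node_id)
  sn <- unique(data.frame(node_id = super_of,
                          class = net$nodes$class,
                          module = unname(partition[net$nodes$node_id]),
                          stringsAsFactors = FALSE))
  sn$size <- as.integer(rowsum(as.numeric(sizes), super_of)[sn$node_id, 1])
  e <- net$edges
  if (nrow(e)) {
    su <- node_map[e$u]; sv <- node_map[e$v]
    flip <- su > sv
    tmp <- su[flip]; su[flip] <- sv[flip]; sv[flip] <- tmp
    key <- paste(su, sv)
    agg <- rowsum(e$weight, key)
    first <- !duplicated(key)
    ce <- data.frame(u = su[first], v = sv[first],
                     weight = agg[key[first], 1], stringsAsFactors = FALSE)
  } else {
    ce <- data.frame(u = character(), v = character(), weight = numeric())
  }
  coarse <- hetnet(sn[, c("node_id", "class", "size")], ce,
                   allow_selfloops = TRUE)
  lineage <- stats::setNames(sn$module, sn$node_id)
  list(coarse = coarse, lineage = lineage, node_map = node_map)
}

#' Detect mixed modules by Louvain-style mixed-modularity optimization
#'
#' Alternates local moving ([local_moving_pass()]) with aggregation
#' ([aggregate_modules()]): after each aggregation the next level starts
#' from the partition that co-assigns the two supernodes of every module, so
#' mixed modularity carries over exactly and can only grow. Optimization
#' stops when a level improves mixed modularity by less than
#' `config$min_gain`, when aggregation no longer shrinks the network, or at
#' `config$max_levels`. The final partition is projected back to the
#' original nodes.
#'
#' @param net a `hetnet`.
#' @param config a [detect_config()].
#' @return List of class `mixmod_result`: `partition` (named, canonical ids
#'   1..K), `mQ`, `n_modules`, `n_mixed_modules`, `module_type` (from
#'   [classify_modules()]), `levels`, `per_level_mQ`, `config`.
#' @export
mixmod_detect <- function(net, config = detect_config()) {
  stopifnot(inherits(net, "hetnet"))
  orig <- net
  assign_chain <- stats::setNames(orig$nodes$node_id, orig$nodes$node_id)
  cur <- net
  partition <- singleton_partition(cur)
  per_level_mQ <- numeric()
  level <- 0L
  repeat {
    level <- level + 1L
    lev_cfg <- config
    lev_cfg$seed <- as.integer((config$seed + 7919 * (level - 1)) %% 2147483647)
    pass <- local_moving_pass(cur, partition, lev_cfg)
    proj <- stats::setNames(unname(pass$partition[assign_chain]),
                            names(assign_chain))
    per_level_mQ <- c(per_level_mQ, mixed_modularity(orig, proj))
    n_mod <- length(unique(pass$partition))
    if (level >= config$max_levels ||
        pass$gain < config$min_gain ||
        n_mod == nrow(cur$nodes)) break
    agg <- aggregate_modules(cur, pass$partition)
    assign_chain <- stats::setNames(unname(agg$node_map[assign_chain]),
                                    names(assign_chain))
    cur <- agg$coarse
    partition <- agg$lineage
  }
  final <- canonicalize_partition(as_partition(proj, orig))
  types <- classify_modules(orig, final)
  structure(list(
    partition = final,
    mQ = per_level_mQ[length(per_level_mQ)],
    n_modules = length(types),
    n_mixed_modules = sum(types == "mixed"),
    module_type = types,
    levels = level,
    per_level_mQ = per_level_mQ,
    config = config
  ), class = "mixmod_result")
}

#' @export
print.mixmod_result <- function(x, ...) {
  cat(sprintf(
    "<mixmod_result> %d modules (%d mixed), mQ = %.4f, %d level(s)\n",
    x$n_modules, x$n_mixed_modules, x$mQ, x$levels))
  invisible(x)
}
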