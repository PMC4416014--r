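#' Coerce and validate a partition of a network's nodes
#'
#' A partition is a named integer vector mapping every node id of the
#' network to a module id. Module ids are arbitrary integers on input;
#' [canonicalize_partition()] relabels them to contiguous 1..K in order of
#' first appearance.
#'
#' @param x named vector (names = node ids), or a data.frame with columns
#'   `node_id` and `module_id`.
#' @param net a `hetnet` the partition must cover.
#' @return Named integer vector over exactly the nodes of `net`.
#' @export
as_partition <- function(x, net) {
  if (is.data.frame(x)) x <- stats::setNames(x$module_id, x$node_id)
  if (is.null(names(x))) stop("partition must be named by node id")
  ids <- net$nodes$node_id
  if (!setequal(names(x), ids) || length(x) != length(ids))
    stop("partition must cover every node of the network exactly once")
  stats::setNames(as.integer(x[ids]), ids)
}

#' @rdname as_partition
#' @export
canonicalize_partition <- function(x) {
  stats::setNames(as.integer(factor(x, levels = unique(x))), names(x))
}

#' Singleton partition: every node its own module
#' @param net a `hetnet`.
#' @export
singleton_partition <- function(net) {
  ids <- net$nodes$node_id
  stats::setNames(seq_along(ids), ids)
}

#' Read/write a partition as a two-column TSV
#'
#' Columns `node_id` and `module_id`, with header.
#'
#' @param path TSV path.
#' @param partition named integer vector.
#' @export
read_partition <- function(path) {
  d <- utils::read.delim(path, colClasses = c("character", "integer"))
  stats::setNames(d$module_id, d$node_id)
}

#' @rdname read_partition
#' @export
write_partition <- function(partition, path) {
  utils::write.table(
    data.frame(node_id = names(partition), module_id = unname(partition)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Classify modules as mixed or single-class
#'
#' A mixed module contains at least one node of each class; modules made of
#' a single class are a degenerate special case that still takes part in the
#' optimization.
#'
#' @param net a `hetnet`.
#' @param partition named integer vector covering `net`.
#' @return Named character vector over module ids with values `"mixed"`,
#'   `"A_only"` or `"B_only"`.
#' @export
classify_modules <- function(net, partition) {
  partition <- as_partition(partition, net)
  cls <- net$nodes$class
  mods <- sort(unique(partition))
  hasA <- tapply(cls == "A", partition[net$nodes$node_id], any)
  hasB <- tapply(cls == "B", partition[net$nodes$node_id], any)
  out <- ifelse(hasA & hasB, "mixed", ifelse(hasA, "A_only", "B_only"))
  stats::setNames(as.character(out[as.character(mods)]), mods)
}
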