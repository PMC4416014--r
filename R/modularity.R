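#' Per-module channel statistics under a partition
#'
#' For every module c the quantities entering the mixed-modularity formula:
#' internal weight per channel (`lA`, `lPi`, `lB`, counting edges with both
#' endpoints in c) and the per-channel degree sums of its members (`dA`,
#' `kPi` over A members, `dPi` over B members, `dB`). Channel totals are
#' carried along in `$subnet`.
#'
#' @param net a `hetnet`.
#' @param partition named integer vector covering `net`.
#' @param subnet optional precomputed [subnetwork_stats()].
#' @return List of class `module_stats`: `modules` (sorted module ids) and
#'   numeric vectors `lA`, `lPi`, `lB`, `dA`, `kPi`, `dPi`, `dB` named by
#'   module id, plus `subnet`.
#' @export
module_stats <- function(net, partition, subnet = NULL) {
  partition <- as_partition(partition, net)
  if (is.null(subnet)) subnet <- subnetwork_stats(net)
  mods <- sort(unique(unname(partition)))
  zero <- stats::setNames(numeric(length(mods)), mods)
  internal <- function(ed) {
    l <- zero
    if (nrow(ed)) {
      keep <- partition[ed$u] == partition[ed$v]
      if (any(keep)) {
        s <- rowsum(ed$weight[keep], partition[ed$u][keep])
        l[rownames(s)] <- s[, 1]
      }
    }
    l
  }
  degsum <- function(d) {
    s <- rowsum(unname(d), partition[names(d)])
    out <- zero
    out[rownames(s)] <- s[, 1]
    out
  }
  e <- net$edges
  structure(list(
    modules = mods,
    lA  = internal(e[e$channel == "AA", ]),
    lPi = internal(e[e$channel == "AB", ]),
    lB  = internal(e[e$channel == "BB", ]),
    dA  = degsum(subnet$dA),
    kPi = degsum(subnet$kPi),
    dPi = degsum(subnet$dPi),
    dB  = degsum(subnet$dB),
    subnet = subnet
  ), class = "module_stats")
}

# per-module mixed-modularity contributions from a module_stats object;
# a channel with zero total weight contributes 0 (limit convention)
module_terms <- function(ms) {
  sn <- ms$subnet
  tA <- if (sn$mA > 0) ms$lA / sn$mA - (ms$dA / (2 * sn$mA))^2 else 0 * ms$lA
  tP <- if (sn$mPi > 0) ms$lPi / sn$mPi - ms$kPi * ms$dPi / sn$mPi^2 else 0 * ms$lPi
  tB <- if (sn$mB > 0) ms$lB / sn$mB - (ms$dB / (2 * sn$mB))^2 else 0 * ms$lB
  (tA + tP + tB) / 3
}

#' Mixed modularity of a partition of a 2-HN
#'
#' The quality function is the average of three per-channel modularities,
#' evaluated module by module:
#' \deqn{mQ = \frac{1}{3}\sum_c \left[\frac{l_{Ac}}{m_A} -
#'   \left(\frac{d_{Ac}}{2m_A}\right)^2\right] +
#'   \left[\frac{l_{\Pi c}}{m_\Pi} - \frac{k_{\Pi c} d_{\Pi c}}{m_\Pi^2}\right] +
#'   \left[\frac{l_{Bc}}{m_B} - \left(\frac{d_{Bc}}{2m_B}\right)^2\right]}
#' i.e. Newman-Girvan modularity on the AA and BB channels and Barber
#' bipartite modularity on the AB channel, each normalized by its own
#' channel total, so the value is invariant under any positive rescaling of
#' the weights of a single channel. Weighted networks use strengths
#' throughout; a channel with zero total weight contributes 0. The
#' all-in-one-module partition scores exactly 0.
#'
#' @inheritParams module_stats
#' @return A single number, at most 1.
#' @export
mixed_modularity <- function(net, partition, subnet = NULL) {
  partition <- as_partition(partition, net)
  if (length(partition) == 0) stop("empty partition")
  ms <- module_stats(net, partition, subnet)
  sum(module_terms(ms))
}

#' Incremental mixed-modularity gain of a single-node move
#'
#' Returns `mixed_modularity` after moving `node` to `target_module` minus
#' its current value, computed from cached per-module statistics without
#' rescoring the whole partition. Only the terms of the source and target
#' modules change; all other modules cancel.
#'
#' @inheritParams module_stats
#' @param node a node id.
#' @param target_module an existing module id or a fresh id (empty module).
#' @param cached [module_stats()] consistent with `partition`.
#' @export
move_gain <- function(net, partition, node, target_module, cached = NULL) {
  partition <- as_partition(partition, net)
  if (is.null(cached)) cached <- module_stats(net, partition)
  s <- unname(partition[node])
  t <- as.integer(target_module)
  if (identical(s, t)) return(0)
  sn <- cached$subnet
  cls <- net$nodes$class[match(node, net$nodes$node_id)]

  e <- net$edges
  inc <- e[(e$u == node | e$v == node) & e$u != e$v, ]
  other <- ifelse(inc$u == node, inc$v, inc$u)
  omod <- partition[other]
  w_to <- function(channel, mod) {
    sum(inc$weight[inc$channel == channel & omod == mod])
  }
  # self-loops move with the node: they cancel in the gain
  getm <- function(vec, mod) {
    i <- match(as.character(mod), names(vec))
    if (is.na(i)) 0 else vec[[i]]
  }
  term <- function(lA, dA, lPi, kPi, dPi, lB, dB) {
    (if (sn$mA > 0) lA / sn$mA - (dA / (2 * sn$mA))^2 else 0) +
    (if (sn$mPi > 0) lPi / sn$mPi - kPi * dPi / sn$mPi^2 else 0) +
    (if (sn$mB > 0) lB / sn$mB - (dB / (2 * sn$mB))^2 else 0)
  }
  mod_term <- function(mod, with_node) {
    lA <- getm(cached$lA, mod); dA <- getm(cached$dA, mod)
    lPi <- getm(cached$lPi, mod); kPi <- getm(cached$kPi, mod)
    dPi <- getm(cached$dPi, mod); lB <- getm(cached$lB, mod)
    dB <- getm(cached$dB, mod)
    # cached values include the node while it sits in s; adjust to the
    # requested membership state
    in_cache <- identical(unname(mod), s)
    delta <- as.numeric(with_node) - as.numeric(in_cache)
    if (delta != 0) {
      base <- if (with_node) mod else s  # edges to members excluding node
      if (cls == "A") {
        dA <- dA + delta * sn$dA[[node]]
        kPi <- kPi + delta * sn$kPi[[node]]
        lA <- lA + delta * w_to("AA", base)
        lPi <- lPi + delta * w_to("AB", base)
      } else {
        dB <- dB + delta * sn$dB[[node]]
        dPi <- dPi + delta * sn$dPi[[node]]
        lB <- lB + delta * w_to("BB", base)
        lPi <- lPi + delta * w_to("AB", base)
      }
    }
    term(lA, dA, lPi, kPi, dPi, lB, dB)
  }
  gain <- (mod_term(s, FALSE) + mod_term(t, TRUE)) -
          (mod_term(s, TRUE) + mod_term(t, FALSE))
  gain / 3
}
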