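# fixtures and independent oracles shared across test files

# random small 2-HN: every unordered pair kept with prob p_edge
random_hetnet <- function(n = 12, p_edge = 0.3, weighted = TRUE) {
  nodes <- data.frame(node_id = paste0("n", seq_len(n)),
                      class = sample(c("A", "B"), n, replace = TRUE))
  # ensure both classes present
  nodes$class[1] <- "A"; nodes$class[2] <- "B"
  pairs <- t(utils::combn(n, 2))
  pick <- pairs[stats::runif(nrow(pairs)) < p_edge, , drop = FALSE]
  w <- if (weighted) round(stats::runif(nrow(pick), 0.5, 3), 2)
       else rep(1, nrow(pick))
  edges <- data.frame(u = paste0("n", pick[, 1]),
                      v = paste0("n", pick[, 2]), weight = w)
  hetnet(nodes, edges)
}

random_partition <- function(net, k = 4) {
  ids <- net$nodes$node_id
  as_partition(stats::setNames(sample(seq_len(k), length(ids), replace = TRUE),
                               ids), net)
}

# three-planted-module toy: two chemicals + two genes per module, dense
# inside, single bridges between modules
toy_3module <- function() {
  nodes <- data.frame(
    node_id = c(paste0("a", 1:6), paste0("b", 1:6)),
    class = rep(c("A", "B"), each = 6))
  mod_edges <- function(i) {
    a <- paste0("a", c(2 * i - 1, 2 * i)); b <- paste0("b", c(2 * i - 1, 2 * i))
    data.frame(u = c(a[1], b[1], a[1], a[2], a[1]),
               v = c(a[2], b[2], b[1], b[2], b[2]),
               weight = 1)
  }
  bridges <- data.frame(u = c("a2", "b2"), v = c("a3", "b5"), weight = 1)
  net <- hetnet(nodes, rbind(mod_edges(1), mod_edges(2), mod_edges(3), bridges))
  part <- as_partition(stats::setNames(rep(1:3, each = 2)[c(1:6, 1:6)],
                                       nodes$node_id), net)
  list(net = net, partition = part)
}

# independent oracle: Newman-Girvan on GA and GB via igraph, Barber
# bipartite modularity evaluated directly from its formula
oracle_mixed_modularity <- function(net, part) {
  e <- net$edges
  q <- 0
  for (ch in c("AA", "BB")) {
    cl <- if (ch == "AA") "A" else "B"
    sub <- e[e$channel == ch, ]
    ids <- net$nodes$node_id[net$nodes$class == cl]
    if (nrow(sub) > 0) {
      g <- igraph::graph_from_data_frame(sub[, c("u", "v")],
                                         directed = FALSE, vertices = ids)
      q <- q + igraph::modularity(g, membership = part[ids],
                                  weights = sub$weight)
    }
  }
  ab <- e[e$channel == "AB", ]
  if (nrow(ab) > 0) {
    m <- sum(ab$weight)
    kA <- tapply(ab$weight, ab$u, sum)
    dB <- tapply(ab$weight, ab$v, sum)
    for (c in unique(part)) {
      members <- names(part)[part == c]
      l <- sum(ab$weight[ab$u %in% members & ab$v %in% members])
      kc <- sum(kA[names(kA) %in% members])
      dc <- sum(dB[names(dB) %in% members])
      q <- q + l / m - kc * dc / m^2
    }
  }
  q / 3
}

# brute-force best one-to-one matching over all module permutations
brute_force_ca <- function(real, found) {
  cm <- unclass(confusion_matrix(real, found))
  nr <- nrow(cm); nc <- ncol(cm)
  k <- min(nr, nc)
  big <- max(nr, nc)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    unlist(lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))), recursive = FALSE)
  }
  best <- 0
  for (p in perms(seq_len(big))) {
    sel <- p[seq_len(k)]
    tot <- if (nr <= nc) sum(cm[cbind(seq_len(k), sel)])
           else sum(cm[cbind(sel, seq_len(k))])
    best <- max(best, tot)
  }
  best / sum(cm)
}
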