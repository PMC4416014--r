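#' Parameters of the labeled 2-HN benchmark generator
#'
#' The generator builds a 2-HN with planted mixed modules in five steps:
#' (1) an LFR-style subnetwork for class A (power-law degrees with mean
#' `kA` and maximum `maxkA`, power-law community sizes, per-node mixing
#' fraction `muA`); (2) likewise for class B; (3) the A and B communities
#' are randomly grouped into `min(nA, nB)` mixed modules, each containing
#' at least one community of each class; (4) `round(kPi * NA)` bipartite
#' edges are placed, each within a planted mixed module with probability
#' `p` and between arbitrary A and B nodes otherwise; (5) the three
#' channels are integrated and every node carries its mixed-module label.
#' Optionally, one channel is weighted with the weighted-LFR scheme: node
#' strengths approximate degree^`beta` and a fraction `muW` of each node's
#' strength is carried by edges leaving its community.
#'
#' @param NA_,kA,maxkA,muA class-A subnetwork: node count, mean degree,
#'   maximum degree, topological mixing parameter.
#' @param NB,kB,maxkB,muB likewise for class B.
#' @param p probability that a bipartite edge falls inside a planted mixed
#'   module.
#' @param kPi mean bipartite degree per A node (the AB channel has
#'   `round(kPi * NA_)` edges).
#' @param tau1,tau2 power-law exponents of the degree and community-size
#'   distributions.
#' @param weighting which channel to weight (`"none"`, `"GA"`, `"GPi"`,
#'   `"GB"`).
#' @param beta strength exponent of the weighted scheme.
#' @param muW weight mixing parameter; defaults to `muA`, `1 - p` or `muB`
#'   according to the weighted channel.
#' @param seed integer seed; the same spec and seed reproduce the network
#'   exactly.
#' @export
benchmark_spec <- function(NA_ = 400, kA = 4, maxkA = 16, muA = 0.2,
                           NB = 600, kB = 12, maxkB = 48, muB = 0.2,
                           p = 0.5, kPi = 4, tau1 = 2, tau2 = 1,
                           weighting = c("none", "GA", "GPi", "GB"),
                           beta = 2, muW = NULL, seed = 1L) {
  weighting <- match.arg(weighting)
  stopifnot(muA >= 0, muA <= 1, muB >= 0, muB <= 1, p >= 0, p <= 1,
            kA <= maxkA, maxkA < NA_, kB <= maxkB, maxkB < NB, kPi > 0)
  if (is.null(muW))
    muW <- switch(weighting, none = NA_real_, GA = muA, GPi = 1 - p, GB = muB)
  structure(list(NA_ = NA_, kA = kA, maxkA = maxkA, muA = muA,
                 NB = NB, kB = kB, maxkB = maxkB, muB = muB,
                 p = p, kPi = kPi, tau1 = tau1, tau2 = tau2,
                 weighting = weighting, beta = beta, muW = muW,
                 seed = as.integer(seed)),
            class = "benchmark_spec")
}

sample_powerlaw_int <- function(n, xmin, xmax, exponent) {
  xs <- xmin:xmax
  if (length(xs) == 1) return(rep(xs, n))
  sample(xs, n, replace = TRUE, prob = xs^(-exponent))
}

# degree sequence with mean ~ k: pick the lower cutoff whose power-law mean
# is closest to k, then redraw until the empirical mean is within 5%
draw_degrees <- function(N, k, maxk, tau1) {
  means <- vapply(seq_len(maxk), function(kmin) {
    xs <- kmin:maxk
    sum(xs^(1 - tau1)) / sum(xs^(-tau1))
  }, numeric(1))
  kmin <- which.min(abs(means - k))
  for (i in 1:200) {
    deg <- sample_powerlaw_int(N, kmin, maxk, tau1)
    if (abs(mean(deg) - k) / k <= 0.05) {
      if (sum(deg) %% 2 == 1) {
        j <- which.max(deg)
        deg[j] <- deg[j] - 1L
      }
      return(deg)
    }
  }
  stop("could not realize the requested mean degree")
}

draw_community_sizes <- function(N, cmin, cmax, tau2) {
  cmin <- min(cmin, max(2, floor(N / 2)))
  cmax <- max(cmin, cmax)
  for (i in 1:100) {
    sizes <- integer(0)
    while (sum(sizes) < N)
      sizes <- c(sizes, sample_powerlaw_int(1, cmin, cmax, tau2))
    excess <- sum(sizes) - N
    while (excess > 0) {
      j <- which.max(sizes)
      cut <- min(excess, sizes[j] - cmin)
      if (cut == 0) break
      sizes[j] <- sizes[j] - cut
      excess <- excess - cut
    }
    if (sum(sizes) == N && length(sizes) >= 2) return(sizes)
  }
  stop("could not draw a feasible community-size sequence")
}

# capacity-aware random assignment: a node with internal degree d needs a
# community of size > d
assign_nodes_to_communities <- function(int_deg, sizes) {
  ord <- order(int_deg, decreasing = TRUE)
  for (i in 1:100) {
    slots <- sizes
    comm <- integer(length(int_deg))
    ok <- TRUE
    for (v in ord) {
      feas <- which(slots > 0 & sizes > int_deg[v])
      if (!length(feas)) { ok <- FALSE; break }
      cc <- if (length(feas) == 1) feas else sample(feas, 1, prob = slots[feas])
      comm[v] <- cc
      slots[cc] <- slots[cc] - 1
    }
    if (ok) return(comm)
  }
  stop("infeasible degree/community combination")
}

# configuration-model stub pairing; forbids self-loops, duplicates and
# (optionally) pairs inside the same group. When leftover stubs cannot pair
# among themselves (e.g. all from one hub), already-accepted edges are
# dissolved back into the pool and rewired; truly irreparable leftovers are
# dropped at the end.
pair_stubs <- function(stubs, group = NULL, forbid_same_group = FALSE,
                       max_rounds = 200) {
  out_u <- integer(0); out_v <- integer(0)
  seen <- character(0)
  stall <- 0
  for (r in 1:max_rounds) {
    if (length(stubs) < 2) break
    prev_left <- length(stubs)
    stubs <- sample(stubs)
    if (length(stubs) %% 2 == 1) stubs <- stubs[-length(stubs)]
    u <- stubs[c(TRUE, FALSE)]; v <- stubs[c(FALSE, TRUE)]
    lo <- pmin(u, v); hi <- pmax(u, v)
    key <- paste(lo, hi)
    bad <- lo == hi | duplicated(key) | key %in% seen
    if (forbid_same_group) bad <- bad | group[lo] == group[hi]
    out_u <- c(out_u, lo[!bad]); out_v <- c(out_v, hi[!bad])
    seen <- c(seen, key[!bad])
    if (!any(bad)) return(cbind(u = out_u, v = out_v))
    stubs <- c(lo[bad], hi[bad])
    stall <- if (length(stubs) >= prev_left) stall + 1 else 0
    if (stall >= 3 && length(out_u) > 0) {
      k <- min(length(out_u), max(4L, length(stubs)))
      pick <- sample.int(length(out_u), k)
      stubs <- c(stubs, out_u[pick], out_v[pick])
      out_u <- out_u[-pick]; out_v <- out_v[-pick]
      seen <- seen[-pick]
      stall <- 0
    }
  }
  cbind(u = out_u, v = out_v)
}

#' Generate one LFR-style single-class subnetwork
#'
#' Power-law degree sequence (exponent `tau1`, mean about `k`, maximum
#' `maxk`), power-law community sizes (exponent `tau2`, bounded by
#' `[max(10, maxk/2), N/5]` by default) and per-node mixing fraction about
#' `mu`: each node keeps a share `1 - mu` of its edges inside its community
#' (wired by a within-community configuration model) and sends the rest to
#' other communities.
#'
#' @param N,k,maxk,mu see [benchmark_spec()].
#' @param tau1,tau2 power-law exponents.
#' @param cmin,cmax community-size bounds.
#' @param seed optional integer seed.
#' @return List with `edges` (integer data.frame `u`, `v`), `labels`
#'   (community id per node) and `degrees` (the drawn degree sequence).
#' @export
generate_lfr_subnetwork <- function(N, k, maxk, mu, tau1 = 2, tau2 = 1,
                                    cmin = max(10, ceiling(maxk / 2)),
                                    cmax = max(cmin, floor(N / 5)),
                                    seed = NULL) {
  run <- function() {
    deg <- draw_degrees(N, k, maxk, tau1)
    # stochastic rounding keeps E[external share] = mu even for low degrees
    raw <- (1 - mu) * deg
    int_deg <- floor(raw) + (stats::runif(N) < raw - floor(raw))
    ext_deg <- deg - int_deg
    sizes <- draw_community_sizes(N, cmin, cmax, tau2)
    comm <- assign_nodes_to_communities(int_deg, sizes)
    # internal stub sums must be even within each community; the odd stub
    # is dropped (not turned external, which would leak mixing)
    for (cc in seq_along(sizes)) {
      members <- which(comm == cc)
      if (sum(int_deg[members]) %% 2 == 1) {
        j <- members[which.max(int_deg[members])]
        int_deg[j] <- int_deg[j] - 1L
      }
    }
    if (sum(ext_deg) %% 2 == 1) {
      j <- which.max(ext_deg)
      ext_deg[j] <- ext_deg[j] - 1L
    }
    internal <- do.call(rbind, lapply(seq_along(sizes), function(cc) {
      members <- which(comm == cc)
      pair_stubs(rep(members, int_deg[members]))
    }))
    external <- pair_stubs(rep(seq_len(N), ext_deg), group = comm,
                           forbid_same_group = TRUE)
    edges <- rbind(internal, external)
    # drop cross-list duplicates (cannot arise: internal pairs share a
    # community, external pairs never do)
    list(edges = data.frame(u = edges[, 1], v = edges[, 2]),
         labels = comm, degrees = deg)
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

#' Group single-class communities into mixed modules
#'
#' Sets the number of mixed modules to `nc = min(nA, nB)` and assigns every
#' A community and every B community to one of the `nc` modules uniformly at
#' random, subject to each module receiving at least one community of each
#' class.
#'
#' @param labelsA,labelsB community label vectors of the two subnetworks.
#' @param seed optional integer seed.
#' @return List with `A` and `B`: integer vectors mapping community id to
#'   mixed-module id, and `nc`.
#' @export
assign_mixed_modules <- function(labelsA, labelsB, seed = NULL) {
  run <- function() {
    nA <- length(unique(labelsA)); nB <- length(unique(labelsB))
    stopifnot(nA >= 1, nB >= 1)
    nc <- min(nA, nB)
    place <- function(ncomm) {
      mod <- integer(ncomm)
      ord <- sample(ncomm)
      mod[ord[seq_len(nc)]] <- seq_len(nc)   # guarantee coverage
      rest <- ord[-seq_len(nc)]
      if (length(rest))
        mod[rest] <- sample(nc, length(rest), replace = TRUE)
      mod
    }
    list(A = place(nA), B = place(nB), nc = nc)
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

#' Place the bipartite (AB) channel of a benchmark 2-HN
#'
#' Draws `round(kPi * |A|)` distinct A-B edges. Each edge is, with
#' probability `p`, placed inside one planted mixed module (the module drawn
#' proportionally to its number of A x B pairs, endpoints uniform within
#' it) and otherwise between an arbitrary A node and an arbitrary B node.
#'
#' @param n_A,n_B numbers of A and B nodes.
#' @param module_A,module_B mixed-module id per A node / per B node.
#' @param p,kPi see [benchmark_spec()].
#' @param seed optional integer seed.
#' @return Integer data.frame with columns `a`, `b`.
#' @export
generate_bipartite_links <- function(n_A, n_B, module_A, module_B,
                                     p, kPi, seed = NULL) {
  run <- function() {
    M <- round(kPi * n_A)
    A_by_mod <- split(seq_len(n_A), module_A)
    B_by_mod <- split(seq_len(n_B), module_B)
    mods <- intersect(names(A_by_mod), names(B_by_mod))
    pair_counts <- vapply(mods, function(m)
      length(A_by_mod[[m]]) * length(B_by_mod[[m]]), numeric(1))
    if (M > n_A * n_B ||
        (p == 1 && M > sum(pair_counts)))
      stop("requested bipartite edges exceed simple-graph capacity")
    a_out <- integer(0); b_out <- integer(0)
    seen <- character(0)
    for (i in 1:1000) {
      need <- M - length(a_out)
      if (need == 0) break
      nd <- ceiling(need * 1.3) + 8
      within <- stats::runif(nd) < p
      a <- integer(nd); b <- integer(nd)
      nw <- sum(within)
      if (nw) {
        mi <- sample(seq_along(mods), nw, replace = TRUE, prob = pair_counts)
        a[within] <- vapply(mi, function(m) {
          am <- A_by_mod[[mods[m]]]
          am[sample.int(length(am), 1)]
        }, integer(1))
        b[within] <- vapply(mi, function(m) {
          bm <- B_by_mod[[mods[m]]]
          bm[sample.int(length(bm), 1)]
        }, integer(1))
      }
      if (nw < nd) {
        a[!within] <- sample.int(n_A, nd - nw, replace = TRUE)
        b[!within] <- sample.int(n_B, nd - nw, replace = TRUE)
      }
      key <- paste(a, b)
      keep <- !duplicated(key) & !(key %in% seen)
      keep[which(keep)[seq_len(max(0, sum(keep) - need))]] <- FALSE
      a_out <- c(a_out, a[keep]); b_out <- c(b_out, b[keep])
      seen <- c(seen, key[keep])
    }
    if (length(a_out) < M)
      stop("could not place the requested number of bipartite edges")
    data.frame(a = a_out, b = b_out)
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

# weighted-LFR weight assignment for one channel: node strengths approach
# degree^beta with a share muW carried by edges leaving the community;
# iterative proportional fitting on the internal/external strength targets
assign_channel_weights <- function(n_edges, eu, ev, internal, deg,
                                   beta, muW, iters = 80) {
  w <- rep(1, n_edges)
  t_int <- (1 - muW) * deg^beta
  t_ext <- muW * deg^beta
  for (it in seq_len(iters)) {
    ri <- rep(1, length(deg))
    re <- rep(1, length(deg))
    if (any(internal)) {
      s_int <- rowsum(c(w[internal], w[internal]),
                      c(eu[internal], ev[internal]))
      idx <- as.integer(rownames(s_int))
      ri[idx] <- t_int[idx] / pmax(s_int[, 1], 1e-12)
    }
    if (any(!internal)) {
      s_ext <- rowsum(c(w[!internal], w[!internal]),
                      c(eu[!internal], ev[!internal]))
      idx <- as.integer(rownames(s_ext))
      re[idx] <- t_ext[idx] / pmax(s_ext[, 1], 1e-12)
    }
    fac <- ifelse(internal, sqrt(ri[eu] * ri[ev]), sqrt(re[eu] * re[ev]))
    w <- pmax(w * fac, 1e-9)
  }
  w
}

#' Generate a labeled benchmark 2-HN with planted mixed modules
#'
#' Runs the five generator steps described in [benchmark_spec()]. Node ids
#' are `a1..aNA` (class A) and `b1..bNB` (class B); the planted mixed-module
#' label of every node is stored in the node table's `module` column and
#' returned in `labels`.
#'
#' @param spec a [benchmark_spec()].
#' @return List of class `labeled_hetnet`: `net` (a `hetnet`), `labels`
#'   (named integer vector of planted labels), `communities` (per-class
#'   community labels) and `spec`.
#' @export
generate_benchmark <- function(spec) {
  stopifnot(inherits(spec, "benchmark_spec"))
  withr::with_seed(spec$seed, {
    ga <- generate_lfr_subnetwork(spec$NA_, spec$kA, spec$maxkA, spec$muA,
                                  spec$tau1, spec$tau2)
    gb <- generate_lfr_subnetwork(spec$NB, spec$kB, spec$maxkB, spec$muB,
                                  spec$tau1, spec$tau2)
    mix <- assign_mixed_modules(ga$labels, gb$labels)
    modA <- mix$A[ga$labels]
    modB <- mix$B[gb$labels]
    bip <- generate_bipartite_links(spec$NA_, spec$NB, modA, modB,
                                    spec$p, spec$kPi)

    wA <- rep(1, nrow(ga$edges)); wB <- rep(1, nrow(gb$edges))
    wPi <- rep(1, nrow(bip))
    if (spec$weighting == "GA") {
      dg <- tabulate(c(ga$edges$u, ga$edges$v), spec$NA_)
      wA <- assign_channel_weights(nrow(ga$edges), ga$edges$u, ga$edges$v,
                                   ga$labels[ga$edges$u] == ga$labels[ga$edges$v],
                                   dg, spec$beta, spec$muW)
    } else if (spec$weighting == "GB") {
      dg <- tabulate(c(gb$edges$u, gb$edges$v), spec$NB)
      wB <- assign_channel_weights(nrow(gb$edges), gb$edges$u, gb$edges$v,
                                   gb$labels[gb$edges$u] == gb$labels[gb$edges$v],
                                   dg, spec$beta, spec$muW)
    } else if (spec$weighting == "GPi") {
      # bipartite: index B nodes after A nodes in one degree vector
      eu <- bip$a; ev <- bip$b + spec$NA_
      dg <- tabulate(c(eu, ev), spec$NA_ + spec$NB)
      wPi <- assign_channel_weights(nrow(bip), eu, ev,
                                    modA[bip$a] == modB[bip$b],
                                    dg, spec$beta, spec$muW)
    }

    aid <- paste0("a", seq_len(spec$NA_))
    bid <- paste0("b", seq_len(spec$NB))
    nodes <- data.frame(
      node_id = c(aid, bid),
      class = rep(c("A", "B"), c(spec$NA_, spec$NB)),
      module = c(modA, modB),
      stringsAsFactors = FALSE)
    edges <- rbind(
      data.frame(u = aid[ga$edges$u], v = aid[ga$edges$v], weight = wA),
      data.frame(u = aid[bip$a], v = bid[bip$b], weight = wPi),
      data.frame(u = bid[gb$edges$u], v = bid[gb$edges$v], weight = wB))
    net <- hetnet(nodes, edges)
    structure(list(
      net = net,
      labels = stats::setNames(c(modA, modB), c(aid, bid)),
      communities = list(A = ga$labels, B = gb$labels),
      spec = spec
    ), class = "labeled_hetnet")
  })
}

#' Realized mixing fraction of a labeled single-class network
#'
#' Mean over nodes of the fraction of incident edge weight that leaves the
#' node's community; the empirical counterpart of the LFR mixing parameter.
#'
#' @param edges data.frame `u`, `v` (integer node indexes) and optionally
#'   `weight`.
#' @param labels community label per node.
#' @export
realized_mixing <- function(edges, labels) {
  w <- if (is.null(edges$weight)) rep(1, nrow(edges)) else edges$weight
  ext <- labels[edges$u] != labels[edges$v]
  n <- length(labels)
  tot <- rowsum(c(w, w), c(edges$u, edges$v))
  out <- rowsum(c(w * ext, w * ext), c(edges$u, edges$v))
  tot_v <- stats::setNames(numeric(n), seq_len(n))
  ext_v <- tot_v
  tot_v[rownames(tot)] <- tot[, 1]
  ext_v[rownames(out)] <- out[, 1]
  mean((ext_v / pmax(tot_v, 1))[tot_v > 0])
}
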