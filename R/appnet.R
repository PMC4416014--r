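#' Tanimoto coefficient of two binary fingerprints
#'
#' Number of on-bits shared by both fingerprints divided by the number of
#' bits on in either: |f1 AND f2| / |f1 OR f2|.
#'
#' @param f1,f2 logical or 0/1 vectors of equal length; at least one must
#'   have a nonzero bit.
#' @return A number in [0, 1].
#' @export
tanimoto <- function(f1, f2) {
  f1 <- as.logical(f1); f2 <- as.logical(f2)
  stopifnot(length(f1) == length(f2))
  un <- sum(f1 | f2)
  if (un == 0) stop("Tanimoto undefined: both fingerprints are all-zero")
  sum(f1 & f2) / un
}

#' Read fingerprints from a TSV of hex-encoded bit strings
#'
#' Columns `node_id` and `fingerprint` (hexadecimal, most significant
#' nibble first; all rows must decode to the same bit length).
#'
#' @param path TSV path.
#' @return Named list of logical vectors.
#' @export
read_fingerprints <- function(path) {
  d <- utils::read.delim(path, colClasses = "character")
  fps <- lapply(d$fingerprint, hex_to_bits)
  if (length(unique(lengths(fps))) > 1)
    stop("fingerprints must share one bit length")
  stats::setNames(fps, d$node_id)
}

hex_to_bits <- function(h) {
  nib <- strtoi(strsplit(tolower(h), "")[[1]], base = 16L)
  if (anyNA(nib)) stop("invalid hex fingerprint: ", h)
  as.logical(as.vector(vapply(nib, function(x)
    as.integer(intToBits(x))[4:1], integer(4))))
}

#' Chemical-similarity edges (AA channel) from fingerprints
#'
#' All unordered pairs with Tanimoto similarity at or above `threshold`
#' (the boundary is inclusive). By default edges carry weight 1 and the
#' similarity value is kept in a `similarity` column; with
#' `weighted = TRUE` the similarity becomes the edge weight.
#'
#' @param fingerprints named list of logical vectors.
#' @param threshold inclusion threshold in [0, 1].
#' @param weighted use the similarity as edge weight.
#' @return data.frame `u`, `v`, `weight`, `similarity`.
#' @export
similarity_edges <- function(fingerprints, threshold = 0.7,
                             weighted = FALSE) {
  ids <- names(fingerprints)
  out <- list()
  if (length(ids) >= 2) {
    mat <- do.call(cbind, fingerprints)
    ab <- crossprod(mat)                   # pairwise |AND|
    ones <- diag(ab)
    orr <- outer(ones, ones, "+") - ab     # |OR|
    sim <- ifelse(orr > 0, ab / orr, NA)
    pick <- which(upper.tri(sim) & !is.na(sim) & sim >= threshold,
                  arr.ind = TRUE)
    out <- data.frame(u = ids[pick[, 1]], v = ids[pick[, 2]],
                      similarity = sim[pick], stringsAsFactors = FALSE)
  }
  if (!length(out) || !nrow(out))
    return(data.frame(u = character(), v = character(),
                      weight = numeric(), similarity = numeric()))
  out$weight <- if (weighted) out$similarity else 1
  out[, c("u", "v", "weight", "similarity")]
}

#' Gene-interaction edges (BB channel) weighted by database support
#'
#' One edge per unordered gene pair found in at least one source table;
#' the weight is the number of distinct source databases reporting the
#' pair (duplicates within one database count once).
#'
#' @param tables data.frame with columns `u`, `v`, `source_db`, or a list
#'   of two-column data.frames (one per database, names used as db ids).
#' @return data.frame `u`, `v`, `weight`.
#' @export
gene_edges <- function(tables) {
  if (is.data.frame(tables)) {
    d <- tables
  } else {
    nm <- names(tables)
    if (is.null(nm)) nm <- paste0("db", seq_along(tables))
    d <- do.call(rbind, lapply(seq_along(tables), function(i) {
      t <- tables[[i]]
      data.frame(u = as.character(t[[1]]), v = as.character(t[[2]]),
                 source_db = nm[i], stringsAsFactors = FALSE)
    }))
  }
  lo <- pmin(d$u, d$v); hi <- pmax(d$u, d$v)
  keep <- !duplicated(paste(lo, hi, d$source_db)) & lo != hi
  lo <- lo[keep]; hi <- hi[keep]
  key <- paste(lo, hi)
  w <- rowsum(rep(1, length(key)), key)
  first <- !duplicated(key)
  data.frame(u = lo[first], v = hi[first],
             weight = w[key[first], 1], stringsAsFactors = FALSE)
}

#' Integrate the three channels into a validated 2-HN
#'
#' Declared nodes without edges are retained as isolated nodes.
#'
#' @param sim_edges AA-channel edges (`u`, `v`, `weight`), e.g. from
#'   [similarity_edges()].
#' @param chem_gene_edges AB-channel edges (`u` = chemical, `v` = gene,
#'   optional `weight`).
#' @param gg_edges BB-channel edges, e.g. from [gene_edges()].
#' @param chemicals,genes optional character vectors of declared node ids.
#' @return A `hetnet`.
#' @export
build_2hn <- function(sim_edges, chem_gene_edges, gg_edges,
                      chemicals = NULL, genes = NULL) {
  std <- function(e) {
    if (is.null(e) || !nrow(e))
      return(data.frame(u = character(), v = character(), weight = numeric()))
    e <- as.data.frame(e)
    if (is.null(e$weight)) e$weight <- 1
    data.frame(u = as.character(e$u), v = as.character(e$v),
               weight = as.numeric(e$weight), stringsAsFactors = FALSE)
  }
  sim <- std(sim_edges); cg <- std(chem_gene_edges); gg <- std(gg_edges)
  chemicals <- union(chemicals, c(sim$u, sim$v, cg$u))
  genes <- union(genes, c(gg$u, gg$v, cg$v))
  both <- intersect(chemicals, genes)
  if (length(both))
    stop("node(s) appear as both chemical and gene: ",
         paste(utils::head(both, 5), collapse = ", "))
  nodes <- data.frame(
    node_id = c(chemicals, genes),
    class = rep(c("A", "B"), c(length(chemicals), length(genes))),
    stringsAsFactors = FALSE)
  hetnet(nodes, rbind(sim, cg, gg))
}

#' Spearman correlation between chemical similarity and target interaction
#'
#' For every unordered pair of A nodes, x is the Tanimoto similarity of
#' their fingerprints and y counts the interactions between their target
#' sets in the BB channel: BB edges with one endpoint in each target set,
#' plus (optionally, default on) the number of shared targets. Returns the
#' Spearman rank correlation of (x, y) with its large-sample p-value.
#'
#' @param net a `hetnet` with populated AB and BB channels.
#' @param fingerprints named list of logical vectors covering the A nodes.
#' @param count_shared_targets count shared targets as interactions.
#' @return List with `rho`, `p_value`, `n_pairs`.
#' @export
similarity_interaction_correlation <- function(net, fingerprints,
                                               count_shared_targets = TRUE) {
  stopifnot(inherits(net, "hetnet"))
  a_ids <- net$nodes$node_id[net$nodes$class == "A"]
  a_ids <- intersect(a_ids, names(fingerprints))
  if (length(a_ids) < 3) stop("need at least 3 A nodes with fingerprints")
  ab <- net$edges[net$edges$channel == "AB", ]
  targets <- split(ab$v, factor(ab$u, levels = a_ids))
  bb <- net$edges[net$edges$channel == "BB", ]
  bb_adj <- split(c(bb$v, bb$u), c(bb$u, bb$v))

  mat <- do.call(cbind, fingerprints[a_ids])
  andm <- crossprod(mat)
  ones <- diag(andm)
  orm <- outer(ones, ones, "+") - andm
  simm <- ifelse(orm > 0, andm / orm, 0)

  pairs <- utils::combn(length(a_ids), 2)
  x <- simm[cbind(pairs[1, ], pairs[2, ])]
  y <- vapply(seq_len(ncol(pairs)), function(i) {
    ta <- targets[[pairs[1, i]]]
    tb <- targets[[pairs[2, i]]]
    if (!length(ta) || !length(tb)) return(0)
    inter <- sum(vapply(ta, function(g)
      sum(bb_adj[[g]] %in% tb), numeric(1)))
    if (count_shared_targets) inter <- inter + length(intersect(ta, tb))
    inter
  }, numeric(1))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance in similarity or interaction counts")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n_pairs = length(x))
}

#' Permutation test of label-induced module structure
#'
#' Scores the mixed modularity of the partition induced by external labels
#' (e.g. disease clusters), then rebuilds it under `n_perm` permutations
#' that shuffle the labels within each node class -- preserving class sizes
#' and the per-class cluster-size profile -- and reports the empirical
#' p-value (1 + #{null >= observed}) / (n_perm + 1).
#'
#' @param net a `hetnet`.
#' @param labels named integer vector covering `net` (cluster per node).
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @return List with `observed_mQ`, `null_mQ` (summary stats), `empirical_p`.
#' @export
label_permutation_test <- function(net, labels, n_perm = 999, seed = 1L) {
  labels <- as_partition(labels, net)
  stopifnot(n_perm >= 99)
  sn <- subnetwork_stats(net)
  observed <- mixed_modularity(net, labels, sn)
  isA <- net$nodes$class == "A"
  ids <- net$nodes$node_id
  null_mQ <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(i) {
      perm <- labels
      perm[ids[isA]] <- sample(unname(labels[ids[isA]]))
      perm[ids[!isA]] <- sample(unname(labels[ids[!isA]]))
      mixed_modularity(net, perm, sn)
    }, numeric(1))
  })
  list(observed_mQ = observed,
       null_mQ = c(mean = mean(null_mQ), sd = stats::sd(null_mQ),
                   max = max(null_mQ)),
       empirical_p = (1 + sum(null_mQ >= observed)) / (n_perm + 1))
}
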