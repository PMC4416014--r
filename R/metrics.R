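#' Confusion matrix of two partitions over the same node set
#'
#' Entry (i, j) counts the nodes that belong to real module i and found
#' module j.
#'
#' @param real,found named integer vectors over the same node ids.
#' @return Integer matrix with real modules as rows, found modules as
#'   columns.
#' @export
confusion_matrix <- function(real, found) {
  if (!setequal(names(real), names(found)) ||
      length(real) != length(found))
    stop("partitions must cover the same node set")
  found <- found[names(real)]
  table(real = unname(real), found = unname(found))
}

#' Normalized mutual information between two partitions
#'
#' The confusion-matrix form with natural logarithms:
#' \deqn{NMI = \frac{-2 \sum_{ij} N_{ij}\,
#'   \ln\!\frac{N_{ij} N}{N_{i.} N_{.j}}}
#'   {\sum_i N_{i.} \ln\frac{N_{i.}}{N} + \sum_j N_{.j}\ln\frac{N_{.j}}{N}}}
#' equivalently twice the mutual information over the sum of the two
#' partition entropies. Identical partitions score 1; a single-module
#' partition compared against any non-trivial one scores 0 (it carries no
#' information); two single-module partitions are identical, hence 1.
#'
#' @param real,found named integer vectors over the same node ids.
#' @return A number in [0, 1].
#' @export
nmi <- function(real, found) {
  N_ij <- confusion_matrix(real, found)
  N <- sum(N_ij)
  N_i <- rowSums(N_ij)
  N_j <- colSums(N_ij)
  denom <- sum(N_i * log(N_i / N)) + sum(N_j * log(N_j / N))
  if (denom == 0) return(1)  # both partitions trivial => identical
  ratio <- N_ij * N / outer(N_i, N_j)
  num <- sum(ifelse(N_ij > 0, N_ij * log(pmax(ratio, 1e-300)), 0))
  val <- -2 * num / denom
  min(max(val, 0), 1)
}

# best one-to-one module matching on a confusion matrix: maximum-weight
# bipartite matching (igraph); returns total matched overlap
max_overlap_matching <- function(cm) {
  nr <- nrow(cm); nc <- ncol(cm)
  idx <- which(cm > 0, arr.ind = TRUE)
  if (!nrow(idx)) return(0)
  g <- igraph::make_bipartite_graph(
    types = rep(c(FALSE, TRUE), c(nr, nc)),
    edges = as.vector(t(cbind(idx[, 1], nr + idx[, 2]))))
  m <- igraph::max_bipartite_match(g, weights = cm[idx])
  m$matching_weight
}

greedy_overlap_matching <- function(cm) {
  tot <- 0
  while (length(cm) && any(cm > 0)) {
    ij <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    tot <- tot + cm[ij[1], ij[2]]
    cm <- cm[-ij[1], -ij[2], drop = FALSE]
  }
  tot
}

#' Classification accuracy between two partitions
#'
#' Determines a one-to-one matching between real and found modules that
#' maximizes the total overlap (by default an optimal maximum-weight
#' bipartite matching on the confusion matrix; `matching = "greedy"`
#' repeatedly takes the largest remaining overlap instead) and returns the
#' fraction of nodes covered by the matched overlaps. Unmatched modules
#' contribute nothing; the denominator is always the total node count.
#'
#' @param real,found named integer vectors over the same node ids.
#' @param matching `"optimal"` or `"greedy"`.
#' @return A number in (0, 1].
#' @export
classification_accuracy <- function(real, found,
                                    matching = c("optimal", "greedy")) {
  matching <- match.arg(matching)
  cm <- confusion_matrix(real, found)
  tot <- if (matching == "optimal") max_overlap_matching(unclass(cm))
         else greedy_overlap_matching(unclass(cm))
  tot / sum(cm)
}

#' Evaluate a found partition against a reference partition
#'
#' @param real,found named integer vectors over the same node ids.
#' @param net optional `hetnet`, used to count mixed modules in `found`.
#' @param matching passed to [classification_accuracy()].
#' @return One-row data.frame with `n_modules_found`, `n_mixed_found`
#'   (NA without `net`), `nmi` and `ca`.
#' @export
evaluate_partition <- function(real, found, net = NULL,
                               matching = "optimal") {
  n_mixed <- NA_integer_
  if (!is.null(net)) {
    types <- classify_modules(net, found)
    n_mixed <- sum(types == "mixed")
  }
  data.frame(
    n_modules_found = length(unique(unname(found))),
    n_mixed_found = n_mixed,
    nmi = nmi(real, found),
    ca = classification_accuracy(real, found, matching))
}
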