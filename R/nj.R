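#' Build a neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration implemented directly: at each step the pair
#' minimising the Q criterion `Q(i,j) = (r-2) d(i,j) - R(i) - R(j)` is joined
#' (ties broken toward the lexicographically first pair, so the result does
#' not depend on input order beyond the distances themselves), branch lengths
#' follow the standard formulas, and the two clusters are replaced by their
#' join with `d(u,k) = (d(i,k) + d(j,k) - d(i,j)) / 2`. Negative branch
#' lengths — a known artefact of NJ on non-additive data — are clamped to
#' zero; the original values are kept in the `negative_branch_lengths`
#' attribute for diagnostics.
#'
#' @param dist a `pairwise_dist` (see [divergent_sites()]) or a symmetric
#'   numeric matrix with dimnames.
#' @return An unrooted `phylo` tree (compatible with the \pkg{ape} toolset;
#'   export with [export_newick()]).
#' @export
build_nj <- function(dist) {
  D <- if (inherits(dist, "pairwise_dist")) dist$d else as.matrix(dist)
  n <- nrow(D)
  if (n < 3L) stop("neighbour-joining needs at least 3 accessions")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  ids <- rownames(D)
  if (any(grepl("[(),:;\\s]", ids, perl = TRUE))) {
    stop("accession ids contain characters unsafe for newick output")
  }
  neg <- numeric(0)
  clamp <- function(x) {
    bad <- x < 0
    if (any(bad)) neg <<- c(neg, x[bad])
    pmax(x, 0)
  }
  fmt <- function(s, len) sprintf("%s:%.12g", s, len)
  node <- ids
  while (length(node) > 3L) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    hit <- which(Q == min(Q), arr.ind = TRUE)
    hit <- hit[hit[, 1L] < hit[, 2L], , drop = FALSE]
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
    i <- hit[1L, 1L]; j <- hit[1L, 2L]
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- D[i, j] - li
    li <- clamp(li); lj <- clamp(lj)
    merged <- sprintf("(%s,%s)", fmt(node[i], li), fmt(node[j], lj))
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    node <- c(node[keep], merged)
    dimnames(D2) <- NULL
    D <- D2
  }
  l1 <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  l2 <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  l3 <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  newick <- sprintf("(%s,%s,%s);", fmt(node[1L], l1), fmt(node[2L], l2),
                    fmt(node[3L], l3))
  tree <- ape::read.tree(text = newick)
  attr(tree, "negative_branch_lengths") <- neg
  tree
}

#' Classify accessions by the smallest NJ subtree they occur in
#'
#' Midpoint-roots the tree (deterministic and independent of input order),
#' then walks each query leaf's clade ladder: the level-1 neighbourhood is
#' the smallest clade properly containing the query. If a strict majority
#' (> 50%) of the non-query leaves in that clade share a species, the query
#' is assigned it; otherwise the rule escalates exactly once, to the next
#' enclosing clade. With no majority there either, the call is [AMBIGUOUS].
#' The query's own a-priori label never votes — its classification should not
#' confirm itself.
#'
#' @param tree a `phylo` tree from [build_nj()], leaves all labelled.
#' @param labels a [label_set()] covering the leaves.
#' @param root `"midpoint"` (default) or `"none"` to classify on an
#'   already-rooted tree as given.
#' @return A `species_predictions` data.frame; `support` records the clade
#'   level used and the leaf composition.
#' @export
classify_nj <- function(tree, labels, root = c("midpoint", "none")) {
  root <- match.arg(root)
  if (root == "midpoint") tree <- phangorn::midpoint(tree)
  tips <- tree$tip.label
  lab <- unclass(labels[tips])
  parent_of <- function(x) {
    p <- tree$edge[tree$edge[, 2L] == x, 1L]
    if (length(p)) p else NA_integer_
  }
  call <- support <- character(length(tips))
  for (i in seq_along(tips)) {
    node <- parent_of(i)
    level <- 0L
    decided <- FALSE
    while (!is.na(node) && level < 2L) {
      level <- level + 1L
      leaves <- phangorn::Descendants(tree, node, type = "tips")[[1L]]
      others <- setdiff(leaves, i)
      votes <- table(lab[others])
      if (length(votes) && max(votes) > length(others) / 2) {
        call[i] <- names(votes)[which.max(votes)]
        support[i] <- sprintf("level=%d;leaves=%d", level, length(others))
        decided <- TRUE
        break
      }
      node <- parent_of(node)
    }
    if (!decided) {
      call[i] <- AMBIGUOUS
      support[i] <- "no majority within two clade levels"
    }
  }
  new_predictions(tips, lab, call, support, "nj")
}

#' Write a tree in newick format
#'
#' @param tree a `phylo` object.
#' @param path output path.
#' @export
export_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
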