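# Predictions are plain data.frames so they print and subset naturally:
# columns accession, a_priori, call (species or AMBIGUOUS), support
# (diagnostic string), plus classifier-specific extras.
new_predictions <- function(accession, a_priori, call, support, classifier, ...) {
  df <- data.frame(accession = accession, a_priori = a_priori, call = call,
                   support = support, ..., row.names = NULL)
  attr(df, "classifier") <- classifier
  class(df) <- c("species_predictions", "data.frame")
  df
}

#' @export
print.species_predictions <- function(x, ...) {
  cat(sprintf("predictions (%s): %d accessions, %d ambiguous, %d disagree with a priori\n",
              attr(x, "classifier"), nrow(x), sum(x$call == AMBIGUOUS),
              sum(x$call != AMBIGUOUS & x$call != x$a_priori)))
  NextMethod()
}

#' 1-nearest-neighbour species classification
#'
#' Leave-one-out nearest neighbour: each accession is assigned the species of
#' its most similar *other* accession; its own label is never consulted. This
#' is the baseline rule — any method that cannot beat it is not worth
#' deploying — but it has a known failure mode: in a mutual nearest pair with
#' one wrong label, it fixes the wrong one and breaks the right one.
#'
#' Ties for the nearest neighbour are resolved by majority label among all
#' tied neighbours; with no strict majority the call is [AMBIGUOUS].
#'
#' @param dist a `pairwise_dist` (conventionally [divergent_sites()]).
#' @param labels a [label_set()] covering all accessions.
#' @return A `species_predictions` data.frame.
#' @export
classify_1nn <- function(dist, labels) {
  d <- dist$d
  ids <- rownames(d)
  if (length(ids) < 2L) stop("need at least 2 accessions")
  lab <- unclass(labels[ids])
  call <- support <- character(length(ids))
  for (i in seq_along(ids)) {
    di <- d[i, -i]
    nn <- names(di)[di == min(di)]
    votes <- table(lab[nn])
    top <- votes[votes == max(votes)]
    call[i] <- if (length(top) == 1L) names(top) else AMBIGUOUS
    support[i] <- sprintf("nn=%s;d=%g", paste(nn, collapse = ","), min(di))
  }
  new_predictions(ids, lab, call, support, "1nn")
}

#' Conservative 3-nearest-neighbours classification
#'
#' The recommended rule for genebank curation. The neighbour set of a query
#' consists of the query itself (at distance zero, contributing its a-priori
#' label as one vote) plus its two nearest other accessions — plus every
#' accession tied with the second-nearest other when `include_all_ties` is
#' on. A species wins when it holds the unique maximum vote count and at
#' least `l` votes; otherwise the call is [AMBIGUOUS].
#'
#' Including the query among its own neighbours raises the burden of proof to
#' overturn an a-priori label (two dissenting neighbours are needed) while a
#' single agreeing neighbour suffices to confirm it — so a species needs only
#' two correctly labelled accessions for an unambiguous self-confirmation,
#' rather than three.
#'
#' @param dist a `pairwise_dist`; Euclidean distance on imputed codes is the
#'   conventional pairing ([euclidean_distance()]).
#' @param labels a [label_set()] covering all accessions.
#' @param k neighbourhood size including the query; fixed at 3 for the
#'   conservative rule.
#' @param l minimum votes the winning species must gather (`l <= k`).
#' @param include_all_ties when several accessions tie with the k-th
#'   neighbour, let them all vote.
#' @return A `species_predictions` data.frame with a `votes` column.
#' @export
classify_3nn_conservative <- function(dist, labels, k = 3L, l = 2L,
                                      include_all_ties = TRUE) {
  stopifnot(k >= 1L, l <= k)
  d <- dist$d
  ids <- rownames(d)
  if (length(ids) < k) stop(sprintf("need at least %d accessions", k))
  lab <- unclass(labels[ids])
  call <- support <- votes_str <- character(length(ids))
  for (i in seq_along(ids)) {
    di <- d[i, -i]
    ord <- order(di, names(di)) # stable
    kth <- di[ord[k - 1L]]
    nn <- if (include_all_ties) names(di)[di <= kth] else names(di)[ord[seq_len(k - 1L)]]
    votes <- table(c(lab[i], lab[nn]))
    top <- votes[votes == max(votes)]
    ok <- length(top) == 1L && top[1L] >= l
    call[i] <- if (ok) names(top) else AMBIGUOUS
    votes_str[i] <- paste(sprintf("%s:%d", names(votes), votes), collapse = ",")
    support[i] <- sprintf("neighbours=%s", paste(nn, collapse = ","))
  }
  new_predictions(ids, lab, call, support, "3nn", votes = votes_str)
}
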