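#' Random-forest classification by out-of-bag voting
#'
#' Grows a classification forest (bootstrap with replacement, gini impurity
#' splits, `mtry = floor(sqrt(p))` by default) via \pkg{ranger}, then calls
#' each accession from the trees for which it was out of bag — the trees
#' whose bootstrap sample did not contain it — so no accession is judged by
#' trees it helped build. With `B` trees and `n` accessions each sample is
#' out of bag for about `B (1 - 1/n)^n ~ 0.368 B` trees (about 3,680 of the
#' default 10,000), which is why the forest is grown this large.
#'
#' The call is the plurality species over OOB trees, ties broken toward the
#' lexicographically first species. An accession that is in-bag for every
#' tree (only possible for tiny forests) is called [AMBIGUOUS].
#'
#' @param gm a fully imputed [genotype_matrix()] (no missing calls).
#' @param labels a [label_set()] covering all accessions; at least 2 species.
#' @param n_trees number of trees (default 10000).
#' @param mtry features tried per split; default `floor(sqrt(p))`.
#' @param seed integer seed for the forest.
#' @return A `species_predictions` data.frame with `oob_fraction` (vote
#'   fraction of the winning species over OOB trees) and `n_oob` (number of
#'   OOB trees per accession).
#' @export
classify_rf_oob <- function(gm, labels, n_trees = 10000L, mtry = NULL,
                            seed = NULL) {
  if (anyNA(gm)) stop("missing calls present; run impute_most_common() first")
  lab <- unclass(align_labels(gm, labels))
  classes <- sort(unique(lab))
  if (length(classes) < 2L) stop("need at least 2 species")
  y <- factor(lab, levels = classes)
  x <- as.data.frame(unclass(gm))
  colnames(x) <- make.names(colnames(x), unique = TRUE)
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(x))))
  fit <- ranger::ranger(x = x, y = y, num.trees = n_trees, mtry = mtry,
                        splitrule = "gini", replace = TRUE,
                        keep.inbag = TRUE, seed = seed,
                        num.threads = 1L, verbose = FALSE)
  # per-tree predictions come back as factor level codes of y
  pa <- stats::predict(fit, x, predict.all = TRUE,
                       num.threads = 1L)$predictions
  inbag <- do.call(cbind, fit$inbag.counts)
  oob <- inbag == 0L
  n <- nrow(x)
  call <- character(n)
  frac <- numeric(n)
  n_oob <- rowSums(oob)
  for (i in seq_len(n)) {
    if (n_oob[i] == 0L) {
      call[i] <- AMBIGUOUS
      frac[i] <- NA_real_
      next
    }
    votes <- tabulate(pa[i, oob[i, ]], nbins = length(classes))
    w <- which.max(votes) # first max = lexicographic (classes sorted)
    call[i] <- classes[w]
    frac[i] <- votes[w] / n_oob[i]
  }
  new_predictions(accessions(gm), lab, call,
                  sprintf("oob_trees=%d", n_oob), "rf",
                  oob_fraction = frac, n_oob = n_oob)
}
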