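#' Random-forest proximity matrix
#'
#' Grows a forest on the labelled accessions and records, for every pair,
#' the fraction of trees in which the two land in the same terminal node.
#' The proximity of an accession to others of its declared species is the
#' raw material of the misclassification screen in [outlier_scores()].
#'
#' Proximity can be accumulated over all trees (the classical convention,
#' default) or over out-of-bag pairs only (`oob_only = TRUE`), which is less
#' optimistic for pairs that co-occurred in many bootstrap samples.
#'
#' @param gm a fully imputed [genotype_matrix()].
#' @param labels a [label_set()] covering all accessions.
#' @param n_trees number of trees; the screen is conventionally run with a
#'   large forest (default 50000) so proximities are well resolved.
#' @param seed integer seed.
#' @param oob_only accumulate proximity over out-of-bag pairs only.
#' @return A symmetric matrix of proximities in `[0, 1]` with unit diagonal,
#'   accession ids as dimnames.
#' @export
rf_proximity <- function(gm, labels, n_trees = 50000L, seed = NULL,
                         oob_only = FALSE) {
  if (anyNA(gm)) stop("missing calls present; run impute_most_common() first")
  lab <- unclass(align_labels(gm, labels))
  y <- factor(lab, levels = sort(unique(lab)))
  x <- as.data.frame(unclass(gm))
  colnames(x) <- make.names(colnames(x), unique = TRUE)
  fit <- local_seed(seed, randomForest::randomForest(
    x = x, y = y, ntree = n_trees, proximity = TRUE, oob.prox = oob_only))
  prox <- fit$proximity
  dimnames(prox) <- list(accessions(gm), accessions(gm))
  diag(prox) <- 1
  prox
}

#' Proximity-based misclassification screen
#'
#' Flags accessions with small proximities to the other members of their
#' declared species, relative to the proximities those members have to each
#' other. The raw outlyingness of accession `i` in a class of size `n` is
#' `n / sum of squared proximities to its classmates` (self excluded); per
#' class, scores are centred by the class median and scaled by the class
#' MAD (standard consistency constant). Scores above `threshold` (default
#' 10, the conventional cut-off) are flagged.
#'
#' The screen is advisory. When missing data were imputed with the
#' per-marker modal call, accessions with heavy missingness are dragged
#' toward the majority species' genotype and show up as false-positive
#' outliers of their own species; do not exclude flagged accessions on this
#' screen alone if the input had substantial missingness.
#'
#' @param prox proximity matrix from [rf_proximity()].
#' @param labels a [label_set()] covering the accessions.
#' @param threshold flag scores strictly above this value.
#' @return A data.frame (class `outlier_scores`) with columns `accession`,
#'   `species`, `score`, `flagged`. Accessions whose species has a single
#'   member get `NA` scores and are never flagged.
#' @export
outlier_scores <- function(prox, labels, threshold = 10) {
  ids <- rownames(prox)
  lab <- unclass(labels[ids])
  score <- rep(NA_real_, length(ids))
  for (cl in unique(lab)) {
    member <- which(lab == cl)
    n <- length(member)
    if (n < 2L) next
    sub <- prox[member, member, drop = FALSE]
    raw <- vapply(seq_len(n), function(i) {
      s <- sum(sub[i, -i]^2)
      n / max(s, .Machine$double.eps)
    }, numeric(1))
    med <- stats::median(raw)
    scale <- stats::mad(raw)
    if (scale == 0) {
      warning(sprintf("class '%s': zero MAD of raw outlyingness; scores left unscaled", cl))
      scale <- 1
    }
    score[member] <- (raw - med) / scale
  }
  out <- data.frame(accession = ids, species = lab,
                    score = score,
                    flagged = !is.na(score) & score > threshold,
                    row.names = NULL)
  attr(out, "threshold") <- threshold
  class(out) <- c("outlier_scores", "data.frame")
  out
}

#' @rdname outlier_scores
#' @param scores an `outlier_scores` data.frame.
#' @param path output path (TSV).
#' @export
write_outlier_scores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
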