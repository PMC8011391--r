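#' Pairwise dissimilarities between accessions
#'
#' Two dissimilarities are used by the classifiers, matching how each was
#' originally paired with its distance:
#'
#' * [divergent_sites()] — the number of markers at which two accessions
#'   carry different calls, with *pairwise deletion*: markers missing in
#'   either accession are ignored for that pair. The raw count is kept
#'   deliberately — it is **not** normalised by the number of comparable
#'   sites, so accessions with heavy missingness tend to look artificially
#'   close to everything. This reproduces the behaviour of the classical
#'   divergent-site distance as used for 1-NN and neighbour-joining; treat
#'   nearest-neighbour results for missing-rich accessions with care.
#' * [euclidean_distance()] — Euclidean distance on the integer dosage codes
#'   of a fully imputed matrix, used by the conservative 3-NN rule.
#'
#' @param gm a [genotype_matrix()]; for [euclidean_distance()] it must be
#'   free of missing calls (run [impute_most_common()] first).
#' @return An object of class `pairwise_dist`: a list with `d` (symmetric
#'   numeric matrix, zero diagonal), `comparable_sites` (integer matrix of
#'   per-pair comparable marker counts; `NULL` for Euclidean), and `method`.
#' @name distances
NULL

new_pairwise_dist <- function(d, comparable, method) {
  structure(list(d = d, comparable_sites = comparable, method = method),
            class = "pairwise_dist")
}

#' @export
print.pairwise_dist <- function(x, ...) {
  cat(sprintf("pairwise distances (%s): %d accessions\n",
              x$method, nrow(x$d)))
  invisible(x)
}

#' @rdname distances
#' @export
divergent_sites <- function(gm) {
  if (nrow(gm) < 2L) stop("need at least 2 accessions")
  calls <- unclass(gm)
  obs <- !is.na(calls)
  mode(obs) <- "numeric"
  comparable <- tcrossprod(obs)
  equal <- matrix(0, nrow(calls), nrow(calls))
  for (v in genotype_alphabet(ploidy_mode(gm))) {
    ind <- (!is.na(calls)) & calls == v
    mode(ind) <- "numeric"
    equal <- equal + tcrossprod(ind)
  }
  d <- comparable - equal
  diag(d) <- 0
  off <- comparable == 0
  diag(off) <- FALSE
  if (any(off)) {
    ij <- which(off, arr.ind = TRUE)[1L, ]
    stop(sprintf("accessions '%s' and '%s' share no comparable sites; distance undefined",
                 rownames(calls)[ij[1L]], rownames(calls)[ij[2L]]))
  }
  dimnames(d) <- list(rownames(calls), rownames(calls))
  storage.mode(comparable) <- "integer"
  dimnames(comparable) <- dimnames(d)
  new_pairwise_dist(d, comparable, "divergent_sites")
}

#' @rdname distances
#' @export
euclidean_distance <- function(gm) {
  if (anyNA(gm)) {
    stop("missing calls present; run impute_most_common() before euclidean_distance()")
  }
  d <- as.matrix(stats::dist(unclass(gm), method = "euclidean"))
  dimnames(d) <- list(accessions(gm), accessions(gm))
  new_pairwise_dist(d, NULL, "euclidean")
}

#' Export a distance matrix as square TSV
#'
#' Header row and first column carry accession ids.
#'
#' @param pd a `pairwise_dist`.
#' @param path output path.
#' @export
write_distance <- function(pd, path) {
  df <- data.frame(accession = rownames(pd$d), pd$d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
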