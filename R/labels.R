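#' Accession-to-species label assignments
#'
#' A named character vector of species labels keyed by accession id, carrying
#' a provenance flag: `a_priori` for labels as documented in the collection,
#' `perturbed` for labels after simulated misclassification injection (see
#' [inject_misclassifications()]), `predicted` for classifier output. When
#' labels are perturbed, the originals are retained in the `true_labels`
#' attribute so benchmark accuracy can be scored against the truth.
#'
#' @param species character vector of species names, named by accession id,
#'   or a two-column data.frame (accession, species).
#' @param provenance one of `"a_priori"`, `"perturbed"`, `"predicted"`.
#' @param true_labels optional named character vector of the pre-perturbation
#'   labels.
#' @return An object of class `label_set`.
#' @export
label_set <- function(species, provenance = c("a_priori", "perturbed", "predicted"),
                      true_labels = NULL) {
  provenance <- match.arg(provenance)
  if (is.data.frame(species)) {
    if (ncol(species) < 2L) stop("label data.frame needs (accession, species) columns")
    species <- stats::setNames(as.character(species[[2L]]),
                               as.character(species[[1L]]))
  }
  if (is.null(names(species)) || anyDuplicated(names(species))) {
    stop("labels must be named by unique accession ids")
  }
  nm <- names(species)
  species <- stats::setNames(as.character(species), nm)
  if (any(!nzchar(species)) || anyNA(species)) stop("species names must be non-empty")
  if (any(species == AMBIGUOUS)) {
    stop(sprintf("'%s' is reserved and cannot be a species name", AMBIGUOUS))
  }
  structure(species, provenance = provenance, true_labels = true_labels,
            class = "label_set")
}

#' @export
print.label_set <- function(x, ...) {
  cat(sprintf("label set: %d accessions, %d species (%s)\n",
              length(x), length(unique(unclass(x))), attr(x, "provenance")))
  print(sort(table(unclass(x)), decreasing = TRUE))
  invisible(x)
}

#' @export
`[.label_set` <- function(x, i) {
  tl <- attr(x, "true_labels")
  y <- unclass(x)[i]
  label_set(y, attr(x, "provenance"),
            true_labels = if (!is.null(tl)) tl[names(y)] else NULL)
}

#' @rdname label_set
#' @param labels a `label_set`.
#' @export
label_provenance <- function(labels) attr(labels, "provenance")

#' @rdname label_set
#' @export
true_labels <- function(labels) {
  attr(labels, "true_labels") %||% stats::setNames(unclass(labels), names(labels))
}

# Assert that labels cover the accessions of gm; return them in gm order.
align_labels <- function(gm, labels) {
  ids <- accessions(gm)
  missing_ids <- setdiff(ids, names(labels))
  if (length(missing_ids)) {
    stop(sprintf("unlabelled accessions: %s",
                 paste(utils::head(missing_ids, 5L), collapse = ", ")))
  }
  labels[ids]
}

#' Read / write two-column label tables
#'
#' Tab-separated, two columns: accession id, species name. A header line is
#' detected and skipped if its first field is `accession`.
#'
#' @param path file path.
#' @return [read_labels()] returns a `label_set`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop_specurate(paste("cannot read", path), "specurate_io_error")
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "")
  if (nrow(df) && identical(tolower(df[1L, 1L]), "accession")) df <- df[-1L, , drop = FALSE]
  if (nrow(df) == 0L) stop_empty("label file contains no rows")
  label_set(df)
}

#' @rdname read_labels
#' @param labels a `label_set`.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(
    data.frame(accession = names(labels), species = unclass(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
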