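#' Construct a genotype matrix
#'
#' The central container of the toolkit: an accessions x markers integer
#' matrix of genotype calls. Diploid SNP data are coded as ALT-allele dosage
#' (0, 1, 2); dominant marker systems such as AFLP are coded presence/absence
#' (0, 1). Missing calls are `NA`. One integer alphabet serves both
#' resequencing and dominant data, so every classifier downstream works on
#' either.
#'
#' @param calls integer matrix with unique rownames (accession ids) and
#'   unique colnames (marker ids). `NA` marks missing calls.
#' @param ploidy_mode `"dosage"` (calls in 0:2) or `"dominant"` (calls in 0:1).
#' @param het_markers character vector of marker ids flagged as carrying
#'   heterozygous scores in dominant data (an anomaly for AFLP; see
#'   [filter_dominant_markers()]).
#'
#' @return An object of class `geno_matrix`: the integer matrix with
#'   attributes `ploidy_mode` and `het_markers`.
#' @seealso [read_genotype_matrix()], [read_vcf_genotypes()],
#'   [impute_most_common()]
#' @export
genotype_matrix <- function(calls, ploidy_mode = c("dosage", "dominant"),
                            het_markers = character()) {
  ploidy_mode <- match.arg(ploidy_mode)
  if (!is.matrix(calls)) stop("`calls` must be a matrix")
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls)) || is.null(colnames(calls))) {
    stop("`calls` needs rownames (accessions) and colnames (markers)")
  }
  if (anyDuplicated(rownames(calls))) stop("duplicate accession ids")
  if (anyDuplicated(colnames(calls))) stop("duplicate marker ids")
  alphabet <- genotype_alphabet(ploidy_mode)
  bad <- !is.na(calls) & !(calls %in% alphabet)
  if (any(bad)) {
    stop(sprintf("calls outside {%s} found for ploidy_mode '%s'",
                 paste(alphabet, collapse = ","), ploidy_mode))
  }
  het_markers <- as.character(het_markers)
  if (!all(het_markers %in% colnames(calls))) {
    stop("het_markers contains unknown marker ids")
  }
  structure(calls, ploidy_mode = ploidy_mode, het_markers = het_markers,
            class = c("geno_matrix", "matrix", "array"))
}

genotype_alphabet <- function(ploidy_mode) {
  if (ploidy_mode == "dosage") 0:2 else 0:1
}

#' @export
print.geno_matrix <- function(x, ...) {
  miss <- mean(is.na(x))
  cat(sprintf("genotype matrix: %d accessions x %d markers (%s), %.1f%% missing\n",
              nrow(x), ncol(x), attr(x, "ploidy_mode"), 100 * miss))
  if (length(attr(x, "het_markers"))) {
    cat(sprintf("  %d marker(s) flagged heterozygous\n",
                length(attr(x, "het_markers"))))
  }
  invisible(x)
}

#' @rdname genotype_matrix
#' @param gm a `geno_matrix`.
#' @export
accessions <- function(gm) rownames(gm)

#' @rdname genotype_matrix
#' @export
markers <- function(gm) colnames(gm)

#' @rdname genotype_matrix
#' @export
ploidy_mode <- function(gm) attr(gm, "ploidy_mode")

#' @rdname genotype_matrix
#' @export
het_markers <- function(gm) attr(gm, "het_markers")

# Rebuild a geno_matrix after subsetting, preserving attributes.
keep_markers <- function(gm, idx) {
  calls <- unclass(gm)[, idx, drop = FALSE]
  genotype_matrix(calls, ploidy_mode(gm),
                  intersect(het_markers(gm), colnames(calls)))
}

keep_accessions <- function(gm, idx) {
  calls <- unclass(gm)[idx, , drop = FALSE]
  genotype_matrix(calls, ploidy_mode(gm), het_markers(gm))
}

#' Remove flagged and rare dominant markers
#'
#' Curation rule for dominant (presence/absence) marker data: markers flagged
#' as heterozygous at read time are removed first — heterozygous scores are
#' anomalous for a dominant system — then markers whose minor allele frequency
#' falls below `min_maf` are removed. For dominant data the MAF of a marker is
#' `min(p, 1 - p)` with `p` the presence frequency over non-missing calls.
#'
#' @param gm a dominant-mode [genotype_matrix()].
#' @param min_maf minimum minor allele frequency; markers with MAF strictly
#'   below it are dropped. Default 0.01.
#' @return The filtered `geno_matrix`. May hold zero markers; this is
#'   reported with a warning rather than an error.
#' @export
filter_dominant_markers <- function(gm, min_maf = 0.01) {
  if (ploidy_mode(gm) != "dominant") {
    stop("filter_dominant_markers() expects dominant-mode data")
  }
  keep <- !(markers(gm) %in% het_markers(gm))
  gm2 <- keep_markers(gm, keep)
  p <- colMeans(unclass(gm2), na.rm = TRUE)
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0 # all-missing markers carry no signal
  out <- keep_markers(gm2, maf >= min_maf)
  if (ncol(out) == 0L) warning("no markers survive the dominant-marker filter")
  out
}

#' Randomly thin markers to a maximum count
#'
#' Draws a uniform random subset of markers without replacement, preserving
#' the original marker order. Random thinning is one of the two marker
#' selection strategies offered for large resequencing panels (the other
#' being strict quality filtering, see [filter_spec()]).
#'
#' @inheritParams filter_dominant_markers
#' @param max_sites maximum number of markers to retain (>= 1).
#' @param seed optional integer; fixes the subset.
#' @return A `geno_matrix` with `min(max_sites, ncol(gm))` markers.
#' @export
thin_markers <- function(gm, max_sites, seed = NULL) {
  stopifnot(max_sites >= 1)
  p <- ncol(gm)
  if (max_sites >= p) return(gm)
  idx <- local_seed(seed, sort(sample.int(p, max_sites)))
  keep_markers(gm, idx)
}

#' Impute missing calls with the per-marker modal value
#'
#' Replaces each missing call with the most common non-missing call of its
#' marker column. This is deliberately crude: it is fast, makes no model
#' assumptions, and uses no class information — but it biases missing-rich
#' accessions toward the majority genotype, which matters for the proximity
#' outlier screen (see [outlier_scores()]). Modal ties are broken toward the
#' lowest code so that results are reproducible.
#'
#' @inheritParams filter_dominant_markers
#' @return A `geno_matrix` with no missing calls. Idempotent.
#' @export
impute_most_common <- function(gm) {
  calls <- unclass(gm)
  na_cols <- which(colSums(is.na(calls)) > 0L)
  for (j in na_cols) {
    col <- calls[, j]
    obs <- col[!is.na(col)]
    if (length(obs) == 0L) {
      stop(sprintf("marker '%s' has no observed calls; cannot impute",
                   colnames(calls)[j]))
    }
    tab <- tabulate(obs + 1L, nbins = max(genotype_alphabet(ploidy_mode(gm))) + 1L)
    modal <- which(tab == max(tab))[1L] - 1L # ties -> lowest code
    col[is.na(col)] <- modal
    calls[, j] <- col
  }
  genotype_matrix(calls, ploidy_mode(gm), het_markers(gm))
}

#' Drop accessions with excessive missing data
#'
#' A genotype-level proxy for sequencing-depth quality control on accessions:
#' raw-read counts are unavailable once data are reduced to genotype calls, so
#' accessions are screened by their fraction of missing calls instead.
#'
#' @inheritParams filter_dominant_markers
#' @param max_missing maximum tolerated fraction of missing calls per
#'   accession; accessions strictly above it are removed.
#' @return The filtered `geno_matrix`.
#' @export
filter_missing_accessions <- function(gm, max_missing) {
  stopifnot(max_missing >= 0, max_missing <= 1)
  frac <- rowMeans(is.na(unclass(gm)))
  out <- keep_accessions(gm, frac <= max_missing)
  if (nrow(out) == 0L) stop_empty("no accessions survive the missingness filter")
  out
}
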