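#' Site and genotype filter settings for VCF import
#'
#' Mirrors the standard quality filters applied to resequencing panels before
#' classification: per-genotype read-depth masking, then site-level call-rate
#' and minor-allele-frequency thresholds, with indel (and multi-allelic)
#' records removed.
#'
#' @param min_call_rate minimum fraction of non-missing genotypes a site must
#'   retain (after depth masking) to be kept.
#' @param min_maf minimum minor allele frequency (allele-count based) a site
#'   must retain to be kept.
#' @param drop_indels drop records whose REF or ALT is not a single base.
#' @param min_call_depth genotype calls backed by fewer than this many reads
#'   are set to missing before the site filters run; 0 disables and the VCF
#'   then needs no DP field.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(min_call_rate = 0, min_maf = 0, drop_indels = TRUE,
                        min_call_depth = 0) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1,
            min_maf >= 0, min_maf <= 1,
            min_call_depth >= 0)
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 drop_indels = isTRUE(drop_indels),
                 min_call_depth = as.integer(min_call_depth)),
            class = "filter_spec")
}

#' Read a genotype matrix from a VCF file
#'
#' Imports biallelic SNP genotypes as ALT-allele dosage (0/1/2). Multi-allelic
#' records are always dropped; indels are dropped when the filter says so.
#' When `min_call_depth > 0`, individual genotype calls with `DP` below the
#' threshold are masked to missing *before* the site-level call-rate and MAF
#' filters are evaluated, so depth masking can itself push a site below the
#' call-rate threshold.
#'
#' @param path path to a VCF 4.x file (plain or bgzipped) with per-sample GT,
#'   and per-genotype DP if depth filtering is requested.
#' @param spec a [filter_spec()].
#' @return A dosage-mode [genotype_matrix()] (accessions x markers). Marker
#'   ids are `CHROM:POS`.
#' @export
read_vcf_genotypes <- function(path, spec = filter_spec()) {
  if (!file.exists(path)) stop_specurate(paste("cannot read", path), "specurate_io_error")
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop_specurate(
                  paste("failed to parse VCF:", conditionMessage(e)),
                  "specurate_io_error"))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) # biallelic only
  if (spec$drop_indels) {
    keep <- keep & nchar(ref) == 1L & nchar(alt) == 1L & alt != "*"
  }
  if (!any(keep)) stop_empty("no biallelic SNP records in VCF")

  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  dosage <- gt_to_dosage(gt)
  if (spec$min_call_depth > 0L) {
    if (!grepl("DP", unique(v@gt[, "FORMAT"])[1L], fixed = TRUE)) {
      stop("min_call_depth > 0 requires a per-genotype DP field")
    }
    dp <- suppressWarnings(
      vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))[keep, , drop = FALSE]
    dosage[is.na(dp) | dp < spec$min_call_depth] <- NA_integer_
  }

  called <- rowMeans(!is.na(dosage))
  alt_af <- rowSums(dosage, na.rm = TRUE) / (2 * rowSums(!is.na(dosage)))
  maf <- pmin(alt_af, 1 - alt_af)
  maf[is.nan(maf)] <- 0
  ok <- called >= spec$min_call_rate & maf >= spec$min_maf
  if (!any(ok)) stop_empty("no sites survive the call-rate/MAF filters")
  dosage <- dosage[ok, , drop = FALSE]
  ids <- paste(fix[keep, "CHROM"], fix[keep, "POS"], sep = ":")[ok]
  rownames(dosage) <- ids
  genotype_matrix(t(dosage), "dosage")
}

# "0/1", "0|1", "./." etc. -> ALT dosage; anything unparseable -> NA
gt_to_dosage <- function(gt) {
  code <- function(x) {
    alleles <- strsplit(x, "[/|]")
    vapply(alleles, function(a) {
      if (length(a) != 2L || any(a == ".") || anyNA(a)) return(NA_integer_)
      sum(a == "1")
    }, integer(1))
  }
  out <- matrix(code(as.vector(gt)), nrow = nrow(gt), dimnames = dimnames(gt))
  out
}

#' Read / write a delimited genotype matrix
#'
#' Plain-text dialect: header row of marker ids, first column of accession
#' ids, cells integer calls or the token `NA` for missing. Tab- or
#' comma-separated (chosen by file extension, `.csv` meaning comma).
#'
#' In dominant mode a cell equal to 2 — a "heterozygous" score, anomalous for
#' a dominant marker system — is accepted at read time: the affected marker is
#' flagged (see [het_markers()]) and the cell stored as missing, leaving the
#' decision to [filter_dominant_markers()]. Any other out-of-alphabet or
#' non-integer cell is an error.
#'
#' @param path file path.
#' @param ploidy_mode `"dosage"` or `"dominant"`.
#' @return A [genotype_matrix()].
#' @export
read_genotype_matrix <- function(path, ploidy_mode = c("dosage", "dominant")) {
  ploidy_mode <- match.arg(ploidy_mode)
  if (!file.exists(path)) stop_specurate(paste("cannot read", path), "specurate_io_error")
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- tryCatch(
    utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                      colClasses = "character", quote = ""),
    error = function(e) stop_specurate(
      paste("failed to read matrix:", conditionMessage(e)), "specurate_io_error"))
  if (nrow(df) == 0L || ncol(df) < 2L) stop_empty("matrix file has no data cells")
  ids <- df[[1L]]
  if (anyDuplicated(ids)) stop("duplicate accession ids in matrix file")
  mk <- colnames(df)[-1L]
  if (anyDuplicated(mk)) stop("duplicate marker ids in matrix file")
  cells <- as.matrix(df[, -1L, drop = FALSE])
  is_na_tok <- is.na(cells) | cells == "NA" | cells == ""
  num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  if (any(is.na(num) & !is_na_tok)) stop("non-integer cell in matrix file")
  if (any(!is.na(num) & num != floor(num))) stop("non-integer cell in matrix file")
  calls <- matrix(as.integer(num), nrow = length(ids),
                  dimnames = list(ids, mk))
  het <- character()
  if (ploidy_mode == "dominant") {
    het_cells <- !is.na(calls) & calls == 2L
    het <- mk[colSums(het_cells) > 0L]
    calls[het_cells] <- NA_integer_
  }
  genotype_matrix(calls, ploidy_mode, het_markers = het)
}

#' @rdname read_genotype_matrix
#' @param gm a `geno_matrix`.
#' @export
write_genotype_matrix <- function(gm, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(accession = accessions(gm), unclass(gm),
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
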