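#' Generate a synthetic multi-species genotype collection
#'
#' Simulates a genotyped germplasm collection with controllable species
#' divergence, for validating the classifiers and the benchmark harness.
#' Per marker, an ancestral allele frequency `p` is drawn uniformly from
#' `ancestral_maf`; each species then receives its own frequency from the
#' Balding-Nichols model,
#' `p_s ~ Beta(p (1 - F) / F, (1 - p)(1 - F) / F)`,
#' whose divergence parameter `F` is the expected FST between species.
#' Genotypes are `Binomial(2, p_s)` dosages (or `Bernoulli(p_s)` presence
#' calls in dominant mode), and a missing mask is applied i.i.d. at
#' `missing_rate`. Markers are unlinked.
#'
#' The defaults mirror the curated-benchmark conditions: 8 species of 10
#' accessions, 2000 markers, strong divergence (F = 0.5) of the kind seen
#' between well-separated congeners, no missing data.
#'
#' @param n_species number of species.
#' @param n_per_species accessions per species; scalar or one count per
#'   species.
#' @param n_markers number of markers.
#' @param divergence Balding-Nichols F, in (0, 1).
#' @param ancestral_maf range the ancestral allele frequency is drawn from.
#' @param missing_rate i.i.d. missing-call probability, in `[0, 1)`.
#' @param ploidy_mode `"dosage"` or `"dominant"`.
#' @param seed integer seed; the same seed reproduces the collection
#'   bit-identically.
#' @return A list: `genotypes` ([genotype_matrix()]), `labels`
#'   ([label_set()], provenance `a_priori`), and `truth` — the ancestral and
#'   per-species allele frequencies plus the parameters, for downstream
#'   checks.
#' @export
generate_collection <- function(n_species = 8L, n_per_species = 10L,
                                n_markers = 2000L, divergence = 0.5,
                                ancestral_maf = c(0.05, 0.5),
                                missing_rate = 0, ploidy_mode = c("dosage", "dominant"),
                                seed = NULL) {
  ploidy_mode <- match.arg(ploidy_mode)
  stopifnot(n_species >= 1L, n_markers >= 1L,
            divergence > 0, divergence < 1,
            missing_rate >= 0, missing_rate < 1,
            length(ancestral_maf) == 2L, all(ancestral_maf > 0 & ancestral_maf < 1))
  counts <- rep_len(as.integer(n_per_species), n_species)
  stopifnot(all(counts >= 1L))
  sp_names <- sprintf("sp%02d", seq_len(n_species))
  local_seed(seed, {
    p_anc <- stats::runif(n_markers, ancestral_maf[1L], ancestral_maf[2L])
    f <- divergence
    p_sp <- vapply(seq_len(n_species), function(s) {
      stats::rbeta(n_markers, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
    }, numeric(n_markers))  # markers x species
    copies <- if (ploidy_mode == "dosage") 2L else 1L
    rows <- vector("list", n_species)
    ids <- character(0)
    for (s in seq_len(n_species)) {
      g <- matrix(stats::rbinom(counts[s] * n_markers, copies,
                                rep(p_sp[, s], each = counts[s])),
                  nrow = counts[s])
      rows[[s]] <- g
      ids <- c(ids, sprintf("%s_%03d", sp_names[s], seq_len(counts[s])))
    }
    calls <- do.call(rbind, rows)
    if (missing_rate > 0) {
      calls[stats::runif(length(calls)) < missing_rate] <- NA_integer_
    }
    dimnames(calls) <- list(ids, sprintf("m%05d", seq_len(n_markers)))
    gm <- genotype_matrix(calls, ploidy_mode)
    labels <- label_set(stats::setNames(rep(sp_names, counts), ids))
    list(genotypes = gm, labels = labels,
         truth = list(p_ancestral = p_anc, p_species = p_sp,
                      params = list(n_species = n_species, counts = counts,
                                    n_markers = n_markers,
                                    divergence = divergence,
                                    ancestral_maf = ancestral_maf,
                                    missing_rate = missing_rate,
                                    ploidy_mode = ploidy_mode, seed = seed)))
  })
}

#' Write a minimal synthetic VCF for a dosage genotype matrix
#'
#' Emits a small, valid VCF 4.2 file (GT plus optional per-genotype DP) so
#' that the VCF import path can be exercised on synthetic collections. This
#' is a fixture emitter, not a general-purpose VCF writer: one synthetic
#' chromosome, positions 1..p, REF/ALT fixed to A/T.
#'
#' @param gm a dosage-mode [genotype_matrix()].
#' @param path output path.
#' @param depths optional accessions x markers integer matrix of read
#'   depths to emit as DP.
#' @export
write_synthetic_vcf <- function(gm, path, depths = NULL) {
  stopifnot(ploidy_mode(gm) == "dosage")
  if (!is.null(depths)) stopifnot(identical(dim(depths), dim(unclass(gm))))
  gt_of <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=chrS>",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               if (!is.null(depths))
                 '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", accessions(gm)), collapse = "\t")),
             con)
  calls <- unclass(gm)
  fmt <- if (is.null(depths)) "GT" else "GT:DP"
  for (j in seq_len(ncol(calls))) {
    gts <- ifelse(is.na(calls[, j]), "./.", gt_of[calls[, j] + 1L])
    if (!is.null(depths)) gts <- paste(gts, depths[, j], sep = ":")
    writeLines(paste(c("chrS", j, colnames(calls)[j], "A", "T", ".", "PASS",
                       ".", fmt, gts), collapse = "\t"), con)
  }
  invisible(path)
}
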