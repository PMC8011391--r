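# Fixture builders and independent oracles shared across the suite.

# A deterministic collection of tight, well-separated species clusters:
# each species has a private block of markers fixed at dosage 2, everything
# else 0. Within-species distance is 0, between-species distance is large.
tight_clusters <- function(sizes, block = NULL) {
  n_sp <- length(sizes)
  sp <- names(sizes) %||% sprintf("sp%02d", seq_len(n_sp))
  n <- sum(sizes)
  # the species block must dominate the per-accession jitter (max 2n - 1
  # jitter sites between a pair) so clusters stay tight under both distances
  block <- block %||% max(10L, n)
  calls <- matrix(0L, n, n_sp * block)
  ids <- character(n)
  lab <- character(n)
  row <- 0L
  for (s in seq_len(n_sp)) {
    for (i in seq_len(sizes[s])) {
      row <- row + 1L
      calls[row, (s - 1L) * block + seq_len(block)] <- 2L
      ids[row] <- sprintf("%s_%02d", sp[s], i)
      lab[row] <- sp[s]
    }
  }
  # accession r carries r private jitter markers: every distance from a
  # fixed query is then unique, so neighbour ranks have no accidental ties
  jitter <- matrix(0L, n, n * (n + 1L) / 2L)
  col <- 0L
  for (r in seq_len(n)) {
    jitter[r, col + seq_len(r)] <- 1L
    col <- col + r
  }
  calls <- cbind(calls, jitter)
  dimnames(calls) <- list(ids, sprintf("m%04d", seq_len(ncol(calls))))
  list(genotypes = genotype_matrix(calls, "dosage"),
       labels = label_set(stats::setNames(lab, ids)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hand-rolled pairwise_dist for vote-rule fixtures.
manual_dist <- function(d, method = "euclidean") {
  specurate:::new_pairwise_dist(d, NULL, method)
}

# Brute-force divergent-site counts: explicit double loop over sites.
brute_divergent <- function(calls) {
  n <- nrow(calls)
  d <- comp <- matrix(0, n, n, dimnames = list(rownames(calls), rownames(calls)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    for (m in seq_len(ncol(calls))) {
      a <- calls[i, m]; b <- calls[j, m]
      if (!is.na(a) && !is.na(b)) {
        comp[i, j] <- comp[i, j] + 1
        if (a != b) d[i, j] <- d[i, j] + 1
      }
    }
  }
  list(d = d, comparable = comp)
}

# Naive per-pair Euclidean summation.
brute_euclidean <- function(calls) {
  n <- nrow(calls)
  d <- matrix(0, n, n, dimnames = list(rownames(calls), rownames(calls)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (m in seq_len(ncol(calls))) s <- s + (calls[i, m] - calls[j, m])^2
    d[i, j] <- sqrt(s)
  }
  d
}

# Weir & Cockerham (1984) multi-population theta from dosage genotypes:
# the independent check that generated collections carry the divergence
# they were asked for.
wc_fst <- function(calls, lab) {
  pops <- split(seq_len(nrow(calls)), lab)
  r <- length(pops)
  A <- B <- C <- 0
  for (m in seq_len(ncol(calls))) {
    g <- calls[, m]
    n_i <- vapply(pops, function(ix) sum(!is.na(g[ix])), numeric(1))
    if (any(n_i < 2)) next
    p_i <- vapply(pops, function(ix) mean(g[ix], na.rm = TRUE) / 2, numeric(1))
    h_i <- vapply(pops, function(ix) mean(g[ix] == 1, na.rm = TRUE), numeric(1))
    nbar <- mean(n_i)
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    A <- A + a; B <- B + b; C <- C + cc
  }
  A / (A + B + C)
}

# Write a small hand-specified VCF; `rows` are pre-formatted record lines.
write_test_vcf <- function(path, samples, rows, format = "GT") {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    rows), path)
  path
}

vcf_row <- function(pos, ref, alt, format, calls, id = ".") {
  paste(c("chr1", pos, id, ref, alt, ".", "PASS", ".", format, calls),
        collapse = "\t")
}
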