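#' Curate a collection for benchmarking
#'
#' Removes explicitly excluded accessions (e.g. those flagged by the outlier
#' screen or by tree inspection) and then drops every species whose
#' accession count — after the exclusions — falls below `min_species_size`.
#' A species pushed under the cutoff by exclusions is therefore dropped
#' entirely, remaining members included.
#'
#' @param gm a [genotype_matrix()].
#' @param labels a [label_set()] covering `gm`.
#' @param min_species_size minimum accessions a species needs to stay
#'   (default 10).
#' @param exclude accession ids to remove before the size cutoff is applied.
#' @return `list(genotypes = , labels = )`, curated.
#' @export
curate <- function(gm, labels, min_species_size = 10L, exclude = character()) {
  labels <- align_labels(gm, labels)
  keep_ids <- setdiff(accessions(gm), exclude)
  lab <- unclass(labels)[keep_ids]
  sizes <- table(lab)
  keep_sp <- names(sizes)[sizes >= min_species_size]
  if (length(keep_sp) < 2L) {
    stop_empty("fewer than 2 species survive curation")
  }
  keep_ids <- keep_ids[lab %in% keep_sp]
  list(genotypes = keep_accessions(gm, keep_ids),
       labels = labels[keep_ids])
}

#' Subsample each species to a fixed representation
#'
#' Draws exactly `n_per_species` accessions per species, uniformly without
#' replacement, to construct datasets of controlled species representation.
#'
#' @inheritParams curate
#' @param n_per_species accessions to keep per species; every species must
#'   have at least this many.
#' @param seed integer seed; the same seed reproduces the same selection.
#' @return `list(genotypes = , labels = )`.
#' @export
subsample <- function(gm, labels, n_per_species, seed = NULL) {
  labels <- align_labels(gm, labels)
  lab <- unclass(labels)
  sizes <- table(lab)
  if (any(sizes < n_per_species)) {
    stop(sprintf("species too small for n_per_species=%d: %s", n_per_species,
                 paste(names(sizes)[sizes < n_per_species], collapse = ", ")))
  }
  keep <- local_seed(seed, {
    unlist(lapply(split(names(lab), lab), function(ids) {
      ids[sample.int(length(ids), n_per_species)]
    }), use.names = FALSE)
  })
  keep <- keep[order(match(keep, names(lab)))] # preserve input order
  list(genotypes = keep_accessions(gm, keep), labels = labels[keep])
}

#' Inject random species misclassifications
#'
#' Alters the species label of exactly `round(rate * N)` accessions (half-up
#' rounding), chosen uniformly; each altered accession receives a species
#' drawn uniformly from the *other* species present in the label set, so an
#' altered label always differs from the original. The returned labels carry
#' provenance `perturbed` and keep the originals (see [true_labels()]) so
#' downstream accuracy can be scored against the truth.
#'
#' @param labels a [label_set()] with at least 2 species.
#' @param rate fraction of labels to alter, in (0, 1).
#' @param seed integer seed.
#' @return A perturbed `label_set`. If `round(rate * N)` is zero the input
#'   is returned unchanged with a warning.
#' @export
inject_misclassifications <- function(labels, rate, seed = NULL) {
  stopifnot(rate > 0, rate < 1)
  lab <- unclass(labels)
  species <- unique(lab)
  if (length(species) < 2L) stop("need at least 2 species to misclassify")
  n_alter <- round_half_up(rate * length(lab))
  if (n_alter == 0L) {
    warning("round(rate * N) is 0; labels returned unchanged")
    return(labels)
  }
  local_seed(seed, {
    hit <- sample.int(length(lab), n_alter)
    new <- vapply(lab[hit], function(s) {
      others <- species[species != s]
      others[sample.int(length(others), 1L)]
    }, character(1))
    out <- lab
    out[hit] <- new
    label_set(out, provenance = "perturbed", true_labels = lab)
  })
}

#' Define a benchmark grid
#'
#' The full factorial design of the misclassification-recovery experiment:
#' species representations x misclassification rates x replicates. The
#' defaults are the study conditions — representations 2, 4, 6, 8, 10;
#' rates 6.25%, 12.5%, 18.75%; 5000 replicates — enumerating 75,000
#' perturbed datasets.
#'
#' @param representations per-species accession counts (each >= 2).
#' @param rates misclassification fractions, each in (0, 1).
#' @param replicates replicates per cell (>= 1).
#' @param seed master seed; spawns one child seed per subsample and
#'   injection so any cell is reproducible in isolation.
#' @return A `sim_design` list.
#' @export
sim_design <- function(representations = c(2L, 4L, 6L, 8L, 10L),
                       rates = c(0.0625, 0.125, 0.1875),
                       replicates = 5000L, seed = 1L) {
  stopifnot(all(representations >= 2L), all(rates > 0 & rates < 1),
            replicates >= 1L)
  structure(list(representations = as.integer(representations),
                 rates = rates, replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "sim_design")
}

design_cells <- function(design) {
  cells <- expand.grid(replicate = seq_len(design$replicates),
                       rate = design$rates,
                       representation = design$representations)
  cells <- cells[, c("representation", "rate", "replicate")]
  n <- nrow(cells)
  seeds <- local_seed(design$seed,
                      matrix(sample.int(.Machine$integer.max - 1L, 2L * n,
                                        replace = FALSE), ncol = 2L))
  cells$seed_subsample <- seeds[, 1L]
  cells$seed_inject <- seeds[, 2L]
  cells
}

#' Count the perturbed datasets a design enumerates
#'
#' Generates every per-cell label perturbation of the design — subsampled
#' representation, then injected misclassifications — without running any
#' classifier, and returns the count of distinct perturbed datasets along
#' with bookkeeping checks (each perturbation altered exactly
#' `round(rate * N)` labels, all differing from their originals).
#'
#' @param labels a [label_set()] of the curated collection.
#' @param design a [sim_design()].
#' @return `list(n_datasets, n_cells, all_alterations_valid)`.
#' @export
enumerate_perturbations <- function(labels, design) {
  cells <- design_cells(design)
  lab <- unclass(labels)
  by_sp <- split(names(lab), lab)
  valid <- TRUE
  for (r in seq_len(nrow(cells))) {
    n_per <- cells$representation[r]
    ids <- local_seed(cells$seed_subsample[r],
                      unlist(lapply(by_sp, function(x)
                        x[sample.int(length(x), n_per)]), use.names = FALSE))
    sub <- label_set(lab[ids])
    pert <- suppressWarnings(
      inject_misclassifications(sub, cells$rate[r], cells$seed_inject[r]))
    altered <- unclass(pert) != true_labels(pert)
    valid <- valid &&
      sum(altered) == round_half_up(cells$rate[r] * length(ids))
  }
  list(n_datasets = nrow(cells), n_cells = nrow(cells),
       all_alterations_valid = valid)
}

# One replicate: run the requested classifiers on a perturbed label set and
# score against the true labels. Shared inputs (distances, imputation) are
# computed once per replicate; all classifiers see the same perturbed labels.
run_classifiers_once <- function(gm, perturbed, classifiers,
                                 rf_trees = 10000L, rf_seed = NULL,
                                 nb_mode = "resubstitution") {
  shared <- new.env(parent = emptyenv())
  get_shared <- function(name, make) {
    if (!exists(name, envir = shared, inherits = FALSE)) {
      assign(name, make(), envir = shared)
    }
    get(name, envir = shared, inherits = FALSE)
  }
  lapply(stats::setNames(classifiers, classifiers), function(cl) {
    switch(cl,
      "1nn" = classify_1nn(get_shared("div", function() divergent_sites(gm)),
                           perturbed),
      "3nn" = classify_3nn_conservative(
        get_shared("euc", function()
          euclidean_distance(get_shared("imp", function() impute_most_common(gm)))),
        perturbed),
      "nj" = classify_nj(build_nj(get_shared("div", function() divergent_sites(gm))),
                         perturbed),
      "rf" = classify_rf_oob(get_shared("imp", function() impute_most_common(gm)),
                             perturbed, n_trees = rf_trees, seed = rf_seed),
      "nb" = classify_nb(
        fit_nb(get_shared("imp", function() impute_most_common(gm)), perturbed),
        get_shared("imp", function() impute_most_common(gm)), mode = nb_mode),
      "echo" = new_predictions(names(perturbed), unclass(perturbed),
                               unclass(perturbed), "echo", "echo"),
      stop(sprintf("unknown classifier '%s'", cl))
    )
  })
}

#' Run the misclassification-recovery benchmark grid
#'
#' For every cell of the design: subsample the curated collection to the
#' cell's species representation, inject misclassifications at the cell's
#' rate, let each classifier predict from the identical perturbed label set,
#' and score predictions against the *true* (pre-perturbation) labels — the
#' question being whether a classifier improves a bad dataset. Results are
#' bit-identical under a fixed design seed, and any cell can be reproduced
#' in isolation.
#'
#' `"echo"` is a diagnostic pseudo-classifier that returns the perturbed
#' labels unchanged; scored against the truth it attains exactly
#' `1 - rate`, which anchors the harness analytically.
#'
#' @inheritParams curate
#' @param design a [sim_design()].
#' @param classifiers subset of `c("1nn", "3nn", "nj", "rf", "nb", "echo")`.
#' @param rf_trees trees for the RF classifier inside the grid.
#' @param nb_mode naive Bayes evaluation mode (see [classify_nb()]).
#' @param score_against `"true"` (default) or `"perturbed"` labels.
#' @param out_file optional TSV path; rows are appended as they complete.
#' @return A `benchmark_result` data.frame with columns `representation`,
#'   `rate`, `replicate`, `classifier`, `accuracy`, `n_ambiguous`, `error`.
#'   Classifier failures are recorded per cell, not fatal to the grid.
#' @export
run_grid <- function(gm, labels, design,
                     classifiers = c("1nn", "3nn", "nj", "rf", "nb"),
                     rf_trees = 10000L, nb_mode = "resubstitution",
                     score_against = c("true", "perturbed"),
                     out_file = NULL) {
  score_against <- match.arg(score_against)
  labels <- align_labels(gm, labels)
  cells <- design_cells(design)
  rows <- vector("list", nrow(cells) * length(classifiers))
  ri <- 0L
  for (r in seq_len(nrow(cells))) {
    sub <- subsample(gm, labels, cells$representation[r],
                     seed = cells$seed_subsample[r])
    pert <- suppressWarnings(inject_misclassifications(
      sub$labels, cells$rate[r], seed = cells$seed_inject[r]))
    target <- if (score_against == "true") true_labels(pert) else unclass(pert)
    preds <- lapply(stats::setNames(classifiers, classifiers), function(cl) {
      tryCatch(run_classifiers_once(sub$genotypes, pert, cl,
                                    rf_trees = rf_trees,
                                    rf_seed = cells$seed_inject[r],
                                    nb_mode = nb_mode)[[1L]],
               error = function(e) e)
    })
    for (cl in classifiers) {
      ri <- ri + 1L
      p <- preds[[cl]]
      if (inherits(p, "error")) {
        row <- data.frame(representation = cells$representation[r],
                          rate = cells$rate[r], replicate = cells$replicate[r],
                          classifier = cl, accuracy = NA_real_,
                          n_ambiguous = NA_integer_,
                          error = conditionMessage(p))
      } else {
        acc <- accuracy(p, target)
        row <- data.frame(representation = cells$representation[r],
                          rate = cells$rate[r], replicate = cells$replicate[r],
                          classifier = cl, accuracy = acc$overall,
                          n_ambiguous = acc$n_ambiguous, error = NA_character_)
      }
      rows[[ri]] <- row
      if (!is.null(out_file)) {
        utils::write.table(row, out_file, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = !file.exists(out_file),
                           append = file.exists(out_file))
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "design") <- design
  class(out) <- c("benchmark_result", "data.frame")
  out
}

#' Median accuracy per design cell
#'
#' Aggregates a [run_grid()] result to the familiar benchmark layout: one
#' row per (representation, rate), one column per classifier, entries the
#' median accuracy over replicates, with the per-row best classifier(s)
#' flagged.
#'
#' @param result a `benchmark_result`.
#' @return A data.frame of medians with a `best` column.
#' @export
summarize_benchmark <- function(result) {
  agg <- stats::aggregate(accuracy ~ representation + rate + classifier,
                          data = result, FUN = stats::median, na.rm = TRUE)
  wide <- stats::reshape(agg, idvar = c("representation", "rate"),
                         timevar = "classifier", direction = "wide")
  names(wide) <- sub("^accuracy\\.", "", names(wide))
  cls <- setdiff(names(wide), c("representation", "rate"))
  wide$best <- apply(wide[cls], 1L, function(x)
    paste(cls[!is.na(x) & x == max(x, na.rm = TRUE)], collapse = ","))
  wide[order(wide$representation, wide$rate), , drop = FALSE]
}
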