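test_that("curation drops small species, exclusions can drop a species entirely", {
  fix <- tight_clusters(c(A = 12, B = 9, C = 11, D = 15))
  cur <- curate(fix$genotypes, fix$labels, min_species_size = 10)
  expect_setequal(unique(unclass(cur$labels)), c("A", "C", "D"))

  # C:11 with 2 exclusions falls to 9 < 10 and is dropped entirely
  cur2 <- curate(fix$genotypes, fix$labels, min_species_size = 10,
                 exclude = c("C_01", "C_02"))
  expect_setequal(unique(unclass(cur2$labels)), c("A", "D"))
  expect_false(any(startsWith(names(cur2$labels), "C_")))
  # identity when nothing is below the cutoff
  cur3 <- curate(fix$genotypes, fix$labels, min_species_size = 9)
  expect_identical(names(cur3$labels), accessions(fix$genotypes))
  expect_error(curate(fix$genotypes, fix$labels, min_species_size = 16),
               class = "specurate_empty_result")
})

test_that("subsampling fixes per-species representation reproducibly", {
  fix <- tight_clusters(c(A = 10, B = 10, C = 10, D = 10,
                          E = 10, F = 10, G = 10, H = 10))
  s2 <- subsample(fix$genotypes, fix$labels, 2, seed = 3)
  expect_identical(length(s2$labels), 16L)
  expect_true(all(table(unclass(s2$labels)) == 2))
  s10 <- subsample(fix$genotypes, fix$labels, 10, seed = 3)
  expect_identical(length(s10$labels), 80L)
  s2b <- subsample(fix$genotypes, fix$labels, 2, seed = 3)
  expect_identical(names(s2$labels), names(s2b$labels))
  expect_error(subsample(fix$genotypes, fix$labels, 11, seed = 1), "too small")
})

test_that("misclassification injection alters exactly round(rate*N) labels, all differently", {
  fix <- tight_clusters(c(A = 20, B = 20, C = 20, D = 20))
  labels <- fix$labels
  pert <- inject_misclassifications(labels, 0.0625, seed = 5)
  altered <- unclass(pert) != true_labels(pert)
  expect_identical(sum(altered), 5L) # 0.0625 * 80
  expect_identical(label_provenance(pert), "perturbed")
  expect_true(all(unclass(pert)[altered] != true_labels(pert)[altered]))
  expect_true(all(unclass(pert)[altered] %in% c("A", "B", "C", "D")))

  # boundary: round(rate*N) = N alters everything
  pert_all <- inject_misclassifications(labels, 0.999, seed = 6)
  expect_true(all(unclass(pert_all) != true_labels(pert_all)))

  # rate too small to alter anything: unchanged with a warning
  small <- labels[c(1:4, 21:24)]
  expect_warning(p0 <- inject_misclassifications(small, 0.05, seed = 7),
                 "unchanged")
  expect_identical(unclass(p0), unclass(small))
})

test_that("the full factorial design enumerates representations x rates x replicates", {
  fix <- tight_clusters(c(A = 10, B = 10, C = 10))
  d <- sim_design(replicates = 2, seed = 11)
  e <- enumerate_perturbations(fix$labels, d)
  expect_identical(e$n_datasets, 5L * 3L * 2L)
  expect_true(e$all_alterations_valid)
})

test_that("a label-echo classifier scores exactly 1 - rate against the truth", {
  # 8 species, sixteenth rates: rate * N is integral for every representation
  fix <- tight_clusters(c(A = 4, B = 4, C = 4, D = 4,
                          E = 4, F = 4, G = 4, H = 4))
  d <- sim_design(representations = c(2L, 4L),
                  rates = c(0.0625, 0.125, 0.1875), replicates = 2, seed = 13)
  res <- run_grid(fix$genotypes, fix$labels, d, classifiers = "echo")
  expect_identical(nrow(res), 2L * 3L * 2L)
  expect_equal(res$accuracy, 1 - res$rate)
})

test_that("grids are bit-identical under a master seed and share perturbations across classifiers", {
  fix <- tight_clusters(c(A = 6, B = 6, C = 6))
  d <- sim_design(representations = c(2L, 4L), rates = 0.125,
                  replicates = 2, seed = 17)
  r1 <- run_grid(fix$genotypes, fix$labels, d, classifiers = c("1nn", "echo"))
  r2 <- run_grid(fix$genotypes, fix$labels, d, classifiers = c("1nn", "echo"))
  expect_identical(r1$accuracy, r2$accuracy)
  # echo rows do not depend on which other classifiers run: the perturbed
  # label set is a property of the cell, not of the classifier roster
  r3 <- run_grid(fix$genotypes, fix$labels, d, classifiers = "echo")
  expect_equal(r1$accuracy[r1$classifier == "echo"], r3$accuracy)
})

test_that("replicates=1 with one classifier yields one accuracy per design cell", {
  fix <- tight_clusters(c(A = 10, B = 10, C = 10, D = 10,
                          E = 10, F = 10, G = 10, H = 10))
  d <- sim_design(replicates = 1, seed = 19)
  res <- run_grid(fix$genotypes, fix$labels, d, classifiers = "3nn")
  expect_identical(nrow(res), 15L)
  expect_true(all(!is.na(res$accuracy)))
  # tight separation: recovery should comfortably beat the echo baseline
  expect_gte(stats::median(res$accuracy), stats::median(1 - res$rate))
})

test_that("streamed results match the returned table", {
  fix <- tight_clusters(c(A = 5, B = 5))
  d <- sim_design(representations = 2L, rates = 0.125, replicates = 2, seed = 23)
  path <- withr::local_tempfile(fileext = ".tsv")
  res <- run_grid(fix$genotypes, fix$labels, d, classifiers = "1nn",
                  out_file = path)
  back <- utils::read.table(path, sep = "\t", header = TRUE)
  expect_equal(back$accuracy, res$accuracy)
})
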