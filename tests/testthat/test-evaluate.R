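make_preds <- function(calls, truth) {
  ids <- names(truth)
  specurate:::new_predictions(ids, unname(truth), unname(calls[ids]),
                              "", "test")
}

test_that("accuracy excludes ambiguous calls from both sides of the ratio", {
  truth <- stats::setNames(rep("A", 16), sprintf("a%02d", 1:16))
  calls <- truth
  calls["a01"] <- "B"
  expect_equal(accuracy(make_preds(calls, truth), truth)$overall, 15 / 16)

  calls["a02"] <- AMBIGUOUS
  rep <- accuracy(make_preds(calls, truth), truth)
  expect_equal(rep$overall, 14 / 15)
  expect_identical(rep$n_ambiguous, 1L)

  all_amb <- stats::setNames(rep(AMBIGUOUS, 16), names(truth))
  rep2 <- accuracy(make_preds(all_amb, truth), truth)
  expect_true(is.na(rep2$overall))
  expect_true(rep2$all_ambiguous)
})

test_that("accuracy is invariant to accession order and reported per species", {
  truth <- stats::setNames(c(rep("A", 4), rep("B", 4)), sprintf("a%d", 1:8))
  calls <- truth
  calls[c("a1", "a5")] <- c("B", AMBIGUOUS)
  p <- make_preds(calls, truth)
  r1 <- accuracy(p, truth)
  r2 <- accuracy(p[sample.int(8), ], truth)
  expect_equal(r1$overall, r2$overall)
  per <- r1$per_species
  expect_equal(per$accuracy[per$species == "A"], 3 / 4)
  expect_equal(per$accuracy[per$species == "B"], 3 / 3)
})

test_that("confusion rows are exact fractions that sum to one", {
  n <- 19
  truth <- stats::setNames(rep("pet", n), sprintf("a%02d", 1:n))
  calls <- truth
  calls[17] <- "neg"     # the other focus species
  calls[18] <- "ann"     # a non-focus species -> Other
  calls[19] <- AMBIGUOUS
  truth2 <- c(truth, stats::setNames(rep("neg", 4), sprintf("b%d", 1:4)))
  calls2 <- c(calls, stats::setNames(rep("neg", 4), sprintf("b%d", 1:4)))
  cm <- confusion(make_preds(calls2, truth2), truth2, c("pet", "neg"))
  expect_equal(cm["pet", ], c(pet = 16 / 19, neg = 1 / 19, Other = 1 / 19,
                              AMBIGUOUS = 1 / 19))
  expect_equal(unname(rowSums(cm)), c(1, 1))
  expect_equal(cm["neg", "neg"], 1)
  expect_error(confusion(make_preds(calls2, truth2), truth2, c("pet", "ghost")),
               "absent")
})

test_that("aligned ranks statistic vanishes on constant tables and ignores row shifts", {
  tab <- matrix(0.8, 6, 4)
  res <- friedman_aligned_ranks(tab)
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)

  set.seed(31)
  tab2 <- matrix(runif(25), 5, 5)
  t1 <- friedman_aligned_ranks(tab2)$statistic
  tab3 <- tab2
  tab3[2, ] <- tab3[2, ] + 10 # alignment removes problem effects
  expect_equal(friedman_aligned_ranks(tab3)$statistic, t1)
})

test_that("chi-squared p agrees with the exhaustive sign permutation at k = 2", {
  set.seed(3)
  tab <- matrix(round(runif(16, 0.6, 1), 3), 8, 2)
  obs <- friedman_aligned_ranks(tab)
  perm_stats <- vapply(0:255, function(m) {
    t2 <- tab
    for (i in 1:8) if (bitwAnd(m, bitwShiftL(1L, i - 1L))) t2[i, ] <- rev(t2[i, ])
    friedman_aligned_ranks(t2)$statistic
  }, numeric(1))
  p_perm <- mean(perm_stats >= obs$statistic - 1e-12)
  # the chi-squared reference is an approximation; at n = 8 the exhaustive
  # permutation law is granular (steps of 1/256), so agreement is coarse
  expect_lt(abs(obs$p.value - p_perm), 0.1)
})

test_that("Finner adjustment matches the closed form and is monotone", {
  expect_equal(finner_adjust(0.37), 0.37)
  adj <- finner_adjust(c(0.01, 0.02, 0.03))
  expect_equal(adj[1], 1 - 0.99^3)
  expect_equal(adj[2], 1 - 0.98^1.5)
  expect_equal(adj[3], 0.03)
  expect_equal(finner_adjust(rep(1, 4)), rep(1, 4))

  set.seed(37)
  for (i in 1:5) {
    p <- runif(sample(2:8, 1))
    adj <- finner_adjust(p)
    expect_true(all(adj <= 1 & adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("post-hoc runs only after a significant omnibus and excludes the control", {
  set.seed(41)
  # one classifier dominating every problem by a wide margin
  n <- 20
  tab <- cbind(best = runif(n, 0.9, 1), mid = runif(n, 0.5, 0.6),
               low = runif(n, 0.3, 0.4))
  omni <- friedman_aligned_ranks(tab)
  expect_lt(omni$p.value, 0.05)
  ph <- posthoc_vs_control(omni)
  expect_true(ph$performed)
  expect_identical(ph$control, "best")
  expect_false("best" %in% ph$comparisons$classifier)
  expect_true(all(ph$comparisons$reject))

  # null table: omnibus not significant, no comparisons performed
  null_tab <- matrix(runif(60), 20, 3)
  omni0 <- friedman_aligned_ranks(null_tab)
  ph0 <- posthoc_vs_control(omni0, omnibus_p = 0.5)
  expect_false(ph0$performed)
})

test_that("the grouped comparison stack runs end to end on a benchmark result", {
  fix <- tight_clusters(c(A = 8, B = 8, C = 8))
  d <- sim_design(representations = c(2L, 4L), rates = c(0.125, 0.1875),
                  replicates = 4, seed = 43)
  res <- run_grid(fix$genotypes, fix$labels, d,
                  classifiers = c("1nn", "3nn", "echo"))
  cmp <- compare_classifiers(res, by = "group")
  expect_length(cmp$omnibus, 4L)
  expect_true(all(cmp$p_adj >= vapply(cmp$omnibus, `[[`, numeric(1), "p.value") - 1e-12))
  cmp2 <- compare_classifiers(res, by = "overall")
  expect_s3_class(cmp2$omnibus, "aligned_ranks_test")
})
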