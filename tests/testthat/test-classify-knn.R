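test_that("1-NN assigns the nearest other accession's species", {
  d <- matrix(c(0, 5, 1,
                5, 0, 4,
                1, 4, 0), 3, 3,
              dimnames = list(c("a", "b", "q"), c("a", "b", "q")))
  labels <- label_set(c(a = "A", b = "B", q = "C"))
  p <- classify_1nn(manual_dist(d, "divergent_sites"), labels)
  expect_identical(p$call[p$accession == "q"], "A")
})

test_that("1-NN propagates the wrong label across a mutual nearest pair", {
  # x (truly A, labelled A) and y (truly A, mislabelled B) are mutual NNs:
  # the rule fixes y but then breaks x.
  d <- matrix(10, 4, 4,
              dimnames = list(c("x", "y", "c1", "c2"),
                              c("x", "y", "c1", "c2")))
  diag(d) <- 0
  d["x", "y"] <- d["y", "x"] <- 1
  d["c1", "c2"] <- d["c2", "c1"] <- 2
  labels <- label_set(c(x = "A", y = "B", c1 = "C", c2 = "C"))
  p <- classify_1nn(manual_dist(d), labels)
  expect_identical(p$call[p$accession == "y"], "A") # corrected
  expect_identical(p$call[p$accession == "x"], "B") # broken by the pair
})

test_that("1-NN nearest-neighbour ties resolve by majority, else ambiguous", {
  d <- matrix(c(0, 1, 1, 9,
                1, 0, 9, 9,
                1, 9, 0, 9,
                9, 9, 9, 0), 4, 4,
              dimnames = list(c("q", "n1", "n2", "f"),
                              c("q", "n1", "n2", "f")))
  labels <- label_set(c(q = "X", n1 = "A", n2 = "B", f = "X"))
  p <- classify_1nn(manual_dist(d), labels)
  expect_identical(p$call[p$accession == "q"], AMBIGUOUS)

  labels2 <- label_set(c(q = "X", n1 = "A", n2 = "A", f = "X"))
  p2 <- classify_1nn(manual_dist(d), labels2)
  expect_identical(p2$call[p2$accession == "q"], "A")
})

test_that("conservative 3-NN needs one neighbour to confirm, two to overturn", {
  # query q labelled A; two nearest others carry the decisive votes
  base <- matrix(50, 5, 5,
                 dimnames = list(c("q", "n1", "n2", "f1", "f2"),
                                 c("q", "n1", "n2", "f1", "f2")))
  diag(base) <- 0
  base["q", "n1"] <- base["n1", "q"] <- 1
  base["q", "n2"] <- base["n2", "q"] <- 2
  base["f1", "f2"] <- base["f2", "f1"] <- 1

  # both neighbours B -> overturned to B
  lab <- label_set(c(q = "A", n1 = "B", n2 = "B", f1 = "B", f2 = "B"))
  p <- classify_3nn_conservative(manual_dist(base), lab)
  expect_identical(p$call[p$accession == "q"], "B")

  # nearest neighbour A, other B -> confirmed A (one vote suffices)
  lab <- label_set(c(q = "A", n1 = "A", n2 = "B", f1 = "B", f2 = "B"))
  p <- classify_3nn_conservative(manual_dist(base), lab)
  expect_identical(p$call[p$accession == "q"], "A")

  # neighbours B and C -> votes A:1 B:1 C:1, nothing reaches l=2
  lab <- label_set(c(q = "A", n1 = "B", n2 = "C", f1 = "B", f2 = "C"))
  p <- classify_3nn_conservative(manual_dist(base), lab)
  expect_identical(p$call[p$accession == "q"], AMBIGUOUS)
})

test_that("ties for the third neighbour all enter the vote", {
  ids <- c("q", "n1", "t1", "t2", "t3", "f")
  d <- matrix(50, 6, 6, dimnames = list(ids, ids))
  diag(d) <- 0
  d["q", "n1"] <- d["n1", "q"] <- 1
  for (t in c("t1", "t2", "t3")) d["q", t] <- d[t, "q"] <- 2
  lab <- label_set(c(q = "A", n1 = "A", t1 = "B", t2 = "B", t3 = "B", f = "C"))
  p <- classify_3nn_conservative(manual_dist(d), lab)
  # votes: A:2 (q + n1), B:3 (all tied third neighbours) -> B wins
  expect_identical(p$call[p$accession == "q"], "B")
  expect_match(p$support[p$accession == "q"], "t1")
  expect_match(p$support[p$accession == "q"], "t3")
})

test_that("3-NN vote rule is exact over all label configurations of the neighbourhood", {
  # query + 2 nearest others, labels ranging over {A,B,C}: the winner must
  # be the unique plurality with >= 2 votes, otherwise ambiguous.
  ids <- c("q", "n1", "n2", "p1", "p2")
  d <- matrix(100, 5, 5, dimnames = list(ids, ids))
  diag(d) <- 0
  d["q", "n1"] <- d["n1", "q"] <- 1
  d["q", "n2"] <- d["n2", "q"] <- 2
  d["p1", "p2"] <- d["p2", "p1"] <- 1
  for (lq in c("A", "B", "C")) for (l1 in c("A", "B", "C")) for (l2 in c("A", "B", "C")) {
    lab <- label_set(c(q = lq, n1 = l1, n2 = l2, p1 = "P", p2 = "P"))
    p <- classify_3nn_conservative(manual_dist(d), lab)
    votes <- table(c(lq, l1, l2))
    top <- votes[votes == max(votes)]
    want <- if (length(top) == 1L && top[1L] >= 2L) names(top) else AMBIGUOUS
    expect_identical(p$call[p$accession == "q"], want,
                     label = sprintf("labels (%s,%s,%s)", lq, l1, l2))
    # never a species with fewer than l votes
    if (p$call[p$accession == "q"] != AMBIGUOUS) {
      expect_gte(votes[[p$call[p$accession == "q"]]], 2L)
    }
  }
})

test_that("two correctly labelled conspecifics suffice for unambiguous confirmation", {
  confirm_at <- function(m) {
    sizes <- c(T = m, B = 4, C = 4, D = 4)
    fix <- tight_clusters(sizes)
    eu <- euclidean_distance(fix$genotypes)
    p <- classify_3nn_conservative(eu, fix$labels)
    q <- p[p$accession == "T_01", ]
    q$call == "T"
  }
  expect_false(confirm_at(1))
  expect_true(confirm_at(2))
  expect_true(confirm_at(3))
})

test_that("all five classifiers agree on tight well-separated clusters", {
  fix <- tight_clusters(c(A = 3, B = 3, C = 4))
  gm <- fix$genotypes
  labels <- fix$labels
  dv <- divergent_sites(gm)
  eu <- euclidean_distance(gm)
  accs <- c(
    accuracy(classify_1nn(dv, labels), labels)$overall,
    accuracy(classify_3nn_conservative(eu, labels), labels)$overall,
    accuracy(classify_nj(build_nj(dv), labels), labels)$overall,
    accuracy(classify_rf_oob(gm, labels, n_trees = 300, seed = 1), labels)$overall,
    accuracy(classify_nb(fit_nb(gm, labels), gm, "loo"), labels)$overall)
  expect_equal(accs, rep(1, 5))
})
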