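#' Prediction accuracy with ambiguity exclusion
#'
#' Accuracy is the number of correct predictions divided by the number of
#' predictions, with [AMBIGUOUS] calls excluded from both numerator and
#' denominator — declining to call is neither right nor wrong here. Note
#' that overall accuracy is sensitive to class imbalance; it is a fair
#' summary when species are equally represented (as in the benchmark grid),
#' and the per-species breakdown should be consulted otherwise.
#'
#' @param preds a `species_predictions` data.frame.
#' @param true_labels a [label_set()] or named character vector giving the
#'   reference species per accession.
#' @return An `accuracy_report` list: `overall` (NA with `all_ambiguous =
#'   TRUE` when every call was ambiguous), `per_species` data.frame,
#'   `n`, `n_ambiguous`.
#' @export
accuracy <- function(preds, true_labels) {
  truth <- unclass(true_labels)[preds$accession]
  if (anyNA(truth)) stop("predictions cover accessions absent from true_labels")
  amb <- preds$call == AMBIGUOUS
  correct <- !amb & preds$call == truth
  overall <- if (all(amb)) NA_real_ else sum(correct) / sum(!amb)
  per <- do.call(rbind, lapply(split(seq_along(truth), truth), function(ix) {
    a <- amb[ix]
    data.frame(species = truth[ix][1L], n = length(ix),
               n_ambiguous = sum(a),
               accuracy = if (all(a)) NA_real_ else sum(correct[ix]) / sum(!a))
  }))
  rownames(per) <- NULL
  structure(list(overall = overall, per_species = per,
                 n = length(truth), n_ambiguous = sum(amb),
                 all_ambiguous = all(amb)),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  if (x$all_ambiguous) {
    cat(sprintf("accuracy undefined: all %d predictions ambiguous\n", x$n))
  } else {
    cat(sprintf("accuracy %.4f (%d predictions, %d ambiguous excluded)\n",
                x$overall, x$n, x$n_ambiguous))
  }
  invisible(x)
}

#' Fractional confusion matrix for selected species
#'
#' Rows are the focus species (by true label); columns are each focus
#' species, `Other` (any non-focus species), and `AMBIGUOUS`. Each row holds
#' the fractions of that species' accessions falling in each outcome and
#' sums to one exactly.
#'
#' @inheritParams accuracy
#' @param focus_species non-empty character vector of species to tabulate.
#' @return A numeric matrix of class `confusion_matrix`.
#' @export
confusion <- function(preds, true_labels, focus_species) {
  if (!length(focus_species)) stop("focus_species must be non-empty")
  truth <- unclass(true_labels)[preds$accession]
  absent <- setdiff(focus_species, truth)
  if (length(absent)) {
    stop(sprintf("species absent from predictions: %s",
                 paste(absent, collapse = ", ")))
  }
  cols <- c(focus_species, "Other", AMBIGUOUS)
  out <- matrix(0, length(focus_species), length(cols),
                dimnames = list(focus_species, cols))
  for (sp in focus_species) {
    calls <- preds$call[truth == sp]
    bucket <- ifelse(calls == AMBIGUOUS, AMBIGUOUS,
                     ifelse(calls %in% focus_species, calls, "Other"))
    tab <- table(factor(bucket, levels = cols))
    out[sp, ] <- as.numeric(tab) / length(calls)
  }
  class(out) <- c("confusion_matrix", class(out))
  out
}

#' Friedman Aligned Ranks omnibus test
#'
#' Nonparametric comparison of k classifiers over n problems. Observations
#' are aligned by subtracting each problem's mean, all `k * n` aligned
#' values are ranked jointly (mid-ranks for ties), and the statistic
#' \deqn{T = \frac{(k-1)\left[\sum_j \hat R_{\cdot j}^2 - (kn^2/4)(kn+1)^2\right]}
#'   {\frac{kn(kn+1)(2kn+1)}{6} - \frac{1}{k}\sum_i \hat R_{i\cdot}^2}}
#' is referred to a chi-squared distribution with `k - 1` degrees of
#' freedom, where \eqn{\hat R_{\cdot j}} and \eqn{\hat R_{i\cdot}} are the
#' aligned-rank sums per classifier and per problem. Aligning makes the test
#' sensitive with few classifiers (k of 4 or 5), where the plain Friedman
#' test loses power. If the aligned values are all identical (every
#' classifier equal within each problem) the statistic is 0 and p = 1.
#'
#' @param tab numeric matrix, problems x classifiers, complete (no NA).
#' @return An `aligned_ranks_test` list: `statistic`, `df`, `p.value`,
#'   `mean_ranks` and `rank_sums` per classifier, `rank_sums_problem`,
#'   `mean_values` (per-classifier means of the raw table, used to pick the
#'   post-hoc control), `n`, `k`.
#' @export
friedman_aligned_ranks <- function(tab) {
  tab <- as.matrix(tab)
  if (anyNA(tab)) stop("table must be complete")
  n <- nrow(tab); k <- ncol(tab)
  if (k < 2L || n < 2L) stop("need at least 2 classifiers and 2 problems")
  if (is.null(colnames(tab))) colnames(tab) <- paste0("c", seq_len(k))
  aligned <- tab - rowMeans(tab)
  rk <- matrix(rank(as.vector(aligned)), n, k, dimnames = dimnames(tab))
  Rj <- colSums(rk)
  Ri <- rowSums(rk)
  num <- (k - 1) * (sum(Rj^2) - (k * n^2 / 4) * (k * n + 1)^2)
  den <- k * n * (k * n + 1) * (2 * k * n + 1) / 6 - sum(Ri^2) / k
  if (den <= .Machine$double.eps^0.5 || abs(num) < .Machine$double.eps^0.5) {
    stat <- 0
    p <- 1
  } else {
    stat <- num / den
    p <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
  }
  structure(list(statistic = stat, df = k - 1L, p.value = p,
                 mean_ranks = colMeans(rk), rank_sums = Rj,
                 rank_sums_problem = Ri,
                 mean_values = colMeans(tab), n = n, k = k),
            class = "aligned_ranks_test")
}

#' @export
print.aligned_ranks_test <- function(x, ...) {
  cat(sprintf("Friedman Aligned Ranks: T = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p.value))
  print(round(x$mean_ranks, 2))
  invisible(x)
}

#' Finner step-down p-value adjustment
#'
#' For m hypotheses ordered by ascending p, the adjusted value is
#' `max over j <= i of min(1, 1 - (1 - p_(j))^(m/j))`, returned in the
#' original order. More powerful than Bonferroni-Dunn and comparable to
#' Holm/Hochberg-family corrections with a simpler form.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
finner_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  if (m <= 1L) return(p)
  o <- order(p)
  ps <- p[o]
  adj <- pmin(1, 1 - (1 - ps)^(m / seq_len(m)))
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Post-hoc comparisons against the best classifier
#'
#' Run after a significant [friedman_aligned_ranks()] omnibus: each
#' classifier is compared with the control — the classifier with the
#' highest mean accuracy — by the aligned-rank z statistic
#' `z = (Rbar_j - Rbar_0) / sqrt(k (kn + 1) / 6)` with `Rbar` the mean
#' aligned ranks, two-sided normal p-values, Finner-corrected over the
#' `k - 1` comparisons. When the omnibus p (pass the adjusted value if it
#' was itself corrected) is not below `alpha`, no comparisons are made and
#' a no-comparison marker is returned.
#'
#' @param stat an `aligned_ranks_test`.
#' @param alpha significance level gate for the omnibus (default 0.05).
#' @param omnibus_p the omnibus p-value to gate on; defaults to
#'   `stat$p.value`.
#' @return A `posthoc_result` list: `performed`, `control`, and (when
#'   performed) a `comparisons` data.frame with z, raw and adjusted p, and
#'   the rejection decision at `alpha`.
#' @export
posthoc_vs_control <- function(stat, alpha = 0.05, omnibus_p = stat$p.value) {
  control <- names(stat$mean_values)[which.max(stat$mean_values)]
  if (!(omnibus_p < alpha)) {
    return(structure(list(performed = FALSE, control = control,
                          omnibus_p = omnibus_p, alpha = alpha),
                     class = "posthoc_result"))
  }
  k <- stat$k; n <- stat$n
  se <- sqrt(k * (k * n + 1) / 6)
  others <- setdiff(names(stat$mean_ranks), control)
  z <- (stat$mean_ranks[others] - stat$mean_ranks[control]) / se
  p <- 2 * stats::pnorm(-abs(z))
  p_adj <- finner_adjust(p)
  structure(list(performed = TRUE, control = control, omnibus_p = omnibus_p,
                 alpha = alpha,
                 comparisons = data.frame(classifier = others, z = unname(z),
                                          p = unname(p), p_adj = p_adj,
                                          reject = p_adj < alpha,
                                          row.names = NULL)),
            class = "posthoc_result")
}

#' @export
print.posthoc_result <- function(x, ...) {
  if (!x$performed) {
    cat(sprintf("omnibus p = %.4g >= %.2f: no post-hoc comparisons\n",
                x$omnibus_p, x$alpha))
  } else {
    cat(sprintf("post-hoc vs control '%s' (Finner-adjusted):\n", x$control))
    print(x$comparisons)
  }
  invisible(x)
}

#' Full statistical comparison of a benchmark result
#'
#' The comparison stack applied to a [run_grid()] result. In the default
#' `by = "group"` mode, accuracies are grouped by (representation, rate):
#' within each group the replicates x classifiers table is tested by
#' [friedman_aligned_ranks()], the omnibus p-values are Finner-corrected
#' across groups, and each significant group is followed up with
#' [posthoc_vs_control()]. `by = "overall"` instead aggregates each group
#' to its median accuracy and runs a single omnibus over the groups x
#' classifiers table of medians.
#'
#' @param result a `benchmark_result` (complete cells only; rows with
#'   failed or all-ambiguous classifiers are dropped pairwise by replicate).
#' @param by `"group"` or `"overall"`.
#' @param alpha significance level.
#' @return A list of per-group results (`omnibus`, `p_adj`, `posthoc`), or
#'   a single such record for `by = "overall"`.
#' @export
compare_classifiers <- function(result, by = c("group", "overall"),
                                alpha = 0.05) {
  by <- match.arg(by)
  cls <- sort(unique(result$classifier))
  if (by == "overall") {
    agg <- stats::aggregate(accuracy ~ representation + rate + classifier,
                            data = result, FUN = stats::median, na.rm = TRUE)
    tab <- stats::reshape(agg, idvar = c("representation", "rate"),
                          timevar = "classifier", direction = "wide")
    m <- as.matrix(tab[, paste0("accuracy.", cls)])
    colnames(m) <- cls
    omni <- friedman_aligned_ranks(m)
    return(list(omnibus = omni, p_adj = omni$p.value,
                posthoc = posthoc_vs_control(omni, alpha)))
  }
  groups <- split(result, list(result$representation, result$rate), drop = TRUE)
  omni <- lapply(groups, function(g) {
    tab <- stats::reshape(g[, c("replicate", "classifier", "accuracy")],
                          idvar = "replicate", timevar = "classifier",
                          direction = "wide")
    m <- as.matrix(tab[, paste0("accuracy.", cls)])
    colnames(m) <- cls
    m <- m[stats::complete.cases(m), , drop = FALSE]
    friedman_aligned_ranks(m)
  })
  p_adj <- finner_adjust(vapply(omni, `[[`, numeric(1), "p.value"))
  names(p_adj) <- names(omni)
  posthoc <- mapply(function(o, pa) posthoc_vs_control(o, alpha, omnibus_p = pa),
                    omni, p_adj, SIMPLIFY = FALSE)
  list(groups = names(omni), omnibus = omni, p_adj = p_adj, posthoc = posthoc)
}
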