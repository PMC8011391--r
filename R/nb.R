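#' Categorical naive Bayes over genotype calls
#'
#' Each marker is treated as a categorical variable over the genotype
#' alphabet of the data (0/1/2 for dosage, 0/1 for dominant), assumed
#' independent given the species — i.e. linkage between markers is
#' disregarded. Class priors are the species frequencies in the training
#' labels; per-marker conditionals receive Laplace smoothing, `alpha` added
#' to every cell of the class x call count table. Posteriors are accumulated
#' in log space, so `alpha = 0` with an unseen call simply drives a class to
#' log-probability `-Inf` (the class is excluded) without numeric failure.
#'
#' @param gm a fully imputed [genotype_matrix()].
#' @param labels a [label_set()] covering all accessions.
#' @param alpha Laplace smoothing pseudo-count (default 1).
#' @return An `nb_model` object for [classify_nb()].
#' @export
fit_nb <- function(gm, labels, alpha = 1) {
  stopifnot(alpha >= 0)
  if (anyNA(gm)) stop("missing calls present; run impute_most_common() first")
  lab <- unclass(align_labels(gm, labels))
  classes <- sort(unique(lab))
  alphabet <- genotype_alphabet(ploidy_mode(gm))
  calls <- unclass(gm)
  # counts: class x level x marker
  counts <- array(0L, dim = c(length(classes), length(alphabet), ncol(calls)),
                  dimnames = list(classes, alphabet, colnames(calls)))
  for (ci in seq_along(classes)) {
    rows <- calls[lab == classes[ci], , drop = FALSE]
    for (vi in seq_along(alphabet)) {
      counts[ci, vi, ] <- colSums(rows == alphabet[vi])
    }
  }
  structure(list(counts = counts, classes = classes, alphabet = alphabet,
                 class_n = as.vector(table(factor(lab, classes))),
                 alpha = alpha, ploidy_mode = ploidy_mode(gm),
                 train_ids = accessions(gm), train_lab = lab),
            class = "nb_model")
}

#' @export
print.nb_model <- function(x, ...) {
  cat(sprintf("naive Bayes model: %d species, %d markers, alpha=%g\n",
              length(x$classes), dim(x$counts)[3L], x$alpha))
  invisible(x)
}

nb_log_posterior <- function(counts, class_n, alpha, alphabet, calls) {
  # counts: class x level x marker; calls: accessions x markers (integer)
  n_lev <- length(alphabet)
  logcond <- log(sweep(counts + alpha, 1, class_n + alpha * n_lev, "/"))
  logprior <- log(class_n / sum(class_n))
  vi <- match(calls, alphabet) # vectorised over the whole matrix
  n <- nrow(calls); p <- ncol(calls); k <- dim(counts)[1L]
  post <- matrix(rep(logprior, each = n), n, k)
  for (ci in seq_len(k)) {
    lc <- matrix(logcond[ci, , ], n_lev, p) # level x marker
    idx <- cbind(as.vector(vi), rep(seq_len(p), each = n))
    post[, ci] <- post[, ci] + rowSums(matrix(lc[idx], n, p))
  }
  dimnames(post) <- list(rownames(calls), rownames(counts))
  post
}

#' Classify accessions with a naive Bayes model
#'
#' `mode = "resubstitution"` scores the training accessions against the
#' model as fitted. `mode = "loo"` refits for each query with that query
#' removed (done by down-dating the count tables, so it costs little more
#' than resubstitution); this gives an unbiased estimate when the queries
#' are the training set itself. A species reduced to zero accessions by the
#' removal drops out via its zero prior. Posterior ties break toward the
#' lexicographically first species; if every class has posterior zero the
#' call is [AMBIGUOUS].
#'
#' @param model an `nb_model` from [fit_nb()].
#' @param gm genotype matrix of the accessions to classify (imputed).
#' @param mode `"resubstitution"` or `"loo"` (queries must be the training
#'   accessions for `"loo"`).
#' @return A `species_predictions` data.frame with the winning log-posterior.
#' @export
classify_nb <- function(model, gm, mode = c("resubstitution", "loo")) {
  mode <- match.arg(mode)
  if (anyNA(gm)) stop("missing calls present; run impute_most_common() first")
  calls <- unclass(gm)
  ids <- accessions(gm)
  if (mode == "resubstitution") {
    post <- nb_log_posterior(model$counts, model$class_n, model$alpha,
                             model$alphabet, calls)
  } else {
    if (!identical(ids, model$train_ids)) {
      stop("loo mode requires classifying the training accessions")
    }
    post <- matrix(NA_real_, nrow(calls), length(model$classes),
                   dimnames = list(ids, model$classes))
    for (i in seq_len(nrow(calls))) {
      counts <- model$counts
      cn <- model$class_n
      ci <- match(model$train_lab[i], model$classes)
      vi <- match(calls[i, ], model$alphabet)
      dec <- cbind(ci, vi, seq_along(vi))
      counts[dec] <- counts[dec] - 1L
      cn[ci] <- cn[ci] - 1L
      keep <- cn > 0L
      post[i, keep] <- nb_log_posterior(
        counts[keep, , , drop = FALSE], cn[keep], model$alpha,
        model$alphabet, calls[i, , drop = FALSE])
      post[i, !keep] <- -Inf
    }
  }
  lab <- unname(model$train_lab[match(ids, model$train_ids)])
  call <- character(length(ids))
  best <- numeric(length(ids))
  for (i in seq_along(ids)) {
    pi <- post[i, ]
    if (all(!is.finite(pi))) {
      call[i] <- AMBIGUOUS
      best[i] <- -Inf
    } else {
      w <- which.max(pi) # ties -> first (classes sorted)
      call[i] <- model$classes[w]
      best[i] <- pi[w]
    }
  }
  new_predictions(ids, lab, call, sprintf("mode=%s", mode), "nb",
                  log_posterior = best)
}
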