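#' ROC curve and AUC from held-out candidate ranks
#'
#' Builds a pooled ROC curve from cross-validation trials, each recording
#' the rank of a held-out association among its disease's candidate
#' microbes. Because candidate-set sizes differ across diseases, ranks are
#' mapped to percentiles `(rank - 1) / (n_candidates - 1)` and the threshold
#' is swept over percentiles: at threshold `t` a trial is a true positive if
#' its held-out percentile is at most `t` (sensitivity), while the false
#' positive rate is the mean, over trials, of the fraction of that trial's
#' non-test candidates ranked at or above the threshold. AUC is obtained by
#' trapezoidal integration; an AUC of 1 means every held-out association was
#' ranked first, 0.5 is random performance.
#'
#' @param trials A data frame with columns `rank` (rank of the held-out
#'   association, average ranks for ties allowed) and `n_candidates`.
#' @return A list with `roc` (tibble of `threshold`, `fpr`, `tpr`, starting
#'   at (0,0) and ending at (1,1)) and `auc`.
#' @examples
#' rank_roc(tibble::tibble(rank = c(1, 3), n_candidates = c(3, 3)))$auc
#' @export
rank_roc <- function(trials) {
  trials <- as.data.frame(trials)
  if (nrow(trials) == 0) abort("no trials to build a ROC from",
                               class = "ncpmd_empty_trials")
  r <- trials$rank
  n <- trials$n_candidates
  if (any(r < 1 | r > n)) abort("ranks must lie in [1, n_candidates]")
  eps <- 1e-9
  pct_test <- ifelse(n > 1, (r - 1) / (n - 1), 0)
  # every percentile at which any trial's positive set can change
  pos_pcts <- unlist(lapply(unique(n), function(nn) {
    if (nn > 1) (seq_len(nn) - 1) / (nn - 1) else 0
  }))
  thr <- sort(unique(c(0, pos_pcts, pct_test, 1)))

  # trials x thresholds: candidates called positive at each threshold
  n_pos <- pmin(matrix(n, length(n), length(thr)),
                floor(1 + outer(n - 1, thr) + eps))
  tp <- outer(pct_test, thr, function(p, t) p <= t + eps)
  fp <- n_pos - tp
  fp_frac <- ifelse(n > 1, 1 / (n - 1), 0) * fp # rowwise scaling recycles by column

  tpr <- colMeans(tp)
  fpr <- colMeans(fp_frac)
  roc <- tibble::tibble(threshold = c(-Inf, thr), fpr = c(0, fpr),
                        tpr = c(0, tpr))
  roc <- roc[!duplicated(roc[, c("fpr", "tpr")]), ]
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
  list(roc = roc, auc = auc)
}

new_ncp_cv <- function(trials, roc, auc, protocol, mode, seed = NULL, k = NULL,
                       fold_auc = NULL, skipped = 0L) {
  structure(
    list(trials = trials, roc = roc, auc = auc, protocol = protocol,
         mode = mode, seed = seed, k = k, fold_auc = fold_auc,
         skipped = skipped),
    class = "ncp_cv"
  )
}

#' @export
print.ncp_cv <- function(x, ...) {
  cat(sprintf("<ncp_cv %s mode=%s> %d trials, AUC = %.4f\n",
              x$protocol, x$mode, nrow(x$trials), x$auc))
  if (!is.null(x$fold_auc)) {
    cat("  per-fold AUC:", paste(sprintf("%.4f", x$fold_auc), collapse = " "), "\n")
  }
  invisible(x)
}

# score the reduced network and rank each held-out edge among its disease's
# candidates (microbes without a remaining known association, test edge incl.)
rank_held_out <- function(net, A_reduced, test_edges, SS, mode, delta,
                          gamma_prime) {
  net2 <- net
  net2$A <- A_reduced
  sc <- ncp_predict(net2, symptom = SS, mode = mode, delta = delta,
                    gamma_prime = gamma_prime)$scores
  purrr::map_dfr(seq_len(nrow(test_edges)), function(t) {
    i <- test_edges[t, 1]; j <- test_edges[t, 2]
    cand <- which(A_reduced[i, ] == 0L)
    rk <- rank(-sc[i, cand], ties.method = "average")
    tibble::tibble(
      disease = net$diseases[i], microbe = net$microbes[j],
      rank = rk[match(j, cand)], n_candidates = length(cand)
    )
  })
}

resolve_ss <- function(net, symptom, mode, log_base) {
  if (is.null(symptom) || mode == "gip_only") return(NULL)
  if (inherits(symptom, "symptom_profile")) {
    cosine_symptom_similarity(tfidf_weights(symptom, log_base = log_base))
  } else {
    symptom
  }
}

#' Leave-one-out cross-validation
#'
#' Each known association is removed in turn; the GIP kernels (and hence the
#' integrated disease similarity) are recomputed on the reduced network, the
#' scoring pipeline is re-run, and the held-out microbe is ranked among the
#' disease's candidate set (microbes without a remaining known association,
#' which includes the held-out one). Symptom similarity does not depend on
#' the association network and is computed once. Pooled ranks feed
#' [rank_roc()].
#'
#' @inheritParams ncp_predict
#' @return An `ncp_cv` object: per-trial ranks, ROC points, AUC.
#' @export
ncp_loocv <- function(net, symptom = NULL,
                      mode = c("full", "gip_only", "microbe_space_only",
                               "disease_space_only"),
                      delta = 1e-30, gamma_prime = 1, log_base = 10) {
  stopifnot(inherits(net, "association_network"))
  mode <- match.arg(mode)
  edges <- which(net$A == 1L, arr.ind = TRUE)
  if (nrow(edges) < 2) abort("need at least two known associations for LOOCV")
  SS <- resolve_ss(net, symptom, mode, log_base)
  skipped <- 0L
  trials <- purrr::map_dfr(seq_len(nrow(edges)), function(e) {
    A2 <- net$A
    A2[edges[e, 1], edges[e, 2]] <- 0L
    if (sum(A2) == 0) {
      warn("trial left an empty network; skipped", class = "ncpmd_skipped_trial")
      skipped <<- skipped + 1L
      return(NULL)
    }
    rank_held_out(net, A2, edges[e, , drop = FALSE], SS, mode, delta,
                  gamma_prime)
  })
  rr <- rank_roc(trials)
  new_ncp_cv(trials, rr$roc, rr$auc, protocol = "loocv", mode = mode,
             skipped = skipped)
}

#' k-fold cross-validation
#'
#' Known associations are shuffled once with the given seed and divided into
#' `k` nearly equal subsets. For each fold, all its edges are removed
#' simultaneously, similarities are recomputed on the reduced network, and
#' each removed edge is ranked among its disease's candidates. Ranks pooled
#' across folds give one ROC/AUC; per-fold AUCs are also reported. The same
#' seed always reproduces the same partition and result.
#'
#' @inheritParams ncp_predict
#' @param k Number of folds, default 5.
#' @param seed Integer seed for the fold partition.
#' @return An `ncp_cv` object with `fold_auc` per-fold AUC values.
#' @export
ncp_kfold <- function(net, symptom = NULL,
                      mode = c("full", "gip_only", "microbe_space_only",
                               "disease_space_only"),
                      k = 5, seed = 1,
                      delta = 1e-30, gamma_prime = 1, log_base = 10) {
  stopifnot(inherits(net, "association_network"))
  mode <- match.arg(mode)
  edges <- which(net$A == 1L, arr.ind = TRUE)
  n_edges <- nrow(edges)
  if (k < 2) abort("k must be at least 2")
  if (k > n_edges) abort("k exceeds the number of known associations",
                         class = "ncpmd_bad_k")
  SS <- resolve_ss(net, symptom, mode, log_base)
  perm <- withr::with_seed(seed, sample.int(n_edges))
  fold_of <- integer(n_edges)
  fold_of[perm] <- rep(seq_len(k), length.out = n_edges)

  skipped <- 0L
  per_fold <- purrr::map(seq_len(k), function(f) {
    test <- edges[fold_of == f, , drop = FALSE]
    A2 <- net$A
    A2[test] <- 0L
    if (sum(A2) == 0) {
      warn("fold left an empty network; skipped", class = "ncpmd_skipped_trial")
      skipped <<- skipped + 1L
      return(NULL)
    }
    rank_held_out(net, A2, test, SS, mode, delta, gamma_prime) |>
      dplyr::mutate(fold = f)
  })
  trials <- dplyr::bind_rows(per_fold)
  rr <- rank_roc(trials)
  fold_auc <- vapply(per_fold, function(tr) {
    if (is.null(tr) || nrow(tr) == 0) NA_real_ else rank_roc(tr)$auc
  }, numeric(1))
  new_ncp_cv(trials, rr$roc, rr$auc, protocol = "kfold", mode = mode,
             seed = seed, k = k, fold_auc = fold_auc, skipped = skipped)
}

#' @describeIn ncp_loocv Per-trial tibble (`disease`, `microbe`, `rank`,
#'   `n_candidates`, and `fold` for k-fold runs).
#' @param x An `ncp_cv` object.
#' @param ... Unused.
#' @export
tidy.ncp_cv <- function(x, ...) tibble::as_tibble(x$trials)

#' @describeIn ncp_loocv One-row summary: AUC, trial count, protocol, seed.
#' @export
glance.ncp_cv <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, n_trials = nrow(x$trials), protocol = x$protocol,
    mode = x$mode, k = x$k %||% NA_integer_, seed = x$seed %||% NA_integer_,
    skipped = x$skipped
  )
}

#' ROC curve plot for a cross-validation result
#'
#' @param object An `ncp_cv` object.
#' @param ... Unused.
#' @return A ggplot object of the ROC curve with the chance diagonal.
#' @export
autoplot.ncp_cv <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("%s (%s), AUC = %.4f", object$protocol, object$mode,
                      object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Serialize a cross-validation result to JSON
#'
#' Writes trials, ROC points, AUC and protocol metadata as stable JSON
#' (fixed field order, full precision) so repeated runs with the same seed
#' are byte-identical.
#'
#' @param cv An `ncp_cv` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cv_json <- function(cv, path) {
  payload <- list(
    protocol = cv$protocol, mode = cv$mode,
    seed = cv$seed, k = cv$k, auc = cv$auc,
    fold_auc = cv$fold_auc, skipped = cv$skipped,
    trials = as.data.frame(cv$trials),
    roc = as.data.frame(cv$roc)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Export ROC points as TSV
#'
#' @param cv An `ncp_cv` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_roc_tsv <- function(cv, path) {
  readr::write_tsv(tibble::as_tibble(cv$roc), path, progress = FALSE)
  invisible(path)
}
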