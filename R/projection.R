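#' Replace adjacency zeros by a tiny positive constant
#'
#' Projection denominators are vector lengths of adjacency rows/columns; a
#' disease or microbe with no known association would give length 0. Every
#' zero of the adjacency matrix is therefore replaced by a small `delta`
#' (default `1e-30`) before projection, which keeps all norms strictly
#' positive while perturbing dot products by an invisible amount.
#'
#' @param A Binary adjacency matrix.
#' @param delta Small positive constant; default `1e-30`.
#' @return Numeric matrix with 1s kept and 0s replaced by `delta`.
#' @export
substitute_delta <- function(A, delta = 1e-30) {
  if (!is.numeric(delta) || length(delta) != 1 || delta <= 0) {
    abort("delta must be a single positive number", class = "ncpmd_bad_delta")
  }
  Ap <- A * 1
  Ap[Ap == 0] <- delta
  Ap
}

#' Microbe space projection
#'
#' Projects each microbe's similarity vector onto each disease's association
#' vector: `msp(i, j) = <A'_i, MS_j> / ||A'_i||`, where `A'_i` is row `i` of
#' the delta-substituted adjacency and `MS_j` is column `j` of the microbe
#' similarity matrix.
#'
#' @param Aprime Delta-substituted adjacency matrix (diseases x microbes).
#' @param MS Microbe [similarity_matrix()] aligned with the columns of
#'   `Aprime`.
#' @return Numeric matrix (diseases x microbes).
#' @export
microbe_space_projection <- function(Aprime, MS) {
  if (ncol(Aprime) != nrow(MS)) abort("Aprime columns must match MS dimension",
                                      class = "ncpmd_shape_mismatch")
  (Aprime %*% unclass(MS)) / sqrt(rowSums(Aprime^2))
}

#' Disease space projection
#'
#' Projects each disease's similarity vector onto each microbe's association
#' vector: `dsp(i, j) = <DS_i, A'_j> / ||A'_j||`, where `A'_j` is column `j`
#' of the delta-substituted adjacency and `DS_i` is row `i` of the
#' integrated disease similarity matrix.
#'
#' @param Aprime Delta-substituted adjacency matrix (diseases x microbes).
#' @param DS Disease [similarity_matrix()] aligned with the rows of `Aprime`.
#' @return Numeric matrix (diseases x microbes).
#' @export
disease_space_projection <- function(Aprime, DS) {
  if (nrow(Aprime) != nrow(DS)) abort("Aprime rows must match DS dimension",
                                      class = "ncpmd_shape_mismatch")
  (unclass(DS) %*% Aprime) / matrix(sqrt(colSums(Aprime^2)),
                                    nrow(Aprime), ncol(Aprime), byrow = TRUE)
}

#' Combine the two projections into the network consistency score
#'
#' `ncp(i, j) = (dsp(i, j) + msp(i, j)) / (||DS_i|| + ||MS_j||)`. Both
#' similarity matrices have unit diagonal, so the denominator is always
#' at least 2 and the score is finite everywhere.
#'
#' @param msp,dsp Projection matrices (diseases x microbes).
#' @param DS,MS Disease and microbe similarity matrices used for the
#'   normalising vector lengths.
#' @return Numeric matrix of final projection scores.
#' @export
ncp_combine <- function(msp, dsp, DS, MS) {
  denom <- outer(sqrt(rowSums(unclass(DS)^2)),
                 sqrt(colSums(unclass(MS)^2)), `+`)
  (msp + dsp) / denom
}

#' Score all microbe-disease pairs by network consistency projection
#'
#' Runs the full scoring pipeline on an association network: GIP kernels for
#' microbes and diseases, optional symptom-based disease similarity
#' integrated into the disease similarity, delta substitution, both space
#' projections, and the combined score. The method has no tunable
#' parameters; `gamma_prime = 1` and `delta = 1e-30` are fixed by
#' construction and exposed only for sensitivity checks.
#'
#' @param net An [association_network()].
#' @param symptom Optional symptom input: a [similarity_matrix()] with role
#'   `"SS"`, a [symptom_profile()] (TF-IDF/cosine similarity is computed
#'   from it), or `NULL`.
#' @param mode Scoring mode: `"full"` (both projections, integrated disease
#'   similarity), `"gip_only"` (both projections, kernel disease similarity
#'   only), `"microbe_space_only"` (`msp / ||MS_j||`), or
#'   `"disease_space_only"` (`dsp / ||DS_i||`).
#' @param delta Zero-substitution constant, default `1e-30`.
#' @param gamma_prime GIP bandwidth multiplier, default 1.
#' @param log_base IDF log base when `symptom` is a profile of counts.
#' @return An `ncp_scores` object: `scores` (diseases x microbes), component
#'   matrices `msp`/`dsp`, the similarity matrices used, mode and delta.
#' @examples
#' net <- association_network(
#'   tibble::tibble(d = c("d1", "d1", "d2"), m = c("m1", "m2", "m2"))
#' )
#' ncp_predict(net)
#' @export
ncp_predict <- function(net, symptom = NULL,
                        mode = c("full", "gip_only", "microbe_space_only",
                                 "disease_space_only"),
                        delta = 1e-30, gamma_prime = 1, log_base = 10) {
  stopifnot(inherits(net, "association_network"))
  mode <- match.arg(mode)
  A <- net$A
  MS <- gip_kernel(t(A), gamma_prime = gamma_prime, role = "MS")
  GS <- gip_kernel(A, gamma_prime = gamma_prime, role = "GS")

  SS <- NULL
  if (!is.null(symptom) && mode != "gip_only") {
    SS <- if (inherits(symptom, "symptom_profile")) {
      cosine_symptom_similarity(tfidf_weights(symptom, log_base = log_base))
    } else if (inherits(symptom, "similarity_matrix")) {
      symptom
    } else {
      abort("symptom must be a symptom_profile, an SS similarity_matrix, or NULL")
    }
  }
  DS <- if (mode == "gip_only" || is.null(SS)) {
    integrate_disease_similarity(NULL, GS)
  } else {
    integrate_disease_similarity(SS, GS)
  }

  Ap <- substitute_delta(A, delta)
  msp <- microbe_space_projection(Ap, MS)
  dsp <- disease_space_projection(Ap, DS)
  scores <- switch(
    mode,
    full = ,
    gip_only = ncp_combine(msp, dsp, DS, MS),
    microbe_space_only = msp / matrix(sqrt(colSums(unclass(MS)^2)),
                                      nrow(msp), ncol(msp), byrow = TRUE),
    disease_space_only = dsp / sqrt(rowSums(unclass(DS)^2))
  )
  dimnames(scores) <- dimnames(A)
  structure(
    list(diseases = net$diseases, microbes = net$microbes,
         scores = scores, msp = msp, dsp = dsp,
         MS = MS, DS = DS, A = A, mode = mode, delta = delta),
    class = "ncp_scores"
  )
}

#' @export
print.ncp_scores <- function(x, ...) {
  cat(sprintf("<ncp_scores mode=%s> %d diseases x %d microbes (delta=%g)\n",
              x$mode, length(x$diseases), length(x$microbes), x$delta))
  invisible(x)
}

#' @describeIn ncp_predict Long tibble of per-pair scores with a
#'   `known` flag for associations already in the training network.
#' @param x An `ncp_scores` object.
#' @param ... Unused.
#' @export
tidy.ncp_scores <- function(x, ...) {
  tibble::tibble(
    disease = rep(x$diseases, times = length(x$microbes)),
    microbe = rep(x$microbes, each = length(x$diseases)),
    score = as.vector(x$scores),
    known = as.vector(x$A == 1L)
  ) |> dplyr::arrange(.data$disease, .data$microbe)
}

#' Rank candidate microbes per disease
#'
#' For each disease, ranks the candidate microbes (those without a known
#' association) by descending projection score. Ties are broken by microbe
#' label (ascending) so output order is reproducible. Known associations are
#' listed separately with `known = TRUE` and no rank.
#'
#' @param scores An `ncp_scores` object from [ncp_predict()].
#' @param top_k Keep at most this many candidates per disease (`Inf` = all).
#' @return A tibble `(disease, rank, microbe, score, known)`; known pairs
#'   follow the ranked candidates of each disease with `rank = NA`.
#' @export
rank_predictions <- function(scores, top_k = Inf) {
  stopifnot(inherits(scores, "ncp_scores"))
  tidy(scores) |>
    dplyr::group_by(.data$disease) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$microbe, .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::if_else(.data$known, NA_integer_,
                                        cumsum(!.data$known))) |>
    dplyr::filter(.data$known | .data$rank <= top_k) |>
    dplyr::arrange(.data$known, .by_group = TRUE) |>
    dplyr::ungroup() |>
    dplyr::select("disease", "rank", "microbe", "score", "known")
}

#' Write ranked per-disease predictions to a TSV
#'
#' @inheritParams rank_predictions
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ranked_predictions <- function(scores, path, top_k = Inf) {
  ranked <- rank_predictions(scores, top_k = top_k)
  names(ranked)[names(ranked) == "known"] <- "is_known"
  writeLines("# ranked candidate microbes per disease (ties broken by microbe label)",
             path)
  readr::write_tsv(ranked, path, col_names = TRUE, append = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Heatmap of projection scores
#'
#' @param object An `ncp_scores` object.
#' @param ... Unused.
#' @return A ggplot object: disease-by-microbe score heatmap with known
#'   associations outlined.
#' @export
autoplot.ncp_scores <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$microbe, y = .data$disease)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$score)) +
    ggplot2::geom_tile(data = dplyr::filter(df, .data$known),
                       fill = NA, colour = "black", linewidth = 0.4) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "microbe", y = "disease", fill = "score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}
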