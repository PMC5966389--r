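#' Similarity matrix container
#'
#' A square, symmetric, labelled similarity matrix with a role tag:
#' `"MS"` (GIP microbe similarity), `"GS"` (GIP disease similarity),
#' `"SS"` (symptom-based disease similarity, with a presence mask marking
#' which pairs were actually scored), or `"DS"` (integrated disease
#' similarity).
#'
#' @param S Square numeric matrix with matching dimnames.
#' @param role One of `"MS"`, `"GS"`, `"SS"`, `"DS"`.
#' @param presence Logical matrix marking scored pairs (SS only).
#' @param gamma Kernel bandwidth actually used (GIP roles, metadata).
#' @return A `similarity_matrix` (numeric matrix subclass).
#' @export
similarity_matrix <- function(S, role = c("MS", "GS", "SS", "DS"),
                              presence = NULL, gamma = NULL) {
  role <- match.arg(role)
  if (nrow(S) != ncol(S)) abort("similarity matrix must be square")
  if (nrow(S) > 0 && max(abs(S - t(S))) > 1e-12) {
    abort("similarity matrix must be symmetric", class = "ncpmd_asymmetric")
  }
  structure(S, class = c("similarity_matrix", "matrix", "array"),
            role = role, presence = presence, gamma = gamma)
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix role=%s> %d x %d\n",
              attr(x, "role"), nrow(x), ncol(x)))
  if (nrow(x) > 0) print(head(unclass(x)[, seq_len(min(6, ncol(x))), drop = FALSE]))
  invisible(x)
}

#' @describeIn similarity_matrix Long tibble of pairwise similarities
#'   (upper triangle including the diagonal; SS adds a `scored` column).
#' @param x A `similarity_matrix`.
#' @param ... Unused.
#' @export
tidy.similarity_matrix <- function(x, ...) {
  n <- nrow(x)
  if (n == 0) {
    return(tibble::tibble(from = character(), to = character(),
                          similarity = numeric()))
  }
  idx <- which(upper.tri(x, diag = TRUE), arr.ind = TRUE)
  out <- tibble::tibble(
    from = rownames(x)[idx[, 1]],
    to = colnames(x)[idx[, 2]],
    similarity = x[idx]
  )
  pres <- attr(x, "presence")
  if (!is.null(pres)) out$scored <- pres[idx]
  out
}

# squared Euclidean distances between rows of P, stable and loop-free
row_sq_dists <- function(P) {
  n2 <- rowSums(P^2)
  D2 <- outer(n2, n2, "+") - 2 * tcrossprod(P)
  D2[D2 < 0] <- 0
  D2
}

#' Gaussian interaction profile (GIP) kernel similarity
#'
#' Computes `S(a, b) = exp(-gamma * ||p_a - p_b||^2)` between binary
#' interaction profiles (rows of `profiles`). The bandwidth is normalised by
#' the mean squared profile norm: `gamma = gamma_prime / mean(||p||^2)`, so
#' the kernel width tracks the average number of associations per entity.
#' For microbe similarity pass the columns of the adjacency matrix (profiles
#' over diseases); for disease similarity pass the rows (profiles over
#' microbes).
#'
#' @param profiles Numeric matrix; each row is one entity's binary
#'   interaction profile.
#' @param gamma_prime Positive bandwidth multiplier; the method fixes it at 1.
#' @param role Role tag for the result, `"MS"` or `"GS"`.
#' @return A [similarity_matrix()] with entries in `(0, 1]`, diagonal 1 and
#'   the realised `gamma` stored as an attribute.
#' @examples
#' A <- diag(2) # two diseases, two microbes, one association each
#' gip_kernel(t(A), role = "MS") # off-diagonal exp(-2)
#' @export
gip_kernel <- function(profiles, gamma_prime = 1, role = c("MS", "GS")) {
  role <- match.arg(role)
  P <- as.matrix(profiles)
  if (nrow(P) < 1) abort("need at least one profile")
  if (gamma_prime <= 0) abort("gamma_prime must be positive")
  msn <- mean(rowSums(P^2))
  if (msn == 0) {
    abort("all interaction profiles are zero: GIP bandwidth undefined",
          class = "ncpmd_degenerate_network")
  }
  gamma <- gamma_prime / msn
  S <- exp(-gamma * row_sq_dists(P))
  S <- (S + t(S)) / 2
  diag(S) <- 1
  dimnames(S) <- list(rownames(P), rownames(P))
  similarity_matrix(S, role = role, gamma = gamma)
}

#' TF-IDF weights for disease-symptom co-occurrence
#'
#' Weights each co-occurrence count by the inverse document frequency of its
#' symptom: `w[i, m] = W[i, m] * log(N / n_m)`, where `N` is the number of
#' diseases and `n_m` the number of diseases co-occurring with symptom `m`.
#' Symptoms shared by every disease get zero weight; symptoms never observed
#' get zero weight everywhere. The log base (default 10) rescales all weights
#' by a common factor and therefore never changes the cosine similarity
#' built from them.
#'
#' @param profile A [symptom_profile()].
#' @param log_base Base of the IDF logarithm; default 10.
#' @return A `tfidf_weights` list: `diseases`, `symptoms`, `w` (weight
#'   matrix; rows are the disease vectors `d_i`).
#' @export
tfidf_weights <- function(profile, log_base = 10) {
  stopifnot(inherits(profile, "symptom_profile"))
  W <- profile$W
  N <- nrow(W)
  n_m <- colSums(W > 0)
  idf <- ifelse(n_m > 0, log(N / n_m, base = log_base), 0)
  w <- sweep(W, 2, idf, `*`)
  structure(
    list(diseases = profile$diseases, symptoms = profile$symptoms,
         w = w, log_base = log_base),
    class = "tfidf_weights"
  )
}

#' @export
print.tfidf_weights <- function(x, ...) {
  cat(sprintf("<tfidf_weights> %d diseases x %d symptoms (log base %g)\n",
              nrow(x$w), ncol(x$w), x$log_base))
  invisible(x)
}

#' Symptom-based disease similarity (cosine over TF-IDF vectors)
#'
#' `SS(i, n) = <d_i, d_n> / (||d_i|| ||d_n||)` over the TF-IDF-weighted
#' symptom vectors. Values lie in `[0, 1]`: 0 means no shared symptoms, 1
#' identical symptom profiles. Diseases whose weight vector is all zero have
#' no usable symptom information; their similarities (including the
#' diagonal) are set to 0 and excluded from the presence mask so they fall
#' back to kernel similarity during integration.
#'
#' @param weights A [tfidf_weights()] object.
#' @return A [similarity_matrix()] with role `"SS"` and a presence mask that
#'   is `TRUE` exactly for pairs of diseases with nonzero symptom vectors.
#' @export
cosine_symptom_similarity <- function(weights) {
  stopifnot(inherits(weights, "tfidf_weights"))
  w <- weights$w
  norms <- sqrt(rowSums(w^2))
  nonzero <- norms > 0
  if (any(!nonzero)) {
    inform(sprintf("%d disease(s) have zero symptom vectors; SS set to 0 for them",
                   sum(!nonzero)))
  }
  safe <- ifelse(nonzero, norms, 1)
  U <- w / safe
  S <- tcrossprod(U)
  S[!nonzero, ] <- 0
  S[, !nonzero] <- 0
  S[S < 0] <- 0
  S[S > 1] <- 1
  S <- (S + t(S)) / 2
  diag(S)[nonzero] <- 1
  P <- outer(nonzero, nonzero, `&`)
  dimnames(S) <- list(weights$diseases, weights$diseases)
  dimnames(P) <- dimnames(S)
  similarity_matrix(S, role = "SS", presence = P)
}

#' Integrated disease similarity
#'
#' Combines symptom-based similarity with kernel similarity: where a disease
#' pair was actually scored by symptoms (presence mask `TRUE`, even if the
#' score is 0), the symptom similarity is used; everywhere else the Gaussian
#' interaction profile kernel similarity stands in. The result covers
#' exactly the diseases of `GS` (the association network); `SS` may be
#' partial or cover extra diseases, matched by label.
#'
#' @param SS A [similarity_matrix()] with role `"SS"` and presence mask, or
#'   `NULL` for no symptom information.
#' @param GS A [similarity_matrix()] with role `"GS"` covering all network
#'   diseases.
#' @return A [similarity_matrix()] with role `"DS"`, diagonal 1.
#' @export
integrate_disease_similarity <- function(SS, GS) {
  stopifnot(inherits(GS, "similarity_matrix"))
  D <- unclass(GS)
  attr(D, "gamma") <- NULL
  if (is.null(SS) || nrow(SS) == 0) {
    return(similarity_matrix(D, role = "DS"))
  }
  stopifnot(inherits(SS, "similarity_matrix"))
  pres <- attr(SS, "presence")
  if (is.null(pres)) pres <- matrix(TRUE, nrow(SS), ncol(SS), dimnames = dimnames(SS))
  gs_labs <- tolower(rownames(D))
  ss_labs <- tolower(rownames(SS))
  idx <- match(gs_labs, ss_labs)
  hit <- which(!is.na(idx))
  if (length(hit) > 0) {
    sub_ss <- unclass(SS)[idx[hit], idx[hit], drop = FALSE]
    sub_p <- pres[idx[hit], idx[hit], drop = FALSE]
    block <- D[hit, hit, drop = FALSE]
    block[sub_p] <- sub_ss[sub_p]
    D[hit, hit] <- block
  }
  diag(D) <- 1
  similarity_matrix(D, role = "DS")
}
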