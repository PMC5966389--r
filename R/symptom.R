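#' Disease-by-symptom co-occurrence profile
#'
#' Holds the non-negative count matrix `W` where `W[i, m]` is the number of
#' times disease `i` and symptom `m` appear together (term co-occurrence).
#' Feeds TF-IDF weighting and cosine symptom similarity.
#'
#' @param counts A data frame of `(disease, symptom, count)` triples, or a
#'   matrix/wide data frame whose rows are diseases and columns symptoms.
#' @return A `symptom_profile`: list with `diseases`, `symptoms`, `W`.
#' @examples
#' symptom_profile(tibble::tibble(
#'   disease = c("d1", "d1", "d2"), symptom = c("s1", "s2", "s1"),
#'   count = c(2, 1, 1)
#' ))
#' @export
symptom_profile <- function(counts) {
  if (is.matrix(counts)) {
    W <- counts
  } else {
    counts <- as.data.frame(counts)
    if (ncol(counts) >= 3 && !is.numeric(counts[[2]])) {
      # long triples
      d_raw <- trimws(as.character(counts[[1]]))
      s_raw <- trimws(as.character(counts[[2]]))
      val <- as.numeric(counts[[3]])
      diseases <- d_raw[!duplicated(tolower(d_raw))]
      symptoms <- s_raw[!duplicated(tolower(s_raw))]
      W <- matrix(0, length(diseases), length(symptoms),
                  dimnames = list(diseases, symptoms))
      ij <- cbind(match(tolower(d_raw), tolower(diseases)),
                  match(tolower(s_raw), tolower(symptoms)))
      # repeated triples accumulate
      for (k in seq_along(val)) W[ij[k, 1], ij[k, 2]] <- W[ij[k, 1], ij[k, 2]] + val[k]
    } else {
      # wide: first column disease labels, remaining columns symptom counts
      W <- as.matrix(counts[, -1, drop = FALSE])
      storage.mode(W) <- "double"
      rownames(W) <- trimws(as.character(counts[[1]]))
    }
  }
  if (any(W < 0)) abort("symptom counts must be non-negative",
                        class = "ncpmd_negative_counts")
  if (nrow(W) >= 1 && any(rowSums(W) == 0)) {
    inform(sprintf("%d disease(s) have all-zero symptom rows (retained)",
                   sum(rowSums(W) == 0)))
  }
  structure(
    list(diseases = rownames(W), symptoms = colnames(W), W = W),
    class = "symptom_profile"
  )
}

#' @export
print.symptom_profile <- function(x, ...) {
  cat(sprintf("<symptom_profile> %d diseases x %d symptoms, total count %g\n",
              nrow(x$W), ncol(x$W), sum(x$W)))
  invisible(x)
}

#' @describeIn symptom_profile Long tibble of nonzero co-occurrence counts.
#' @param x A `symptom_profile`.
#' @param ... Unused.
#' @export
tidy.symptom_profile <- function(x, ...) {
  idx <- which(x$W > 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  tibble::tibble(
    disease = x$diseases[idx[, 1]],
    symptom = x$symptoms[idx[, 2]],
    count = x$W[idx]
  )
}

#' Read disease-symptom co-occurrence counts
#'
#' Accepts either long TSV triples `(disease, symptom, count)` or a wide
#' table whose header row names the symptoms and whose first column names the
#' diseases. The format is detected from the first data row.
#'
#' @param path Path to the counts file.
#' @param delim Field delimiter, default tab.
#' @return A [symptom_profile()].
#' @export
read_symptom_counts <- function(path, delim = "\t") {
  if (!file.exists(path)) {
    abort(sprintf("symptom counts file not found: %s", path),
          class = "ncpmd_missing_file")
  }
  tab <- readr::read_delim(
    path, delim = delim, col_names = FALSE, comment = "#",
    col_types = readr::cols(.default = readr::col_character()),
    trim_ws = TRUE, progress = FALSE
  )
  if (nrow(tab) == 0) abort("symptom counts file is empty",
                            class = "ncpmd_empty_input")
  first_row <- unlist(tab[1, ])
  looks_long <- ncol(tab) == 3 &&
    all(!is.na(suppressWarnings(as.numeric(unlist(tab[[3]])))) |
          tolower(unlist(tab[[3]])) %in% c("count", "n"))
  if (looks_long) {
    if (tolower(first_row[3]) %in% c("count", "n")) tab <- tab[-1, , drop = FALSE]
    df <- data.frame(disease = tab[[1]], symptom = tab[[2]],
                     count = as.numeric(tab[[3]]))
    symptom_profile(df)
  } else {
    # wide: header row of symptoms, first column of diseases
    symptoms <- unlist(tab[1, -1])
    body <- tab[-1, , drop = FALSE]
    W <- as.matrix(as.data.frame(lapply(body[, -1, drop = FALSE], as.numeric)))
    dimnames(W) <- list(trimws(unlist(body[, 1])), trimws(symptoms))
    symptom_profile(W)
  }
}

#' Write symptom co-occurrence counts as long TSV triples
#'
#' @param profile A [symptom_profile()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_symptom_counts <- function(profile, path) {
  readr::write_tsv(tidy(profile), path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a precomputed symptom-based disease similarity file
#'
#' Reads TSV triples `(disease_a, disease_b, score)` with scores in `[0, 1]`
#' and returns a symmetric similarity matrix over the union of mentioned
#' diseases. Pairs not listed in the file are ABSENT -- recorded in the
#' presence mask as `FALSE`, distinct from an explicit 0 score -- and fall
#' back to kernel similarity during integration. The diagonal of listed
#' diseases is set to 1.
#'
#' @param path Path to the similarity triples file.
#' @param delim Field delimiter, default tab.
#' @return A [similarity_matrix()] with role `"SS"` and a presence mask.
#' @export
read_symptom_similarity <- function(path, delim = "\t") {
  if (!file.exists(path)) {
    abort(sprintf("symptom similarity file not found: %s", path),
          class = "ncpmd_missing_file")
  }
  tab <- readr::read_delim(
    path, delim = delim, col_names = FALSE, comment = "#",
    col_types = readr::cols(.default = readr::col_character()),
    trim_ws = TRUE, progress = FALSE
  )
  if (nrow(tab) == 0) {
    return(similarity_matrix(matrix(numeric(0), 0, 0), role = "SS",
                             presence = matrix(logical(0), 0, 0)))
  }
  if (ncol(tab) < 3) abort("symptom similarity needs (disease, disease, score) triples",
                           class = "ncpmd_bad_columns")
  if (is.na(suppressWarnings(as.numeric(tab[[3]][1])))) tab <- tab[-1, , drop = FALSE]
  da <- trimws(tab[[1]]); db <- trimws(tab[[2]])
  sc <- as.numeric(tab[[3]])
  if (any(is.na(sc)) || any(sc < 0 | sc > 1)) {
    abort("symptom similarity scores must be numbers in [0, 1]",
          class = "ncpmd_bad_score")
  }
  self <- tolower(da) == tolower(db)
  if (any(self & sc != 1)) {
    warn("self-pair with score != 1 coerced to 1", class = "ncpmd_selfpair")
    sc[self] <- 1
  }
  labs <- c(da, db)
  labs <- labs[!duplicated(tolower(labs))]
  n <- length(labs)
  S <- matrix(0, n, n, dimnames = list(labs, labs))
  P <- matrix(FALSE, n, n, dimnames = list(labs, labs))
  ia <- match(tolower(da), tolower(labs))
  ib <- match(tolower(db), tolower(labs))
  S[cbind(ia, ib)] <- sc; S[cbind(ib, ia)] <- sc
  P[cbind(ia, ib)] <- TRUE; P[cbind(ib, ia)] <- TRUE
  diag(S) <- 1; diag(P) <- TRUE
  similarity_matrix(S, role = "SS", presence = P)
}

#' Write a similarity matrix
#'
#' Full square TSV with a header row and a leading label column.
#'
#' @param sim A [similarity_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(sim, path) {
  df <- as.data.frame(unclass(sim))
  df <- cbind(label = rownames(sim), df)
  readr::write_tsv(tibble::as_tibble(df), path, progress = FALSE)
  invisible(path)
}
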