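#' Build a microbe-disease association network from an edge table
#'
#' Constructs the binary disease-by-microbe adjacency matrix \eqn{A} from a
#' two-column table of known associations. `A[i, j] = 1` iff disease `i` and
#' microbe `j` are associated. Duplicate edges collapse to a single
#' association with a warning (mirroring database de-duplication at load
#' time). Labels are matched case-insensitively after whitespace trimming;
#' the first-seen casing is kept for display.
#'
#' @param edges A data frame whose first two columns are disease and microbe
#'   labels (character). Extra columns are ignored.
#' @param order Label ordering for rows/columns: `"first-appearance"`
#'   (default) or `"lexicographic"`. Recorded in the object so matrices are
#'   reproducible.
#' @return An `association_network`: a list with `diseases`, `microbes`
#'   (ordered label vectors) and `A` (binary matrix, diseases x microbes).
#' @examples
#' net <- association_network(
#'   tibble::tibble(disease = c("d1", "d1", "d2"), microbe = c("m1", "m2", "m1"))
#' )
#' net$A
#' @export
association_network <- function(edges, order = c("first-appearance", "lexicographic")) {
  order <- match.arg(order)
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2) {
    abort("edge table needs at least two columns (disease, microbe)",
          class = "ncpmd_bad_columns")
  }
  if (nrow(edges) == 0) {
    abort("edge table is empty", class = "ncpmd_empty_edgelist")
  }
  d_raw <- trimws(as.character(edges[[1]]))
  m_raw <- trimws(as.character(edges[[2]]))
  d_key <- tolower(d_raw)
  m_key <- tolower(m_raw)

  dup <- duplicated(paste(d_key, m_key, sep = "\r"))
  if (any(dup)) {
    warn(sprintf("collapsed %d duplicate association(s)", sum(dup)),
         class = "ncpmd_duplicate_edges")
    d_raw <- d_raw[!dup]; m_raw <- m_raw[!dup]
    d_key <- d_key[!dup]; m_key <- m_key[!dup]
  }

  pick_labels <- function(raw, key) {
    first <- raw[!duplicated(key)]
    if (order == "lexicographic") first <- first[order(tolower(first))]
    first
  }
  diseases <- pick_labels(d_raw, d_key)
  microbes <- pick_labels(m_raw, m_key)

  A <- matrix(0L, length(diseases), length(microbes),
              dimnames = list(diseases, microbes))
  A[cbind(match(d_key, tolower(diseases)), match(m_key, tolower(microbes)))] <- 1L

  structure(
    list(diseases = diseases, microbes = microbes, A = A, order = order),
    class = "association_network"
  )
}

#' @export
print.association_network <- function(x, ...) {
  cat(sprintf(
    "<association_network> %d diseases x %d microbes, %d associations\n",
    length(x$diseases), length(x$microbes), sum(x$A)
  ))
  invisible(x)
}

#' @describeIn association_network Edge-list view of the network (one row per
#'   known association, in row-major matrix order).
#' @param x An `association_network`.
#' @param ... Unused.
#' @export
tidy.association_network <- function(x, ...) {
  idx <- which(x$A == 1L, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  tibble::tibble(
    disease = x$diseases[idx[, 1]],
    microbe = x$microbes[idx[, 2]]
  )
}

#' Read a microbe-disease association edge list
#'
#' Reads a TSV (or CSV) whose first two columns are disease and microbe
#' labels. Lines starting with `#` are skipped. A header line is
#' auto-detected: if the first row, read as data, duplicates no other row and
#' looks like column names (`disease`/`microbe`), it is dropped.
#'
#' @param path Path to the edge-list file.
#' @param delim Field delimiter, default tab.
#' @inheritParams association_network
#' @return An [association_network()].
#' @export
read_association_edgelist <- function(path, delim = "\t",
                                      order = c("first-appearance", "lexicographic")) {
  if (!file.exists(path)) {
    abort(sprintf("association file not found: %s", path),
          class = "ncpmd_missing_file")
  }
  tab <- readr::read_delim(
    path, delim = delim, col_names = FALSE, comment = "#",
    col_types = readr::cols(.default = readr::col_character()),
    trim_ws = TRUE, progress = FALSE
  )
  if (nrow(tab) == 0) {
    abort("edge list file contains no data rows", class = "ncpmd_empty_edgelist")
  }
  if (ncol(tab) < 2) {
    abort("edge list needs at least two columns (disease, microbe)",
          class = "ncpmd_bad_columns")
  }
  first <- tolower(trimws(unlist(tab[1, 1:2])))
  if (all(first %in% c("disease", "microbe", "disease_name", "microbe_name"))) {
    tab <- tab[-1, , drop = FALSE]
    if (nrow(tab) == 0) {
      abort("edge list file contains only a header", class = "ncpmd_empty_edgelist")
    }
  }
  net <- association_network(tab, order = match.arg(order))
  inform(sprintf(
    "loaded %d associations between %d microbes and %d diseases",
    sum(net$A), length(net$microbes), length(net$diseases)
  ))
  net
}

#' Write an association network back to an edge-list TSV
#'
#' @param net An [association_network()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_association_edgelist <- function(net, path) {
  readr::write_tsv(tidy(net), path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Global network statistics
#'
#' Counts, mean degrees and degree histograms of a bipartite association
#' network. The mean microbe degree is `n_associations / n_microbes` (average
#' number of diseases per microbe) and the mean disease degree is
#' `n_associations / n_diseases`.
#'
#' @param net An [association_network()].
#' @return A `network_stats` list with `n_diseases`, `n_microbes`,
#'   `n_associations`, `mean_microbe_degree`, `mean_disease_degree`, and the
#'   two degree histograms (tibbles `degree`, `count`).
#' @examples
#' net <- association_network(
#'   tibble::tibble(d = c("d1", "d1", "d2"), m = c("m1", "m2", "m1"))
#' )
#' network_stats(net)
#' @export
network_stats <- function(net) {
  stopifnot(inherits(net, "association_network"))
  mdeg <- colSums(net$A)
  ddeg <- rowSums(net$A)
  n_assoc <- sum(net$A)
  hist_tbl <- function(deg) {
    tb <- table(deg)
    tibble::tibble(degree = as.integer(names(tb)), count = as.integer(tb))
  }
  structure(
    list(
      n_diseases = length(net$diseases),
      n_microbes = length(net$microbes),
      n_associations = n_assoc,
      mean_microbe_degree = n_assoc / length(net$microbes),
      mean_disease_degree = n_assoc / length(net$diseases),
      microbe_degree_histogram = hist_tbl(mdeg),
      disease_degree_histogram = hist_tbl(ddeg)
    ),
    class = "network_stats"
  )
}

#' @export
print.network_stats <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<network_stats>\n  microbes: %d  diseases: %d  associations: %d\n",
      "  mean microbe degree: %.4f\n  mean disease degree: %.4f\n"
    ),
    x$n_microbes, x$n_diseases, x$n_associations,
    x$mean_microbe_degree, x$mean_disease_degree
  ))
  invisible(x)
}

#' @describeIn network_stats One-row summary tibble.
#' @param x A `network_stats` object.
#' @param ... Unused.
#' @export
glance.network_stats <- function(x, ...) {
  tibble::tibble(
    n_diseases = x$n_diseases,
    n_microbes = x$n_microbes,
    n_associations = x$n_associations,
    mean_microbe_degree = x$mean_microbe_degree,
    mean_disease_degree = x$mean_disease_degree
  )
}
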