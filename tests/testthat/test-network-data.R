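test_that("association_network builds the adjacency from an edge table", {
  net <- association_network(
    tibble::tibble(disease = c("d1", "d1", "d2"), microbe = c("m1", "m2", "m1"))
  )
  expect_equal(unname(net$A), matrix(c(1L, 1L, 1L, 0L), 2, 2, byrow = TRUE))
  expect_equal(net$diseases, c("d1", "d2"))
  expect_equal(net$microbes, c("m1", "m2"))
})

test_that("duplicate edges collapse to one association with a warning", {
  edges <- tibble::tibble(d = c("d1", "d1", "d2", "d1"),
                          m = c("m1", "m2", "m1", "m1"))
  expect_warning(net <- association_network(edges),
                 class = "ncpmd_duplicate_edges")
  clean <- association_network(edges[1:3, ])
  expect_identical(net$A, clean$A)
})

test_that("labels are matched case-insensitively with whitespace trimmed", {
  net <- association_network(
    tibble::tibble(d = c("Asthma", " asthma", "Obesity"),
                   m = c("m1", "m2", "m1"))
  )
  expect_equal(net$diseases, c("Asthma", "Obesity"))
  expect_equal(sum(net$A), 3)
})

test_that("lexicographic ordering changes index maps but not statistics", {
  edges <- tibble::tibble(d = c("zeta", "zeta", "alpha"),
                          m = c("mB", "mA", "mB"))
  first <- association_network(edges)
  lexi <- association_network(edges, order = "lexicographic")
  expect_equal(first$diseases, c("zeta", "alpha"))
  expect_equal(lexi$diseases, c("alpha", "zeta"))
  expect_equal(glance(network_stats(first)), glance(network_stats(lexi)))
})

test_that("edge-list read/write round-trips the adjacency exactly", {
  set.seed(11)
  net <- random_net(6, 9, 0.3)
  # an edge list only carries connected entities; align labels before comparing
  keep_d <- rowSums(net$A) > 0
  keep_m <- colSums(net$A) > 0
  path <- withr::local_tempfile(fileext = ".tsv")
  write_association_edgelist(net, path)
  back <- suppressMessages(read_association_edgelist(path))
  expect_identical(back$A[net$diseases[keep_d], net$microbes[keep_m]],
                   net$A[keep_d, keep_m])
})

test_that("the reader skips comments, detects headers and signals bad input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "disease\tmicrobe", "d1\tm1", "d2\tm2"), path)
  net <- suppressMessages(read_association_edgelist(path))
  expect_equal(sum(net$A), 2)

  expect_error(read_association_edgelist(tempfile()),
               class = "ncpmd_missing_file")
  one_col <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("d1", "d2"), one_col)
  expect_error(suppressMessages(read_association_edgelist(one_col)),
               class = "ncpmd_bad_columns")
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("# nothing here", empty)
  expect_error(read_association_edgelist(empty),
               class = "ncpmd_empty_edgelist")
})

test_that("network_stats reports exact counts, means and histograms", {
  net <- toy_net(matrix(c(1L, 1L, 1L, 0L), 2, 2, byrow = TRUE))
  st <- network_stats(net)
  expect_equal(st$n_associations, 3)
  expect_equal(st$mean_microbe_degree, 1.5)
  expect_equal(st$mean_disease_degree, 1.5)
  expect_equal(sum(st$microbe_degree_histogram$count), st$n_microbes)
  expect_equal(sum(st$disease_degree_histogram$count), st$n_diseases)
})

test_that("degree-mean identities and row-permutation invariance hold", {
  set.seed(5)
  for (rep in 1:5) {
    edges <- tidy(random_net(5, 8, 0.35))
    net <- association_network(edges)
    st <- network_stats(net)
    expect_equal(st$mean_microbe_degree * st$n_microbes, st$n_associations)
    expect_equal(st$mean_disease_degree * st$n_diseases, st$n_associations)

    shuffled <- association_network(edges[sample(nrow(edges)), ])
    expect_equal(glance(network_stats(shuffled)), glance(st))
  }
})

test_that("symptom counts accept long triples and wide tables equivalently", {
  long <- symptom_profile(tibble::tibble(
    disease = c("d1", "d1", "d2"), symptom = c("s1", "s2", "s1"),
    count = c(2, 1, 1)
  ))
  expect_equal(unname(long$W), matrix(c(2, 1, 1, 0), 2, 2, byrow = TRUE))

  wide <- symptom_profile(data.frame(disease = c("d1", "d2"),
                                     s1 = c(2, 1), s2 = c(1, 0)))
  expect_equal(unname(wide$W), unname(long$W))

  path_long <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("d1\ts1\t2", "d1\ts2\t1", "d2\ts1\t1"), path_long)
  path_wide <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("disease\ts1\ts2", "d1\t2\t1", "d2\t1\t0"), path_wide)
  expect_equal(unname(read_symptom_counts(path_long)$W),
               unname(read_symptom_counts(path_wide)$W))
})

test_that("negative counts are rejected and zero rows retained with a note", {
  expect_error(symptom_profile(matrix(c(1, -1), 1, 2,
                                      dimnames = list("d1", c("s1", "s2")))),
               class = "ncpmd_negative_counts")
  expect_message(
    p <- symptom_profile(matrix(c(1, 0, 0, 0), 2, 2, byrow = TRUE,
                                dimnames = list(c("d1", "d2"), c("s1", "s2")))),
    "all-zero"
  )
  expect_equal(nrow(p$W), 2)
})

test_that("symptom similarity triples load as a symmetric masked matrix", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("d1\td2\t0.3", path)
  ss <- read_symptom_similarity(path)
  expect_equal(ss["d1", "d2"], 0.3)
  expect_equal(ss["d2", "d1"], 0.3)
  expect_equal(unname(diag(ss)), c(1, 1))
  expect_true(all(attr(ss, "presence")))

  empty <- withr::local_tempfile(fileext = ".tsv")
  file.create(empty)
  ss0 <- read_symptom_similarity(empty)
  expect_equal(nrow(ss0), 0)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("d1\td2\t1.7", bad)
  expect_error(read_symptom_similarity(bad), class = "ncpmd_bad_score")

  selfpair <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("d1\td1\t0.4", "d1\td2\t0.2"), selfpair)
  expect_warning(ssc <- read_symptom_similarity(selfpair),
                 class = "ncpmd_selfpair")
  expect_equal(ssc["d1", "d1"], 1)
})

test_that("ranked predictions exclude known pairs and respect top_k and ties", {
  net <- toy_net(matrix(c(1L, 0L, 0L, 0L), 1, 4))
  sc <- ncp_predict(net)
  sc$scores[1, ] <- c(0.9, 0.5, 0.7, 0.5)
  ranked <- rank_predictions(sc)
  cand <- dplyr::filter(ranked, !known)
  expect_equal(cand$microbe, c("m3", "m2", "m4")) # tie m2/m4 by label
  expect_equal(cand$rank, 1:3)
  expect_true(all(is.na(dplyr::filter(ranked, known)$rank)))

  top2 <- rank_predictions(sc, top_k = 2)
  expect_equal(nrow(dplyr::filter(top2, !known)), 2)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_ranked_predictions(sc, path, top_k = 2)
  lines <- readLines(path)
  expect_match(lines[1], "^#")
  expect_equal(length(lines), 2 + 3) # header x2, 2 candidates + 1 known
})
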