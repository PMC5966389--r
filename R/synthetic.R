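#' Specification for a synthetic microbe-disease benchmark
#'
#' A planted-partition bipartite model: diseases and microbes are divided
#' into `n_blocks` communities; within-community associations appear with
#' probability `p_in`, cross-community with `p_out < p_in`, giving the
#' scoring method a recoverable signal. Defaults match the scale of curated
#' genus-level association data: 20 diseases, 94 microbes, and association
#' probabilities chosen so the expected edge count is about 155 (mean
#' disease degree near 8, mean microbe degree near 1.7). Symptom profiles
#' cover a `symptom_coverage` fraction of diseases (default 0.65, about 13
#' of 20 diseases, mirroring the partial symptom coverage of real data) with
#' Poisson counts concentrated on block-specific symptom subsets.
#'
#' @param n_diseases,n_microbes Network dimensions.
#' @param n_blocks Number of disease-microbe communities.
#' @param p_in,p_out Within-/between-block association probabilities;
#'   requires `0 <= p_out < p_in <= 1` (equal values are allowed for null
#'   models via `allow_flat`).
#' @param symptom_coverage Fraction of diseases that receive a symptom
#'   profile, in `[0, 1]`.
#' @param n_symptoms Number of symptom terms.
#' @param symptom_signal In `[0, 1]`: concentration of a disease's symptom
#'   counts on its block's own symptoms. 1 = symptoms are fully
#'   block-specific; 0 = no block structure in symptoms.
#' @param seed Integer seed; identical spec + seed give identical output.
#' @param allow_flat Allow `p_in == p_out` (degenerate, for calibration
#'   checks).
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_diseases = 20, n_microbes = 94, n_blocks = 4,
                           p_in = 0.28, p_out = 0.017,
                           symptom_coverage = 0.65, n_symptoms = 40,
                           symptom_signal = 0.8, seed = 1,
                           allow_flat = FALSE) {
  if (p_out > p_in || (!allow_flat && p_out == p_in) ||
      p_out < 0 || p_in > 1) {
    abort("need 0 <= p_out < p_in <= 1", class = "ncpmd_bad_spec")
  }
  if (symptom_coverage < 0 || symptom_coverage > 1) {
    abort("symptom_coverage must lie in [0, 1]", class = "ncpmd_bad_spec")
  }
  structure(
    list(n_diseases = n_diseases, n_microbes = n_microbes,
         n_blocks = n_blocks, p_in = p_in, p_out = p_out,
         symptom_coverage = symptom_coverage, n_symptoms = n_symptoms,
         symptom_signal = symptom_signal, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# balanced block assignment for n items over n_blocks blocks
block_assign <- function(n, n_blocks) {
  sort(rep(seq_len(n_blocks), length.out = n))
}

#' Generate a synthetic association network
#'
#' Draws the bipartite adjacency from the planted-partition model of a
#' [synthetic_spec()]. Diseases and microbes keep their block labels as an
#' attribute; empty rows or columns are retained (some entities genuinely
#' have no or one association at these densities).
#'
#' @param spec A [synthetic_spec()].
#' @return An [association_network()] with a `blocks` attribute listing
#'   disease and microbe block memberships.
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  d_block <- block_assign(spec$n_diseases, spec$n_blocks)
  m_block <- block_assign(spec$n_microbes, spec$n_blocks)
  p <- matrix(spec$p_out, spec$n_diseases, spec$n_microbes)
  same <- outer(d_block, m_block, `==`)
  p[same] <- spec$p_in
  A <- withr::with_seed(spec$seed, {
    matrix(rbinom(length(p), 1L, as.vector(p)), nrow(p), ncol(p))
  })
  diseases <- sprintf("disease_%02d", seq_len(spec$n_diseases))
  microbes <- sprintf("microbe_%03d", seq_len(spec$n_microbes))
  dimnames(A) <- list(diseases, microbes)
  net <- structure(
    list(diseases = diseases, microbes = microbes, A = A,
         order = "first-appearance"),
    class = "association_network"
  )
  attr(net, "blocks") <- list(disease = d_block, microbe = m_block)
  net
}

#' Generate synthetic disease-symptom co-occurrence counts
#'
#' A `symptom_coverage` fraction of diseases (deterministically the first
#' ones of each block under the spec's seed) receive Poisson count vectors.
#' Symptoms are split evenly over blocks; a covered disease draws counts
#' with mean `3 * symptom_signal + 0.3` on its own block's symptoms and
#' `0.3 * (1 - symptom_signal)` elsewhere, so same-block diseases share
#' symptom mass and cross-block pairs do not.
#'
#' @param spec A [synthetic_spec()].
#' @param net The [generate_network()] result for the same spec (provides
#'   block memberships and labels).
#' @return A [symptom_profile()] over the covered diseases (possibly empty).
#' @export
generate_symptom_counts <- function(spec, net) {
  stopifnot(inherits(spec, "synthetic_spec"),
            inherits(net, "association_network"))
  blocks <- attr(net, "blocks")
  if (is.null(blocks)) abort("net must come from generate_network()")
  n_cov <- round(spec$symptom_coverage * spec$n_diseases)
  if (n_cov == 0 || spec$n_symptoms == 0) {
    W <- matrix(0, 0, spec$n_symptoms,
                dimnames = list(character(0),
                                sprintf("symptom_%02d", seq_len(spec$n_symptoms))))
    return(symptom_profile(W))
  }
  s_block <- block_assign(spec$n_symptoms, spec$n_blocks)
  covered <- withr::with_seed(spec$seed + 1L,
                              sort(sample.int(spec$n_diseases, n_cov)))
  lam_in <- 3 * spec$symptom_signal + 0.3
  lam_out <- 0.3 * (1 - spec$symptom_signal)
  lam <- matrix(lam_out, n_cov, spec$n_symptoms)
  same <- outer(blocks$disease[covered], s_block, `==`)
  lam[same] <- lam_in
  W <- withr::with_seed(spec$seed + 2L, {
    matrix(rpois(length(lam), as.vector(lam)), nrow(lam), ncol(lam))
  })
  dimnames(W) <- list(net$diseases[covered],
                      sprintf("symptom_%02d", seq_len(spec$n_symptoms)))
  suppressMessages(symptom_profile(W))
}

#' Generate a full synthetic benchmark (network + symptoms)
#'
#' @param spec A [synthetic_spec()].
#' @return List with `net` (association network) and `symptoms`
#'   (symptom profile, possibly empty).
#' @export
generate_benchmark <- function(spec) {
  net <- generate_network(spec)
  list(net = net, symptoms = generate_symptom_counts(spec, net))
}
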