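# Shared fixture builders for the suite.

# Small single-class cohort with optional planted effects.
small_cohort <- function(seed = 1L, n_genes = 5L, n_variants_per_gene = 60L,
                         planted = numeric(), prevalence = NULL) {
  args <- list(
    seed = seed, n_genes = n_genes,
    protein_length_range = c(150L, 250L),
    classes = c(enzyme = 1),
    planted_log_or = planted,
    n_variants_per_gene = n_variants_per_gene
  )
  if (!is.null(prevalence)) args$bernoulli_prev <- prevalence
  simulate_cohort(do.call(simulation_config, args))
}

# Independent permutation oracle for the two-sided Mann-Whitney test:
# enumerates every split of the pooled values, computing U from scratch by
# pairwise comparisons (not via rank sums).
mw_permutation_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  z <- c(x, y)
  u_pairwise <- function(xs, ys) {
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_pairwise(x, y)
  mu <- n1 * n2 / 2
  splits <- utils::combn(n1 + n2, n1)
  stats <- apply(splits, 2, function(ix) u_pairwise(z[ix], z[-ix]))
  mean(abs(stats - mu) >= abs(u_obs - mu) - 1e-9)
}

# Hand-built one-row residue feature table over a catalog.
feature_row <- function(on, catalog = feature_catalog(),
                        protein = "P1", pos = 1L, ref_aa = "A") {
  bits <- as.list(stats::setNames(integer(nrow(catalog)), catalog$id))
  bits[on] <- 1L
  cbind(data.frame(protein = protein, pos = pos, ref_aa = ref_aa,
                   unresolved = FALSE, stringsAsFactors = FALSE),
        as.data.frame(bits, check.names = FALSE))
}
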