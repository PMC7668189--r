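#' Parameter-recovery experiment
#'
#' Repeatedly simulates cohorts with a single planted per-feature log odds
#' ratio and checks that the burden analysis recovers it: with exactly one
#' nonzero coefficient the marginal 2x2 odds ratio equals the conditional
#' logistic coefficient, so the sample OR should land inside its own Woolf
#' 95 percent CI in about 95 percent of replicates. (With several nonzero
#' coefficients the collapsed OR is attenuated — non-collapsibility — which
#' is why the experiment plants one effect at a time.)
#'
#' @param n_seeds number of replicate cohorts.
#' @param n_variants total variants per cohort.
#' @param beta planted log odds ratio.
#' @param prevalence presence probability of the planted feature.
#' @param feature feature carrying the planted effect (a Bernoulli-type
#'   catalog feature).
#' @param base_seed first seed; replicate r uses `base_seed + r - 1`.
#' @return data frame per seed: `seed`, `or`, `ci_low`, `ci_high`,
#'   `covered` (CI contains `exp(beta)`), `p`.
#' @export
experiment_parameter_recovery <- function(n_seeds = 100, n_variants = 50000,
                                          beta = log(4), prevalence = 0.3,
                                          feature = "func_modular_domain",
                                          base_seed = 1L) {
  n_genes <- 10L
  target <- exp(beta)
  out <- vector("list", n_seeds)
  for (r in seq_len(n_seeds)) {
    cfg <- simulation_config(
      seed = base_seed + r - 1L,
      n_genes = n_genes,
      protein_length_range = c(400L, 500L),
      classes = c(enzyme = 1),
      bernoulli_prev = stats::setNames(prevalence, feature),
      planted_log_or = stats::setNames(beta, feature),
      n_variants_per_gene = as.integer(ceiling(n_variants / n_genes))
    )
    ch <- simulate_cohort(cfg)
    tab <- build_table(ch$variants, ch$residues, feature)
    or <- sample_or(tab)
    ci <- or_ci(tab)
    out[[r]] <- data.frame(seed = cfg$seed, or = or,
                           ci_low = ci[1], ci_high = ci[2],
                           covered = ci[1] <= target & target <= ci[2],
                           p = fisher_two_sided(tab))
  }
  do.call(rbind, out)
}

#' Null-calibration experiment
#'
#' Simulates cohorts with every planted log odds ratio at zero and collects
#' the uncorrected Fisher p value of every testable feature, plus whether
#' the derived association sets (at q < alpha, multiplier = number of tests
#' in the cohort) are empty. Under the null the fraction of p < 0.05 should
#' sit near 0.05 (slightly below: the exact test is conservative on
#' discrete tables), and the association sets should almost always be
#' empty.
#'
#' @param n_seeds number of replicate cohorts.
#' @param n_genes,n_variants_per_gene cohort size per replicate.
#' @param alpha significance level for the association sets.
#' @param base_seed first seed.
#' @return list: `p_values` (vector over all seeds and features),
#'   `frac_sig` (fraction with p < 0.05), `empty_assoc` (logical per
#'   seed), `n_tests`.
#' @export
experiment_null_calibration <- function(n_seeds = 25, n_genes = 20L,
                                        n_variants_per_gene = 100L,
                                        alpha = 0.05, base_seed = 1000L) {
  ps <- list(); empty <- logical(n_seeds)
  for (r in seq_len(n_seeds)) {
    cfg <- simulation_config(seed = base_seed + r - 1L, n_genes = n_genes,
                             protein_length_range = c(150L, 300L),
                             classes = c(enzyme = 1),
                             n_variants_per_gene = n_variants_per_gene)
    ch <- simulate_cohort(cfg)
    res <- run_burden(ch$variants, ch$residues, class_map = NULL,
                      catalog = cfg$catalog, config = burden_config())
    ps[[r]] <- res$p[!is.na(res$p)]
    assoc <- derive_associations(res, alpha)
    empty[r] <- !length(assoc[[ALL_GENES_GROUP]]$pathogenic) &&
      !length(assoc[[ALL_GENES_GROUP]]$population)
  }
  p_values <- unlist(ps)
  list(p_values = p_values, frac_sig = mean(p_values < 0.05),
       empty_assoc = empty, n_tests = length(p_values))
}

# planted effects used by the ensemble-ordering experiment: structural
# signal independent of the predictor scores
ordering_planted_betas <- function() {
  c(exp_core = log(2.5), exp_exposed = -log(2.5),
    aa_aromatic = log(1.6), aa_aliphatic = -log(1.7),
    bond_disulfide_inter = log(8), ptm_near_sumoylation = log(4),
    func_modular_domain = log(3), ss_strand = log(1.3))
}

#' Ensemble-ordering experiment
#'
#' Replicates the model comparison on synthetic cohorts where the
#' structural index carries signal independent of the (deliberately weak)
#' predictor scores: per seed, a cohort is simulated, association sets are
#' derived from its own burden analysis, per-variant indices are computed
#' in the all-genes and first-class contexts, and three ensembles (with
#' class index, with all-genes index, without) are trained and evaluated on
#' a common split. Reports per-seed MCCs and whether the index-bearing
#' model matches or beats the index-free one.
#'
#' @param n_seeds number of replicate cohorts.
#' @param n_genes,n_variants_per_gene cohort size per replicate.
#' @param n_trees trees per ensemble (kept modest; the published default of
#'   2,000 is unnecessary for the ordering question).
#' @param informative if `FALSE`, plants no effects so the index is pure
#'   noise (the null version of the experiment).
#' @param base_seed first seed.
#' @return data frame per seed: `seed`, `mcc_with_class`,
#'   `mcc_with_global`, `mcc_without`, `auc_with_class`, `auc_without`,
#'   `ordered` (with-class MCC >= without MCC).
#' @export
experiment_ensemble_ordering <- function(n_seeds = 25, n_genes = 30L,
                                         n_variants_per_gene = 150L,
                                         n_trees = 300L,
                                         informative = TRUE,
                                         base_seed = 2000L) {
  weak_scores <- list(
    sift = list(pathogenic = c(3.5, 4.5), benign = c(4.5, 3.5)),
    polyphen2 = list(pathogenic = c(4.5, 3.5), benign = c(3.5, 4.5)),
    cadd = list(pathogenic = c(shape = 5, rate = 0.3),
                benign = c(shape = 4, rate = 0.3))
  )
  out <- vector("list", n_seeds)
  for (r in seq_len(n_seeds)) {
    cfg <- simulation_config(
      seed = base_seed + r - 1L, n_genes = n_genes,
      protein_length_range = c(200L, 400L),
      classes = c(enzyme = 0.5, transporter = 0.4,
                  nucleic_acid_binding = 0.4),
      planted_log_or = if (informative) ordering_planted_betas() else
        numeric(),
      n_variants_per_gene = n_variants_per_gene,
      score_models = weak_scores
    )
    ch <- simulate_cohort(cfg)
    res <- run_burden(ch$variants, ch$residues, class_map = ch$classes,
                      catalog = cfg$catalog, config = burden_config())
    assoc <- derive_associations(res, 0.05)

    glob <- score_residues(ch$residues, assoc, ALL_GENES_GROUP, cfg$catalog)
    first_class <- ch$classes$class[match(ch$variants$gene,
                                          ch$classes$gene)]
    rkey <- paste(glob$protein, glob$pos)
    hit <- match(paste(ch$variants$protein, ch$variants$pos), rkey)
    dat <- ch$scores
    dat$p3dfi_global <- glob$index[hit]
    cls_idx <- rep(NA_integer_, nrow(dat))
    for (cl in unique(first_class)) {
      sc <- score_residues(ch$residues, assoc, cl, cfg$catalog)
      ix <- which(first_class == cl)
      cls_idx[ix] <- sc$index[hit[ix]]
    }
    dat$p3dfi_class <- cls_idx
    dat$label <- ifelse(dat$label == "pathogenic", "pathogenic", "benign")

    cmp <- compare_models(dat, ensemble_spec(n_trees = n_trees,
                                             seed = cfg$seed))
    gm <- function(model, col) cmp[cmp$model == model, col]
    out[[r]] <- data.frame(
      seed = cfg$seed,
      mcc_with_class = gm("with_class_p3dfi", "mcc"),
      mcc_with_global = gm("with_global_p3dfi", "mcc"),
      mcc_without = gm("without_p3dfi", "mcc"),
      auc_with_class = gm("with_class_p3dfi", "auc"),
      auc_without = gm("without_p3dfi", "auc"),
      ordered = gm("with_class_p3dfi", "mcc") >= gm("without_p3dfi", "mcc")
    )
  }
  do.call(rbind, out)
}
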