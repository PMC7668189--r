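#' Synthetic cohort configuration
#'
#' The generator is a stand-in for a structure-annotated variant cohort: the
#' source study used real variant and structure databases and states no
#' generative model, so every distributional choice here is a documented
#' synthetic default. Residue features are drawn conditionally independent
#' given the gene's class context — one secondary-structure class and one
#' exposure bin per residue (multinomial), Bernoulli presence for the bond,
#' PTM and functional features — and the physicochemical bits are derived
#' from the sampled reference amino acid (a pure function of it). Variant
#' labels are Bernoulli with `P(pathogenic | f) = plogis(beta0 + sum_j
#' beta_j f_j)`; the default baseline log-odds matches a roughly 1:5
#' pathogenic:population mix.
#'
#' @param seed integer seed; identical config + seed gives identical
#'   cohorts.
#' @param n_genes number of genes (one protein per gene).
#' @param protein_length_range integer pair, inclusive.
#' @param classes named numeric vector: per-gene membership probability per
#'   protein class (multi-membership; a gene ending up with no class is
#'   assigned one draw proportional to these probabilities).
#' @param ss_probs,exposure_probs,aa_freqs multinomial weights for the
#'   secondary-structure class, exposure bin and reference amino acid.
#' @param bernoulli_prev named per-feature presence probabilities for the
#'   Bernoulli features (bond, PTM site, PTM proximity, functional), or a
#'   feature-by-class matrix; a gene in several classes uses the average of
#'   its classes' columns.
#' @param planted_log_or named numeric vector (or feature-by-class matrix)
#'   of planted per-feature log odds ratios `beta_j`; features not named
#'   default to 0.
#' @param baseline_log_odds baseline `beta0`.
#' @param n_variants_per_gene variants simulated per gene.
#' @param score_models label-conditional score distributions: `sift` and
#'   `polyphen2` as Beta shape pairs per label, `cadd` as Gamma
#'   (shape, rate) per label.
#' @param fitness_slope,fitness_noise_sd slope `alpha` and noise SD `sigma`
#'   of the synthetic fitness model `fitness = -alpha * index + eps`.
#' @param catalog feature catalog.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(
    seed = 1L,
    n_genes = 50L,
    protein_length_range = c(200L, 600L),
    classes = c(enzyme = 0.45, kinase = 0.15, transporter = 0.15,
                nucleic_acid_binding = 0.20, receptor = 0.15,
                structural_protein = 0.10),
    ss_probs = c(ss_helix_alpha = 0.32, ss_helix_310 = 0.04,
                 ss_helix_pi = 0.006, ss_strand = 0.21, ss_bridge = 0.012,
                 ss_turn = 0.11, ss_bend = 0.08, ss_loop = 0.222),
    exposure_probs = c(exp_core = 0.13, exp_buried = 0.27,
                       exp_medium_buried = 0.22, exp_medium_exposed = 0.20,
                       exp_exposed = 0.18),
    aa_freqs = c(A = 0.083, R = 0.055, N = 0.040, D = 0.055, C = 0.014,
                 Q = 0.039, E = 0.067, G = 0.071, H = 0.023, I = 0.059,
                 L = 0.097, K = 0.058, M = 0.024, F = 0.039, P = 0.047,
                 S = 0.066, T = 0.053, W = 0.011, Y = 0.029, V = 0.069),
    bernoulli_prev = c(
      bond_hbond_intra = 0.45, bond_hbond_inter = 0.05,
      bond_salt_bridge_intra = 0.08, bond_salt_bridge_inter = 0.01,
      bond_disulfide_intra = 0.02, bond_disulfide_inter = 0.002,
      ptm_site_phosphorylation = 0.03, ptm_site_acetylation = 0.01,
      ptm_site_other = 0.01,
      ptm_near_phosphorylation = 0.15, ptm_near_sumoylation = 0.02,
      ptm_near_oglcnac = 0.02, ptm_near_methylation = 0.03,
      ptm_near_acetylation = 0.04, ptm_near_ubiquitination = 0.05,
      func_modular_domain = 0.45, func_modified_residue = 0.03,
      func_binding_region = 0.10, func_active_site = 0.01,
      func_ligand_binding = 0.03, func_signal_motif = 0.02),
    planted_log_or = numeric(),
    baseline_log_odds = log(1 / 5),
    n_variants_per_gene = 150L,
    score_models = list(
      sift = list(pathogenic = c(2, 8), benign = c(8, 2)),
      polyphen2 = list(pathogenic = c(8, 2), benign = c(2, 8)),
      cadd = list(pathogenic = c(shape = 6, rate = 0.25),
                  benign = c(shape = 3, rate = 1 / 3))),
    fitness_slope = 1,
    fitness_noise_sd = 1,
    catalog = feature_catalog()) {
  if (!length(classes)) stop("class list must be non-empty")
  chk_prob <- function(x, nm) {
    if (any(!is.finite(x)) || any(x < 0 | x > 1)) {
      stop(nm, " must contain probabilities in [0, 1]")
    }
  }
  chk_prob(classes, "classes")
  chk_prob(bernoulli_prev, "bernoulli_prev")
  if (any(protein_length_range < 1) ||
      protein_length_range[2] < protein_length_range[1]) {
    stop("protein_length_range must be an increasing pair of lengths >= 1")
  }
  if (n_genes < 1 || n_variants_per_gene < 1) {
    stop("n_genes and n_variants_per_gene must be >= 1")
  }
  if (fitness_noise_sd < 0) stop("fitness_noise_sd must be >= 0")
  structure(
    list(seed = as.integer(seed), n_genes = as.integer(n_genes),
         protein_length_range = as.integer(protein_length_range),
         classes = classes,
         ss_probs = ss_probs / sum(ss_probs),
         exposure_probs = exposure_probs / sum(exposure_probs),
         aa_freqs = aa_freqs / sum(aa_freqs),
         bernoulli_prev = bernoulli_prev,
         planted_log_or = planted_log_or,
         baseline_log_odds = baseline_log_odds,
         n_variants_per_gene = as.integer(n_variants_per_gene),
         score_models = score_models,
         fitness_slope = fitness_slope,
         fitness_noise_sd = fitness_noise_sd,
         catalog = catalog),
    class = "simulation_config"
  )
}

# Resolve a per-feature vector/matrix parameter for a gene's class set:
# a matrix (features x classes) is averaged over the member classes.
resolve_by_class <- function(param, member_classes, feature_ids) {
  out <- stats::setNames(numeric(length(feature_ids)), feature_ids)
  if (is.matrix(param)) {
    cls <- intersect(member_classes, colnames(param))
    if (length(cls)) {
      v <- rowMeans(param[, cls, drop = FALSE])
      out[intersect(names(v), feature_ids)] <-
        v[intersect(names(v), feature_ids)]
    }
  } else if (length(param)) {
    out[intersect(names(param), feature_ids)] <-
      param[intersect(names(param), feature_ids)]
  }
  out
}

#' Simulate a complete synthetic cohort
#'
#' Generates genes, per-residue feature vectors, labelled variants,
#' label-conditional predictor scores and index-linked fitness values with
#' known planted effects (see [simulation_config()] for the generative
#' model). The truth — the config and the planted association sets (the
#' features with positive / negative planted log odds ratio) — travels with
#' the cohort.
#'
#' @param config a [simulation_config()].
#' @return list of class `synthetic_cohort`: `residues` (feature table),
#'   `variants`, `classes` (gene-to-class long table), `scores`, `fitness`,
#'   `truth` (the config), `truth_associations`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  catalog <- config$catalog
  cls_names <- names(config$classes)

  genes <- sprintf("G%04d", seq_len(config$n_genes))
  lens <- sample(seq(config$protein_length_range[1],
                     config$protein_length_range[2]),
                 config$n_genes, replace = TRUE)

  # class membership (multi-membership; guarantee >= 1 class)
  memb <- matrix(
    stats::runif(config$n_genes * length(cls_names)) <
      rep(config$classes, each = config$n_genes),
    nrow = config$n_genes
  )
  for (i in which(rowSums(memb) == 0)) {
    memb[i, sample(length(cls_names), 1, prob = config$classes)] <- TRUE
  }
  classes <- do.call(rbind, lapply(seq_along(genes), function(i) {
    data.frame(gene = genes[i], class = cls_names[memb[i, ]],
               stringsAsFactors = FALSE)
  }))

  bern_ids <- names(config$bernoulli_prev)
  if (is.matrix(config$bernoulli_prev)) {
    bern_ids <- rownames(config$bernoulli_prev)
  }
  aa_letters <- names(config$aa_freqs)
  group_of <- aa_groups(aa_letters)   # list per letter

  res <- vector("list", config$n_genes)
  for (i in seq_along(genes)) {
    L <- lens[i]
    member <- cls_names[memb[i, ]]
    prev <- resolve_by_class(config$bernoulli_prev, member, bern_ids)
    aa <- sample(aa_letters, L, replace = TRUE, prob = config$aa_freqs)
    bits <- matrix(0L, nrow = L, ncol = nrow(catalog),
                   dimnames = list(NULL, catalog$id))
    ss <- sample(names(config$ss_probs), L, replace = TRUE,
                 prob = config$ss_probs)
    bits[cbind(seq_len(L), match(ss, catalog$id))] <- 1L
    expo <- sample(names(config$exposure_probs), L, replace = TRUE,
                   prob = config$exposure_probs)
    bits[cbind(seq_len(L), match(expo, catalog$id))] <- 1L
    for (k in seq_along(aa_letters)) {
      rows <- aa == aa_letters[k]
      if (any(rows)) {
        bits[rows, paste0("aa_", group_of[[k]])] <- 1L
      }
    }
    for (f in bern_ids) {
      if (f %in% catalog$id && prev[f] > 0) {
        bits[, f] <- as.integer(stats::runif(L) < prev[f])
      }
    }
    res[[i]] <- data.frame(protein = genes[i], pos = seq_len(L),
                           ref_aa = aa, unresolved = FALSE,
                           stringsAsFactors = FALSE)
    res[[i]] <- cbind(res[[i]], as.data.frame(bits))
  }
  residues <- do.call(rbind, res)
  rownames(residues) <- NULL

  # variants: uniform positions, logistic label model
  vrows <- vector("list", config$n_genes)
  gene_start <- cumsum(c(0, lens))[seq_along(genes)]
  for (i in seq_along(genes)) {
    member <- cls_names[memb[i, ]]
    beta <- resolve_by_class(config$planted_log_or, member, catalog$id)
    nv <- config$n_variants_per_gene
    pos <- sample.int(lens[i], nv, replace = TRUE)
    ridx <- gene_start[i] + pos
    eta <- config$baseline_log_odds +
      as.numeric(as.matrix(residues[ridx, catalog$id]) %*% beta)
    lab <- ifelse(stats::runif(nv) < stats::plogis(eta),
                  "pathogenic", "population")
    ref <- residues$ref_aa[ridx]
    alt <- vapply(ref, function(r) {
      sample(setdiff(names(config$aa_freqs), r), 1)
    }, character(1))
    vrows[[i]] <- data.frame(gene = genes[i], protein = genes[i],
                             pos = pos, ref_aa = ref, alt_aa = unname(alt),
                             label = lab, source = "synthetic",
                             stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, vrows)
  rownames(variants) <- NULL

  truth_assoc <- planted_associations(config)
  scores <- simulate_scores(variants, config$score_models,
                            seed = config$seed + 1L)
  fitness <- simulate_fitness(residues, truth_assoc,
                              fitness_slope = config$fitness_slope,
                              fitness_noise_sd = config$fitness_noise_sd,
                              seed = config$seed + 2L,
                              catalog = catalog)
  structure(
    list(residues = residues, variants = variants, classes = classes,
         scores = scores, fitness = fitness, truth = config,
         truth_associations = truth_assoc),
    class = "synthetic_cohort"
  )
}

#' Planted association sets of a configuration
#'
#' The ground-truth association table implied by the planted log odds
#' ratios: features with `beta_j > 0` form the pathogenic set, `beta_j < 0`
#' the population set, for every class and the all-genes pool.
#'
#' @param config a [simulation_config()].
#' @return an `association_table`.
#' @export
planted_associations <- function(config) {
  groups <- c(ALL_GENES_GROUP, names(config$classes))
  sets <- lapply(groups, function(g) {
    beta <- if (is.matrix(config$planted_log_or)) {
      resolve_by_class(config$planted_log_or,
                       if (g == ALL_GENES_GROUP) {
                         colnames(config$planted_log_or)
                       } else g,
                       config$catalog$id)
    } else {
      resolve_by_class(config$planted_log_or, g, config$catalog$id)
    }
    list(pathogenic = names(beta)[beta > 0],
         population = names(beta)[beta < 0])
  })
  association_table(stats::setNames(sets, groups), config$catalog)
}

#' Simulate label-conditional predictor scores
#'
#' SIFT-like and PolyPhen2-like scores are Beta-distributed in `[0, 1]`;
#' the CADD-like score is Gamma-distributed (unbounded positive). Each is
#' drawn conditional on the variant's label (population treated as benign
#' for score purposes).
#'
#' @param variants labelled variant table.
#' @param score_models see [simulation_config()].
#' @param seed integer seed.
#' @return data frame `gene`, `protein`, `pos`, `ref_aa`, `alt_aa`,
#'   `label`, `sift`, `polyphen2`, `cadd`.
#' @export
simulate_scores <- function(variants, score_models, seed = 1L) {
  if (any(!variants$label %in% c("pathogenic", "population", "benign"))) {
    stop("every variant must carry a label")
  }
  set.seed(seed)
  n <- nrow(variants)
  cond <- ifelse(variants$label == "pathogenic", "pathogenic", "benign")
  draw_beta <- function(model) {
    out <- numeric(n)
    for (lab in c("pathogenic", "benign")) {
      ix <- cond == lab
      par <- model[[lab]]
      out[ix] <- stats::rbeta(sum(ix), par[1], par[2])
    }
    out
  }
  out <- variants[, c("gene", "protein", "pos", "ref_aa", "alt_aa",
                      "label")]
  out$sift <- draw_beta(score_models$sift)
  out$polyphen2 <- draw_beta(score_models$polyphen2)
  cadd <- numeric(n)
  for (lab in c("pathogenic", "benign")) {
    ix <- cond == lab
    par <- score_models$cadd[[lab]]
    cadd[ix] <- stats::rgamma(sum(ix), shape = par[["shape"]],
                              rate = par[["rate"]])
  }
  out$cadd <- cadd
  rownames(out) <- NULL
  out
}

#' Simulate index-linked fitness scores
#'
#' `fitness_i = -alpha * index_i + eps_i`, with `eps ~ Normal(0, sigma^2)`
#' and the index computed against the supplied association table in the
#' all-genes context — a synthetic stand-in for mean per-residue saturation
#' mutagenesis readouts.
#'
#' @param residues residue feature table.
#' @param assoc an `association_table` providing the context.
#' @param fitness_slope slope `alpha`.
#' @param fitness_noise_sd noise SD `sigma`.
#' @param seed integer seed.
#' @param group context group used for the index.
#' @param catalog feature catalog.
#' @return data frame `protein`, `pos`, `index`, `fitness`.
#' @export
simulate_fitness <- function(residues, assoc, fitness_slope = 1,
                             fitness_noise_sd = 1, seed = 1L,
                             group = ALL_GENES_GROUP,
                             catalog = feature_catalog()) {
  set.seed(seed)
  sc <- score_residues(residues, assoc, group, catalog)
  eps <- stats::rnorm(nrow(sc), 0, fitness_noise_sd)
  data.frame(protein = sc$protein, pos = sc$pos, index = sc$index,
             fitness = -fitness_slope * sc$index + eps,
             stringsAsFactors = FALSE)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("<synthetic cohort> %d genes, %d residues, %d variants",
                     " (%d pathogenic / %d population)\n"),
              length(unique(x$residues$protein)), nrow(x$residues),
              nrow(x$variants), sum(x$variants$label == "pathogenic"),
              sum(x$variants$label == "population")))
  invisible(x)
}
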