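test_that("configuration validation rejects impossible settings", {
  expect_error(simulation_config(classes = numeric()), "non-empty")
  expect_error(simulation_config(classes = c(enzyme = 1.4)),
               "probabilities in")
  expect_error(simulation_config(protein_length_range = c(100L, 50L)),
               "increasing pair")
  expect_error(simulation_config(n_genes = 0), ">= 1")
  expect_error(simulation_config(fitness_noise_sd = -1), ">= 0")
  expect_error(simulation_config(
    bernoulli_prev = c(bond_hbond_intra = 2)), "probabilities in")
})

test_that("the same config and seed give identical cohorts and files", {
  cfg <- function() simulation_config(seed = 5, n_genes = 3,
                                      n_variants_per_gene = 30)
  c1 <- simulate_cohort(cfg()); c2 <- simulate_cohort(cfg())
  expect_identical(c1, c2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixture_files(c1, d1); write_fixture_files(c2, d2)
  for (f in c("variants.tsv", "residue_features.tsv", "classes.tsv",
              "scores.tsv", "fitness.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("cohort structure invariants hold", {
  ch <- small_cohort(seed = 51, n_genes = 6, n_variants_per_gene = 40)
  # every variant references an existing residue
  rkey <- paste(ch$residues$protein, ch$residues$pos)
  expect_true(all(paste(ch$variants$protein, ch$variants$pos) %in% rkey))
  # ref amino acid taken from the residue record; alt differs
  hit <- match(paste(ch$variants$protein, ch$variants$pos), rkey)
  expect_equal(ch$variants$ref_aa, ch$residues$ref_aa[hit])
  expect_true(all(ch$variants$ref_aa != ch$variants$alt_aa))
  # every gene has at least one class
  expect_true(all(unique(ch$variants$gene) %in% ch$classes$gene))
  # physicochemical bits are the pure function of the reference residue
  for (k in sample(nrow(ch$residues), 25)) {
    groups <- aa_groups(ch$residues$ref_aa[k])
    on <- paste0("aa_", groups)
    aa_cols <- paste0("aa_", names(aa_group_map()))
    expect_setequal(aa_cols[ch$residues[k, aa_cols] == 1L], on)
  }
  # exactly one secondary-structure class and one exposure bin per residue
  sscols <- feature_catalog()$id[1:8]
  expcols <- feature_catalog()$id[9:13]
  expect_true(all(rowSums(ch$residues[, sscols]) == 1L))
  expect_true(all(rowSums(ch$residues[, expcols]) == 1L))
})

test_that("a null cohort gives a sample OR compatible with one", {
  ch <- small_cohort(seed = 52, n_genes = 10, n_variants_per_gene = 500,
                     prevalence = c(func_modular_domain = 0.4))
  tab <- build_table(ch$variants, ch$residues, "func_modular_domain")
  ci <- or_ci(tab)
  expect_true(ci[1] <= 1 && 1 <= ci[2])
})

test_that("a planted fourfold effect is recovered by the burden analysis", {
  ch <- small_cohort(seed = 53, n_genes = 10, n_variants_per_gene = 5000,
                     planted = c(func_modular_domain = log(4)),
                     prevalence = c(func_modular_domain = 0.3))
  expect_equal(nrow(ch$variants), 50000)
  tab <- build_table(ch$variants, ch$residues, "func_modular_domain")
  or <- sample_or(tab)
  expect_gt(or, 3.5); expect_lt(or, 4.6)
  ci <- or_ci(tab)
  expect_true(ci[1] <= 4 && 4 <= ci[2])
})

test_that("score generator honours degenerate and null models", {
  v <- data.frame(gene = "G", protein = "G", pos = 1:2000, ref_aa = "A",
                  alt_aa = "C",
                  label = rep(c("pathogenic", "population"), 1000))
  # zero-variance separated means -> perfect separation, AUC 1
  sep <- simulate_scores(v, list(
    sift = list(pathogenic = c(1e6, 1), benign = c(1, 1e6)),
    polyphen2 = list(pathogenic = c(1e6, 1), benign = c(1, 1e6)),
    cadd = list(pathogenic = c(shape = 1e6, rate = 1e3),
                benign = c(shape = 1, rate = 1))), seed = 1)
  lab <- ifelse(sep$label == "pathogenic", "pathogenic", "benign")
  expect_equal(compute_metrics(lab, predict_label(sep$sift),
                               sep$sift)$auc, 1)
  # identical distributions -> chance AUC
  null <- simulate_scores(v, list(
    sift = list(pathogenic = c(2, 2), benign = c(2, 2)),
    polyphen2 = list(pathogenic = c(2, 2), benign = c(2, 2)),
    cadd = list(pathogenic = c(shape = 3, rate = 1),
                benign = c(shape = 3, rate = 1))), seed = 2)
  expect_equal(compute_metrics(lab, predict_label(null$sift),
                               null$sift)$auc, 0.5, tolerance = 0.08)
  expect_error(simulate_scores(transform(v, label = "odd"), NULL),
               "label")
})

test_that("Beta-model AUC matches the closed-form separation probability", {
  v <- data.frame(gene = "G", protein = "G", pos = 1:5000, ref_aa = "A",
                  alt_aa = "C",
                  label = rep(c("pathogenic", "population"), 2500))
  sc <- simulate_scores(v, list(
    sift = list(pathogenic = c(8, 2), benign = c(2, 8)),
    polyphen2 = list(pathogenic = c(8, 2), benign = c(2, 8)),
    cadd = list(pathogenic = c(shape = 6, rate = 0.25),
                benign = c(shape = 3, rate = 1 / 3))), seed = 3)
  lab <- ifelse(sc$label == "pathogenic", "pathogenic", "benign")
  emp <- compute_metrics(lab, predict_label(sc$sift), sc$sift)$auc
  # numeric-integration oracle for P(X_path > X_benign)
  closed <- stats::integrate(function(x) {
    stats::dbeta(x, 8, 2) * stats::pbeta(x, 2, 8)
  }, 0, 1, rel.tol = 1e-10)$value
  expect_equal(emp, closed, tolerance = 0.02)
})

test_that("noiseless fitness is a perfect line; a zero slope kills it", {
  ch <- small_cohort(seed = 54, n_genes = 4, n_variants_per_gene = 10,
                     planted = c(bond_hbond_intra = log(3),
                                 exp_core = log(2),
                                 aa_aliphatic = -log(2)))
  assoc <- planted_associations(ch$truth)
  sc <- score_residues(ch$residues, assoc, "all_genes")
  noiseless <- simulate_fitness(ch$residues, assoc, fitness_slope = 1,
                                fitness_noise_sd = 0, seed = 1)
  expect_equal(correlate_fitness(sc, noiseless)$r2, 1)
  flat <- simulate_fitness(ch$residues, assoc, fitness_slope = 0,
                           fitness_noise_sd = 1, seed = 2)
  expect_lt(correlate_fitness(sc, flat)$r2, 0.02)
})

test_that("planted association sets reflect the coefficient signs", {
  cfg <- simulation_config(planted_log_or = c(exp_core = 1.2,
                                              aa_aliphatic = -0.7))
  pa <- planted_associations(cfg)
  expect_equal(pa$all_genes$pathogenic, "exp_core")
  expect_equal(pa$all_genes$population, "aa_aliphatic")
  expect_true(all(c("all_genes", names(cfg$classes)) %in% names(pa)))
})

test_that("pathogenic variants carry larger indices when effects are planted", {
  # directional consistency, replicated over seeds
  for (s in 1:3) {
    ch <- small_cohort(seed = 60 + s, n_genes = 8,
                       n_variants_per_gene = 300,
                       planted = c(bond_hbond_intra = log(3),
                                   func_modular_domain = log(2.5),
                                   aa_aliphatic = -log(2)))
    assoc <- planted_associations(ch$truth)
    sc <- score_residues(ch$residues, assoc, "all_genes")
    hit <- match(paste(ch$variants$protein, ch$variants$pos),
                 paste(sc$protein, sc$pos))
    idx <- sc$index[hit]
    expect_gt(mean(idx[ch$variants$label == "pathogenic"]),
              mean(idx[ch$variants$label == "population"]))
  }
})
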