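test_that("build_table counts qualifying variants into the four cells", {
  cat40 <- feature_catalog()
  feats <- rbind(feature_row("func_modular_domain", pos = 1L),
                 feature_row(character(), pos = 2L))
  v <- data.frame(
    gene = "P1", protein = "P1",
    pos = c(1, 1, 2, 1, 2, 2),
    ref_aa = "A", alt_aa = c("C", "D", "E", "F", "G", "H"),
    label = c("pathogenic", "pathogenic", "pathogenic",
              "population", "population", "population"),
    stringsAsFactors = FALSE
  )
  tab <- build_table(v, feats, "func_modular_domain")
  expect_equal(unname(unlist(tab[c("a", "b", "c", "d")])), c(2, 1, 1, 2))
  expect_true(tab$testable)

  # benign-labelled validation variants are excluded (10-variant fixture)
  v10 <- v[c(1:6, 1:4), ]
  v10$alt_aa <- LETTERS[c(3:8, 10:13)]
  v10$label[7:10] <- "benign"
  t10 <- build_table(v10, feats, "func_modular_domain")
  expect_equal(unname(unlist(t10[c("a", "b", "c", "d")])), c(2, 1, 1, 2))

  # duplicates (same gene/pos/ref/alt from two sources) are counted once
  vdup <- rbind(v, v[1, ])
  tdup <- build_table(vdup, feats, "func_modular_domain")
  expect_equal(tdup$a, 2)

  # unresolved positions are excluded
  feats2 <- feats; feats2$unresolved[1] <- TRUE
  t2 <- build_table(v, feats2, "func_modular_domain")
  expect_equal(unname(unlist(t2[c("a", "b", "c", "d")])), c(0, 1, 0, 2))
  expect_false(t2$testable)
})

test_that("a gene in two classes is counted in both groups' tables", {
  feats <- rbind(feature_row("bond_hbond_intra", protein = "G1", pos = 1L),
                 feature_row(character(), protein = "G1", pos = 2L))
  v <- data.frame(gene = "G1", protein = "G1", pos = c(1, 2),
                  ref_aa = "A", alt_aa = c("C", "D"),
                  label = c("pathogenic", "population"),
                  stringsAsFactors = FALSE)
  cm <- data.frame(gene = "G1", class = c("kinase", "transporter"))
  for (grp in c("kinase", "transporter")) {
    tab <- build_table(v, feats, "bond_hbond_intra", grp, cm)
    expect_equal(unname(unlist(tab[c("a", "b", "c", "d")])), c(1, 0, 0, 1))
  }
})

test_that("fisher_two_sided reproduces enumerated exact values", {
  expect_equal(fisher_two_sided(c(10, 10, 10, 10)), 1.0)
  expect_equal(fisher_two_sided(c(5, 0, 0, 5)), 2 / 252)
  expect_equal(fisher_two_sided(c(2, 1, 1, 2)), 1.0)
  expect_error(fisher_two_sided(c(0, 0, 3, 4)), "untestable")
})

test_that("fisher_two_sided matches the reference implementation on a sweep", {
  # exhaustive over all margin-positive tables with total n <= 14
  for (n in 2:14) {
    grid <- expand.grid(a = 0:n, b = 0:n, c = 0:n)
    grid <- grid[grid$a + grid$b + grid$c <= n, ]
    grid$d <- n - grid$a - grid$b - grid$c
    ok <- (grid$a + grid$b) > 0 & (grid$c + grid$d) > 0 &
      (grid$a + grid$c) > 0 & (grid$b + grid$d) > 0
    grid <- grid[ok, ]
    for (i in seq_len(nrow(grid))) {
      tb <- as.numeric(grid[i, c("a", "b", "c", "d")])
      expect_equal(fisher_two_sided(tb),
                   stats::fisher.test(matrix(tb, 2, byrow = TRUE))$p.value,
                   tolerance = 1e-12)
    }
  }
})

test_that("sample OR uses sentinels for zero products", {
  expect_equal(sample_or(c(10, 10, 10, 10)), 1.0)
  expect_equal(sample_or(c(5, 1, 1, 5)), 25.0)
  expect_equal(sample_or(c(0, 7, 3, 11)), 0.0)
  expect_equal(sample_or(c(4, 0, 3, 2)), Inf)
  expect_true(is.nan(sample_or(c(0, 5, 0, 7))))
})

test_that("Woolf interval matches the closed form and handles zero cells", {
  ci <- or_ci(c(10, 10, 10, 10))
  z <- stats::qnorm(0.975)
  expect_equal(ci, exp(c(-1, 1) * z * sqrt(0.4)))
  expect_equal(prod(ci), 1, tolerance = 1e-12)  # symmetric about 1 on log

  # zero cell: finite interval containing the +0.5-corrected OR
  ci0 <- or_ci(c(5, 0, 2, 9))
  or_corr <- (5.5 * 9.5) / (0.5 * 2.5)
  expect_true(all(is.finite(ci0)))
  expect_true(ci0[1] < or_corr && or_corr < ci0[2])
})

test_that("multiplicative correction multiplies and caps", {
  expect_equal(correct_p(1e-5, 1000), 0.01)
  expect_equal(correct_p(0.5, 1000), 1.0)
  expect_equal(correct_p(0, 1000), 0)
  expect_error(correct_p(1.2, 10), "p must lie")
  # monotone non-decreasing in p
  p <- sort(stats::runif(50))
  expect_false(is.unsorted(correct_p(p, 37)))
})

test_that("relative risk follows its definition", {
  expect_equal(relative_risk(c(10, 10, 10, 10)), 1.0)
  expect_equal(relative_risk(c(8, 2, 2, 8)), 4.0)
  expect_equal(relative_risk(c(0, 3, 5, 7)), 0)
  expect_true(is.nan(relative_risk(c(0, 0, 3, 4))))
})

test_that("transposing variant rows inverts OR and preserves p", {
  set.seed(11)
  for (i in 1:25) {
    tb <- stats::rpois(4, lambda = 8) + c(1, 0, 0, 1)
    sw <- tb[c(3, 4, 1, 2)]  # swap pathogenic/population rows
    expect_equal(fisher_two_sided(tb), fisher_two_sided(sw),
                 tolerance = 1e-12)
    expect_equal(sample_or(sw), 1 / sample_or(tb))
  }
})

test_that("swapping feature and not-feature inverts the OR", {
  set.seed(12)
  for (i in 1:25) {
    tb <- stats::rpois(4, lambda = 10) + 1
    sw <- tb[c(2, 1, 4, 3)]
    expect_equal(sample_or(sw), 1 / sample_or(tb))
    expect_equal(fisher_two_sided(tb), fisher_two_sided(sw),
                 tolerance = 1e-12)
  }
})

test_that("RR approximates OR when the pathogenic outcome is rare", {
  # OR/RR = (1 - p0)/(1 - p1) with p1 = a/(a+c), p0 = b/(b+d): with the
  # pathogenic fraction <= 10% in both feature strata the two agree within
  # 25%
  set.seed(13)
  for (i in 1:40) {
    c_ <- sample(200:2000, 1); d <- sample(800:8000, 1)
    a <- sample.int(max(2, round(c_ / 9)), 1)
    b <- sample.int(max(2, round(d / 9)), 1)
    or <- sample_or(c(a, b, c_, d)); rr <- relative_risk(c(a, b, c_, d))
    expect_lt(abs(rr - or) / or, 0.25)
  }
})

test_that("run_burden flags planted signal and degenerate features", {
  ch <- small_cohort(
    seed = 21, n_genes = 8L, n_variants_per_gene = 400L,
    planted = c(bond_disulfide_inter = log(19)),
    prevalence = c(bond_disulfide_inter = 0.05, bond_hbond_intra = 0.4)
  )
  res <- run_burden(ch$variants, ch$residues)
  assoc <- derive_associations(res, 0.05)
  expect_true("bond_disulfide_inter" %in%
                assoc[["all_genes"]]$pathogenic)
  expect_length(intersect(assoc[["all_genes"]]$pathogenic,
                          assoc[["all_genes"]]$population), 0)

  # a feature absent from every residue is untestable, association none
  row <- res[res$feature == "func_active_site", ]
  expect_true(is.na(row$p))
  expect_equal(row$association, "none")

  # serialized ordering is (group, feature-in-catalog-order)
  expect_equal(res$group, sort(res$group))
})

test_that("fixed-multiplier correction reproduces the historical q rule", {
  ch <- small_cohort(seed = 22, n_genes = 3L, n_variants_per_gene = 80L)
  res <- run_burden(ch$variants, ch$residues,
                    config = burden_config(correction = "fixed", m = 1000))
  tested <- !is.na(res$p)
  expect_equal(res$q[tested], pmin(1, res$p[tested] * 1000))
  expect_true(all(res$q[tested] >= res$p[tested]))
})

test_that("association tables validate disjointness and round-trip as TSV", {
  expect_error(association_table(list(
    g = list(pathogenic = "exp_core", population = "exp_core"))),
    "disjoint")
  expect_error(association_table(list(
    g = list(pathogenic = "no_such_feature", population = character()))),
    "unknown feature")
  at <- association_table(list(
    g1 = list(pathogenic = c("exp_core", "aa_aromatic"),
              population = "exp_exposed"),
    g2 = list(pathogenic = character(), population = "aa_aliphatic")))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_associations(at, f)
  back <- read_associations(f)
  expect_setequal(back$g1$pathogenic, at$g1$pathogenic)
  expect_setequal(back$g2$population, at$g2$population)
})
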