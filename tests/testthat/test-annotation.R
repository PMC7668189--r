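test_that("parse_dssp reads fixed-column residue records", {
  # header-only file -> no residues
  f <- withr::local_tempfile(fileext = ".dssp")
  write_dssp_fixture(data.frame(resnum = integer(), chain = character(),
                                aa = character(), ss = character(),
                                asa = numeric()), f)
  expect_equal(nrow(parse_dssp(f)), 0L)

  st <- data.frame(resnum = c(10L, 11L, 12L), chain = "A",
                   aa = c("M", "K", "W"), ss = c("I", "-", "E"),
                   asa = c(129, 0, 42), x = c(0, 3.8, 7.6), y = 0, z = 0)
  write_dssp_fixture(st, f)
  got <- parse_dssp(f)
  expect_equal(got$ss, c("I", "-", "E"))     # pi-helix retained
  expect_equal(got$asa, c(129, 0, 42))
  expect_equal(got$resnum, 10:12)
  expect_equal(got$x, c(0, 3.8, 7.6))
})

test_that("parse_dssp skips chain breaks and rejects malformed fields", {
  f <- withr::local_tempfile(fileext = ".dssp")
  st <- data.frame(resnum = 1:2, chain = "A", aa = c("A", "G"),
                   ss = "-", asa = c(10, 20))
  write_dssp_fixture(st, f)
  lines <- readLines(f)
  brk <- "    2        !              0   0    0"
  writeLines(append(lines, brk, after = length(lines) - 1L), f)
  expect_equal(nrow(parse_dssp(f)), 2L)

  bad <- lines
  substr(bad[length(bad)], 35, 38) <- "  xy"
  writeLines(bad, f)
  expect_error(parse_dssp(f), "ACC field at DSSP line")
  expect_error(parse_dssp(withr::local_tempfile(lines = "not dssp")),
               "no residue header")
})

test_that("RSA is ASA over MaxASA, capped at one", {
  expect_equal(compute_rsa(0, "F"), 0)
  expect_equal(compute_rsa(max_asa_table()[["W"]], "W"), 1)
  expect_equal(compute_rsa(64.5, "A"), 0.5)   # MaxASA(Ala) = 129
  expect_equal(compute_rsa(1e5, "G"), 1)      # cap
  expect_error(compute_rsa(10, "Z"), "missing from MaxASA")
  expect_error(compute_rsa(-1, "A"), "non-negative")
})

test_that("exposure bins are half-open and partition [0,1]", {
  expect_equal(bin_exposure(0.03), "core")
  expect_equal(bin_exposure(0.05), "buried")      # left edge inclusive
  expect_equal(bin_exposure(0.80), "exposed")
  expect_equal(bin_exposure(c(0, 0.25, 0.5, 0.75, 1)),
               c("core", "medium_buried", "medium_exposed", "exposed",
                 "exposed"))
  expect_error(bin_exposure(1.2), "rsa")
  # partition property: every grid point maps to exactly one bin
  grid <- seq(0, 1, by = 0.001)
  bins <- bin_exposure(grid)
  expect_true(all(bins %in% c("core", "buried", "medium_buried",
                              "medium_exposed", "exposed")))
  expect_false(is.unsorted(match(bins, c("core", "buried", "medium_buried",
                                         "medium_exposed", "exposed"))))
})

test_that("ptm_proximity uses a strict cutoff and handles degenerate sites", {
  tgt <- list(x = 0, y = 0, z = 0)
  none <- ptm_proximity(tgt, NULL)
  expect_true(all(!none$flag))
  expect_true(all(is.na(none$min_dist)))

  self <- data.frame(x = 0, y = 0, z = 0, ptm_type = "phosphorylation")
  got <- ptm_proximity(tgt, self)
  expect_true(got$flag[got$ptm_type == "phosphorylation"])
  expect_equal(got$min_dist[got$ptm_type == "phosphorylation"], 0)

  near <- data.frame(x = 0, y = 0, z = 9.9, ptm_type = "sumoylation")
  at <- data.frame(x = 0, y = 0, z = 10.0, ptm_type = "sumoylation")
  expect_true(ptm_proximity(tgt, near)$flag[2])
  expect_false(ptm_proximity(tgt, at)$flag[2])   # strict <

  # missing coordinates: skipped with warning; all skipped -> NA flag
  missing <- data.frame(x = NA_real_, y = 0, z = 0,
                        ptm_type = "methylation")
  expect_warning(got <- ptm_proximity(tgt, missing), "skipped")
  expect_true(is.na(got$flag[got$ptm_type == "methylation"]))
})

test_that("ptm_proximity flags are monotone in the cutoff", {
  set.seed(42)
  tgt <- list(x = 0, y = 0, z = 0)
  for (i in 1:20) {
    sites <- data.frame(x = stats::rnorm(6, sd = 6),
                        y = stats::rnorm(6, sd = 6),
                        z = stats::rnorm(6, sd = 6),
                        ptm_type = sample(c("phosphorylation", "sumoylation",
                                            "acetylation"), 6, TRUE))
    f5 <- ptm_proximity(tgt, sites, annotation_config(ptm_cutoff = 5))
    f15 <- ptm_proximity(tgt, sites, annotation_config(ptm_cutoff = 15))
    raised <- !is.na(f5$flag) & f5$flag
    expect_true(all(f15$flag[raised]))   # raising cutoff never clears
  }
})

test_that("consolidate applies derivation rules and flags unresolved", {
  # F1704-like: core beta-strand aromatic residue in a domain, near a
  # phosphosite, with an input H-bond flag
  st <- data.frame(aa = "F", ss = "E", asa = 0)
  ptm <- data.frame(ptm_type = "phosphorylation", flag = TRUE,
                    min_dist = 6.8)
  v <- consolidate("BRCA1", 1704, "F", struct = st, ptm = ptm,
                   region_features = "modular_domain",
                   bond_features = "hbond_intra")
  on <- names(v$bits)[v$bits == 1]
  expect_setequal(on, c("ss_strand", "exp_core", "aa_aromatic",
                        "bond_hbond_intra", "ptm_near_phosphorylation",
                        "func_modular_domain"))
  expect_false(v$unresolved)

  # glycine without structure: only the physicochemical bit is derivable
  g <- consolidate("P2", 5, "G")
  expect_true(g$unresolved)
  expect_equal(names(g$bits)[g$bits == 1], "aa_special")

  # two structures, exposed in one and core in the other: both bits under
  # the any-structure rule
  st2 <- data.frame(aa = c("L", "L"), ss = c("H", "H"), asa = c(0, 180))
  v2 <- consolidate("P3", 9, "L", struct = st2)
  expect_equal(unname(v2$bits[c("exp_core", "exp_exposed")]), c(1L, 1L))
})

test_that("residue feature TSV round-trips identically", {
  ch <- small_cohort(seed = 3, n_genes = 2, n_variants_per_gene = 10)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_residue_features(ch$residues, f)
  back <- read_residue_features(f)
  expect_equal(back, ch$residues)
  expect_error(read_residue_features(withr::local_tempfile(
    lines = "protein\tpos\n")), "lacks catalog column")
})

test_that("annotate_residues reconciles numbering through the mapping", {
  ex <- brct_example_inputs()
  feats <- annotate_residues(c(brct_synthetic = ex$dssp), ex$mapping,
                             ex$ptm_sites, ex$regions, ex$bonds)
  expect_equal(nrow(feats), 17L)                  # one row per mapped pos
  expect_equal(sort(feats$pos), 1696:1712)
  f1704 <- feats[feats$pos == 1704, ]
  expect_equal(f1704$ref_aa, "F")
  expect_equal(f1704$exp_core, 1L)
  expect_equal(f1704$ptm_near_phosphorylation, 1L)
  # the phosphosite itself carries the site bit
  s1708 <- feats[feats$pos == 1708, ]
  expect_equal(s1708$ptm_site_phosphorylation, 1L)
  expect_equal(s1708$ptm_near_phosphorylation, 1L)  # distance 0 to itself
})

test_that("PDB reader recovers the written Cα coordinates", {
  ex <- brct_example_inputs()
  ca <- read_pdb_ca(ex$pdb)
  expect_equal(nrow(ca), 17L)
  expect_equal(ca$aa[ca$resnum == 1704], "F")
  d <- parse_dssp(ex$dssp)
  expect_equal(ca$x, d$x, tolerance = 0.06)  # DSSP columns are coarser
})
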