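#' Synthetic BRCT-domain worked-example fixtures
#'
#' Writes a miniature, fully synthetic structure fixture modelled on the
#' BRCT region of BRCA1 around residue F1704: a DSSP-format file and a
#' Cα-only PDB file for positions 1696-1712 of chain X, a SIFTS-like
#' residue mapping, a phosphosite record at position 1708, a modular-domain
#' region record, and PDBsum-style bond flags. The geometry is an idealised
#' helical Cα trace whose pitch is chosen so that the Cα of position 1704
#' lies 6.8 angstrom from the Cα of the phosphosite four residues away; the
#' F1704 line carries an accessible surface area of 0 and a beta-strand
#' structure code. These are the printed properties of the real residue,
#' embedded in invented coordinates: the files are synthetic stand-ins, not
#' database extracts.
#'
#' @param dir directory to write into (created if needed).
#' @return named list of file paths and input tables (`dssp`, `pdb`,
#'   `mapping`, `ptm_sites`, `regions`, `bonds`).
#' @export
brct_example_inputs <- function(dir = tempfile("brct")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pos <- 1696:1712
  aa <- c("L", "V", "L", "G", "R", "T", "M", "Y", "F", "A", "K", "E",
          "S", "G", "I", "D", "E")
  ss <- c("-", "-", "T", "T", "-", "E", "E", "E", "E", "E", "E", "-",
          "-", "S", "-", "-", "-")
  asa <- c(60, 35, 12, 40, 110, 8, 3, 15, 0, 20, 95, 120,
           80, 55, 10, 70, 130)
  # helical trace with the pitch solving |CA(1704) - CA(1708)| = 6.8 A
  rise <- sqrt(6.8^2 - (2 * 2.3 * sin(200 * pi / 180))^2) / 4
  trace <- helix_ca_trace(length(pos), rise = rise)
  st <- data.frame(resnum = pos, chain = "X", aa = aa, ss = ss, asa = asa,
                   trace, stringsAsFactors = FALSE)

  dssp_path <- file.path(dir, "brct_synthetic.dssp")
  write_dssp_fixture(st, dssp_path, pdb_id = "synt")
  pdb_path <- file.path(dir, "brct_synthetic.pdb")
  write_pdb_fixture(st, pdb_path, pdb_id = "synt")

  protein <- "BRCA1"
  mapping <- data.frame(pdb_id = "brct_synthetic", chain = "X",
                        pdb_resnum = pos, uniprot_acc = protein,
                        uniprot_pos = pos, stringsAsFactors = FALSE)
  ptm_sites <- data.frame(protein = protein, pos = 1708L,
                          ptm_type = "phosphorylation",
                          stringsAsFactors = FALSE)
  regions <- data.frame(protein = protein, start = 1646L, end = 1736L,
                        category = "modular_domain",
                        stringsAsFactors = FALSE)
  bonds <- data.frame(protein = protein,
                      pos = c(1700L, 1704L),
                      bond = c("salt_bridge_intra", "hbond_intra"),
                      stringsAsFactors = FALSE)
  list(dssp = dssp_path, pdb = pdb_path, mapping = mapping,
       ptm_sites = ptm_sites, regions = regions, bonds = bonds,
       protein = protein)
}

#' Pathogenic/population association sets of the nucleic-acid-binding class
#'
#' A reconstruction of the class-level association sets used in the F1704
#' worked example, shipped as
#' `extdata/associations_nucleic_acid_binding_reconstruction.tsv`. The
#' members follow the published class-level statements: core and buried
#' exposure, aromatic and special residues, beta-strand and (for this
#' class) alpha-helical context, hydrogen-bond-forming sites,
#' phosphosite proximity and the functional annotations are
#' pathogenic-associated; the solvent-exposed bins and the
#' aliphatic/neutral groups are population-associated. It is a
#' reconstruction — the full class table is not printed in the source
#' material — and is versioned with the catalog.
#'
#' @return an `association_table` with the single group
#'   `nucleic_acid_binding`.
#' @export
nucleic_acid_binding_associations <- function() {
  path <- system.file("extdata",
                      "associations_nucleic_acid_binding_reconstruction.tsv",
                      package = "p3dfi", mustWork = TRUE)
  read_associations(path)
}

#' Run the F1704 worked example
#'
#' Builds the synthetic BRCT fixtures, runs the full annotation pipeline
#' (DSSP parsing, residue mapping, PTM spatial proximity, region and bond
#' flags, consolidation) and scores position 1704 against the
#' nucleic-acid-binding association sets. With the default catalog the
#' residue carries six pathogenic-associated features (modular domain,
#' core exposure, beta-strand context, aromatic residue, intramolecular
#' hydrogen bond, phosphosite proximity) and no population-associated
#' feature, so the index is 6.
#'
#' @param catalog feature catalog.
#' @param config an [annotation_config()].
#' @return list with the annotated `features` table, the F1704
#'   `vector` row, the `score` (a `p3dfi_score`), and the fixture `inputs`.
#' @export
brct_worked_example <- function(catalog = feature_catalog(),
                                config = annotation_config()) {
  inputs <- brct_example_inputs()
  features <- annotate_residues(
    dssp = c(brct_synthetic = inputs$dssp),
    mapping = inputs$mapping, ptm_sites = inputs$ptm_sites,
    regions = inputs$regions, bonds = inputs$bonds,
    catalog = catalog, config = config
  )
  assoc <- nucleic_acid_binding_associations()
  row <- features[features$pos == 1704L, , drop = FALSE]
  bits <- stats::setNames(as.integer(row[1, catalog$id]), catalog$id)
  vec <- structure(
    list(protein = row$protein, pos = row$pos, ref_aa = row$ref_aa,
         bits = bits, unresolved = row$unresolved, provenance = NULL),
    class = "residue_feature_vector"
  )
  score <- compute_p3dfi(vec, assoc, "nucleic_acid_binding", catalog)
  list(features = features, vector = vec, score = score, inputs = inputs)
}
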