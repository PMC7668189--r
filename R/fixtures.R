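#' Write a DSSP-format fixture file
#'
#' Emits a syntactically valid classic DSSP output file (header block plus
#' fixed-column residue lines, including the trailing Cα coordinate
#' columns) from a structure-residue table. Intended for fixtures and
#' round-trip tests of [parse_dssp()].
#'
#' @param residues data frame with `resnum`, `chain`, `aa`, `ss`, `asa` and
#'   optionally `x`, `y`, `z`.
#' @param path output file path.
#' @param pdb_id identifier written into the header.
#' @return `path`, invisibly.
#' @export
write_dssp_fixture <- function(residues, path, pdb_id = "XXXX") {
  hdr <- c(
    "==== Secondary Structure Definition by the program DSSP, CMBI version ====",
    "REFERENCE  SYNTHETIC FIXTURE",
    sprintf("HEADER     SYNTHETIC STRUCTURE                     01-JAN-00   %s", pdb_id),
    sprintf("%5d%3d%3d%3d%3d TOTAL NUMBER OF RESIDUES, NUMBER OF CHAINS, NUMBER OF SS BRIDGES(TOTAL,INTRACHAIN,INTERCHAIN)",
            nrow(residues), length(unique(residues$chain)), 0L, 0L, 0L),
    paste0("  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N",
           "    N-H-->O    O-->H-N    TCO  KAPPA ALPHA  PHI   PSI",
           "    X-CA   Y-CA   Z-CA")
  )
  has_xyz <- all(c("x", "y", "z") %in% names(residues))
  lines <- vapply(seq_len(nrow(residues)), function(i) {
    r <- residues[i, ]
    sprintf("%5d%5d %1s %1s  %1s%17s%4d%77s%7.1f%7.1f%7.1f",
            i, r$resnum, substr(r$chain, 1, 1), r$aa, r$ss, "",
            as.integer(round(r$asa)), "",
            if (has_xyz) r$x else 0, if (has_xyz) r$y else 0,
            if (has_xyz) r$z else 0)
  }, character(1))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Write a Cα-only PDB-format fixture file
#'
#' @param residues data frame with `resnum`, `chain`, `aa` (one-letter),
#'   `x`, `y`, `z`.
#' @param path output file path.
#' @param pdb_id identifier written into the HEADER record.
#' @return `path`, invisibly.
#' @export
write_pdb_fixture <- function(residues, path, pdb_id = "XXXX") {
  hdr <- sprintf("HEADER    SYNTHETIC STRUCTURE                     01-JAN-00   %s",
                 pdb_id)
  lines <- vapply(seq_len(nrow(residues)), function(i) {
    r <- residues[i, ]
    sprintf("ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, bio3d::aa123(r$aa), substr(r$chain, 1, 1), r$resnum,
            r$x, r$y, r$z)
  }, character(1))
  writeLines(c(hdr, lines, "END"), path)
  invisible(path)
}

# idealised helical CA trace (rise/radius/turn give consecutive CA ~3.8 A)
helix_ca_trace <- function(n, rise = 1.5, radius = 2.3, turn_deg = 100) {
  t <- (seq_len(n) - 1) * turn_deg * pi / 180
  data.frame(x = radius * cos(t), y = radius * sin(t),
             z = rise * (seq_len(n) - 1))
}

#' Write a synthetic cohort to disk
#'
#' Emits `variants.tsv`, `residue_features.tsv`, `classes.tsv`,
#' `scores.tsv`, `fitness.tsv`, a miniature DSSP and Cα-only PDB fixture
#' pair under `fixtures/` (derived from the first residues of the first
#' gene, with ASA values consistent with the residues' exposure bins), and
#' a `manifest.json`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @param fixture_len residues used for the miniature structure fixtures.
#' @return named character vector of written paths (the manifest), invisibly.
#' @export
write_fixture_files <- function(cohort, dir, fixture_len = 25L) {
  dir.create(file.path(dir, "fixtures"), recursive = TRUE,
             showWarnings = FALSE)
  tsv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  manifest <- c(
    variants = tsv(cohort$variants, "variants.tsv"),
    residue_features = tsv(cohort$residues, "residue_features.tsv"),
    classes = tsv(cohort$classes, "classes.tsv"),
    scores = tsv(cohort$scores, "scores.tsv"),
    fitness = tsv(cohort$fitness, "fitness.tsv")
  )

  if (nrow(cohort$residues)) {
    g1 <- cohort$residues[cohort$residues$protein ==
                            cohort$residues$protein[1], , drop = FALSE]
    g1 <- g1[seq_len(min(fixture_len, nrow(g1))), , drop = FALSE]
    ss_cols <- names(SS_FEATURE)
    ss <- apply(g1[, unname(SS_FEATURE), drop = FALSE], 1, function(b) {
      hit <- which(b == 1L)
      if (length(hit)) ss_cols[hit[1]] else "-"
    })
    # mid-bin RSA consistent with the exposure bit
    rsa_mid <- c(exp_core = 0.02, exp_buried = 0.15, exp_medium_buried = 0.37,
                 exp_medium_exposed = 0.62, exp_exposed = 0.85)
    expo <- apply(g1[, names(rsa_mid), drop = FALSE], 1, function(b) {
      hit <- which(b == 1L)
      if (length(hit)) names(rsa_mid)[hit[1]] else "exp_buried"
    })
    asa <- round(rsa_mid[expo] * max_asa_table()[g1$ref_aa])
    trace <- helix_ca_trace(nrow(g1))
    st <- data.frame(resnum = g1$pos, chain = "A", aa = g1$ref_aa, ss = ss,
                     asa = unname(asa), trace, stringsAsFactors = FALSE)
    pid <- tolower(g1$protein[1])
    manifest["dssp_fixture"] <- file.path(dir, "fixtures",
                                          paste0(pid, ".dssp"))
    write_dssp_fixture(st, manifest[["dssp_fixture"]], pdb_id = pid)
    manifest["pdb_fixture"] <- file.path(dir, "fixtures",
                                         paste0(pid, ".pdb"))
    write_pdb_fixture(st, manifest[["pdb_fixture"]], pdb_id = pid)
  }

  manifest["manifest"] <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(files = as.list(basename(manifest[names(manifest) != "manifest"])),
         n_variants = nrow(cohort$variants),
         n_residues = nrow(cohort$residues),
         seed = cohort$truth$seed),
    manifest[["manifest"]], auto_unbox = TRUE, pretty = TRUE
  )
  invisible(manifest)
}

#' Read a written cohort back from disk
#'
#' Inverse of [write_fixture_files()] for the tabular components (the truth
#' config and structure fixtures are not round-tripped).
#'
#' @param dir directory written by [write_fixture_files()].
#' @param catalog feature catalog.
#' @return list with `residues`, `variants`, `classes`, `scores`,
#'   `fitness`.
#' @export
read_cohort <- function(dir, catalog = feature_catalog()) {
  rd <- function(name) {
    utils::read.table(file.path(dir, name), sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE)
  }
  list(
    residues = read_residue_features(file.path(dir, "residue_features.tsv"),
                                     catalog),
    variants = rd("variants.tsv"),
    classes = rd("classes.tsv"),
    scores = rd("scores.tsv"),
    fitness = rd("fitness.tsv")
  )
}
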