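#' The default 40-feature 3D feature catalog
#'
#' Binary residue-level features in seven categories: secondary structure
#' (the eight DSSP classes), solvent exposure (five relative-accessibility
#' bins), physicochemical class of the reference amino acid, bond
#' participation (hydrogen bond, salt bridge, disulfide; each split into
#' intra- and inter-molecular), PTM site type, spatial proximity (< 10
#' angstrom by default) to PTM sites of six types, and UniProt-style
#' functional annotations. The exact identities of several entries are a
#' documented reconstruction (catalog version "v1"): the source material for
#' this catalog prints the category structure and a subset of the feature
#' names, so the remaining names were chosen to complete each category with
#' its standard members. The catalog is an ordinary data frame and fully
#' configurable; every downstream function takes a `catalog` argument.
#'
#' @param version catalog version string; only `"v1"` is shipped.
#' @return data frame with columns `id`, `label`, `category` and attribute
#'   `catalog_version`. Row order fixes the feature-vector index.
#' @export
#' @examples
#' cat40 <- feature_catalog()
#' nrow(cat40)          # 40
#' table(cat40$category)
feature_catalog <- function(version = "v1") {
  if (!identical(version, "v1")) {
    stop("unknown catalog version: ", version)
  }
  def <- rbind(
    c("ss_helix_alpha",    "Alpha-helix (H)",               "secondary_structure"),
    c("ss_helix_310",      "3-10 helix (G)",                "secondary_structure"),
    c("ss_helix_pi",       "Pi-helix (I)",                  "secondary_structure"),
    c("ss_strand",         "Beta-strand (E)",               "secondary_structure"),
    c("ss_bridge",         "Beta-bridge (B)",               "secondary_structure"),
    c("ss_turn",           "Hydrogen-bonded turn (T)",      "secondary_structure"),
    c("ss_bend",           "Bend (S)",                      "secondary_structure"),
    c("ss_loop",           "Loop / irregular (-)",          "secondary_structure"),
    c("exp_core",          "Core (RSA < 5%)",               "exposure"),
    c("exp_buried",        "Buried (5% <= RSA < 25%)",      "exposure"),
    c("exp_medium_buried", "Medium-buried (25% <= RSA < 50%)", "exposure"),
    c("exp_medium_exposed","Medium-exposed (50% <= RSA < 75%)", "exposure"),
    c("exp_exposed",       "Exposed (RSA >= 75%)",          "exposure"),
    c("aa_aliphatic",      "Aliphatic residue",             "physicochemical"),
    c("aa_aromatic",       "Aromatic residue",              "physicochemical"),
    c("aa_charged",        "Charged residue",               "physicochemical"),
    c("aa_neutral",        "Neutral residue",               "physicochemical"),
    c("aa_polar",          "Polar residue",                 "physicochemical"),
    c("aa_special",        "Special residue (C/G/P)",       "physicochemical"),
    c("bond_hbond_intra",  "Hydrogen bond (intra-chain)",   "bond"),
    c("bond_hbond_inter",  "Hydrogen bond (inter-chain)",   "bond"),
    c("bond_salt_bridge_intra", "Salt bridge (intra-chain)", "bond"),
    c("bond_salt_bridge_inter", "Salt bridge (inter-chain)", "bond"),
    c("bond_disulfide_intra",   "Disulfide bond (intra-chain)", "bond"),
    c("bond_disulfide_inter",   "Disulfide bond (inter-chain)", "bond"),
    c("ptm_site_phosphorylation", "Phosphorylation site",   "ptm_site"),
    c("ptm_site_acetylation",     "Acetylation site",       "ptm_site"),
    c("ptm_site_other",           "Other PTM site",         "ptm_site"),
    c("ptm_near_phosphorylation", "Near phosphorylation site", "ptm_proximity"),
    c("ptm_near_sumoylation",     "Near SUMOylation site",     "ptm_proximity"),
    c("ptm_near_oglcnac",         "Near O-GlcNAc site",        "ptm_proximity"),
    c("ptm_near_methylation",     "Near methylation site",     "ptm_proximity"),
    c("ptm_near_acetylation",     "Near acetylation site",     "ptm_proximity"),
    c("ptm_near_ubiquitination",  "Near ubiquitination site",  "ptm_proximity"),
    c("func_modular_domain",  "Modular domain",            "functional"),
    c("func_modified_residue","Modified residue",          "functional"),
    c("func_binding_region",  "Functional/binding region", "functional"),
    c("func_active_site",     "Active site",               "functional"),
    c("func_ligand_binding",  "Ligand-binding site",       "functional"),
    c("func_signal_motif",    "Signal/targeting motif",    "functional")
  )
  out <- data.frame(
    id = def[, 1], label = def[, 2], category = def[, 3],
    stringsAsFactors = FALSE
  )
  stopifnot(nrow(out) == 40L, !anyDuplicated(out$id))
  attr(out, "catalog_version") <- version
  out
}

#' Names of the seven feature categories
#' @return character vector of category ids in catalog order.
#' @export
feature_categories <- function() {
  c("secondary_structure", "exposure", "physicochemical", "bond",
    "ptm_site", "ptm_proximity", "functional")
}

# PTM types recognised by default; `other` pools the rarer PhosphoSitePlus
# classes into the third ptm_site feature.
PTM_TYPES <- c("phosphorylation", "sumoylation", "oglcnac",
               "methylation", "acetylation", "ubiquitination")

#' Default amino-acid physicochemical group map
#'
#' `special` (C, G, P) and `aromatic` (F, W, Y) memberships are fixed by the
#' catalog definition; the remaining groups are an editable default that
#' partitions the other fourteen residues.
#'
#' @return named list mapping group id (without the `aa_` prefix) to a
#'   character vector of one-letter residue codes.
#' @export
aa_group_map <- function() {
  list(
    aliphatic = c("I", "L", "M", "V"),
    aromatic  = c("F", "W", "Y"),
    charged   = c("D", "E", "K", "R"),
    neutral   = c("A", "S", "T"),
    polar     = c("H", "N", "Q"),
    special   = c("C", "G", "P")
  )
}

#' Physicochemical groups of a reference amino acid
#'
#' Pure function of the one-letter code. Errors on any letter outside the
#' standard 20-residue alphabet.
#'
#' @param aa one-letter amino-acid code (vectorised).
#' @param map group membership map, as [aa_group_map()].
#' @return for a single `aa`, a character vector of group ids; for several, a
#'   list of such vectors.
#' @export
#' @examples
#' aa_groups("C")  # "special"
#' aa_groups("W")  # "aromatic"
aa_groups <- function(aa, map = aa_group_map()) {
  aa <- toupper(aa)
  valid <- unique(unlist(map, use.names = FALSE))
  bad <- setdiff(aa, valid)
  if (length(bad)) {
    stop("nonstandard amino-acid code(s): ", paste(bad, collapse = ", "))
  }
  one <- function(x) names(map)[vapply(map, function(g) x %in% g, logical(1))]
  if (length(aa) == 1L) one(aa) else lapply(aa, one)
}

#' Theoretical maximum accessible surface areas (square angstrom)
#'
#' The theoretical MaxASA normalisation of Tien et al. (2013), used to turn a
#' DSSP accessible surface area into a relative solvent accessibility.
#' Replaceable: every RSA computation takes a `table` argument.
#'
#' @return named numeric vector over the 20 one-letter codes.
#' @export
max_asa_table <- function() {
  c(A = 129, R = 274, N = 195, D = 193, C = 167,
    Q = 225, E = 223, G = 104, H = 224, I = 197,
    L = 201, K = 236, M = 224, F = 240, P = 159,
    S = 155, T = 172, W = 285, Y = 263, V = 174)
}

#' Annotation configuration
#'
#' @param exposure_breaks strictly increasing RSA bin edges in (0,1); the
#'   five bins are `[0,e1) [e1,e2) [e2,e3) [e3,e4) [e4,1]`.
#' @param ptm_cutoff PTM proximity cutoff in angstrom (strict `<`).
#' @param distance one of `"ca"` (Cα–Cα, default) or `"min"` (minimum
#'   heavy-atom, if full coordinates are supplied).
#' @param max_asa MaxASA normalisation table.
#' @param aa_map physicochemical group map.
#' @param consolidation rule across multiple mapped structures; only
#'   `"any"` (feature present if present in at least one structure) is
#'   implemented.
#' @return list of class `annotation_config`.
#' @export
annotation_config <- function(exposure_breaks = c(0.05, 0.25, 0.50, 0.75),
                              ptm_cutoff = 10,
                              distance = c("ca", "min"),
                              max_asa = max_asa_table(),
                              aa_map = aa_group_map(),
                              consolidation = "any") {
  distance <- match.arg(distance)
  if (length(exposure_breaks) != 4L || any(diff(exposure_breaks) <= 0) ||
      any(exposure_breaks <= 0) || any(exposure_breaks >= 1)) {
    stop("exposure_breaks must be 4 strictly increasing values in (0,1)")
  }
  if (!is.numeric(ptm_cutoff) || ptm_cutoff <= 0) {
    stop("ptm_cutoff must be positive")
  }
  if (!identical(consolidation, "any")) {
    stop("unsupported consolidation rule: ", consolidation)
  }
  structure(
    list(exposure_breaks = exposure_breaks, ptm_cutoff = ptm_cutoff,
         distance = distance, max_asa = max_asa, aa_map = aa_map,
         consolidation = consolidation),
    class = "annotation_config"
  )
}
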