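#' Parse a DSSP output file
#'
#' Reads the fixed-column residue block of a classic DSSP output file (the
#' text format produced by DSSP 2.x/3.x). One record is returned per residue
#' line; chain-break lines (`!` in the amino-acid column) are skipped; a
#' blank secondary-structure column is mapped to `"-"`; lowercase amino-acid
#' letters (DSSP's convention for SS-bonded cysteines) are mapped to `C`.
#' Cα coordinates are read from the trailing X-CA/Y-CA/Z-CA columns when the
#' line is long enough, otherwise set to `NA`.
#'
#' @param file path to a DSSP output file.
#' @return data frame with columns `resnum`, `icode`, `chain`, `aa`, `ss`,
#'   `asa`, `x`, `y`, `z`.
#' @export
parse_dssp <- function(file) {
  lines <- readLines(file, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (!length(hdr)) stop("not a DSSP output file (no residue header): ", file)
  body <- lines[seq.int(hdr[1] + 1L, length.out = length(lines) - hdr[1])]
  body <- body[nzchar(trimws(body))]
  empty <- data.frame(resnum = integer(), icode = character(),
                      chain = character(), aa = character(),
                      ss = character(), asa = numeric(),
                      x = numeric(), y = numeric(), z = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(body)) return(empty)

  aa <- substr(body, 14, 14)
  keep <- aa != "!"
  body <- body[keep]
  aa <- aa[keep]
  if (!length(body)) return(empty)

  num_field <- function(txt, what, lineno) {
    out <- suppressWarnings(as.numeric(trimws(txt)))
    bad <- which(is.na(out) & nzchar(trimws(txt)))
    if (length(bad)) {
      stop(sprintf("malformed %s field at DSSP line %d", what, lineno[bad[1]]))
    }
    out
  }
  lineno <- hdr[1] + which(keep)
  resnum <- num_field(substr(body, 6, 10), "residue-number", lineno)
  if (anyNA(resnum)) {
    stop(sprintf("malformed residue-number field at DSSP line %d",
                 lineno[which(is.na(resnum))[1]]))
  }
  asa <- num_field(substr(body, 35, 38), "ACC", lineno)
  if (anyNA(asa) || any(asa < 0)) {
    stop(sprintf("malformed ACC field at DSSP line %d",
                 lineno[which(is.na(asa) | asa < 0)[1]]))
  }
  ss <- substr(body, 17, 17)
  ss[ss == " "] <- "-"
  bad_ss <- !ss %in% c("H", "G", "I", "E", "B", "T", "S", "-")
  if (any(bad_ss)) {
    stop(sprintf("unknown structure code '%s' at DSSP line %d",
                 ss[bad_ss][1], lineno[bad_ss][1]))
  }
  aa[aa %in% letters] <- "C"
  coord <- function(lo, hi) {
    txt <- ifelse(nchar(body) >= hi, substr(body, lo, hi), "")
    suppressWarnings(as.numeric(trimws(txt)))
  }
  data.frame(
    resnum = as.integer(resnum),
    icode = trimws(substr(body, 11, 11)),
    chain = substr(body, 12, 12),
    aa = aa, ss = ss, asa = asa,
    x = coord(116, 122), y = coord(123, 129), z = coord(130, 136),
    stringsAsFactors = FALSE
  )
}

#' Read Cα coordinates from a PDB coordinate file
#'
#' Thin wrapper over [bio3d::read.pdb()] restricted to `ATOM` Cα records.
#'
#' @param file path to a PDB-format file.
#' @return data frame with columns `chain`, `resnum`, `aa` (one-letter),
#'   `x`, `y`, `z`.
#' @export
read_pdb_ca <- function(file) {
  pdb <- bio3d::read.pdb(file, verbose = FALSE)
  sel <- bio3d::atom.select(pdb, "calpha", verbose = FALSE)
  at <- pdb$atom[sel$atom, , drop = FALSE]
  data.frame(
    chain = at$chain,
    resnum = as.integer(at$resno),
    aa = unname(bio3d::aa321(at$resid)),
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  )
}

#' Relative solvent accessibility
#'
#' `RSA = min(1, ASA / MaxASA(aa))`, with MaxASA from a theoretical
#' normalisation table ([max_asa_table()] by default).
#'
#' @param asa accessible surface area in square angstrom (vectorised).
#' @param aa one-letter residue code (recycled against `asa`).
#' @param table MaxASA normalisation table.
#' @return RSA fraction in `[0, 1]`.
#' @export
compute_rsa <- function(asa, aa, table = max_asa_table()) {
  aa <- toupper(aa)
  if (any(!aa %in% names(table))) {
    stop("residue letter(s) missing from MaxASA table: ",
         paste(unique(aa[!aa %in% names(table)]), collapse = ", "))
  }
  if (any(asa < 0)) stop("ASA must be non-negative")
  pmin(1, asa / unname(table[aa]))
}

EXPOSURE_BINS <- c("core", "buried", "medium_buried", "medium_exposed",
                   "exposed")

#' Bin a relative solvent accessibility into an exposure category
#'
#' Five half-open bins `[lo, hi)` over `[0, 1]`; with the default edges:
#' core (< 5%), buried (5-25%), medium-buried (25-50%), medium-exposed
#' (50-75%), exposed (>= 75%).
#'
#' @param rsa RSA fraction(s) in `[0, 1]`.
#' @param config an [annotation_config()].
#' @return character vector of exposure categories.
#' @export
bin_exposure <- function(rsa, config = annotation_config()) {
  if (any(rsa < 0 | rsa > 1)) stop("rsa must lie in [0, 1]")
  idx <- findInterval(rsa, c(0, config$exposure_breaks, 1),
                      rightmost.closed = TRUE)
  EXPOSURE_BINS[idx]
}

#' Spatial proximity of a residue to PTM sites
#'
#' For each PTM type, reports whether the target residue lies strictly
#' within the configured cutoff (default 10 angstrom, Cα–Cα) of any site of
#' that type, and the minimum distance. A site lacking coordinates is
#' skipped with a warning; if every site of a type is skipped the type gets
#' an `NA` flag (no structural evidence). The target being itself a PTM site
#' yields distance 0.
#'
#' @param target list or one-row data frame with Cα coordinates `x`,`y`,`z`.
#' @param sites data frame of PTM-site residues with `x`, `y`, `z`,
#'   `ptm_type`.
#' @param config an [annotation_config()].
#' @param types PTM types to report on.
#' @return data frame with one row per type: `ptm_type`, `flag`, `min_dist`.
#' @export
ptm_proximity <- function(target, sites, config = annotation_config(),
                          types = PTM_TYPES) {
  out <- data.frame(ptm_type = types, flag = FALSE, min_dist = NA_real_,
                    stringsAsFactors = FALSE)
  if (is.null(sites) || !nrow(sites)) return(out)
  ok <- stats::complete.cases(sites[, c("x", "y", "z")])
  if (any(!ok)) {
    warning(sum(!ok), " PTM site(s) skipped: missing coordinates")
  }
  for (i in seq_along(types)) {
    si <- sites[sites$ptm_type == types[i], , drop = FALSE]
    if (!nrow(si)) next
    oki <- stats::complete.cases(si[, c("x", "y", "z")])
    if (!any(oki)) {              # sites exist but none with evidence
      out$flag[i] <- NA
      next
    }
    si <- si[oki, , drop = FALSE]
    d <- sqrt((si$x - target$x)^2 + (si$y - target$y)^2 +
                (si$z - target$z)^2)
    out$min_dist[i] <- min(d)
    out$flag[i] <- min(d) < config$ptm_cutoff
  }
  out
}

# DSSP code -> catalog feature id
SS_FEATURE <- c(H = "ss_helix_alpha", G = "ss_helix_310", I = "ss_helix_pi",
                E = "ss_strand", B = "ss_bridge", T = "ss_turn",
                S = "ss_bend", "-" = "ss_loop")

#' Consolidate evidence for one protein position into a feature vector
#'
#' Applies the derivation rule of every catalog feature under the
#' "present in at least one mapped structure" consolidation rule.
#' Physicochemical bits are a pure function of the reference amino acid and
#' functional bits need no structural evidence; secondary-structure,
#' exposure, bond and PTM-proximity bits require at least one mapped
#' structure residue — with none, the record is flagged `unresolved` (such
#' positions are excluded from burden analysis).
#'
#' @param protein protein (UniProt-style) identifier.
#' @param pos 1-based UniProt position.
#' @param ref_aa reference amino acid (one-letter).
#' @param struct data frame of mapped structure residues (`aa`, `ss`, `asa`,
#'   optionally `pdb_id`, `chain`, `resnum`), possibly empty.
#' @param ptm per-type proximity results as returned by [ptm_proximity()],
#'   or `NULL`.
#' @param ptm_site_types character vector of PTM types for which this
#'   position is itself a site.
#' @param region_features character vector of functional feature ids (or
#'   bare category names without the `func_` prefix) covering this position.
#' @param bond_features character vector of bond feature ids (or bare names
#'   without the `bond_` prefix); these arrive as input flags.
#' @param catalog feature catalog.
#' @param config an [annotation_config()].
#' @return list of class `residue_feature_vector` with `protein`, `pos`,
#'   `ref_aa`, `bits` (named 0/1 integer vector of length `nrow(catalog)`),
#'   `unresolved`, `provenance`.
#' @export
consolidate <- function(protein, pos, ref_aa,
                        struct = NULL, ptm = NULL,
                        ptm_site_types = character(),
                        region_features = character(),
                        bond_features = character(),
                        catalog = feature_catalog(),
                        config = annotation_config()) {
  bits <- stats::setNames(integer(nrow(catalog)), catalog$id)
  set_bit <- function(ids) {
    ids <- ids[ids %in% names(bits)]
    bits[ids] <<- 1L
  }
  qualify <- function(x, prefix) {
    ifelse(startsWith(x, prefix), x, paste0(prefix, x))
  }

  set_bit(paste0("aa_", aa_groups(ref_aa, config$aa_map)))
  set_bit(qualify(region_features, "func_"))
  if (length(ptm_site_types)) {
    mapped <- ifelse(ptm_site_types %in% c("phosphorylation", "acetylation"),
                     ptm_site_types, "other")
    set_bit(paste0("ptm_site_", mapped))
  }

  unresolved <- is.null(struct) || !nrow(struct)
  if (!unresolved) {
    set_bit(unname(SS_FEATURE[struct$ss]))
    rsa <- compute_rsa(struct$asa, struct$aa, config$max_asa)
    set_bit(paste0("exp_", bin_exposure(rsa, config)))
    set_bit(qualify(bond_features, "bond_"))
    if (!is.null(ptm) && nrow(ptm)) {
      near <- ptm$ptm_type[!is.na(ptm$flag) & ptm$flag]
      set_bit(paste0("ptm_near_", near))
    }
  }

  structure(
    list(protein = protein, pos = as.integer(pos), ref_aa = ref_aa,
         bits = bits, unresolved = unresolved,
         provenance = if (unresolved) NULL else struct),
    class = "residue_feature_vector"
  )
}

#' @export
print.residue_feature_vector <- function(x, ...) {
  cat(sprintf("<residue %s %s%d>%s %d/%d features set\n",
              x$protein, x$ref_aa, x$pos,
              if (x$unresolved) " [unresolved]" else "",
              sum(x$bits), length(x$bits)))
  on <- names(x$bits)[x$bits == 1L]
  if (length(on)) cat(" ", paste(on, collapse = ", "), "\n")
  invisible(x)
}

#' Annotate all mapped positions of a set of structures
#'
#' Driver over [consolidate()]: parses DSSP files, reconciles author
#' numbering to UniProt positions through the mapping table, computes PTM
#' spatial proximity within each structure chain, and consolidates evidence
#' across structures per UniProt position.
#'
#' @param dssp named list of parsed DSSP tables (names = pdb ids), or a
#'   character vector of DSSP file paths (names default to basenames).
#' @param mapping data frame `pdb_id`, `chain`, `pdb_resnum`, `uniprot_acc`,
#'   `uniprot_pos` (SIFTS-like residue mapping).
#' @param ptm_sites data frame `protein`, `pos`, `ptm_type`, or `NULL`.
#' @param regions data frame `protein`, `start`, `end`, `category`, or
#'   `NULL`.
#' @param bonds data frame `protein`, `pos`, `bond` (bond feature id or bare
#'   name), or `NULL`.
#' @param catalog feature catalog.
#' @param config an [annotation_config()].
#' @return residue feature table: one row per annotated UniProt position
#'   with columns `protein`, `pos`, `ref_aa`, `unresolved`, then one 0/1
#'   column per catalog feature.
#' @export
annotate_residues <- function(dssp, mapping, ptm_sites = NULL,
                              regions = NULL, bonds = NULL,
                              catalog = feature_catalog(),
                              config = annotation_config()) {
  if (is.character(dssp)) {
    nm <- if (is.null(names(dssp))) {
      sub("\\.dssp$", "", basename(dssp))
    } else names(dssp)
    dssp <- stats::setNames(lapply(dssp, parse_dssp), nm)
  }
  need <- c("pdb_id", "chain", "pdb_resnum", "uniprot_acc", "uniprot_pos")
  if (!all(need %in% names(mapping))) {
    stop("mapping must have columns: ", paste(need, collapse = ", "))
  }

  # per-structure tables joined to UniProt coordinates
  evid <- list(); ptm_evid <- list()
  for (pid in names(dssp)) {
    dt <- dssp[[pid]]
    mp <- mapping[mapping$pdb_id == pid, , drop = FALSE]
    if (!nrow(dt) || !nrow(mp)) next
    key <- paste(dt$chain, dt$resnum)
    mkey <- paste(mp$chain, mp$pdb_resnum)
    hit <- match(key, mkey)
    ok <- !is.na(hit)
    st <- cbind(dt[ok, , drop = FALSE],
                protein = mp$uniprot_acc[hit[ok]],
                upos = mp$uniprot_pos[hit[ok]],
                pdb_id = pid, stringsAsFactors = FALSE)
    evid[[pid]] <- st
    # PTM proximity within each chain of this structure
    if (!is.null(ptm_sites) && nrow(ptm_sites)) {
      for (ch in unique(st$chain)) {
        stc <- st[st$chain == ch, , drop = FALSE]
        skey <- paste(ptm_sites$protein, ptm_sites$pos)
        here <- match(paste(stc$protein, stc$upos), skey)
        site_rows <- which(!is.na(here))
        if (!length(site_rows)) next
        site_tab <- data.frame(
          x = stc$x[site_rows], y = stc$y[site_rows], z = stc$z[site_rows],
          ptm_type = ptm_sites$ptm_type[here[site_rows]],
          stringsAsFactors = FALSE
        )
        for (i in seq_len(nrow(stc))) {
          pr <- ptm_proximity(stc[i, ], site_tab, config)
          near <- pr$ptm_type[!is.na(pr$flag) & pr$flag]
          if (length(near)) {
            ptm_evid[[length(ptm_evid) + 1L]] <- data.frame(
              protein = stc$protein[i], upos = stc$upos[i],
              ptm_type = near, stringsAsFactors = FALSE
            )
          }
        }
      }
    }
  }
  evid <- if (length(evid)) do.call(rbind, evid) else NULL
  ptm_evid <- if (length(ptm_evid)) do.call(rbind, ptm_evid) else NULL
  if (is.null(evid) || !nrow(evid)) {
    stop("no structure residue maps to a UniProt position")
  }

  keys <- unique(evid[, c("protein", "upos")])
  keys <- keys[order(keys$protein, keys$upos), , drop = FALSE]
  rows <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    p <- keys$protein[i]; u <- keys$upos[i]
    st <- evid[evid$protein == p & evid$upos == u, , drop = FALSE]
    ref <- st$aa[1]
    near <- if (is.null(ptm_evid)) character() else
      unique(ptm_evid$ptm_type[ptm_evid$protein == p & ptm_evid$upos == u])
    ptm_res <- data.frame(ptm_type = near,
                          flag = rep(TRUE, length(near)),
                          min_dist = rep(NA_real_, length(near)),
                          stringsAsFactors = FALSE)
    site_types <- if (is.null(ptm_sites)) character() else
      ptm_sites$ptm_type[ptm_sites$protein == p & ptm_sites$pos == u]
    reg <- if (is.null(regions)) character() else
      regions$category[regions$protein == p & regions$start <= u &
                         regions$end >= u]
    bnd <- if (is.null(bonds)) character() else
      bonds$bond[bonds$protein == p & bonds$pos == u]
    v <- consolidate(p, u, ref, struct = st, ptm = ptm_res,
                     ptm_site_types = site_types, region_features = reg,
                     bond_features = bnd, catalog = catalog, config = config)
    rows[[i]] <- c(list(protein = p, pos = as.integer(u), ref_aa = ref,
                        unresolved = v$unresolved), as.list(v$bits))
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write / read a residue feature table as TSV
#'
#' Columns: `protein`, `pos`, `ref_aa`, `unresolved`, then one 0/1 column
#' per catalog feature, in catalog order.
#'
#' @param features residue feature table.
#' @param path file path.
#' @rdname residue_features_io
#' @export
write_residue_features <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @param catalog feature catalog the table must conform to.
#' @rdname residue_features_io
#' @export
read_residue_features <- function(path, catalog = feature_catalog()) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(catalog$id, names(out))
  if (length(missing)) {
    stop("feature table lacks catalog column(s): ",
         paste(missing, collapse = ", "))
  }
  out
}
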