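#' Burden-analysis configuration
#'
#' @param alpha significance level on the corrected q value (default 0.05).
#' @param correction multiple-testing multiplier rule: `"n_tests"` (default;
#'   the number of testable feature-by-group tables actually run) or
#'   `"fixed"` with `m` set, which reproduces the historical convention of a
#'   fixed multiplier (e.g. 1,000 = 40 features x 25 groups).
#' @param m fixed multiplier when `correction = "fixed"`.
#' @param or_estimate `"sample"` (ad/bc, default) or `"cmle"` (conditional
#'   maximum likelihood, via [stats::fisher.test()]) — the latter is meant
#'   for cross-checks.
#' @return list of class `burden_config`.
#' @export
burden_config <- function(alpha = 0.05,
                          correction = c("n_tests", "fixed"),
                          m = 1000,
                          or_estimate = c("sample", "cmle")) {
  correction <- match.arg(correction)
  or_estimate <- match.arg(or_estimate)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)")
  }
  if (correction == "fixed" && (!is.numeric(m) || m < 1)) {
    stop("fixed correction needs m >= 1")
  }
  structure(list(alpha = alpha, correction = correction, m = m,
                 or_estimate = or_estimate),
            class = "burden_config")
}

ALL_GENES_GROUP <- "all_genes"

#' Build the 2x2 variant-by-feature contingency table
#'
#' Cells: a = pathogenic variants at feature-bearing positions, b =
#' pathogenic without the feature, c = population with, d = population
#' without. Only variants labelled pathogenic or population at
#' structure-resolved positions qualify; benign-labelled (validation)
#' variants and unresolved positions are excluded. Duplicate variants (same
#' gene/protein/pos/ref/alt) are counted once.
#'
#' @param variants variant table (`gene`, `protein`, `pos`, `ref_aa`,
#'   `alt_aa`, `label`).
#' @param features residue feature table (from [annotate_residues()] or the
#'   cohort generator).
#' @param feature_id catalog feature id.
#' @param group `"all_genes"` or a protein-class label.
#' @param class_map data frame `gene`, `class` (long format; multi-class
#'   membership allowed). Ignored for the all-genes group.
#' @return list of class `contingency_table` with `a`, `b`, `c`, `d`,
#'   `feature`, `group`, `testable` (FALSE when a margin is empty).
#' @export
build_table <- function(variants, features, feature_id, group = ALL_GENES_GROUP,
                        class_map = NULL) {
  if (!feature_id %in% names(features)) {
    stop("unknown feature: ", feature_id)
  }
  v <- variants[variants$label %in% c("pathogenic", "population"), ,
                drop = FALSE]
  v <- v[!duplicated(v[, c("gene", "protein", "pos", "ref_aa", "alt_aa")]), ,
         drop = FALSE]
  if (group != ALL_GENES_GROUP) {
    if (is.null(class_map)) stop("class_map required for a class group")
    v <- v[v$gene %in% class_map$gene[class_map$class == group], ,
           drop = FALSE]
  }
  fk <- paste(features$protein, features$pos)
  hit <- match(paste(v$protein, v$pos), fk)
  ok <- !is.na(hit)
  if ("unresolved" %in% names(features)) {
    ok <- ok & !features$unresolved[hit]
  }
  v <- v[ok, , drop = FALSE]
  has <- features[[feature_id]][hit[ok]] == 1L
  path <- v$label == "pathogenic"
  tab <- list(a = sum(path & has), b = sum(path & !has),
              c = sum(!path & has), d = sum(!path & !has),
              feature = feature_id, group = group)
  tab$testable <- (tab$a + tab$b) > 0 && (tab$c + tab$d) > 0 &&
    (tab$a + tab$c) > 0 && (tab$b + tab$d) > 0
  structure(tab, class = "contingency_table")
}

as_table_cells <- function(table) {
  if (inherits(table, "contingency_table")) {
    unlist(table[c("a", "b", "c", "d")])
  } else {
    stopifnot(length(table) == 4L)
    stats::setNames(as.numeric(table), c("a", "b", "c", "d"))
  }
}

#' Two-sided Fisher exact test p value
#'
#' Probability-ordering ("minlike") two-sided rule: with all margins fixed,
#' the p value is the sum of hypergeometric probabilities of every table
#' whose probability does not exceed that of the observed table (within a
#' relative tolerance of 1e-7, the convention of mainstream
#' implementations).
#'
#' @param table a `contingency_table` or numeric vector `c(a, b, c, d)`.
#' @return two-sided p value in `(0, 1]`.
#' @export
fisher_two_sided <- function(table) {
  x <- as_table_cells(table)
  a <- x[["a"]]; b <- x[["b"]]; c <- x[["c"]]; d <- x[["d"]]
  if ((a + b) <= 0 || (c + d) <= 0 || (a + c) <= 0 || (b + d) <= 0) {
    stop("untestable table: empty margin")
  }
  m <- a + b          # pathogenic total (white balls)
  n <- c + d          # population total
  k <- a + c          # feature-bearing total (draws)
  support <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  min(1, sum(dens[dens <= p_obs * (1 + 1e-7)]))
}

#' Sample odds ratio of a 2x2 table
#'
#' `OR = (a*d) / (b*c)` with sentinels: `Inf` when `b*c = 0 < a*d`, `0` when
#' `a*d = 0 < b*c`, `NaN` when both products vanish.
#'
#' @inheritParams fisher_two_sided
#' @return odds ratio (possibly `0`, `Inf`, or `NaN`).
#' @export
sample_or <- function(table) {
  x <- as_table_cells(table)
  num <- x[["a"]] * x[["d"]]; den <- x[["b"]] * x[["c"]]
  if (num == 0 && den == 0) return(NaN)
  if (den == 0) return(Inf)
  num / den
}

#' Woolf logit 95 percent confidence interval for the odds ratio
#'
#' `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. Any zero cell triggers
#' the Haldane–Anscombe correction (+0.5 to all four cells) for the interval
#' only; the point estimate is not modified.
#'
#' @inheritParams fisher_two_sided
#' @param level confidence level.
#' @return numeric `c(ci_low, ci_high)`.
#' @export
or_ci <- function(table, level = 0.95) {
  x <- as_table_cells(table)
  if (any(x == 0)) x <- x + 0.5
  z <- stats::qnorm(1 - (1 - level) / 2)
  lor <- log(x[["a"]] * x[["d"]] / (x[["b"]] * x[["c"]]))
  se <- sqrt(sum(1 / x))
  unname(exp(lor + c(-1, 1) * z * se))
}

#' Multiplicative multiple-testing correction
#'
#' `q = min(1, p * m)` — Bonferroni-style multiplication by the number of
#' tests, capped at 1.
#'
#' @param p p value(s).
#' @param m number of tests (>= 1).
#' @return corrected q value(s).
#' @export
correct_p <- function(p, m) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  if (m < 1) stop("m must be >= 1")
  pmin(1, p * m)
}

#' Relative risk of pathogenicity given a feature
#'
#' `RR = [a/(a+c)] / [b/(b+d)]`: the probability that a variant is
#' pathogenic given the altered residue has the feature, over the same
#' probability without the feature.
#'
#' @inheritParams fisher_two_sided
#' @return relative risk (`NaN` when undefined).
#' @export
relative_risk <- function(table) {
  x <- as_table_cells(table)
  if ((x[["a"]] + x[["c"]]) == 0 || (x[["b"]] + x[["d"]]) == 0) return(NaN)
  p1 <- x[["a"]] / (x[["a"]] + x[["c"]])
  p0 <- x[["b"]] / (x[["b"]] + x[["d"]])
  if (p0 == 0) return(if (p1 == 0) NaN else Inf)
  p1 / p0
}

#' Run the full per-feature, per-group burden analysis
#'
#' One two-sided Fisher exact test per catalog feature and per gene group
#' (the all-genes pool plus every protein class in `class_map`), with
#' odds ratio, Woolf 95 percent CI, corrected q, relative risk and the
#' association call (`pathogenic` iff OR > 1 and q < alpha; `population`
#' iff OR < 1 and q < alpha; otherwise `none`). Untestable tables (an empty
#' margin) are reported with `NA` statistics and association `none`.
#'
#' @inheritParams build_table
#' @param catalog feature catalog.
#' @param config a [burden_config()].
#' @param groups groups to analyse; defaults to the all-genes pool plus
#'   every class present in `class_map`.
#' @return data frame sorted by (group, feature): `group`, `feature`, `a`,
#'   `b`, `c`, `d`, `or`, `ci_low`, `ci_high`, `p`, `q`, `rr`,
#'   `association`.
#' @export
run_burden <- function(variants, features, class_map = NULL,
                       catalog = feature_catalog(),
                       config = burden_config(), groups = NULL) {
  if (is.null(groups)) {
    groups <- c(ALL_GENES_GROUP,
                if (!is.null(class_map)) sort(unique(class_map$class)))
  }
  grid <- expand.grid(feature = catalog$id, group = groups,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$group, match(grid$feature, catalog$id)), ,
               drop = FALSE]
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    tab <- build_table(variants, features, grid$feature[i], grid$group[i],
                       class_map)
    if (tab$testable) {
      or <- if (config$or_estimate == "cmle") {
        m <- matrix(c(tab$a, tab$b, tab$c, tab$d), 2, byrow = TRUE)
        unname(stats::fisher.test(m)$estimate)
      } else {
        sample_or(tab)
      }
      ci <- or_ci(tab)
      p <- fisher_two_sided(tab)
      res[[i]] <- data.frame(
        group = tab$group, feature = tab$feature,
        a = tab$a, b = tab$b, c = tab$c, d = tab$d,
        or = or, ci_low = ci[1], ci_high = ci[2], p = p, q = NA_real_,
        rr = relative_risk(tab), association = NA_character_,
        stringsAsFactors = FALSE
      )
    } else {
      res[[i]] <- data.frame(
        group = tab$group, feature = tab$feature,
        a = tab$a, b = tab$b, c = tab$c, d = tab$d,
        or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        p = NA_real_, q = NA_real_, rr = NA_real_,
        association = "none", stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, res)
  m <- if (config$correction == "fixed") config$m else sum(!is.na(out$p))
  tested <- !is.na(out$p)
  out$q[tested] <- correct_p(out$p[tested], max(1, m))
  out$association[tested] <- ifelse(
    out$q[tested] < config$alpha & out$or[tested] > 1, "pathogenic",
    ifelse(out$q[tested] < config$alpha & out$or[tested] < 1, "population",
           "none"))
  rownames(out) <- NULL
  out
}

#' Derive the per-group association sets
#'
#' Splits significant burden results into the pathogenic-associated and
#' population-associated feature sets of each group (the universes from
#' which the per-residue index counts its 3DF_PATH and 3DF_POP components).
#' The two sets are disjoint by construction.
#'
#' @param results output of [run_burden()].
#' @param alpha significance level on q.
#' @return list of class `association_table`: per group, a list with
#'   `pathogenic` and `population` character vectors of feature ids.
#' @export
derive_associations <- function(results, alpha = 0.05) {
  out <- lapply(split(results, results$group), function(r) {
    sig <- !is.na(r$q) & r$q < alpha
    list(pathogenic = r$feature[sig & r$or > 1],
         population = r$feature[sig & r$or < 1])
  })
  structure(out, class = "association_table")
}

#' Build an association table directly from feature sets
#'
#' Constructor used for externally specified (e.g. reconstructed or
#' hand-planted) association sets.
#'
#' @param sets named list: per group, a list with `pathogenic` and
#'   `population` character vectors.
#' @param catalog catalog the feature ids must belong to.
#' @return an `association_table`.
#' @export
association_table <- function(sets, catalog = feature_catalog()) {
  for (g in names(sets)) {
    s <- sets[[g]]
    bad <- setdiff(c(s$pathogenic, s$population), catalog$id)
    if (length(bad)) {
      stop("unknown feature id(s) in group ", g, ": ",
           paste(bad, collapse = ", "))
    }
    if (length(intersect(s$pathogenic, s$population))) {
      stop("association sets must be disjoint in group ", g)
    }
  }
  structure(sets, class = "association_table")
}

#' Read / write association tables as TSV
#'
#' Long format: columns `group`, `feature`, `association` (one of
#' `pathogenic` / `population`).
#'
#' @param assoc an `association_table`.
#' @param path file path.
#' @rdname association_io
#' @export
write_associations <- function(assoc, path) {
  rows <- do.call(rbind, lapply(names(assoc), function(g) {
    s <- assoc[[g]]
    data.frame(
      group = g,
      feature = c(s$pathogenic, s$population),
      association = rep(c("pathogenic", "population"),
                        c(length(s$pathogenic), length(s$population))),
      stringsAsFactors = FALSE
    )
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @param catalog catalog used to validate feature ids.
#' @rdname association_io
#' @export
read_associations <- function(path, catalog = feature_catalog()) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  sets <- lapply(split(df, df$group), function(r) {
    list(pathogenic = r$feature[r$association == "pathogenic"],
         population = r$feature[r$association == "population"])
  })
  association_table(sets, catalog)
}
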