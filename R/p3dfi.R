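#' Per-residue pathogenic 3D feature index
#'
#' Counts how many of the residue's set features belong to the context
#' group's pathogenic-associated set (`n_path`) and population-associated
#' set (`n_pop`); the index is `n_path - n_pop`. A positive index marks a
#' 3D mutational hotspot.
#'
#' @param vector a `residue_feature_vector` (from [consolidate()]) or a
#'   named 0/1 vector over the catalog.
#' @param assoc an `association_table`.
#' @param group context group (the all-genes pool or a class label).
#' @param catalog feature catalog the vector must conform to.
#' @return list of class `p3dfi_score`: `protein`, `pos`, `ref_aa`,
#'   `group`, `n_path`, `n_pop`, `index`, `hotspot`.
#' @export
compute_p3dfi <- function(vector, assoc, group,
                          catalog = feature_catalog()) {
  if (!group %in% names(assoc)) {
    stop("group not present in association table: ", group)
  }
  meta <- list(protein = NA_character_, pos = NA_integer_,
               ref_aa = NA_character_)
  if (inherits(vector, "residue_feature_vector")) {
    meta <- vector[c("protein", "pos", "ref_aa")]
    vector <- vector$bits
  }
  if (!identical(sort(names(vector)), sort(catalog$id))) {
    stop("feature vector does not match the catalog")
  }
  on <- names(vector)[vector == 1]
  s <- assoc[[group]]
  n_path <- length(intersect(on, s$pathogenic))
  n_pop <- length(intersect(on, s$population))
  structure(
    c(meta, list(group = group, n_path = n_path, n_pop = n_pop,
                 index = n_path - n_pop, hotspot = n_path - n_pop > 0)),
    class = "p3dfi_score"
  )
}

#' @export
print.p3dfi_score <- function(x, ...) {
  cat(sprintf("<P3DFi %s %s%s | %s> path %d - pop %d = %+d%s\n",
              x$protein, x$ref_aa,
              ifelse(is.na(x$pos), "", x$pos), x$group,
              x$n_path, x$n_pop, x$index,
              if (isTRUE(x$hotspot)) "  [3D mutational hotspot]" else ""))
  invisible(x)
}

#' Score every residue of a feature table
#'
#' Vectorised driver over [compute_p3dfi()]. Unresolved residues get `NA`
#' scores.
#'
#' @param features residue feature table.
#' @param assoc an `association_table`.
#' @param group context group.
#' @param catalog feature catalog.
#' @return data frame `protein`, `pos`, `ref_aa`, `group`, `n_path`,
#'   `n_pop`, `index`, `bin`.
#' @export
score_residues <- function(features, assoc, group,
                           catalog = feature_catalog()) {
  if (!group %in% names(assoc)) {
    stop("group not present in association table: ", group)
  }
  s <- assoc[[group]]
  mat <- as.matrix(features[, catalog$id, drop = FALSE])
  n_path <- as.integer(mat[, s$pathogenic, drop = FALSE] %*%
                         rep(1, length(s$pathogenic)))
  n_pop <- as.integer(mat[, s$population, drop = FALSE] %*%
                        rep(1, length(s$population)))
  idx <- n_path - n_pop
  if ("unresolved" %in% names(features)) {
    idx[features$unresolved] <- NA_integer_
    n_path[features$unresolved] <- NA_integer_
    n_pop[features$unresolved] <- NA_integer_
  }
  data.frame(
    protein = features$protein, pos = features$pos,
    ref_aa = features$ref_aa, group = group,
    n_path = n_path, n_pop = n_pop, index = idx,
    bin = ifelse(is.na(idx), NA_character_, bin_p3dfi(idx)),
    stringsAsFactors = FALSE
  )
}

P3DFI_BINS <- c("<-2", "-2", "-1", "0", "1", "2", ">2")

#' Bin an index value
#'
#' Integer values -2..2 map to their own bins; values beyond map to the
#' `"<-2"` / `">2"` tail bins. The seven bins partition the integers.
#'
#' @param index integer index value(s).
#' @return character bin label(s), ordered factor levels in [P3DFI_BINS].
#' @export
bin_p3dfi <- function(index) {
  ifelse(index < -2, "<-2", ifelse(index > 2, ">2", as.character(index)))
}

#' High-confidence classification from the index tails
#'
#' `index > upper` is pathogenic-like, `index < lower` benign-like,
#' anything else indeterminate (strict inequalities, so the boundary values
#' stay indeterminate).
#'
#' @param index integer index value(s).
#' @param upper,lower tail thresholds (defaults 2 and -2).
#' @return character classification(s).
#' @export
classify_high_confidence <- function(index, upper = 2, lower = -2) {
  if (upper <= lower) stop("upper threshold must exceed lower")
  ifelse(index > upper, "pathogenic-like",
         ifelse(index < lower, "benign-like", "indeterminate"))
}

#' Two-sided Mann–Whitney U test
#'
#' U is computed from midrank sums. When the exact branch is feasible
#' (`choose(n1 + n2, n1)` at most `max_exact`), the two-sided p value is
#' obtained by complete enumeration of all splits of the observed values
#' (a permutation distribution, exact under ties); otherwise the normal
#' approximation with tie correction is used (no continuity correction).
#' With all values identical across both samples, p = 1.
#'
#' @param x,y numeric samples.
#' @param max_exact largest enumeration size for the exact branch.
#' @return list of class `rank_test`: `U` (for `x`), `p`, `method`.
#' @export
mann_whitney_two_sided <- function(x, y, max_exact = 50000) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both samples must be non-empty")
  z <- c(x, y)
  r <- rank(z)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (length(unique(z)) == 1L) {
    return(structure(list(U = U, p = 1, method = "degenerate"),
                     class = "rank_test"))
  }
  if (choose(n1 + n2, n1) <= max_exact) {
    splits <- utils::combn(n1 + n2, n1)
    stat <- apply(splits, 2, function(ix) {
      sum(r[ix]) - n1 * (n1 + 1) / 2
    })
    eps <- sqrt(.Machine$double.eps)
    p <- mean(abs(stat - mu) >= abs(U - mu) - eps)
    method <- "exact"
  } else {
    n <- n1 + n2
    ties <- table(z)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    zstat <- (U - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(zstat))
    method <- "normal-approx"
  }
  structure(list(U = U, p = min(1, p), method = method),
            class = "rank_test")
}

#' Correlate index values with experimental fitness scores
#'
#' Pearson product-moment correlation between per-position index values and
#' mean mutational fitness scores, reported as r-squared with the two-sided
#' p value from the t transform.
#'
#' @param scores data frame with `protein`, `pos`, `index` (as from
#'   [score_residues()]).
#' @param fitness data frame with `protein`, `pos`, `fitness`.
#' @return list of class `correlation_result`: `r`, `r2`, `p`, `n`.
#' @export
correlate_fitness <- function(scores, fitness) {
  key <- paste(fitness$protein, fitness$pos)
  hit <- match(paste(scores$protein, scores$pos), key)
  ok <- !is.na(hit) & !is.na(scores$index)
  xi <- scores$index[ok]
  yi <- fitness$fitness[hit[ok]]
  if (length(xi) < 3) stop("need at least 3 paired positions")
  if (stats::sd(xi) == 0 || stats::sd(yi) == 0) {
    stop("correlation undefined for a constant input")
  }
  ct <- stats::cor.test(xi, yi, method = "pearson")
  structure(list(r = unname(ct$estimate), r2 = unname(ct$estimate)^2,
                 p = ct$p.value, n = length(xi)),
            class = "correlation_result")
}
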