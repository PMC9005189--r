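## G protein x G protein co-coupling matrices and the correlation tree.

#' Per-G-protein activation vectors over receptors
#'
#' For each subtype, the supported coupling values across receptors: the mean
#' of the two sources' log(Emax/EC50) where both couple, else the single
#' coupling source's value. With `zero_fill = TRUE` non-coupling cells get 0
#' (the convention for the Pearson co-coupling analysis); otherwise they stay
#' NA (the convention for Jaccard and activation-difference analyses).
#'
#' @param map coupling_map
#' @param receptors optional receptor subset (e.g. the class A receptors);
#'   defaults to the quantitative section
#' @param zero_fill logical
#' @return Numeric matrix subtypes x receptors.
#' @export
coupling_vectors <- function(map, receptors = NULL, zero_fill = TRUE) {
  if (is.null(receptors)) receptors <- map$receptors$quantitative
  m <- matrix(if (zero_fill) 0 else NA_real_,
              length(map$subtypes), length(receptors),
              dimnames = list(map$subtypes, receptors))
  e <- map$entries[map$entries$receptor %in% receptors, , drop = FALSE]
  if (nrow(e)) m[cbind(e$gprotein, e$receptor)] <- e$map_value
  m
}

#' Pairwise Pearson correlation of G protein activation vectors
#'
#' Standard two-tailed Pearson per pair of zero-filled vectors, with
#' significance stars at p <= 0.05 / 0.005 / 0.0005 (no multiple-testing
#' correction). Constant vectors yield NA entries.
#'
#' @param vectors matrix subtypes x receptors (zero-filled)
#' @return list(r, p, stars), each a symmetric subtype x subtype matrix.
#' @export
pearson_matrix <- function(vectors) {
  if (ncol(vectors) < 3) stop("need at least 3 receptors")
  g <- rownames(vectors)
  n <- length(g)
  r <- p <- matrix(NA_real_, n, n, dimnames = list(g, g))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      x <- vectors[i, ]; y <- vectors[j, ]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) next
      ct <- stats::cor.test(x, y, method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  stars <- matrix("", n, n, dimnames = list(g, g))
  stars[!is.na(p) & p <= 0.05] <- "*"
  stars[!is.na(p) & p <= 0.005] <- "**"
  stars[!is.na(p) & p <= 0.0005] <- "***"
  diag(stars) <- ""
  list(r = r, p = p, stars = stars)
}

#' Jaccard index matrix of coupled receptor sets
#'
#' |A intersect B| / |A union B| per G protein pair, from the per-subtype
#' sets of coupled receptors.
#'
#' @param vectors matrix subtypes x receptors, non-NA (if not zero-filled) or
#'   nonzero entries mark couplings; or a logical matrix
#' @return Symmetric matrix of Jaccard indices (NA where both sets empty).
#' @export
jaccard_matrix <- function(vectors) {
  coupled <- if (is.logical(vectors)) vectors else !is.na(vectors) & vectors != 0
  g <- rownames(coupled)
  n <- length(g)
  jm <- matrix(NA_real_, n, n, dimnames = list(g, g))
  for (i in seq_len(n)) {
    for (j in i:n) {
      u <- sum(coupled[i, ] | coupled[j, ])
      jm[i, j] <- jm[j, i] <- if (u == 0) NA_real_ else
        sum(coupled[i, ] & coupled[j, ]) / u
    }
  }
  jm
}

#' Mean activation-level difference over co-coupled receptors
#'
#' For each G protein pair, the absolute difference of the two subtypes' mean
#' log(Emax/EC50) over the receptors coupling both (NA if no receptor couples
#' both).
#'
#' @param vectors matrix subtypes x receptors with NA for non-couplers
#'   (`zero_fill = FALSE` convention)
#' @return Symmetric matrix of mean absolute differences.
#' @export
activation_difference <- function(vectors) {
  g <- rownames(vectors)
  n <- length(g)
  d <- matrix(NA_real_, n, n, dimnames = list(g, g))
  for (i in seq_len(n)) {
    for (j in i:n) {
      both <- !is.na(vectors[i, ]) & !is.na(vectors[j, ])
      d[i, j] <- d[j, i] <- if (!any(both)) NA_real_ else
        abs(mean(vectors[i, both]) - mean(vectors[j, both]))
    }
  }
  diag(d) <- ifelse(rowSums(!is.na(vectors)) > 0, 0, NA_real_)
  d
}

#' Hierarchical clustering of G proteins on correlation distance
#'
#' Average-linkage clustering on the distance 1 - r; the result is invariant
#' to the input ordering of G proteins up to leaf rotation.
#'
#' @param r complete symmetric Pearson correlation matrix
#' @return An `hclust` object.
#' @export
correlation_tree <- function(r) {
  if (anyNA(r)) stop("correlation matrix has missing entries")
  stats::hclust(stats::as.dist(1 - r), method = "average")
}

#' Newick serialization of a correlation tree
#'
#' @param tree hclust object from [correlation_tree()]
#' @param file optional path; when NULL the Newick string is returned
#' @return Newick string (invisibly when written to file).
#' @export
tree_newick <- function(tree, file = NULL) {
  phy <- ape::as.phylo(tree)
  if (is.null(file)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = file)
  invisible(ape::write.tree(phy))
}

#' All co-coupling matrices of a map
#'
#' Convenience wrapper computing the Pearson (zero-filled), Jaccard and
#' activation-difference matrices and the correlation tree for one receptor
#' universe.
#'
#' @param map coupling_map
#' @param receptors optional receptor subset (class A receptors in the
#'   reference analysis)
#' @return list(pearson_r, pearson_p, stars, jaccard, activation_diff, tree).
#' @export
cocoupling_matrices <- function(map, receptors = NULL) {
  v0 <- coupling_vectors(map, receptors, zero_fill = TRUE)
  vm <- coupling_vectors(map, receptors, zero_fill = FALSE)
  pm <- pearson_matrix(v0)
  list(pearson_r = pm$r, pearson_p = pm$p, stars = pm$stars,
       jaccard = jaccard_matrix(vm),
       activation_diff = activation_difference(vm),
       tree = if (anyNA(pm$r)) NULL else correlation_tree(pm$r))
}
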