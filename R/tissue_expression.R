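## Tissue/organ expression profiling of the 16 G protein genes.

#' First-quartile expression threshold
#'
#' The 25th percentile of all values of a gene x tissue nTPM matrix, with
#' linear interpolation (R's default quantile type 7). The numeric result is
#' release-sensitive: it depends on the expression atlas version the matrix
#' was extracted from.
#'
#' @param m numeric matrix (genes x tissues, nTPM)
#' @return Single numeric threshold.
#' @export
quartile_threshold <- function(m) {
  if (!length(m)) stop("empty expression matrix")
  unname(stats::quantile(as.numeric(m), 0.25, type = 7, na.rm = TRUE))
}

#' Number of tissues at or above an expression threshold
#'
#' @param m numeric gene x tissue matrix
#' @param t threshold (inclusive: counts nTPM >= t)
#' @return Named integer vector, one count per gene.
#' @export
tissues_above_threshold <- function(m, t) {
  if (!is.numeric(t) || length(t) != 1 || t < 0) stop("t must be a single value >= 0")
  rowSums(m >= t, na.rm = TRUE)
}

#' Z-score transform each gene across tissues
#'
#' Centers and scales every row; the scale is the sample (n-1) standard
#' deviation. Constant genes cannot be scaled and return NA rows with a
#' warning.
#'
#' @param m numeric gene x tissue matrix
#' @return Matrix of z-scores (row means 0, row SDs 1 for non-constant genes).
#' @export
zscore_per_gene <- function(m) {
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  flat <- sd == 0
  if (any(flat)) {
    warning("constant gene(s) flagged, z undefined: ",
            paste(rownames(m)[flat], collapse = ", "))
    sd[flat] <- NA_real_
  }
  (m - mu) / sd
}

#' Display cap for expression heatmaps
#'
#' The median over genes of each gene's maximum nTPM: heatmap colors are
#' capped there so focally expressed genes do not flatten the rest of the
#' scale.
#'
#' @param m numeric gene x tissue matrix
#' @return Single numeric cap.
#' @export
display_cap <- function(m) {
  if (!length(m)) stop("empty expression matrix")
  unname(stats::median(apply(m, 1, max)))
}

#' Gene-gene co-expression and display clustering
#'
#' Pearson correlation of gene pairs over their tissue profiles, with
#' average-linkage hierarchical clustering on the correlation distance 1 - r
#' for a display order. Constant genes are excluded with a warning.
#'
#' @param m numeric gene x tissue matrix
#' @return list(r, tree (hclust), order) over the retained genes.
#' @export
coexpression_cluster <- function(m) {
  sd <- apply(m, 1, stats::sd)
  if (any(sd == 0)) {
    warning("excluding constant gene(s): ",
            paste(rownames(m)[sd == 0], collapse = ", "))
    m <- m[sd > 0, , drop = FALSE]
  }
  r <- stats::cor(t(m))
  tree <- stats::hclust(stats::as.dist(1 - r), method = "average")
  list(r = r, tree = tree, order = rownames(m)[tree$order])
}

#' Simulate an atlas-shaped G protein expression matrix
#'
#' Generates a synthetic 16-gene x 50-tissue nTPM matrix with the structural
#' features of the consensus atlas data that the expression analyses assume:
#' two ubiquitously expressed genes (GNAS, GNAI2), a coherent brain-enriched
#' program shared by GNAL, GNAO1, GNAZ, GNAQ and GNA12, sensory genes with
#' focal expression (GNAT1/GNAT2 in retina, GNAT3 in the intestinal tissues),
#' and lognormal baseline expression elsewhere. It is a synthetic stand-in
#' for validating code paths, not a reproduction of any atlas release.
#'
#' @param seed integer seed
#' @param n_tissues number of tissues (default 50)
#' @return Numeric matrix, 16 gene symbols x tissues, nonnegative nTPM.
#' @export
simulate_expression_matrix <- function(seed = 1, n_tissues = 50) {
  set.seed(seed)
  genes <- unique(gprotein_panel()$gene)
  brain_program <- c("GNAL", "GNAO1", "GNAZ", "GNAQ", "GNA12")
  tissues <- c(paste0("brain_", 1:8), "retina", "intestine_1", "intestine_2",
               paste0("tissue_", seq_len(n_tissues - 11)))
  m <- matrix(stats::rlnorm(length(genes) * length(tissues),
                            meanlog = log(15), sdlog = 0.8),
              length(genes), length(tissues),
              dimnames = list(genes, tissues))
  brain <- grep("^brain_", tissues)
  m[brain_program, brain] <- m[brain_program, brain] *
    matrix(stats::runif(length(brain_program) * length(brain), 6, 12),
           length(brain_program))
  m[c("GNAS", "GNAI2"), ] <- matrix(
    stats::rlnorm(2 * length(tissues), meanlog = log(120), sdlog = 0.25), 2)
  for (g in c("GNAT1", "GNAT2")) {
    m[g, ] <- stats::rlnorm(length(tissues), meanlog = log(0.8), sdlog = 0.5)
    m[g, "retina"] <- stats::runif(1, 300, 500)
  }
  m["GNAT3", ] <- stats::rlnorm(length(tissues), meanlog = log(0.5), sdlog = 0.5)
  m["GNAT3", c("intestine_1", "intestine_2")] <- stats::runif(2, 60, 100)
  m[c("GNAI3", "GNA14"), ] <- m[c("GNAI3", "GNA14"), ] * 0.3
  round(m, 2)
}

#' Write an expression matrix in the consensus-atlas TSV dialect
#'
#' @param m gene x tissue matrix
#' @param path output path
#' @return Invisibly, `path`.
#' @export
write_expression_table <- function(m, path) {
  df <- data.frame(
    Gene = paste0("ENSG_", rownames(m))[row(m)],
    `Gene name` = rownames(m)[row(m)],
    Tissue = colnames(m)[col(m)],
    nTPM = as.numeric(m),
    check.names = FALSE
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
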