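## Cross-dataset coupling/noncoupling agreement and detection-threshold
## optimization.

#' Coupling grid from thresholded measurements
#'
#' @param ms measurement data.frame with a `coupler` column (see
#'   [apply_sd_cutoff()])
#' @param subtypes column universe; defaults to the subtypes present
#' @param receptors row universe; defaults to the receptors present
#' @return Logical matrix receptors x subtypes; NA marks untested cells.
#' @export
coupling_grid <- function(ms, subtypes = NULL, receptors = NULL) {
  if (is.null(ms$coupler)) stop("measurements lack a coupler column; run apply_sd_cutoff()")
  if (is.null(receptors)) receptors <- sort(unique(ms$receptor))
  if (is.null(subtypes)) subtypes <- sort(unique(ms$gprotein))
  m <- matrix(NA, length(receptors), length(subtypes),
              dimnames = list(receptors, subtypes))
  keep <- ms$receptor %in% receptors & ms$gprotein %in% subtypes
  sub <- ms[keep, , drop = FALSE]
  m[cbind(match(sub$receptor, receptors), match(sub$gprotein, subtypes))] <-
    sub$coupler
  m
}

#' Aggregate a subtype coupling grid to the family level
#'
#' A family cell is TRUE if any tested member subtype is a coupler, FALSE if
#' members were tested and none couple, NA if no member was tested.
#'
#' @param grid logical matrix receptors x subtypes (NA = untested)
#' @param panel G protein panel
#' @return Logical matrix receptors x families.
#' @export
family_grid <- function(grid, panel = gprotein_panel()) {
  fams <- gprotein_families()
  fam_of <- subtype_family(colnames(grid), panel)
  out <- matrix(NA, nrow(grid), length(fams),
                dimnames = list(rownames(grid), fams))
  for (f in fams) {
    cols <- grid[, fam_of == f, drop = FALSE]
    if (!ncol(cols)) next
    any_true <- apply(cols, 1, function(x) any(x %in% TRUE))
    tested <- apply(cols, 1, function(x) any(!is.na(x)))
    out[, f] <- ifelse(tested, any_true, NA)
  }
  out
}

.agreement_over <- function(match_mat, compared_mat) {
  per_unit <- colSums(match_mat, na.rm = TRUE) / colSums(compared_mat)
  per_unit <- per_unit[colSums(compared_mat) > 0]
  structure(
    list(per_unit = per_unit,
         mean_agreement = mean(per_unit),
         n_pairs = sum(compared_mat)),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Coupling agreement over %d compared cells\n", x$n_pairs))
  cat(sprintf("  mean (unweighted over %d units): %.3f\n",
              length(x$per_unit), x$mean_agreement))
  print(round(x$per_unit, 3))
  invisible(x)
}

#' Pairwise coupling agreement between two datasets
#'
#' Restricted to receptors and units tested by both sources; both coupler and
#' non-coupler matches count as agreement. Per-unit agreement is matching
#' cells over compared cells; the summary is the unweighted mean over units.
#' The function is symmetric in its two arguments.
#'
#' @param A,B logical coupling grids (receptors x units, NA = untested)
#' @return An `agreement_result`: list(per_unit, mean_agreement, n_pairs).
#' @export
pairwise_agreement <- function(A, B) {
  rs <- intersect(rownames(A), rownames(B))
  us <- intersect(colnames(A), colnames(B))
  if (!length(rs) || !length(us)) stop("no common receptors/units between grids")
  a <- A[rs, us, drop = FALSE]
  b <- B[rs, us, drop = FALSE]
  compared <- !is.na(a) & !is.na(b)
  if (!any(compared)) stop("no cells tested by both sources")
  .agreement_over((a == b) & compared, compared)
}

#' Three-way coupling agreement
#'
#' A cell agrees only if all three sources report the same boolean; computed
#' over the triple intersection of tested cells.
#'
#' @param A,B,C logical coupling grids
#' @return An `agreement_result`.
#' @export
threeway_agreement <- function(A, B, C) {
  rs <- Reduce(intersect, list(rownames(A), rownames(B), rownames(C)))
  us <- Reduce(intersect, list(colnames(A), colnames(B), colnames(C)))
  if (!length(rs) || !length(us)) stop("no common receptors/units between grids")
  a <- A[rs, us, drop = FALSE]; b <- B[rs, us, drop = FALSE]; c <- C[rs, us, drop = FALSE]
  compared <- !is.na(a) & !is.na(b) & !is.na(c)
  if (!any(compared)) stop("no cells tested by all three sources")
  .agreement_over((a == b) & (b == c) & compared, compared)
}

#' Agreement stratified by shared-agonist status
#'
#' Splits receptors by whether both sources used the same agonist and reports
#' the mean per-receptor qualitative agreement within each stratum.
#'
#' @param A,B logical coupling grids
#' @param ligand_shared named logical vector over receptors (TRUE = both
#'   sources used the same agonist)
#' @return list(fraction_same, fraction_diff, n_same, n_diff); an empty
#'   stratum yields NA with a warning.
#' @export
agreement_by_ligand_match <- function(A, B, ligand_shared) {
  rs <- intersect(intersect(rownames(A), rownames(B)), names(ligand_shared))
  us <- intersect(colnames(A), colnames(B))
  if (!length(rs) || !length(us)) stop("no common receptors/units between grids")
  a <- A[rs, us, drop = FALSE]
  b <- B[rs, us, drop = FALSE]
  compared <- !is.na(a) & !is.na(b)
  per_receptor <- rowSums((a == b) & compared, na.rm = TRUE) / rowSums(compared)
  strat <- function(sel) {
    v <- per_receptor[sel & is.finite(per_receptor)]
    if (!length(v)) {
      warning("empty agonist stratum; fraction undefined")
      return(NA_real_)
    }
    mean(v)
  }
  shared <- ligand_shared[rs] %in% TRUE
  list(fraction_same = strat(shared), fraction_diff = strat(!shared),
       n_same = sum(shared), n_diff = sum(!shared))
}

#' Optimize the basal-SD detection threshold
#'
#' Scans a grid of thresholds, applies [apply_sd_cutoff()] to both raw
#' measurement sets at each value and scores the mean coupling agreement over
#' cells tested by both sources. Returns the argmax; ties go to the smallest
#' threshold.
#'
#' @param A_raw,B_raw raw measurement data.frames (pre-threshold)
#' @param grid nonempty vector of candidate thresholds (SD units, >= 0)
#' @param level "subtype" (default) or "family" agreement cells
#' @param panel G protein panel
#' @return list(k_star, curve) where curve is a data.frame(k, mean_agreement).
#' @export
optimize_sd_cutoff <- function(A_raw, B_raw, grid = seq(0, 3, by = 0.1),
                               level = c("subtype", "family"),
                               panel = gprotein_panel()) {
  level <- match.arg(level)
  if (!length(grid) || any(grid < 0)) stop("grid must be nonempty with values >= 0")
  grid <- sort(grid)
  score <- vapply(grid, function(k) {
    ga <- coupling_grid(apply_sd_cutoff(A_raw, k))
    gb <- coupling_grid(apply_sd_cutoff(B_raw, k))
    if (level == "family") {
      ga <- family_grid(ga, panel)
      gb <- family_grid(gb, panel)
    }
    pairwise_agreement(ga, gb)$mean_agreement
  }, numeric(1))
  k_star <- grid[which.max(score)]  # which.max takes the first (smallest) tie
  list(k_star = k_star,
       curve = data.frame(k = grid, mean_agreement = score))
}
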