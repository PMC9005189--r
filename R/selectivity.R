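## Receptor promiscuity and G protein coverage statistics.

#' Supported family-level coupling matrix of a map
#'
#' One row per mapped receptor, one column per family. Quantitatively tested
#' receptors contribute supported subtype couplings aggregated to families
#' plus annotated families that no quantitative source tested;
#' annotation-only receptors contribute their annotated families.
#'
#' @param map coupling_map
#' @return Logical matrix receptors x 4 families.
#' @export
family_coupling_matrix <- function(map) {
  fams <- gprotein_families()
  receptors <- map$receptors$all
  m <- matrix(FALSE, length(receptors), length(fams),
              dimnames = list(receptors, fams))
  e <- map$entries
  if (nrow(e)) m[cbind(e$receptor, e$family)] <- TRUE
  # annotated families with no quantitative test remain supported
  ann <- map$annotations
  for (i in seq_len(nrow(ann))) {
    ev <- map$evidence[map$evidence$receptor == ann$receptor[i] &
                         map$evidence$family == ann$family[i], , drop = FALSE]
    if (!nrow(ev)) m[ann$receptor[i], ann$family[i]] <- TRUE
  }
  m
}

#' Supported subtype-level coupling matrix (quantitative section)
#'
#' @param map coupling_map
#' @return Logical matrix over quantitatively tested receptors x subtypes;
#'   NA = untested by both sources.
#' @export
subtype_coupling_matrix <- function(map) {
  receptors <- map$receptors$quantitative
  m <- matrix(NA, length(receptors), length(map$subtypes),
              dimnames = list(receptors, map$subtypes))
  ev <- map$evidence
  m[cbind(ev$receptor, ev$gprotein)] <- FALSE
  e <- map$entries
  if (nrow(e)) m[cbind(e$receptor, e$gprotein)] <- TRUE
  m
}

#' Receptor promiscuity distribution
#'
#' Counts receptors coupling 1, 2, 3 or 4 G protein families (supported
#' couplings, annotation-only receptors included at family level) and the
#' mean number of families per coupled receptor.
#'
#' @param map coupling_map
#' @return list(counts = named 1..4 vector, mean_families, universe,
#'   n_zero_family).
#' @export
promiscuity_distribution <- function(map) {
  m <- family_coupling_matrix(map)
  nf <- rowSums(m)
  coupled <- nf[nf > 0]
  counts <- vapply(1:4, function(i) sum(coupled == i), integer(1))
  names(counts) <- 1:4
  list(counts = counts,
       mean_families = if (length(coupled)) mean(coupled) else NA_real_,
       universe = length(coupled),
       n_zero_family = sum(nf == 0))
}

#' Receptors covered per G protein family and subtype
#'
#' Family coverage counts receptors with a supported coupling to any family
#' member (annotation-only receptors included); subtype coverage uses the
#' quantitative section only. When Golf is in the subtype universe, receptors
#' tested for Gs but not Golf are excluded from the Gs-family subtype
#' analysis and Golf couplings count only alongside a supported Gs coupling.
#'
#' @param map coupling_map
#' @return list(per_family counts, pct_family, mean_family, per_subtype,
#'   universe).
#' @export
gprotein_coverage <- function(map) {
  fm <- family_coupling_matrix(map)
  per_family <- colSums(fm)
  universe <- nrow(fm)
  sm <- subtype_coupling_matrix(map)
  keep <- rep(TRUE, nrow(sm))
  if (all(c("Gs", "Golf") %in% colnames(sm))) {
    tested_gs <- !is.na(sm[, "Gs"])
    tested_golf <- !is.na(sm[, "Golf"])
    keep_gs <- !(tested_gs & !tested_golf)
    sm[!keep_gs, c("Gs", "Golf")] <- NA
    sm[, "Golf"] <- sm[, "Golf"] & sm[, "Gs"]
  }
  per_subtype <- colSums(sm, na.rm = TRUE)
  list(per_family = per_family,
       pct_family = 100 * per_family / universe,
       mean_family = mean(per_family),
       per_subtype = per_subtype,
       universe = universe)
}

#' Fraction of receptors activating every member of a coupled family
#'
#' For each family, among quantitatively profiled receptors with at least one
#' supported coupling in the family and with every member subtype tested,
#' the fraction that couples to all members.
#'
#' @param map coupling_map
#' @param panel G protein panel
#' @return Named numeric vector (one fraction per family; NA if no receptor
#'   qualifies).
#' @export
within_family_promiscuity <- function(map, panel = gprotein_panel()) {
  sm <- subtype_coupling_matrix(map)
  fam_of <- subtype_family(colnames(sm), panel)
  out <- stats::setNames(rep(NA_real_, length(gprotein_families())),
                         gprotein_families())
  for (f in gprotein_families()) {
    cols <- sm[, fam_of == f, drop = FALSE]
    if (!ncol(cols)) next
    all_tested <- rowSums(is.na(cols)) == 0
    any_coupled <- rowSums(cols, na.rm = TRUE) > 0
    qual <- all_tested & any_coupled
    if (!any(qual)) next
    out[f] <- mean(rowSums(cols[qual, , drop = FALSE]) == ncol(cols))
  }
  out
}

#' Venn region counts of a coupling matrix
#'
#' Counts receptors in each nonempty region of the set system defined by the
#' columns of a logical coupling matrix (the 15 regions of a 4-family Venn at
#' family level; within-family subtype Venns analogously). Region counts sum
#' to the number of receptors with at least one coupling.
#'
#' @param m logical matrix receptors x sets (NA treated as FALSE)
#' @return Named integer vector over regions ("Gs", "Gs+Gi/o", ...).
#' @export
venn_intersections <- function(m) {
  m[is.na(m)] <- FALSE
  sets <- colnames(m)
  combos <- unlist(lapply(seq_along(sets), function(k) {
    utils::combn(sets, k, paste, collapse = "+", simplify = FALSE)
  }))
  counts <- stats::setNames(integer(length(combos)), combos)
  profile <- apply(m, 1, function(x) paste(sets[x], collapse = "+"))
  tab <- table(profile[profile != ""])
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Family-level Venn regions of a coupling map
#'
#' @param map coupling_map
#' @param level "family" (default) or a family token for its within-family
#'   subtype Venn
#' @param panel G protein panel
#' @return Named integer vector of region counts.
#' @export
map_venn <- function(map, level = "family", panel = gprotein_panel()) {
  if (identical(level, "family")) {
    return(venn_intersections(family_coupling_matrix(map)))
  }
  sm <- subtype_coupling_matrix(map)
  fam_of <- subtype_family(colnames(sm), panel)
  if (!level %in% fam_of) stop("unknown level: ", level)
  venn_intersections(sm[, fam_of == level, drop = FALSE])
}
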