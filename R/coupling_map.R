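## Evidence classification and assembly of the unified coupling map.

#' Classify the evidence pattern of one receptor-G protein cell
#'
#' Applies the standardized evidence terminology:
#' \describe{
#'   \item{supported}{coupler in at least two sources, counting a literature
#'     family annotation as one source; or annotated with no quantitative
#'     test of the cell (literature annotations aggregate multiple
#'     publications and self-support)}
#'   \item{novel}{coupler in both quantitative sources but not annotated}
#'   \item{proposed}{coupler in exactly one quantitative source with no other
#'     source having tested the cell}
#'   \item{unique:<source>}{coupler in one source while at least one other
#'     source tested the cell and none of the others couple}
#'   \item{missing:<source>}{a quantitative source tested the cell and found
#'     non-coupling while another source couples}
#' }
#' A literature annotation "tests" a cell whenever the receptor is present in
#' the annotation dataset (family-level coverage expanded to subtypes).
#'
#' @param tested_by character vector of quantitative sources that tested the
#'   cell
#' @param coupler_in character vector of quantitative sources reporting a
#'   coupler (subset of `tested_by`)
#' @param annotated logical, family-level literature coupling (expanded to
#'   this subtype)
#' @param annotation_tested logical, receptor present in the annotation
#'   dataset
#' @return Character vector of labels (possibly empty).
#' @export
classify_evidence <- function(tested_by, coupler_in, annotated,
                              annotation_tested) {
  stopifnot(all(coupler_in %in% tested_by))
  labels <- character(0)
  n_support <- length(coupler_in) + as.integer(annotated)
  if (n_support >= 2 || (annotated && length(tested_by) == 0)) {
    labels <- c(labels, "supported")
  }
  if (length(coupler_in) >= 2 && !annotated) labels <- c(labels, "novel")

  couplers <- c(coupler_in, if (annotated) "annotation")
  testers <- c(tested_by, if (annotation_tested) "annotation")
  if (length(coupler_in) == 1 && length(testers) == 1 && !annotated) {
    labels <- c(labels, "proposed")
  }
  for (s in couplers) {
    others <- setdiff(testers, s)
    if (length(others) && !length(setdiff(couplers, s))) {
      labels <- c(labels, paste0("unique:", s))
    }
  }
  for (s in setdiff(tested_by, coupler_in)) {
    if (length(setdiff(couplers, s))) labels <- c(labels, paste0("missing:", s))
  }
  labels
}

#' Build the unified coupling map
#'
#' Runs the threshold + harmonization protocol on two quantitative coupling
#' datasets, expands family-level literature annotations to subtypes,
#' classifies every tested cell, and assembles the map: one quantitative
#' entry per supported (receptor, G protein) with the mean log(Emax/EC50)
#' over coupling sources, plus family-level entries for receptors covered by
#' annotation only.
#'
#' @param A,B measurement data.frames for the two quantitative sources; a
#'   `coupler` column is honoured, otherwise [qc_filter()] is applied at `k`
#' @param annotations optional annotation records (receptor, family, rank)
#' @param k basal-SD detection threshold (default 1.4)
#' @param subtypes subtype universe for the map (default: the 12 analysis
#'   subtypes); both sources must use these tokens (expand shedding-assay
#'   probes first, see [expand_probe_measurements()])
#' @param panel G protein panel
#' @return An object of class `coupling_map`: list with elements `evidence`
#'   (all tested cells with labels), `entries` (supported quantitative
#'   cells), `annotation_only` (family-level records for receptors without
#'   quantitative data), `sources`, `k`, `subtypes`, `receptors` (quantitative
#'   and annotation-only universes).
#' @export
build_coupling_map <- function(A, B, annotations = NULL, k = 1.4,
                               subtypes = analysis_subtypes(panel),
                               panel = gprotein_panel()) {
  if (is.null(A$coupler)) A <- qc_filter(A, k, other = B, annotations = annotations, panel = panel)
  if (is.null(B$coupler)) B <- qc_filter(B, k, other = A, annotations = annotations, panel = panel)
  A_h <- harmonize_measurements(A)
  B_h <- harmonize_measurements(B)
  src <- c(unique(A$source)[1], unique(B$source)[1])
  if (anyNA(src) || src[1] == src[2]) stop("the two datasets must carry distinct source tokens")

  quant <- rbind(A_h, B_h)
  quant <- quant[quant$gprotein %in% subtypes, , drop = FALSE]
  receptors_quant <- sort(unique(quant$receptor))

  ann <- if (is.null(annotations)) {
    data.frame(receptor = character(0), family = character(0),
               rank = character(0), stringsAsFactors = FALSE)
  } else annotations
  ann_receptors <- unique(ann$receptor)
  ann_sub <- expand_annotation_to_subtypes(
    ann, subtypes = subtypes,
    receptors = union(receptors_quant, ann_receptors), panel = panel)

  key <- unique(quant[, c("receptor", "gprotein")])
  fam_of <- subtype_family(key$gprotein, panel)
  find <- function(h) {
    match(paste(key$receptor, key$gprotein),
          paste(h$receptor, h$gprotein))
  }
  ia <- find(A_h); ib <- find(B_h)
  ev <- data.frame(
    receptor = key$receptor, gprotein = key$gprotein, family = fam_of,
    tested_a = !is.na(ia), tested_b = !is.na(ib),
    coupler_a = !is.na(ia) & A_h$coupler[ia],
    coupler_b = !is.na(ib) & B_h$coupler[ib],
    value_a = ifelse(!is.na(ia), A_h$log_emax_ec50[ia], NA_real_),
    value_b = ifelse(!is.na(ib), B_h$log_emax_ec50[ib], NA_real_),
    stringsAsFactors = FALSE
  )
  ev$annotation_tested <- ev$receptor %in% ann_receptors
  ev$annotated <- ann_sub[cbind(ev$receptor, ev$gprotein)]

  labels <- character(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    lab <- classify_evidence(
      tested_by = src[c(ev$tested_a[i], ev$tested_b[i])],
      coupler_in = src[c(ev$coupler_a[i], ev$coupler_b[i])],
      annotated = ev$annotated[i],
      annotation_tested = ev$annotation_tested[i]
    )
    labels[i] <- paste(lab, collapse = ";")
  }
  ev$labels <- labels
  ev$supported <- grepl("(^|;)supported(;|$)", labels)
  ev$novel <- grepl("(^|;)novel(;|$)", labels)
  ev$support_count <- ev$coupler_a + ev$coupler_b +
    (ev$annotated & (ev$coupler_a | ev$coupler_b | !(ev$tested_a | ev$tested_b)))
  # map value: mean over quantitative coupling sources only (never averaged
  # with zeros from a non-coupling source)
  vals <- cbind(ifelse(ev$coupler_a, ev$value_a, NA),
                ifelse(ev$coupler_b, ev$value_b, NA))
  ev$map_value <- rowMeans(vals, na.rm = TRUE)
  ev$map_value[is.nan(ev$map_value)] <- NA_real_

  annotation_only <- ann[!(ann$receptor %in% receptors_quant), , drop = FALSE]
  rownames(annotation_only) <- NULL

  structure(
    list(evidence = ev,
         entries = ev[ev$supported & (ev$coupler_a | ev$coupler_b), , drop = FALSE],
         annotation_only = annotation_only,
         annotations = ann,
         sources = src, k = k, subtypes = subtypes,
         receptors = list(
           quantitative = receptors_quant,
           annotation_only = sort(setdiff(ann_receptors, receptors_quant)),
           all = sort(union(receptors_quant, ann_receptors))
         ),
         panel = panel),
    class = "coupling_map"
  )
}

#' @export
print.coupling_map <- function(x, ...) {
  cat("Unified GPCR-G protein coupling map\n")
  cat(sprintf("  sources: %s + %s + %s\n", x$sources[1], x$sources[2],
              if (nrow(x$annotations)) "literature annotation" else "(no annotation)"))
  cat(sprintf("  detection threshold: Emax > basal + %.1f SD\n", x$k))
  cat(sprintf("  receptors: %d quantitative, %d annotation-only\n",
              length(x$receptors$quantitative),
              length(x$receptors$annotation_only)))
  cat(sprintf("  supported quantitative couplings: %d (of %d tested cells)\n",
              nrow(x$entries), nrow(x$evidence)))
  invisible(x)
}

#' @export
summary.coupling_map <- function(object, ...) {
  nov <- find_novel(object)
  prom <- promiscuity_distribution(object)
  out <- list(map = object, novel = nov, promiscuity = prom)
  class(out) <- "summary.coupling_map"
  out
}

#' @export
print.summary.coupling_map <- function(x, ...) {
  print(x$map)
  cat(sprintf("  novel couplings: %d across %d receptors\n",
              x$novel$n_couplings, x$novel$n_receptors))
  cat(sprintf("  families per receptor: mean %.2f; 1/2/3/4-family counts: %s\n",
              x$promiscuity$mean_families,
              paste(x$promiscuity$counts, collapse = "/")))
  invisible(x)
}

#' Heatmap of the quantitative section of a coupling map
#'
#' @param x coupling_map
#' @param ... passed to [graphics::image()]
#' @return Invisibly, the plotted receptor x subtype value matrix.
#' @export
plot.coupling_map <- function(x, ...) {
  e <- x$entries
  m <- matrix(NA_real_, length(x$receptors$quantitative), length(x$subtypes),
              dimnames = list(x$receptors$quantitative, x$subtypes))
  m[cbind(e$receptor, e$gprotein)] <- e$map_value
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m), axes = FALSE,
                  xlab = "G protein", ylab = "receptor",
                  main = "Supported couplings, log(Emax/EC50)", ...)
  graphics::axis(1, seq_len(ncol(m)), colnames(m), las = 2, cex.axis = 0.7)
  invisible(m)
}

#' Novel couplings jointly supported by both quantitative sources
#'
#' @param map coupling_map
#' @return list(n_receptors, n_couplings, receptors, couplings,
#'   family_counts) where `family_counts` counts (receptor, family) pairs
#'   with at least one novel subtype (a family is novel-shared if at least
#'   one member subtype couples in both sources without annotation).
#' @export
find_novel <- function(map) {
  nv <- map$evidence[map$evidence$novel, , drop = FALSE]
  fam_pairs <- unique(nv[, c("receptor", "family")])
  fc <- table(factor(fam_pairs$family, levels = gprotein_families()))
  list(n_receptors = length(unique(nv$receptor)),
       n_couplings = nrow(nv),
       receptors = sort(unique(nv$receptor)),
       couplings = nv[, c("receptor", "gprotein", "family", "map_value")],
       family_counts = fc)
}

#' Literature annotations contradicted by both quantitative sources
#'
#' An annotated family coupling is contradicted when both quantitative
#' sources tested the family (at least one member subtype each) and every
#' tested member subtype fell below the detection threshold in both.
#'
#' @param map coupling_map
#' @return data.frame(receptor, family) of contradicted annotations.
#' @export
find_contradicted_annotations <- function(map) {
  ann <- map$annotations
  out <- list()
  for (i in seq_len(nrow(ann))) {
    ev <- map$evidence[map$evidence$receptor == ann$receptor[i] &
                         map$evidence$family == ann$family[i], , drop = FALSE]
    if (!nrow(ev)) next
    tested_a <- any(ev$tested_a); tested_b <- any(ev$tested_b)
    if (tested_a && tested_b && !any(ev$coupler_a) && !any(ev$coupler_b)) {
      out[[length(out) + 1]] <- ann[i, c("receptor", "family")]
    }
  }
  if (!length(out)) {
    return(data.frame(receptor = character(0), family = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Unique and missing couplings per source and G protein
#'
#' Over a common receptor set (all receptors count in the denominator,
#' including non-couplers), reports for each quantitative source and subtype
#' the percentage of receptors with a coupling unique to that source
#' (positive) and the percentage missed by it (negative).
#'
#' @param map coupling_map
#' @param common_receptors receptors present in all compared sources
#' @return data.frame(source, gprotein, pct_unique, pct_missing).
#' @export
unique_missing_summary <- function(map, common_receptors) {
  ev <- map$evidence[map$evidence$receptor %in% common_receptors, , drop = FALSE]
  n <- length(common_receptors)
  rows <- list()
  for (s in map$sources) {
    uniq_lab <- paste0("unique:", s)
    miss_lab <- paste0("missing:", s)
    for (g in map$subtypes) {
      sub <- ev[ev$gprotein == g, , drop = FALSE]
      has <- function(lab) sum(vapply(
        strsplit(sub$labels, ";"), function(l) lab %in% l, logical(1)))
      rows[[length(rows) + 1]] <- data.frame(
        source = s, gprotein = g,
        pct_unique = 100 * has(uniq_lab) / n,
        pct_missing = -100 * has(miss_lab) / n,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
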