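## End-to-end pipeline driver, coverage summary and run manifest.

#' Run the full coupling-map pipeline
#'
#' Executes ingest -> QC filtering -> detection threshold (fixed or optimized
#' by cross-dataset agreement) -> harmonization -> map assembly ->
#' selectivity and co-coupling statistics. Inputs may be measurement
#' data.frames or paths to canonical TSVs. Deterministic given identical
#' inputs; when `outdir` is set the TSV/JSON bundle (including the run
#' manifest) is written there.
#'
#' @param A,B quantitative measurement tables (data.frame or TSV path)
#' @param annotations annotation records (data.frame or TSV path), optional
#' @param k detection threshold in basal-SD units, or "optimize" to grid
#'   search 0-3 by 0.1 on cross-dataset agreement
#' @param receptors_cocoupling optional receptor subset for the co-coupling
#'   matrices (the reference analysis restricts to one receptor class)
#' @param outdir optional output directory for the TSV/JSON bundle
#' @param panel G protein panel
#' @return list(map, k, cutoff_curve, agreement, coverage, selectivity,
#'   cocoupling, manifest).
#' @export
run_pipeline <- function(A, B, annotations = NULL, k = 1.4,
                         receptors_cocoupling = NULL, outdir = NULL,
                         panel = gprotein_panel()) {
  if (is.character(A)) A <- read_quantitative_table(A, panel = panel)
  if (is.character(B)) B <- read_quantitative_table(B, panel = panel)
  if (is.character(annotations)) annotations <- read_annotation_table(annotations)

  cutoff_curve <- NULL
  A_q <- qc_filter(A, k = 0, other = B, annotations = annotations, panel = panel)
  B_q <- qc_filter(B, k = 0, other = A, annotations = annotations, panel = panel)
  if (identical(k, "optimize")) {
    opt <- optimize_sd_cutoff(A_q, B_q, panel = panel)
    k <- opt$k_star
    cutoff_curve <- opt$curve
  }
  A_q <- apply_sd_cutoff(A_q, k)
  B_q <- apply_sd_cutoff(B_q, k)

  map <- build_coupling_map(A_q, B_q, annotations, k = k, panel = panel)

  ga <- coupling_grid(A_q); gb <- coupling_grid(B_q)
  agreement <- list(
    subtype = pairwise_agreement(ga, gb),
    family = pairwise_agreement(family_grid(ga, panel), family_grid(gb, panel))
  )
  if (!is.null(annotations) && nrow(map$annotations)) {
    gann <- annotation_family_grid(map$annotations,
                                   receptors = map$receptors$all)
    agreement$threeway_family <- tryCatch(
      threeway_agreement(family_grid(ga, panel), family_grid(gb, panel), gann),
      error = function(e) NULL)
  }

  selectivity <- list(
    promiscuity = promiscuity_distribution(map),
    coverage = gprotein_coverage(map),
    within_family = within_family_promiscuity(map, panel),
    venn_family = map_venn(map, "family", panel)
  )
  cocoupling <- cocoupling_matrices(map, receptors_cocoupling)
  coverage <- summarize_coverage(A_q, B_q, map$annotations, panel = panel)

  manifest <- list(
    package_version = as.character(utils::packageVersion("couplemap")),
    sources = map$sources,
    k = k, k_optimized = !is.null(cutoff_curve),
    universes = list(
      quantitative = length(map$receptors$quantitative),
      annotation_only = length(map$receptors$annotation_only),
      all = length(map$receptors$all)
    ),
    counts = list(
      tested_cells = nrow(map$evidence),
      supported = nrow(map$entries),
      novel = find_novel(map)$n_couplings
    )
  )
  bundle <- list(map = map, k = k, cutoff_curve = cutoff_curve,
                 agreement = agreement, coverage = coverage,
                 selectivity = selectivity, cocoupling = cocoupling,
                 manifest = manifest)
  if (!is.null(outdir)) write_bundle(bundle, outdir)
  bundle
}

#' Write a pipeline bundle to disk
#'
#' Emits the evidence and entries tables, the agreement curve (when the
#' threshold was optimized), the co-coupling matrices as TSV, the correlation
#' tree as Newick, and the run manifest as JSON.
#'
#' @param bundle list from [run_pipeline()]
#' @param outdir output directory (created if missing)
#' @return Invisibly, the manifest path.
#' @export
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) utils::write.table(
    df, file.path(outdir, name), sep = "\t", row.names = FALSE, quote = FALSE)
  w(bundle$map$evidence, "evidence.tsv")
  w(bundle$map$entries, "map_entries.tsv")
  if (nrow(bundle$map$annotation_only)) w(bundle$map$annotation_only, "annotation_only.tsv")
  if (!is.null(bundle$cutoff_curve)) w(bundle$cutoff_curve, "cutoff_curve.tsv")
  wm <- function(m, name) utils::write.table(
    data.frame(gprotein = rownames(m), m, check.names = FALSE),
    file.path(outdir, name), sep = "\t", row.names = FALSE, quote = FALSE)
  wm(bundle$cocoupling$pearson_r, "cocoupling_pearson.tsv")
  wm(bundle$cocoupling$jaccard, "cocoupling_jaccard.tsv")
  wm(bundle$cocoupling$activation_diff, "cocoupling_activation_diff.tsv")
  if (!is.null(bundle$cocoupling$tree)) {
    tree_newick(bundle$cocoupling$tree, file.path(outdir, "cocoupling_tree.nwk"))
  }
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(bundle$manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest_path)
}

#' Coverage summary across datasets
#'
#' Receptor counts per source and their intersections, the fraction of
#' coupler cells per source at family level, the mean number of coupled
#' families per receptor, and each source's family share distribution.
#'
#' @param A_q,B_q thresholded measurement data.frames (with `coupler`)
#' @param annotations annotation records (may have zero rows)
#' @param panel G protein panel
#' @return list(n_receptors, intersections, pct_coupler_cells,
#'   mean_families_per_receptor, family_share).
#' @export
summarize_coverage <- function(A_q, B_q, annotations = NULL,
                               panel = gprotein_panel()) {
  if (is.null(annotations)) {
    annotations <- data.frame(receptor = character(0), family = character(0),
                              rank = character(0))
  }
  grids <- list(
    family_grid(coupling_grid(A_q), panel),
    family_grid(coupling_grid(B_q), panel)
  )
  names(grids) <- c(unique(A_q$source)[1], unique(B_q$source)[1])
  if (nrow(annotations)) grids$annotation <- annotation_family_grid(annotations)

  recs <- lapply(grids, rownames)
  stats_per <- lapply(grids, function(g) {
    tested <- !is.na(g)
    coup <- g %in% TRUE & tested
    dim(coup) <- dim(g)
    list(n_receptors = nrow(g),
         pct_coupler = 100 * sum(coup) / sum(tested),
         mean_families = mean(rowSums(coup)),
         family_share = colSums(coup) / max(sum(coup), 1))
  })
  list(
    n_receptors = vapply(stats_per, `[[`, numeric(1), "n_receptors"),
    union_receptors = length(Reduce(union, recs)),
    common_receptors = Reduce(intersect, recs),
    pct_coupler_cells = vapply(stats_per, `[[`, numeric(1), "pct_coupler"),
    mean_families_per_receptor = vapply(stats_per, `[[`, numeric(1), "mean_families"),
    family_share = lapply(stats_per, `[[`, "family_share")
  )
}
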