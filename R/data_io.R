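## Canonical long-format ingest/egest for coupling measurements,
## literature annotations and tissue-expression tables.

.measurement_columns <- c("source", "receptor", "gprotein", "ligand",
                          "ligand_type", "ligand_shared", "pec50", "emax",
                          "basal_mean", "basal_sd", "curve_status",
                          "enzymatic_units", "exclusion")

.required_columns <- c("receptor", "gprotein", "pec50", "emax",
                       "basal_mean", "basal_sd")

.curve_statuses <- c("converged", "unconverged_approximate", "no_activity")

#' Read a quantitative coupling table
#'
#' Reads one measurement per (receptor, G protein) row from a long-format
#' TSV/CSV with the canonical column set. Rows with missing pEC50 or Emax are
#' recorded as `no_activity` (tested, no concentration-response detected).
#'
#' @param path file path (TSV by default; `sep` passes through)
#' @param source_id source token stamped on every record (overrides any
#'   `source` column)
#' @param panel G protein panel used to validate `gprotein` tokens; tokens
#'   may also be shedding-assay probe ids (e.g. "Gi1-2")
#' @param sep field separator (default tab)
#' @return data.frame of coupling measurements with the canonical columns.
#' @seealso [write_coupling_table()], [as_coupling_measurements()]
#' @export
read_quantitative_table <- function(path, source_id = NULL,
                                    panel = gprotein_panel(), sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""), quote = "\"")
  as_coupling_measurements(df, source_id = source_id, panel = panel)
}

#' Coerce a data.frame to canonical coupling measurements
#'
#' Validates the schema, fills optional columns with defaults, assigns
#' `curve_status = "no_activity"` where pEC50 or Emax is missing, and checks
#' G protein tokens against the panel (probe tokens are accepted).
#'
#' @inheritParams read_quantitative_table
#' @param df input data.frame
#' @return Canonical measurement data.frame.
#' @export
as_coupling_measurements <- function(df, source_id = NULL,
                                     panel = gprotein_panel()) {
  missing_cols <- setdiff(.required_columns, names(df))
  if (length(missing_cols)) {
    stop("measurement table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!is.null(source_id)) df$source <- source_id
  if (is.null(df$source)) stop("no source column and no source_id given")
  if (is.null(df$ligand)) df$ligand <- NA_character_
  if (is.null(df$ligand_type)) df$ligand_type <- "endogenous"
  if (is.null(df$ligand_shared)) df$ligand_shared <- NA
  if (is.null(df$enzymatic_units)) df$enzymatic_units <- FALSE
  if (is.null(df$exclusion)) df$exclusion <- "none"
  if (is.null(df$curve_status)) df$curve_status <- "converged"

  known <- c(panel$subtype, stats::na.omit(unique(panel$inoue_probe)))
  bad <- setdiff(unique(df$gprotein), known)
  if (length(bad)) {
    stop("unknown G protein token(s) not in panel: ",
         paste(bad, collapse = ", "))
  }
  bad_status <- setdiff(unique(df$curve_status), .curve_statuses)
  if (length(bad_status)) {
    stop("invalid curve_status value(s): ", paste(bad_status, collapse = ", "))
  }

  no_act <- is.na(df$pec50) | is.na(df$emax)
  df$curve_status[no_act] <- "no_activity"
  df$pec50[df$curve_status == "no_activity"] <- NA_real_
  df$emax[df$curve_status == "no_activity"] <- NA_real_

  key <- paste(df$source, df$receptor, df$gprotein, sep = "\r")
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    stop("duplicated (source, receptor, gprotein) rows: ",
         paste(gsub("\r", "/", dups), collapse = "; "))
  }
  if (any(df$basal_sd < 0, na.rm = TRUE)) stop("negative basal_sd")

  df <- df[, .measurement_columns]
  rownames(df) <- NULL
  df
}

#' Write coupling measurements to the canonical TSV
#'
#' @param ms measurement data.frame
#' @param path output path
#' @return Invisibly, `path`. Write-then-read round-trips all fields.
#' @export
write_coupling_table <- function(ms, path) {
  utils::write.table(ms[, .measurement_columns], path, sep = "\t",
                     row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a literature annotation table
#'
#' One record per (receptor, G protein family) with a transducer rank.
#' Receptors absent from the table are "not annotated", which is distinct
#' from an annotated non-coupler (a receptor present in the table whose
#' family has no record).
#'
#' @param path TSV with columns receptor, family, rank
#' @param sep field separator
#' @return data.frame with columns receptor, family, rank.
#' @export
read_annotation_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  as_annotation_records(df)
}

#' Validate annotation records
#'
#' @param df data.frame with columns receptor, family, rank
#' @return Validated data.frame (possibly 0 rows).
#' @export
as_annotation_records <- function(df) {
  need <- c("receptor", "family", "rank")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("annotation table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) return(df[, need])
  bad <- setdiff(unique(df$rank), c("primary", "secondary"))
  if (length(bad)) {
    stop("invalid transducer rank(s): ", paste(bad, collapse = ", "))
  }
  bad_fam <- setdiff(unique(df$family), gprotein_families())
  if (length(bad_fam)) {
    stop("unknown G protein family token(s): ", paste(bad_fam, collapse = ", "))
  }
  key <- paste(df$receptor, df$family, sep = "\r")
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    stop("receptor annotated with more than one rank for a family: ",
         paste(gsub("\r", "/", dups), collapse = "; "))
  }
  rownames(df) <- NULL
  df[, need]
}

#' Expand family-level annotations to subtype level
#'
#' A family-level literature coupling makes every subtype of that family an
#' annotated-coupling-possible cell; every other subtype of a receptor that
#' appears in the annotation dataset is explicitly not annotated. Receptors
#' passed via `receptors` but absent from the records yield all-FALSE rows.
#'
#' @param records annotation data.frame (receptor, family, rank)
#' @param subtypes subtype universe (columns of the result)
#' @param receptors receptor universe (rows); defaults to annotated receptors
#' @param panel G protein panel
#' @return Logical matrix receptors x subtypes with no NA gaps.
#' @export
expand_annotation_to_subtypes <- function(records,
                                          subtypes = analysis_subtypes(panel),
                                          receptors = NULL,
                                          panel = gprotein_panel()) {
  if (is.null(receptors)) receptors <- sort(unique(records$receptor))
  fam_of <- subtype_family(subtypes, panel)
  m <- matrix(FALSE, length(receptors), length(subtypes),
              dimnames = list(receptors, subtypes))
  if (nrow(records)) {
    rec <- records[records$receptor %in% receptors, , drop = FALSE]
    for (i in seq_len(nrow(rec))) {
      m[rec$receptor[i], fam_of == rec$family[i]] <- TRUE
    }
  }
  m
}

#' Family-level annotation grid
#'
#' @inheritParams expand_annotation_to_subtypes
#' @return Logical matrix receptors x 4 families.
#' @export
annotation_family_grid <- function(records, receptors = NULL) {
  if (is.null(receptors)) receptors <- sort(unique(records$receptor))
  fams <- gprotein_families()
  m <- matrix(FALSE, length(receptors), length(fams),
              dimnames = list(receptors, fams))
  rec <- records[records$receptor %in% receptors, , drop = FALSE]
  if (nrow(rec)) m[cbind(rec$receptor, rec$family)] <- TRUE
  m
}

#' Read a consensus tissue-expression table
#'
#' Reads the Human Protein Atlas consensus-tissue dialect (columns Gene,
#' "Gene name", Tissue, nTPM) into a gene x tissue matrix.
#'
#' @param path TSV path
#' @param genes optional gene symbols to keep (row order of the result)
#' @return Numeric matrix, rows = gene names, cols = tissues, values = nTPM.
#' @export
read_expression_table <- function(path, genes = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "\"")
  need <- c("Gene name", "Tissue", "nTPM")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("expression table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(df$nTPM < 0)) stop("negative nTPM values")
  if (!is.null(genes)) df <- df[df$`Gene name` %in% genes, , drop = FALSE]
  gene <- df$`Gene name`
  tissue <- df$Tissue
  g <- if (is.null(genes)) sort(unique(gene)) else genes
  t <- unique(tissue)
  m <- matrix(NA_real_, length(g), length(t), dimnames = list(g, t))
  m[cbind(match(gene, g), match(tissue, t))] <- df$nTPM
  m
}
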