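#' G protein panel metadata
#'
#' Returns the panel of heterotrimeric G protein alpha subunits used
#' throughout the package: the 16 human subtypes grouped into the four
#' canonical families (Gs, Gi/o, Gq/11, G12/13), with the GoA/GoB isoform
#' split of GNAO1, per-source tested status for the two quantitative assay
#' platforms, and the chimeric-probe equivalence classes of the shedding
#' assay (identical C-terminal hexamers mean one measured probe stands for
#' several subtypes: Gi1/Gi2 (and the transducins/gustducin), GoA/GoB, and
#' Gq/G11).
#'
#' @return A data.frame with one row per panel entry and columns:
#'   \describe{
#'     \item{subtype}{panel token, including the GoA/GoB isoforms}
#'     \item{canonical}{canonical subtype (collapses GoA/GoB to Go); 16
#'       distinct values}
#'     \item{family}{one of "Gs", "Gi/o", "Gq/11", "G12/13"}
#'     \item{gene}{HGNC gene symbol (GNAS, GNAL, GNAI1-3, GNAO1, GNAZ,
#'       GNAT1-3, GNAQ, GNA11, GNA14, GNA15, GNA12, GNA13)}
#'     \item{bouvier}{logical, tested by the BRET effector-translocation
#'       platform}
#'     \item{inoue_probe}{token of the chimeric probe measuring this subtype
#'       in the shedding assay, or NA if untested}
#'   }
#' @examples
#' panel <- gprotein_panel()
#' table(panel$family[!duplicated(panel$canonical)])
#' @export
gprotein_panel <- function() {
  p <- data.frame(
    subtype = c("Gs", "Golf",
                "Gi1", "Gi2", "Gi3", "GoA", "GoB", "Gz", "Gt1", "Gt2", "Ggust",
                "Gq", "G11", "G14", "G15",
                "G12", "G13"),
    canonical = c("Gs", "Golf",
                  "Gi1", "Gi2", "Gi3", "Go", "Go", "Gz", "Gt1", "Gt2", "Ggust",
                  "Gq", "G11", "G14", "G15",
                  "G12", "G13"),
    family = c(rep("Gs", 2), rep("Gi/o", 9), rep("Gq/11", 4), rep("G12/13", 2)),
    gene = c("GNAS", "GNAL",
             "GNAI1", "GNAI2", "GNAI3", "GNAO1", "GNAO1", "GNAZ",
             "GNAT1", "GNAT2", "GNAT3",
             "GNAQ", "GNA11", "GNA14", "GNA15",
             "GNA12", "GNA13"),
    bouvier = c(TRUE, FALSE,
                TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE,
                TRUE, TRUE, TRUE, TRUE,
                TRUE, TRUE),
    inoue_probe = c("Gs", "Golf",
                    "Gi1-2", "Gi1-2", "Gi3", "Go", "Go", "Gz",
                    "Gi1-2", "Gi1-2", "Gi1-2",
                    "Gq", "Gq", "G14", "G15",
                    "G12", "G13"),
    stringsAsFactors = FALSE
  )
  p
}

#' Families of the G protein panel
#'
#' @return Character vector of the four family tokens, in canonical order.
#' @export
gprotein_families <- function() c("Gs", "Gi/o", "Gq/11", "G12/13")

#' Subtypes common to both quantitative assay platforms
#'
#' The 12 analysis subtypes measured by both large-scale screens:
#' Gs, Gi1, Gi2, GoA, GoB, Gz, Gq, G11, G14, G15, G12 and G13. Golf, Gi3 and
#' the sensory G proteins are excluded because only one platform probes them.
#'
#' @param panel panel data.frame from [gprotein_panel()]
#' @return Character vector of subtype tokens.
#' @export
analysis_subtypes <- function(panel = gprotein_panel()) {
  panel$subtype[panel$bouvier & !is.na(panel$inoue_probe)]
}

#' Map subtype tokens to families
#'
#' @param subtypes character vector of subtype tokens
#' @param panel panel data.frame
#' @return Character vector of family tokens, same length as `subtypes`.
#' @export
subtype_family <- function(subtypes, panel = gprotein_panel()) {
  idx <- match(subtypes, panel$subtype)
  if (anyNA(idx)) {
    stop("unknown G protein token(s): ",
         paste(unique(subtypes[is.na(idx)]), collapse = ", "))
  }
  panel$family[idx]
}

#' Members of a family within a subtype set
#'
#' @param family family token
#' @param subtypes subtype universe (default: the 12 analysis subtypes)
#' @param panel panel data.frame
#' @return Character vector of member subtypes.
#' @export
family_members <- function(family, subtypes = analysis_subtypes(panel),
                           panel = gprotein_panel()) {
  subtypes[subtype_family(subtypes, panel) == family]
}

#' Isoform pairing between the two quantitative sources
#'
#' The BRET platform measures the GoA and GoB isoforms of GNAO1 separately
#' while the shedding assay reports a single Go value; comparisons pair
#' GoA <-> Go and GoB <-> Go.
#'
#' @param subtype character vector of subtype tokens
#' @param panel panel data.frame
#' @return Canonical subtype tokens (GoA/GoB collapsed to Go).
#' @export
canonical_subtype <- function(subtype, panel = gprotein_panel()) {
  idx <- match(subtype, panel$subtype)
  if (anyNA(idx)) {
    stop("unknown G protein token(s): ",
         paste(unique(subtype[is.na(idx)]), collapse = ", "))
  }
  panel$canonical[idx]
}

#' Expand shedding-assay probe measurements to subtype equivalence classes
#'
#' Subtypes measured by a physically identical chimeric probe receive the
#' same measured value: the Gi1-2 probe stands for Gi1 and Gi2 (and, when in
#' the requested subtype set, the transducins and gustducin), the Go probe
#' for GoA and GoB, and the Gq probe for Gq and G11.
#'
#' @param ms measurement data.frame whose `gprotein` column holds probe
#'   tokens (see [gprotein_panel()] column `inoue_probe`)
#' @param subtypes subtype tokens to expand to (default: analysis set)
#' @param panel panel data.frame
#' @return Measurement data.frame with one row per (receptor, subtype);
#'   duplicated probe rows carry identical measured values.
#' @export
expand_probe_measurements <- function(ms, subtypes = analysis_subtypes(panel),
                                      panel = gprotein_panel()) {
  probe_of <- panel$inoue_probe[match(subtypes, panel$subtype)]
  if (anyNA(probe_of)) {
    stop("subtype(s) without a probe: ",
         paste(subtypes[is.na(probe_of)], collapse = ", "))
  }
  pieces <- lapply(seq_along(subtypes), function(i) {
    sub <- ms[ms$gprotein == probe_of[i], , drop = FALSE]
    if (nrow(sub)) sub$gprotein <- subtypes[i]
    sub
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
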