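## Inclusion/exclusion rules and the basal-SD detection threshold.

#' Shift pEC50 values recorded in enzymatic concentration units
#'
#' Ligands supplied by enzymatic activity (e.g. thrombin in mU/ml) yield
#' negative pEC50 values on the molar scale; a fixed offset (default 10)
#' moves them onto a comparable range, leaving all other records untouched.
#'
#' @param ms measurement data.frame
#' @param offset value added to pEC50 where `enzymatic_units` is TRUE
#' @return Measurement data.frame with shifted pEC50.
#' @export
shift_enzymatic_pec50 <- function(ms, offset = 10) {
  flag <- ms$enzymatic_units %in% TRUE & !is.na(ms$pec50)
  ms$pec50[flag] <- ms$pec50[flag] + offset
  ms$enzymatic_units[flag] <- FALSE
  ms
}

#' Remove responses equivalent to endogenous receptor expression
#'
#' Drops records flagged `exclusion == "endogenous_equivalent"` (responses of
#' overexpressed receptors indistinguishable from the endogenously expressed
#' receptor's response).
#'
#' @param ms measurement data.frame
#' @return Filtered data.frame; attribute `n_excluded` records the count.
#' @export
apply_exclusions <- function(ms) {
  drop <- ms$exclusion %in% "endogenous_equivalent"
  out <- ms[!drop, , drop = FALSE]
  if (all(drop) && nrow(ms)) {
    warning("all measurements flagged endogenous_equivalent; empty output")
  }
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(drop)
  out
}

#' Build a cross-support lookup for unconverged curves
#'
#' For every (receptor, gprotein) pair, records whether another quantitative
#' source supports the coupling (a converged curve for the pair) or
#' contradicts it (the pair was tested and showed no activity), and whether
#' the receptor's family is annotated in the literature dataset. The lookup
#' always covers every requested pair: "untested elsewhere" is an explicit
#' state (neither supported nor contradicted).
#'
#' @param pairs data.frame with columns receptor, gprotein (pairs to resolve)
#' @param other measurement data.frame of the other quantitative source
#' @param annotations optional annotation records (receptor, family, rank)
#' @param level "subtype" (default) matches pairs on the canonical subtype;
#'   "family" matches on the family
#' @param panel G protein panel
#' @return data.frame(receptor, gprotein, supported, contradicted).
#' @export
build_cross_support <- function(pairs, other, annotations = NULL,
                                level = c("subtype", "family"),
                                panel = gprotein_panel()) {
  level <- match.arg(level)
  unit <- function(g) {
    if (level == "family") subtype_family(g, panel) else canonical_subtype(g, panel)
  }
  other_unit <- unit(other$gprotein)
  other_active <- other$curve_status == "converged"
  supported <- contradicted <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    hit <- other$receptor == pairs$receptor[i] &
      other_unit == unit(pairs$gprotein[i])
    tested <- any(hit)
    active <- any(hit & other_active)
    supported[i] <- active
    contradicted[i] <- tested && !active
    if (!active && !is.null(annotations) && nrow(annotations)) {
      fam <- subtype_family(pairs$gprotein[i], panel)
      supported[i] <- any(annotations$receptor == pairs$receptor[i] &
                            annotations$family == fam)
    }
  }
  data.frame(receptor = pairs$receptor, gprotein = pairs$gprotein,
             supported = supported, contradicted = contradicted,
             stringsAsFactors = FALSE)
}

#' Resolve unconverged-curve measurements
#'
#' Measurements with only approximate Emax/pEC50 (the concentration-response
#' curve did not converge) are kept only if the coupling is supported
#' elsewhere (other quantitative source or literature annotation) and not
#' contradicted by the other quantitative source. Dropped records are
#' attached as the `dropped` attribute with a reason code.
#'
#' @param ms measurement data.frame
#' @param lookup cross-support data.frame from [build_cross_support()]; must
#'   cover every unconverged pair in `ms`
#' @return Measurement data.frame with unresolved approximate records removed
#'   (kept ones are relabelled `converged`).
#' @export
resolve_unconverged <- function(ms, lookup) {
  pending <- which(ms$curve_status == "unconverged_approximate")
  if (!length(pending)) {
    attr(ms, "dropped") <- ms[0, c("receptor", "gprotein")]
    return(ms)
  }
  idx <- match(paste(ms$receptor[pending], ms$gprotein[pending]),
               paste(lookup$receptor, lookup$gprotein))
  if (anyNA(idx)) {
    miss <- pending[is.na(idx)]
    stop("cross-support lookup is missing pair(s): ",
         paste(ms$receptor[miss], ms$gprotein[miss], sep = "-", collapse = ", "))
  }
  keep <- lookup$supported[idx] & !lookup$contradicted[idx]
  dropped <- ms[pending[!keep], c("receptor", "gprotein"), drop = FALSE]
  if (nrow(dropped)) {
    dropped$reason <- ifelse(lookup$contradicted[idx][!keep],
                             "contradicted_elsewhere", "unsupported")
  } else {
    dropped$reason <- character(0)
  }
  ms$curve_status[pending[keep]] <- "converged"
  out <- ms[-pending[!keep], , drop = FALSE]
  if (!length(pending[!keep])) out <- ms
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Apply the basal-SD detection threshold
#'
#' A measurement is a coupler iff a concentration-response was observed and
#' its raw Emax strictly exceeds `basal_mean + k * basal_sd`. Non-coupler
#' quantitative values are retained in the table but carry `coupler = FALSE`
#' so downstream quantitative analyses mask them.
#'
#' @param ms measurement data.frame
#' @param k threshold in basal-SD units (nonnegative; the integrated-map
#'   default elsewhere in the package is 1.4)
#' @return Measurement data.frame with a logical `coupler` column.
#' @export
apply_sd_cutoff <- function(ms, k) {
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 0) {
    stop("k must be a single nonnegative number")
  }
  active <- ms$curve_status != "no_activity" & !is.na(ms$emax)
  ms$coupler <- active & (ms$emax > ms$basal_mean + k * ms$basal_sd)
  ms
}

#' Full QC filter chain
#'
#' Applies, in order: endogenous-equivalent exclusions, unconverged-curve
#' resolution (if a lookup or other source is given), the enzymatic-units
#' pEC50 shift, and the basal-SD cut-off. The chain is idempotent: running
#' it a second time on its own output changes nothing.
#'
#' @param ms measurement data.frame
#' @param k basal-SD threshold
#' @param other optional other-source measurements for cross-support
#' @param annotations optional annotation records for cross-support
#' @param offset enzymatic pEC50 offset
#' @param panel G protein panel
#' @return Measurement data.frame with `coupler` column.
#' @export
qc_filter <- function(ms, k = 1.4, other = NULL, annotations = NULL,
                      offset = 10, panel = gprotein_panel()) {
  ms <- apply_exclusions(ms)
  pending <- ms$curve_status == "unconverged_approximate"
  if (any(pending)) {
    if (is.null(other)) {
      stop("unconverged records present but no cross-support source given")
    }
    lookup <- build_cross_support(ms[pending, c("receptor", "gprotein")],
                                  other, annotations, panel = panel)
    ms <- resolve_unconverged(ms, lookup)
  }
  ms <- shift_enzymatic_pec50(ms, offset)
  apply_sd_cutoff(ms, k)
}
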