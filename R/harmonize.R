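## Emax normalization, the combined log(Emax/EC50) activity value,
## member-to-family aggregation, and normalization-protocol evaluation.

#' Min-max normalize Emax within each (source, G protein)
#'
#' The normalized quantity is the agonist-induced signal over basal
#' (`emax - basal_mean`); the minimum is fixed at 0 (the no-agonist signal)
#' and the maximum is the largest coupler signal for that G protein across
#' receptors, which maps to exactly 1. Non-couplers get NA.
#'
#' @param ms measurement data.frame with `coupler` column
#' @return `ms` with an added `emax_frac` column in (0, 1] for couplers.
#' @export
minmax_normalize_emax <- function(ms) {
  if (is.null(ms$coupler)) stop("run apply_sd_cutoff() first")
  net <- ms$emax - ms$basal_mean
  ms$emax_frac <- NA_real_
  for (grp in split(seq_len(nrow(ms)), list(ms$source, ms$gprotein), drop = TRUE)) {
    cpl <- grp[ms$coupler[grp]]
    if (!length(cpl)) next
    top <- max(net[cpl])
    if (top <= 0) {
      warning("all coupler responses <= basal for ", ms$gprotein[cpl[1]],
              " in ", ms$source[cpl[1]], "; normalization undefined")
      next
    }
    ms$emax_frac[cpl] <- net[cpl] / top
  }
  ms
}

#' Combined efficacy-potency value log(Emax/EC50)
#'
#' With Emax as a fraction of the per-G-protein maximum, the combined value is
#' `log10(emax_frac) + pec50`; it equals pEC50 iff the Emax fraction is 1 and
#' is strictly increasing in both arguments.
#'
#' @param emax_frac Emax fraction in (0, 1]
#' @param pec50 -log10 molar EC50
#' @return Numeric vector; NA inputs propagate.
#' @export
log_emax_ec50 <- function(emax_frac, pec50) {
  ok <- !is.na(emax_frac)
  if (any(emax_frac[ok] <= 0 | emax_frac[ok] > 1)) {
    stop("emax_frac must lie in (0, 1]; a zero fraction is a non-coupler")
  }
  log10(emax_frac) + pec50
}

#' Harmonize one or more thresholded measurement tables
#'
#' Adds `emax_frac` (min-max normalized per source x G protein) and
#' `log_emax_ec50` columns; both are NA for non-couplers.
#'
#' @param ms measurement data.frame with `coupler` column
#' @return Harmonized measurement data.frame.
#' @export
harmonize_measurements <- function(ms) {
  ms <- minmax_normalize_emax(ms)
  ms$log_emax_ec50 <- NA_real_
  cpl <- which(ms$coupler & !is.na(ms$emax_frac))
  ms$log_emax_ec50[cpl] <- log_emax_ec50(ms$emax_frac[cpl], ms$pec50[cpl])
  ms
}

#' Aggregate subtype values to the family level
#'
#' With `rule = "max"` (the integrated-map default) the family value is the
#' maximum coupler subtype value, and the family's Emax fraction and pEC50 are
#' those of the argmax subtype. `rule = "mean"` averages coupler subtypes and
#' is provided for protocol evaluation. A family with no coupler subtype is a
#' non-coupler.
#'
#' @param h harmonized measurement data.frame (see [harmonize_measurements()])
#' @param rule "max" or "mean"
#' @param value column aggregated (default `log_emax_ec50`)
#' @param panel G protein panel
#' @return data.frame(source, receptor, gprotein = family token, family,
#'   emax_frac, pec50, value column, coupler) with one row per
#'   (source, receptor, family) tested.
#' @export
aggregate_to_family <- function(h, rule = c("max", "mean"),
                                value = "log_emax_ec50",
                                panel = gprotein_panel()) {
  rule <- match.arg(rule)
  fam <- subtype_family(h$gprotein, panel)
  idx <- split(seq_len(nrow(h)), list(h$source, h$receptor, fam), drop = TRUE)
  rows <- lapply(idx, function(i) {
    cpl <- i[h$coupler[i] & !is.na(h[[value]][i])]
    out <- data.frame(source = h$source[i[1]], receptor = h$receptor[i[1]],
                      gprotein = fam[i[1]], family = fam[i[1]],
                      emax_frac = NA_real_, pec50 = NA_real_,
                      coupler = length(cpl) > 0, stringsAsFactors = FALSE)
    out[[value]] <- NA_real_
    if (length(cpl)) {
      if (rule == "max") {
        top <- cpl[which.max(h[[value]][cpl])]
        out[[value]] <- h[[value]][top]
        out$emax_frac <- h$emax_frac[top]
        out$pec50 <- h$pec50[top]
      } else {
        out[[value]] <- mean(h[[value]][cpl])
        out$emax_frac <- mean(h$emax_frac[cpl])
        out$pec50 <- mean(h$pec50[cpl])
      }
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Symmetric similarity ratio of two positive values
#'
#' `min(x, y) / max(x, y)`: symmetric, scale-invariant and 1 iff the values
#' are equal, so averages over datapoints stay in (0, 1] regardless of which
#' source reports the larger value. Nonpositive pairs are undefined (NA).
#'
#' @param xa,xb positive numeric vectors
#' @return Numeric vector of ratios in (0, 1].
#' @export
similarity <- function(xa, xb) {
  out <- pmin(xa, xb) / pmax(xa, xb)
  bad <- !is.na(xa) & !is.na(xb) & (xa <= 0 | xb <= 0)
  out[bad] <- NA_real_
  out
}

#' Mean per-receptor squared linear correlation across units
#'
#' For each receptor with at least `min_n` common coupler datapoints, the
#' squared Pearson correlation of the two sources' values across G proteins
#' (or families); the summary is the unweighted mean over qualifying
#' receptors.
#'
#' @param pairs data.frame with columns receptor, a, b (paired values)
#' @param min_n minimum common datapoints per receptor (default 3)
#' @return list(mean_r2, per_receptor).
#' @export
receptorwise_r2 <- function(pairs, min_n = 3) {
  .groupwise_r2(pairs$receptor, pairs$a, pairs$b, min_n)
}

#' Mean per-G-protein squared linear correlation across receptors
#'
#' @param pairs data.frame with columns gprotein, a, b
#' @param min_n minimum common datapoints per G protein
#' @return list(mean_r2, per_unit).
#' @export
gproteinwise_r2 <- function(pairs, min_n = 3) {
  .groupwise_r2(pairs$gprotein, pairs$a, pairs$b, min_n)
}

.groupwise_r2 <- function(group, a, b, min_n) {
  per <- vapply(split(seq_along(group), group), function(i) {
    if (length(i) < min_n) return(NA_real_)
    if (stats::sd(a[i]) == 0 || stats::sd(b[i]) == 0) return(NA_real_)
    stats::cor(a[i], b[i])^2
  }, numeric(1))
  list(mean_r2 = mean(per, na.rm = TRUE), per_unit = per[!is.na(per)])
}

#' Paired common-coupler values between two harmonized sources
#'
#' Joins two harmonized tables on (receptor, gprotein) keeping cells where
#' both sources produced a coupler (quantitative comparisons never impute
#' zeros for non-couplers).
#'
#' @param A_h,B_h harmonized measurement data.frames
#' @param value value column to pair
#' @param receptors optional receptor subset
#' @return data.frame(receptor, gprotein, a, b).
#' @export
common_coupler_pairs <- function(A_h, B_h, value = "log_emax_ec50",
                                 receptors = NULL) {
  pick <- function(h) {
    keep <- h$coupler & !is.na(h[[value]])
    if (!is.null(receptors)) keep <- keep & h$receptor %in% receptors
    h[keep, c("receptor", "gprotein", value)]
  }
  a <- pick(A_h); b <- pick(B_h)
  m <- merge(a, b, by = c("receptor", "gprotein"), suffixes = c("_a", "_b"))
  data.frame(receptor = m$receptor, gprotein = m$gprotein,
             a = m[[paste0(value, "_a")]], b = m[[paste0(value, "_b")]],
             stringsAsFactors = FALSE)
}

.double_normalize <- function(h, value) {
  # second normalization: within each (source, receptor) across G proteins
  for (grp in split(seq_len(nrow(h)), list(h$source, h$receptor), drop = TRUE)) {
    cpl <- grp[h$coupler[grp] & !is.na(h[[value]][grp])]
    if (!length(cpl)) next
    top <- max(h[[value]][cpl])
    if (top > 0) h[[value]][cpl] <- h[[value]][cpl] / top
  }
  h
}

#' Evaluate candidate normalization protocols
#'
#' Scores each harmonization scheme (raw Emax over basal, min-max normalized
#' Emax, double-normalized Emax, raw pEC50, log(Emax/EC50); plus family
#' aggregation of the three pharmacological values by max and by mean) by the
#' mean similarity ratio over common coupler datapoints and the mean squared
#' linear correlation per receptor (across G proteins) and per G protein
#' (across receptors). The scheme used for the integrated map (min-max Emax +
#' raw pEC50 combined into log(Emax/EC50), family aggregation by max) is
#' flagged.
#'
#' @param A,B thresholded measurement data.frames (with `coupler`), already
#'   restricted upstream to the comparable receptor subset (same-agonist,
#'   single receptor class) and on a shared subtype vocabulary
#' @param receptors optional receptor subset
#' @param panel G protein panel
#' @return data.frame(scheme, level, aggregation, similarity, r2_receptor,
#'   r2_gprotein, selected).
#' @export
evaluate_protocols <- function(A, B, receptors = NULL,
                               panel = gprotein_panel()) {
  A_h <- harmonize_measurements(A)
  B_h <- harmonize_measurements(B)
  A_h$emax_net <- A_h$emax - A_h$basal_mean
  B_h$emax_net <- B_h$emax - B_h$basal_mean
  A_d <- .double_normalize(A_h, "emax_frac")
  B_d <- .double_normalize(B_h, "emax_frac")
  A_d$log_emax_ec50 <- log_emax_ec50(pmin(A_d$emax_frac, 1), A_d$pec50)
  B_d$log_emax_ec50 <- log_emax_ec50(pmin(B_d$emax_frac, 1), B_d$pec50)
  A_dp <- A_d; B_dp <- B_d
  A_dp$pec50 <- .double_norm_vec(A_d, "pec50")
  B_dp$pec50 <- .double_norm_vec(B_d, "pec50")

  score <- function(ha, hb, value, scheme, level, aggregation) {
    pr <- common_coupler_pairs(ha, hb, value, receptors)
    data.frame(
      scheme = scheme, level = level, aggregation = aggregation,
      similarity = mean(similarity(pr$a, pr$b), na.rm = TRUE),
      r2_receptor = receptorwise_r2(pr)$mean_r2,
      r2_gprotein = gproteinwise_r2(pr)$mean_r2,
      stringsAsFactors = FALSE
    )
  }

  rows <- list(
    score(A_h, B_h, "emax_net", "emax_raw", "subtype", "none"),
    score(A_h, B_h, "emax_frac", "emax_minmax", "subtype", "none"),
    score(A_d, B_d, "emax_frac", "emax_double_norm", "subtype", "none"),
    score(A_dp, B_dp, "pec50", "pec50_double_norm", "subtype", "none"),
    score(A_d, B_d, "log_emax_ec50", "log_emax_ec50_double_norm", "subtype", "none"),
    score(A_h, B_h, "pec50", "pec50", "subtype", "none"),
    score(A_h, B_h, "log_emax_ec50", "log_emax_ec50", "subtype", "none")
  )
  for (rule in c("max", "mean")) {
    fa <- aggregate_to_family(A_h, rule, panel = panel)
    fb <- aggregate_to_family(B_h, rule, panel = panel)
    rows <- c(rows, list(
      score(fa, fb, "emax_frac", "emax_minmax", "family", rule),
      score(fa, fb, "pec50", "pec50", "family", rule),
      score(fa, fb, "log_emax_ec50", "log_emax_ec50", "family", rule)
    ))
  }
  out <- do.call(rbind, rows)
  out$selected <- out$scheme == "log_emax_ec50" &
    (out$level == "subtype" | out$aggregation == "max")
  rownames(out) <- NULL
  out
}

.double_norm_vec <- function(h, value) {
  v <- h[[value]]
  for (grp in split(seq_len(nrow(h)), list(h$source, h$receptor), drop = TRUE)) {
    cpl <- grp[h$coupler[grp] & !is.na(v[grp])]
    if (!length(cpl)) next
    top <- max(v[cpl])
    if (top > 0) v[cpl] <- v[cpl] / top
  }
  v
}
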