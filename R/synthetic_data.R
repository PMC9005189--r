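## Seeded generators: ground-truth couplomes, simulated biosensor assays and
## biased literature annotation, so the whole pipeline can be validated
## against known truth without any external download.

#' Default ground-truth couplome parameters
#'
#' Family coupling prevalences follow the reference family coverage fractions
#' (Gs 0.34, Gi/o 0.69, Gq/11 0.52, G12/13 0.19); a coupled family activates
#' each member subtype with probability 0.75 (at least one member always
#' couples); pEC50 ~ Normal(7, 1); the Emax fraction is drawn from a mixture
#' with a 15% weak-coupling tail (0.05-0.3) and a 85% main component
#' (0.3-1), emulating the weak couplings that sit near assay detection
#' limits.
#'
#' @param n_receptors number of receptors
#' @return Parameter list for [generate_truth()].
#' @export
default_truth_params <- function(n_receptors = 300) {
  list(
    n_receptors = n_receptors,
    family_prevalence = c("Gs" = 0.34, "Gi/o" = 0.69,
                          "Gq/11" = 0.52, "G12/13" = 0.19),
    member_prob = 0.75,
    pec50_mean = 7, pec50_sd = 1,
    weak_tail_prob = 0.15,
    weak_range = c(0.05, 0.3),
    main_range = c(0.3, 1)
  )
}

#' Generate a ground-truth couplome
#'
#' Draws family couplings per receptor from the family prevalences, member
#' subtypes conditionally on the family (with at least one member forced),
#' and true pEC50/Emax values for couplers. Bit-reproducible given the seed.
#' The expected mean number of coupled families per receptor is the sum of
#' the prevalences.
#'
#' @param params list from [default_truth_params()]
#' @param seed integer seed
#' @param subtypes subtype universe (default: 12 analysis subtypes)
#' @param panel G protein panel
#' @return Object of class `synthetic_truth`: list(couplome (logical
#'   receptor x subtype matrix), family_couplome, pec50, emax_frac, params,
#'   seed).
#' @export
generate_truth <- function(params = default_truth_params(), seed = 1,
                           subtypes = analysis_subtypes(panel),
                           panel = gprotein_panel()) {
  pv <- params$family_prevalence
  if (any(pv < 0 | pv > 1) || params$member_prob < 0 || params$member_prob > 1) {
    stop("probabilities must lie in [0, 1]")
  }
  set.seed(seed)
  n <- params$n_receptors
  receptors <- sprintf("R%04d", seq_len(n))
  fams <- gprotein_families()
  fam_of <- subtype_family(subtypes, panel)

  fam_cpl <- matrix(stats::runif(n * length(fams)) < rep(pv[fams], each = n),
                    n, length(fams), dimnames = list(receptors, fams))
  couplome <- matrix(FALSE, n, length(subtypes),
                     dimnames = list(receptors, subtypes))
  for (f in fams) {
    members <- which(fam_of == f)
    if (!length(members)) next
    on <- which(fam_cpl[, f])
    if (!length(on)) next
    draw <- matrix(stats::runif(length(on) * length(members)) < params$member_prob,
                   length(on), length(members))
    none <- rowSums(draw) == 0
    if (any(none)) {
      forced <- sample.int(length(members), sum(none), replace = TRUE)
      draw[cbind(which(none), forced)] <- TRUE
    }
    couplome[on, members] <- draw
  }
  fam_cpl <- do.call(cbind, lapply(fams, function(f) {
    rowSums(couplome[, fam_of == f, drop = FALSE]) > 0
  }))
  dimnames(fam_cpl) <- list(receptors, fams)

  pec50 <- emax <- matrix(NA_real_, n, length(subtypes),
                          dimnames = list(receptors, subtypes))
  k <- sum(couplome)
  pec50[couplome] <- stats::rnorm(k, params$pec50_mean, params$pec50_sd)
  weak <- stats::runif(k) < params$weak_tail_prob
  e <- numeric(k)
  e[weak] <- stats::runif(sum(weak), params$weak_range[1], params$weak_range[2])
  e[!weak] <- stats::runif(sum(!weak), params$main_range[1], params$main_range[2])
  emax[couplome] <- e

  structure(list(couplome = couplome, family_couplome = fam_cpl,
                 pec50 = pec50, emax_frac = emax,
                 params = params, seed = seed, subtypes = subtypes),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("Synthetic couplome: %d receptors x %d subtypes, %d couplings\n",
              nrow(x$couplome), ncol(x$couplome), sum(x$couplome)))
  cat(sprintf("  mean families per receptor: %.2f (expected %.2f)\n",
              mean(rowSums(x$family_couplome)),
              sum(x$params$family_prevalence)))
  invisible(x)
}

#' Assay model for the simulated biosensor screens
#'
#' Describes one simulated platform: per-G-protein raw signal windows
#' (smaller windows emulate low signal-to-noise G proteins such as Gs and G12
#' on the BRET platform), per-G-protein detection sensitivity, basal signal
#' statistics, measurement noise on pEC50 and Emax, a raw-signal detection
#' floor, and a rate of spurious sub-threshold responses in true non-coupler
#' cells (the weak false signals that the basal-SD cut-off exists to remove).
#'
#' @param source_id source token stamped on simulated records
#' @param window named or scalar raw-units window (signal at Emax fraction 1)
#' @param sensitivity named or scalar detection probability in [0, 1]
#' @param basal_mean,basal_sd basal signal statistics (raw units)
#' @param pec50_noise_sd SD of additive pEC50 noise
#' @param emax_noise_frac multiplicative Emax noise SD (fraction of signal)
#' @param detection_floor raw-units signal below which no activity is called
#' @param spurious_rate probability a true non-coupler cell shows a weak
#'   converged response
#' @param spurious_sds_range spurious response size range in basal-SD units
#' @param basal_sd_jitter per-record multiplicative range on `basal_sd`
#'   (interday variability varies across receptor/G protein pairs)
#' @param mimic_chimera if TRUE, subtype pairs measured by one physical probe
#'   (Gi1/Gi2, GoA/GoB, Gq/G11) report duplicated values
#' @return Assay model list.
#' @export
assay_model <- function(source_id,
                        window = c(default = 100, Gs = 40, G12 = 40),
                        sensitivity = 1,
                        basal_mean = 100, basal_sd = 2,
                        pec50_noise_sd = 0.1, emax_noise_frac = 0.05,
                        detection_floor = 0,
                        spurious_rate = 0.05,
                        spurious_sds_range = c(0.2, 1.2),
                        basal_sd_jitter = c(0.8, 1.2),
                        mimic_chimera = FALSE) {
  if (any(window[!is.na(window)] <= 0)) stop("window must be positive")
  if (any(sensitivity < 0 | sensitivity > 1)) stop("sensitivity must lie in [0, 1]")
  list(source_id = source_id, window = window, sensitivity = sensitivity,
       basal_mean = basal_mean, basal_sd = basal_sd,
       pec50_noise_sd = pec50_noise_sd, emax_noise_frac = emax_noise_frac,
       detection_floor = detection_floor, spurious_rate = spurious_rate,
       spurious_sds_range = spurious_sds_range,
       basal_sd_jitter = basal_sd_jitter, mimic_chimera = mimic_chimera)
}

.per_gprotein <- function(x, subtypes) {
  if (length(x) == 1 && is.null(names(x))) {
    return(stats::setNames(rep(x, length(subtypes)), subtypes))
  }
  out <- stats::setNames(rep(unname(x["default"]), length(subtypes)), subtypes)
  if (is.na(out[1]) && !"default" %in% names(x)) out[] <- NA
  hit <- intersect(names(x), subtypes)
  out[hit] <- x[hit]
  if (anyNA(out)) stop("window/sensitivity missing for some subtypes and no default")
  out
}

#' Simulate one biosensor assay over a ground-truth couplome
#'
#' True couplers produce `emax = basal + window * emax_frac * (1 + noise)`
#' with a noisy pEC50, detected with the model's per-G-protein sensitivity
#' and dropped to `no_activity` under the detection floor. True non-couplers
#' are reported as `no_activity` except for spurious weak responses below the
#' configured basal-SD range. Bit-reproducible given the seed.
#'
#' @param truth synthetic_truth object
#' @param model assay model from [assay_model()]
#' @param seed integer seed
#' @return Canonical coupling-measurement data.frame (one row per tested
#'   receptor x subtype).
#' @export
simulate_assay <- function(truth, model, seed = 1) {
  set.seed(seed)
  subtypes <- truth$subtypes
  win <- .per_gprotein(model$window, subtypes)
  sens <- .per_gprotein(model$sensitivity, subtypes)
  receptors <- rownames(truth$couplome)
  grid <- expand.grid(receptor = receptors, gprotein = subtypes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(grid)
  idx <- cbind(match(grid$receptor, receptors), match(grid$gprotein, subtypes))
  is_cpl <- truth$couplome[idx]
  basal_sd <- model$basal_sd *
    stats::runif(n, model$basal_sd_jitter[1], model$basal_sd_jitter[2])
  pec50 <- rep(NA_real_, n)
  emax <- rep(NA_real_, n)
  status <- rep("no_activity", n)

  detected <- is_cpl & (stats::runif(n) < sens[grid$gprotein])
  if (any(detected)) {
    signal <- win[grid$gprotein[detected]] * truth$emax_frac[idx][detected] *
      (1 + stats::rnorm(sum(detected), 0, model$emax_noise_frac))
    signal <- pmax(signal, 0)
    ok <- signal >= model$detection_floor & signal > 0
    di <- which(detected)[ok]
    emax[di] <- model$basal_mean + signal[ok]
    pec50[di] <- truth$pec50[idx][di] +
      stats::rnorm(length(di), 0, model$pec50_noise_sd)
    status[di] <- "converged"
  }
  spurious <- !is_cpl & (stats::runif(n) < model$spurious_rate)
  if (any(spurious)) {
    sds <- stats::runif(sum(spurious), model$spurious_sds_range[1],
                        model$spurious_sds_range[2])
    emax[spurious] <- model$basal_mean + sds * basal_sd[spurious]
    pec50[spurious] <- stats::rnorm(sum(spurious), 5.5, 0.8)
    status[spurious] <- "converged"
  }

  ms <- data.frame(
    source = model$source_id,
    receptor = grid$receptor, gprotein = grid$gprotein,
    ligand = paste0("L_", grid$receptor), ligand_type = "endogenous",
    ligand_shared = TRUE,
    pec50 = pec50, emax = emax,
    basal_mean = model$basal_mean, basal_sd = basal_sd,
    curve_status = status, enzymatic_units = FALSE, exclusion = "none",
    stringsAsFactors = FALSE
  )
  if (isTRUE(model$mimic_chimera)) {
    for (pair in list(c("Gi1", "Gi2"), c("GoA", "GoB"), c("Gq", "G11"))) {
      if (!all(pair %in% subtypes)) next
      from <- ms$gprotein == pair[1]
      to <- ms$gprotein == pair[2]
      cols <- c("pec50", "emax", "basal_sd", "curve_status")
      ms[to, cols] <- ms[from, cols][match(ms$receptor[to], ms$receptor[from]), ]
    }
  }
  ms
}

#' Simulate biased literature annotation of a couplome
#'
#' Each truly coupled (receptor, family) pair is annotated with a per-family
#' report probability (lower probabilities emulate families underrepresented
#' in literature, e.g. G12/13). Optionally the report probability is weighted
#' by the family's true activation strength so strong couplings are likelier
#' to be published. The family with the receptor's highest true Emax is
#' ranked primary, others secondary.
#'
#' @param truth synthetic_truth
#' @param report_prob named per-family probability (or scalar)
#' @param seed integer seed
#' @param activity_weighted logical; if TRUE the report probability is scaled
#'   by the family's maximum true Emax fraction
#' @param panel G protein panel
#' @return Annotation data.frame (receptor, family, rank).
#' @export
simulate_annotation <- function(truth, report_prob = c(
  "Gs" = 0.8, "Gi/o" = 0.8, "Gq/11" = 0.8, "G12/13" = 0.2),
  seed = 1, activity_weighted = FALSE, panel = gprotein_panel()) {
  if (any(report_prob < 0 | report_prob > 1)) stop("probabilities must lie in [0, 1]")
  set.seed(seed)
  fams <- gprotein_families()
  p <- if (length(report_prob) == 1) {
    stats::setNames(rep(report_prob, length(fams)), fams)
  } else report_prob[fams]
  fam_of <- subtype_family(truth$subtypes, panel)
  fam_strength <- sapply(fams, function(f) {
    cols <- truth$emax_frac[, fam_of == f, drop = FALSE]
    apply(cols, 1, function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  })
  rows <- list()
  for (r in rownames(truth$family_couplome)) {
    coupled <- fams[truth$family_couplome[r, ]]
    if (!length(coupled)) next
    strength <- fam_strength[r, coupled]
    prob <- p[coupled]
    if (activity_weighted) prob <- prob * strength
    reported <- coupled[stats::runif(length(coupled)) < prob]
    if (!length(reported)) next
    primary <- coupled[which.max(strength)]
    rows[[length(rows) + 1]] <- data.frame(
      receptor = r, family = reported,
      rank = ifelse(reported == primary, "primary", "secondary"),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(receptor = character(0), family = character(0),
                      rank = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-assay scenario with an injected detection threshold
#'
#' Builds a matched pair of simulated assays in which true couplings always
#' exceed `k_true` basal SDs (with a weak tail just above it) and spurious
#' non-coupler responses fall strictly below `k_true` SDs, independently in
#' the two sources. Scanning the SD cut-off on this pair recovers `k_true`:
#' below it, source-independent spurious responses disagree; above it,
#' boundary couplings drop out asymmetrically.
#'
#' @param k_true injected detection threshold in basal-SD units
#' @param n_receptors number of receptors
#' @param seed integer seed
#' @param spurious_rate spurious-response rate in non-coupler cells
#' @return list(truth, A, B) with two canonical measurement data.frames.
#' @export
threshold_scenario <- function(k_true = 2, n_receptors = 200, seed = 1,
                               spurious_rate = 0.3) {
  params <- default_truth_params(n_receptors)
  params$weak_range <- c(0.05, 0.3)
  truth <- generate_truth(params, seed = seed)
  basal_sd <- 2
  # window such that the weakest coupler sits just above k_true SDs
  window <- (k_true + 0.3) * basal_sd / params$weak_range[1]
  mk <- function(src, s) {
    # fixed basal SD so signal sizes in SD units are controlled
    m <- assay_model(src, window = window, basal_mean = 100,
                     basal_sd = basal_sd, pec50_noise_sd = 0.05,
                     emax_noise_frac = 0.03, spurious_rate = spurious_rate,
                     spurious_sds_range = c(0.2, k_true - 0.05),
                     basal_sd_jitter = c(1, 1))
    simulate_assay(truth, m, seed = s)
  }
  list(truth = truth, A = mk("assayA", seed + 1), B = mk("assayB", seed + 2),
       k_true = k_true)
}
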