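# Shared simulated scenarios, built once per test run.

.scenario_cache <- new.env(parent = emptyenv())

# Low-noise two-assay scenario with literature annotation: the default study
# conditions for end-to-end checks.
default_scenario <- function(n = 120, seed = 42) {
  key <- paste0("default_", n, "_", seed)
  if (!is.null(.scenario_cache[[key]])) return(.scenario_cache[[key]])
  truth <- generate_truth(default_truth_params(n), seed = seed)
  A <- simulate_assay(truth, assay_model("bouvier"), seed = seed + 1)
  B <- simulate_assay(truth, assay_model("inoue", window = 120), seed = seed + 2)
  ann <- simulate_annotation(truth, seed = seed + 3)
  sc <- list(truth = truth, A = A, B = B, ann = ann)
  .scenario_cache[[key]] <- sc
  sc
}

# Tiny hand-built measurement table (one source).
toy_measurements <- function(source = "src",
                             receptors = c("R1", "R2"),
                             gproteins = c("Gs", "Gq")) {
  grid <- expand.grid(receptor = receptors, gprotein = gproteins,
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  data.frame(
    source = source, receptor = grid$receptor, gprotein = grid$gprotein,
    ligand = "L", ligand_type = "endogenous", ligand_shared = TRUE,
    pec50 = 7, emax = 150, basal_mean = 100, basal_sd = 10,
    curve_status = "converged", enzymatic_units = FALSE, exclusion = "none",
    stringsAsFactors = FALSE
  )
}

# Coupling grid constructor for agreement toys.
toy_grid <- function(values, receptors, units) {
  matrix(values, nrow = length(receptors), ncol = length(units),
         dimnames = list(receptors, units))
}
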