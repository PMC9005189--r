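test_that("evidence patterns classify to the standard terminology", {
  # dual quantitative coupling without annotation: supported and novel
  expect_setequal(
    classify_evidence(c("bouvier", "inoue"), c("bouvier", "inoue"),
                      annotated = FALSE, annotation_tested = TRUE),
    c("supported", "novel"))
  # annotated coupling contradicted by both quantitative screens
  expect_setequal(
    classify_evidence(c("bouvier", "inoue"), character(0),
                      annotated = TRUE, annotation_tested = TRUE),
    c("unique:annotation", "missing:bouvier", "missing:inoue"))
  # single-source coupling untested elsewhere and unannotated
  expect_equal(
    classify_evidence("bouvier", "bouvier", FALSE, FALSE), "proposed")
  # annotation-only coupling self-supports
  expect_equal(
    classify_evidence(character(0), character(0), TRUE, TRUE), "supported")
  # annotation + one quantitative source: supported, and unique for neither
  expect_setequal(
    classify_evidence(c("bouvier", "inoue"), "bouvier", TRUE, TRUE),
    c("supported", "missing:inoue"))
  # coupler in one source while the other tested negative
  expect_setequal(
    classify_evidence(c("bouvier", "inoue"), "inoue", FALSE, FALSE),
    c("unique:inoue", "missing:bouvier"))
})

test_that("map values average the two sources and respect missing sources", {
  A <- toy_measurements("bouvier", "R1", "Gs")
  B <- toy_measurements("inoue", "R1", "Gs")
  # emax at the per-G-protein max in both sources -> emax_frac 1, value = pec50
  A$pec50 <- 7; B$pec50 <- 8
  map <- build_coupling_map(A, B, k = 0)
  expect_equal(map$entries$map_value, 7.5)
  expect_equal(map$entries$support_count, 2)

  # one source non-coupler: the coupling source's value is used, not averaged
  B2 <- B; B2$emax <- B2$basal_mean + 1   # below any positive threshold
  ann <- data.frame(receptor = "R1", family = "Gs", rank = "primary")
  map2 <- build_coupling_map(A, B2, ann, k = 1.4)
  expect_equal(map2$entries$map_value, 7)
  expect_match(map2$entries$labels, "missing:inoue")
})

test_that("annotation-only receptors form a separate family-level section", {
  sc <- default_scenario()
  ann <- rbind(sc$ann,
               data.frame(receptor = "LITONLY", family = "Gq/11",
                          rank = "primary"))
  map <- build_coupling_map(sc$A, sc$B, ann, k = 1.4)
  expect_true("LITONLY" %in% map$receptors$annotation_only)
  expect_false("LITONLY" %in% map$receptors$quantitative)
  # universe conservation: quantitative + annotation-only = all, no overlap
  expect_setequal(c(map$receptors$quantitative, map$receptors$annotation_only),
                  map$receptors$all)
  expect_length(intersect(map$receptors$quantitative,
                          map$receptors$annotation_only), 0)
  fm <- family_coupling_matrix(map)
  expect_true(fm["LITONLY", "Gq/11"])
})

test_that("label sets are internally consistent on simulated data", {
  sc <- default_scenario()
  map <- build_coupling_map(sc$A, sc$B, sc$ann, k = 1.4)
  ev <- map$evidence
  labs <- strsplit(ev$labels, ";")
  has <- function(l, x) vapply(l, function(v) x %in% v, logical(1))
  expect_true(all(!has(labs, "novel") | has(labs, "supported")))
  expect_true(all(!(has(labs, "proposed") & has(labs, "supported"))))
  for (s in map$sources) {
    expect_false(any(has(labs, paste0("unique:", s)) &
                       has(labs, paste0("missing:", s))))
  }
  expect_true(all(map$entries$support_count >= 2 |
                    (map$entries$annotated &
                       !(map$entries$tested_a | map$entries$tested_b))))
  expect_true(all(ev$coupler_a <= ev$tested_a & ev$coupler_b <= ev$tested_b))
})

test_that("novel couplings match an exhaustive set comparison", {
  sc <- default_scenario()
  map <- build_coupling_map(sc$A, sc$B, sc$ann, k = 1.4)
  nov <- find_novel(map)
  # brute force: couplers in both sources, family not annotated
  ga <- coupling_grid(qc_filter(sc$A, 1.4))
  gb <- coupling_grid(qc_filter(sc$B, 1.4))
  ann_sub <- expand_annotation_to_subtypes(sc$ann, receptors = rownames(ga))
  brute <- 0
  for (r in rownames(ga)) for (g in colnames(ga)) {
    if (isTRUE(ga[r, g]) && isTRUE(gb[r, g]) && !ann_sub[r, g]) brute <- brute + 1
  }
  expect_equal(nov$n_couplings, brute)
  expect_equal(sum(nov$family_counts) >= nov$n_receptors, TRUE)

  # fully annotated truth leaves nothing novel
  full_ann <- unique(data.frame(
    receptor = rownames(sc$truth$family_couplome)[row(sc$truth$family_couplome)[sc$truth$family_couplome]],
    family = colnames(sc$truth$family_couplome)[col(sc$truth$family_couplome)[sc$truth$family_couplome]],
    rank = "primary"))
  map_full <- build_coupling_map(sc$A, sc$B, full_ann, k = 1.4)
  expect_equal(find_novel(map_full)$n_couplings, 0)

  # no annotation at all makes every dual coupling novel
  map_none <- build_coupling_map(sc$A, sc$B, NULL, k = 1.4)
  expect_equal(find_novel(map_none)$n_couplings,
               sum(ga %in% TRUE & gb %in% TRUE))
})

test_that("contradicted annotations require negatives from both sources", {
  A <- toy_measurements("bouvier", c("R1", "R2"), c("Gs", "Gq"))
  B <- toy_measurements("inoue", c("R1", "R2"), c("Gs", "Gq"))
  flat <- function(ms, rec, g) {
    i <- ms$receptor == rec & ms$gprotein == g
    ms$emax[i] <- ms$basal_mean[i] + 0.5  # below threshold
    ms
  }
  A <- flat(A, "R1", "Gs"); B <- flat(B, "R1", "Gs")
  A <- flat(A, "R2", "Gq")                 # R2-Gq contradicted in one source only
  ann <- data.frame(receptor = c("R1", "R2"), family = c("Gs", "Gq/11"),
                    rank = "primary")
  map <- build_coupling_map(A, B, ann, k = 1.4)
  con <- find_contradicted_annotations(map)
  expect_equal(con, data.frame(receptor = "R1", family = "Gs"))

  map0 <- build_coupling_map(A, B, NULL, k = 1.4)
  expect_equal(nrow(find_contradicted_annotations(map0)), 0)
})

test_that("unique/missing summaries are zero for identical sources", {
  A <- toy_measurements("bouvier", c("R1", "R2"), c("Gs", "Gq"))
  B <- A; B$source <- "inoue"
  map <- build_coupling_map(A, B, k = 0)
  um <- unique_missing_summary(map, c("R1", "R2"))
  expect_true(all(um$pct_unique == 0))
  expect_true(all(um$pct_missing == 0))

  sc <- default_scenario()
  map2 <- build_coupling_map(sc$A, sc$B, sc$ann, k = 1.4)
  common <- intersect(rownames(sc$truth$couplome), unique(sc$A$receptor))
  um2 <- unique_missing_summary(map2, common)
  expect_true(all(um2$pct_unique >= 0 & um2$pct_unique <= 100))
  expect_true(all(um2$pct_missing <= 0 & um2$pct_missing >= -100))
})
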