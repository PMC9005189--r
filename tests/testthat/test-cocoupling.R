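test_that("activation vectors average sources and honour zero-filling", {
  A <- toy_measurements("bouvier", c("R1", "R2"), "Gs")
  B <- toy_measurements("inoue", c("R1", "R2"), "Gs")
  A$pec50 <- 6; B$pec50 <- 8
  # R2 coupled in one source only
  B$emax[B$receptor == "R2"] <- B$basal_mean[B$receptor == "R2"] + 0.5
  ann <- data.frame(receptor = "R2", family = "Gs", rank = "primary")
  map <- build_coupling_map(A, B, ann, k = 1.4)
  v <- coupling_vectors(map, zero_fill = FALSE)
  # R2 emax is below the R1 max in source A -> frac < 1 lowers the value
  expect_equal(v["Gs", "R1"], 7)           # both sources, frac 1: (6+8)/2
  expect_equal(v["Gs", "R2"], map$entries$map_value[map$entries$receptor == "R2"])
  v0 <- coupling_vectors(map, zero_fill = TRUE)
  expect_false(anyNA(v0))
})

test_that("Pearson matrix matches a two-pass covariance oracle", {
  pearson_oracle <- function(x, y) {
    cx <- x - mean(x); cy <- y - mean(y)
    sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
  }
  set.seed(11)
  v <- matrix(rnorm(3 * 10), 3, 10, dimnames = list(c("a", "b", "c"), NULL))
  colnames(v) <- paste0("R", 1:10)
  pm <- pearson_matrix(v)
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(pm$r[i, j], pearson_oracle(v[i, ], v[j, ]))
    expect_equal(pm$r[i, j], pm$r[j, i])
  }
  expect_equal(unname(diag(pm$r)), c(1, 1, 1))
  expect_equal(pearson_matrix(rbind(a = v[1, ], b = v[1, ]))$r["a", "b"], 1)
  expect_equal(pearson_matrix(rbind(a = v[1, ], b = -v[1, ]))$r["a", "b"], -1)
  flat <- rbind(a = v[1, ], b = rep(2, 10), c = v[3, ])
  expect_true(is.na(pearson_matrix(flat)$r["a", "b"]))
})

test_that("Jaccard indices equal brute-force set arithmetic", {
  sets <- list(g1 = c("A", "B", "C"), g2 = c("B", "C", "D"),
               g3 = c("E"), g4 = c("A", "B", "C", "D", "E"), g5 = character(0))
  recs <- c("A", "B", "C", "D", "E")
  v <- t(sapply(sets, function(s) as.numeric(recs %in% s) * 5))
  v[v == 0] <- NA
  colnames(v) <- recs
  jm <- jaccard_matrix(v)
  expect_equal(jm["g1", "g2"], 0.5)
  expect_equal(jm["g1", "g3"], 0)
  expect_equal(unname(diag(jm)[1:4]), rep(1, 4))
  expect_true(is.na(jm["g5", "g5"]))
  for (i in names(sets)) for (j in names(sets)) {
    u <- union(sets[[i]], sets[[j]])
    if (!length(u)) next
    expect_equal(jm[i, j], length(intersect(sets[[i]], sets[[j]])) / length(u))
  }
})

test_that("activation differences average over co-coupled receptors only", {
  v <- rbind(a = c(6, 8, NA, 2), b = c(5, 7, 4, NA))
  colnames(v) <- paste0("R", 1:4)
  d <- activation_difference(v)
  # co-coupled receptors are R1, R2: |mean(6,8) - mean(5,7)| = 1
  expect_equal(d["a", "b"], 1)
  expect_equal(d["a", "a"], 0)
  expect_equal(activation_difference(rbind(a = 1:4, b = 1:4))["a", "b"], 0)
  lone <- rbind(a = c(1, NA), b = c(NA, 2))
  expect_true(is.na(activation_difference(lone)["a", "b"]))
  # 4-receptor brute-force oracle
  both <- !is.na(v["a", ]) & !is.na(v["b", ])
  expect_equal(d["a", "b"],
               abs(mean(v["a", both]) - mean(v["b", both])))
})

test_that("the correlation tree clusters blocks and ignores input order", {
  r <- diag(4)
  rownames(r) <- colnames(r) <- c("a1", "a2", "b1", "b2")
  r["a1", "a2"] <- r["a2", "a1"] <- 0.95
  r["b1", "b2"] <- r["b2", "b1"] <- 0.9
  r[r == 0] <- -0.2
  tree <- correlation_tree(r)
  merged_first <- cutree(tree, k = 2)
  expect_equal(merged_first[["a1"]], merged_first[["a2"]])
  expect_equal(merged_first[["b1"]], merged_first[["b2"]])
  expect_true(merged_first[["a1"]] != merged_first[["b1"]])

  perm <- c("b2", "a1", "b1", "a2")
  tree2 <- correlation_tree(r[perm, perm])
  d1 <- as.matrix(cophenetic(tree))
  d2 <- as.matrix(cophenetic(tree2))[rownames(d1), colnames(d1)]
  expect_equal(d1, d2)

  r_na <- r; r_na[1, 2] <- NA
  expect_error(correlation_tree(r_na), "missing")
  nwk <- tree_newick(tree)
  expect_match(nwk, "^\\(.*\\);$")
})

test_that("family-block structure yields stronger within-family correlation", {
  sc <- default_scenario()
  map <- build_coupling_map(sc$A, sc$B, sc$ann, k = 1.4)
  cc <- cocoupling_matrices(map)
  fam_of <- subtype_family(rownames(cc$pearson_r))
  same <- outer(fam_of, fam_of, "==") & upper.tri(cc$pearson_r)
  diff <- outer(fam_of, fam_of, "!=") & upper.tri(cc$pearson_r)
  margin <- mean(cc$pearson_r[same], na.rm = TRUE) -
    mean(cc$pearson_r[diff], na.rm = TRUE)
  expect_gt(margin, 0.2)
  # Jaccard shows the same block structure
  expect_gt(mean(cc$jaccard[same], na.rm = TRUE),
            mean(cc$jaccard[diff], na.rm = TRUE))
})
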