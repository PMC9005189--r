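.fixture_matrix <- function() {
  path <- system.file("extdata", "synthetic_hpa_ntpm.tsv",
                      package = "couplemap")
  read_expression_table(path)
}

test_that("the quartile threshold is the interpolated 25th percentile", {
  m <- matrix(rep(c(1, 2, 3, 4), 5), nrow = 4,
              dimnames = list(paste0("g", 1:4), paste0("t", 1:5)))
  # order-statistic oracle (type 7): h = 1 + 0.25 * (n - 1)
  v <- sort(as.numeric(m))
  h <- 1 + 0.25 * (length(v) - 1)
  oracle <- v[floor(h)] + (h - floor(h)) * (v[floor(h) + 1] - v[floor(h)])
  expect_equal(quartile_threshold(m), oracle)
  expect_equal(quartile_threshold(matrix(7, 2, 2)), 7)
  expect_error(quartile_threshold(matrix(numeric(0), 0, 0)), "empty")
})

test_that("tissue counts are inclusive at the threshold and antitone in it", {
  m <- rbind(hi = c(10, 20, 30), lo = c(1, 1, 1))
  expect_equal(unname(tissues_above_threshold(m, 20)), c(2, 0))
  expect_equal(unname(tissues_above_threshold(m, 0)), c(3, 3))
  prev <- tissues_above_threshold(m, 0)
  for (t in c(1, 5, 15, 25, 35)) {
    cur <- tissues_above_threshold(m, t)
    expect_true(all(cur <= prev))
    prev <- cur
  }
})

test_that("per-gene z-scores follow the sample-SD convention", {
  m <- rbind(g = c(0, 0, 10))
  z <- zscore_per_gene(m)
  expect_equal(unname(z["g", ]), c(-0.5774, -0.5774, 1.1547), tolerance = 1e-4)
  mm <- rbind(a = c(1, 5, 9, 2), b = c(10, 2, 4, 4))
  zz <- zscore_per_gene(mm)
  expect_equal(unname(rowMeans(zz)), c(0, 0))
  expect_equal(unname(apply(zz, 1, sd)), c(1, 1))
  # ranking within a gene is preserved
  expect_equal(order(zz["a", ]), order(mm["a", ]))
  expect_warning(zc <- zscore_per_gene(rbind(flat = c(2, 2, 2))), "constant")
  expect_true(all(is.na(zc)))
})

test_that("the display cap is the median of per-gene maxima", {
  m <- rbind(a = c(1, 10), b = c(20, 3), c = c(5, 30))
  expect_equal(display_cap(m), 20)
  expect_equal(display_cap(m["a", , drop = FALSE]), 10)
})

test_that("co-expression clustering recovers engineered tissue programs", {
  expect_equal(coexpression_cluster(rbind(a = c(1, 5, 2, 8), b = c(1, 5, 2, 8),
                                          c = c(9, 1, 3, 0)))$r["a", "b"], 1)
  # two anti-correlated tissue programs split into two clusters
  set.seed(9)
  prog <- runif(20, 1, 100)
  m <- rbind(
    p1_a = prog * runif(20, 0.9, 1.1), p1_b = prog * runif(20, 0.9, 1.1),
    p2_a = (101 - prog) * runif(20, 0.9, 1.1),
    p2_b = (101 - prog) * runif(20, 0.9, 1.1))
  cl <- coexpression_cluster(m)
  groups <- cutree(cl$tree, k = 2)
  expect_equal(groups[["p1_a"]], groups[["p1_b"]])
  expect_equal(groups[["p2_a"]], groups[["p2_b"]])
  expect_true(groups[["p1_a"]] != groups[["p2_a"]])
  # gene input order does not change the correlation structure
  perm <- sample(rownames(m))
  r2 <- coexpression_cluster(m[perm, ])$r[rownames(m), rownames(m)]
  expect_equal(cl$r, r2)
})

test_that("the bundled synthetic atlas fixture satisfies all invariants", {
  m <- .fixture_matrix()
  expect_equal(dim(m), c(16, 50))
  expect_setequal(rownames(m), unique(gprotein_panel()$gene))
  expect_true(all(m >= 0))
  q1 <- quartile_threshold(m)
  cap <- display_cap(m)
  expect_true(q1 > 0 && cap > q1)
  counts <- tissues_above_threshold(m, q1)
  expect_true(all(counts >= 0 & counts <= 50))
  # ubiquitous genes reach all tissues at the first-quartile threshold
  expect_equal(unname(counts[c("GNAS", "GNAI2")]), c(50, 50))
  # focal sensory genes have very few tissues above threshold
  expect_true(all(counts[c("GNAT1", "GNAT2", "GNAT3")] <= 3))
  z <- zscore_per_gene(m)
  expect_equal(unname(rowMeans(z)), rep(0, 16), tolerance = 1e-12)
  # the engineered brain program forms one coherent cluster
  cl <- coexpression_cluster(m)
  brain <- c("GNAL", "GNAO1", "GNAZ", "GNAQ", "GNA12")
  grp <- cutree(cl$tree, k = 4)
  expect_equal(length(unique(grp[brain])), 1)
})
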