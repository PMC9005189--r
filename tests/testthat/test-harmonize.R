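test_that("min-max normalization maps the strongest coupler to exactly 1", {
  ms <- toy_measurements(receptors = c("R1", "R2", "R3"), gproteins = "G15")
  ms$emax <- 100 + c(20, 50, 100)
  ms <- apply_sd_cutoff(ms, 0)
  out <- minmax_normalize_emax(ms)
  expect_equal(out$emax_frac, c(0.2, 0.5, 1.0))

  single <- apply_sd_cutoff(toy_measurements(receptors = "R1", gproteins = "Gz"), 0)
  expect_equal(minmax_normalize_emax(single)$emax_frac, 1)

  # rank order within a G protein is unchanged
  set.seed(7)
  rnd <- toy_measurements(receptors = sprintf("R%02d", 1:15), gproteins = "Gq")
  rnd$emax <- rnd$basal_mean + runif(15, 5, 500)
  rnd <- minmax_normalize_emax(apply_sd_cutoff(rnd, 0))
  expect_equal(order(rnd$emax_frac), order(rnd$emax))
  expect_true(all(rnd$emax_frac > 0 & rnd$emax_frac <= 1))
})

test_that("log(Emax/EC50) combines the fraction and pEC50 on the log scale", {
  expect_equal(log_emax_ec50(1.0, 7.0), 7.0)
  expect_equal(log_emax_ec50(0.5, 8.0), 7.69897, tolerance = 1e-6)
  expect_equal(log_emax_ec50(0.1, 5.0), 4.0)
  expect_error(log_emax_ec50(0, 5), "non-coupler")
  # strictly increasing in each argument, bounded above by pEC50
  f <- runif(20, 0.05, 1); p <- runif(20, 4, 9)
  v <- log_emax_ec50(f, p)
  expect_true(all(v <= p))
  expect_true(all(log_emax_ec50(pmin(f * 1.1, 1), p) >= v))
  expect_true(all(log_emax_ec50(f, p + 0.5) > v))
})

test_that("family aggregation by max takes the strongest member", {
  h <- data.frame(
    source = "s", receptor = "R1",
    gprotein = c("Gi1", "Gi2", "GoA", "Gz"),
    emax_frac = c(0.9, 0.8, 0.2, NA), pec50 = c(7.2, 6.9, 5.7, NA),
    log_emax_ec50 = c(7.2, 6.8, 5.0, NA),
    coupler = c(TRUE, TRUE, TRUE, FALSE)
  )
  agg <- aggregate_to_family(h, "max")
  expect_equal(agg$log_emax_ec50[agg$family == "Gi/o"], 7.2)
  expect_equal(agg$pec50[agg$family == "Gi/o"], 7.2)   # argmax subtype carries over

  h0 <- h; h0$coupler <- FALSE; h0$log_emax_ec50 <- NA_real_
  agg0 <- aggregate_to_family(h0, "max")
  expect_false(agg0$coupler)
  expect_true(is.na(agg0$log_emax_ec50))

  # max dominates members; mean lies between min and max
  mx <- aggregate_to_family(h, "max")$log_emax_ec50
  mn <- aggregate_to_family(h, "mean")$log_emax_ec50
  vals <- h$log_emax_ec50[h$coupler]
  expect_equal(mx, max(vals))
  expect_true(mn >= min(vals) && mn <= max(vals))

  one <- h[1, ]
  expect_equal(aggregate_to_family(one, "max")$log_emax_ec50, 7.2)
})

test_that("the similarity ratio is symmetric, scale-invariant and bounded", {
  expect_equal(similarity(2, 4), 0.5)
  expect_equal(similarity(5, 5), 1)
  x <- runif(30, 0.1, 10); y <- runif(30, 0.1, 10)
  expect_equal(similarity(x, y), similarity(y, x))
  expect_equal(similarity(3 * x, 3 * y), similarity(x, y))
  expect_true(all(similarity(x, y) > 0 & similarity(x, y) <= 1))
  expect_true(all((similarity(x, y) == 1) == (x == y)))
  expect_true(is.na(similarity(-1, 2)))
})

test_that("receptor-wise r2 matches the closed-form Pearson oracle", {
  # independent oracle: two-pass covariance formula
  r2_oracle <- function(a, b) {
    ca <- a - mean(a); cb <- b - mean(b)
    (sum(ca * cb) / sqrt(sum(ca^2) * sum(cb^2)))^2
  }
  pairs <- data.frame(receptor = "R1", a = c(1, 2, 10), b = c(2.1, 3.9, 7.5))
  expect_equal(receptorwise_r2(pairs)$mean_r2,
               r2_oracle(pairs$a, pairs$b))

  prop <- data.frame(receptor = "R1", a = 1:5, b = 2 * (1:5) + 3)
  expect_equal(receptorwise_r2(prop)$mean_r2, 1)

  few <- data.frame(receptor = "R1", a = 1:2, b = 2:3)
  expect_equal(length(receptorwise_r2(few)$per_unit), 0)

  set.seed(3)
  multi <- data.frame(receptor = rep(c("R1", "R2"), each = 5),
                      a = rnorm(10), b = rnorm(10))
  got <- receptorwise_r2(multi)
  want <- mean(c(r2_oracle(multi$a[1:5], multi$b[1:5]),
                 r2_oracle(multi$a[6:10], multi$b[6:10])))
  expect_equal(got$mean_r2, want)
})

test_that("identical datasets score perfectly under every protocol", {
  sc <- default_scenario()
  A <- qc_filter(sc$A, 1.4)
  B <- A; B$source <- "copy"
  ev <- evaluate_protocols(A, B)
  expect_true(all(abs(ev$similarity - 1) < 1e-12))
  expect_true(all(abs(ev$r2_receptor - 1) < 1e-12))
  expect_true(sum(ev$selected) >= 1)
  expect_true(all(ev$similarity > 0 & ev$similarity <= 1))
})
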