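test_that("relative_abundance follows the reads-per-kilobase-percent convention", {
  expect_equal(relative_abundance(1000, 1e6, 1000), 0.1)
  expect_equal(relative_abundance(0, 1e6, 1000), 0)
  # scale invariance in (m, T) and linearity / inverse length
  expect_equal(relative_abundance(2000, 2e6, 1000),
               relative_abundance(1000, 1e6, 1000))
  expect_equal(relative_abundance(500, 1e6, 1000),
               relative_abundance(1000, 1e6, 1000) / 2)
  expect_equal(relative_abundance(1000, 1e6, 2000),
               relative_abundance(1000, 1e6, 1000) / 2)
  expect_error(relative_abundance(1, 0, 1000), "total")
  expect_error(relative_abundance(10, 5, 1000), "m <= total")
})

test_that("abundance_series validates targets and orders by time", {
  counts <- data.table::data.table(
    sample_id = c("s2", "s1"), time_index = c(2L, 1L),
    total_reads = 1e6, target_id = "p", mapped_reads = c(100L, 200L))
  expect_error(abundance_series(counts, c(q = 1000)), "No genome length")
  ab <- abundance_series(counts, c(p = 1000))
  expect_equal(ab$time_index, 1:2)
  expect_equal(ab$abundance, c(0.02, 0.01))
})

test_that("identical series give the closed-form LS and delay 0", {
  for (n in c(5, 8, 10)) {
    x <- cumsum(runif(n) + 0.1)          # strictly monotone
    res <- local_similarity(x, x, max_delay = 0, n_perm = 50, seed = 1)
    z <- qnorm(rank(x) / (n + 1))
    expect_equal(res$ls_score, mean(z^2))
    expect_equal(res$delay, 0L)
    expect_identical(res$sign, "+")
    expect_equal(res$ls_score, lsa_oracle_d0(x, x))
  }
})

test_that("LS at D = 0 equals the exhaustive interval-search oracle", {
  set.seed(8)
  for (rep in 1:25) {
    n <- sample(4:10, 1)
    x <- rnorm(n); y <- rnorm(n)
    res <- local_similarity(x, y, max_delay = 0, n_perm = 10, seed = rep)
    expect_equal(res$ls_score, lsa_oracle_d0(x, y), tolerance = 1e-12)
  }
})

test_that("local similarity is symmetric with negated delay", {
  set.seed(15)
  for (rep in 1:5) {
    x <- rnorm(12); y <- rnorm(12)
    a <- local_similarity(x, y, max_delay = 3, n_perm = 200, seed = 42)
    b <- local_similarity(y, x, max_delay = 3, n_perm = 200, seed = 42)
    expect_equal(a$ls_score, b$ls_score)
    expect_equal(a$delay, -b$delay)
    expect_equal(a$p_value, b$p_value)
  }
})

test_that("LS is invariant to strictly monotone transformations", {
  set.seed(23)
  x <- rnorm(15); y <- rnorm(15)
  base <- local_similarity(x, y, max_delay = 2, n_perm = 100, seed = 5)
  warped <- local_similarity(exp(x), y^3 + 2 * y, max_delay = 2,
                             n_perm = 100, seed = 5)
  expect_equal(base$ls_score, warped$ls_score)
  expect_equal(base$delay, warped$delay)
  expect_equal(base$p_value, warped$p_value)
})

test_that("a planted shift is recovered as the optimal delay", {
  hits <- 0L
  for (rep in 1:20) {
    sim <- gen_timeseries(tempfile(), n_points = 20, lag = 1,
                          coupling = 0.9, noise_sd = 0.1, seed = 3000 + rep)
    x <- sim$truth$latent_host
    y <- sim$truth$latent_phage
    res <- local_similarity(x, y, max_delay = 3, n_perm = 20, seed = rep)
    if (res$delay == 1L && res$sign == "+") hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("local_similarity rejects degenerate inputs and interpolates gaps", {
  expect_error(local_similarity(1:10, rep(1, 10), n_perm = 10, seed = 1),
               "constant")
  expect_error(local_similarity(1:3, 3:1, n_perm = 10, seed = 1), ">= 4")
  expect_error(local_similarity(1:10, 1:9, n_perm = 10, seed = 1),
               "equal length")
  expect_error(local_similarity(1:10, 10:1, n_perm = 10), "seed")

  y <- rnorm(12); y[4] <- NA
  expect_warning(res <- local_similarity(1:12, y, n_perm = 20, seed = 2),
                 "interpolation")
  expect_s3_class(res, "lsa_result")
  y2 <- rnorm(12); y2[1:4] <- NA
  expect_error(local_similarity(1:12, y2, n_perm = 20, seed = 2), "25%")
})

test_that("p-value uses the add-one permutation estimator", {
  x <- sin(seq(0, 3, length.out = 16))
  res <- local_similarity(x, x, max_delay = 0, n_perm = 99, seed = 3)
  expect_gte(res$p_value, 1 / 100)
  expect_lte(res$p_value, 1)
})

test_that("phage_host_report couples series and checks the time grid", {
  sim <- gen_timeseries(tempfile(), n_points = 20, lag = 1, coupling = 0.9,
                        noise_sd = 0.1, seed = 12)
  ab <- abundance_series(sim$counts, c(host = sim$truth$host_length,
                                       phage = sim$truth$phage_length))
  rep <- phage_host_report(ab, "phage", "host", n_perm = 200, seed = 9)
  expect_identical(rep$sign, "+")
  expect_equal(rep$delay, 1L)
  expect_lt(rep$p_value, 0.05)

  # identical series is the most similar possible pair
  ab2 <- rbind(ab, data.table::copy(ab[target_id == "host"])[
    , target_id := "clone"])
  rep2 <- phage_host_report(ab2, c("phage", "clone"), "host",
                            n_perm = 100, seed = 9)
  expect_gte(rep2[rep2$phage_id == "clone"]$ls_score,
             rep2[rep2$phage_id == "phage"]$ls_score)

  bad <- ab[!(target_id == "phage" & time_index == 3)]
  expect_error(phage_host_report(bad, "phage", "host", n_perm = 10, seed = 1),
               "Time grids")
})

test_that("functional_profile excludes unknown-function genes from the denominator", {
  counts <- data.table::data.table(
    gene_id = c("a", "b", "c"), sample_id = "s1",
    count = c(30, 10, 60))
  cats <- data.table::data.table(
    gene_id = c("a", "b", "c"),
    category = c("structural", "host lysis", "unknown"))
  fp <- functional_profile(counts, cats)
  expect_equal(fp[category == "structural", percent], 75)
  expect_equal(fp[category == "host lysis", percent], 25)

  one <- functional_profile(counts[1], cats[1])
  expect_equal(one$percent, 100)

  zero <- data.table::copy(counts)[, count := c(0, 0, 10)]
  expect_warning(fp0 <- functional_profile(zero, cats), "no known-function")
  expect_true(all(is.na(fp0$percent)))
  expect_error(functional_profile(counts, cats[1:2]), "category")
})
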