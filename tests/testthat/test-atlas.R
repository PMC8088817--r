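atlas_fixture <- function(n = 120, seed = 6) {
  withr::with_seed(seed, {
    coords <- matrix(runif(3 * n, 0, 100), ncol = 3)
    values <- rnorm(n, mean = 2, sd = 0.5)
    list(coords = coords, values = values)
  })
}

test_that("atlas queries average exactly the k nearest sites with index tie-breaking", {
  fx <- atlas_fixture()
  atlas <- build_atlas(fx$coords, fx$values, k = 10)
  q <- c(50, 50, 50)
  res <- query_atlas(atlas, q)
  d <- sqrt(colSums((t(fx$coords) - q)^2))
  sel <- order(d, seq_along(d))[1:10]
  expect_equal(res$mu, mean(fx$values[sel]), tolerance = 1e-12)
  expect_equal(res$sigma, sd(fx$values[sel]), tolerance = 1e-12)
  # exact distance ties resolve by site index
  coords <- rbind(c(0, 0, 1), c(0, 0, -1), c(0, 0, 5))
  a2 <- build_atlas(coords, c(10, 20, 30), k = 2)
  expect_equal(query_atlas(a2, c(0, 0, 0))$mu, 15)   # sites 1 and 2, not 3
})

test_that("outlier exclusion is one-sided and single-pass, matching the arithmetic oracle", {
  # a lone outlier among k values has z at most (k-1)/sqrt(k), so the
  # 10-SD rule can only ever fire for k > 101 neighbours
  n <- 115
  coords <- cbind(seq_len(n), 0, 0)                  # site 1 nearest to 0
  values <- c(1e6, rep(1, n - 1))
  atlas <- build_atlas(coords, values, k = 112, outlier_sd = 10)
  res <- query_atlas(atlas, c(0, 0, 0))
  expect_equal(res$n_used, 111)                      # the outlier was dropped
  expect_equal(res$mu, 1, tolerance = 1e-9)
  expect_equal(res$sigma, 0)                         # survivors identical
  # low values are never excluded, however extreme
  vals_lo <- c(-1e6, rep(1, n - 1))
  res_lo <- query_atlas(build_atlas(coords, vals_lo, k = 112), c(0, 0, 0))
  expect_equal(res_lo$n_used, 112)
  # full agreement with the longhand oracle on random data
  fx <- atlas_fixture(n = 80, seed = 14)
  atlas <- build_atlas(fx$coords, fx$values, k = 20)
  for (i in c(1, 17, 53)) {
    zo <- oracle_zscore(fx$coords, fx$values, fx$coords[i, ], fx$values[i],
                        k = 20, outlier_sd = 10, self = i)
    zs <- zscore_channels(atlas, fx$coords[i, , drop = FALSE], fx$values[i],
                          self_index = i)
    expect_equal(zs$z, zo, tolerance = 1e-12)
  }
})

test_that("identical neighbour values give sigma zero and an NA z, not an error", {
  coords <- matrix(seq_len(30), ncol = 3)
  atlas <- build_atlas(coords, rep(3, 10), k = 5)
  res <- query_atlas(atlas, c(0, 0, 0))
  expect_equal(res$sigma, 0)
  expect_true(is.na(zscore_value(4, res$mu, res$sigma)$z))
})

test_that("the k sweep reproduces the single-k path at every k", {
  fx <- atlas_fixture(n = 90, seed = 20)
  atlas <- build_atlas(fx$coords, fx$values, k = 60)
  q <- matrix(runif(15, 0, 100), ncol = 3)
  qv <- rnorm(5, 2, 0.5)
  sweep_out <- zscore_cohort(atlas, q, qv, k_sweep = c(10, 60))
  for (k in c(10, 60)) {
    a <- atlas; a$k <- as.integer(k)
    expect_equal(sweep_out[[paste0("k", k)]], zscore_channels(a, q, qv))
  }
  expect_warning(zscore_cohort(atlas, q, qv, k_sweep = 500), "skipped")
})

test_that("atlas construction rejects undersized or non-finite inputs", {
  fx <- atlas_fixture(n = 30)
  expect_error(build_atlas(fx$coords, fx$values, k = 60), "at least k")
  expect_error(build_atlas(fx$coords, replace(fx$values, 3, NA)), "finite")
  expect_error(query_atlas(build_atlas(fx$coords, fx$values, k = 30),
                           c(0, 0, 0), exclude_site = 1), "only 29")
})
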