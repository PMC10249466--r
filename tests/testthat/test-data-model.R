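test_that("variable groups validate their structure", {
  expect_error(
    var_group(data.frame(sample = c("a", "a"), x = 1:2), "g", "measured"),
    class = "tmrnet_error_validation"
  )
  expect_error(
    var_group(data.frame(sample = "a", x = "text"), "g", "measured"),
    class = "tmrnet_error_validation"
  )
  expect_message(
    g <- var_group(data.frame(sample = c("a", "b"), x = c(1, NA)),
                   "g", "measured"),
    "dropped 1 sample"
  )
  expect_equal(vg_samples <- g$data$sample, "a")
  expect_equal(g$meta$n_dropped, 1)
})

test_that("alignment intersects samples in canonical order", {
  a <- make_group(matrix(1:3, ncol = 1, dimnames = list(NULL, "x")),
                  "A", "treatment", samples = c("m1", "m2", "m3"))
  b <- make_group(matrix(4:6, ncol = 1, dimnames = list(NULL, "y")),
                  "B", "measured", samples = c("m2", "m3", "m4"))
  ds <- align_dataset(list(a, b))
  expect_equal(ds$sample_index, c("m2", "m3"))
  expect_equal(ds$groups$A$data$sample, c("m2", "m3"))
  expect_equal(ds$groups$B$data$sample, c("m2", "m3"))
  # identity case: identical sample sets keep everything
  ds2 <- align_dataset(list(a, make_group(
    matrix(7:9, ncol = 1, dimnames = list(NULL, "z")),
    "C", "measured", samples = c("m1", "m2", "m3"))))
  expect_equal(length(ds2$sample_index), 3)
})

test_that("alignment matches brute-force row lookup on permuted groups", {
  withr::with_seed(42, {
    universe <- sprintf("mouse%02d", 1:30)
    groups <- lapply(1:5, function(k) {
      ids <- sample(universe, 25)
      make_group(matrix(rnorm(25 * 3), ncol = 3,
                        dimnames = list(NULL, paste0("v", 1:3, "_", k))),
                 paste0("G", k), "measured", samples = ids)
    })
    originals <- lapply(groups, function(g) {
      m <- vg_matrix(g)
      m
    })
    ds <- align_dataset(groups)
    idx <- ds$sample_index
    expect_gt(length(idx), 2)
    for (k in 1:5) {
      aligned <- vg_matrix(ds$groups[[paste0("G", k)]])
      expect_identical(rownames(aligned), idx)
      # oracle: direct per-sample lookup in the original matrix
      expect_equal(aligned, originals[[k]][idx, , drop = FALSE])
    }
  })
})

test_that("alignment is idempotent and rejects degenerate input", {
  ds <- toy_dataset(n = 20)
  ds2 <- align_dataset(unname(ds$groups))
  expect_identical(ds2$sample_index, ds$sample_index)
  expect_identical(lapply(ds2$groups, function(g) g$data),
                   lapply(ds$groups, function(g) g$data))

  a <- make_group(matrix(1, 1, 1, dimnames = list(NULL, "x")), "A",
                  samples = "s1")
  b <- make_group(matrix(1, 1, 1, dimnames = list(NULL, "x")), "B",
                  samples = "s2")
  expect_error(align_dataset(list(a, b)), class = "tmrnet_error_alignment")
  expect_error(align_dataset(list(a, a)), class = "tmrnet_error_validation")
})

test_that("response features recover exact lines and match the OLS oracle", {
  feats <- derive_response_features(c(0, 10, 20), c(3, 5, 7))
  expect_equal(feats$baseline, 3)
  expect_equal(feats$slope, 0.2)
  expect_equal(derive_response_features(c(0, 1, 2, 3), c(4, 4, 4, 4))$slope, 0)

  withr::with_seed(7, {
    doses <- c(0, 3.125, 12.5, 25, 50)
    y <- 2 + 0.15 * doses + rnorm(5, sd = 0.3)
    got <- derive_response_features(doses, y)
    o <- oracle_ols(y, matrix(doses, ncol = 1))
    expect_equal(got$slope, o$beta[2], tolerance = 1e-10)
    expect_equal(got$baseline, y[1])
    # joint permutation of (dose, response) pairs changes nothing
    perm <- sample(5)
    got2 <- derive_response_features(doses[perm], y[perm])
    expect_equal(got2, got)
  })

  # affine responses are recovered exactly, linear and log dose scales
  for (ab in list(c(2, 0.5), c(-1, 0), c(0, -3))) {
    d <- c(0, 1, 2, 5, 9)
    expect_equal(
      as.numeric(derive_response_features(d, ab[1] + ab[2] * d)),
      ab, tolerance = 1e-12
    )
    expect_equal(
      derive_response_features(d, ab[1] + ab[2] * log(d + 1),
                               dose_scale = "log")$slope,
      ab[2], tolerance = 1e-12
    )
  }

  expect_error(derive_response_features(0, 1),
               class = "tmrnet_error_insufficient_data")
  expect_error(derive_response_features(c(0, 1), c(1, NA)),
               class = "tmrnet_error_validation")
  expect_error(derive_response_features(c(0, 0, 1), c(1, 2, 3)),
               class = "tmrnet_error_validation")
})

test_that("dose-response tables reduce to per-parameter features", {
  df <- data.frame(
    sample = c("s1", "s2"),
    `G@0` = c(5, 6), `G@10` = c(7, 6), `G@20` = c(9, 6),
    `H@0` = c(30, 31), `H@20` = c(34, 31),
    check.names = FALSE
  )
  out <- derive_response_group(df)
  expect_named(out, c("sample", "G_baseline", "G_slope",
                      "H_baseline", "H_slope"))
  expect_equal(out$G_slope, c(0.2, 0))
  expect_equal(out$H_baseline, c(30, 31))
})

test_that("datasets round-trip through per-group TSVs and a manifest", {
  ds <- toy_dataset(n = 12, seed = 3)
  dir <- withr::local_tempdir()
  manifest <- write_dataset(ds, dir)
  back <- read_dataset(manifest)
  expect_equal(back$sample_index, ds$sample_index)
  expect_equal(names(back$groups), names(ds$groups))
  for (nm in names(ds$groups)) {
    expect_equal(vg_matrix(back$groups[[nm]]), vg_matrix(ds$groups[[nm]]),
                 tolerance = 1e-8)
    expect_equal(back$groups[[nm]]$role, ds$groups[[nm]]$role)
  }
})
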