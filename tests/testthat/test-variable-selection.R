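test_that("transform choice follows Shapiro-Wilk normality", {
  withr::with_seed(21, {
    x_normal <- rnorm(50)
    rec <- choose_transform(x_normal)
    # gate: raw Shapiro-Wilk p for this draw is above 0.05 (reference test)
    expect_gt(stats::shapiro.test(x_normal)$p.value, 0.05)
    expect_equal(rec$chosen, "identity")
    expect_true(is.na(rec$W_sqrt) && is.na(rec$W_log))

    x_lognormal <- exp(rnorm(50, sd = 1.5))
    rec2 <- choose_transform(x_lognormal)
    expect_equal(rec2$chosen, "log")
    expect_gt(rec2$W_log, rec2$W_raw)
    # oracle: W of the log-scale values from the reference implementation
    expect_equal(rec2$W_log,
                 unname(stats::shapiro.test(log(x_lognormal))$statistic))
  })
})

test_that("negative values disable sqrt and log transforms", {
  withr::with_seed(22, {
    x <- c(-5, exp(rnorm(40, sd = 2))) # skewed and partly negative
    expect_lt(stats::shapiro.test(x)$p.value, 0.05)
    rec <- choose_transform(x)
    expect_equal(rec$chosen, "identity")
    expect_true(is.na(rec$W_sqrt) && is.na(rec$W_log))
  })
  expect_error(choose_transform(rep(1, 10)), class = "tmrnet_error_degenerate")
  expect_error(choose_transform(c(1, 2)),
               class = "tmrnet_error_insufficient_data")
})

test_that("zeros get an order-preserving half-minimum log offset", {
  withr::with_seed(23, {
    x <- c(0, 0, exp(rnorm(48, sd = 2)))
    rec <- choose_transform(x)
    expect_equal(rec$log_offset, min(x[x > 0]) / 2)
    expect_true(is.finite(rec$W_log))
  })
})

test_that("duplicate-variable geometry picks proxies as expected", {
  withr::with_seed(31, {
    z <- rnorm(100)
    # orthogonalize so the correlation matrix is exactly block-diagonal
    ind <- residuals(lm(rnorm(100) ~ z))
    df <- data.frame(sample = sprintf("s%03d", 1:100),
                     dup_b = z, dup_a = z, solo = ind)
    sel <- pca_select(df, transform = FALSE)
    # PC1 carries the duplicated pair; lexicographic tie-break
    expect_equal(sel$selections$proxy[1], "dup_a")
    expect_equal(abs(sel$selections$proxy_correlation[1]), 1, tolerance = 1e-9)
    expect_equal(sel$selections$proxy[2], "solo")
    expect_equal(abs(sel$selections$proxy_correlation[2]), 1, tolerance = 1e-9)
  })
})

test_that("independent variables give near-equal variance fractions", {
  withr::with_seed(32, {
    df <- data.frame(sample = sprintf("s%03d", 1:500),
                     a = rnorm(500), b = rnorm(500), c = rnorm(500))
    sel <- pca_select(df, transform = FALSE)
    expect_equal(nrow(sel$selections), 3) # all retained at the 1% threshold
    expect_true(all(abs(sel$selections$variance_fraction - 1 / 3) < 0.1))
    expect_equal(sum(sel$variance_fractions), 1, tolerance = 1e-9)
  })
})

test_that("a planted two-factor structure is captured by few strong proxies", {
  withr::with_seed(33, {
    n <- 200
    f1 <- rnorm(n)
    # orthogonal factors of unequal strength so the leading eigenvalues are
    # well separated and the PCs identify the factor subspaces
    f2 <- residuals(lm(rnorm(n) ~ f1))
    m <- sapply(1:8, function(j) {
      f <- if (j <= 5) f1 else f2
      f + rnorm(n, sd = 0.3)
    })
    colnames(m) <- paste0("v", 1:8)
    df <- data.frame(sample = sprintf("s%03d", 1:n), m)
    sel <- pca_select(df, transform = FALSE)
    big <- sel$selections[sel$selections$variance_fraction > 0.1, ]
    expect_equal(nrow(big), 2)
    expect_gt(sum(big$variance_fraction), 0.85)
    expect_true(all(abs(big$proxy_correlation) > 0.90))
    # cross-check retained fractions against a reference PCA
    ref <- prcomp(scale(m))$sdev^2
    expect_equal(sel$variance_fractions, ref / sum(ref), tolerance = 1e-9)
  })
})

test_that("proxy selection is stable under column reordering", {
  withr::with_seed(34, {
    n <- 150
    f <- rnorm(n)
    df <- data.frame(sample = sprintf("s%03d", 1:n),
                     p = f + rnorm(n, 0.2), q = f + rnorm(n, sd = 0.4),
                     r = rnorm(n), s = rnorm(n))
    s1 <- pca_select(df, transform = FALSE)
    s2 <- pca_select(df[, c("sample", "s", "r", "q", "p")], transform = FALSE)
    expect_setequal(s1$selections$proxy, s2$selections$proxy)
    # proxies mutually distinct; cumulative variance nondecreasing
    expect_equal(anyDuplicated(s1$selections$proxy), 0)
    expect_true(all(diff(cumsum(s1$selections$variance_fraction)) > 0))
  })
})

test_that("selection errors on degenerate input", {
  df <- data.frame(sample = c("a", "b", "c"), x = c(1, 1, 1), y = c(1, 2, 3))
  expect_error(pca_select(df, transform = FALSE),
               class = "tmrnet_error_degenerate")
  expect_error(
    pca_select(data.frame(sample = c("a", "b"), x = 1:2, y = 2:1),
               transform = FALSE),
    class = "tmrnet_error_insufficient_data"
  )
})

test_that("select_dataset reduces measured groups only", {
  withr::with_seed(35, {
    n <- 60
    f <- rnorm(n)
    # one strong factor, little idiosyncratic noise: minor PCs fall under 1%
    measured <- sapply(1:6, function(j) f + rnorm(n, sd = 0.1))
    colnames(measured) <- paste0("m", 1:6)
    ds <- align_dataset(list(
      make_group(cbind(trt = rep(0:1, each = n / 2)), "trt", "treatment"),
      make_group(measured, "omics", "measured"),
      make_group(cbind(out = rnorm(n)), "resp", "response")
    ))
    red <- select_dataset(ds)
    expect_lt(length(vg_vars(red$dataset$groups$omics)), 6)
    expect_equal(vg_vars(red$dataset$groups$trt), "trt")
    expect_s3_class(red$selection$omics, "pca_selection")
  })
})
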