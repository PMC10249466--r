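test_that("null configs carry no true edges; generation is deterministic", {
  cfg <- config_null()
  study <- generate_study(cfg, seed = 9)
  expect_equal(nrow(study$true_edges), 0)

  s1 <- generate_study(study_config(), seed = 4)
  s2 <- generate_study(study_config(), seed = 4)
  for (nm in names(s1$dataset$groups)) {
    expect_identical(s1$dataset$groups[[nm]]$data, s2$dataset$groups[[nm]]$data)
  }
  expect_identical(s1$true_edges, s2$true_edges)
  s3 <- generate_study(study_config(), seed = 5)
  expect_false(identical(s1$dataset$groups$`16S_DNA`$data,
                         s3$dataset$groups$`16S_DNA`$data))
})

test_that("the default study has the configured shape", {
  study <- generate_study(study_config(), seed = 1)
  ds <- study$dataset
  expect_equal(length(ds$sample_index), 40)
  roles <- vapply(ds$groups, function(g) g$role, character(1))
  expect_equal(sum(roles == "treatment"), 1)
  expect_equal(sum(roles == "measured"), 7) # 2 16S + 3 metabolite + 2 expression
  expect_equal(sum(roles == "response"), 1)
  expect_equal(nrow(study$true_edges), 5)

  # compositional layers: counts summing to the configured depth
  counts <- vg_matrix(ds$groups$`16S_DNA`)
  expect_true(all(counts >= 0))
  expect_true(all(rowSums(counts) == 50000))
  rel <- to_relative_abundance(ds$groups$`16S_DNA`)
  expect_true(all(abs(rowSums(vg_matrix(rel)) - 1) < 1e-12))

  # dose-response table encodes the response features exactly
  dr <- derive_response_group(study$dose_response)
  resp <- ds$groups$flexiVent$data
  expect_equal(dr$G_slope, resp$G_slope, tolerance = 1e-9)
  expect_equal(dr$Rn_baseline, resp$Rn_baseline, tolerance = 1e-9)
})

test_that("planted effects are recovered by OLS on the modeling scale", {
  study <- generate_study(study_config(), seed = 6)
  trans <- transform_measured(study$dataset)
  truth <- study$true_edges
  for (k in seq_len(nrow(truth))) {
    src <- study$effect_sources[[k]]
    tgt_group <- trans$groups[[truth$target_group[k]]]
    expect_true(truth$target[k] %in% vg_vars(tgt_group))
    y <- vg_matrix(tgt_group)[, truth$target[k]]
    o <- oracle_ols(y, matrix(src, ncol = 1))
    expect_lt(abs(o$beta[2] - truth$beta[k]), 3 * o$se[2])
  }
})

test_that("invalid effect configurations are rejected", {
  expect_error(
    study_config(effects = list(list(source = c("treatments", "HDM"),
                                     target = c("16S_DNA", "nope"),
                                     beta = 1, category = 1))),
    class = "tmrnet_error_config"
  )
  expect_error(
    study_config(effects = list(list(
      source = c("cecum_metabolites", "cecum_m01"),
      target = c("16S_DNA", "dna_t01"), beta = 1, category = 2))),
    class = "tmrnet_error_config"
  )
})

test_that("transform_measured puts groups on their modeling scales", {
  study <- generate_study(study_config(), seed = 8)
  trans <- transform_measured(study$dataset, top_n = 10)
  dna <- trans$groups$`16S_DNA`
  expect_equal(length(vg_vars(dna)), 10) # top 10 kept, remainder consumed as reference
  expect_equal(dna$meta$alr_reference, "Remainder")
  met <- trans$groups$cecum_metabolites
  expect_true(isTRUE(met$meta$log_transformed))
  expect_equal(vg_matrix(met),
               log(vg_matrix(study$dataset$groups$cecum_metabolites)),
               tolerance = 1e-12)
  # treatment and response groups untouched
  expect_identical(trans$groups$treatments$data,
                   study$dataset$groups$treatments$data)
})

test_that("recovery scoring counts endpoint overlaps", {
  truth <- tibble::tibble(
    source_group = "A", source = c("a", "b", "c"),
    target_group = "B", target = c("x", "y", "z"),
    beta = 1, category = 2L
  )
  mk_found <- function(p_, r_) {
    tibble::tibble(
      predictor_group = "A", predictor = p_, response_group = "B",
      response = r_, beta = 1, se = 1, t = 3, p = 0.001, category = 2L,
      sign = "positive", covariate_surfaced = FALSE,
      model_predictor = NA_character_, covariates_controlled = ""
    )
  }
  perfect <- mk_found(c("a", "b", "c"), c("x", "y", "z"))
  expect_equal(score_recovery(perfect, truth)$precision, 1)
  expect_equal(score_recovery(perfect, truth)$recall, 1)
  expect_equal(score_recovery(perfect, truth)$orientation_accuracy, 1)

  none <- perfect[0, ]
  expect_equal(score_recovery(none, truth)$precision, 0)
  expect_equal(score_recovery(none, truth)$recall, 0)

  two_thirds <- mk_found(c("a", "b", "d"), c("x", "y", "w"))
  sc <- score_recovery(two_thirds, truth)
  expect_equal(sc$precision, 2 / 3)
  expect_equal(sc$recall, 2 / 3)

  # reversed direction still matches endpoints, not orientation
  flipped <- tibble::tibble(
    predictor_group = "B", predictor = "x", response_group = "A",
    response = "a", beta = 1, se = 1, t = 3, p = 0.001, category = 2L,
    sign = "positive", covariate_surfaced = FALSE,
    model_predictor = NA_character_, covariates_controlled = ""
  )
  sc2 <- score_recovery(flipped, truth)
  expect_equal(sc2$recall, 1 / 3)
  expect_equal(sc2$orientation_accuracy, 0)
})
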