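test_that("a planted cross-group effect is recovered by the scan", {
  ds <- toy_dataset(n = 60, seed = 51, planted_beta = 3)
  edges <- tmr_scan(ds)
  hit <- dplyr::filter(edges, predictor == "u", response == "v",
                       category == 2, !covariate_surfaced)
  expect_equal(nrow(hit), 1)
  expect_lt(hit$p, 0.005)
  expect_gt(hit$beta, 2.5)
  expect_lt(hit$beta, 3.5)
  # the edge's stats match a direct covariate-adjusted oracle fit
  a <- vg_matrix(ds$groups$A)
  b <- vg_matrix(ds$groups$B)
  trt <- vg_matrix(ds$groups$trt)
  o <- oracle_ols(b[, "v"], cbind(a[, "u"], trt))
  expect_equal(hit$beta, unname(o$beta[2]), tolerance = 1e-10)
  expect_equal(hit$t, unname(o$t[2]), tolerance = 1e-10)
})

test_that("scan emits all three categories with controlled covariates", {
  ds <- toy_dataset(n = 40, seed = 52)
  edges <- tmr_scan(ds)
  expect_setequal(unique(edges$category), c(1, 2, 3))
  # category 1: one edge per covariate per measured variable
  c1 <- dplyr::filter(edges, category == 1)
  expect_equal(nrow(c1), 2 * 4) # 2 covariates x 4 measured variables
  expect_true(all(c1$predictor_group == "trt"))
  # category 2: both directions of every cross-group pair
  c2 <- dplyr::filter(edges, category == 2, !covariate_surfaced)
  expect_equal(nrow(c2), 2 * 2 * 2)
  # covariates recorded on every controlled model
  expect_true(all(edges$covariates_controlled == "dose + weight"))
  # sign annotation matches the coefficient
  expect_equal(edges$sign, ifelse(edges$beta >= 0, "positive", "negative"))
})

test_that("optional FDR adjustment matches p.adjust on primary edges", {
  ds <- toy_dataset(n = 40, seed = 58)
  edges <- tmr_scan(ds, adjust = "BH")
  primary <- !edges$covariate_surfaced
  expect_equal(edges$p_adj[primary],
               p.adjust(edges$p[primary], method = "BH"))
  expect_true(all(is.na(edges$p_adj[!primary])))
  expect_false("p_adj" %in% names(tmr_scan(ds)))
})

test_that("category-2 self-pairing is rejected", {
  ds <- toy_dataset(n = 30, seed = 53)
  expect_error(
    tmr_scan(ds, pairs = data.frame(i = "A", j = "A")),
    class = "tmrnet_error_parameter"
  )
  expect_error(
    tmr_scan(ds, pairs = data.frame(i = "A", j = "nope")),
    class = "tmrnet_error_parameter"
  )
})

test_that("bidirectional conflicts keep the stronger direction", {
  mk_edge <- function(pg, p_, rg, r_, pval, tval) {
    tibble::tibble(
      predictor_group = pg, predictor = p_, response_group = rg,
      response = r_, beta = 1, se = 1, t = tval, p = pval, category = 2L,
      sign = "positive", covariate_surfaced = FALSE,
      model_predictor = NA_character_, covariates_controlled = "c"
    )
  }
  both <- dplyr::bind_rows(
    mk_edge("A", "u", "B", "v", 0.001, 3.5),
    mk_edge("B", "v", "A", "u", 0.004, 3.0)
  )
  out <- resolve_bidirectional(both, alpha = 0.05)
  expect_equal(nrow(out), 1)
  expect_equal(out$predictor, "u")
  expect_equal(attr(out, "removed")$predictor, "v")

  # only one direction significant: nothing removed
  one <- dplyr::bind_rows(
    mk_edge("A", "u", "B", "v", 0.001, 3.5),
    mk_edge("B", "v", "A", "u", 0.5, 0.7)
  )
  expect_equal(nrow(resolve_bidirectional(one, alpha = 0.05)), 2)

  # p tie: larger |t| wins
  tie <- dplyr::bind_rows(
    mk_edge("A", "u", "B", "v", 0.01, 2.9),
    mk_edge("B", "v", "A", "u", 0.01, -3.2)
  )
  out3 <- resolve_bidirectional(tie, alpha = 0.05)
  expect_equal(out3$predictor, "v")

  empty <- both[0, ]
  expect_equal(nrow(resolve_bidirectional(empty)), 0)
})

test_that("resolution never removes an edge without a significant reverse", {
  ds <- toy_dataset(n = 50, seed = 54, planted_beta = 2)
  edges <- tmr_scan(ds)
  res <- resolve_bidirectional(edges, alpha = 0.05)
  expect_lte(nrow(res), nrow(edges))
  removed <- attr(res, "removed")
  if (nrow(removed) > 0) {
    for (i in seq_len(nrow(removed))) {
      reverse <- dplyr::filter(
        res, predictor_group == removed$response_group[i],
        predictor == removed$response[i],
        response_group == removed$predictor_group[i],
        response == removed$predictor[i])
      expect_equal(nrow(reverse), 1)
      expect_lt(reverse$p, 0.05)
      expect_lte(reverse$p, removed$p[i])
    }
  }
})

test_that("network construction applies a strict cutoff and drops isolates", {
  empty <- build_network(tmr_scan(toy_dataset(n = 20, seed = 55))[0, ])
  expect_equal(nrow(empty$edges), 0)
  expect_equal(nrow(empty$nodes), 0)

  edges <- tibble::tibble(
    predictor_group = "A", predictor = c("u1", "u2"),
    response_group = "B", response = c("v1", "v2"),
    beta = c(1, -1), se = 1, t = c(3, -3), p = c(0.004, 0.006),
    category = 2L, sign = c("positive", "negative"),
    covariate_surfaced = FALSE, model_predictor = NA_character_,
    covariates_controlled = "c"
  )
  net <- build_network(edges, alpha = 0.005)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$response, "v1")
  expect_setequal(net$nodes$variable, c("u1", "v1"))

  # retained set equals a brute-force filter of a real scan table
  scan <- tmr_scan(toy_dataset(n = 40, seed = 56, planted_beta = 2))
  net2 <- build_network(scan, alpha = 0.05)
  expect_equal(nrow(net2$edges), sum(scan$p < 0.05))

  expect_error(build_network(edges, alpha = 0), class = "tmrnet_error_parameter")
  expect_error(build_network(edges, alpha = 1), class = "tmrnet_error_parameter")
})

test_that("networks export to GraphML and edge lists", {
  ds <- toy_dataset(n = 60, seed = 57, planted_beta = 3)
  net <- build_network(tmr_scan(ds), alpha = 0.005)
  expect_gte(nrow(net$edges), 1)
  g <- as_igraph(net)
  expect_equal(igraph::gorder(g), nrow(net$nodes))
  expect_equal(igraph::gsize(g), nrow(net$edges))
  dir <- withr::local_tempdir()
  gml <- file.path(dir, "net.graphml")
  etsv <- file.path(dir, "edges.tsv")
  write_network(net, gml, etsv)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gsize(back), nrow(net$edges))
  expect_equal(nrow(utils::read.delim(etsv)), nrow(net$edges))
})
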