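# Fixture builders and independent oracles used across the suite.

# internal accessors exercised directly by the suite
vg_matrix <- tmrnet:::vg_matrix
vg_vars <- tmrnet:::vg_vars
first_merge_pair <- tmrnet:::first_merge_pair
dataset_groups_list <- tmrnet:::dataset_groups

# quick variable group from a matrix (samples in rows)
make_group <- function(values, name, role = "measured",
                       samples = sprintf("s%02d", seq_len(nrow(values))),
                       compositional = FALSE, meta = list()) {
  df <- data.frame(sample = samples, values, check.names = FALSE)
  var_group(df, name = name, role = role, compositional = compositional,
            meta = meta)
}

# closed-form OLS via the normal equations (independent of lm)
oracle_ols <- function(y, x) {
  x1 <- cbind(1, as.matrix(x))
  xtx_inv <- solve(t(x1) %*% x1)
  beta <- xtx_inv %*% t(x1) %*% y
  resid <- y - x1 %*% beta
  df <- length(y) - ncol(x1)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(diag(xtx_inv) * sigma2)
  tss <- sum((y - mean(y))^2)
  list(beta = drop(beta), se = se, t = drop(beta) / se,
       r_squared = 1 - sum(resid^2) / tss, df = df)
}

# explicit double-loop Euclidean distances
oracle_euclidean <- function(m) {
  n <- nrow(m)
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      out[i, j] <- sqrt(sum((m[i, ] - m[j, ])^2))
    }
  }
  out
}

# Pearson correlation over flattened strict upper triangles
oracle_mantel <- function(a, b) {
  am <- as.matrix(a)
  bm <- as.matrix(b)
  stats::cor(am[upper.tri(am)], bm[upper.tri(bm)])
}

# RMS coordinate error after optimal rigid (rotation/reflection +
# translation) alignment of configuration x onto y
procrustes_rms <- function(x, y) {
  x <- scale(as.matrix(x), scale = FALSE)
  y <- scale(as.matrix(y), scale = FALSE)
  s <- svd(t(y) %*% x)
  rot <- s$v %*% t(s$u)
  sqrt(mean((x %*% rot - y)^2))
}

# a tiny aligned dataset with one treatment, two measured, one response group
toy_dataset <- function(n = 60, seed = 1, planted_beta = 0) {
  withr::with_seed(seed, {
    trt <- cbind(dose = rep(c(0, 1), length.out = n),
                 weight = rnorm(n, 30, 2))
    u <- rnorm(n)
    a <- cbind(u = u, a2 = rnorm(n))
    v <- planted_beta * u + rnorm(n, sd = 0.5)
    b <- cbind(v = v, b2 = rnorm(n))
    r <- cbind(out = rnorm(n))
    align_dataset(list(
      make_group(trt, "trt", "treatment"),
      make_group(a, "A", "measured"),
      make_group(b, "B", "measured"),
      make_group(r, "resp", "response")
    ))
  })
}

table1_path <- function() {
  system.file("extdata", "published_taxa_damping_fit.tsv", package = "tmrnet")
}

read_table1 <- function() {
  utils::read.delim(table1_path(), comment.char = "#")
}
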