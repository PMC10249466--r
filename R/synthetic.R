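#' Configure a synthetic TMR study
#'
#' Describes a synthetic multi-omics study shaped like a four-arm murine
#' asthma experiment: a naive arm, an adjuvant-only control arm, an allergic
#' airway disease (AAD) vehicle arm and an AAD arm receiving an
#' anti-inflammatory treatment. The treatment group carries three binary
#' indicators (`HDM` allergen sensitization, `CT` adjuvant, `NO2OA`
#' treatment) and two continuous weight covariates (`weight_final`,
#' `weight_pct`). Measured layers are two compositional 16S taxa tables
#' (Dirichlet-multinomial counts whose log-abundance means shift linearly
#' with planted sources), three metabolite compartments and two expression
#' compartments (log-normal, effects planted on the log scale). The response
#' group holds forced-oscillation lung-function features: per-parameter
#' baselines and methacholine dose-response slopes, linear in their planted
#' sources plus Gaussian noise.
#'
#' Planted effects are expressed per standard deviation of the (realized)
#' source variable on its modeling scale, so `beta / noise_sd` is the
#' standardized effect size. The defaults (`beta` 1.5--2 against
#' `noise_sd = 0.5`) give essentially complete per-test power at n = 40.
#'
#' @param n_per_arm Samples per treatment arm (4 arms; default 10).
#' @param taxa_layers Named integer vector: taxa count per 16S layer.
#' @param metabolite_groups,expression_groups Named integer vectors:
#'   variables per compartment.
#' @param response_params Lung-function parameter names; each contributes a
#'   `_baseline` and `_slope` response feature.
#' @param doses Methacholine challenge doses (mg/mL) used to lay out the
#'   dose-response table.
#' @param depth Sequencing depth per sample (multinomial total).
#' @param concentration Dirichlet concentration controlling compositional
#'   overdispersion (larger = less overdispersed).
#' @param noise_sd Gaussian noise SD on every modeling scale (default 0.5).
#' @param effects List of planted effects, each
#'   `list(source = c(group, variable), target = c(group, variable),
#'   beta = , category = )`. Sources must belong to a stage generated before
#'   the target (treatments, then taxa, then expression, then metabolites,
#'   then responses).
#' @param shared_latent Optional `list(groups = c(a, b), strength = s)`:
#'   adds `s` times a shared standard-normal latent factor to every variable
#'   of the named measured groups, inducing inter-group structure for
#'   dendrogram studies.
#' @return A `study_config` list.
#' @seealso [generate_study()], [config_recovery_benchmark()],
#'   [config_null()], [config_latent_benchmark()]
#' @export
study_config <- function(n_per_arm = 10,
                         taxa_layers = c("16S_DNA" = 16, "16S_RNA" = 16),
                         metabolite_groups = c(cecum_metabolites = 8,
                                               serum_metabolites = 8,
                                               lung_metabolites = 8),
                         expression_groups = c(lung_expression = 8,
                                               colon_expression = 8),
                         response_params = c("Rn", "G", "H", "Rrs", "Ers"),
                         doses = c(0, 3.125, 12.5, 25, 50),
                         depth = 50000,
                         concentration = 500,
                         noise_sd = 0.5,
                         effects = default_effects(),
                         shared_latent = NULL) {
  cfg <- list(
    n_per_arm = n_per_arm, taxa_layers = taxa_layers,
    metabolite_groups = metabolite_groups,
    expression_groups = expression_groups,
    response_params = response_params, doses = doses,
    depth = depth, concentration = concentration, noise_sd = noise_sd,
    effects = effects, shared_latent = shared_latent
  )
  class(cfg) <- "study_config"
  validate_study_config(cfg)
  cfg
}

#' Default planted effects for the synthetic study
#'
#' Five single-step effects, one or two per model category: two treatment
#' effects on taxa (category 1), a taxon-on-metabolite and an
#' expression-on-metabolite effect (category 2), and a metabolite effect on
#' a lung-function dose-response slope (category 3).
#'
#' @return A list of effect specifications for [study_config()].
#' @export
default_effects <- function() {
  list(
    list(source = c("treatments", "NO2OA"), target = c("16S_DNA", "dna_t03"),
         beta = 1.5, category = 1),
    list(source = c("treatments", "HDM"), target = c("16S_RNA", "rna_t05"),
         beta = -1.5, category = 1),
    list(source = c("16S_DNA", "dna_t04"),
         target = c("cecum_metabolites", "cecum_m02"), beta = 1.5, category = 2),
    list(source = c("lung_expression", "lung_g01"),
         target = c("serum_metabolites", "serum_m03"), beta = 1.5, category = 2),
    list(source = c("cecum_metabolites", "cecum_m01"),
         target = c("flexiVent", "G_slope"), beta = 1.5, category = 3)
  )
}

# variable names of each configured group, plus its generation stage
config_layout <- function(cfg) {
  layout <- list(
    treatments = list(stage = 0L, vars = c("HDM", "CT", "NO2OA",
                                           "weight_final", "weight_pct"))
  )
  taxa_prefix <- function(nm) {
    paste0(tolower(sub("^16S_", "", nm)), "_t")
  }
  token <- function(nm) strsplit(nm, "_")[[1]][1]
  for (nm in names(cfg$taxa_layers)) {
    layout[[nm]] <- list(
      stage = 1L,
      vars = sprintf("%s%02d", taxa_prefix(nm), seq_len(cfg$taxa_layers[[nm]]))
    )
  }
  for (nm in names(cfg$expression_groups)) {
    layout[[nm]] <- list(
      stage = 2L,
      vars = sprintf("%s_g%02d", token(nm), seq_len(cfg$expression_groups[[nm]]))
    )
  }
  for (nm in names(cfg$metabolite_groups)) {
    layout[[nm]] <- list(
      stage = 3L,
      vars = sprintf("%s_m%02d", token(nm), seq_len(cfg$metabolite_groups[[nm]]))
    )
  }
  layout[["flexiVent"]] <- list(
    stage = 4L,
    vars = as.vector(t(outer(cfg$response_params, c("_baseline", "_slope"),
                             paste0)))
  )
  layout
}

validate_study_config <- function(cfg) {
  if (!is_scalar_number(cfg$n_per_arm) || cfg$n_per_arm < 2) {
    abort_tmr("`n_per_arm` must be at least 2.", class = "config")
  }
  layout <- config_layout(cfg)
  for (e in cfg$effects) {
    for (side in c("source", "target")) {
      ref <- e[[side]]
      if (is.null(layout[[ref[1]]]) || !ref[2] %in% layout[[ref[1]]]$vars) {
        abort_tmr(
          sprintf("Effect %s '%s:%s' does not exist in the configured study.",
                  side, ref[1], ref[2]),
          class = "config"
        )
      }
    }
    if (!is.finite(e$beta)) {
      abort_tmr("Effect beta must be finite.", class = "config")
    }
    if (layout[[e$source[1]]]$stage >= layout[[e$target[1]]]$stage) {
      abort_tmr(
        sprintf("Effect source '%s' is not generated before target '%s'.",
                e$source[1], e$target[1]),
        class = "config"
      )
    }
  }
  invisible(cfg)
}

#' Generate a synthetic TMR study
#'
#' Draws a complete study from a [study_config()]: treatment assignment per
#' arm, compositional 16S counts, log-normal metabolite and expression
#' tables, and lung-function baseline/slope response features, with every
#' configured effect planted as a linear shift (per SD of the realized
#' source) on the target's modeling scale. The full methacholine
#' dose-response table implied by the baselines and slopes is also returned
#' so the response-feature derivation can be exercised end to end.
#' Deterministic given `seed`; the caller's RNG state is left untouched.
#'
#' @param config A `study_config`.
#' @param seed Integer seed.
#' @return A `synthetic_study`: list with `dataset` (aligned `tmr_dataset`;
#'   16S layers as counts flagged compositional, metabolite/expression
#'   groups on their natural exponentiated scale flagged `lognormal`),
#'   `true_edges` (tibble: `source_group`, `source`, `target_group`,
#'   `target`, `beta`, `category`), `effect_sources` (list of the realized
#'   standardized source vectors actually used), `dose_response` (wide
#'   `<param>@<dose>` tibble), `config` and `seed`.
#' @export
generate_study <- function(config, seed = 1) {
  if (!inherits(config, "study_config")) {
    abort_tmr("`config` must come from study_config().", class = "config")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  cfg <- config
  layout <- config_layout(cfg)
  n <- cfg$n_per_arm * 4
  samples <- sprintf("m%03d", seq_len(n))
  arm <- rep(c("Naive", "Control", "AAD_Vehicle", "AAD_NO2OA"),
             each = cfg$n_per_arm)

  # modeling-scale value registry, group -> samples x variables matrix
  modeling <- list()
  effect_sources <- vector("list", length(cfg$effects))

  # treatment design: naive gets nothing, control gets adjuvant only,
  # both AAD arms get allergen + adjuvant, one also the treatment compound
  treatments <- cbind(
    HDM = as.numeric(arm %in% c("AAD_Vehicle", "AAD_NO2OA")),
    CT = as.numeric(arm != "Naive"),
    NO2OA = as.numeric(arm == "AAD_NO2OA"),
    weight_final = stats::rnorm(n, 45, 3),
    weight_pct = stats::rnorm(n, 60, 10)
  )
  rownames(treatments) <- samples
  modeling$treatments <- treatments

  # planted shifts for targets within one group, from earlier-stage sources
  planted_shift <- function(group_name, vars) {
    shift <- matrix(0, n, length(vars), dimnames = list(samples, vars))
    for (k in seq_along(cfg$effects)) {
      e <- cfg$effects[[k]]
      if (e$target[1] != group_name) next
      src <- modeling[[e$source[1]]][, e$source[2]]
      src_std <- as.numeric(scale(src))
      effect_sources[[k]] <<- src_std
      shift[, e$target[2]] <- shift[, e$target[2]] + e$beta * src_std
    }
    shift
  }

  latent <- stats::rnorm(n)
  latent_shift <- function(group_name, k_vars) {
    sl <- cfg$shared_latent
    if (is.null(sl) || !group_name %in% sl$groups) {
      return(matrix(0, n, k_vars))
    }
    sl$strength * matrix(latent, n, k_vars)
  }

  groups <- list(var_group(
    tibble::as_tibble(cbind(data.frame(sample = samples),
                            as.data.frame(treatments))),
    name = "treatments", role = "treatment"
  ))

  softmax_rows <- function(l) {
    e <- exp(l - apply(l, 1, max))
    e / rowSums(e)
  }

  # 16S layers: latent log-abundances with an abundance gradient
  for (nm in names(cfg$taxa_layers)) {
    vars <- layout[[nm]]$vars
    tn <- length(vars)
    base <- seq(2, -1, length.out = tn)
    l <- matrix(base, n, tn, byrow = TRUE,
                dimnames = list(samples, vars)) +
      matrix(stats::rnorm(n * tn, 0, cfg$noise_sd), n, tn) +
      latent_shift(nm, tn)
    l <- l + planted_shift(nm, vars)
    modeling[[nm]] <- l
    comp <- softmax_rows(l)
    counts <- t(vapply(seq_len(n), function(i) {
      gam <- stats::rgamma(tn, shape = cfg$concentration * comp[i, ])
      stats::rmultinom(1, cfg$depth, gam / sum(gam))[, 1]
    }, numeric(tn)))
    dimnames(counts) <- list(samples, vars)
    groups[[length(groups) + 1L]] <- var_group(
      tibble::as_tibble(cbind(data.frame(sample = samples),
                              as.data.frame(counts))),
      name = nm, role = "measured", compositional = TRUE
    )
  }

  # expression then metabolites: log-normal with planted log-scale effects
  lognormal_group <- function(nm) {
    vars <- layout[[nm]]$vars
    kv <- length(vars)
    z <- matrix(stats::rnorm(n * kv, 0, cfg$noise_sd), n, kv,
                dimnames = list(samples, vars)) +
      latent_shift(nm, kv)
    z <- z + planted_shift(nm, vars)
    modeling[[nm]] <<- z
    var_group(
      tibble::as_tibble(cbind(data.frame(sample = samples),
                              as.data.frame(exp(z)))),
      name = nm, role = "measured", meta = list(lognormal = TRUE)
    )
  }
  for (nm in names(cfg$expression_groups)) {
    groups[[length(groups) + 1L]] <- lognormal_group(nm)
  }
  for (nm in names(cfg$metabolite_groups)) {
    groups[[length(groups) + 1L]] <- lognormal_group(nm)
  }

  # lung-function response features; typical magnitudes per parameter
  base_baseline <- c(Rn = 0.3, G = 5, H = 30, Rrs = 0.6, Ers = 35)
  base_slope <- c(Rn = 0.01, G = 0.05, H = 0.2, Rrs = 0.01, Ers = 0.3)
  vars <- layout$flexiVent$vars
  resp <- matrix(0, n, length(vars), dimnames = list(samples, vars))
  for (p in cfg$response_params) {
    bb <- if (p %in% names(base_baseline)) base_baseline[[p]] else 1
    bs <- if (p %in% names(base_slope)) base_slope[[p]] else 0.1
    resp[, paste0(p, "_baseline")] <- bb + stats::rnorm(n, 0, cfg$noise_sd)
    resp[, paste0(p, "_slope")] <- bs + stats::rnorm(n, 0, cfg$noise_sd)
  }
  resp <- resp + planted_shift("flexiVent", vars)
  modeling$flexiVent <- resp
  groups[[length(groups) + 1L]] <- var_group(
    tibble::as_tibble(cbind(data.frame(sample = samples),
                            as.data.frame(resp))),
    name = "flexiVent", role = "response"
  )

  # the dose-response table those features imply (exact lines)
  dr <- tibble::tibble(sample = samples)
  for (p in cfg$response_params) {
    for (d in cfg$doses) {
      dr[[paste0(p, "@", d)]] <-
        resp[, paste0(p, "_baseline")] + d * resp[, paste0(p, "_slope")]
    }
  }

  true_edges <- if (length(cfg$effects) > 0) {
    dplyr::bind_rows(lapply(cfg$effects, function(e) {
      tibble::tibble(
        source_group = e$source[1], source = e$source[2],
        target_group = e$target[1], target = e$target[2],
        beta = e$beta, category = as.integer(e$category)
      )
    }))
  } else {
    tibble::tibble(source_group = character(), source = character(),
                   target_group = character(), target = character(),
                   beta = numeric(), category = integer())
  }

  structure(
    list(
      dataset = align_dataset(groups),
      true_edges = true_edges,
      effect_sources = effect_sources,
      dose_response = dr,
      config = cfg,
      seed = seed
    ),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> seed %d, %d planted effect(s)\n",
              x$seed, nrow(x$true_edges)))
  print(x$dataset)
  invisible(x)
}

#' Put measured groups on their modeling scale
#'
#' Compositional (taxa count) groups are converted to relative abundances,
#' pooled to the top `top_n` taxa with a remainder bucket (skipped when the
#' group already has `top_n` taxa or fewer), and ALR-transformed; log-normal
#' groups (meta flag `lognormal`) are log-transformed. All other groups pass
#' through unchanged.
#'
#' @param dataset A `tmr_dataset`.
#' @param top_n Taxa kept per compositional group before pooling
#'   (default 10).
#' @param pseudocount,reference Passed to [alr_transform()]; the default
#'   reference is the remainder bucket when pooling occurred, else the
#'   minimum log-variance taxon.
#' @return The dataset with measured groups transformed (re-aligned).
#' @export
transform_measured <- function(dataset, top_n = 10, pseudocount = 1e-6,
                               reference = NULL) {
  groups <- lapply(dataset$groups, function(g) {
    if (g$role != "measured") return(g)
    if (isTRUE(g$meta$compositional)) {
      g <- to_relative_abundance(g)
      if (length(vg_vars(g)) > top_n) {
        g <- select_top_taxa(g, n = top_n)
      }
      g <- alr_transform(g, reference = reference, pseudocount = pseudocount)
    } else if (isTRUE(g$meta$lognormal)) {
      m <- vg_matrix(g)
      if (any(m <= 0)) {
        abort_tmr(sprintf("Group '%s' has non-positive values; cannot log.",
                          g$name),
                  class = "validation")
      }
      g <- vg_replace_values(g, log(m))
      g$meta$lognormal <- FALSE
      g$meta$log_transformed <- TRUE
    }
    g
  })
  align_dataset(unname(groups))
}

#' Score recovered associations against planted truth
#'
#' Compares a found edge set with the generator's planted edges by their
#' endpoints (variable pairs labeled by group), ignoring effect size.
#' Direction is ignored by default because bidirectional resolution orients
#' measured-measured edges by significance, a heuristic; orientation
#' agreement among the matched edges is reported separately.
#' Covariate-surfaced edges are deliberate re-reports of treatment
#' associations inside controlled models and are excluded from scoring
#' unless `include_surfaced = TRUE`.
#'
#' @param found A `tmr_edges` table or `tmr_network`.
#' @param truth A tibble of planted edges
#'   (`source_group`, `source`, `target_group`, `target`), e.g.
#'   `synthetic_study$true_edges`.
#' @param ignore_direction Match unordered endpoint pairs (default `TRUE`).
#' @param include_surfaced Count covariate-surfaced edges as findings.
#' @return A one-row tibble: `precision`, `recall`, `n_found`, `n_truth`,
#'   `n_matched`, `orientation_accuracy` (`NA` when no directed match
#'   applies).
#' @export
score_recovery <- function(found, truth, ignore_direction = TRUE,
                           include_surfaced = FALSE) {
  edges <- if (inherits(found, "tmr_network")) found$edges else
    tibble::as_tibble(found)
  if (!include_surfaced && "covariate_surfaced" %in% names(edges)) {
    edges <- dplyr::filter(edges, !.data$covariate_surfaced)
  }
  key <- function(g1, v1, g2, v2, undirected) {
    a <- paste(g1, v1, sep = ":")
    b <- paste(g2, v2, sep = ":")
    if (undirected) {
      ifelse(a < b, paste(a, b, sep = "~"), paste(b, a, sep = "~"))
    } else {
      paste(a, b, sep = "->")
    }
  }
  found_keys <- unique(key(edges$predictor_group, edges$predictor,
                           edges$response_group, edges$response,
                           ignore_direction))
  truth_keys <- unique(key(truth$source_group, truth$source,
                           truth$target_group, truth$target,
                           ignore_direction))
  n_matched <- length(intersect(found_keys, truth_keys))
  precision <- if (length(found_keys) == 0) 0 else
    n_matched / length(found_keys)
  recall <- if (length(truth_keys) == 0) 0 else n_matched / length(truth_keys)

  orientation <- NA_real_
  if (ignore_direction && nrow(edges) > 0 && nrow(truth) > 0) {
    fk_dir <- unique(key(edges$predictor_group, edges$predictor,
                         edges$response_group, edges$response, FALSE))
    tk_dir <- unique(key(truth$source_group, truth$source,
                         truth$target_group, truth$target, FALSE))
    fk_und <- unique(key(edges$predictor_group, edges$predictor,
                         edges$response_group, edges$response, TRUE))
    matched_und <- intersect(fk_und, truth_keys)
    if (length(matched_und) > 0) {
      orientation <- length(intersect(fk_dir, tk_dir)) / length(matched_und)
    }
  }
  tibble::tibble(
    precision = precision, recall = recall,
    n_found = length(found_keys), n_truth = length(truth_keys),
    n_matched = n_matched, orientation_accuracy = orientation
  )
}

#' Compact study configuration for planted-edge recovery benchmarking
#'
#' A deliberately small variant of the default study used to measure
#' precision and recall of the full pipeline at stringent cutoffs: one 16S
#' layer of 16 taxa (so the top-10 rule pools a six-taxon remainder
#' whose averaged noise makes a stable ALR reference), one
#' metabolite compartment of 6 variables, no expression layers and two
#' lung-function parameters, with the same four-arm design and noise level
#' as [study_config()] and eight planted effects spanning the three model
#' categories. At this size the scan runs about 250 tests, so at
#' `alpha = 0.005` the expected number of false positives is near one and
#' precision/recall reflect the planted signal rather than the raw-p
#' multiplicity of a large scan (an uncorrected p-cutoff network at full
#' omics width necessarily carries `alpha` times thousands of tests in false
#' edges).
#'
#' @return A `study_config`.
#' @export
config_recovery_benchmark <- function() {
  study_config(
    taxa_layers = c("16S_DNA" = 16),
    metabolite_groups = c(cecum_metabolites = 6),
    expression_groups = c(),
    response_params = c("G", "H"),
    effects = list(
      list(source = c("treatments", "NO2OA"), target = c("16S_DNA", "dna_t03"),
           beta = 1.5, category = 1),
      list(source = c("treatments", "HDM"), target = c("16S_DNA", "dna_t05"),
           beta = -1.5, category = 1),
      list(source = c("treatments", "CT"),
           target = c("cecum_metabolites", "cecum_m05"), beta = 1.5,
           category = 1),
      list(source = c("16S_DNA", "dna_t04"),
           target = c("cecum_metabolites", "cecum_m02"), beta = 1.5,
           category = 2),
      list(source = c("16S_DNA", "dna_t01"),
           target = c("cecum_metabolites", "cecum_m04"), beta = 1.5,
           category = 2),
      list(source = c("16S_DNA", "dna_t02"),
           target = c("cecum_metabolites", "cecum_m06"), beta = -1.5,
           category = 2),
      list(source = c("cecum_metabolites", "cecum_m01"),
           target = c("flexiVent", "G_slope"), beta = 1.5, category = 3),
      list(source = c("16S_DNA", "dna_t06"),
           target = c("flexiVent", "H_baseline"), beta = 1.5, category = 3)
    )
  )
}

#' Null study configuration (no planted effects)
#'
#' Two log-normal measured compartments and the standard treatment design
#' with no effects anywhere: every association test in a scan of this study
#' is a true null, which makes it the calibration workload for type-I error
#' checks.
#'
#' @param n_vars Variables per measured compartment (default 15).
#' @return A `study_config`.
#' @export
config_null <- function(n_vars = 15) {
  study_config(
    taxa_layers = c(),
    metabolite_groups = stats::setNames(c(n_vars, n_vars),
                                        c("cecum_metabolites",
                                          "serum_metabolites")),
    expression_groups = c(),
    response_params = c("G", "H"),
    effects = list()
  )
}

#' Three-group configuration with a shared latent factor
#'
#' Three equal measured compartments in which the first two share a latent
#' per-sample factor while the third is independent; used to check that the
#' Mantel/Ward group dendrogram merges the related pair first.
#'
#' @param strength Latent factor loading (default 2).
#' @param n_vars Variables per compartment (default 8).
#' @return A `study_config`.
#' @export
config_latent_benchmark <- function(strength = 2, n_vars = 8) {
  study_config(
    taxa_layers = c(),
    metabolite_groups = stats::setNames(
      rep(n_vars, 3), c("cecum_metabolites", "serum_metabolites",
                        "lung_metabolites")),
    expression_groups = c(),
    response_params = c("G"),
    effects = list(),
    shared_latent = list(groups = c("cecum_metabolites", "serum_metabolites"),
                         strength = strength)
  )
}
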