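test_that("simulation_config validates fields by name", {
  expect_s3_class(simulation_config(), "simulation_config")
  expect_error(simulation_config(n_regions = 0), "n_regions")
  expect_error(simulation_config(expr_spatial_rho = 1), "expr_spatial_rho")
  expect_error(simulation_config(subject_noise_sd = -1), "subject_noise_sd")
  expect_error(simulation_config(n_genes = 10, n_causal = 11), "n_causal")
})

test_that("expression generator has unit marginals, ids, determinism, and spatial structure", {
  cfg <- simulation_config(n_regions = 308, n_genes = 200,
                           expr_spatial_rho = 0.3, seed = 1)
  E <- generate_expression(cfg)
  expect_identical(dim(E), c(308L, 200L))
  expect_identical(rownames(E)[1], "R0001")
  expect_identical(colnames(E)[1], "G00001")
  # AR(1) with unit innovations has unit marginal variance; the mean of
  # the per-gene sample variances should sit near 1
  expect_lt(abs(mean(apply(E, 2, var)) - 1), 3 / sqrt(308))

  cfg0 <- simulation_config(n_regions = 100, n_genes = 50,
                            expr_spatial_rho = 0, seed = 7)
  expect_identical(generate_expression(cfg0), generate_expression(cfg0))

  lag1 <- function(E) mean(vapply(seq_len(ncol(E)), function(j) {
    cor(E[-1, j], E[-nrow(E), j])
  }, numeric(1)))
  Eh <- generate_expression(simulation_config(n_regions = 100,
                                              n_genes = 500,
                                              expr_spatial_rho = 0.9,
                                              seed = 2))
  El <- generate_expression(simulation_config(n_regions = 100,
                                              n_genes = 500,
                                              expr_spatial_rho = 0,
                                              seed = 2))
  expect_gt(lag1(Eh), lag1(El))
})

test_that("cohort generator plants the advertised linear signal", {
  # noiseless limit: the group difference is exactly the scaled pattern
  cfg <- simulation_config(n_regions = 60, n_genes = 100, n_causal = 10,
                           n_subjects_a = 8, n_subjects_b = 8,
                           effect_size = 1, subject_noise_sd = 0,
                           seed = 5)
  E <- generate_expression(cfg)
  gen <- generate_cohort(E, cfg)
  dct <- compute_delta_ct(gen$cohort, "stable", "converter")
  expect_equal(unname(dct$values),
               unname(cfg$effect_size * cfg$delta_scale *
                        gen$truth$planted_delta),
               tolerance = 1e-12)
  # planted pattern is standardized and weights live on the causal set
  expect_lt(abs(mean(gen$truth$planted_delta)), 1e-10)
  expect_equal(var(gen$truth$planted_delta), 1, tolerance = 1e-10)
  expect_setequal(names(gen$truth$causal_weights), gen$truth$causal_genes)
  expect_true(all(gen$truth$causal_weights != 0))

  # determinism
  gen2 <- generate_cohort(E, cfg)
  expect_identical(gen, gen2)
})

test_that("with zero effect the thickness difference is decoupled from the pattern", {
  cfg <- simulation_config(n_regions = 308, n_genes = 150, n_causal = 20,
                           n_subjects_a = 40, n_subjects_b = 40,
                           effect_size = 0, seed = 9)
  E <- generate_expression(cfg)
  gen <- generate_cohort(E, cfg)
  dct <- compute_delta_ct(gen$cohort, "stable", "converter")
  expect_lt(abs(cor(dct$values, gen$truth$planted_delta)), 0.2)
})

test_that("regressing the simulated difference on the planted pattern recovers the effect", {
  # generative-consistency: slope of delta-CT on planted_delta should be
  # effect_size * delta_scale on average, within 2 SE over replicates
  slopes <- vapply(1:200, function(s) {
    cfg <- simulation_config(n_regions = 60, n_genes = 80, n_causal = 10,
                             n_subjects_a = 15, n_subjects_b = 15,
                             effect_size = 1.2, subject_noise_sd = 0.1,
                             seed = 1000 + s)
    E <- generate_expression(cfg)
    gen <- generate_cohort(E, cfg)
    dct <- compute_delta_ct(gen$cohort, "stable", "converter")
    unname(coef(lm(dct$values ~ gen$truth$planted_delta))[2])
  }, numeric(1))
  expected <- 1.2 * 0.1
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - expected), 2 * se + 1e-4)
})

test_that("annotation generator controls marker overlap and partitions regions evenly", {
  cfg <- simulation_config(n_regions = 308, n_genes = 500, n_causal = 60,
                           seed = 3)
  E <- generate_expression(cfg)
  gen <- generate_cohort(E, cfg)
  ann <- generate_annotations(E, gen$truth, n_sets = 7, set_size = 100,
                              causal_overlap_frac = 0.5, seed = 4)
  sets <- ann$collection$sets
  expect_length(sets, 7)
  expect_identical(length(intersect(sets[[1]], gen$truth$causal_genes)),
                   50L)
  for (i in 2:7) {
    expect_length(intersect(sets[[i]], gen$truth$causal_genes), 0)
  }
  sizes <- table(ann$class_map$class_label)
  expect_length(sizes, 7)
  expect_true(all(sizes == 44))  # 308 = 7 * 44

  ann0 <- generate_annotations(E, gen$truth, n_sets = 3, set_size = 40,
                               causal_overlap_frac = 0, seed = 4)
  expect_length(intersect(unlist(ann0$collection$sets),
                          gen$truth$causal_genes), 0)
  # uneven region count: class sizes differ by at most one
  cfg2 <- simulation_config(n_regions = 100, n_genes = 50, n_causal = 0,
                            seed = 2)
  E2 <- generate_expression(cfg2)
  gen2 <- generate_cohort(E2, cfg2)
  ann2 <- generate_annotations(E2, gen2$truth, n_sets = 2, set_size = 10,
                               causal_overlap_frac = 0, seed = 1)
  expect_lte(diff(range(table(ann2$class_map$class_label))), 1)

  expect_error(
    generate_annotations(E, gen$truth, n_sets = 2, set_size = 100,
                         causal_overlap_frac = 0.9, seed = 1),
    "exceeds"
  )
})
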