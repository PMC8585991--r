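tiny_collection <- function() {
  universe <- sprintf("g%02d", 1:10)
  gene_set_collection(list(s1 = universe[1:4]), universe)
}

test_that("hypergeometric overlap p matches exact enumeration", {
  # universe 10, list 5, set 4, overlap 3:
  # P(X >= 3) = (C(5,3) C(5,1) + C(5,4) C(5,0)) / C(10,4) = 55/210
  coll <- tiny_collection()
  gene_list <- c("g01", "g02", "g03", "g05", "g06")  # overlap 3 with s1
  res <- ora(gene_list, coll)
  expect_identical(res$n_overlap, 3L)
  expect_equal(res$p_hypergeom, 55 / 210, tolerance = 1e-12)

  # permutation p converges to the same value
  perm <- overlap_test(gene_list, coll, n_perm = 20000, seed = 5)
  expect_lt(abs(perm$p_perm - 55 / 210), 0.015)
  expect_equal(perm$p_hypergeom, 55 / 210, tolerance = 1e-12)
})

test_that("zero overlap gives p = 1 and complete overlap the minimal p", {
  universe <- sprintf("g%02d", 1:20)
  coll <- gene_set_collection(list(hit = universe[1:5],
                                   miss = universe[11:15]),
                              universe)
  res <- overlap_test(universe[6:10], coll, n_perm = 300, seed = 2)
  expect_equal(res$p_perm[res$set_name == "miss"], 1)
  expect_equal(res$p_hypergeom[res$set_name == "miss"], 1)

  # annotation set identical to the list in a universe twice its size:
  # p = 1 / C(n_universe, n_list), the smallest achievable value
  coll2 <- gene_set_collection(list(exact = universe[1:10]), universe)
  res2 <- ora(universe[1:10], coll2)
  expect_equal(res2$p_hypergeom, 1 / choose(20, 10), tolerance = 1e-12)
  # and a disjoint set gives 1
  res3 <- ora(universe[11:20], gene_set_collection(
    list(other = universe[1:10]), universe))
  expect_equal(res3$p_hypergeom, 1)
})

test_that("results are invariant to gene ordering in all inputs", {
  set.seed(6)
  universe <- sprintf("g%03d", 1:60)
  sets <- list(a = sample(universe, 12), b = sample(universe, 15))
  gl <- sample(universe, 20)
  r1 <- overlap_test(gl, gene_set_collection(sets, universe),
                     n_perm = 400, seed = 9)
  r2 <- overlap_test(rev(gl),
                     gene_set_collection(lapply(sets, rev),
                                         rev(universe)),
                     n_perm = 400, seed = 9)
  expect_equal(r1$n_overlap, r2$n_overlap)
  expect_equal(r1$p_hypergeom, r2$p_hypergeom, tolerance = 1e-12)
})

test_that("q-values adjust across sets per the step-up oracle", {
  set.seed(7)
  universe <- sprintf("g%03d", 1:100)
  sets <- setNames(lapply(1:6, function(i) sample(universe, 20)),
                   paste0("s", 1:6))
  res <- overlap_test(sample(universe, 30),
                      gene_set_collection(sets, universe),
                      n_perm = 500, seed = 3)
  expect_equal(res$q, bh_stepup_oracle(res$p_perm), tolerance = 1e-12)
  ores <- ora(sample(universe, 30), gene_set_collection(sets, universe))
  expect_equal(ores$q, bh_stepup_oracle(ores$p_hypergeom),
               tolerance = 1e-12)
  expect_true(!is.unsorted(ores$p_hypergeom))
})

test_that("universe restriction drops foreign ids with a message", {
  universe <- sprintf("g%02d", 1:10)
  expect_message(
    coll <- gene_set_collection(list(s = c("g01", "zz9")), universe),
    "outside the universe"
  )
  expect_identical(coll$sets$s, "g01")
  expect_message(
    res <- overlap_test(c("g01", "not_a_gene"), coll, n_perm = 200,
                        seed = 1),
    "outside the universe"
  )
  expect_identical(res$n_list, 1L)
  expect_error(overlap_test("not_a_gene", coll, n_perm = 200, seed = 1),
               "empty gene list")
})

test_that("GMT files round-trip", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g4", "g5"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  coll <- read_gmt(path)
  expect_identical(coll$sets, sets)
  expect_setequal(coll$universe, unlist(sets))
  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines("just_a_name\tdesc", bad)
  expect_error(read_gmt(bad), "malformed")
})

test_that("the planted marker set ranks first when tested with recovered genes", {
  # end-to-end gene-set check on the generator's ground truth
  firsts <- vapply(1:6, function(s) {
    cfg <- simulation_config(n_regions = 120, n_genes = 400,
                             n_causal = 40, n_subjects_a = 30,
                             n_subjects_b = 30, effect_size = 2,
                             subject_noise_sd = 0.05, seed = 1200 + s)
    E <- generate_expression(cfg)
    gen <- generate_cohort(E, cfg)
    ann <- generate_annotations(E, gen$truth, n_sets = 7, set_size = 60,
                                causal_overlap_frac = 0.5,
                                seed = 1300 + s)
    dct <- compute_delta_ct(gen$cohort, "stable", "converter")
    X <- standardize_genes(E)
    tab <- bootstrap_gene_weights(X, dct, n_boot = 150, seed = 1400 + s)
    lists <- significant_gene_lists(tab)
    hits <- c(lists$up, lists$down)
    if (length(hits) < 3) return(NA_character_)
    ora(hits, ann$collection)$set_name[1]
  }, character(1))
  expect_gte(sum(firsts == "astrocytes", na.rm = TRUE), 5)
})
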