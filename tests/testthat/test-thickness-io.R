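test_that("thickness TSV round-trips and validates its contract", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tiny_thickness(path)
  cohort <- read_thickness(path)
  expect_s3_class(cohort, "thickness_cohort")
  expect_length(cohort$regions, 2)
  expect_identical(sort(unique(cohort$groups)), c("MCI_AD", "MCI_S"))

  out <- withr::local_tempfile(fileext = ".tsv")
  write_thickness(cohort, out)
  expect_identical(read_thickness(out), cohort)
})

test_that("malformed thickness files are rejected with informative errors", {
  # one NaN cell: the error names the subject and region
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subject_id\tgroup\tR0001\tR0002",
               "S1\ta\t2.1\t2.2",
               "S2\tb\tNA\t2.3"), path)
  expect_error(read_thickness(path), "S2/R0001")

  # three group labels
  path3 <- withr::local_tempfile(fileext = ".tsv")
  write_tiny_thickness(path3, groups = c("a", "b", "c"))
  expect_error(read_thickness(path3), "exactly two groups required")

  # non-numeric thickness
  pathx <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subject_id\tgroup\tR0001",
               "S1\ta\tthick", "S2\tb\t2.0"), path)
  expect_error(read_thickness(path), "non-numeric|missing")

  # non-positive thickness names the offending cell
  expect_error(
    thickness_cohort(matrix(c(2, -1), 2, 1,
                            dimnames = list(c("S1", "S2"), "R1")),
                     groups = c("a", "b")),
    "positive.*S2.*R1"
  )
})

test_that("delta-CT is the difference of group means", {
  vals <- rbind(c(2.0), c(2.2), c(1.9), c(2.1), c(2.0))
  colnames(vals) <- "R0001"
  rownames(vals) <- sprintf("S%d", 1:5)
  cohort <- thickness_cohort(vals, groups = c("a", "a", "b", "b", "b"))
  dct <- compute_delta_ct(cohort, "a", "b")
  expect_equal(unname(dct$values), 0.1, tolerance = 1e-12)
  expect_error(compute_delta_ct(cohort, "a", "z"), "unknown group")
})

test_that("delta-CT is antisymmetric and invariant to shared shifts and subject order", {
  set.seed(1)
  vals <- matrix(rnorm(8 * 5, mean = 2.5, sd = 0.1), 8, 5,
                 dimnames = list(sprintf("S%d", 1:8),
                                 sprintf("R%04d", 1:5)))
  g <- rep(c("x", "y"), each = 4)
  cohort <- thickness_cohort(vals, g)
  d_ab <- compute_delta_ct(cohort, "x", "y")
  d_ba <- compute_delta_ct(cohort, "y", "x")
  expect_equal(d_ab$values, -d_ba$values, tolerance = 1e-14)
  # identical groups give exactly zero
  same <- thickness_cohort(rbind(vals[1:4, ], vals[1:4, ]), g)
  expect_equal(max(abs(compute_delta_ct(same, "x", "y")$values)), 0)
  # constant added to every subject cancels
  shifted <- thickness_cohort(vals + 0.7, g)
  expect_equal(compute_delta_ct(shifted, "x", "y")$values, d_ab$values,
               tolerance = 1e-12)
  # subject order is irrelevant
  perm <- sample(8)
  reord <- thickness_cohort(vals[perm, ], g[perm])
  expect_equal(compute_delta_ct(reord, "x", "y")$values, d_ab$values,
               tolerance = 1e-14)
})

test_that("gene standardization centres, scales, drops constants, and is idempotent", {
  m <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(2, 4, 9))
  rownames(m) <- sprintf("R%d", 1:3)
  expect_warning(z <- standardize_genes(m), "zero-variance")
  expect_identical(colnames(z), c("a", "c"))
  expect_equal(unname(z[, "a"]), c(-1, 0, 1), tolerance = 1e-12)
  expect_true(all(abs(colMeans(z)) < 1e-10))
  expect_true(all(abs(apply(z, 2, var) - 1) < 1e-10))
  expect_equal(standardize_genes(z), z, tolerance = 1e-12)
  expect_error(standardize_genes(cbind(a = c(1, 1, 1))), "zero variance")
})

test_that("region alignment uses the sorted id intersection", {
  X <- matrix(rnorm(9), 3, 3,
              dimnames = list(c("R3", "R1", "R2"), c("g1", "g2", "g3")))
  dct <- structure(list(regions = c("R2", "R4", "R1", "R3"),
                        values = setNames(1:4 / 10,
                                          c("R2", "R4", "R1", "R3")),
                        group_a = "a", group_b = "b"),
                   class = "delta_ct")
  al <- align_regions(X, dct, min_regions = 2)
  expect_identical(rownames(al$expr), c("R1", "R2", "R3"))
  expect_identical(al$dct$regions, c("R1", "R2", "R3"))
  expect_equal(unname(al$dct$values), c(0.3, 0.1, 0.4))
  expect_equal(al$expr["R1", ], X["R1", ])

  disj <- structure(list(regions = c("Q1", "Q2"),
                         values = setNames(c(1, 2), c("Q1", "Q2")),
                         group_a = "a", group_b = "b"),
                    class = "delta_ct")
  expect_error(align_regions(X, disj), "disjoint")
  expect_error(align_regions(X, dct, min_regions = 10), "shared")

  # identical ordered ids come back unchanged
  dct2 <- structure(list(regions = c("R1", "R2", "R3"),
                         values = setNames(c(1, 2, 3), c("R1", "R2", "R3")),
                         group_a = "a", group_b = "b"),
                    class = "delta_ct")
  X2 <- X[c("R1", "R2", "R3"), ]
  al2 <- align_regions(X2, dct2, min_regions = 2)
  expect_identical(al2$expr, X2)
  expect_identical(al2$dct$values, dct2$values)
})

test_that("delta-CT TSV round-trips", {
  dct <- structure(list(regions = c("R1", "R2"),
                        values = setNames(c(0.05, -0.02), c("R1", "R2")),
                        group_a = "a", group_b = "b"),
                   class = "delta_ct")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_delta_ct(dct, path)
  back <- read_delta_ct(path, "a", "b")
  expect_equal(back$values, dct$values, tolerance = 1e-12)
})
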