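test_that("the helix trace has uniform, correct CA spacing", {
  bb <- generate_backbone(10)
  expect_equal(dim(bb), c(10L, 3L))
  gaps <- sqrt(rowSums(diff(bb)^2))
  expect_lt(max(gaps) - min(gaps), 1e-9)
  # chord-length formula: sqrt((2 r sin(theta/2))^2 + h^2)
  theta <- 100 * pi / 180
  expect_equal(gaps[1], sqrt((2 * 2.3 * sin(theta / 2))^2 + 1.5^2),
               tolerance = 1e-9)
  expect_equal(gaps[1], 3.81, tolerance = 0.02)
  expect_identical(generate_backbone(10), generate_backbone(10))
  expect_error(generate_backbone(3), class = "trmsd_size")
})

test_that("hinge rotation moves only the segment, rigidly", {
  bb <- generate_backbone(30)
  seg <- 15:29
  expect_identical(hinge_perturbation(bb, seg, 0, axis_seed = 4), bb)
  out <- hinge_perturbation(bb, seg, 90, axis_seed = 4)
  # complement untouched
  expect_equal(out[-seg, ], bb[-seg, ], tolerance = 1e-12)
  # intra-segment and intra-complement distances preserved
  expect_equal(as.numeric(dist(out[seg, ])), as.numeric(dist(bb[seg, ])),
               tolerance = 1e-9)
  expect_equal(as.numeric(dist(out[-seg, ])), as.numeric(dist(bb[-seg, ])),
               tolerance = 1e-9)
  # some cross distance changes substantially
  cross_before <- as.matrix(dist(bb))[seg, -seg]
  cross_after <- as.matrix(dist(out))[seg, -seg]
  expect_gt(max(abs(cross_after - cross_before)), 0.5)
  expect_error(hinge_perturbation(bb, integer(0), 30), class = "trmsd_size")
  expect_error(hinge_perturbation(bb, 10:35, 30), class = "trmsd_size")
})

test_that("families have the advertised cardinality and determinism", {
  fam <- make_family(n_clusters = 3, per_cluster = 4, n_residues = 20,
                     noise_sigma = 0.1, angle_step = 30, seed = 7)
  expect_length(fam$structures, 12L)
  expect_length(fam$msa$ids, 12L)
  expect_equal(fam$msa$length, 20L)
  expect_false(any(grepl("-", fam$msa$seqs, fixed = TRUE)))
  expect_equal(unname(table(fam$truth)), rep(4L, 3L), ignore_attr = TRUE)

  fam2 <- make_family(n_clusters = 3, per_cluster = 4, n_residues = 20,
                      noise_sigma = 0.1, angle_step = 30, seed = 7)
  expect_identical(fam, fam2)
})

test_that("zero noise and zero angle collapse all column matrices to zero", {
  fam <- make_family(n_clusters = 2, per_cluster = 2, n_residues = 12,
                     noise_sigma = 0, angle_step = 0, seed = 3)
  fit <- trmsd(fam$msa, structures = fam$structures)
  expect_true(all(vapply(fit$matrices, function(M) max(abs(M)) < 1e-9,
                         logical(1))))
})

test_that("with zero noise, between-cluster distances are strictly positive
           at columns interacting with the moved segment", {
  fam <- make_family(n_clusters = 2, per_cluster = 2, n_residues = 18,
                     noise_sigma = 0, angle_step = 45, seed = 9)
  fit <- trmsd(fam$msa, structures = fam$structures)
  same <- outer(fam$truth[fam$msa$ids], fam$truth[fam$msa$ids], "==")
  for (M in fit$matrices) {
    expect_lt(max(abs(M[same[rownames(M), colnames(M)]])), 1e-9)
  }
  moved <- fam$perturbed_segment
  for (i in which(fit$scores$alignment_column %in% moved)) {
    M <- fit$matrices[[i]]
    expect_gt(min(M[!same[rownames(M), colnames(M)]]), 0)
  }
})

test_that("planted gap columns never reach the column map", {
  fam <- make_family(n_clusters = 2, per_cluster = 2, n_residues = 16,
                     noise_sigma = 0.05, angle_step = 30, seed = 2,
                     gap_columns = c(3L, 9L))
  expect_true(any(grepl("-", fam$msa$seqs, fixed = TRUE)))
  fit <- trmsd(fam$msa, structures = fam$structures)
  expect_equal(fit$K, 14L)
  expect_false(any(c(3L, 9L) %in% fit$column_map$columns))
})

test_that("written families are complete, runnable input sets", {
  fam <- make_family(n_clusters = 2, per_cluster = 2, n_residues = 12,
                     noise_sigma = 0.05, angle_step = 40, seed = 11)
  dir <- tempfile()
  write_family(fam, dir)
  expect_setequal(list.files(dir, pattern = "\\.(fasta|tsv)$"),
                  c("msa.fasta", "templates.tsv", "truth_labels.tsv"))
  expect_length(list.files(dir, pattern = "\\.pdb$"), 4L)
  fit <- trmsd(file.path(dir, "msa.fasta"),
               templates = file.path(dir, "templates.tsv"))
  expect_s3_class(fit, "trmsd")
  expect_equal(fit$K, 12L)
})
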