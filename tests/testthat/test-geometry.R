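test_that("alignment columns map positionally onto structure residues", {
  msa <- make_msa(c("a", "b"), c("A-CD", "ACCD"))
  sa <- make_structure("a", c("A", "C", "D"), generate_backbone(4)[1:3, ])
  sb <- make_structure("b", c("A", "C", "C", "D"), generate_backbone(4))
  maps <- map_sequences_to_structures(msa, list(a = sa, b = sb))
  expect_equal(maps$a, c(1L, NA, 2L, 3L))
  expect_equal(maps$b, 1:4)
})

test_that("residue mismatches are reported with position and letters", {
  msa <- make_msa(c("a", "b"), c("ACD", "ACD"))
  sa <- make_structure("a", c("A", "C", "E"), generate_backbone(4)[1:3, ])
  sb <- make_structure("b", c("A", "C", "D"), generate_backbone(4)[1:3, ])
  err <- tryCatch(map_sequences_to_structures(msa, list(a = sa, b = sb)),
                  error = identity)
  expect_s3_class(err, "trmsd_mapping")
  expect_match(conditionMessage(err), "column 3")
  expect_match(conditionMessage(err), "'D'")
  expect_match(conditionMessage(err), "'E'")

  # the X wildcard matches anything on either side (e.g. MSE-derived M)
  msa_x <- make_msa(c("a", "b"), c("AXD", "ACD"))
  sa_m <- make_structure("a", c("A", "M", "D"), generate_backbone(4)[1:3, ])
  expect_silent(map_sequences_to_structures(msa_x, list(a = sa_m, b = sb)))

  # length mismatch
  msa_l <- make_msa(c("a", "b"), c("ACDD", "ACDD"))
  expect_error(map_sequences_to_structures(msa_l, list(a = sa, b = sb)),
               class = "trmsd_mapping")
})

test_that("ungapped columns require a residue and a coordinate everywhere", {
  msa <- make_msa(c("a", "b"), c("ACDE", "ACDE"))
  xa <- generate_backbone(4); xb <- generate_backbone(4)
  sa <- make_structure("a", c("A", "C", "D", "E"), xa)
  sb <- make_structure("b", c("A", "C", "D", "E"), xb)
  maps <- map_sequences_to_structures(msa, list(a = sa, b = sb))
  cm <- find_ungapped_columns(msa, maps, list(a = sa, b = sb))
  expect_equal(cm$K, 4L)
  expect_equal(cm$columns, 1:4)

  # a missing coordinate in one structure excludes the column for all
  sb2 <- sb; sb2$residues$x[2] <- NA
  cm2 <- find_ungapped_columns(msa, maps, list(a = sa, b = sb2))
  expect_equal(cm2$K, 3L)
  expect_equal(cm2$columns, c(1L, 3L, 4L))

  # fewer than 2 usable columns aborts
  msa3 <- make_msa(c("a", "b"), c("A-C", "AG-"))
  sa3 <- make_structure("a", c("A", "C"), xa[1:2, ])
  sb3 <- make_structure("b", c("A", "G"), xb[1:2, ])
  maps3 <- map_sequences_to_structures(msa3, list(a = sa3, b = sb3))
  expect_error(find_ungapped_columns(msa3, maps3, list(a = sa3, b = sb3)),
               class = "trmsd_insufficient_columns")
})

test_that("intramolecular distances are plain Euclidean distances", {
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  st <- make_structure("a", c("A", "A", "A"), xyz)
  cm <- structure(list(columns = 1:3,
                       residues = matrix(1:3, ncol = 1, dimnames = list(NULL, "a")),
                       K = 3L), class = "trmsd_columnmap")
  D <- intra_distances(st, cm)
  expect_equal(unname(D), rbind(c(0, 1, 2), c(1, 0, 1), c(2, 1, 0)))

  st2 <- make_structure("a", c("A", "A"), rbind(c(0, 0, 0), c(3, 4, 0)))
  cm2 <- structure(list(columns = 1:2,
                        residues = matrix(1:2, ncol = 1, dimnames = list(NULL, "a")),
                        K = 2L), class = "trmsd_columnmap")
  expect_equal(intra_distances(st2, cm2)[1, 2], 5)

  # invariance under rigid motion
  st3 <- make_structure("a", c("A", "A", "A"), apply_rigid(xyz, 11))
  expect_equal(intra_distances(st3, cm), D, tolerance = 1e-9)
})

test_that("the per-column dRMSD difference matrix matches hand computation", {
  coords <- list(
    A = rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
    B = rbind(c(0, 0, 0), c(2, 0, 0), c(4, 0, 0))
  )
  mats <- pkg_column_matrices(coords)
  # column 1: d_A = (1, 2), d_B = (2, 4): sqrt(((1-2)^2 + (2-4)^2) / 2)
  expect_equal(mats[[1]]["A", "B"], sqrt(2.5), tolerance = 1e-12)
  expect_equal(mats[[1]]["A", "B"], 1.581139, tolerance = 1e-6)

  # identical structures give all-zero matrices, as do rigid copies
  same <- list(A = coords$A, B = coords$A)
  expect_true(all(vapply(pkg_column_matrices(same),
                         function(M) all(M == 0), logical(1))))
  rigid <- list(A = coords$A, B = apply_rigid(coords$A, 3))
  expect_true(all(vapply(pkg_column_matrices(rigid),
                         function(M) max(abs(M)) < 1e-9, logical(1))))
})

test_that("column matrices agree with the naive double-loop oracle", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(2:5, 1); K <- sample(3:6, 1)
    coords <- lapply(seq_len(n), function(i) matrix(rnorm(K * 3, sd = 5), K, 3))
    names(coords) <- paste0("s", seq_len(n))
    mats <- pkg_column_matrices(coords)
    for (c in seq_len(K)) {
      expect_equal(unclass(mats[[c]])[names(coords), names(coords)],
                   naive_column_matrix(c, coords),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
})

test_that("matrices are rigid-motion invariant and permutation equivariant", {
  set.seed(202)
  K <- 5
  coords <- lapply(1:4, function(i) matrix(rnorm(K * 3, sd = 5), K, 3))
  names(coords) <- paste0("s", 1:4)
  base <- pkg_column_matrices(coords)

  moved <- coords
  moved$s2 <- apply_rigid(moved$s2, 5)
  moved$s4 <- apply_rigid(moved$s4, 6)
  for (c in seq_len(K))
    expect_equal(unclass(base[[c]]), unclass(pkg_column_matrices(moved)[[c]]),
                 tolerance = 1e-9, ignore_attr = TRUE)

  perm <- coords[c("s3", "s1", "s4", "s2")]
  permuted <- pkg_column_matrices(perm)
  for (c in seq_len(K))
    expect_equal(unclass(permuted[[c]])[names(coords), names(coords)],
                 unclass(base[[c]])[names(coords), names(coords)],
                 tolerance = 1e-12, ignore_attr = TRUE)

  # uniform scaling of all structures scales every entry
  scaled <- lapply(coords, function(x) 2.5 * x)
  for (c in seq_len(K))
    expect_equal(unclass(pkg_column_matrices(scaled)[[c]]),
                 2.5 * unclass(base[[c]]),
                 tolerance = 1e-9, ignore_attr = TRUE)
})
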