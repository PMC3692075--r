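tr <- function(txt) ape::read.tree(text = txt)

test_that("bipartitions come one per internal edge, trivial splits excluded", {
  expect_equal(pkg_splits(tr("((A,B),(C,D));")), "A|B")
  expect_length(tree_bipartitions(tr("(A,B,C,D,E);")), 0L)
  set.seed(9)
  for (n in 5:8) {
    t <- ape::rtree(n, rooted = FALSE)
    expect_length(tree_bipartitions(t), n - 3L)
    expect_setequal(pkg_splits(t), oracle_splits(t))
  }
})

test_that("majority consensus keeps exactly the splits in more than half the trees", {
  trees <- c(replicate(3, tr("((A,B),(C,D));"), simplify = FALSE),
             replicate(2, tr("((A,C),(B,D));"), simplify = FALSE))
  cons <- majority_consensus(trees)
  expect_equal(pkg_splits(cons), "A|B")
  expect_equal(unname(trmsd:::split_supports(cons)), 3)

  # unanimity: the full topology with support K everywhere
  K <- 7
  one <- tr("((A,B),((C,D),(E,F)));")
  cons2 <- majority_consensus(replicate(K, one, simplify = FALSE))
  expect_setequal(pkg_splits(cons2), oracle_splits(one))
  expect_true(all(trmsd:::split_supports(cons2) == K))

  # a perfect tie is not a strict majority
  cons3 <- majority_consensus(list(tr("((A,B),(C,D));"), tr("((A,C),(B,D));")))
  expect_length(tree_bipartitions(cons3), 0L)
})

test_that("supports equal brute-force split counts and splits are compatible", {
  set.seed(55)
  for (rep in 1:15) {
    n <- sample(4:7, 1)
    K <- sample(3:15, 1)
    trees <- replicate(K, ape::rtree(n, rooted = FALSE), simplify = FALSE)
    cons <- majority_consensus(trees)
    counts <- table(unlist(lapply(trees, oracle_splits)))
    sup <- trmsd:::split_supports(cons)
    keys <- pkg_splits(cons)
    # exactly the strict-majority splits, with exact counts
    expect_setequal(keys, names(counts)[counts > K / 2])
    for (i in seq_along(sup)) {
      key <- paste(sort(trmsd:::split_from_key(names(sup)[i])), collapse = "|")
      expect_equal(unname(sup[i]), unname(counts[key]))
    }
    # pairwise compatibility
    sides <- tree_bipartitions(cons)
    labs <- cons$tip.label
    if (length(sides) > 1) {
      for (i in 1:(length(sides) - 1)) for (j in (i + 1):length(sides))
        expect_true(trmsd:::splits_compatible(sides[[i]], sides[[j]], labs))
    }
  }
})

test_that("consensus rejects inconsistent leaf sets", {
  expect_error(majority_consensus(list(tr("((A,B),(C,D));"),
                                       tr("((A,B),(C,E));"))),
               class = "trmsd_leaf_set")
})

test_that("support normalisation converts counts to 3-decimal fractions", {
  cons <- majority_consensus(c(replicate(7, tr("((A,B),(C,D));"), simplify = FALSE),
                               replicate(3, tr("((A,C),(B,D));"), simplify = FALSE)))
  frac <- normalize_support(cons, K = 10, mode = "fraction")
  expect_true("0.700" %in% frac$node.label)
  full <- normalize_support(majority_consensus(replicate(4, tr("((A,B),(C,D));"),
                                                         simplify = FALSE)),
                            K = 4, mode = "fraction")
  expect_true("1.000" %in% full$node.label)
  expect_identical(normalize_support(cons, K = 10, mode = "count"), cons)
})
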