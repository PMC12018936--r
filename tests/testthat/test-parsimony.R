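test_that("tree length matches hand-computed Fitch and Wagner cases", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  cm <- matrix_from_strings(c(A = "0", B = "0", C = "2", D = "2"))
  expect_identical(tree_length(tr, cm), 1L)                   # unordered
  expect_identical(tree_length(tr, cm, ordered = TRUE), 2L)   # |0-2| cline
  uniform <- matrix_from_strings(c(A = "1", B = "1", C = "1", D = "1"))
  expect_identical(tree_length(tr, uniform), 0L)
})

test_that("tree length and MPR sets equal exhaustive enumeration on random instances", {
  set.seed(2024)
  for (rep in 1:40) {
    inst <- rand_parsimony_instance()
    ref <- enumerate_parsimony(inst$tree, inst$cm)
    expect_identical(tree_length(inst$tree, inst$cm), ref$length)
    for (j in seq_len(inst$cm$n_chars)) {
      if (is.null(ref$mpr[[j]])) next
      got <- mpr_states(inst$tree, inst$cm, j)
      for (nd in names(ref$mpr[[j]]))
        expect_identical(sort(got[[nd]]), sort(ref$mpr[[j]][[nd]]))
    }
  }
})

test_that("unordered lengths agree with phangorn's Fitch implementation", {
  skip_if_not_installed("phangorn")
  set.seed(7)
  for (rep in 1:10) {
    taxa <- sprintf("t%02d", 1:8)
    cm <- rand_matrix(taxa, n_chars = 12, n_states = 3)
    tr <- ape::rtree(8, tip.label = taxa)
    chr <- t(vapply(seq_along(taxa), function(i)
      as.character(vapply(cm$cells[i, ], identity, integer(1))),
      character(cm$n_chars)))
    rownames(chr) <- taxa
    dat <- phangorn::phyDat(chr, type = "USER", levels = as.character(0:2))
    expect_equal(tree_length(tr, cm),
                 as.integer(phangorn::parsimony(tr, dat)))
  }
})

test_that("MPR examples: uniform tips, asymmetric cherry pair, ordered cherry", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  cm <- matrix_from_strings(c(A = "1", B = "1", C = "1", D = "1"))
  m <- mpr_states(tr, cm, 1)
  expect_true(all(vapply(m, identical, logical(1), 1L)))

  cm2 <- matrix_from_strings(c(A = "0", B = "1", C = "1", D = "1"))
  expect_identical(mpr_states(tr, cm2, 1)[["N5"]], 1L)   # root

  cherry <- ape::read.tree(text = "(A,B);")
  cm3 <- matrix_from_strings(c(A = "0", B = "2"), ordered = TRUE)
  expect_identical(mpr_states(cherry, cm3, 1)[["N3"]], c(0L, 1L, 2L))
})

test_that("all-missing characters change no tree length", {
  set.seed(99)
  inst <- rand_parsimony_instance(n_taxa = 6, n_chars = 4)
  cm <- inst$cm
  cells2 <- cbind(cm$cells, matrix(list(integer(0)), nrow(cm$cells), 1))
  rownames(cells2) <- cm$taxa
  cm2 <- character_matrix(cells2, ordered = c(cm$ordered, TRUE))
  expect_identical(tree_length(inst$tree, cm2), tree_length(inst$tree, cm))
})

test_that("polytomies are scored as hard polytomies", {
  star <- ape::read.tree(text = "(A,B,C,D);")
  cm <- matrix_from_strings(c(A = "0", B = "1", C = "1", D = "1"))
  expect_identical(tree_length(star, cm), 1L)
  ref <- enumerate_parsimony(star, cm)
  expect_identical(ref$length, 1L)
  expect_identical(mpr_states(star, cm, 1)[["N5"]], 1L)
})

test_that("unknown tips are reported by name", {
  tr <- ape::read.tree(text = "((A,B),(C,Zeta));")
  cm <- matrix_from_strings(c(A = "0", B = "0", C = "1", D = "1"))
  expect_error(tree_length(tr, cm), "Zeta")
  expect_error(mpr_states(tr, cm, 1), "Zeta")
})
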