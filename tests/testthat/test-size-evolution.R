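test_that("size categories follow the upper-inclusive published bounds", {
  expect_equal(as.character(classify_size(c(766, 580, 150, 400, 700, 90, 701))),
               c("gigantic", "large", "small", "medium", "large", "small",
                 "gigantic"))
  ## monotone in length
  x <- sort(runif(50, 1, 1200))
  expect_true(all(diff(as.integer(classify_size(x))) >= 0))
  expect_error(classify_size(c(100, -5)), "positive")
})

test_that("fine 50-cm bins are upper-inclusive and labelled by their bounds", {
  b <- bin_lengths(c(a = 170, d = 200, e = 201))
  expect_equal(as.character(b), c("150-200", "150-200", "200-250"))
})

test_that("ordered bin reconstruction matches enumeration on small cases", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  lv <- c("small", "medium", "large")
  all_med <- setNames(ordered(rep("medium", 4), levels = lv), LETTERS[1:4])
  m <- asr_bins(tr, all_med)
  expect_true(all(vapply(m, identical, logical(1), "medium")))

  cherry <- ape::read.tree(text = "(A,B);")
  m2 <- asr_bins(cherry, setNames(ordered(c("small", "large"), levels = lv),
                                  c("A", "B")))
  expect_identical(m2[["N3"]], lv)

  ## independent check via the enumeration oracle on integer states
  cm <- matrix_from_strings(c(A = "0", B = "2", C = "2", D = "1"),
                            ordered = TRUE)
  ref <- enumerate_parsimony(tr, cm)$mpr[[1]]
  got <- asr_bins(tr, setNames(ordered(lv[c(1, 3, 3, 2)], levels = lv),
                               LETTERS[1:4]))
  for (nd in c("N5", "N6", "N7"))
    expect_identical(match(got[[nd]], lv) - 1L, ref[[nd]])
})

test_that("a small-bodied clade reconstructs below a large-bodied outgroup root", {
  tr <- ape::read.tree(text = "((O1,O2),(O3,((I1,I2),(I3,I4))));")
  lv <- c("small", "medium", "large")
  bins <- setNames(ordered(c("large", "large", "large",
                             "small", "small", "medium", "small"),
                           levels = lv),
                   c("O1", "O2", "O3", "I1", "I2", "I3", "I4"))
  m <- asr_bins(tr, bins)
  root <- m[["N8"]]                       # tree root
  clade <- m[["N11"]]                     # (I1,I2),(I3,I4) ancestor
  expect_lt(max(match(clade, lv)), max(match(root, lv)))
})

test_that("binary reconstruction handles agreement, conflict and missing tips", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  all_t <- setNames(rep("saltwater_tolerant", 4), LETTERS[1:4])
  m <- asr_binary(tr, all_t)
  expect_true(all(vapply(m, identical, logical(1), "saltwater_tolerant")))

  conf <- setNames(c("0", "1", "0", "1"), LETTERS[1:4])
  m2 <- asr_binary(tr, conf, unknown = character(0))
  expect_identical(sort(m2[["N5"]]), c("0", "1"))

  expect_error(asr_binary(tr, setNames(rep("unknown", 4), LETTERS[1:4])),
               "unknown")
})

test_that("study-style osmoregulation coding yields tolerant crown and one alligatoroid loss", {
  tr <- ape::read.tree(
    text = "(Borealosuchus,(Deinosuchus,((Long1,Long2),(All1,All2))));")
  states <- c(Borealosuchus = "saltwater_tolerant",
              Deinosuchus = "saltwater_tolerant",
              Long1 = "saltwater_tolerant", Long2 = "saltwater_tolerant",
              All1 = "freshwater_only", All2 = "freshwater_only")
  m <- asr_binary(tr, states)
  ## crown root (Longirostres + alligatoroids) is tolerant; the alligatoroid
  ## ancestor is the single loss
  expect_identical(m[["N9"]], "saltwater_tolerant")
  expect_identical(m[["N11"]], "freshwater_only")
  expect_identical(attr(m, "length"), 1L)
  ## agreement with enumeration
  cm <- matrix_from_strings(setNames(
    c("1", "1", "1", "1", "0", "0"), names(states))[tr$tip.label])
  ref <- enumerate_parsimony(tr, cm)$mpr[[1]]
  expect_identical(ref[["N9"]], 1L)
  expect_identical(ref[["N11"]], 0L)
})

test_that("reduction percentages reproduce the published 20-40% band", {
  r <- reduction_percent(c(200, 250), c(150, 200))
  expect_equal(unname(r["min"]), 20)
  expect_equal(unname(r["max"]), 40)
  ## shrinking below 150 cm starts at the 40% mark
  expect_equal(unname(reduction_percent(c(200, 250), c(0, 150))["min"]), 40)
  expect_equal(unname(reduction_percent(c(200, 250), c(200, 250))["min"]), 0)
  ## monotone as the descendant bin slides down
  vals <- vapply(seq(200, 100, by = -25), function(u)
    unname(reduction_percent(c(200, 250), c(u - 50, u))["min"]), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_message(r2 <- reduction_percent(c(150, 200), c(200, 250)), "0")
  expect_equal(unname(r2["min"]), 0)
  expect_error(reduction_percent(c(200, 250), c(700, Inf)), "finite")
})
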