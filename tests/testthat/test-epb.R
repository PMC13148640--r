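test_that("newick parsing validates and round-trips", {
  tr <- parse_newick("((A,B),C);")
  expect_equal(ape::Ntip(tr), 3)
  rt <- parse_newick(ape::write.tree(tr))
  expect_equal(sort(rt$tip.label), sort(tr$tip.label))
  expect_equal(ape::Nnode(rt), ape::Nnode(tr))
  expect_error(parse_newick("((A,A),B);"), "duplicate")
  # polytomies are preserved
  poly <- parse_newick("(A,B,C,D);")
  expect_equal(ape::Nnode(poly), 1)
})

test_that("character matrices parse from CSV with ? and - codes", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("taxon,c1,c2", "A,0,1", "B,1,?", "C,0,-", "D,1,1"), f)
  m <- parse_character_matrix(f)
  expect_equal(dim(m), c(4, 2))
  expect_true(is.na(unclass(m)["B", 2]))       # ? -> any state
  expect_true(attr(m, "inapplicable")["C", 2]) # - flagged separately
  expect_false(attr(m, "inapplicable")["B", 2])
  tr <- parse_newick("((A,B),(C,E));")
  expect_error(parse_character_matrix(f, tree = tr), "E")
})

test_that("character matrices parse from a NEXUS subset", {
  f <- tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "BEGIN CHARACTERS;",
               "DIMENSIONS NCHAR=3;", "MATRIX",
               "A 010", "B 1?1", "C 0-0", ";", "END;"), f)
  m <- parse_character_matrix(f)
  expect_equal(dim(m), c(3, 3))
  expect_equal(unclass(m)["A", ], c(0L, 1L, 0L))
  expect_true(is.na(unclass(m)["B", 2]))
})

test_that("a full-size matrix shape is accepted", {
  set.seed(9)
  f <- tempfile(fileext = ".csv")
  taxa <- paste0("t", 1:48)
  rows <- vapply(taxa, function(tx)
    paste(c(tx, sample(0:1, 107, replace = TRUE)), collapse = ","),
    character(1))
  writeLines(c(paste(c("taxon", paste0("c", 1:107)), collapse = ","), rows), f)
  m <- parse_character_matrix(f)
  expect_equal(dim(m), c(48, 107))
})

test_that("minimum change counts match the textbook four-tip case", {
  tr <- parse_newick("((A,B),(C,D));")
  m <- matrix(c(0L, 1L, 0L, 1L), 4, 1,
              dimnames = list(c("A", "B", "C", "D"), NULL))
  fit <- fitch_optimize(tr, m)
  expect_equal(fit$changes, 2)
  expect_equal(fit$node_states[[1]][[5]], c(0L, 1L))  # ambiguous root
  # constant character: every node fixed, zero changes
  m2 <- matrix(1L, 4, 1, dimnames = list(c("A", "B", "C", "D"), NULL))
  fit2 <- fitch_optimize(tr, m2)
  expect_equal(fit2$changes, 0)
  expect_equal(fit2$node_states[[1]][[5]], 1L)
})

test_that("change counts and MPR sets match exhaustive enumeration", {
  for (seed in c(21, 22, 23, 24)) {
    tc <- make_toy_characters(seed, n_tips = 4 + (seed %% 5),
                              n_chars = 8, n_states = 2 + (seed %% 2))
    fit <- fitch_optimize(tc$tree, tc$matrix)
    n_tip <- ape::Ntip(tc$tree)
    for (ch in seq_along(tc$oracle)) {
      expect_equal(fit$changes[ch], tc$oracle[[ch]]$changes)
      for (i in seq_len(tc$tree$Nnode)) {
        expect_equal(sort(fit$node_states[[ch]][[n_tip + i]]),
                     tc$oracle[[ch]]$node_sets[[i]])
      }
    }
  }
})

test_that("node state sets stay within observed tip states", {
  tc <- make_toy_characters(31, n_tips = 7, n_chars = 12, n_states = 3)
  fit <- fitch_optimize(tc$tree, tc$matrix)
  n_tip <- 7
  for (ch in seq_len(12)) {
    observed <- sort(unique(unclass(tc$matrix)[, ch]))
    for (v in (n_tip + 1):(n_tip + tc$tree$Nnode))
      expect_true(all(fit$node_states[[ch]][[v]] %in% observed))
  }
})

test_that("missing data and all-missing characters are handled", {
  tr <- parse_newick("((A,B),(C,D));")
  m <- matrix(c(0L, NA, 0L, NA, NA, NA, NA, NA), 4, 2,
              dimnames = list(c("A", "B", "C", "D"), NULL))
  fit <- fitch_optimize(tr, m)
  expect_equal(fit$changes[1], 0)
  expect_true(is.na(fit$changes[2]))
  expect_equal(fit$skipped, 2L)
})

test_that("inference levels follow the four-cell truth table", {
  expect_equal(epb_level(1L, correlate_present = TRUE)$level, "I")
  expect_equal(epb_level(1L, correlate_present = FALSE)$level, "I'")
  expect_equal(epb_level(c(0L, 1L), correlate_present = TRUE)$level, "II")
  expect_equal(epb_level(c(0L, 1L), correlate_present = FALSE)$level, "II'")
  # unknown bracket states propagate to the equivocal level
  lv <- epb_level(1L, bracket_states = c(NA, NA), correlate_present = FALSE)
  expect_equal(lv$level, "II'")
  expect_match(lv$rationale, "unknown")
})

test_that("the packaged muscle dictionary builds a 37-row map", {
  dict <- gracilisuchus_muscle_dictionary()
  expect_equal(nrow(dict), 37)
  mm <- build_muscle_map(dict)
  expect_equal(nrow(mm), 37)
  expect_equal(mm$insertion_level[mm$muscle == "CFL"], "[I]")
  expect_equal(mm$origin_level[mm$muscle == "FMTE"], "[I']")
  expect_equal(mm$origin_level[mm$muscle == "PIFE1"], "[II]")
  # CSV round trip preserves the table
  f <- tempfile(fileext = ".csv")
  utils::write.csv(mm, f, row.names = FALSE)
  back <- utils::read.csv(f, stringsAsFactors = FALSE)
  expect_equal(back$muscle, mm$muscle)
  expect_equal(back$origin_level, mm$origin_level)
})

test_that("a toy dictionary maps through an ancestral-state map", {
  tr <- parse_newick("((Focal,Croc),Bird);")
  m <- matrix(c(1L, 1L, 1L, 0L, 1L, 0L), 3, 2,
              dimnames = list(c("Focal", "Croc", "Bird"), NULL))
  fit <- fitch_optimize(tr, m)
  dict <- data.frame(
    muscle = c("M1", "M2", "M3"),
    origin = "somewhere", insertion = "elsewhere",
    origin_level = "I", insertion_level = "I",
    origin_char = c(1L, 2L, NA), insertion_char = c(1L, 1L, NA),
    origin_correlate = c(TRUE, TRUE, TRUE),
    insertion_correlate = c(TRUE, FALSE, TRUE))
  mm <- build_muscle_map(dict, fit, focal_node = 5L)
  expect_equal(nrow(mm), 3)
  expect_equal(mm$origin_level[1], "[I]")   # unambiguous node, correlate
  expect_equal(mm$insertion_level[2], "[I']")
  bad <- dict; bad$origin_char[1] <- 99L
  expect_error(build_muscle_map(bad, fit, focal_node = 5L), "unmapped")
})
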