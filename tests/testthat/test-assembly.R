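three_frags <- function() {
  list(
    sticky_fragment("AATG", "CCC", "GCTT", "a"),
    sticky_fragment("GCTT", "TTTTT", "TACA", "b"),
    sticky_fragment("TACA", "GGGGGGG", "AATG", "c")
  )
}

test_that("three chaining fragments assemble into the hand-computed circle", {
  r <- assemble(three_frags())
  expect_equal(r$status, "success")
  expect_equal(seq_length(r$product), (3L + 4L) + (5L + 4L) + (7L + 4L))
  expect_equal(r$product$topology, "circular")
  # origin anchored on fragment 1: concatenation in cycle order
  expect_equal(r$product$sequence, "AATGCCCGCTTTTTTTTACAGGGGGGG")
})

test_that("duplicate and unmatched fusion sites are diagnosed by name", {
  amb <- assemble(c(three_frags(), list(sticky_fragment("GCTT", "AA", "CCGA", "d"))),
    try_flip = FALSE
  )
  expect_equal(amb$status, "ambiguous")
  expect_true("GCTT" %in% amb$diagnostics$fusion)

  inc <- assemble(
    list(
      sticky_fragment("AATG", "CC", "GCTT", "a"),
      sticky_fragment("CCGA", "TT", "AATG", "b")
    ),
    try_flip = FALSE
  )
  expect_equal(inc$status, "incomplete")
  expect_setequal(inc$diagnostics$fusion, c("GCTT", "CCGA"))
})

test_that("disjoint cycles are reported as multiple circles", {
  r <- assemble(
    list(
      sticky_fragment("AATG", "CC", "GCTT", "a"),
      sticky_fragment("GCTT", "TT", "AATG", "b"),
      sticky_fragment("CCGA", "AA", "TGCC", "c"),
      sticky_fragment("TGCC", "GG", "CCGA", "d")
    ),
    try_flip = FALSE
  )
  expect_equal(r$status, "multiple_circles")
})

test_that("permuting the fragment list changes neither status nor sequence", {
  set.seed(3)
  frags <- three_frags()
  base <- assemble(frags)
  rotations <- function(s) {
    vapply(seq_len(nchar(s)), function(k) {
      paste0(substr(s, k, nchar(s)), substr(s, 1, k - 1))
    }, character(1))
  }
  for (i in 1:6) {
    perm <- sample(3)
    r <- assemble(frags[perm])
    expect_equal(r$status, "success")
    expect_true(r$product$sequence %in% rotations(base$product$sequence))
  }
  # failures permute identically too
  bad <- list(
    sticky_fragment("AATG", "CC", "GCTT", "a"),
    sticky_fragment("CCGA", "TT", "AATG", "b")
  )
  for (i in 1:2) {
    expect_equal(assemble(sample(bad), try_flip = FALSE)$status, "incomplete")
  }
})

test_that("a fragment delivered backwards is rescued by reverse complement", {
  frags <- three_frags()
  frags[[2]] <- moclosim:::flip_fragment(frags[[2]])
  expect_warning(r <- assemble(frags), "reverse-complemented")
  expect_equal(r$status, "success")
  expect_equal(seq_length(r$product), 27L)
  # without rescue the same input is incomplete
  expect_equal(assemble(frags, try_flip = FALSE)$status, "incomplete")
})

test_that("product length and features follow the conservation rule", {
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(2:6, 1)
    fus <- moclosim:::sample_fusion_sites(n, 4)
    frags <- lapply(seq_len(n), function(i) {
      pay_len <- sample(0:40, 1)
      sticky_fragment(
        fus[i],
        paste(sample(c("A", "C", "G", "T"), pay_len, replace = TRUE), collapse = ""),
        fus[(i %% n) + 1],
        source_id = paste0("f", i)
      )
    })
    r <- assemble(frags)
    expect_equal(r$status, "success")
    expect_equal(
      seq_length(r$product),
      sum(vapply(frags, function(f) nchar(f$payload), integer(1))) + n * 4L
    )
  }
})

test_that("graph status matches exhaustive enumeration on small fragment sets", {
  set.seed(9)
  kit <- make_kit(4, 2, seed = 21, dir = tempfile())
  kit_inserts <- lapply(kit$molecules, function(m) {
    select_insert_fragment(digest(m, "BsaI"), "BsaI")
  })
  by_pos <- split(kit_inserts, kit$parts$position[match(
    vapply(kit_inserts, function(f) f$source_id, character(1)),
    kit$parts$plasmid_id
  )])
  pick_set <- function() lapply(by_pos, function(fs) fs[[sample(length(fs), 1)]])
  for (i in 1:12) {
    frags <- pick_set()
    variant <- sample(c("ok", "dup", "drop"), 1)
    if (variant == "dup") {
      extra <- pick_set()[[sample(length(frags), 1)]]
      frags <- c(frags, list(extra))
    } else if (variant == "drop") {
      frags <- frags[-sample(length(frags), 1)]
    }
    if (length(frags) < 2) next
    got <- assemble(unname(frags), try_flip = FALSE)
    n_orderings <- brute_count_circular_orderings(unname(frags))
    if (n_orderings == 1) {
      expect_equal(got$status, "success")
    } else {
      expect_false(got$status == "success")
      if (n_orderings >= 2) expect_equal(got$status, "ambiguous")
    }
  }
})

test_that("one-pot simulation composes digestion, selection and ligation", {
  kit <- make_kit(3, 1, seed = 4, dir = tempfile())
  inputs <- unname(kit$molecules)
  r <- simulate_reaction(inputs, "BsaI")
  expect_equal(r$status, "success")
  # the product is exactly the three inserts chained in grammar order
  inserts <- lapply(inputs, function(m) select_insert_fragment(digest(m, "BsaI"), "BsaI"))
  expect_equal(
    seq_length(r$product),
    sum(vapply(inserts, function(f) nchar(f$payload), integer(1))) + 3L * 4L
  )
  # a recognition-free input set leaves no site in the product
  expect_equal(nrow(find_sites(r$product, "BsaI")), 0L)
  # input without sites fails naming the plasmid
  blank <- dna_molecule(strrep("ACT", 40), id = "pBLANK", topology = "circular")
  expect_error(
    simulate_reaction(c(inputs[1:2], list(blank)), "BsaI"),
    "pBLANK",
    class = "moclosim_no_sites"
  )
  # shared fusion sites across inputs give an ambiguous assembly
  dup <- simulate_reaction(c(inputs, inputs[1]), "BsaI", try_flip = FALSE)
  expect_equal(dup$status, "ambiguous")
})
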