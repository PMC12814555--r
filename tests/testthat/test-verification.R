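test_that("a full-length primer pair amplifies the whole linear template", {
  set.seed(31)
  seqs <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
  tmpl <- dna_molecule(seqs, id = "t", topology = "linear")
  fwd <- primer("F", substr(seqs, 1, 20))
  rev <- primer("R", reverse_complement(substr(seqs, 81, 100)))
  amps <- simulate_pcr(tmpl, fwd, rev)
  expect_equal(nrow(amps), 1L)
  expect_equal(amps$length, 100L)
})

test_that("wraparound amplicons agree with origin rotation on circles", {
  set.seed(37)
  seqs <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  tmpl <- dna_molecule(seqs, id = "circ", topology = "circular")
  # forward near the end, reverse near the start: the amplicon wraps
  fwd <- primer("F", substr(seqs, 261, 280))
  rev <- primer("R", reverse_complement(substr(seqs, 21, 40)))
  wrap <- simulate_pcr(tmpl, fwd, rev)
  expect_equal(nrow(wrap), 1L)
  for (k in c(50, 150, 299)) {
    rot <- simulate_pcr(rotate_molecule(tmpl, k), fwd, rev)
    expect_equal(rot$length, wrap$length)
  }
})

test_that("multiple binding sites enumerate all products, as brute force does", {
  unit <- "ACGTACGTACGTACGTTTTT"
  mid <- strrep("CA", 30)
  seqs <- paste0(unit, mid, unit, strrep("GT", 40), "TTAACCGGTTAACCGGCCAA")
  tmpl <- dna_molecule(seqs, id = "dup", topology = "linear")
  fwd <- primer("F", unit)
  rev <- primer("R", reverse_complement("TTAACCGGTTAACCGGCCAA"))
  expect_warning(amps <- simulate_pcr(tmpl, fwd, rev), "multiple binding sites")
  f_sites <- c(0, nchar(unit) + nchar(mid))
  r_end <- nchar(seqs) - 1
  expect_equal(sort(amps$length), sort(as.integer(r_end - f_sites + 1)))
  # a primer absent from the template names itself in the warning
  expect_warning(
    none <- simulate_pcr(tmpl, primer("ghost", strrep("ACGGT", 4)), rev),
    "ghost"
  )
  expect_equal(nrow(none), 0L)
})

test_that("restriction fragments always sum to the template length", {
  set.seed(41)
  for (i in 1:15) {
    n_sites <- sample(1:6, 1)
    chunks <- vapply(seq_len(n_sites), function(j) {
      paste0("GAATTC", paste(sample(c("A", "C", "G", "T"), sample(50:400, 1),
        replace = TRUE
      ), collapse = ""))
    }, character(1))
    seqs <- paste(chunks, collapse = "")
    circ <- dna_molecule(seqs, id = "c", topology = "circular")
    sizes <- simulate_restriction_digest(circ, "EcoRI")
    expect_equal(sum(sizes), nchar(seqs))
    lin <- dna_molecule(seqs, id = "l", topology = "linear")
    expect_equal(sum(simulate_restriction_digest(lin, "EcoRI")), nchar(seqs))
  }
})

test_that("linear single-cut arithmetic and circular counts are exact", {
  seqs <- paste0(
    paste(rep("A", 194), collapse = ""), "GAATTC",
    paste(rep("C", 800), collapse = "")
  )
  lin <- dna_molecule(seqs, id = "l", topology = "linear")
  # EcoRI G^AATTC: cut gap at 194 + 1 = 195
  expect_equal(sort(simulate_restriction_digest(lin, "EcoRI")), c(195L, 805L))
  circ <- dna_molecule(seqs, id = "c", topology = "circular")
  expect_length(simulate_restriction_digest(circ, "EcoRI"), 1L)
})

test_that("a double digest equals the pooled single-digest cut set", {
  set.seed(43)
  core <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE), collapse = "")
  seqs <- paste0("GAATTC", core, "AAGCTT", substr(core, 1, 500))
  tmpl <- dna_molecule(seqs, id = "dd", topology = "circular")
  both <- simulate_restriction_digest(tmpl, c("EcoRI", "HindIII"))
  eco <- simulate_restriction_digest(tmpl, "EcoRI")
  hind <- simulate_restriction_digest(tmpl, "HindIII")
  expect_equal(sum(both), seq_length(tmpl))
  expect_equal(length(both), length(eco) + length(hind))
  # unknown enzymes list the known ones
  expect_error(
    simulate_restriction_digest(tmpl, "NoSuchEnzyme"),
    "EcoRI",
    class = "moclosim_unknown_enzyme"
  )
  # uncut circles are flagged
  uncut <- dna_molecule(strrep("ACT", 100), id = "u", topology = "circular")
  sizes <- simulate_restriction_digest(uncut, "EcoRI")
  expect_true(isTRUE(attr(sizes, "uncut")))
  expect_equal(as.integer(sizes), 300L)
})

test_that("gel band order is monotone in size and the table round-trips", {
  lanes <- list(
    gel_lane("digest A", c(500, 3000, 1200)),
    gel_lane("digest B", c(500, 3000, 1200))
  )
  gel <- render_gel(lanes)
  tab <- gel$table
  # within every lane, band position increases as size decreases
  for (i in unique(tab$lane_index)) {
    lane <- tab[tab$lane_index == i, ]
    expect_equal(lane$size_bp, sort(lane$size_bp, decreasing = TRUE))
    expect_true(all(diff(lane$position) > 0))
  }
  # identical size lists give identical band positions
  a <- tab[tab$lane == "digest A", c("size_bp", "position")]
  b <- tab[tab$lane == "digest B", c("size_bp", "position")]
  expect_equal(a, b)
  # serializer round trip
  csv <- tempfile(fileext = ".csv")
  write_gel_table(gel, csv)
  back <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(tab))
  # the plot builds without error
  p <- autoplot(gel)
  expect_s3_class(p, "ggplot")
})

test_that("primer validation enforces length and alphabet", {
  expect_error(primer("short", "ACGTACG"), class = "moclosim_bad_primer")
  expect_error(primer("badalpha", strrep("ACGX", 5)), class = "moclosim_bad_primer")
  f <- tempfile(fileext = ".csv")
  writeLines(c("name,sequence", "F1,ACGTACGTACGTACGTACGT"), f)
  prs <- load_primers(f)
  expect_named(prs, "F1")
  expect_equal(prs$F1$sequence, "ACGTACGTACGTACGTACGT")
})
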