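# shared fixture: one kit + campaign per test run
local_kit <- local({
  kit <- NULL
  function() {
    if (is.null(kit)) kit <<- make_kit(3, 2, seed = 1, dir = tempfile("kit"))
    kit
  }
})

test_that("typed campaign rows split cells into typed, subpart-aware references", {
  g <- moclo_grammar(
    "ytk-like", "BsaI",
    tibble::tibble(
      type_name = c("1", "2", "3"),
      generic_name = c("promoter", "cds", "terminator"),
      allows_subparts = c(FALSE, FALSE, TRUE)
    )
  )
  path <- tempfile(fileext = ".csv")
  writeLines(
    c(
      "output_name,promoter (1),cds (2),terminator (3)",
      "myLib1, pTET, EGII, AGA2.tTDH1"
    ),
    path
  )
  rows <- parse_campaign(path, grammar = g)
  expect_equal(nrow(rows), 1L)
  expect_equal(rows$output_name, "myLib1")
  parts <- rows$parts[[1]]
  expect_equal(length(unique(parts$column)), 3L)
  third <- parts[parts$column == 3, ]
  expect_equal(third$name, c("AGA2", "tTDH1"))
  expect_equal(third$subpart_index, c(1L, 2L))
  expect_equal(parts$type_name[parts$column == 1], "1")
  # column-count mismatch names the row and the expected header
  writeLines(c("x,only,two"), path)
  expect_error(parse_campaign(path, grammar = g), "row 1", class = "moclosim_parse_error")
})

test_that("raw campaign rows accept variable arity and skip blank cells", {
  path <- tempfile(fileext = ".csv")
  writeLines(
    c(
      "# comment line",
      "rxn1,pA,pB,pC,pD,pE",
      "rxn2,pA,,pC,"
    ),
    path
  )
  rows <- parse_campaign(path)
  expect_equal(nrow(rows), 2L)
  expect_equal(nrow(rows$parts[[1]]), 5L)
  expect_true(all(is.na(rows$parts[[1]]$type_name)))
  expect_equal(rows$parts[[2]]$name, c("pA", "pC"))
  # semicolon dialect parses identically
  writeLines("rxn1;pA;pB;pC;pD;pE", path)
  expect_equal(nrow(parse_campaign(path)$parts[[1]]), 5L)
  # empty file warns
  writeLines("# nothing here", path)
  expect_warning(empty <- parse_campaign(path), "empty")
  expect_equal(nrow(empty), 0L)
})

test_that("mapping files load with collision detection", {
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  writeLines(c("part_name,part_type,plasmid_id", "pTET,2,pMYT015", "Venus,3,pV3"), f1)
  writeLines(c("part_name,part_type,plasmid_id", "Venus,4,pV4"), f2)
  m <- load_mapping(c(f1, f2))
  expect_equal(nrow(m), 3L)
  # same (name, type) twice across files is an error
  writeLines(c("part_name,part_type,plasmid_id", "Venus,3,pOther"), f2)
  expect_error(load_mapping(c(f1, f2)), "Venus", class = "moclosim_duplicate_mapping")
})

test_that("resolution follows mapping, direct ids and type disambiguation", {
  db <- list(
    pMYT015 = dna_molecule("ACGTACGT", id = "pMYT015"),
    pV3 = dna_molecule("AAGGAAGG", id = "pV3"),
    pV4 = dna_molecule("TTCCTTCC", id = "pV4")
  )
  mapping <- tibble::tibble(
    part_name = c("pTET", "Venus", "Venus"),
    part_type = c("2", "3", "4"),
    plasmid_id = c("pMYT015", "pV3", "pV4")
  )
  # part name through the mapping
  expect_equal(resolve(part_row("pTET", "2"), mapping, db)[[1]]$id, "pMYT015")
  # a token equal to a plasmid id resolves without any mapping row
  expect_equal(resolve(part_row("pV3"), mapping, db)[[1]]$id, "pV3")
  # the same part name under two types resolves to different plasmids
  expect_equal(resolve(part_row("Venus", "3"), mapping, db)[[1]]$id, "pV3")
  expect_equal(resolve(part_row("Venus", "4"), mapping, db)[[1]]$id, "pV4")
  # raw-mode ambiguity is reported
  expect_error(
    resolve(part_row("Venus"), mapping, db, row = 7L),
    "row 7.*Venus",
    class = "moclosim_resolution_error"
  )
  # unresolvable token cites row, column and token
  expect_error(
    resolve(part_row("nope", column = 2L), mapping, db, row = 3L),
    "row 3, column 2.*nope",
    class = "moclosim_resolution_error"
  )
  # mapping to a missing GenBank file names the file
  mapping2 <- tibble::tibble(part_name = "ghost", part_type = NA, plasmid_id = "pGone")
  expect_error(
    resolve(part_row("ghost"), mapping2, db),
    "pGone",
    class = "moclosim_resolution_error"
  )
})

test_that("a campaign with one defective row yields n-1 products and a cited token", {
  kit <- local_kit()
  camp <- make_campaign(kit, 6, error_rows = 4, seed = 1)
  db <- load_database(kit$db_dir)
  mapping <- load_mapping(kit$mapping_path)
  parsed <- parse_campaign(camp$path, grammar = kit$grammar)
  expect_equal(nrow(parsed), 6L)
  report <- run_campaign(parsed, mapping, db, "BsaI", grammar = kit$grammar)
  expect_equal(glance(report)$n_success, 5L)
  expect_equal(glance(report)$n_failed, 1L)
  bad <- report$rows[report$rows$status != "success", ]
  expect_equal(bad$row, 4L)
  expect_match(bad$reason, camp$manifest$injected, fixed = TRUE)
  expect_match(bad$reason, "row 4")
  # generated ids: prefix + zero-padded counter, one per success
  expect_equal(
    report$rows$plasmid_id[report$rows$status == "success"],
    sprintf("oP%03d", 1:5)
  )
  # determinism: the same campaign resimulated gives identical sequences
  report2 <- run_campaign(parsed, mapping, db, "BsaI", grammar = kit$grammar)
  expect_identical(
    lapply(report$products, function(p) p$sequence),
    lapply(report2$products, function(p) p$sequence)
  )
})

test_that("DB_produced closes the loop into a chained second campaign", {
  kit <- local_kit()
  camp <- make_campaign(kit, 4, seed = 2, path = file.path(kit$dir, "c2.csv"))
  db <- load_database(kit$db_dir)
  mapping <- load_mapping(kit$mapping_path)
  report <- run_campaign(
    parse_campaign(camp$path, grammar = kit$grammar),
    mapping, db, "BsaI",
    grammar = kit$grammar
  )
  dbp <- tempfile(fileext = ".csv")
  write_db_produced(report, dbp)
  produced <- load_mapping(dbp)
  expect_equal(nrow(produced), sum(report$rows$status == "success"))
  # products written as GenBank load straight back as a database
  outdir <- tempfile()
  write_products(report, outdir)
  db2 <- load_database(outdir)
  for (nm in produced$part_name) {
    mol <- resolve(part_row(nm), produced, db2)[[1]]
    expect_s3_class(mol, "dna_molecule")
    expect_equal(
      mol$sequence,
      report$products[[produced$plasmid_id[produced$part_name == nm]]]$sequence
    )
  }
  # provenance serializes one record per row without wall-clock fields
  pv <- tempfile(fileext = ".json")
  write_provenance(report, pv)
  rec <- jsonlite::read_json(pv)
  expect_length(rec, nrow(report$rows))
  expect_equal(rec[[1]]$enzyme, "BsaI")
  expect_false("timestamp" %in% names(rec[[1]]))
})

test_that("permuting campaign rows permutes the report identically", {
  kit <- local_kit()
  camp <- make_campaign(kit, 5, seed = 3, path = file.path(kit$dir, "c3.csv"))
  db <- load_database(kit$db_dir)
  mapping <- load_mapping(kit$mapping_path)
  parsed <- parse_campaign(camp$path, grammar = kit$grammar)
  fwd <- run_campaign(parsed, mapping, db, "BsaI", grammar = kit$grammar)
  rev <- run_campaign(parsed[5:1, ], mapping, db, "BsaI", grammar = kit$grammar)
  merged <- dplyr::inner_join(
    fwd$rows[, c("row", "output_name", "status", "length")],
    rev$rows[, c("row", "output_name", "status", "length")],
    by = "row"
  )
  expect_equal(merged$output_name.x, merged$output_name.y)
  expect_equal(merged$status.x, merged$status.y)
  expect_equal(merged$length.x, merged$length.y)
})

test_that("typed and raw specifications of the same designs agree by sequence", {
  kit <- local_kit()
  db <- load_database(kit$db_dir)
  mapping <- load_mapping(kit$mapping_path)
  camp <- make_campaign(kit, 4, seed = 5, path = file.path(kit$dir, "c5.csv"))
  parsed_typed <- parse_campaign(camp$path, grammar = kit$grammar)
  typed <- run_campaign(parsed_typed, mapping, db, "BsaI", grammar = kit$grammar)

  # rewrite each row using plasmid identifiers directly, raw mode
  raw_path <- file.path(kit$dir, "c5_raw.csv")
  raw_lines <- vapply(seq_len(nrow(parsed_typed)), function(k) {
    parts <- parsed_typed$parts[[k]]
    ids <- mapping$plasmid_id[match(
      paste(parts$name, parts$type_name),
      paste(mapping$part_name, mapping$part_type)
    )]
    paste(c(typed$rows$output_name[k], ids), collapse = ",")
  }, character(1))
  writeLines(raw_lines, raw_path)
  raw <- run_campaign(
    parse_campaign(raw_path), mapping, db, "BsaI"
  )
  expect_equal(sum(raw$rows$status == "success"), sum(typed$rows$status == "success"))
  expect_identical(
    unname(vapply(raw$products, function(p) p$sequence, character(1))),
    unname(vapply(typed$products, function(p) p$sequence, character(1)))
  )
})
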