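#' Generate a miniature, internally coherent MoClo fixture kit
#'
#' Builds a self-consistent typed Golden Gate system from scratch so the
#' whole pipeline can be exercised without any external kit data: `n`
#' positions with distinct non-palindromic fusion sites chained into one
#' circle, and for each position a set of entry plasmids whose part is
#' flanked by outward-facing enzyme sites (so digestion releases exactly
#' one recognition-free insert carrying that position's fusion pair). The
#' kit directory receives the GenBank database (`db/`), the iP_mapping CSV
#' and the grammar YAML — the same formats consumed everywhere else. All
#' randomness is derived from `seed`, so the same seed reproduces the kit
#' byte for byte.
#'
#' Fusion sites are sampled from the 4-mers that are not their own reverse
#' complement, also excluding the reverse complement of any site already
#' chosen (mirroring real kit design rules, which avoid self-ligating
#' junctions). Payload lengths are drawn uniformly in 20-200 bp and
#' payloads/stuffers are resampled until the plasmid contains exactly one
#' recognition site per strand.
#'
#' @param n_positions Number of typed positions (2-8).
#' @param parts_per_position Entry plasmids per position (>= 1).
#' @param enzyme A Type IIS [restriction_enzyme][typeiis_enzyme()] or name
#'   (default BsaI).
#' @param seed Integer seed fully determining the kit.
#' @param dir Directory to create the kit in.
#' @return An object of class `fixture_kit`: list with `grammar`,
#'   `molecules` (named list), `mapping` (tibble), `parts` (tibble:
#'   `position`, `type_name`, `part_name`, `plasmid_id`, `left_fusion`,
#'   `right_fusion`), `dir`, `db_dir`, `mapping_path`, `grammar_path`,
#'   `seed`.
#' @examples
#' kit <- make_kit(3, 1, seed = 1, dir = tempfile("kit"))
#' validate_grammar(kit$grammar)
#' @export
make_kit <- function(n_positions, parts_per_position, enzyme = "BsaI",
                     seed = 1L, dir = tempfile("moclo_kit_")) {
  stopifnot(n_positions >= 2, n_positions <= 8, parts_per_position >= 1)
  enzyme <- get_enzyme(enzyme)
  withr::local_seed(as.integer(seed))

  fusions <- sample_fusion_sites(n_positions, enzyme$overhang_length)
  generic <- c(
    "promoter", "cds", "terminator", "marker", "origin",
    "insulator", "tag", "linker"
  )[seq_len(n_positions)]
  positions <- tibble::tibble(
    type_name = as.character(seq_len(n_positions)),
    generic_name = generic,
    allows_subparts = FALSE,
    left_fusion = fusions,
    right_fusion = fusions[c(seq_len(n_positions)[-1], 1L)]
  )
  grammar <- moclo_grammar(
    name = sprintf("fixture_kit_%dx%d", n_positions, parts_per_position),
    enzyme = enzyme$name, positions = positions,
    naming = naming_convention(prefix = "oP", pad_width = 3L)
  )

  dir.create(file.path(dir, "db"), recursive = TRUE, showWarnings = FALSE)
  parts <- list()
  molecules <- list()
  counter <- 1L
  for (i in seq_len(n_positions)) {
    for (j in seq_len(parts_per_position)) {
      part_name <- sprintf("%s%02d", substr(generic[i], 1, 4), j)
      plasmid_id <- sprintf("pFIX%03d", counter)
      counter <- counter + 1L
      mol <- make_entry_plasmid(
        plasmid_id, part_name, enzyme,
        positions$left_fusion[i], positions$right_fusion[i]
      )
      molecules[[plasmid_id]] <- mol
      write_genbank(mol, file.path(dir, "db", paste0(plasmid_id, ".gb")))
      parts[[length(parts) + 1]] <- tibble::tibble(
        position = i, type_name = positions$type_name[i],
        part_name = part_name, plasmid_id = plasmid_id,
        left_fusion = positions$left_fusion[i],
        right_fusion = positions$right_fusion[i]
      )
    }
  }
  parts <- dplyr::bind_rows(parts)
  mapping <- tibble::tibble(
    part_name = parts$part_name, part_type = parts$type_name,
    plasmid_id = parts$plasmid_id
  )
  mapping_path <- file.path(dir, "iP_mapping.csv")
  readr::write_csv(mapping, mapping_path)
  grammar_path <- file.path(dir, "grammar.yml")
  write_grammar(grammar, grammar_path)

  structure(
    list(
      grammar = grammar, molecules = molecules, mapping = mapping,
      parts = parts, dir = dir, db_dir = file.path(dir, "db"),
      mapping_path = mapping_path, grammar_path = grammar_path,
      seed = as.integer(seed)
    ),
    class = "fixture_kit"
  )
}

#' @export
print.fixture_kit <- function(x, ...) {
  cat(sprintf(
    "<fixture_kit> %s: %d positions x %d parts, %s, seed %d\n  %s\n",
    x$grammar$name, nrow(x$grammar$positions),
    nrow(x$parts) / nrow(x$grammar$positions), x$grammar$enzyme, x$seed, x$dir
  ))
  invisible(x)
}

# 4-mers (or k-mers) that are not their own reverse complement, chosen so
# that no site is the reverse complement of another chosen site
sample_fusion_sites <- function(n, k) {
  bases <- c("A", "C", "G", "T")
  all_kmers <- apply(
    expand.grid(rep(list(bases), k), stringsAsFactors = FALSE),
    1, paste, collapse = ""
  )
  pool <- all_kmers[all_kmers != reverse_complement(all_kmers)]
  chosen <- character()
  pool <- sample(pool)
  for (s in pool) {
    if (length(chosen) == n) break
    if (!(s %in% chosen) && !(revcomp_chr(s) %in% chosen)) chosen <- c(chosen, s)
  }
  if (length(chosen) < n) {
    ms_abort(
      sprintf("cannot draw %d distinct non-self-complementary %d-mers", n, k),
      "moclosim_bad_input"
    )
  }
  chosen
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# entry plasmid: stuffer1 + SITE + x + left + payload + right + y + rcSITE
# + stuffer2 (circular); sites face outward from the backbone into the
# part, so the released insert left+payload+right is recognition-free
make_entry_plasmid <- function(plasmid_id, part_name, enzyme, left, right,
                               payload_len = NULL) {
  recog <- enzyme$recognition
  payload_len <- payload_len %||% sample(20:200, 1)
  for (attempt in 1:100) {
    payload <- random_dna(payload_len)
    stuffer1 <- random_dna(sample(30:60, 1))
    stuffer2 <- random_dna(sample(30:60, 1))
    spacer1 <- random_dna(enzyme$spacer_top)
    spacer2 <- random_dna(enzyme$spacer_top)
    seqs <- paste0(
      stuffer1, recog, spacer1, left, payload, right, spacer2,
      revcomp_chr(recog), stuffer2
    )
    n_plus <- length(find_exact(seqs, recog, circular = TRUE))
    n_minus <- length(find_exact(seqs, revcomp_chr(recog), circular = TRUE))
    if (n_plus == 1 && n_minus == 1) {
      part_start <- nchar(stuffer1) + nchar(recog) + nchar(spacer1)
      feats <- tibble::tibble(
        label = part_name, kind = "misc_feature",
        start = as.integer(part_start),
        end = as.integer(part_start + nchar(left) + nchar(payload) + nchar(right)),
        strand = "+"
      )
      return(dna_molecule(
        seqs,
        id = plasmid_id, topology = "circular", features = feats,
        description = sprintf("fixture entry plasmid carrying %s", part_name)
      ))
    }
  }
  ms_abort(
    "could not scrub stray recognition sites from a fixture plasmid",
    "moclosim_fixture_error"
  )
}

#' Write a synthetic campaign file for a fixture kit
#'
#' Draws `n_rows` typed-mode reactions (one random part per grammar
#' position) and writes them as a campaign CSV. Rows listed in
#' `error_rows` get an injected defect so error handling can be tested:
#' `"typo"` misspells a part name, `"wrong_type"` swaps in a part from
#' another position, `"missing_cell"` blanks a cell. The defects are
#' recorded in a sidecar manifest (CSV next to the campaign file) for test
#' assertions. Fully deterministic given `seed`.
#'
#' @param kit A `fixture_kit` from [make_kit()].
#' @param n_rows Number of reactions.
#' @param error_rows Integer row indices to corrupt.
#' @param defects Defect kinds to cycle through on `error_rows`.
#' @param seed Integer seed.
#' @param path Campaign CSV path.
#' @return List with `path`, `manifest_path` and `manifest` (tibble:
#'   `row`, `column`, `defect`, `original`, `injected`).
#' @export
make_campaign <- function(kit, n_rows, error_rows = integer(),
                          defects = c("typo", "wrong_type", "missing_cell"),
                          seed = 1L,
                          path = file.path(kit$dir, "campaign.csv")) {
  stopifnot(inherits(kit, "fixture_kit"), n_rows >= 1)
  defects <- match.arg(defects, several.ok = TRUE)
  withr::local_seed(as.integer(seed))
  p <- kit$grammar$positions
  header <- c("output_name", sprintf("%s (%s)", p$generic_name, p$type_name))

  # draw distinct designs when the combination space allows it (a campaign
  # would not build the same construct twice); fall back to repeats otherwise
  per_pos <- lapply(
    seq_len(nrow(p)),
    function(i) kit$parts$part_name[kit$parts$position == i]
  )
  combos <- expand.grid(per_pos, stringsAsFactors = FALSE)
  draw <- if (nrow(combos) >= n_rows) {
    combos[sample.int(nrow(combos), n_rows), , drop = FALSE]
  } else {
    combos[sample.int(nrow(combos), n_rows, replace = TRUE), , drop = FALSE]
  }

  manifest <- list()
  lines <- character(n_rows)
  for (r in seq_len(n_rows)) {
    cells <- as.character(unlist(draw[r, ]))
    if (r %in% error_rows) {
      kind <- defects[(match(r, error_rows) - 1) %% length(defects) + 1]
      col <- sample.int(nrow(p), 1)
      original <- cells[col]
      injected <- switch(kind,
        typo = paste0(original, "_typo"),
        wrong_type = {
          other_pos <- if (nrow(p) > 1) ((col) %% nrow(p)) + 1 else col
          cand <- kit$parts$part_name[kit$parts$position == other_pos]
          cand[sample.int(length(cand), 1)]
        },
        missing_cell = ""
      )
      cells[col] <- injected
      manifest[[length(manifest) + 1]] <- tibble::tibble(
        row = r, column = col, defect = kind,
        original = original, injected = injected
      )
    }
    lines[r] <- paste(c("", cells), collapse = ",")
  }
  writeLines(c(paste(header, collapse = ","), lines), path)
  manifest <- if (length(manifest) > 0) {
    dplyr::bind_rows(manifest)
  } else {
    tibble::tibble(
      row = integer(), column = integer(), defect = character(),
      original = character(), injected = character()
    )
  }
  manifest_path <- paste0(sub("\\.csv$", "", path), "_manifest.csv")
  readr::write_csv(manifest, manifest_path)
  list(path = path, manifest_path = manifest_path, manifest = manifest)
}
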