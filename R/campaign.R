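#' Load iP_mapping tables
#'
#' iP_mapping files link human part names (and, for typed systems, part
#' types) to plasmid identifiers, which equal GenBank file basenames in the
#' database. Several files may be loaded together; a `(part_name,
#' part_type)` pair appearing twice — within one file or across files — is
#' a load error rather than silently resolved, because the two rows could
#' point to different plasmids.
#'
#' @param paths Character vector of CSV/TSV paths (columns `part_name`,
#'   `part_type` (optional), `plasmid_id`; comma, semicolon or tab
#'   delimited).
#' @return Tibble with columns `part_name`, `part_type`, `plasmid_id`.
#' @export
load_mapping <- function(paths) {
  tabs <- lapply(paths, function(p) {
    if (!file.exists(p)) {
      ms_abort(paste("mapping file not found:", p), "moclosim_io_error")
    }
    rows <- read_delim_rows(p)
    if (length(rows) == 0) {
      return(tibble::tibble(
        part_name = character(), part_type = character(), plasmid_id = character()
      ))
    }
    header <- tolower(rows[[1]])
    need <- c("part_name", "plasmid_id")
    if (!all(need %in% header)) {
      ms_abort(
        sprintf(
          "mapping file '%s' must have columns part_name[, part_type], plasmid_id",
          p
        ),
        "moclosim_parse_error"
      )
    }
    body <- rows[-1]
    get_col <- function(r, col) {
      i <- match(col, header)
      if (is.na(i) || i > length(r)) NA_character_ else r[i]
    }
    purrr::map_dfr(body, function(r) {
      tibble::tibble(
        part_name = get_col(r, "part_name"),
        part_type = get_col(r, "part_type"),
        plasmid_id = get_col(r, "plasmid_id")
      )
    })
  })
  out <- dplyr::bind_rows(tabs) |>
    dplyr::mutate(part_type = dplyr::na_if(.data$part_type, ""))
  key <- paste(out$part_name, out$part_type, sep = "\r")
  dup <- unique(out$part_name[duplicated(key)])
  if (length(dup) > 0) {
    ms_abort(
      sprintf(
        "duplicate (part_name, part_type) entries across mapping files: %s",
        paste(dup, collapse = ", ")
      ),
      "moclosim_duplicate_mapping"
    )
  }
  out
}

# split a delimited text file into rows of cell tokens; the delimiter
# (comma, semicolon or tab) is auto-detected from the first non-comment line
# since spreadsheet CSV exports vary by locale
read_delim_rows <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(list())
  }
  counts <- vapply(
    c(",", ";", "\t"),
    function(d) lengths(regmatches(lines[1], gregexpr(d, lines[1], fixed = TRUE))),
    integer(1)
  )
  delim <- if (all(counts == 0)) "," else c(",", ";", "\t")[which.max(counts)]
  lapply(lines, function(l) {
    cells <- scan(
      text = l, what = character(), sep = delim, quote = "\"",
      quiet = TRUE, blank.lines.skip = FALSE
    )
    trimws(cells)
  })
}

#' Parse a campaign file
#'
#' Each non-empty, non-comment row of a campaign file specifies one one-pot
#' Golden Gate reaction: an output-name cell (may be blank, in which case
#' the name is composed automatically) followed by the part cells. With a
#' grammar the file is read in typed mode — the column count must match the
#' grammar's positions and each cell may hold several subparts joined by
#' the grammar's separator (e.g. `AGA2.tTDH1`). Without a grammar the file
#' is read in raw mode: any number of part cells per row, blank cells
#' skipped, each naming a part or plasmid directly.
#'
#' @param path Campaign CSV/TSV path.
#' @param grammar Optional [moclo_grammar()] switching on typed mode.
#' @return Tibble with one row per reaction: `row` (data-row number),
#'   `output_name`, and `parts`, a list-column of tibbles with one row per
#'   resolvable molecule (`column`, `type_name`, `cell`, `name`,
#'   `subpart_index`).
#' @export
parse_campaign <- function(path, grammar = NULL) {
  if (!file.exists(path)) {
    ms_abort(paste("campaign file not found:", path), "moclosim_io_error")
  }
  rows <- read_delim_rows(path)
  typed <- !is.null(grammar)
  sep <- if (typed) grammar$subpart_separator else "."
  if (length(rows) == 0) {
    warn(paste("campaign file is empty:", path))
    return(tibble::tibble(
      row = integer(), output_name = character(), parts = list()
    ))
  }
  # a header row is recognised by its first cell
  has_header <- tolower(rows[[1]][1]) %in% c("output_name", "output name")
  expected_header <- if (typed) {
    c("output_name", sprintf(
      "%s (%s)",
      grammar$positions$generic_name, grammar$positions$type_name
    ))
  } else {
    NULL
  }
  body <- if (has_header) rows[-1] else rows
  out <- purrr::imap(body, function(cells, i) {
    if (typed) {
      n_expect <- nrow(grammar$positions) + 1L
      # trailing blanks are a spreadsheet artefact, not a structure error
      while (length(cells) > n_expect && !nzchar(cells[length(cells)])) {
        cells <- cells[-length(cells)]
      }
      if (length(cells) != n_expect) {
        ms_abort(
          sprintf(
            "campaign row %d has %d columns; typed mode expects %d (header: %s)",
            i, length(cells), n_expect, paste(expected_header, collapse = ", ")
          ),
          "moclosim_parse_error"
        )
      }
      types <- grammar$positions$type_name
    } else {
      cells <- cells[c(TRUE, nzchar(cells[-1]))]
      types <- rep(NA_character_, max(length(cells) - 1L, 0L))
    }
    part_cells <- cells[-1]
    parts <- purrr::imap_dfr(part_cells, function(cell, j) {
      subs <- if (nzchar(cell)) strsplit(cell, sep, fixed = TRUE)[[1]] else ""
      if (any(!nzchar(subs))) subs <- cell # blank or malformed; caught at resolution
      tibble::tibble(
        column = as.integer(j), type_name = types[j], cell = cell,
        name = subs, subpart_index = seq_along(subs)
      )
    })
    tibble::tibble(row = as.integer(i), output_name = cells[1], parts = list(parts))
  })
  dplyr::bind_rows(out)
}

#' Resolve part references to database molecules
#'
#' Each part reference resolves to one molecule: a name equal to an
#' existing plasmid identifier resolves directly; otherwise the mapping is
#' consulted — by `(part_name, part_type)` in typed mode (falling back to
#' type-agnostic mapping rows), by name alone in raw mode. The same part
#' name may exist under several types pointing to different plasmids (a
#' reporter cloned with different overhangs); typed resolution
#' disambiguates these, and raw resolution reports them as ambiguous.
#'
#' @param parts Parts tibble of one campaign row (see [parse_campaign()]).
#' @param mapping Tibble from [load_mapping()].
#' @param db Named molecule list from [load_database()].
#' @param row Row number, used in error messages.
#' @return List of [dna_molecule()] in part order.
#' @export
resolve <- function(parts, mapping, db, row = NA_integer_) {
  where <- function(i) {
    sprintf(
      "row %s, column %d%s", row, parts$column[i],
      if (parts$subpart_index[i] > 1 || any(parts$column == parts$column[i] & parts$subpart_index > 1)) {
        sprintf(" (subpart %d)", parts$subpart_index[i])
      } else {
        ""
      }
    )
  }
  # lapply, not purrr::map: resolution errors must propagate with their
  # moclosim_* class so run_campaign can capture them per row
  lapply(seq_len(nrow(parts)), function(i) {
    name <- parts$name[i]
    type <- parts$type_name[i]
    if (!nzchar(name)) {
      ms_abort(
        sprintf("%s: empty part cell", where(i)),
        "moclosim_resolution_error"
      )
    }
    if (name %in% names(db)) {
      return(db[[name]])
    }
    hits <- mapping[mapping$part_name == name, , drop = FALSE]
    if (!is.na(type)) {
      typed_hits <- hits[!is.na(hits$part_type) & hits$part_type == type, , drop = FALSE]
      if (nrow(typed_hits) == 0) typed_hits <- hits[is.na(hits$part_type), , drop = FALSE]
      hits <- typed_hits
    }
    if (nrow(hits) == 0) {
      ms_abort(
        sprintf(
          "%s: cannot resolve part '%s'%s", where(i), name,
          if (!is.na(type)) sprintf(" of type '%s'", type) else ""
        ),
        "moclosim_resolution_error"
      )
    }
    ids <- unique(hits$plasmid_id)
    if (length(ids) > 1) {
      ms_abort(
        sprintf(
          "%s: part '%s' is ambiguous, mapped to plasmids %s (specify a type)",
          where(i), name, paste(ids, collapse = ", ")
        ),
        "moclosim_resolution_error"
      )
    }
    if (!ids %in% names(db)) {
      ms_abort(
        sprintf(
          "%s: part '%s' maps to plasmid '%s' but no such GenBank file is in the database",
          where(i), name, ids
        ),
        "moclosim_resolution_error"
      )
    }
    db[[ids]]
  })
}

#' Run a cloning campaign
#'
#' Simulates every campaign row independently — resolution, digestion,
#' fragment selection and assembly — so that a failing row never aborts
#' the rest of the batch. Successful rows receive a generated plasmid
#' identifier (`prefix` + zero-padded counter, continuing past the largest
#' counter already present in the database so identifiers are never
#' reused). In typed mode, digested fragments are cross-checked against
#' the grammar's expected fusion sites and mismatches raise a warning.
#'
#' @param campaign Parsed campaign tibble from [parse_campaign()].
#' @param mapping Tibble from [load_mapping()].
#' @param db Named molecule list from [load_database()].
#' @param enzyme Type IIS enzyme or name.
#' @param grammar Optional [moclo_grammar()] (typed mode; also supplies the
#'   naming convention).
#' @param try_flip Passed to [assemble()].
#' @return A `campaign_report`: list with `rows` (tibble: `row`,
#'   `output_name`, `status`, `reason`, `plasmid_id`, `length`, `inputs`),
#'   `products` (named molecule list), `enzyme`, `grammar_name` and
#'   `provenance` (one record per row). Use [tidy()] / [glance()] to
#'   extract tabular summaries and [write_db_produced()] /
#'   [write_provenance()] to serialize the bookkeeping files.
#' @export
run_campaign <- function(campaign, mapping, db, enzyme, grammar = NULL,
                         try_flip = TRUE) {
  enzyme <- get_enzyme(enzyme)
  naming <- if (!is.null(grammar)) grammar$naming else naming_convention()
  counter <- next_counter(names(db), naming)
  products <- list()
  rows <- vector("list", nrow(campaign))
  provenance <- vector("list", nrow(campaign))
  for (k in seq_len(nrow(campaign))) {
    row_no <- campaign$row[k]
    parts <- campaign$parts[[k]]
    out_name <- campaign$output_name[k]
    status <- "success"
    reason <- NA_character_
    plasmid_id <- NA_character_
    prod_len <- NA_integer_
    input_ids <- character()
    res <- tryCatch(
      {
        if (!nzchar(out_name)) {
          out_name <- compose_output_name(unique_cells(parts), naming)
        }
        inputs <- resolve(parts, mapping, db, row = row_no)
        input_ids <- vapply(inputs, function(m) m$id, character(1))
        simulate_reaction(inputs, enzyme, try_flip = try_flip)
      },
      moclosim_error = function(e) e
    )
    if (inherits(res, "condition")) {
      status <- "failed"
      reason <- conditionMessage(res)
    } else if (res$status != "success") {
      status <- res$status
      reason <- paste(
        sprintf("%s (%s)", res$diagnostics$issue, res$diagnostics$fusion),
        collapse = "; "
      )
    } else {
      if (!is.null(grammar)) check_expected_fusions(res, parts, grammar, row_no)
      plasmid_id <- sprintf("%s%0*d", naming$prefix, naming$pad_width, counter)
      while (plasmid_id %in% c(names(db), names(products))) {
        counter <- counter + 1L
        plasmid_id <- sprintf("%s%0*d", naming$prefix, naming$pad_width, counter)
      }
      counter <- counter + 1L
      product <- res$product
      product$id <- plasmid_id
      product$description <- paste0(out_name, " - ", product$description)
      products[[plasmid_id]] <- product
      prod_len <- seq_length(product)
    }
    rows[[k]] <- tibble::tibble(
      row = row_no, output_name = out_name, status = status, reason = reason,
      plasmid_id = plasmid_id, length = prod_len, inputs = list(input_ids)
    )
    provenance[[k]] <- list(
      row = row_no, output_name = out_name, status = status,
      inputs = as.list(input_ids), enzyme = enzyme$name,
      product_id = plasmid_id,
      software = paste0("moclosim ", as.character(utils::packageVersion("moclosim")))
    )
  }
  structure(
    list(
      rows = if (length(rows) > 0) dplyr::bind_rows(rows) else empty_report_rows(),
      products = products, enzyme = enzyme$name,
      grammar_name = if (!is.null(grammar)) grammar$name else NA_character_,
      provenance = provenance
    ),
    class = "campaign_report"
  )
}

empty_report_rows <- function() {
  tibble::tibble(
    row = integer(), output_name = character(), status = character(),
    reason = character(), plasmid_id = character(), length = integer(),
    inputs = list()
  )
}

unique_cells <- function(parts) {
  parts[parts$subpart_index == 1, , drop = FALSE]$cell
}

next_counter <- function(ids, naming) {
  pat <- paste0("^", escape_regex(naming$prefix), "([0-9]+)$")
  hits <- regmatches(ids, regexec(pat, ids))
  nums <- vapply(hits, function(h) if (length(h) == 2) as.integer(h[2]) else NA_integer_, integer(1))
  nums <- nums[!is.na(nums)]
  if (length(nums) == 0) 1L else max(nums) + 1L
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

check_expected_fusions <- function(res, parts, grammar, row_no) {
  p <- grammar$positions
  frag_idx <- 0L
  for (col in unique(parts$column)) {
    grp <- parts[parts$column == col, , drop = FALSE]
    pos <- p[p$type_name == grp$type_name[1], , drop = FALSE]
    frags <- res$fragments[frag_idx + seq_len(nrow(grp))]
    frag_idx <- frag_idx + nrow(grp)
    if (nrow(pos) == 0 || is.na(pos$left_fusion) || is.na(pos$right_fusion)) next
    left <- frags[[1]]$left_fusion
    right <- frags[[length(frags)]]$right_fusion
    if (left != pos$left_fusion || right != pos$right_fusion) {
      warn(sprintf(
        "row %d: part '%s' (type %s) has fusion sites %s/%s but the grammar expects %s/%s",
        row_no, grp$cell[1], pos$type_name, left, right,
        pos$left_fusion, pos$right_fusion
      ))
    }
  }
}

#' @export
print.campaign_report <- function(x, ...) {
  n <- nrow(x$rows)
  ok <- sum(x$rows$status == "success")
  cat(sprintf(
    "<campaign_report> %d reaction%s with %s: %d succeeded, %d failed\n",
    n, if (n == 1) "" else "s", x$enzyme, ok, n - ok
  ))
  print(x$rows[, c("row", "output_name", "status", "plasmid_id", "length")])
  invisible(x)
}

#' @method tidy campaign_report
#' @export
tidy.campaign_report <- function(x, ...) x$rows

#' @method glance campaign_report
#' @export
glance.campaign_report <- function(x, ...) {
  tibble::tibble(
    n_reactions = nrow(x$rows),
    n_success = sum(x$rows$status == "success"),
    n_failed = sum(x$rows$status != "success"),
    enzyme = x$enzyme,
    grammar = x$grammar_name
  )
}

#' Write campaign bookkeeping files
#'
#' `write_db_produced()` registers the successfully assembled plasmids in
#' the same schema as an iP_mapping file (`part_name` = composed output
#' name, `part_type` empty, `plasmid_id` = generated identifier), so the
#' file can be loaded with [load_mapping()] and the products of one
#' campaign used as inputs of the next without manual editing. Failed rows
#' are omitted. `write_provenance()` serializes one JSON record per
#' campaign row (inputs, enzyme, product id, software version).
#' `write_products()` writes one GenBank map per success into a directory.
#'
#' @param report A `campaign_report`.
#' @param path Output file (or directory for `write_products()`).
#' @return The path, invisibly.
#' @export
write_db_produced <- function(report, path) {
  ok <- report$rows[report$rows$status == "success", , drop = FALSE]
  readr::write_csv(
    tibble::tibble(
      part_name = ok$output_name, part_type = "", plasmid_id = ok$plasmid_id
    ),
    path
  )
  invisible(path)
}

#' @rdname write_db_produced
#' @export
write_provenance <- function(report, path) {
  jsonlite::write_json(report$provenance, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_db_produced
#' @export
write_products <- function(report, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  for (p in report$products) {
    write_genbank(p, file.path(path, paste0(p$id, ".gb")))
  }
  invisible(path)
}
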