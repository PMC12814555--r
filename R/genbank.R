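#' Read and write GenBank plasmid records
#'
#' The input-plasmid database is a directory of GenBank flat files; assembled
#' output plasmid maps are written back in the same format. `read_genbank()`
#' parses a single record: the molecule id is the file basename without
#' extension, topology comes from the LOCUS line, and the feature table is
#' preserved (locations of the forms `a..b`, `complement(a..b)`, single-base
#' `n`, and origin-wrapping `join(a..L,1..b)` on circular records).
#'
#' Records whose LOCUS line declares neither `circular` nor `linear` are
#' treated as circular (the database holds plasmids) with a warning.
#' Ambiguity codes other than `N` are rejected: digestion is only defined
#' over `{A,C,G,T}`.
#'
#' @param path Path to a `.gb`/`.gbk`/`.genbank` file.
#' @return A [dna_molecule()].
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) {
    ms_abort(paste("GenBank file not found:", path), "moclosim_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  locus_idx <- grep("^LOCUS", lines)
  if (length(locus_idx) == 0) {
    ms_abort(paste("not a GenBank file (no LOCUS line):", path), "moclosim_parse_error")
  }
  if (length(locus_idx) > 1) {
    ms_abort(
      paste("multiple LOCUS records in one file are not supported:", path),
      "moclosim_parse_error"
    )
  }

  locus <- lines[locus_idx]
  topology <- if (grepl("\\bcircular\\b", locus, ignore.case = TRUE)) {
    "circular"
  } else if (grepl("\\blinear\\b", locus, ignore.case = TRUE)) {
    "linear"
  } else {
    warn(sprintf(
      "LOCUS line of '%s' declares no topology; assuming circular (plasmid database)",
      basename(path)
    ))
    "circular"
  }

  definition <- ""
  def_idx <- grep("^DEFINITION", lines)
  if (length(def_idx) > 0) {
    i <- def_idx[1]
    def_lines <- sub("^DEFINITION\\s*", "", lines[i])
    while (i + 1 <= length(lines) && grepl("^\\s{5,}", lines[i + 1])) {
      i <- i + 1
      def_lines <- c(def_lines, trimws(lines[i]))
    }
    definition <- sub("\\.$", "", paste(def_lines, collapse = " "))
  }

  origin_idx <- grep("^ORIGIN", lines)
  if (length(origin_idx) == 0) {
    ms_abort(paste("GenBank record has no ORIGIN section:", path), "moclosim_parse_error")
  }
  end_idx <- grep("^//", lines)
  end_idx <- if (length(end_idx) > 0) end_idx[1] else length(lines) + 1L
  seq_lines <- lines[(origin_idx[1] + 1):(end_idx - 1)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0) {
    ms_abort(paste("GenBank record has an empty sequence:", path), "moclosim_parse_error")
  }
  len <- nchar(sequence)

  features <- parse_genbank_features(lines, origin_idx[1], len, path)

  id <- sub("\\.[^.]*$", "", basename(path))
  tryCatch(
    dna_molecule(sequence,
      id = id, topology = topology, features = features,
      description = definition
    ),
    moclosim_bad_sequence = function(e) {
      ms_abort(
        paste0("while reading '", path, "': ", conditionMessage(e)),
        "moclosim_parse_error"
      )
    }
  )
}

parse_genbank_features <- function(lines, origin_idx, len, path) {
  feat_idx <- grep("^FEATURES", lines)
  features <- empty_features()
  if (length(feat_idx) == 0 || feat_idx[1] > origin_idx) {
    return(features)
  }
  block <- lines[(feat_idx[1] + 1):(origin_idx - 1)]
  # a feature line has its key at column 6; qualifier/continuation lines are
  # indented further
  is_key <- grepl("^\\s{1,10}\\S", block) & !grepl("^\\s*/", block) &
    grepl("^.{5}\\S", block)
  rows <- list()
  current <- NULL
  flush <- function(cur) {
    if (is.null(cur)) {
      return(NULL)
    }
    loc <- parse_genbank_location(cur$location, len, path)
    tibble::tibble(
      label = cur$label %||% cur$gene %||% cur$note %||% cur$kind,
      kind = cur$kind, start = loc$start, end = loc$end, strand = loc$strand
    )
  }
  for (i in seq_along(block)) {
    line <- block[i]
    if (!nzchar(trimws(line))) next
    if (is_key[i]) {
      rows <- c(rows, list(flush(current)))
      parts <- strsplit(trimws(line), "\\s+")[[1]]
      current <- list(kind = parts[1], location = paste(parts[-1], collapse = ""))
    } else if (!is.null(current)) {
      q <- trimws(line)
      if (grepl("^/", q)) {
        kv <- sub("^/", "", q)
        key <- sub("=.*$", "", kv)
        val <- if (grepl("=", kv)) gsub('^"|"$', "", sub("^[^=]*=", "", kv)) else TRUE
        if (key %in% c("label", "gene", "note")) current[[key]] <- val
      } else {
        # location continuation
        current$location <- paste0(current$location, q)
      }
    }
  }
  rows <- c(rows, list(flush(current)))
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) features else dplyr::bind_rows(rows)
}

parse_genbank_location <- function(loc, len, path) {
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    pieces <- strsplit(inner, ",")[[1]]
    if (length(pieces) == 2) {
      p1 <- parse_span(pieces[1])
      p2 <- parse_span(pieces[2])
      if (p1$to == len && p2$from == 1) {
        # origin-wrapping feature on a circular record
        return(list(start = p1$from - 1L, end = len + p2$to, strand = strand))
      }
    }
    ms_abort(
      sprintf("unsupported join() location '%s' in %s", loc, path),
      "moclosim_parse_error"
    )
  }
  span <- parse_span(loc)
  list(start = span$from - 1L, end = span$to, strand = strand)
}

parse_span <- function(x) {
  x <- gsub("[<>]", "", x)
  if (grepl("\\.\\.", x)) {
    parts <- as.integer(strsplit(x, "\\.\\.")[[1]])
    list(from = parts[1], to = parts[2])
  } else {
    n <- as.integer(x)
    list(from = n, to = n)
  }
}

#' @rdname read_genbank
#' @param molecule A [dna_molecule()].
#' @details `write_genbank()` emits a record that `read_genbank()` parses
#'   back to an equal molecule (id, sequence, topology, features). The LOCUS
#'   date field is a fixed placeholder so that regenerated files are
#'   byte-identical.
#' @export
write_genbank <- function(molecule, path) {
  stopifnot(inherits(molecule, "dna_molecule"))
  len <- seq_length(molecule)
  id <- molecule$id %||% "unnamed"
  lines <- c(
    sprintf(
      "LOCUS       %-16s %11d bp    DNA     %-8s SYN 01-JAN-2000",
      id, len, molecule$topology
    ),
    sprintf("DEFINITION  %s.", if (nzchar(molecule$description)) molecule$description else id),
    "ACCESSION   .",
    "VERSION     .",
    "KEYWORDS    .",
    "SOURCE      synthetic DNA construct",
    "  ORGANISM  synthetic DNA construct",
    "FEATURES             Location/Qualifiers"
  )
  feats <- molecule$features
  if (nrow(feats) > 0) {
    for (i in seq_len(nrow(feats))) {
      lines <- c(
        lines,
        format_genbank_feature(
          feats$kind[i], feats$start[i], feats$end[i],
          feats$strand[i], feats$label[i], len
        )
      )
    }
  }
  lines <- c(lines, "ORIGIN", format_genbank_origin(molecule$sequence), "//")
  con <- tryCatch(file(path, "w"), error = function(e) {
    ms_abort(paste("cannot write GenBank file:", path), "moclosim_io_error")
  })
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

format_genbank_feature <- function(kind, start, end, strand, label, len) {
  loc <- if (end > len) {
    sprintf("join(%d..%d,1..%d)", start + 1L, len, end - len)
  } else {
    sprintf("%d..%d", start + 1L, end)
  }
  if (strand == "-") loc <- sprintf("complement(%s)", loc)
  c(
    sprintf("     %-15s %s", kind, loc),
    sprintf("                     /label=\"%s\"", label)
  )
}

format_genbank_origin <- function(sequence) {
  sequence <- tolower(sequence)
  starts <- seq(1, nchar(sequence), by = 60)
  vapply(starts, function(s) {
    chunk <- substr(sequence, s, min(s + 59, nchar(sequence)))
    groups <- substring(chunk, seq(1, nchar(chunk), 10), pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    sprintf("%9d %s", s, paste(groups, collapse = " "))
  }, character(1))
}

#' Load a directory of GenBank files as a plasmid database
#'
#' Reads every `.gb`, `.gbk` and `.genbank` file in `directory` into a named
#' list of molecules keyed by file basename (the plasmid identifier).
#' Identifiers are case-sensitive; two files sharing a basename (e.g.
#' `a.gb` and `a.gbk`) are a hard error because the identifier would be
#' ambiguous. A malformed file raises an error naming that file.
#'
#' @param directory Path to the database directory.
#' @return Named list of [dna_molecule()] objects.
#' @export
load_database <- function(directory) {
  if (!dir.exists(directory)) {
    ms_abort(paste("database directory does not exist:", directory), "moclosim_io_error")
  }
  paths <- list.files(directory,
    pattern = "\\.(gb|gbk|genbank)$",
    full.names = TRUE, ignore.case = FALSE
  )
  ids <- sub("\\.[^.]*$", "", basename(paths))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    ms_abort(
      paste("duplicate plasmid identifiers in database:", paste(dup, collapse = ", ")),
      "moclosim_duplicate_id"
    )
  }
  if (length(paths) == 0) {
    warn(paste("database directory contains no GenBank files:", directory))
    return(stats::setNames(list(), character()))
  }
  db <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    db[[i]] <- tryCatch(read_genbank(paths[i]), error = function(e) {
      ms_abort(
        sprintf("failed to load '%s': %s", paths[i], conditionMessage(e)),
        "moclosim_parse_error"
      )
    })
  }
  stats::setNames(db, ids)
}
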