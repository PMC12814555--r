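#' MoClo assembly grammars
#'
#' A MoClo system assigns parts to typed positions; each type is physically
#' encoded by the pair of fusion sites flanking its parts, and a coherent
#' system chains those pairs into a single circle (the right fusion of each
#' position equals the left fusion of the next, and the last wraps to the
#' first). A `moclo_grammar` captures that system: the ordered positions
#' with their type names, generic names, optional expected fusion sites and
#' subpart permission; the associated Type IIS enzyme; the single-character
#' subpart separator used inside campaign cells; and the naming convention
#' used to compose output plasmid names and generate plasmid identifiers.
#'
#' @param name Grammar name.
#' @param enzyme Name of the Type IIS enzyme the system uses.
#' @param positions Tibble (or data frame) with columns `type_name`,
#'   `generic_name`, and optionally `allows_subparts`, `left_fusion`,
#'   `right_fusion`.
#' @param subpart_separator Single character joining subparts inside one
#'   campaign cell (default `"."`).
#' @param naming Naming convention: list with `joiner` (between part names
#'   in composed output names), `prefix` and `pad_width` (generated plasmid
#'   identifiers are `prefix` + zero-padded counter).
#' @return An object of class `moclo_grammar`.
#' @examples
#' g <- moclo_grammar(
#'   "demo", "BsaI",
#'   tibble::tibble(
#'     type_name = c("1", "2", "3"),
#'     generic_name = c("promoter", "cds", "terminator"),
#'     left_fusion = c("AATG", "GCTT", "TACA"),
#'     right_fusion = c("GCTT", "TACA", "AATG")
#'   )
#' )
#' validate_grammar(g)
#' @export
moclo_grammar <- function(name, enzyme, positions, subpart_separator = ".",
                          naming = naming_convention()) {
  positions <- tibble::as_tibble(positions)
  if (nrow(positions) == 0) {
    ms_abort("a grammar needs at least one position", "moclosim_bad_grammar")
  }
  if (!all(c("type_name", "generic_name") %in% names(positions))) {
    ms_abort("positions need columns type_name and generic_name", "moclosim_bad_grammar")
  }
  if (!"allows_subparts" %in% names(positions)) positions$allows_subparts <- FALSE
  if (!"left_fusion" %in% names(positions)) positions$left_fusion <- NA_character_
  if (!"right_fusion" %in% names(positions)) positions$right_fusion <- NA_character_
  positions <- dplyr::mutate(
    positions,
    type_name = as.character(.data$type_name),
    dplyr::across(dplyr::all_of(c("left_fusion", "right_fusion")), toupper)
  )
  if (anyDuplicated(positions$type_name) > 0) {
    ms_abort("position type names must be unique", "moclosim_bad_grammar")
  }
  if (nchar(subpart_separator) != 1) {
    ms_abort("subpart_separator must be a single character", "moclosim_bad_grammar")
  }
  if (any(grepl(subpart_separator, positions$type_name, fixed = TRUE))) {
    ms_abort(
      "the subpart separator may not occur in any type name",
      "moclosim_bad_grammar"
    )
  }
  structure(
    list(
      name = name, enzyme = enzyme, positions = positions,
      subpart_separator = subpart_separator, naming = naming
    ),
    class = "moclo_grammar"
  )
}

#' @rdname moclo_grammar
#' @param joiner,prefix,pad_width See `naming` above.
#' @export
naming_convention <- function(joiner = "-", prefix = "oP", pad_width = 3L) {
  stopifnot(nzchar(prefix), pad_width >= 1)
  list(joiner = joiner, prefix = prefix, pad_width = as.integer(pad_width))
}

#' @export
print.moclo_grammar <- function(x, ...) {
  cat(sprintf(
    "<moclo_grammar> %s: %d positions, enzyme %s, separator '%s'\n",
    x$name, nrow(x$positions), x$enzyme, x$subpart_separator
  ))
  print(x$positions)
  invisible(x)
}

#' Check a grammar for circular coherence
#'
#' A coherent typed system forms one closed chain of fusion sites: for
#' consecutive positions the right fusion of position *i* equals the left
#' fusion of position *i + 1*, the last right fusion wraps to the first
#' left fusion, and no fusion site is reused. Returns findings as a
#' character vector (empty when coherent); positions with no declared
#' fusion sites are skipped.
#'
#' @param grammar A [moclo_grammar()].
#' @return Character vector of findings; `character(0)` if coherent.
#' @export
validate_grammar <- function(grammar) {
  stopifnot(inherits(grammar, "moclo_grammar"))
  p <- grammar$positions
  findings <- character()
  n <- nrow(p)
  has_fusions <- !is.na(p$left_fusion) & !is.na(p$right_fusion)
  for (col in c("left_fusion", "right_fusion")) {
    vals <- p[[col]][!is.na(p[[col]])]
    bad <- vals[!grepl("^[ACGT]+$", vals)]
    if (length(bad) > 0) {
      findings <- c(findings, sprintf(
        "%s not a DNA string: %s", gsub("_", " ", col), paste(bad, collapse = ", ")
      ))
    }
    dup <- unique(vals[duplicated(vals)])
    if (length(dup) > 0) {
      findings <- c(findings, sprintf(
        "duplicated %s across positions: %s", gsub("_", " ", col),
        paste(dup, collapse = ", ")
      ))
    }
  }
  if (all(has_fusions)) {
    for (i in seq_len(n)) {
      j <- (i %% n) + 1
      if (p$right_fusion[i] != p$left_fusion[j]) {
        findings <- c(findings, sprintf(
          "junction mismatch between positions %s and %s: right fusion %s != left fusion %s",
          p$type_name[i], p$type_name[j], p$right_fusion[i], p$left_fusion[j]
        ))
      }
    }
  }
  findings
}

#' Generate the campaign template for a grammar
#'
#' Emits the tabular skeleton users fill in with a spreadsheet program: a
#' comment row documenting the grammar (enzyme, subpart separator and which
#' positions allow subparts) followed by a header row with the output-name
#' column and one column per position, labelled `generic_name (type_name)`.
#' Generation is deterministic: the same grammar always yields a
#' byte-identical file.
#'
#' @param grammar A [moclo_grammar()]; must validate.
#' @param path Optional file to write the CSV template to.
#' @return Invisibly, a zero-row tibble with the template columns.
#' @export
generate_template <- function(grammar, path = NULL) {
  findings <- validate_grammar(grammar)
  if (length(findings) > 0) {
    ms_abort(
      paste0(
        "grammar does not validate:\n",
        paste("-", findings, collapse = "\n")
      ),
      "moclosim_bad_grammar"
    )
  }
  p <- grammar$positions
  header <- c("output_name", sprintf("%s (%s)", p$generic_name, p$type_name))
  sub_note <- if (any(p$allows_subparts)) {
    sprintf(
      "; positions allowing subparts joined with '%s': %s",
      grammar$subpart_separator,
      paste(p$type_name[p$allows_subparts], collapse = ", ")
    )
  } else {
    ""
  }
  comment <- sprintf(
    "# grammar: %s; enzyme: %s; subpart separator: '%s'%s",
    grammar$name, grammar$enzyme, grammar$subpart_separator, sub_note
  )
  if (!is.null(path)) {
    writeLines(c(comment, paste(header, collapse = ",")), path)
  }
  out <- tibble::as_tibble(stats::setNames(
    rep(list(character()), length(header)), header
  ))
  invisible(out)
}

#' Compose an output plasmid name from its part names
#'
#' Output plasmid names are computed automatically by joining the part
#' names with the convention's joiner (e.g. `pTET-EGII-tTDH1`). Part names
#' containing the joiner are rejected: the composed name could not be
#' decomposed unambiguously.
#'
#' @param parts Ordered character vector of part names.
#' @param convention A naming convention (see [naming_convention()]) or a
#'   [moclo_grammar()].
#' @return The composed name.
#' @examples
#' compose_output_name(c("pTET", "EGII", "tTDH1"), naming_convention())
#' @export
compose_output_name <- function(parts, convention = naming_convention()) {
  if (inherits(convention, "moclo_grammar")) convention <- convention$naming
  if (length(parts) == 0) {
    ms_abort("cannot compose a name from an empty part list", "moclosim_bad_input")
  }
  offending <- parts[grepl(convention$joiner, parts, fixed = TRUE)]
  if (length(offending) > 0) {
    ms_abort(
      sprintf(
        "part name(s) contain the joiner '%s': %s",
        convention$joiner, paste(offending, collapse = ", ")
      ),
      "moclosim_bad_name"
    )
  }
  paste(parts, collapse = convention$joiner)
}

#' Read or write a grammar config file
#'
#' Grammars are stored as YAML: top-level keys `name`, `enzyme`,
#' `subpart_separator`, `naming` (`joiner`/`prefix`/`pad_width`) and
#' `positions`, a list of records with `type_name`, `generic_name`,
#' `allows_subparts`, `left_fusion`, `right_fusion`.
#'
#' @param path Path of the YAML grammar file.
#' @return `read_grammar()` returns a [moclo_grammar()];
#'   `write_grammar()` returns `path` invisibly.
#' @export
read_grammar <- function(path) {
  if (!file.exists(path)) {
    ms_abort(paste("grammar file not found:", path), "moclosim_io_error")
  }
  g <- yaml::read_yaml(path)
  positions <- dplyr::bind_rows(lapply(g$positions, function(p) {
    tibble::tibble(
      type_name = as.character(p$type_name),
      generic_name = p$generic_name,
      allows_subparts = isTRUE(p$allows_subparts),
      left_fusion = p$left_fusion %||% NA_character_,
      right_fusion = p$right_fusion %||% NA_character_
    )
  }))
  naming <- naming_convention(
    joiner = g$naming$joiner %||% "-",
    prefix = g$naming$prefix %||% "oP",
    pad_width = g$naming$pad_width %||% 3L
  )
  moclo_grammar(
    name = g$name, enzyme = g$enzyme, positions = positions,
    subpart_separator = g$subpart_separator %||% ".", naming = naming
  )
}

#' @rdname read_grammar
#' @param grammar A [moclo_grammar()].
#' @export
write_grammar <- function(grammar, path) {
  p <- grammar$positions
  yaml::write_yaml(
    list(
      name = grammar$name,
      enzyme = grammar$enzyme,
      subpart_separator = grammar$subpart_separator,
      naming = grammar$naming,
      positions = lapply(seq_len(nrow(p)), function(i) {
        rec <- list(
          type_name = p$type_name[i], generic_name = p$generic_name[i],
          allows_subparts = p$allows_subparts[i]
        )
        if (!is.na(p$left_fusion[i])) rec$left_fusion <- p$left_fusion[i]
        if (!is.na(p$right_fusion[i])) rec$right_fusion <- p$right_fusion[i]
        rec
      })
    ),
    path
  )
  invisible(path)
}
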