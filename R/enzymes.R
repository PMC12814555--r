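#' Restriction enzymes
#'
#' `typeiis_enzyme()` models a Type IIS enzyme: a non-palindromic
#' recognition sequence cut at fixed offsets downstream. Reading the
#' recognition 5'-3', the strand carrying it is cut `spacer_top` nt after
#' its 3' end and the opposite strand `spacer_bottom` nt after, leaving a
#' 5' overhang of `spacer_bottom - spacer_top` nt (the fusion site).
#' `BsaI GGTCTC(1/5)` therefore leaves 4-nt overhangs.
#'
#' `enzyme_table()` lists the built-in enzymes: the Type IIS enzymes used by
#' common MoClo kits (BsaI, BsmBI, BbsI, SapI, AarI) plus standard
#' palindromic cutters for verification digests (EcoRI, BamHI, HindIII,
#' XhoI, NotI), where `cut_offset` is the top-strand cut position within the
#' site (EcoRI `G^AATTC` has offset 1). `get_enzyme()` looks a name up in
#' the built-in table, optionally extended/overridden by a user table or a
#' YAML config file with fields `name`, `recognition`, `spacer_top`,
#' `spacer_bottom` (Type IIS) or `cut_offset` (palindromic).
#'
#' @param name Enzyme name.
#' @param recognition Recognition sequence, top strand 5'-3'.
#' @param spacer_top,spacer_bottom Cut offsets (nt) past the recognition 3'
#'   end on the recognition-carrying and opposite strand.
#' @return `typeiis_enzyme()` and `get_enzyme()` return an object of class
#'   `restriction_enzyme`; `enzyme_table()` returns a tibble.
#' @examples
#' get_enzyme("BsaI")
#' @export
typeiis_enzyme <- function(name, recognition, spacer_top, spacer_bottom) {
  recognition <- toupper(recognition)
  stopifnot(
    nchar(recognition) > 0, grepl("^[ACGT]+$", recognition),
    spacer_top >= 0, spacer_bottom > spacer_top
  )
  if (recognition == revcomp_chr(recognition)) {
    ms_abort(
      sprintf("'%s': a Type IIS recognition site must be non-palindromic", name),
      "moclosim_bad_enzyme"
    )
  }
  structure(
    list(
      name = name, recognition = recognition,
      spacer_top = as.integer(spacer_top), spacer_bottom = as.integer(spacer_bottom),
      overhang_length = as.integer(spacer_bottom - spacer_top),
      kind = "typeIIS"
    ),
    class = "restriction_enzyme"
  )
}

palindromic_enzyme <- function(name, recognition, cut_offset) {
  recognition <- toupper(recognition)
  stopifnot(grepl("^[ACGT]+$", recognition), recognition == revcomp_chr(recognition))
  structure(
    list(
      name = name, recognition = recognition,
      cut_offset = as.integer(cut_offset), kind = "palindromic"
    ),
    class = "restriction_enzyme"
  )
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  if (x$kind == "typeIIS") {
    cat(sprintf(
      "<enzyme> %s %s(%d/%d), %d-nt 5' overhangs\n",
      x$name, x$recognition, x$spacer_top, x$spacer_bottom, x$overhang_length
    ))
  } else {
    cat(sprintf(
      "<enzyme> %s %s^%s (palindromic)\n",
      x$name, substr(x$recognition, 1, x$cut_offset),
      substr(x$recognition, x$cut_offset + 1, nchar(x$recognition))
    ))
  }
  invisible(x)
}

#' @rdname typeiis_enzyme
#' @export
enzyme_table <- function() {
  tibble::tribble(
    ~name, ~recognition, ~spacer_top, ~spacer_bottom, ~cut_offset, ~kind,
    "BsaI", "GGTCTC", 1L, 5L, NA_integer_, "typeIIS",
    "BsmBI", "CGTCTC", 1L, 5L, NA_integer_, "typeIIS",
    "BbsI", "GAAGAC", 2L, 6L, NA_integer_, "typeIIS",
    "SapI", "GCTCTTC", 1L, 4L, NA_integer_, "typeIIS",
    "AarI", "CACCTGC", 4L, 8L, NA_integer_, "typeIIS",
    "EcoRI", "GAATTC", NA_integer_, NA_integer_, 1L, "palindromic",
    "BamHI", "GGATCC", NA_integer_, NA_integer_, 1L, "palindromic",
    "HindIII", "AAGCTT", NA_integer_, NA_integer_, 1L, "palindromic",
    "XhoI", "CTCGAG", NA_integer_, NA_integer_, 1L, "palindromic",
    "NotI", "GCGGCCGC", NA_integer_, NA_integer_, 2L, "palindromic"
  )
}

#' @rdname typeiis_enzyme
#' @param extra Optional extra enzyme definitions: a tibble with the
#'   `enzyme_table()` columns, or the path of a YAML file holding a list of
#'   such records. Extra definitions override built-ins of the same name.
#' @export
get_enzyme <- function(name, extra = NULL) {
  if (inherits(name, "restriction_enzyme")) {
    return(name)
  }
  tab <- enzyme_table()
  if (!is.null(extra)) {
    if (is.character(extra)) {
      defs <- yaml::read_yaml(extra)
      extra <- dplyr::bind_rows(lapply(defs, function(d) {
        tibble::tibble(
          name = d$name, recognition = toupper(d$recognition),
          spacer_top = as.integer(d$spacer_top %||% NA),
          spacer_bottom = as.integer(d$spacer_bottom %||% NA),
          cut_offset = as.integer(d$cut_offset %||% NA),
          kind = if (is.null(d$cut_offset)) "typeIIS" else "palindromic"
        )
      }))
    }
    tab <- dplyr::bind_rows(extra, tab) |> dplyr::distinct(.data$name, .keep_all = TRUE)
  }
  row <- tab[tab$name == name, ]
  if (nrow(row) == 0) {
    ms_abort(
      sprintf(
        "unknown enzyme '%s'; known enzymes: %s",
        name, paste(tab$name, collapse = ", ")
      ),
      "moclosim_unknown_enzyme"
    )
  }
  if (row$kind == "typeIIS") {
    typeiis_enzyme(row$name, row$recognition, row$spacer_top, row$spacer_bottom)
  } else {
    palindromic_enzyme(row$name, row$recognition, row$cut_offset)
  }
}
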