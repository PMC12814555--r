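#' DNA molecules
#'
#' A `dna_molecule` is the unit stored in the input-plasmid database and
#' produced by assembly: a named DNA sequence with circular or linear
#' topology and a table of annotation features. Sequences are uppercase
#' strings over `A`, `C`, `G`, `T`, `N`; coordinates are 0-based,
#' end-exclusive throughout the package and converted to GenBank's 1-based
#' inclusive convention only at serialization.
#'
#' Features live in a tibble with columns `label`, `kind`, `start`, `end`,
#' `strand`. A feature on a circular molecule may wrap the origin, encoded
#' as `end > length(sequence)` (the interval is read modulo the length).
#'
#' @param sequence DNA string; normalized to uppercase.
#' @param id Identifier; for molecules read from disk this equals the file
#'   basename without extension.
#' @param topology `"circular"` or `"linear"`.
#' @param features Tibble as produced by [empty_features()].
#' @param description Free-text description.
#' @return An object of class `dna_molecule`.
#' @examples
#' m <- dna_molecule("GGTCTCAAATGCCCGCTTTGAGACCTTTT", id = "demo")
#' seq_length(m)
#' @export
dna_molecule <- function(sequence, id = NA_character_,
                         topology = c("circular", "linear"),
                         features = empty_features(),
                         description = "") {
  topology <- match.arg(topology)
  stopifnot(is.character(sequence), length(sequence) == 1)
  sequence <- toupper(gsub("[[:space:]]", "", sequence))
  if (nchar(sequence) == 0) {
    ms_abort("DNA sequence must be non-empty", "moclosim_bad_sequence")
  }
  bad <- gsub("[ACGTN]", "", sequence)
  if (nchar(bad) > 0) {
    ms_abort(
      sprintf(
        "sequence contains letters outside {A,C,G,T,N}: %s",
        paste(unique(strsplit(bad, "")[[1]]), collapse = ", ")
      ),
      "moclosim_bad_sequence"
    )
  }
  features <- as_features(features)
  validate_features(features, nchar(sequence), circular = topology == "circular")
  structure(
    list(
      id = id, sequence = sequence, topology = topology,
      features = features, description = description
    ),
    class = "dna_molecule"
  )
}

#' @rdname dna_molecule
#' @export
empty_features <- function() {
  tibble::tibble(
    label = character(), kind = character(),
    start = integer(), end = integer(), strand = character()
  )
}

as_features <- function(x) {
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(names(empty_features()), names(x))
  if (length(missing_cols) > 0) {
    ms_abort(
      paste("feature table lacks columns:", paste(missing_cols, collapse = ", ")),
      "moclosim_bad_features"
    )
  }
  dplyr::mutate(
    x[names(empty_features())],
    start = as.integer(.data$start), end = as.integer(.data$end)
  )
}

validate_features <- function(features, len, circular) {
  if (nrow(features) == 0) {
    return(invisible(features))
  }
  ok_strand <- features$strand %in% c("+", "-")
  max_end <- if (circular) features$start + len else len
  ok <- features$start >= 0 & features$start < len &
    features$end > features$start & features$end <= max_end
  if (!all(ok & ok_strand)) {
    bad <- which(!(ok & ok_strand))[1]
    ms_abort(
      sprintf(
        "feature '%s' [%d, %d) strand '%s' is invalid for a %s molecule of length %d",
        features$label[bad], features$start[bad], features$end[bad],
        features$strand[bad], if (circular) "circular" else "linear", len
      ),
      "moclosim_bad_features"
    )
  }
  invisible(features)
}

#' @rdname dna_molecule
#' @param x A `dna_molecule`.
#' @export
seq_length <- function(x) {
  stopifnot(inherits(x, "dna_molecule"))
  nchar(x$sequence)
}

#' @export
print.dna_molecule <- function(x, ...) {
  cat(sprintf(
    "<dna_molecule> %s: %d bp, %s, %d feature%s\n",
    x$id %||% "(unnamed)", seq_length(x), x$topology,
    nrow(x$features), if (nrow(x$features) == 1) "" else "s"
  ))
  preview <- if (seq_length(x) > 60) {
    paste0(substr(x$sequence, 1, 57), "...")
  } else {
    x$sequence
  }
  cat(" ", preview, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

# plain-string reverse complement (Watson-Crick, via Biostrings)
revcomp_chr <- function(x) {
  if (nchar(x) == 0) {
    return(x)
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Reverse complement
#'
#' Watson-Crick reverse complement of a DNA string or a [dna_molecule()].
#' For molecules, features are remapped to mirrored coordinates with their
#' strand flipped, so annotation follows the sequence.
#'
#' @param x A DNA string or a `dna_molecule`.
#' @return An object of the same type as `x`.
#' @examples
#' reverse_complement("AATG")
#' @export
reverse_complement <- function(x) UseMethod("reverse_complement")

#' @export
reverse_complement.character <- function(x) vapply(x, revcomp_chr, character(1), USE.NAMES = FALSE)

#' @export
reverse_complement.dna_molecule <- function(x) {
  len <- seq_length(x)
  feats <- x$features
  if (nrow(feats) > 0) {
    # wrapping features (end > len) mirror to wrapping features again
    new_start <- (len - feats$end) %% len
    new_end <- new_start + (feats$end - feats$start)
    feats <- dplyr::mutate(
      feats,
      start = as.integer(new_start),
      end = as.integer(new_end),
      strand = ifelse(.data$strand == "+", "-", "+")
    )
  }
  dna_molecule(
    revcomp_chr(x$sequence),
    id = x$id, topology = x$topology, features = feats,
    description = x$description
  )
}

# substring of a (possibly circular) top strand, 0-based [from, to)
circular_substr <- function(seq, from, to, circular = TRUE) {
  len <- nchar(seq)
  if (!circular && (from < 0 || to > len)) {
    ms_abort("window outside a linear molecule", "moclosim_bad_window")
  }
  span <- to - from
  from <- from %% len
  if (span < 0) ms_abort("window with negative span", "moclosim_bad_window")
  if (span == 0) {
    return("")
  }
  doubled <- if (from + span > len) paste0(seq, seq) else seq
  substr(doubled, from + 1, from + span)
}

# 0-based start positions of exact occurrences of `pattern` on `seq`'s top
# strand; on circles, matches may wrap the origin
find_exact <- function(seq, pattern, circular) {
  len <- nchar(seq)
  m <- nchar(pattern)
  if (m > len) {
    return(integer())
  }
  subject <- if (circular && m > 1) paste0(seq, substr(seq, 1, m - 1)) else seq
  hits <- Biostrings::matchPattern(pattern, Biostrings::DNAString(subject), fixed = TRUE)
  starts <- BiocGenerics::start(hits) - 1L
  sort(starts[starts < len])
}
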