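#' Locate Type IIS recognition sites and their cut positions
#'
#' Scans both strands of a molecule for exact occurrences of the enzyme's
#' recognition sequence and computes where each occurrence cuts. Cut
#' positions are gap indices on the top strand, 0-based: a cut at gap `i`
#' falls between positions `i - 1` and `i`. For a plus-strand hit starting
#' at `s` with recognition length `m`, the top strand is cut at
#' `s + m + spacer_top` and the bottom strand at `s + m + spacer_bottom`;
#' for a minus-strand hit (reverse complement of the recognition found at
#' `s` on the top strand) the cuts fall upstream, at `s - spacer_bottom`
#' (top) and `s - spacer_top` (bottom). On circular molecules matching and
#' cut arithmetic wrap the origin (modulo length). The 5' overhang exposed
#' by a cut always occupies top-strand window `[top_cut, top_cut +
#' overhang_length)`.
#'
#' @param molecule A [dna_molecule()] over `{A,C,G,T}`.
#' @param enzyme A Type IIS [restriction_enzyme][typeiis_enzyme()] (or its name).
#' @return A tibble with columns `enzyme`, `strand`, `recognition_start`,
#'   `top_cut`, `bottom_cut`, sorted by `top_cut`.
#' @examples
#' m <- dna_molecule("GGTCTCAAATGCCCGCTTTGAGACCTTTT", id = "demo")
#' find_sites(m, get_enzyme("BsaI"))
#' @export
find_sites <- function(molecule, enzyme) {
  stopifnot(inherits(molecule, "dna_molecule"))
  enzyme <- get_enzyme(enzyme)
  if (enzyme$kind != "typeIIS") {
    ms_abort(
      sprintf("'%s' is not a Type IIS enzyme", enzyme$name),
      "moclosim_bad_enzyme"
    )
  }
  if (grepl("N", molecule$sequence, fixed = TRUE)) {
    ms_abort(
      sprintf("molecule '%s' contains N; Type IIS matching is only defined over {A,C,G,T}", molecule$id),
      "moclosim_bad_sequence"
    )
  }
  len <- seq_length(molecule)
  circ <- molecule$topology == "circular"
  m <- nchar(enzyme$recognition)

  plus <- find_exact(molecule$sequence, enzyme$recognition, circ)
  minus <- find_exact(molecule$sequence, revcomp_chr(enzyme$recognition), circ)

  hit_row <- function(s, strand) {
    if (strand == "+") {
      tc <- s + m + enzyme$spacer_top
      bc <- s + m + enzyme$spacer_bottom
    } else {
      tc <- s - enzyme$spacer_bottom
      bc <- s - enzyme$spacer_top
    }
    if (circ) {
      tc <- tc %% len
      bc <- bc %% len
    } else if (tc < 0 || bc > len) {
      warn(sprintf(
        "%s site at %d on linear '%s' cuts beyond the molecule end; ignored",
        enzyme$name, s, molecule$id
      ))
      return(NULL)
    }
    tibble::tibble(
      enzyme = enzyme$name, strand = strand,
      recognition_start = as.integer(s),
      top_cut = as.integer(tc), bottom_cut = as.integer(bc)
    )
  }
  rows <- c(
    lapply(plus, hit_row, strand = "+"),
    lapply(minus, hit_row, strand = "-")
  )
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(tibble::tibble(
      enzyme = character(), strand = character(),
      recognition_start = integer(), top_cut = integer(), bottom_cut = integer()
    ))
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$top_cut, .data$recognition_start)
}

#' Sticky-ended fragments
#'
#' A `sticky_fragment` is the unit of Golden Gate joining: a double-stranded
#' segment carrying a 5' overhang (fusion site) at each end. The fragment's
#' top-strand representation is `left_fusion + payload`; by the package's
#' assembly convention the right fusion site belongs to the following
#' fragment in the assembled circle, so lengths are conserved as
#' `sum(payload) + n * overhang_length`. Blunt termini of linear digests
#' carry an empty fusion string.
#'
#' @param left_fusion,right_fusion Overhang sequences as read 5'-3' on the
#'   top strand of the final assembled plasmid.
#' @param payload Double-stranded core between the overhangs (may be "").
#' @param source_id Identifier of the molecule the fragment came from.
#' @param features Annotation tibble in fragment-local coordinates
#'   (0 = first base of `left_fusion`).
#' @param has_recognition Logical: does the fragment still contain the
#'   digesting enzyme's recognition site on either strand?
#' @return An object of class `sticky_fragment`.
#' @export
sticky_fragment <- function(left_fusion, payload, right_fusion,
                            source_id = NA_character_,
                            features = empty_features(),
                            has_recognition = NA) {
  stopifnot(
    grepl("^[ACGT]*$", left_fusion), grepl("^[ACGT]*$", right_fusion),
    grepl("^[ACGT]*$", payload)
  )
  structure(
    list(
      left_fusion = left_fusion, payload = payload, right_fusion = right_fusion,
      source_id = source_id, features = as_features(features),
      has_recognition = has_recognition
    ),
    class = "sticky_fragment"
  )
}

#' @export
print.sticky_fragment <- function(x, ...) {
  cat(sprintf(
    "<sticky_fragment> %s | %d bp payload | %s (from %s%s)\n",
    x$left_fusion, nchar(x$payload), x$right_fusion,
    x$source_id %||% "?",
    if (isTRUE(x$has_recognition)) ", retains recognition site" else ""
  ))
  invisible(x)
}

fragment_full_seq <- function(f) paste0(f$left_fusion, f$payload, f$right_fusion)

fragment_has_recognition <- function(f, enzyme) {
  s <- fragment_full_seq(f)
  grepl(enzyme$recognition, s, fixed = TRUE) ||
    grepl(revcomp_chr(enzyme$recognition), s, fixed = TRUE)
}

# reverse-complemented orientation of a fragment
flip_fragment <- function(f) {
  len <- nchar(f$left_fusion) + nchar(f$payload) + nchar(f$right_fusion)
  feats <- f$features
  if (nrow(feats) > 0) {
    new_start <- len - feats$end
    feats <- dplyr::mutate(
      feats,
      end = as.integer(len - .data$start), start = as.integer(new_start),
      strand = ifelse(.data$strand == "+", "-", "+")
    )
  }
  sticky_fragment(
    left_fusion = revcomp_chr(f$right_fusion),
    payload = revcomp_chr(f$payload),
    right_fusion = revcomp_chr(f$left_fusion),
    source_id = f$source_id, features = feats,
    has_recognition = f$has_recognition
  )
}

#' Digest a molecule with a Type IIS enzyme
#'
#' Applies every cut located by [find_sites()] and returns the resulting
#' sticky fragments. On a circular molecule with `n >= 2` cut sites this
#' yields `n` fragments and conserves length:
#' `sum(nchar(payload)) + n * overhang_length == seq_length(molecule)`.
#' Each fragment is classified as recognition-free (candidate insert) or
#' recognition-containing (backbone) via `has_recognition`.
#'
#' Degenerate cases: a circular molecule with no sites is returned uncut
#' (an empty fragment list carrying the molecule in attribute `"uncut"`,
#' with a warning); exactly one site on a circle merely nicks it open and
#' is an error; two cuts falling closer than one overhang length collide
#' (the overhang of one cut would be destroyed by the other) and are an
#' error describing the collision.
#'
#' Features of the source molecule are carried onto the fragment that fully
#' contains them, in fragment-local coordinates.
#'
#' @inheritParams find_sites
#' @return List of [sticky_fragment()] objects.
#' @examples
#' m <- dna_molecule("GGTCTCAAATGCCCGCTTTGAGACCTTTT", id = "demo")
#' digest(m, "BsaI")
#' @export
digest <- function(molecule, enzyme) {
  enzyme <- get_enzyme(enzyme)
  sites <- find_sites(molecule, enzyme)
  len <- seq_length(molecule)
  circ <- molecule$topology == "circular"
  ohl <- enzyme$overhang_length

  cuts <- unique(sites[, c("top_cut", "bottom_cut")])
  if (nrow(cuts) == 0) {
    warn(sprintf(
      "no %s sites in '%s'; molecule returned uncut",
      enzyme$name, molecule$id
    ))
    out <- list()
    attr(out, "uncut") <- molecule
    return(out)
  }
  if (circ && nrow(cuts) == 1) {
    ms_abort(
      sprintf(
        "single %s cut in circular '%s' only nicks the circle open; no fragments released",
        enzyme$name, molecule$id
      ),
      "moclosim_single_cut"
    )
  }
  tc <- sort(cuts$top_cut)
  if (anyDuplicated(tc) > 0) {
    ms_abort(
      sprintf(
        "colliding cuts in '%s': two sites cut the top strand at the same position %d",
        molecule$id, tc[duplicated(tc)][1]
      ),
      "moclosim_cut_collision"
    )
  }
  gaps <- if (circ) diff(c(tc, tc[1] + len)) else diff(tc)
  if (any(gaps < ohl)) {
    i <- which(gaps < ohl)[1]
    ms_abort(
      sprintf(
        "colliding cuts in '%s': cuts at %d and %d are %d nt apart, inside one %d-nt overhang",
        molecule$id, tc[i], tc[(i %% length(tc)) + 1], gaps[i], ohl
      ),
      "moclosim_cut_collision"
    )
  }

  bounds <- if (circ) {
    data.frame(from = tc, to = c(tc[-1], tc[1] + len))
  } else {
    data.frame(from = c(0L, tc), to = c(tc, len))
  }
  frags <- vector("list", nrow(bounds))
  for (i in seq_len(nrow(bounds))) {
    from <- bounds$from[i]
    to <- bounds$to[i]
    # linear outer termini are blunt (empty fusion); every cut boundary
    # exposes the 5' overhang starting at the cut's top-strand position
    left <- if (circ || from %in% tc) {
      circular_substr(molecule$sequence, from, from + ohl, circ)
    } else {
      ""
    }
    right <- if (circ || to %in% tc) {
      circular_substr(molecule$sequence, to, to + ohl, circ)
    } else {
      ""
    }
    payload_from <- from + nchar(left)
    payload <- circular_substr(molecule$sequence, payload_from, to, circ)
    feats <- features_in_window(molecule$features, from, to + nchar(right), len, circ)
    f <- sticky_fragment(
      left_fusion = left, payload = payload, right_fusion = right,
      source_id = molecule$id, features = feats
    )
    f$has_recognition <- fragment_has_recognition(f, enzyme)
    frags[[i]] <- f
  }
  frags
}

# features fully contained in top-strand window [from, to), remapped to
# window-local coordinates; windows and wrapping features are modular on circles
features_in_window <- function(features, from, to, len, circular) {
  if (nrow(features) == 0) {
    return(empty_features())
  }
  f_start <- features$start
  if (circular) {
    # shift each feature start into [from, from + len)
    f_start <- from + ((features$start - from) %% len)
  }
  f_end <- f_start + (features$end - features$start)
  keep <- f_start >= from & f_end <= to
  out <- features[keep, ]
  out$start <- as.integer(f_start[keep] - from)
  out$end <- as.integer(f_end[keep] - from)
  out
}

#' Select the releasable insert from a digest
#'
#' Golden Gate input plasmids are designed so that exactly one digestion
#' fragment — the part to be assembled — is free of the enzyme's
#' recognition site on both strands; the backbone retains the sites and is
#' re-cut in the one-pot reaction. This returns that unique recognition-free
#' fragment.
#'
#' @param fragments List of [sticky_fragment()] from one [digest()] call.
#' @inheritParams find_sites
#' @return The unique recognition-free [sticky_fragment()].
#' @export
select_insert_fragment <- function(fragments, enzyme) {
  enzyme <- get_enzyme(enzyme)
  src <- if (length(fragments) > 0) fragments[[1]]$source_id else "?"
  free <- Filter(function(f) !fragment_has_recognition(f, enzyme), fragments)
  if (length(free) == 0) {
    ms_abort(
      sprintf(
        "no releasable part in '%s': every %s fragment retains a recognition site",
        src, enzyme$name
      ),
      "moclosim_no_insert"
    )
  }
  if (length(free) > 1) {
    pairs <- vapply(free, function(f) paste0(f$left_fusion, "/", f$right_fusion), character(1))
    ms_abort(
      sprintf(
        "ambiguous digest of '%s': %d recognition-free fragments (fusion pairs %s)",
        src, length(free), paste(pairs, collapse = "; ")
      ),
      "moclosim_ambiguous_insert"
    )
  }
  free[[1]]
}
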