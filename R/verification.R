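#' PCR primers
#'
#' A verification primer: a named DNA oligo of 15-40 nt over `{A,C,G,T}`.
#'
#' @param name Primer name.
#' @param sequence Oligo sequence 5'-3'.
#' @return An object of class `pcr_primer`.
#' @export
primer <- function(name, sequence) {
  sequence <- toupper(sequence)
  if (!grepl("^[ACGT]+$", sequence)) {
    ms_abort(sprintf("primer '%s' must be over {A,C,G,T}", name), "moclosim_bad_primer")
  }
  if (nchar(sequence) < 15 || nchar(sequence) > 40) {
    ms_abort(
      sprintf(
        "primer '%s' is %d nt; must be 15-40 nt", name, nchar(sequence)
      ),
      "moclosim_bad_primer"
    )
  }
  structure(list(name = name, sequence = sequence), class = "pcr_primer")
}

#' Load primers from a CSV file
#'
#' @param path CSV with columns `name`, `sequence`.
#' @return Named list of [primer()] objects.
#' @export
load_primers <- function(path) {
  rows <- read_delim_rows(path)
  if (length(rows) < 2) {
    ms_abort(paste("primer file has no data rows:", path), "moclosim_parse_error")
  }
  header <- tolower(rows[[1]])
  ni <- match("name", header)
  si <- match("sequence", header)
  if (is.na(ni) || is.na(si)) {
    ms_abort("primer file needs columns name, sequence", "moclosim_parse_error")
  }
  prs <- lapply(rows[-1], function(r) primer(r[ni], r[si]))
  stats::setNames(prs, vapply(prs, function(p) p$name, character(1)))
}

#' Simulate PCR on a template
#'
#' Exact-match primer binding (no mismatch or 3'-anchor model, so results
#' are deterministic): the forward primer anneals wherever its sequence
#' occurs on the top strand; the reverse primer anneals wherever its
#' reverse complement occurs on the top strand, downstream of the forward
#' site — wrapping through the origin on circular templates. Amplicon
#' length is measured from the forward primer's 5' start to the reverse
#' primer's 5' start, inclusive of both primers. All productive pairings
#' are reported; a primer binding more than once raises a multiplicity
#' warning, and a primer with no binding site produces a "no amplicon"
#' warning naming the primer and an empty result.
#'
#' @param template A [dna_molecule()].
#' @param fwd,rev [primer()] objects (or plain sequences).
#' @return Tibble with columns `fwd_start`, `rev_end` (0-based top-strand
#'   coordinates) and `length` (bp).
#' @export
simulate_pcr <- function(template, fwd, rev) {
  stopifnot(inherits(template, "dna_molecule"))
  if (is.character(fwd)) fwd <- primer("fwd", fwd)
  if (is.character(rev)) rev <- primer("rev", rev)
  circ <- template$topology == "circular"
  len <- seq_length(template)

  f_starts <- find_exact(template$sequence, fwd$sequence, circ)
  r_starts <- find_exact(template$sequence, revcomp_chr(rev$sequence), circ)
  empty <- tibble::tibble(fwd_start = integer(), rev_end = integer(), length = integer())
  for (miss in list(list(p = fwd, hits = f_starts), list(p = rev, hits = r_starts))) {
    if (length(miss$hits) == 0) {
      warn(sprintf(
        "no amplicon: primer '%s' has no binding site on '%s'",
        miss$p$name, template$id
      ))
      return(empty)
    }
  }
  if (length(f_starts) > 1 || length(r_starts) > 1) {
    warn(sprintf(
      "multiple binding sites (%d forward, %d reverse) on '%s'; all products listed",
      length(f_starts), length(r_starts), template$id
    ))
  }
  min_len <- max(nchar(fwd$sequence), nchar(rev$sequence))
  out <- tidyr::expand_grid(fwd_start = f_starts, rev_start = r_starts) |>
    dplyr::mutate(rev_end = .data$rev_start + nchar(rev$sequence) - 1L)
  if (circ) {
    out <- dplyr::mutate(out,
      length = ((.data$rev_end - .data$fwd_start) %% len) + 1L
    )
  } else {
    out <- dplyr::mutate(out, length = .data$rev_end - .data$fwd_start + 1L)
  }
  out |>
    dplyr::filter(.data$length >= min_len) |>
    dplyr::select("fwd_start", "rev_end", "length") |>
    dplyr::arrange(.data$fwd_start, .data$rev_end)
}

#' Simulate a verification restriction digest
#'
#' Pools the cut positions of all named enzymes (standard palindromic
#' cutters and Type IIS enzymes alike) and returns the fragment lengths a
#' gel would show: a circular template with `n` cuts gives `n` fragments, a
#' linear template `n + 1`; lengths always sum to the template length. A
#' circular template with zero cuts returns its full length flagged as
#' uncut (attribute `"uncut"`).
#'
#' @param template A [dna_molecule()].
#' @param enzymes Character vector of enzyme names (see [enzyme_table()])
#'   or `restriction_enzyme` objects.
#' @param extra Optional extra enzyme definitions passed to [get_enzyme()].
#' @return Integer vector of fragment lengths, sorted decreasing.
#' @export
simulate_restriction_digest <- function(template, enzymes, extra = NULL) {
  stopifnot(inherits(template, "dna_molecule"))
  circ <- template$topology == "circular"
  len <- seq_length(template)
  cuts <- integer()
  for (e in enzymes) {
    enz <- get_enzyme(e, extra = extra)
    if (enz$kind == "typeIIS") {
      hits <- find_sites(template, enz)
      cuts <- c(cuts, hits$top_cut)
    } else {
      starts <- find_exact(template$sequence, enz$recognition, circ)
      ec <- starts + enz$cut_offset
      if (circ) ec <- ec %% len else ec <- ec[ec >= 0 & ec <= len]
      cuts <- c(cuts, ec)
    }
  }
  cuts <- sort(unique(cuts))
  if (length(cuts) == 0) {
    if (circ) {
      out <- len
      attr(out, "uncut") <- TRUE
      return(out)
    }
    return(len)
  }
  lens <- if (circ) {
    diff(c(cuts, cuts[1] + len))
  } else {
    diff(unique(c(0L, cuts, len)))
  }
  sort(as.integer(lens), decreasing = TRUE)
}

#' Simulated agarose gels
#'
#' `gel_lane()` builds one lane (a label plus its fragment sizes, stored
#' sorted decreasing); `render_gel()` lays lanes out next to a size ladder
#' (lane 1) and computes band migration positions. Migration is purely
#' presentational — `position = 14 - 3 * log10(size)`, monotone decreasing
#' in log10(size) — and the size table is the testable artifact; the
#' ggplot2 rendering is obtained with [autoplot()] or `plot()`.
#'
#' @param label Lane label.
#' @param sizes Fragment sizes (bp), any order.
#' @param lanes List of `gel_lane` objects.
#' @param ladder Ladder sizes (bp) drawn in lane 1.
#' @return `render_gel()` returns an object of class `gel_sim` whose
#'   `$table` holds columns `lane_index`, `lane`, `size_bp`, `position`.
#' @export
gel_lane <- function(label, sizes) {
  sizes <- as.integer(sizes)
  if (any(sizes < 1)) {
    ms_abort("gel band sizes must be >= 1 bp", "moclosim_bad_input")
  }
  structure(
    list(label = label, fragment_sizes = sort(sizes, decreasing = TRUE)),
    class = "gel_lane"
  )
}

#' @rdname gel_lane
#' @export
render_gel <- function(lanes,
                       ladder = c(
                         10000, 8000, 6000, 5000, 4000, 3000, 2500,
                         2000, 1500, 1000, 750, 500, 250, 100
                       )) {
  if (inherits(lanes, "gel_lane")) lanes <- list(lanes)
  if (length(lanes) < 1) {
    ms_abort("a gel needs at least one lane", "moclosim_bad_input")
  }
  all_lanes <- c(list(gel_lane("ladder", ladder)), lanes)
  table <- purrr::imap_dfr(all_lanes, function(l, i) {
    tibble::tibble(
      lane_index = as.integer(i), lane = l$label,
      size_bp = l$fragment_sizes,
      position = gel_position(l$fragment_sizes)
    )
  })
  structure(list(table = table), class = "gel_sim")
}

gel_position <- function(size) 14 - 3 * log10(size)

#' @export
print.gel_sim <- function(x, ...) {
  cat(sprintf(
    "<gel_sim> %d lanes (incl. ladder), %d bands\n",
    max(x$table$lane_index), nrow(x$table)
  ))
  print(x$table)
  invisible(x)
}

#' @rdname gel_lane
#' @param object,x A `gel_sim`.
#' @param ... Unused.
#' @method autoplot gel_sim
#' @export
autoplot.gel_sim <- function(object, ...) {
  tab <- dplyr::mutate(
    object$table,
    lane_label = stats::reorder(paste0(.data$lane_index, ": ", .data$lane), .data$lane_index)
  )
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$lane_label, y = .data$position)) +
    ggplot2::geom_tile(width = 0.6, height = 0.035, fill = "grey15") +
    ggplot2::geom_text(
      data = tab[tab$lane_index == 1, ],
      ggplot2::aes(label = .data$size_bp),
      hjust = 2.1, size = 2.6, colour = "grey40"
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = "migration", title = "Simulated agarose gel") +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid = ggplot2::element_blank())
}

#' @export
plot.gel_sim <- function(x, ...) print(autoplot(x, ...))

#' @rdname gel_lane
#' @param gel A `gel_sim`.
#' @param path Output CSV path.
#' @export
write_gel_table <- function(gel, path) {
  readr::write_csv(gel$table, path)
  invisible(path)
}
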