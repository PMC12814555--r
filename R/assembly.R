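#' Join sticky fragments by matching fusion sites
#'
#' Builds the directed chaining in which fragment A may precede fragment B
#' iff `A$right_fusion == B$left_fusion`, and reports one of four outcomes:
#'
#' * `success` — the fragments admit exactly one circular chaining using
#'   every fragment once; the product is returned as a circular
#'   [dna_molecule()] whose top strand is the concatenation of
#'   `left_fusion + payload` around the cycle (so its length is
#'   `sum(payload) + n * overhang_length`). The coordinate origin is the
#'   first base of the fusion site of `fragments[[origin_fragment]]`, making
#'   output files deterministic.
#' * `incomplete` — some fusion site has no partner.
#' * `ambiguous` — some fusion site is the left (or right) end of two or
#'   more fragments, so several products could form.
#' * `multiple_circles` — the chaining closes into two or more disjoint
#'   circles instead of one.
#'
#' Ligation is orientation-agnostic chemically, and MoClo kits rely on only
#' one orientation chaining. With `try_flip = TRUE` (default) a fragment
#' whose forward orientation pairs with nothing is retried
#' reverse-complemented (with a warning); a fragment usable in both
#' orientations is reported as ambiguous.
#'
#' @param fragments List of two or more [sticky_fragment()] objects.
#' @param try_flip Attempt reverse-complement rescue of non-chaining
#'   fragments.
#' @param origin_fragment Index of the fragment whose left fusion site
#'   becomes position 0 of the product.
#' @param product_id Identifier given to the product molecule.
#' @return An object of class `assembly_result`: a list with `status`,
#'   `product` (on success), `diagnostics` (tibble of per-fusion findings)
#'   and `fragments` (as oriented for the build).
#' @examples
#' frags <- list(
#'   sticky_fragment("AATG", "CCC", "GCTT", "a"),
#'   sticky_fragment("GCTT", "TTTTT", "TACA", "b"),
#'   sticky_fragment("TACA", "GGGGGGG", "AATG", "c")
#' )
#' assemble(frags)
#' @export
assemble <- function(fragments, try_flip = TRUE, origin_fragment = 1L,
                     product_id = NA_character_) {
  if (length(fragments) < 2) {
    ms_abort("assembly needs at least two fragments", "moclosim_bad_input")
  }
  stopifnot(all(vapply(fragments, inherits, logical(1), "sticky_fragment")))
  n <- length(fragments)

  if (try_flip) {
    oriented <- orient_fragments(fragments)
    fragments <- oriented$fragments
    if (!is.null(oriented$ambiguous_orientation)) {
      return(new_assembly_result(
        "ambiguous",
        diagnostics = oriented$ambiguous_orientation, fragments = fragments
      ))
    }
  }

  lefts <- vapply(fragments, function(f) f$left_fusion, character(1))
  rights <- vapply(fragments, function(f) f$right_fusion, character(1))

  dup_left <- unique(lefts[duplicated(lefts)])
  dup_right <- unique(rights[duplicated(rights)])
  if (length(dup_left) > 0 || length(dup_right) > 0) {
    diag <- dplyr::bind_rows(
      fusion_diag("duplicated left fusion site", dup_left, lefts, fragments),
      fusion_diag("duplicated right fusion site", dup_right, rights, fragments)
    )
    return(new_assembly_result("ambiguous", diagnostics = diag, fragments = fragments))
  }

  unmatched_right <- setdiff(rights, lefts)
  unmatched_left <- setdiff(lefts, rights)
  if (length(unmatched_right) > 0 || length(unmatched_left) > 0 ||
    any(!nzchar(lefts)) || any(!nzchar(rights))) {
    diag <- dplyr::bind_rows(
      fusion_diag("right fusion site without partner", unmatched_right, rights, fragments),
      fusion_diag("left fusion site without partner", unmatched_left, lefts, fragments)
    )
    return(new_assembly_result("incomplete", diagnostics = diag, fragments = fragments))
  }

  # perfect matching: follow the unique successor chain from the origin
  succ <- match(rights, lefts)
  order_idx <- integer(n)
  cur <- as.integer(origin_fragment)
  for (i in seq_len(n)) {
    order_idx[i] <- cur
    cur <- succ[cur]
  }
  if (cur != origin_fragment || anyDuplicated(order_idx) > 0) {
    cycle1 <- unique(order_idx[seq_len(match(TRUE, duplicated(order_idx), nomatch = n + 1) - 1)])
    diag <- tibble::tibble(
      issue = "fragments close into more than one circle",
      fusion = NA_character_,
      fragments = paste(vapply(
        fragments[cycle1], function(f) f$source_id %||% "?",
        character(1)
      ), collapse = "+")
    )
    return(new_assembly_result("multiple_circles", diagnostics = diag, fragments = fragments))
  }

  product <- build_product(fragments[order_idx], product_id)
  new_assembly_result("success",
    product = product, fragments = fragments,
    order = order_idx
  )
}

orient_fragments <- function(fragments) {
  n <- length(fragments)
  lefts <- vapply(fragments, function(f) f$left_fusion, character(1))
  rights <- vapply(fragments, function(f) f$right_fusion, character(1))
  for (i in seq_len(n)) {
    fwd_ok <- lefts[i] %in% rights[-i] && rights[i] %in% lefts[-i]
    fl <- flip_fragment(fragments[[i]])
    flip_ok <- fl$left_fusion %in% rights[-i] && fl$right_fusion %in% lefts[-i]
    if (fwd_ok && flip_ok) {
      return(list(
        fragments = fragments,
        ambiguous_orientation = tibble::tibble(
          issue = "fragment chains in both orientations",
          fusion = paste0(lefts[i], "/", rights[i]),
          fragments = fragments[[i]]$source_id %||% "?"
        )
      ))
    }
    if (!fwd_ok && flip_ok) {
      warn(sprintf(
        "fragment from '%s' only chains reverse-complemented; flipping it",
        fragments[[i]]$source_id %||% "?"
      ))
      fragments[[i]] <- fl
      lefts[i] <- fl$left_fusion
      rights[i] <- fl$right_fusion
    }
  }
  list(fragments = fragments, ambiguous_orientation = NULL)
}

fusion_diag <- function(issue, fusions, ends, fragments) {
  if (length(fusions) == 0) {
    return(NULL)
  }
  purrr::map_dfr(fusions, function(fu) {
    ids <- vapply(
      fragments[ends == fu], function(f) f$source_id %||% "?",
      character(1)
    )
    tibble::tibble(issue = issue, fusion = fu, fragments = paste(ids, collapse = "+"))
  })
}

build_product <- function(ordered, product_id) {
  pieces <- vapply(ordered, function(f) paste0(f$left_fusion, f$payload), character(1))
  offsets <- cumsum(c(0L, nchar(pieces)[-length(pieces)]))
  feats <- purrr::map2_dfr(ordered, offsets, function(f, off) {
    if (nrow(f$features) == 0) {
      return(empty_features())
    }
    dplyr::mutate(f$features,
      start = .data$start + as.integer(off),
      end = .data$end + as.integer(off)
    )
  })
  seqs <- paste(pieces, collapse = "")
  len <- nchar(seqs)
  if (nrow(feats) > 0) {
    # a feature of the last fragment may extend past the seam into the first
    # fusion site; keep it as a wrapping feature
    feats <- feats[feats$start < len, ]
  }
  dna_molecule(
    seqs,
    id = product_id, topology = "circular", features = feats,
    description = paste(
      "Golden Gate assembly of",
      paste(unique(vapply(ordered, function(f) f$source_id %||% "?", character(1))),
        collapse = ", "
      )
    )
  )
}

new_assembly_result <- function(status, product = NULL, diagnostics = NULL,
                                fragments = NULL, order = NULL) {
  if (is.null(diagnostics)) {
    diagnostics <- tibble::tibble(
      issue = character(), fusion = character(), fragments = character()
    )
  }
  structure(
    list(
      status = status, product = product, diagnostics = diagnostics,
      fragments = fragments, order = order
    ),
    class = "assembly_result"
  )
}

#' @export
print.assembly_result <- function(x, ...) {
  cat(sprintf(
    "<assembly_result> %s (%d fragments)\n",
    x$status, length(x$fragments %||% list())
  ))
  if (x$status == "success") {
    cat(sprintf("  product: %d bp circular\n", seq_length(x$product)))
  } else if (nrow(x$diagnostics) > 0) {
    for (i in seq_len(nrow(x$diagnostics))) {
      cat(sprintf(
        "  %s: %s (%s)\n", x$diagnostics$issue[i],
        x$diagnostics$fusion[i] %||% "-", x$diagnostics$fragments[i]
      ))
    }
  }
  invisible(x)
}

#' @method tidy assembly_result
#' @export
tidy.assembly_result <- function(x, ...) {
  tibble::tibble(
    status = x$status,
    product_length = if (x$status == "success") seq_length(x$product) else NA_integer_,
    n_fragments = length(x$fragments %||% list()),
    n_findings = nrow(x$diagnostics)
  )
}

#' Simulate one one-pot Golden Gate reaction
#'
#' Runs the full digestion-selection-ligation pipeline for one reaction:
#' every input molecule is digested with the enzyme, its unique
#' recognition-free fragment is selected (input plasmids — entry parts and
#' acceptors alike — are designed so that the usable piece is the one whose
#' flanking sites face outward, leaving it free of recognition sites), and
#' the selected fragments are assembled by matching overhangs. Digestion and
#' selection failures are re-raised with the offending plasmid id in the
#' message.
#'
#' @param inputs List of [dna_molecule()] objects (the resolved input
#'   plasmids of one campaign row).
#' @inheritParams find_sites
#' @inheritParams assemble
#' @return An `assembly_result`; the product origin is anchored on the
#'   first-listed input's fragment.
#' @export
simulate_reaction <- function(inputs, enzyme, try_flip = TRUE,
                              product_id = NA_character_) {
  enzyme <- get_enzyme(enzyme)
  stopifnot(length(inputs) >= 2)
  inserts <- vector("list", length(inputs))
  for (i in seq_along(inputs)) {
    mol <- inputs[[i]]
    frags <- withCallingHandlers(
      tryCatch(
        digest(mol, enzyme),
        moclosim_error = function(e) {
          ms_abort(
            sprintf("input '%s': %s", mol$id, conditionMessage(e)),
            class(e)[1]
          )
        }
      ),
      warning = function(w) invokeRestart("muffleWarning")
    )
    if (length(frags) == 0) {
      ms_abort(
        sprintf("input '%s': no %s sites; nothing released", mol$id, enzyme$name),
        "moclosim_no_sites"
      )
    }
    inserts[[i]] <- select_insert_fragment(frags, enzyme)
  }
  assemble(inserts,
    try_flip = try_flip, origin_fragment = 1L,
    product_id = product_id
  )
}
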