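# Independent oracles and small fixture builders shared across tests.
# The oracles deliberately avoid the package's own search/assembly code
# paths: plain substring loops and exhaustive enumeration only.

# O(n*m) brute-force scan of both strands for recognition occurrences,
# computing cut positions directly from the spacer geometry definition
brute_find_sites <- function(seq, circular, recognition, spacer_top, spacer_bottom) {
  len <- nchar(seq)
  m <- nchar(recognition)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(recognition)))
  doubled <- paste0(seq, seq)
  hits <- list()
  last <- if (circular) len - 1 else len - m
  for (s in 0:last) {
    window <- substr(doubled, s + 1, s + m)
    if (window == recognition) {
      tc <- s + m + spacer_top
      bc <- s + m + spacer_bottom
      if (circular) {
        tc <- tc %% len
        bc <- bc %% len
      } else if (bc > len) {
        next
      }
      hits[[length(hits) + 1]] <- data.frame(
        strand = "+", recognition_start = s, top_cut = tc, bottom_cut = bc
      )
    }
    if (window == rc) {
      tc <- s - spacer_bottom
      bc <- s - spacer_top
      if (circular) {
        tc <- tc %% len
        bc <- bc %% len
      } else if (tc < 0) {
        next
      }
      hits[[length(hits) + 1]] <- data.frame(
        strand = "-", recognition_start = s, top_cut = tc, bottom_cut = bc
      )
    }
  }
  if (length(hits) == 0) {
    return(data.frame(
      strand = character(), recognition_start = integer(),
      top_cut = integer(), bottom_cut = integer()
    ))
  }
  out <- do.call(rbind, hits)
  out[order(out$top_cut, out$recognition_start), ]
}

# exhaustive enumeration of circular orderings: with fragment 1 pinned first
# (rotations quotiented out), count permutations of the rest in which every
# junction matches, including the wrap-around
brute_count_circular_orderings <- function(fragments) {
  n <- length(fragments)
  lefts <- vapply(fragments, function(f) f$left_fusion, character(1))
  rights <- vapply(fragments, function(f) f$right_fusion, character(1))
  perms <- function(v) {
    if (length(v) <= 1) {
      return(list(v))
    }
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  count <- 0L
  for (tail in perms(seq_len(n)[-1])) {
    ord <- c(1L, tail)
    ok <- TRUE
    for (k in seq_len(n)) {
      nxt <- ord[(k %% n) + 1]
      if (rights[ord[k]] != lefts[nxt]) {
        ok <- FALSE
        break
      }
    }
    if (ok) count <- count + 1L
  }
  count
}

# random circular molecule with >= 2 BsaI sites embedded at random offsets;
# used for conservation / rotation properties. Accidental extra sites are
# fine (the properties must hold for any successful digest).
random_site_circle <- function(id, total_len = NULL, n_sites = NULL) {
  n_sites <- n_sites %||% sample(2:5, 1)
  total_len <- total_len %||% sample(500:9000, 1)
  bases <- c("A", "C", "G", "T")
  chunk_len <- max((total_len %/% n_sites) - 11, 30)
  pieces <- vapply(seq_len(n_sites), function(i) {
    site <- if (i %% 2 == 0) "GGTCTC" else "GGAGACC" # one strand each way
    paste0(site, paste(sample(bases, chunk_len, replace = TRUE), collapse = ""))
  }, character(1))
  dna_molecule(paste(pieces, collapse = ""), id = id, topology = "circular")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rotate a circular molecule's origin by k positions
rotate_molecule <- function(mol, k) {
  len <- seq_length(mol)
  k <- k %% len
  if (k == 0) {
    return(mol)
  }
  seqs <- paste0(
    substr(mol$sequence, k + 1, len),
    substr(mol$sequence, 1, k)
  )
  dna_molecule(seqs, id = mol$id, topology = mol$topology)
}

# canonical form of a fragment multiset for comparisons
fragment_multiset <- function(fragments) {
  sort(vapply(
    fragments,
    function(f) paste(f$left_fusion, f$payload, f$right_fusion, sep = "|"),
    character(1)
  ))
}

# fragments whose payloads each carry a forward BsaI site placed so that
# re-digesting the assembled product regenerates exactly the input cuts
# (acceptor-style: flanking sites are retained in the product)
redigestible_fragments <- function(fusions = c("AATG", "GCTT", "TACA"),
                                   cores = c("CCAATT", "TTGGAACCAA", "ACCA")) {
  n <- length(fusions)
  lapply(seq_len(n), function(i) {
    sticky_fragment(
      left_fusion = fusions[i],
      payload = paste0(cores[i], "GGTCTC", "A"),
      right_fusion = fusions[(i %% n) + 1],
      source_id = paste0("frag", i)
    )
  })
}

# minimal parts tibble for resolve() as parse_campaign would build it
part_row <- function(name, type = NA_character_, column = 1L) {
  tibble::tibble(
    column = as.integer(column), type_name = type, cell = name,
    name = name, subpart_index = 1L
  )
}
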