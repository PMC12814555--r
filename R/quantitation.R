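#' Convert a molar DNA amount to mass
#'
#' Equimolar Golden Gate reactions dose each input plasmid by moles, but
#' stocks are quantified in ng/uL; the conversion uses the average molar
#' mass of double-stranded DNA, 650 g/mol per base pair (overridable):
#' `ng = fmol * length_bp * bp_mass * 1e-6`.
#'
#' @param amount_fmol Amount in femtomoles (> 0).
#' @param length_bp Molecule length in base pairs (>= 1).
#' @param bp_mass Average dsDNA molar mass per bp, g/mol (default 650).
#' @return Mass in nanograms.
#' @examples
#' fmol_to_ng(20, 2000) # 26 ng
#' @export
fmol_to_ng <- function(amount_fmol, length_bp, bp_mass = 650) {
  if (any(amount_fmol <= 0) || any(length_bp < 1) || bp_mass <= 0) {
    ms_abort(
      "fmol_to_ng() needs a positive amount, length and bp mass",
      "moclosim_bad_input"
    )
  }
  amount_fmol * length_bp * bp_mass * 1e-6
}

#' Reaction parameters for dilution planning
#'
#' @param target_fmol Molar amount of each part per reaction (fmol).
#' @param reaction_volume_ul Final one-pot reaction volume (uL).
#' @param min_pipettable_ul Smallest volume the pipettor can transfer (uL);
#'   parts whose required volume falls below it are pre-diluted.
#' @param dead_volume_factor Multiplier (>= 1) applied to per-part totals to
#'   cover pipetting dead volume.
#' @return A list of class `reaction_params`.
#' @export
reaction_params <- function(target_fmol, reaction_volume_ul,
                            min_pipettable_ul = 0.5, dead_volume_factor = 1) {
  stopifnot(
    target_fmol > 0, reaction_volume_ul > 0, min_pipettable_ul > 0,
    dead_volume_factor >= 1
  )
  structure(
    list(
      target_fmol = target_fmol, reaction_volume_ul = reaction_volume_ul,
      min_pipettable_ul = min_pipettable_ul,
      dead_volume_factor = dead_volume_factor
    ),
    class = "reaction_params"
  )
}

#' Load stock concentrations
#'
#' @param path CSV with columns `plasmid_id`, `ng_per_ul`.
#' @return Tibble with those columns.
#' @export
load_stocks <- function(path) {
  rows <- read_delim_rows(path)
  if (length(rows) < 1) {
    ms_abort(paste("stock file is empty:", path), "moclosim_parse_error")
  }
  header <- tolower(rows[[1]])
  pi <- match("plasmid_id", header)
  ci <- match("ng_per_ul", header)
  if (is.na(pi) || is.na(ci)) {
    ms_abort("stock file needs columns plasmid_id, ng_per_ul", "moclosim_parse_error")
  }
  out <- purrr::map_dfr(rows[-1], function(r) {
    tibble::tibble(plasmid_id = r[pi], ng_per_ul = as.numeric(r[ci]))
  })
  if (any(is.na(out$ng_per_ul) | out$ng_per_ul <= 0)) {
    ms_abort("stock concentrations must be positive numbers", "moclosim_parse_error")
  }
  out
}

#' Compute equimolar input-plasmid dilutions for a campaign
#'
#' For every input plasmid used in the campaign, the volume delivering
#' `target_fmol` per reaction is `v = fmol_to_ng(target_fmol, length) /
#' concentration`. When `v` falls below the pipettable minimum, the stock
#' is pre-diluted by the smallest power of 10 `d` such that `v * d >=
#' min_pipettable_ul`, and `v * d` of the 1:`d` intermediate dilution is
#' dispensed instead — the delivered molar amount is exact either way.
#' Per-plasmid master-mix totals are `dispensed volume x reactions using
#' the plasmid x dead_volume_factor`; each reaction is topped up with
#' water to `reaction_volume_ul`, and a reaction whose summed DNA volumes
#' exceed the reaction volume is an infeasibility error naming the row.
#'
#' @param stocks Tibble from [load_stocks()] (`plasmid_id`, `ng_per_ul`).
#' @param params A [reaction_params()].
#' @param report A `campaign_report` from [run_campaign()]; rows whose
#'   inputs resolved (whatever their assembly outcome) count as reactions.
#' @param db Named molecule list from [load_database()], used for lengths.
#' @param bp_mass Average dsDNA molar mass per bp, g/mol.
#' @return An object of class `dilution_plan`: list with `parts` (tibble:
#'   `plasmid_id`, `length_bp`, `ng_per_ul`, `ng_per_reaction`,
#'   `vol_stock_ul`, `dilution_factor`, `vol_dispensed_ul`, `n_reactions`,
#'   `total_ul`), `reactions` (tibble: `row`, `output_name`, `dna_ul`,
#'   `water_ul`) and `params`.
#' @export
compute_dilutions <- function(stocks, params, report, db, bp_mass = 650) {
  stopifnot(inherits(params, "reaction_params"), inherits(report, "campaign_report"))
  used <- report$rows[lengths(report$rows$inputs) > 0, , drop = FALSE]
  all_ids <- unique(unlist(used$inputs))
  missing_stock <- setdiff(all_ids, stocks$plasmid_id)
  if (length(missing_stock) > 0) {
    ms_abort(
      paste(
        "no stock concentration for plasmid(s):",
        paste(missing_stock, collapse = ", ")
      ),
      "moclosim_missing_stock"
    )
  }
  missing_db <- setdiff(all_ids, names(db))
  if (length(missing_db) > 0) {
    ms_abort(
      paste(
        "plasmid(s) absent from the database:",
        paste(missing_db, collapse = ", ")
      ),
      "moclosim_missing_stock"
    )
  }

  usage <- table(unlist(used$inputs))
  parts <- purrr::map_dfr(all_ids, function(id) {
    len <- seq_length(db[[id]])
    conc <- stocks$ng_per_ul[match(id, stocks$plasmid_id)]
    ng <- fmol_to_ng(params$target_fmol, len, bp_mass)
    v <- ng / conc
    d <- 1
    if (v < params$min_pipettable_ul) {
      d <- 10^ceiling(log10(params$min_pipettable_ul / v))
    }
    n_rxn <- as.integer(usage[[id]])
    tibble::tibble(
      plasmid_id = id, length_bp = len, ng_per_ul = conc,
      ng_per_reaction = ng, vol_stock_ul = v, dilution_factor = d,
      vol_dispensed_ul = v * d, n_reactions = n_rxn,
      total_ul = v * d * n_rxn * params$dead_volume_factor
    )
  })

  reactions <- lapply(seq_len(nrow(used)), function(k) {
    ids <- used$inputs[[k]]
    dna <- sum(parts$vol_dispensed_ul[match(ids, parts$plasmid_id)])
    if (dna > params$reaction_volume_ul) {
      ms_abort(
        sprintf(
          "row %d ('%s'): DNA volumes sum to %.2f uL, more than the %.2f uL reaction",
          used$row[k], used$output_name[k], dna, params$reaction_volume_ul
        ),
        "moclosim_infeasible"
      )
    }
    tibble::tibble(
      row = used$row[k], output_name = used$output_name[k],
      dna_ul = dna, water_ul = params$reaction_volume_ul - dna,
      inputs = list(ids)
    )
  })
  reactions <- dplyr::bind_rows(reactions)

  structure(
    list(parts = parts, reactions = reactions, params = params),
    class = "dilution_plan"
  )
}

#' @export
print.dilution_plan <- function(x, ...) {
  cat(sprintf(
    "<dilution_plan> %d plasmids over %d reactions (%g fmol/part, %g uL reactions)\n",
    nrow(x$parts), nrow(x$reactions), x$params$target_fmol,
    x$params$reaction_volume_ul
  ))
  print(x$parts)
  invisible(x)
}

#' @method tidy dilution_plan
#' @export
tidy.dilution_plan <- function(x, ...) x$parts

#' @rdname compute_dilutions
#' @param plan A `dilution_plan`.
#' @param path Output CSV path.
#' @export
write_dilution_plan <- function(plan, path) {
  readr::write_csv(
    dplyr::mutate(plan$parts, dplyr::across(dplyr::where(is.double), ~ round(.x, 2))),
    path
  )
  invisible(path)
}

#' Export a generic liquid-handler picklist
#'
#' Flattens a dilution plan into transfer steps a liquid handler (or a
#' patient human) can execute: first the intermediate dilutions (stock +
#' water into a dilution plate), then per-reaction DNA and water transfers
#' into assembly plate wells assigned row-major A1..H12, continuing onto
#' further plates when a campaign exceeds 96 reactions. Volumes are
#' serialized at 2 decimals; the file is deterministic.
#'
#' @param plan A `dilution_plan` from [compute_dilutions()].
#' @param path Output CSV path.
#' @return Invisibly, the picklist tibble (`step`, `plate`, a
#'   `destination_well`, `source_id`, `volume_ul`).
#' @export
export_picklist <- function(plan, path = NULL) {
  diluted <- plan$parts[plan$parts$dilution_factor > 1, , drop = FALSE]
  dil_steps <- if (nrow(diluted) > 0) {
    purrr::map_dfr(seq_len(nrow(diluted)), function(i) {
      p <- diluted[i, ]
      # total intermediate dilution volume needed, split stock : water = 1 : d-1
      need <- p$total_ul
      stock <- need / p$dilution_factor
      w <- well_name(i, 1)
      tibble::tibble(
        step = "dilution",
        plate = sub("^plate_", "dilution_", w$plate),
        destination_well = w$well,
        source_id = c(p$plasmid_id, "water"),
        volume_ul = c(stock, need - stock)
      )
    })
  } else {
    NULL
  }

  asm_steps <- purrr::map_dfr(seq_len(nrow(plan$reactions)), function(k) {
    rx <- plan$reactions[k, ]
    w <- well_name(k, 1)
    sources <- plan$parts[match(rx$inputs[[1]], plan$parts$plasmid_id), , drop = FALSE]
    dplyr::bind_rows(
      tibble::tibble(
        step = "assembly", plate = w$plate, destination_well = w$well,
        source_id = ifelse(sources$dilution_factor > 1,
          paste0(sources$plasmid_id, " (1:", sources$dilution_factor, ")"),
          sources$plasmid_id
        ),
        volume_ul = sources$vol_dispensed_ul
      ),
      tibble::tibble(
        step = "assembly", plate = w$plate, destination_well = w$well,
        source_id = "water", volume_ul = rx$water_ul
      )
    )
  })

  out <- dplyr::bind_rows(dil_steps, asm_steps) |>
    dplyr::mutate(volume_ul = round(.data$volume_ul, 2))
  if (!is.null(path)) readr::write_csv(out, path)
  invisible(out)
}

well_name <- function(i, plate_base) {
  plate <- (i - 1) %/% 96 + plate_base
  pos <- (i - 1) %% 96
  row <- LETTERS[pos %/% 12 + 1]
  col <- pos %% 12 + 1
  list(plate = paste0("plate_", plate), well = paste0(row, col))
}
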