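# moclosim

Simulation and bookkeeping for large **Golden Gate / Modular Cloning
(MoClo) campaigns** in R.

Golden Gate cloning assembles plasmids in one-pot reactions using Type IIS
restriction enzymes — enzymes such as BsaI (`GGTCTC(1/5)`) that cut at a
fixed offset *outside* their non-palindromic recognition sequence, leaving
programmable 4-nt 5′ overhangs ("fusion sites") that direct ligation and
are eliminated from the product. MoClo kits standardise this into typed
grammars: each part type (promoter, CDS, terminator, ...) is encoded by a
fixed fusion-site pair, and the pairs chain into a closed circle. A
*campaign* is a batch of such reactions specified one per row of a
spreadsheet.

`moclosim` implements the dry-lab side of a campaign:

- **Digestion** — locate recognition sites on both strands, compute cut
  positions from the spacer geometry (top cut at `s + m + spacer_top`,
  bottom at `s + m + spacer_bottom` for a plus-strand site at `s`; mirrored
  upstream for minus-strand sites), and emit sticky fragments. Length is
  conserved exactly: Σ(payload + overhang) = plasmid length.
- **Assembly** — chain fragments by fusion-site equality into a unique
  circular product, diagnosing incomplete, ambiguous and multi-circle sets;
  product maps keep all annotations.
- **Campaigns** — parse raw or typed (grammar-driven, subpart-aware)
  campaign CSVs, resolve part names through iP_mapping tables against a
  GenBank plasmid database, simulate every row independently, and register
  products in a `DB_produced` table that feeds the next campaign.
- **Verification** — exact-match in-silico PCR and multi-enzyme restriction
  digests, rendered as simulated agarose gels (tables + ggplot2).
- **Quantitation** — equimolar dilution plans (650 g·mol⁻¹·bp⁻¹ dsDNA,
  power-of-10 pre-dilutions, dead-volume totals) and 96-well picklists.
- **Fixture kits** — a deterministic generator of miniature coherent MoClo
  kits and campaigns, used throughout the tests.

## A worked example

```r
library(moclosim)

# the unit operation: a 29-nt circle with one BsaI site per strand
m <- dna_molecule("GGTCTCAAATGCCCGCTTTGAGACCTTTT", id = "demo")
digest(m, "BsaI")[[1]]
#> <sticky_fragment> AATG | 3 bp payload | GCTT (from demo)
```

The insert is read left-fusion `AATG`, payload `CCC`, right-fusion `GCTT` —
the overhang windows that the two cuts at top-strand positions 7 and 14
expose.

```r
# a six-reaction campaign on a generated 3-position kit, one typo injected
kit  <- make_kit(3, 2, enzyme = "BsaI", seed = 1, dir = tempfile())
camp <- make_campaign(kit, n_rows = 6, error_rows = 4, seed = 1)

db      <- load_database(kit$db_dir)
mapping <- load_mapping(kit$mapping_path)
report  <- run_campaign(parse_campaign(camp$path, grammar = kit$grammar),
                        mapping, db, "BsaI", grammar = kit$grammar)
report
#> <campaign_report> 6 reactions with BsaI: 5 succeeded, 1 failed
#> # A tibble: 6 × 5
#>     row output_name              status  plasmid_id length
#>   <int> <chr>                    <chr>   <chr>       <int>
#> 1     1 prom01-cds01-term01      success oP001         229
#> 2     2 prom02-cds02-term01      success oP002         323
#> 3     3 prom02-cds02-term02      success oP003         437
#> 4     4 prom02-cds01-term01_typo failed  <NA>           NA
#> 5     5 prom02-cds01-term02      success oP004         370
#> 6     6 prom01-cds02-term01      success oP005         296
```

Five rows assemble; their product lengths equal the sum of the three insert
payloads plus 3 × 4 nt of fusion sites, and each gets a generated plasmid
id (`oP001`...). Row 4 fails with a message citing the row, column and the
misspelled token (`term01_typo`) — one bad row never aborts a campaign.
`write_products()` then writes one GenBank map per success,
`write_db_produced()` the mapping-compatible registry of new plasmids, and
`compute_dilutions()` turns stock concentrations into an equimolar plan:
20 fmol of a 2,000-bp plasmid is `fmol_to_ng(20, 2000)` = 26 ng, 0.26 µL
at 100 ng/µL, dispensed as 2.6 µL of a 1:10 pre-dilution when the
pipettable minimum is 1 µL.

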