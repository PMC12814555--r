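---
title: "Simulating Golden Gate and MoClo cloning campaigns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating Golden Gate and MoClo cloning campaigns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moclosim)
```

## The problem

Golden Gate cloning builds plasmids in one-pot reactions: a Type IIS
restriction enzyme cuts *outside* its non-palindromic recognition sequence,
releasing DNA parts with programmable 4-nt (3-nt for SapI) single-stranded
5' overhangs — *fusion sites* — that direct which fragments ligate to which.
Because the recognition sites face outward from each part, they are
eliminated upon ligation, so cutting and joining proceed in the same tube.
Modular Cloning (MoClo) standardises this: a kit assigns parts to typed
positions (promoter, CDS, terminator, ...), each type physically encoded by
a fixed pair of fusion sites, and the type chain forms a closed grammar.

At campaign scale — dozens of one-pot reactions specified together — the
bench work is routinely automated, but the bookkeeping (which plasmid holds
which part, what each product's map is, how to dilute the inputs to
equimolar amounts, what a verification gel should look like) is error-prone
by hand. `moclosim` implements that dry-lab layer: campaign files in,
simulated products and companion tables out.

## The digestion model

An enzyme is `recognition(spacer_top/spacer_bottom)`: reading the
recognition 5'→3', the strand carrying it is cut `spacer_top` nt after its
3' end, the opposite strand `spacer_bottom` nt after, leaving a 5' overhang
of `spacer_bottom − spacer_top` nt. BsaI is `GGTCTC(1/5)`. Cut positions
are gap indices on the top strand, 0-based; for a plus-strand site starting
at $s$ with recognition length $m$,

$$\text{top cut} = s + m + \text{spacer}_{top}, \qquad
  \text{bottom cut} = s + m + \text{spacer}_{bottom},$$

and for a minus-strand site (reverse complement found at $s$ on the top
strand) the cuts fall upstream at $s - \text{spacer}_{bottom}$ and
$s - \text{spacer}_{top}$. Either way the exposed overhang occupies the
top-strand window `[top_cut, top_cut + overhang_length)`, which is why a
fusion site can be *named* by its top-strand 4-mer and junction matching
reduces to string equality — the convention used by MoClo kits (e.g. the
`AATG` start-codon overhang).

A circular molecule with $n \ge 2$ cuts yields $n$ sticky fragments. Each
fragment is represented as `left_fusion + payload`, with its right fusion
site belonging to the next fragment in the assembled circle; length
conservation is then exact:

$$\sum_i \left(|\text{payload}_i| + \text{overhang}\right) = L.$$

Numerical/degenerate choices, each asserted by tests:

* Fragments spanning the circular origin are handled by modular
  arithmetic; digesting any rotation of a circle yields the same fragment
  multiset.
* Exactly one site on a circle only nicks it open — reported as an error
  rather than a fragment.
* Two cuts closer than one overhang length destroy each other's overhangs
  (a malformed part plasmid); this is a hard error, never silently
  resolved.
* Sequences are restricted to `{A,C,G,T}` for digestion; records with `N`
  load but cannot be cut, and other ambiguity codes are rejected at load.
  Type IIS matching over degenerate bases has no agreed semantics, and
  exact matching keeps every result reproducible.
* GenBank records that declare no topology are assumed circular (the
  database holds plasmids) with a warning.

## Selection and assembly

Input plasmids are designed so that the usable piece is the unique
digestion fragment free of recognition sites on both strands: entry parts
carry sites pointing into the part, acceptors carry sites pointing into
their drop-out, so one uniform rule — *use the recognition-free fragment* —
covers both. Zero recognition-free fragments ("no releasable part") and
two or more (an ambiguous entry vector) are reported per input plasmid.

Assembly builds the directed chaining in which fragment $A$ may precede
$B$ iff $A$'s right fusion equals $B$'s left fusion. The outcome is

* `success` — exactly one circular chaining using every fragment once;
* `ambiguous` — a fusion site is the left (or right) end of ≥ 2 fragments;
* `incomplete` — a fusion site has no partner;
* `multiple_circles` — the perfect matching closes into ≥ 2 disjoint
  circles.

The product's top strand is the concatenation of `left_fusion + payload`
around the cycle, its origin anchored at the first-listed input's fragment
so repeated runs give bit-identical files. Features are carried over with
shifted coordinates. Since ligation is chemically orientation-agnostic, a
fragment whose forward orientation pairs with nothing is retried
reverse-complemented (`try_flip`, default on, with a warning); a fragment
usable in both orientations is itself an ambiguity. The default is rescue
because kits are designed so only one orientation chains, and a silent
failure on a flipped-but-rescuable fragment would hide a real product;
`try_flip = FALSE` recovers strict behaviour. On sets of ≤ 7 fragments the
graph classification is tested against exhaustive enumeration of all
circular orderings.

## Campaigns, grammars, names

A campaign file holds one one-pot reaction per row: an output-name cell
(blank means "compose it for me") followed by part cells. In *raw* mode
cells name parts or plasmids directly and rows may have any arity. In
*typed* mode a `moclo_grammar` fixes one column per position; a cell may
hold several subparts joined by the grammar's separator (default `.`, as
in `AGA2.tTDH1`), each resolving to its own plasmid. Part names resolve
through iP_mapping tables (`part_name`, `part_type`, `plasmid_id`) against
a directory of GenBank files whose basenames are the plasmid identifiers;
a token equal to an identifier resolves directly. The same name may exist
under several types (a reporter cloned with different overhangs): typed
lookup disambiguates, raw lookup reports the ambiguity. Duplicate
`(name, type)` rows across mapping files are a load error — last-wins
semantics could silently swap plasmids.

Every row is simulated independently; a failure (with its row, column and
offending token in the message) never aborts the batch. Successes receive
generated identifiers `prefix + zero-padded counter`, continuing past the
largest counter already in the database, and are registered in
`DB_produced.csv` — the same schema as an iP_mapping file, so one
campaign's outputs feed the next without editing. A JSON provenance record
accompanies the report; it carries inputs, enzyme, product id and software
version but deliberately no wall-clock timestamp, so that identical runs
serialize identically (determinism is itself a tested contract).

## Verification and dilutions

`simulate_pcr()` uses exact full-length primer binding only — no
mismatch or 3'-anchor model, which the underlying chemistry literature
would require parameters we do not want to guess; exactness keeps every
amplicon length a deterministic integer. Amplicon length is measured from
the forward primer's 5' start to the reverse primer's 5' start inclusive
of both primers (the common gel-facing convention; documented here because
"between 3' ends" is the other defensible choice). On circular templates
binding and products wrap the origin, and results are invariant under
origin rotation. `simulate_restriction_digest()` pools cut positions
across enzymes (palindromic verification cutters and the Type IIS table
alike); a circle with $n$ cuts gives $n$ fragments, a linear molecule
$n+1$, and lengths always sum to the template. Gels are rendered with
migration $14 - 3\log_{10}(\text{size})$ — purely presentational; the
lane/size table is the artifact tests bind to.

Dilution planning converts the per-part molar dose to mass with the
community-standard 650 g·mol⁻¹·bp⁻¹ average for dsDNA (overridable):
20 fmol of a 2,000-bp plasmid is 26 ng, i.e. 0.26 µL at 100 ng/µL. Volumes
below the pipettable minimum trigger a pre-dilution by the smallest power
of 10 that clears it (powers of 10 are bench-realistic and deterministic);
the delivered molar amount stays exact either way. Master-mix totals are
`dispensed volume × usage × dead-volume factor`; the target amount,
reaction volume, pipettable minimum and dead-volume factor are user
parameters with no asserted biological defaults. Exported picklists round
volumes to 2 decimals; internal arithmetic is exact.

## What the fixture generator emulates — and what it does not

`make_kit()` builds a miniature coherent kit: distinct non-self-
complementary fusion sites chained into one circle (no chosen site is the
reverse complement of another, mirroring real kit rules against
self-ligating junctions), entry plasmids with outward-facing sites around
`left + payload + right`, payloads of 20–200 bp resampled until exactly
one site per strand remains, 30–60 bp stuffers. `make_campaign()` draws
distinct designs and can inject typo / wrong-type / missing-cell defects
recorded in a sidecar manifest. Everything is a deterministic function of
the seed.

These fixtures emulate the *combinatorics* of a MoClo kit, not its
biology: payloads are random DNA, not promoters or CDSs; there is no
ligation-fidelity model for near-cognate overhangs, no methylation
sensitivity, no star activity, and single-tier assembly only. Passing
tests therefore demonstrate that digestion geometry, overhang matching,
bookkeeping and arithmetic are correct on any kit obeying MoClo design
rules — they say nothing about how a particular real kit behaves in a
tube.

## Problem sizes used in the test suite

The suite exercises: 500 random circles of 0.5–9 kb for length
conservation; exhaustive ordering enumeration for fragment sets of 2–7;
kits of 2–4 positions × 1–2 parts; campaigns of 4–6 rows. These sizes
fully cover the combinatorial cases (the properties are size-invariant)
while keeping the default test run fast.

## A worked example

```{r example, eval = FALSE}
kit <- make_kit(3, 2, enzyme = "BsaI", seed = 1, dir = tempfile())
camp <- make_campaign(kit, n_rows = 6, error_rows = 4, seed = 1)

db <- load_database(kit$db_dir)
mapping <- load_mapping(kit$mapping_path)
report <- run_campaign(
  parse_campaign(camp$path, grammar = kit$grammar),
  mapping, db, "BsaI", grammar = kit$grammar
)
glance(report)
tidy(report)

write_db_produced(report, "DB_produced.csv")
write_products(report, "plasmids/")
```

## Known limitations

Single Type IIS enzyme per reaction (no two-enzyme assemblies), single
assembly tier, exact-match primer binding only, no thermodynamics or
ligation-fidelity scoring, GenBank as the only sequence format, and
feature locations limited to spans, complements and origin-wrapping joins.
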