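---
title: "Assembling multi-isoform transcriptomes with isoasm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling multi-isoform transcriptomes with isoasm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoasm)
```

## The problem

Transcriptomes such as snake venom glands express families of closely
related isoforms: paralogous toxin genes that differ by a few percent of
substitutions spread along their length. De Bruijn graph assemblers
struggle here in two ways. They may collapse isoforms, reporting fewer
variants than exist; or they may walk graph paths that cross between
isoforms, emitting *chimeric* transcripts — artificial recombinants whose
breakpoints come from the assembly, not the biology. Chimeras are
pernicious because they look plausible: only the phasing between variable
sites is wrong, which destroys downstream analyses (co-evolving sites,
phylogenetics, recombination detection) that depend on exactly that
phasing.

isoasm implements a six-stage pipeline whose central idea is to keep
*physical read linkage* attached to every assembly decision, so that a
consensus path can only be extended where a single sequenced molecule
certifies the junction.

## The pipeline

1. **Partitioning** (`partition_reads()`). Forward reads are grouped at
   roughly the protein-family level by iterative seed expansion: a random
   read seeds a partition, and any unallocated read sharing 70% identity
   over a 100-base window (either orientation) joins. Each cycle draws up
   to 12 probe reads from the previous cycle's additions, which lets a
   partition "walk" along a transcript and capture reads with no direct
   overlap with the seed. Partitions with fewer than 3 reads are deferred
   — their reads re-enter at mapping, so nothing is discarded.

2. **Guide construction** (`build_guides()`, `merge_guides()`). Each
   partition is greedily assembled: a random read starts a growing guide
   sequence, and any read anchoring at 98% identity over a 100-base window
   with an overhang extends it. Guide bases win inside the overlap: guides
   are deliberately *approximate* templates. Per-site diversity lost here
   is recovered by the later stages, which is why the pipeline tolerates
   collapsing sibling isoforms into one guide. A final join pass applies
   the same rule with guides as both pool and seeds. Reads that anchor
   without overhang stay in the pool (they may seed further guides, which
   is how a second isoform sharing one conserved window still gets its own
   template); byte-identical guides collapse to one.

3. **Mapping** (`build_scaffolds()`). All input reads — both mates,
   deferred reads included — are placed on the guide they are most similar
   to by 10-mer voting: each read k-mer votes for the (guide, offset,
   orientation) bin its indexed positions imply, and the max-vote bin
   wins. Offsets are exact (no indel slack): the data model is
   substitution-dominated short reads. The result is one scaffold
   alignment per guide with reads positionally consistent, possibly
   overhanging the guide ends.

4. **Networking** (`build_network()`). Windows of one third of the
   minimum read length tile each scaffold span. Reads fully spanning a
   window contribute a truncated fragment; fragments are single-linkage
   clustered at 96% hamming identity into nodes, each with a majority-vote
   consensus. An edge joins nodes in *adjacent* windows when their member
   sets share at least two physical reads.

5. **Traversal** (`traverse_network()`, `confirm_with_pairs()`,
   `emit_transcripts()`). Paths start at every node of the first window
   and at interior in-degree-0 nodes. The second node must be
   edge-connected; every later node needs at least one read present in
   the candidate *and* the two previous nodes — a single molecule spanning
   three consecutive windows. This triplet rule is the chimera control:
   at a window where two isoforms are locally identical (a merged node),
   a path can only continue into the variant that some read physically
   connects across the merge. With paired input, a path is discarded when
   fewer than 30% of its supporting reads' mates place back onto its
   span. Transcripts are the concatenated node consensi, at least 250
   bases, exact duplicates collapsed.

6. **Expression** (`quantify_expression()`). All reads are remapped to
   the finished transcripts; expression is the length-normalised density
   c/L as a percent of the sum over transcripts, embedded in the output
   FASTA headers.

## Parameters that matter

| parameter | default | role |
|---|---|---|
| `partition_window` / `partition_identity` | 100 bases / 0.70 | family-level grouping; permissive on purpose |
| `guide_window` / `guide_identity` | 100 bases / 0.98 | greedy extension; strict so guides stay per-isoform where coverage allows |
| `kmer_length` | 10 | mapping index resolution |
| `min_read_len` | 150 (hard floor 120) | window width is `floor(min_read_len/3)`; below 120 a window carries too little sequence to cluster on diversity |
| `min_isoform_sim` | 0.96 | hamming link threshold separating isoform fragments inside a window |
| `edge_min_shared_reads` | 2 | physical linkage needed for an edge |
| `pair_confirm_fraction` | 0.30 | mate confirmation; exactly 30% keeps |
| `min_transcript_len` | 250 | output filter |

Note an interaction worth knowing: reads of exactly `min_read_len` span
three windows only when aligned to window boundaries, so the triplet rule
chains reliably when typical reads are comfortably longer than
`min_read_len` (e.g. 250-base reads against the default 150). This
matches the intended use, where `min_read_len` is a lower bound on the
input, not its typical length.

## Design choices where the design was open

* **`min_isoform_sim` placement.** The published defaults name a "minimum
  isoform similarity" without assigning it to a stage; here it is the
  window-fragment clustering threshold, because window clustering is
  precisely where isoforms are (or are not) separated, and it is the only
  similarity parameter otherwise unassigned.
* **Clustering linkage.** "Clustered using hamming distance" names no
  linkage; single linkage (connected components of the ≥96% identity
  graph) is parameter-free, deterministic, and mirrors the
  component-flavoured logic of the other stages.
* **Identity metric.** Transcript/reference similarity uses a global
  alignment with end gaps charged half an internal gap (match +1,
  mismatch −1, internal gap −2, terminal gap −1/base), reporting matches
  over the columns between the first and last aligned pair. Fully free
  end gaps would rate `AAAA` vs `AAAT` as a perfect overhang match (1.0)
  rather than a substitution (0.75); fully charged end gaps would punish
  an honest 3'-truncated reconstruction. The half-cost compromise makes a
  clean truncation score 1.0 while single substitutions are still
  substitutions. Evaluation results are sensitive to this choice; it is
  stated here so they are reproducible.
* **Path initiation.** The description initiates paths "within the first
  window" only; isoasm additionally starts paths at interior nodes with
  no incoming edge, since isoforms whose 5' end lacks coverage would
  otherwise be dropped entirely.
* **Trailing windows.** A trailing remainder of at least half a window
  becomes a final short window; a smaller one is appended to the last
  full window. Without this, up to 49 terminal bases of every transcript
  would be discarded.
* **Orientation.** Reads are unstranded: every similarity scan considers
  the reverse complement, the chosen orientation is recorded at mapping,
  and fragments are oriented to scaffold coordinates before clustering.
* **N bases** never match anywhere — in windows, hamming clustering, or
  k-mers — so ambiguity cannot inflate identity.
* **Seeded-diagonal scan.** At the 98%/100-base threshold, a qualifying
  window must contain an exact run of at least 33 bases (pigeonhole with
  at most 2 mismatches), so guide extension only evaluates diagonals
  sharing an exact 32-mer. This is an exact optimisation, not a
  heuristic; thresholds that do not guarantee a 32-base run fall back to
  the exhaustive scan.

## The simulator and what a green test establishes

`simulate_reads()` emulates the validation design of the original study:
reads copied verbatim from reference transcripts at uniform random
positions, per-transcript counts proportional to length
(largest-remainder rounding, so totals are exact and expected per-site
coverage is uniform), each mate drawn uniformly from a 500-base window
anchored on the forward read's last base and emitted reverse-complemented
(FR geometry), and independent per-site substitutions at a configurable
rate. `make_isoform_families()` generates synthetic reference sets: one
random ancestor per family, isoforms derived by substituting a chosen
fraction of sites at independent positions.

The benchmark world the tests assert on is 5 families × 3 isoforms of
1500 bases, with per-family divergence spanning 4–10% (evenly spaced),
error-free 250-base pairs at ~150× per-site coverage (forward plus mate
bases). The error-tolerance sweep runs the same design scaled down
(3 families × 3 isoforms, 1200 bases, ~100×) at per-site error rates
0.002 and 0.01 to stay inside the test-suite time budget.

What the simulator does *not* model: indels, quality-correlated or
position-dependent error profiles, PCR duplicates, coverage bias,
incomplete (fragmented) transcripts, and genuinely repetitive sequence
shared across families. A green recovery test therefore establishes that
the algorithm separates substitution-diverged isoforms and avoids
crossover paths under uniform coverage — not that it is robust to indel
error or biased libraries, which are outside the algorithm's data model
(exact-offset mapping assumes substitution-dominated reads).

Chimera screening (`detect_chimeras()`) labels each 50-base transcript
window with its best-matching reference and calls a transcript chimeric
when the label sequence switches between sources each supported by at
least 3 consecutive windows. The window and run-length constants are this
package's operationalisation (exposed as arguments); ties give no label,
so identical references cannot produce false switches.

## Numerical conventions

All coordinates are 0-based half-open. Window-match tie-breaks are
deterministic: highest identity, forward orientation before reverse
complement, then smallest `(offset_a, offset_b)`. Mapping ties break to
the lowest guide id, then lowest offset, then forward orientation.
Consensus column ties resolve to the lexicographically smallest base.
All stochastic choices (partition seeding, probe sampling, guide
seeding, simulation) draw from the single generator seeded by
`rng_seed`, so a fixed seed reproduces outputs byte-for-byte. Traversal
is breadth-first with a 10,000 live-path cap and a warning on
truncation. Quartiles in `length_stats()` interpolate linearly between
closest ranks.

## Known limitations

* Indels between read and guide are out of model; a frame-shifted read
  maps poorly or not at all.
* Multi-mapping reads are assigned wholly to their vote-winning
  transcript, which biases expression for near-identical isoforms.
* The greedy guide stage is order-dependent (by design, seeded RNG);
  different seeds can split or join guides differently, though the
  network/traversal stages largely absorb this.
* Reverse-complement handling assumes an unstranded library.

## A worked example

```{r example, eval = FALSE}
refs <- make_isoform_families(2, 2, 600, divergence = 0.06, seed = 3)
bm <- run_benchmark(refs, n_reads = 384, params = assembly_params(rng_seed = 7))
bm$match
#>   threshold transcripts_matched references_matched
#> 1      0.90                   4                  4
#> 2      0.95                   4                  4
#> 3      0.99                   4                  4
sum(bm$chimeras$verdicts$chimeric)
#> [1] 0
```

Both isoforms of both families are recovered at ≥99% identity with no
chimeric transcript; the numbers above are the output of the command
shown, also exercised by the package's test suite.
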