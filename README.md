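# gillesim

Forward-time Monte Carlo simulation of biological sequence evolution along a
rooted phylogeny, for R. Substitutions, insertions and deletions act as
concurrent Poisson processes integrated by the exact **Gillespie algorithm**,
and the **true multiple alignment** implied by the simulated indel history is
tracked throughout. The package is aimed at people who benchmark multiple
sequence aligners, gene predictors or phylogenetic inference methods and need
realistic synthetic data with known ground truth — in particular indels that
are *not* uniformly distributed along the sequence.

## The model

Sequence evolution along each branch is simulated in two repeated steps: the
waiting time to the next event is exponential with rate equal to the sum of
all event rates, `R = Σ_i r_i`, and the event to perform is then chosen with
probability proportional to its rate. Time is measured in expected
substitutions per site: every substitution model's rate matrix `Q` is
normalized so that `Σ_i π_i Σ_{j≠i} Q_ij = 1` at equilibrium, and branch
lengths are read directly in those units.

Substitution processes are continuous-time Markov chains over **arbitrary
alphabets** — built-in constructors cover K80, GTR, UNREST, the GY94 codon
model (61 sense codons; `Q_ij = π_j · κ^[transition] · ω^[nonsynonymous]` for
single-nucleotide changes), empirical amino-acid models (WAG, JTT, LG, or any
exchangeability file), and fully general user matrices (e.g. a special
process on the three stop codons). Several substitution processes can act on
the same site, among-site rate variation (+Γ, +I+Γ, or any user rule) applies
to substitution *and* indel initiation rates, and per-site parameters can be
rewritten at internal nodes ("node hooks") for heterotachy.

Indels follow **field models**: each site carries a deletion tolerance
`d_i ∈ [0, 1]`, a proposed deletion spanning sites `ℐ` is accepted with
probability `Π_{i∈ℐ} d_i`, so `d_i = 1` deletes at the background rate and
`d_i = 0` is undeletable — selective constraints on indels without partition
"edge effects" (deletion spans cross partition boundaries freely). The
**fast field** variant proposes deletions at the rate the sequence would have
if every site were as tolerant as its most tolerant one (`rate × D`,
`D = max d_i`) and accepts with `Π d_i / D`: exactly the same realized
deletion law with far fewer wasted rejections when deletions are strongly
selected against. Insertions are gated by the initiating site's insertion
tolerance, and the inserted content is fully programmable (equilibrium draws
by default; e.g. tandem duplications via `duplication_generator()`).

## A worked example

The shipped example config simulates 120 nucleotide sites under K80
(κ = 2) with discrete-gamma rate variation (α = 0.8), a fast-field deletion
process (rate 0.05/site, tolerance 0.7) and an insertion process
(rate 0.03/site) along a five-taxon mammal-like tree:

```r
library(gillesim)
cfg <- system.file("extdata", "example_k80_indel.yaml", package = "gillesim")
res <- run_simulation(cfg, "out/run")

counts <- count_events(res$result$events)
# events: 164 substitutions, 5/5 insertions, 1/2 deletions (accepted/proposed)

aln <- res$alignment   # the true alignment: 5 rows x 132 columns
substr(aln$sequences["human"], 1, 70)
# "GAAATCAC-TTGACGAACCCGAGG------TTTAAAAGTATGTGCGTCCGTTATATATTGAGACATAACC"
substr(aln$sequences["chimp"], 1, 70)
# "GAAATAAC-TTGACTGCCCCAAGG------TTTAAAAGTATGTGCGCCCGTTATATATAGAGATATTGCC"
```

The 132 columns are the 120 root sites plus the 12 sites created by the five
accepted insertions; gaps mark lineages in which a column's site never
existed or was deleted. Closed-form estimators recover the simulation
parameters from a pair of rows (121 comparable columns here, so sampling
error is visible):

```r
pq  <- pq_fractions(aln$tokens["human", ], aln$tokens["chimp", ])
est <- k80_estimates(pq$P, pq$Q)
# p-distance 0.182, d_hat 0.209 (true path length 0.22), kappa_hat 1.78 (true 2)
```

`run_simulation()` writes `<prefix>_tips.fasta` (ungapped tip sequences),
`<prefix>_alignment.fasta` (gapped true alignment), `<prefix>_tracks.tsv`
(per-column partition annotation — e.g. the true exon/intron structure of the
`coding_region` fixture), `<prefix>_events.tsv` (the full event log) and
`<prefix>_manifest.yaml`. Identical config + seed gives byte-identical
outputs. A thin command-line wrapper is installed at `exec/gillesim`
(`run`, `fixture`, `validate-config`, `diagnose` subcommands).

`generate_fixture()` builds deterministic demo scenarios: a random tree with
indels, a miniature genomic region (K80 flanks and intron, fixed start codon
and splice motifs, two GY94 exons, a special stop-codon process), and a
two-domain protein (WAG/LG, deletion-intolerant core vs tolerant linker).

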