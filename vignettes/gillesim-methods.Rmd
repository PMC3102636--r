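---
title: "Simulating sequence evolution with gillesim: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating sequence evolution with gillesim: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gillesim)
```

# The simulation model

gillesim simulates the evolution of a sequence of discrete sites along a
rooted phylogeny, forward in time, with substitutions, insertions and
deletions treated as concurrent Poisson processes. One exact stochastic
simulation (Gillespie) loop drives everything: if the current total event
rate is $R = \sum_i r_i$, the waiting time to the next event is
$\Delta t \sim \mathrm{Exp}(R)$; the event is selected with probability
$r_k / R$; it is applied (or, for indels, accepted/rejected — see below); the
affected rates are updated; and the loop repeats until the waiting time would
overrun the branch length. There is no tau-leaping or other approximation.

**Time units.** Branch lengths are expected substitutions per site. Every
substitution model is normalized so that
$\sum_i \pi_i \sum_{j \neq i} Q_{ij} = 1$ at equilibrium; the rates of all
other processes (indel initiation, special motif processes) are specified
relative to that unit. A constructor flag (`normalize = FALSE`) keeps a rate
matrix exactly as given, for processes such as the slow stop-codon switch of
the `coding_region` fixture whose absolute rate is part of the model.

**Arbitrary alphabets.** A substitution process is a continuous-time Markov
chain over any ordered token set — nucleotides, amino acids, codons
(triplet tokens; one codon is one site), or custom spaces such as the three
stop codons. When the stationary distribution is not supplied it is solved
deterministically from $\pi Q = 0$, $\sum \pi = 1$ (augmented linear system,
not an eigendecomposition), which requires an irreducible chain; the
constructor verifies strong connectivity and names unreachable states.
A supplied $\pi$ is only checked for stationarity, because legitimate models
can be reducible — GY94 with $\omega = 0$ never leaves an amino-acid class,
yet its $\pi$ still satisfies detailed balance.

**Per-site, per-process parameters.** Each site holds a list of *bindings*;
a binding attaches a process with a site-specific rate multiplier $r_i$, a
deletion tolerance $d_i \in [0,1]$ and an insertion tolerance $\in [0,1]$.
Multiple substitution processes may act on one site (their leave rates add)
provided they share an alphabet; sites with no substitution binding are
legal and inert — that is how fixed motifs (start codons, splice sites) are
represented. Partitions are just ranges of sites with their own bindings;
because parameters live on sites, any per-site pattern is expressible and
node hooks can edit it locally.

# Among-site rate variation

`site_rate_model()` supplies multipliers for substitution *and* indel
initiation rates: constant; discrete gamma with $k$ equal-probability
categories; continuous gamma ($\mathrm{Gamma}(\alpha, \alpha)$, mean 1);
invariant-plus-gamma (multiplier 0 with probability $p_{inv}$, otherwise
gamma with mean $1/(1-p_{inv})$, keeping the marginal mean at 1); or any
user function of the site index. Discrete-gamma categories are represented
by their conditional **means**, computed from the incomplete-gamma identity
$E[X \mathbf{1}(a < X \le b)] = F_{\alpha+1}(b) - F_{\alpha+1}(a)$ for
$X \sim \mathrm{Gamma}(\alpha, \alpha)$, so the category mean is exactly 1
for every $\alpha$ and $k$. Medians are the other common convention; means
were chosen because they preserve the normalization exactly, which the test
suite asserts to $10^{-9}$. Users comparing against median-based software
should expect small differences at extreme $\alpha$.

# Field indel models

Deletions are proposed per site at rate `rate` $\times\, r_i$ with a length
from the process's distribution; the proposed span starts at the initiating
site and extends rightward, and is accepted with probability
$\prod_{i \in \mathcal{I}} d_i$ over the span. $d_i = 1$ is the neutral
background, $d_i = 0$ is undeletable, and hotspots are sites with large
$d_i$ inside intolerant context. A **rejected event still consumes its
Gillespie time step** — rejection is how constraints slow a process down,
not a re-draw; this matters when comparing event budgets across processes.

**Fast field deletion.** An intolerant sequence wastes almost all proposals.
The rescaled process proposes at `rate` $\times\, r_i \times D$, where
$D = \max_i d_i$ over the sites bound to the process, and accepts with
$\prod_{i \in \mathcal{I}} d_i / D$. Dividing the acceptance *product* by $D$
exactly once (rather than dividing each site's tolerance, which would change
multi-site dynamics by $D^{|\mathcal{I}|-1}$) makes the realized per-span
deletion rate algebraically identical to the plain process for every span
length:
$(\text{rate} \cdot D) \cdot (\prod d_i / D) = \text{rate} \cdot \prod d_i$,
while single-site proposals at the most tolerant sites are never rejected.
Since $d_i \le D \le 1$ for all bound sites, $\prod d_i / D \le 1$ always.
$D$ is cached per sequence and invalidated by any tolerance edit or indel,
so hooks changing tolerances mid-tree are handled correctly.

Three boundary rules, chosen where the behaviour was genuinely open:

* spans overrunning the sequence end are **truncated**, not rejected
  (rejection would re-introduce an edge effect at the sequence boundary);
  acceptance uses only the surviving sites, and the event log flags the
  truncation;
* deletion spans **cross partition boundaries freely**; a span site not
  bound to the proposing process reads $d_i = 1$ (the neutral default all
  site parameters start from);
* insertions are gated by the **initiating site's** insertion tolerance
  only (no multi-site interaction rule exists for insertions), and the
  insertion point is immediately right of the initiating site — insertions
  before the first site are not modelled.

Insertions draw a length, then invoke a generator with the flanking context;
the default draws states from the template model's equilibrium and binds the
template processes (multipliers freshly drawn from the template's rate
model), and `duplication_generator()` copies the left flank's states *and*
bindings. If the sequence ever shrinks to length zero all rates are zero and
the branch fast-forwards; insertions cannot restart from an empty sequence
(no virtual origin site) — a documented limitation.

# The true alignment

Every site carries an immutable integer identity from its creation (root
site or insertion) to its deletion. A global ordered column list holds every
identity ever created: deletions leave columns in place (other lineages may
still carry the site), and an insertion splices its new columns immediately
to the right of the initiating site's column. That position is forced by
intra-branch consistency: a branch inserting twice at the same flank must
see its later insert closer to the flank, so between sibling lineages the
later-traversed insertion also lands closest to the flank. Simultaneous
insertions at one flank on different branches are *not* homologous and
always occupy distinct columns; any relative order is valid, and this one
requires no bookkeeping beyond the anchor column.

A node's alignment row places its tokens at its identities' columns and gaps
elsewhere, so each row degaps to exactly the node's sequence, and a column's
residues all descend from the same root site or insertion event. Per-branch
alignment operations (insert-columns, delete-ids) are logged; the test suite
rebuilds every node's row and the column structure purely from the log and
requires exact agreement. Tip output drops columns that are all-gap among
the emitted rows by default (an insertion on an internal branch later
deleted everywhere leaves no evidence at the tips).

# Determinism and numerics

* **Draw order** within an event is frozen: waiting time, site, binding
  (only when a site has more than one), substitution target or indel
  length, acceptance uniform, insertion-generator draws (only if accepted).
  With a fixed seed a run is bit-reproducible.
* **Substreams.** `simulate_evolution(seed = s)` seeds each branch with a
  deterministic hash of `(s, child label)`, and `run_simulation()` derives a
  separate substream for building the root, so adding outputs or reordering
  post-processing never perturbs the simulation.
* **Rate caching.** Site rates are cached; substitutions update one site in
  $O(1)$, indels and property edits trigger a full recompute. The cached
  total is audited against an independent recomputation at every branch
  start and every 1,000 events at relative tolerance $10^{-9}$; a mismatch
  aborts the run. Event selection additionally cross-checks the cached site
  rate against the itemized binding rates at every event.
* **Site selection** uses cumulative sums over the cached rates, with an
  $O(1)$ uniform shortcut when all site rates are equal; a vectorized
  rebuild path covers the common one-model-per-site layout. These are pure
  optimizations — the selected distribution is identical.
* **Stationary solve and matrix exponential.** $\pi$ comes from a QR solve
  of the augmented system; $P(t) = e^{Qt}$ uses `Matrix::expm` and is tested
  against an independent truncated power series to $10^{-8}$.

# Validation strategy and problem sizes

Validation is internal parameter recovery — no external ML software. The
acceptance suite (also re-run standalone by `scripts/acceptance.R`) checks:
single-site end-state distributions against $e^{Qt}$ rows under K80 and a
random non-reversible model ($\chi^2$, 50,000 replicates, $t = 0.3$);
the Poisson substitution budget (2,000 sites, $t = 0.5$); recovery of
$d = 0.5$ and $\kappa = 2$ by the closed-form K80 estimators from a
50,000-site two-tip simulation, plus their exact self-consistency when fed
$P, Q$ from the matrix exponential; zero nonsynonymous events under
$\omega = 0$ (500 codons); the $\prod d_i$ acceptance law at $10^5$
proposals; distributional equality of plain and fast field deletion with
strictly fewer rejections in fast mode (500 sites, $d_i = 0.05$, 500
replicates per mode); the Poisson deletion budget (mean 10 over 200
replicates); alignment soundness over 50 random mixed indel scenarios;
halving of a subtree's event count by a rate-halving node hook; and
byte-identical outputs for identical config and seed. These sizes were
chosen so each statistical check has conventional power (3σ bands, χ²
thresholds of $10^{-3}$–$10^{-2}$) while a full run stays in the
low minutes on one CPU.

**What the synthetic data does and does not emulate.** The generator
reproduces the *model's* world: homogeneous-in-time Markov substitution with
independent sites (given their multipliers), geometric/tabulated indel
lengths, and independence between the indel location process and sequence
content. Real sequences violate several of these — context-dependent
mutation, correlated indel and substitution constraint beyond what shared
tolerances express, selection on the protein as a whole. Passing tests show
the simulator implements its model exactly; they do not certify the model as
a complete description of any genome.

# Known limitations

* Node hooks may only alter site properties (multipliers, tolerances,
  attaching processes); arbitrary state edits would corrupt homology
  tracking and are refused at run time.
* No likelihood computation or tree inference; diagnostics are closed-form
  estimators (p-distance, K80 $d$ and $\kappa$, event tallies).
* Unrooted trees are not accepted; per-branch model switching is expressed
  through hooks, not Newick annotations.
* Empty sequences stay empty; tolerance interactions between neighbouring
  sites are deliberately out of scope (the field model's one-parameter-per-
  site design is the point).
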