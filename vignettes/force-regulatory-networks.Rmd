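---
title: "Methods: force-responsive regulatory network inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: force-responsive regulatory network inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forcenet)
```

# Scope and model

`forcenet` infers how mechanical force reorganizes the RNA regulatory layer
of bone cells. The object of inference is not a single parameter but a set
of linked, typed networks built from heterogeneous evidence:
force-sensitive mRNAs from differential expression under two force
regimes, literature-curated force-sensitive miRNAs, a competing endogenous
RNA (ceRNA) network joining lncRNA–miRNA sponge pairs to miRNA–mRNA target
pairs, TF→lncRNA regulation predicted from promoter motif scanning, and
closed TF–lncRNA–miRNA feedback circuits composed from the two networks.
This vignette records the statistical model behind each stage, the
parameters that matter, the design decisions taken where the procedure was
genuinely open, and what the synthetic benchmark does and does not
demonstrate.

# Differential expression

## Model

Counts are normalized to transcripts per kilobase million,
$\mathrm{TPM}_g = 10^6 \, (c_g/\ell_g) / \sum_h (c_h/\ell_h)$, which removes
library-size and gene-length effects and makes every sample sum to $10^6$.
Per gene, a two-sided two-sample t-test is run on $\log_2(\mathrm{TPM}+1)$
values, p-values are Benjamini–Hochberg adjusted across all genes, and the
reported fold change is
$\log_2\!\big((\bar x_{case}+c)/(\bar x_{ctrl}+c)\big)$ with pseudocount
$c = 1$ on the normalized scale (stabilizing ratios at zeros). A gene is
significant iff $\mathrm{FDR} < \alpha$ and $|\log_2\mathrm{FC}| > \tau$
(defaults $\alpha = 0.05$, $\tau = 1$); its direction is the fold-change
sign when significant. Force-sensitive (FS) mRNAs are the
direction-consistent intersection of the significant sets of the two force
contrasts — consistency is required because the FS set is interpreted as
"promoted or inhibited by load regardless of force type", which is only
coherent when the sign agrees.

## The t-test variant

The t-test flavour was an open choice. We default to the pooled-variance
Student's t (`var_equal = TRUE`) rather than Welch's test. The reason is
calibration at the designs this pipeline targets: with triplicates the
Welch–Satterthwaite degrees of freedom collapse to ≈ 2–3 and the test
becomes conservative enough to leave the nominal 5% band (the package's
calibration tests measure this directly on null negative binomial counts);
the pooled test at df = 4 stays within $0.05 \pm 0.01$. Welch remains one
flag away for unbalanced or heteroscedastic designs. Degenerate genes are
handled without exceptions: zero variance in both groups with equal means
gives $p = 1$, with unequal means $p = 0$.

"Recovery" of a planted fold change is assessed at the raw-p threshold
($p < 0.05$, $|\log_2\mathrm{FC}| > 1$, correct sign). At $n = 3/3$ no
per-gene t-procedure can push 95% of 2-fold-change genes through a BH-FDR
cut among 10,000 genes — the attainable p-values are bounded by the tiny
degrees of freedom — so FDR-based recovery is not a meaningful benchmark at
this design size, while the raw-p rate pairs naturally with the type-I
calibration check.

# Curation of force-sensitive miRNAs

The curated table is shipped as a plain-text transcription with one row per
printed miRNA mention per study. Family notations are expanded
(`miR-29 family (a,b,c)` → three records; `miR-30b/c/d/e` → four;
`miR-466i/f-5p` → two arm-suffixed records). Deduplication across studies
uses: species-prefix and star-notation stripping; legacy-name aliases
(miR-103 → miR-103a, miR-122a → miR-122); collapsing of an armless printing
onto its arm-resolved form when exactly one arm occurs; and sign resolution
with functional evidence outranking qPCR-only, a unanimous top tier
deciding, majority over all records otherwise, and residual ties flagged
(fatal under `strict = TRUE`).

The fixture carries an `included` column recording the curation screen —
cross-species conservation of rodent-specific miRNAs plus evidence
reliability. The table prints what each study reported; the flag encodes
which mentions the curated reference list retains (rodent-only identifiers
with no human counterpart, e.g. the mouse miR-466/467 cluster members, and
rodent qPCR-only minor entries are screened out). This is a curated
judgment shipped as data, not something the code infers: conservation
checking against a sequence database is out of scope by design.

# ceRNA network assembly

Sponge pairs enter if their CLIP-style `evidence_count` ≥ 3 (the
conventional high-stringency cutoff); target pairs enter only on a
unanimous three-database consensus. After restricting targets to FS mRNAs
and both pair types to curated miRNAs, two structural constraints apply:

* **Triplet constraint.** A miRNA survives only with ≥ 1 surviving sponge
  partner *and* ≥ 1 surviving target, so every retained edge participates
  in a complete lncRNA–miRNA–mRNA triplet.
* **Degree pruning.** lncRNAs with sponge degree < 3 are removed in a
  *single pass*, then newly orphaned miRNA/mRNA nodes are dropped. A single
  pass mirrors a one-shot network-viewer filter applied to a displayed
  network; an iterated fixed-point mode exists behind `iterate = TRUE` but
  is not the default because cascading removals can empty sparsely
  connected networks that the one-shot filter (and the published network
  sizes this emulates) would retain. The degree counted is sponge degree —
  the lncRNA's only edge type — and pruning runs after triplet enforcement,
  the only order under which "degree" is well defined on the final edge
  set.

Centralities are computed on the undirected graph: degree, shortest-path
betweenness, and component-local closeness
$(r-1)/\sum d$ over the $r$ reachable vertices, with isolates assigned 0.
The component-local convention is needed because ceRNA graphs are routinely
disconnected, where the global convention degenerates. Consensus hubs are
the intersection of the three per-metric top-$k$ lists ($k = 15$ by
default), restricted to one node type, with deterministic ordering (metric
descending, id ascending) so ties cannot reorder results between runs.

# Co-expression

Pearson correlation across all pooled samples, with the t-transform
p-value $t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$ df. Edges require
$|r| > 0.8$ and $p < 0.05$ (raw, uncorrected — a BH option exists but
defaults off to match standard ceRNA-network practice). The magnitude
threshold with recorded sign, rather than a strictly positive one, is the
default because co-expression networks in this field display negative
correlations as first-class edges; `signed = FALSE` gives the
positive-only reading. Constant genes are skipped with a warning rather
than propagating undefined correlations.

# Promoter scanning

Position frequency matrices are converted to log2-odds with a
background-distributed pseudocount:
$W_{bj} = \log_2\frac{(n_{bj} + 0.8\,q_b)/(N_j + 0.8)}{q_b}$, with uniform
background by default and pseudocount 0.8 (a common PWM default;
configurable). Every window of the motif width on both strands of the
1,000 bp upstream sequence is scored; a hit requires min–max relative score
$(s - s_{\min})/(s_{\max} - s_{\min}) \ge 0.95$. The "95% cutoff" is
interpreted as this relative score — the convention of the standard
PWM toolkits — not as a score percentile; an absolute-score mode is
available for users who calibrate thresholds differently. Numerical edges:
relative scores are clamped to $[0,1]$ to absorb floating-point epsilon at
the consensus; windows containing `N` are skipped rather than scored with
background odds; a degenerate motif with $s_{\max} = s_{\min}$ scores every
window 1.0 with a warning. Reverse-strand hits are reported at the
forward-strand start coordinate, and position 1 means −1000 relative to the
transcription start (sequences arrive strand-resolved, so the scanner needs
no genome-strand logic).

The TF–lncRNA network keeps one edge per (TF, promoter) with ≥ 1 hit and
drops TFs binding fewer than 5 promoters — a presentation filter from the
display conventions of published TF regulons, which is why circuit
enumeration (below) is typically run on the unfiltered network
(`min_tf_degree = 0`).

# Feedback circuits

A circuit $(t, L, m)$ requires tfbs$(t \to L)$, sponge$(L - m)$ and
target$(m \to g(t))$ where $g(t)$ maps the TF to its own mRNA — identity on
gene symbols by default, overridable by an explicit two-column map. No
direction constraint is imposed on the TF's own differential expression:
the circuit is a topological object, and sign/logic inference on loops is
out of scope. Output is canonically sorted and grouped as
`TF-(L1/L2/…)-miR-x-TF`.

# Over-representation

The hypergeometric upper tail $P(X \ge k)$ with BH adjustment across terms
and `gene_ratio` $= k/n$ ordering. Only over-representation is tested
(depletion is never of interest in this pipeline), and the universe
defaults to the expressed genes of the count matrix rather than the
genome — the standard expressed-background choice.

# The synthetic benchmark

`simulate_bundle()` generates every pipeline input with recorded ground
truth. Counts are negative binomial with
$\mathrm{Var} = \mu + \phi\mu^2$ ($\phi = 0$ degenerating to Poisson);
planted genes have their mean multiplied by $2^{\pm 2}$ in their force
group(s), with a configurable fraction shared (same sign) between the two
contrasts — those shared genes are the synthetic FS mRNAs. The reference
conditions are a triplicate three-group design (control, intermittent,
static), 2,000 genes of which 60 are lncRNAs, 30 miRNAs, NB mean 100 and
dispersion 0.05, 10% planted DE genes half of them shared, 15 planted
triplets, 3 planted circuits, 1,000 bp promoters at GC 0.5, and noise-free
interaction tables. Calibration checks run at 10,000 genes. These sizes
are the package's benchmark design: large enough that rate estimates are
stable, small enough that the whole suite re-simulates from scratch in
seconds.

Planted structure is built for end-to-end recoverability: every planted
lncRNA takes part in ≥ 3 triplets (surviving degree pruning), planted
sponge pairs carry evidence ≥ 3, planted target pairs sit in all three
databases, triplet mRNAs are drawn from the shared planted DE genes, and a
circuit is planted by electing a triplet's mRNA as a TF, giving it a sharp
PFM, and inserting that PFM's consensus (forward or reverse-complemented)
at a recorded position in the triplet lncRNA's promoter. Decoys are drawn
from the same identifier namespaces with evidence < 3 or sub-unanimous
database support, so they stress exactly the filters that are supposed to
remove them. The decoy rates are free parameters, not estimates — no noise
model for the real databases exists to estimate them from.

What the generator does *not* emulate: read-level sequencing noise,
GC/length bias, batch effects, correlated expression between the members
of a triplet (counts are independent given the design), realistic motif
information content distributions, or biological false positives in CLIP
and target databases beyond the simple decoy model. Passing the planted
recovery tests therefore demonstrates the correctness of the filtering and
composition logic — that the pipeline recovers exactly what its rules
define under inputs satisfying those rules — not the biological accuracy
of any recovered network on real data.

# Determinism and numerical conventions

Every generator is a pure function of its configuration: sub-generators
derive fixed offsets from the configured seed, and the RNG state of the
caller is restored afterwards. BH adjustment delegates to the standard
step-up implementation, with `NaN` propagated (and excluded from the
multiplicity count) under a warning. Ranks are dense (ties share a rank);
top-$k$ selection breaks metric ties by node id. All set-valued outputs
are canonically sorted so that row order never depends on input order.

# Known limitations

* The per-gene t-test is the specified contract, but count-model methods
  (negative binomial GLMs with shared dispersion estimation) dominate it
  in power at $n = 3$; the DE module should be read as the faithful
  procedure, not the recommended analysis for new data.
* Sign resolution in curation implements a documented precedence, but the
  printed evidence does not uniquely determine any rule; conflicting
  literature (e.g. miR-132 across force types) is resolved by majority and
  flagged, and `strict` mode surfaces rather than hides the ambiguity.
* Closeness and betweenness are unweighted; evidence counts and
  correlation strengths are carried as edge attributes but do not enter
  the centrality consensus.
* The PWM false-positive rate at the 95% relative cutoff depends strongly
  on motif information content; sharp synthetic motifs understate the
  multiple-testing burden of scanning real vertebrate PFM collections.
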