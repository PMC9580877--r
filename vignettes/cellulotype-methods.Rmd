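---
title: "Genotyping putative cellulolytic anaerobes: methods and design"
author: "Cellulotype authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping putative cellulolytic anaerobes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(Cellulotype)
```

# The model

Cellulose hydrolysis by anaerobes depends on synergy at two levels, and the
package's whole procedure is a formalization of that idea.

**Within a gene.** Cellulolytic enzymes are modular. The catalytic glycoside
hydrolase (GH) domains split by activity: *exoglucanases* processively chew
the ends of cellulose chains, *endoglucanases* cut internal amorphous
sites, *xylanases* attack hemicellulose, and lytic polysaccharide
monooxygenases (LPMOs) cleave glycosidic bonds oxidatively. Non-catalytic
partners matter just as much: cellulose-binding carbohydrate-binding
modules (cCBM) hold a catalytic domain on its substrate; the surface layer
homology (SLH) domain anchors a protein to the bacterial cell wall; cohesin
and dockerin are the complementary plug-and-socket modules from which
cellulosomes are assembled. We call the union of exo-, endoglucanase and
LPMO families *cGH*.

**Within a genome.** A cohesin-repeat scaffoldin (three or more cohesins)
can assemble dockerin-bearing catalytic subunits into a cellulosome. If the
scaffoldin also carries an SLH domain — directly (type A1), or indirectly
by pairing its dockerin tail (A2-a) with an SLH+cohesin carrier (A2-b) —
the whole complex is held at the cell surface, sandwiching enzymes between
cell and fiber (a cellulose–enzyme–microbe complex). A scaffoldin with
neither route (A3) yields a *free* cellulosome, which is a real functional
difference: strains with A3-only cellulosome clusters are known to be inert
on crystalline cellulose. Independently of cellulosomes, a gene combining
SLH with a cCBM (type B) encodes a plausible cell–fiber glue.

The pairing logic behind A2 is not an assumption but an observable corpus
property: across gene architectures, SLH and dockerin essentially never
co-occur in one gene (the package's co-occurrence statistic makes this
checkable on any corpus: `freq(dockerin | SLH)`), so SLH can only reach a
scaffoldin backbone through a cohesin, never through a dockerin.

## Gene typing

For each gene we count module occurrences by role —
`(n_slh, n_dockerin, n_cohesin, n_cgh, n_ccbm)` — and evaluate eight
predicates (see `assignTypes()`): A1, A2-a, A2-b, A3 (scaffold types), A-s
(dockerin + cGH, the cellulosomal catalytic component), B (SLH + cCBM),
C (cGH + cCBM) and D (cGH without cCBM). The predicates overlap by design;
two resolution rules make the result usable downstream:

* **Scaffold precedence** A1 > A2-a > A2-b > A3: a gene is at most one kind
  of scaffoldin. A gene with SLH and three cohesins satisfies both A1 and
  A2-b literally; it *is* an A1 scaffoldin. The full order is
  implementer-imposed — SLH/dockerin conflicts (A1 vs A2-a) are theoretical
  precisely because those modules never share a gene — but ties must
  resolve deterministically.
* **Primary type**: the first satisfied label in the order A1, A2-a, A2-b,
  A3, A-s, B, C, D. Non-scaffold labels stay multi-label in
  `satisfied_types` (an A-s gene without cCBM also meets D's literal
  predicate), but genome-level tallies use the primary type only, so
  cellulosomal genes never inflate the non-cellulosome B/C/D columns. Both
  views are in the per-gene report, so either counting convention can be
  reproduced.

The A-s predicate is strict by default (`dockerin >= 1 & cgh >= 1`);
`strictAs = FALSE` switches to the looser reading
(`dockerin >= 1 & (cgh >= 1 | ccbm >= 1)`) that also admits dockerin-borne
binding-only components.

## Genome classification

`classifyGenome()` runs a fixed decision sequence over per-genome
presence/absence: (0) no CAZy annotation at all → `NO_CAZY`; (1) missing
the exoglucanase or the endoglucanase role → `II`; (2) adhering scaffold →
`I-a`; (3) free scaffold, split on SLH-cCBM genes → `I-b`/`I-c`; (4)
SLH-cCBM genes without a cellulosome → `I-d`; (5) cellulose-binding
cellulases → `I-e`; (6) otherwise → `I-f`. Genomes that have CAZy modules
but none with a catalog role still reach step 1 and fall to `II`;
`NO_CAZY` is reserved for genomes absent from the annotation output.

One genuinely open point is the unpaired A2-a: a dockerin-tailed
scaffoldin with no A2-b partner anywhere in the genome cannot acquire an
SLH anchor, so by default it routes to the *free*-scaffold branch
(`a2RequiresPair = TRUE`). The switch exists because the alternative
reading — any A2-a counts as adhering — is defensible if one assumes the
partner is merely unannotated.

## Co-occurrence statistics

For each focal module *m*: collect all genes containing ≥ 1 occurrence of
*m*; let *N* be the total occurrences of *m* in those genes and *n_i* the
total occurrences of partner *i* there; report `100 · n_i / N`. Genes with
several focal modules are counted independently per focal, and frequencies
above 100% are legitimate (one GH9 flanked by two CBM3 gives 200%).
Heatmaps use `log10(x + 0.01)`, mapping 0% to exactly −2.

Self-partnership needs care. Excluding focal modules from the partner axis
entirely would make "these two modules never share a gene" unreadable (the
column would vanish rather than read 0%), so the partner axis always
carries the focal modules and only the self *cells* are masked (`NA`) by
default; `includeSelf = TRUE` turns them into extra-copy counts,
`n_self = N − (number of focal genes)`.

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `maxEvalue` | 1e-15 | HMM hit E-value ceiling |
| `minCoverage` | 0.35 | HMM coverage floor (fraction of the profile) |
| `overlapPolicy` | `best_per_region` | same-family hits overlapping > ½ of the shorter interval collapse to the lowest-E hit |
| `a2RequiresPair` | `TRUE` | unpaired A2-a routes to the free-scaffold branch |
| `strictAs` | `TRUE` | A-s requires a catalytic cGH module |
| `includeSelf` | `FALSE` | self cells masked vs extra-copy counts |

The score cutoffs are the widely used defaults for dbCAN-style HMM
annotation; the upstream platform recommends cutoffs without a single
canonical pair of numbers, so both are plain arguments. Deduplication of
overlapping same-family hits is a policy choice (tandem repeats of
cohesins are real and must survive; overlapping rescoring artifacts must
not) — `keep_all` is available for corpora where the annotation is already
deduplicated.

The module catalog is data, not code: `defaultCatalog()` is an
implementer-curated vocabulary (4 exoglucanase, 7 endoglucanase, 7
xylanase GH families, 3 LPMOs, 18 cellulose-binding CBM families; GH9
deliberately carries both the exo and endo roles, reflecting its
documented promiscuity), and any lab-specific list drops in via
`readCatalog()` without touching the engine. No EC-level subdivision of
families is attempted: a family with any documented exoglucanase activity
counts as an exoglucanase family.

# The synthetic-data generator

`generateCorpus()` builds annotated genomes bottom-up from per-group gene
blueprints: each blueprint gene carries the minimal module counts of its
intended type (an A1 scaffoldin is SLH + 3 cohesins; a B gene SLH + CBM3;
…), and every Group-I genome carries both an exoglucanase (GH48 or GH9)
and an endoglucanase (GH5 or GH9) family so the group-membership
prerequisite holds by construction. Randomized surplus — duplicated
blueprint genes and decoy modules drawn only from families with *no*
catalog role (GT2, GH13, CBM50, …) — cannot flip a gene's primary type or
a genome's group, which is what makes 100% truth recovery a meaningful
test of the classifier rather than of the generator. Module lengths
(60–200 aa), inter-module gaps (5–25 aa), E-values (1e-50–1e-20) and
coverages (0.5–0.98) are drawn to resemble passing dbCAN hits; three
genomes per group is the default corpus. Generation is a pure function of
the design (seed included), and the corpus is written in the exact ingest
dialect (10-column hmmscan-parser tables with `.hmm`-suffixed names, plus
a protein FASTA and truth tables).

What the generator does *not* emulate: realistic HMM score distributions
near the cutoffs, truncated genes from draft assemblies, annotation
disagreement between tools, or biologically realistic protein sequences
(they are uniform random strings — coordinates, not residues, drive the
pipeline). Passing tests therefore demonstrate the correctness of the
rule engine and plumbing, not robustness to noisy real-world annotation.

# Numerical and degenerate-input choices

* Frequencies are exact rational arithmetic in doubles (`100 * n / N`); the
  tests check integer recovery `freq · N / 100 = n` rather than decimal
  prints.
* A focal module absent from a corpus yields `N = 0` and an all-`NA` row,
  flagged with a message — never a division by zero.
* Empty inputs: zero-hit annotation tables parse to empty hit frames;
  `batchClassify()` reports such genomes as `NO_CAZY` when they are named
  in `genomeIds`; writing an empty FASTA or rendering an empty gene map is
  a validation error.
* GenBank CDS without a `/translation` are translated from the spliced
  nucleotide span under genetic code 11 with the trailing stop stripped;
  `/pseudo` features are skipped with a message. Compound (join)
  locations collapse to min-start/max-end with a `multi_segment` flag —
  coordinates are reporting metadata here, not typing inputs.
* Protein-id collisions across replicons of one strain are resolved by
  replicon-prefixing both sides, deterministically.
* Gene-map SVGs are integer-formatted XML written in binary mode, so
  identical input gives byte-identical files on every platform.

# Problem sizes used in the checks

The exhaustive gene-typing sweep covers all 3,125 count vectors in
{0..4}^5 against an independently coded predicate evaluator; the decision
tree is swept over all 64 presence/absence combinations; end-to-end truth
recovery runs the default 24-genome corpus across five seeds; the
co-occurrence implementation is compared to a brute-force per-gene scan on
100 random corpora of up to 50 genes. These sizes fully cover the discrete
rule spaces and keep the whole suite under a minute of compute.

# Known limitations

* The genotype is a *potential*: the engine predicts machinery, not
  measured hydrolysis, and non-CAZy adhesion mechanisms (extracellular
  polymeric substances, Fn3/LysM domains) are invisible to a CAZy-based
  annotation, so some genuinely cellulolytic strains will sit in I-e or
  I-c.
* Results are only as good as the catalog; the shipped default is a
  curated stand-in, and corpus-scale numbers (group counts, co-occurrence
  percentages) shift with the vocabulary and with the upstream HMM
  release.
* The GenBank parser targets well-formed prokaryote flat files; it is not
  a validator for the format's full grammar.
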