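---
title: "Duplex-UMI consensus calling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Duplex-UMI consensus calling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duplexumi)
library(data.table)
```

## The problem

Detecting single-nucleotide variants at allele fractions of 0.1--0.4% --
the regime of circulating tumour DNA assays -- is limited not by sequencing
depth but by base-level artifacts introduced before and during library
construction: oxidative G-to-T lesions from sonication (observed as C>A in
the polymerase frame), cytosine deamination, and polymerase errors in the
first PCR cycles. Unique molecular identifiers (UMIs) remove late-cycle PCR
and sequencing errors by consensus over reads of one founding molecule, but
they cannot remove damage already present on the template strand. Duplex
evidence can: a lesion sits on one strand of the original double-stranded
fragment, so an allele confirmed independently by both strands is almost
certainly real.

This package implements a *single-end* duplex-UMI design: a 12-nt random
UMI and a 2-nt strand barcode are carried on one adapter, so read 1 alone
identifies both the molecule and the strand. The barcode is a deliberate
base mismatch held in the adapter duplex; top-strand reads show `TT`,
bottom-strand reads show `CC` (as sequenced). Reads sharing sample, locus,
fragmentation position, UMI and strand label form a *UMI family*; a top and
a bottom family with the same UMI and nearby fragmentation positions are
the two strands of one molecule and form a *duplex group*.

## Read layout and decoding

Read 1 is `UMI(12) + TTCTGAGCGA + TT|CC + ATAGGAGTCCT + insert`, so the
genomic insert begins at 0-based offset 35; read 2 starts with the
gene-specific primer of the locus (single-primer extension chemistry).
Decoding (`extract_umi_strand()`) tolerates one mismatch per spacer --
spacers are 10--11 nt, so a single sequencing error should not discard the
read -- but requires the barcode to be exact, because the barcode *is* the
strand signal and a miscalled barcode would silently convert duplex
evidence into contradiction. Failures are tallied (`TOO_SHORT`,
`BAD_SPACER`, `BAD_BARCODE`) rather than raised. Insertions or deletions
inside the UMI slot shift the spacer out of register and are caught by the
spacer check, which is why UMI comparison can use plain Hamming distance.

Alignment is consumed, not computed: the pipeline takes either the
simulator's truth placement table or pre-aligned reads whose UMI and strand
label travel in `UM`/`SL` tags (`read_tagged_bam()`).

## Family grouping, merging, pairing

Families are keyed by (sample, locus, fragmentation position, UMI, strand
label); the sample index is part of the key so that molecules from pooled
libraries tagged with the same UMI do not collide. UMI sequencing errors
fragment true families, so a family is absorbed by a larger one when the
UMIs are within Hamming distance 1, the fragmentation positions are within
5 bp, and the larger family has at least 5 times more reads
(`merge_config()`). The 1-mismatch and 5-bp thresholds follow the assay's
processing rules; the 5:1 ratio quantifies "much larger", which the
protocol leaves qualitative, and is configurable. Merging visits families
in descending read count (ties broken lexicographically by UMI) and is
single-pass: an absorbed family never absorbs others, and the merged family
keeps the dominant family's key, including its fragmentation position.

Duplex pairing reuses the 5 bp position tolerance: within (sample, locus,
UMI), a TOP and a BOTTOM family within 5 bp pair greedily by position
distance. Unpaired families remain single-plex. Two same-strand families
that survive merging stay separate single-plex groups.

## Consensus rules

A family reaches consensus at a site when at least 80% of all covering
reads *and* at least 80% of the high-quality covering reads agree
(both thresholds inclusive, so exactly 80% passes). High quality requires
base quality ≥ 25 at the site, mapping quality ≥ 30, at most 3 reference
mismatches in the read, and -- at sites inside a homopolymer run of 5 or
more -- that the read span the run plus one flanking base on each side.
The 80/80 rule is the assay's own; the four HQ thresholds are conventional
values for "a set of thresholds" that the protocol does not enumerate, and
all are configurable (`consensus_config()`). Singleton families are
excluded outright: one read cannot be error-corrected. A family whose
high-quality read set is empty cannot reach consensus.

A duplex group needs both strand families to reach consensus individually:
equal alleles confirm each other; unequal alleles mark the site
*discordant*, the signature of single-strand damage. Discordant duplexes
are excluded from both the numerator and the denominator of every count:
discordance is positive evidence of artifact, and counting the reference
strand as single-plex reference evidence would bias the background error
rates downward. The discordant count is reported per site so the
alternative accounting can be reconstructed. When only one strand of a
duplex covers a site (staggered read ends), the covering strand is counted
as single-plex evidence at that site -- evidence class is a per-site
property, not a per-molecule one.

For non-event bases the per-read representative base quality (the median
of the read's quality string) stands in for the site-level base quality;
mismatching bases always use their own quality. Reads of one family share
the fragment end and read length, so family spans coincide and the
vectorised counting path agrees exactly with the per-family reference
implementation (this equivalence is asserted in the test-suite on
simulations with damage, PCR and sequencing errors).

## Background error model

At each site with reference base $R_i$, $N_i$ qualified (non-singleton,
consensus) UMI families and $n_i$ of them carrying consensus allele $A$,
the panel-wise mean $R{>}A$ error rate is
$\sum_i I(R_i = R)\, n_i \,/\, \sum_i I(R_i = R)\, N_i$,
with Wilson 95% intervals on the pooled counts. Rates are computed in the
*polymerase frame*: a bottom-strand family reads the complementary
template, so a reference-coordinate G-to-T observation on the bottom strand
counts toward C>A. Types with no eligible site are reported missing, never
zero. Known variant sites of the sample must be excluded before estimation.

Variant calling needs a *distribution* of the per-site error rate, not just
the mean. The site rate is modelled as $e_i \sim \mathrm{Beta}(\alpha,
\beta)$ and fitted by maximum likelihood on the *counts*,
$n_i \sim \mathrm{BetaBin}(N_i, \alpha, \beta)$, using `stats::optim` on
$(\log\alpha, \log\beta)$. Fitting counts rather than empirical rates is
deliberate: at a background of $5\times10^{-5}$ and 10--20 thousand UMIs
per site most sites observe zero errors, and a Beta likelihood on exact
zeros is undefined. When every site is zero the dispersion is undetermined;
the fit is flagged `UNDETERMINED` rather than guessed at. Only the G>A
profile -- the most abundant residual error class -- is fitted by default
and conservatively applied to all twelve types; per-type fits are available
behind a flag. Rarer types at the one-per-million magnitude are not
fittable at realistic depths, which is why no per-type threshold is
hard-coded.

The end-repair artifact signature is tested with a Welch two-sample t
statistic comparing distances from non-reference duplex-supported sites to
the ligated (UMI-bearing) 5' fragment end, one-sided for "artifacts sit
closer". Distances are measured in bp from the terminal base, inclusive of
0. Degenerate input (both groups constant and equal) returns p = 0.5.

## The caller

Calling is model selection between $M_0$ (no mutation; all non-reference
UMIs are background error) and $M_1$ (all non-reference UMIs are real).
With $N_1$ single-plex and $N_2$ duplex qualified UMIs, $n_1$ and $n_2$
non-reference:

* under $M_0$: $n_1 \sim \mathrm{BetaBin}(N_1, \alpha, \beta)$ and
  $n_2 \sim \mathrm{Binomial}(N_2, e_d)$ with
  $e_d = \max(\hat e^2, 10^{-7})$, $\hat e = \alpha/(\alpha+\beta)$ --
  a duplex non-reference consensus requires the same error independently
  on both strands, hence the squared rate; the floor guards against
  zero-probability likelihoods from end-repair-copied damage, which
  violates the independence assumption near fragment ends;
* under $M_1$: $n_1 \sim \mathrm{Binomial}(N_1, \hat f)$,
  $n_2 \sim \mathrm{Binomial}(N_2, \hat f)$ with the profile-likelihood
  plug-in $\hat f = (n_1+n_2)/(N_1+N_2)$.

The score is the natural-log likelihood ratio
$\log L(M_1) - \log L(M_0)$; a site is called when the score reaches the
threshold (default 6, i.e. $M_1$ about $e^6$ times more likely) with at
least 2 non-reference UMIs. This generalised-likelihood-ratio construction
is this package's explicit design choice for the stated $M_0/M_1$ setup,
isolated in `log_likelihood_ratio()` so an alternative likelihood can be
swapped in; whether $\hat f$ should instead be marginalised over a prior is
genuinely open, and the plug-in was chosen for transparency and speed.
Single-plex mode -- used for head-to-head comparisons -- first remaps
counts as $N_1 \leftarrow N_1 + 2N_2$, $n_1 \leftarrow n_1 + 2n_2$: each
duplex contributes its two strand families as independent single-plex
evidence, conserving the total strand-family count.

## The simulator

`simulate_molecules()` / `tag_and_sequence()` emulate the reference-mixture
experiments used to characterise the assay:

* diploid reference with SNVs spiked at configurable fractions (0.1--0.4%
  in the mixtures the defaults mirror); a variant is carried by *both*
  strands of a carrier molecule;
* fragments of Normal(170, 25) bp truncated at 50 bp, ligated-end position
  shared by both strands (without this, duplex pairing by fragmentation
  position would be impossible);
* strand-specific damage per substitution type at per-base per-strand
  rates up to $10^{-2}$, applied in the polymerase frame *before* tagging;
  lesions strictly within `end_repair_copy_distance` (default 15 bp) of
  the ligated end are copied to the complementary strand, emulating
  end-repair fill-in -- the mechanism by which single-strand damage gains
  false duplex support near fragment ends. Distance 0 disables copying;
* independent per-strand capture with probability $s$ (default 0.387),
  giving a duplex share of observed UMI groups of $s/(2-s) \approx 0.24$,
  the share observed in these libraries (two captured strands out of
  $2s - s^2$ observable outcomes);
* family sizes $1 + \mathrm{Poisson}(\mu - 1)$ with $\mu = 4.5$ reads per
  UMI, matching the observed mean while guaranteeing one read; the true
  size distribution is not reported, so the simplest guaranteed-positive
  form was chosen;
* PCR errors once per family founder copy (UMI-consistent within a family,
  absent from the sister strand), sequencing errors independently per read
  over the full read including the UMI and spacers. Applying damage before
  tagging and PCR error after is exactly the distinction the duplex method
  exploits, and the simulator preserves it structurally.

The simulator does not model quality-score distributions (qualities are
constant Q40), indels, adapter dimers, polymerase-specific error spectra,
or GC-dependent capture bias. Consensus therefore exercises the quality
*rules* but not realistic quality noise, and passing tests show the
machinery is correct under the stated generative model -- not that real
libraries meet that model. Read 2 is emitted for interface completeness
but consensus uses read 1 only, whose insert covers about 115 bp inward
from the ligated end; `random_panel()` places target intervals inside the
well-covered band by default.

`simulate_site_counts()` draws qualified per-site UMI counts directly
(skipping the read level) for caller evaluation at full panel scale:
depth $\mathrm{Poisson}$(mean), duplex split binomial, background
$e_i \sim \mathrm{Beta}(2, 40000)$ (mean $5\times10^{-5}$),
$n_1 \sim \mathrm{Bin}(N_1, e_i)$, $n_2 \sim \mathrm{Bin}(N_2, e_i^2)$.
Optional strand-specific damage adds single-plex-only errors with per-site
rates from a heavy-tailed Beta (shape 0.5) around the requested mean,
emulating damage hotspots; hotspot dispersion is what makes single-plex
calling genuinely harder, and a shape below 1 is the simplest way to get
it. Damage-induced duplex discordance (which would slightly deplete
$N_2$) is ignored at this level.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; VCF and the site-count TSV
  are written 1-based.
* Ties at exactly 80% agreement pass ("at least 80%"); majority-allele
  ties break lexicographically, as do alternative-allele ties per site.
* `fit_beta` initialises at $\alpha = 1$, $\beta = (1-\bar e)/\bar e$ from
  the pooled rate and optimises Nelder-Mead on the log scale with
  `reltol` $10^{-10}$; unique $(n, N)$ pairs are collapsed with weights.
* Zero qualified UMIs at a site gives `NO_CALL`, distinct from a negative
  score; sites below the 2-UMI evidence minimum are `MIN_ALT` and are
  never called at any threshold in ROC sweeps.
* Same-seed runs are byte-identical including FASTQ output; the molecule
  and sequencing stages reseed deterministically from the configured seed.

## Problem sizes used in the test-suite

Module tests run hundreds to a few thousand molecules per simulation. The
caller evaluation simulates the panel at full scale -- 87 variant and
17,772 wild-type sites at mean depths of 14,221 and 16,928 qualified UMIs
-- at the count level, averaged over 5 seeds; the read-level end-to-end
check uses 10,000 molecules over two loci with variants at 0.5--1%, sizes
at which the duplex-share estimate has a standard error well inside the
±0.02 tolerance asserted. The duplex-versus-single-plex comparison uses 20
seeds with damage hotspots at 5× the background mean. These sizes are the
package's chosen balance between statistical resolution and a test-suite
that runs in a few minutes.

## Known limitations

* The likelihood under $M_1$ uses a plug-in fraction rather than
  marginalising; scores are mildly optimistic at very low counts (the
  2-UMI minimum absorbs the worst of it).
* Only the top alternative allele is scored per site; multi-allelic sites
  and indels are out of scope.
* The BAM reader handles fully-aligned (`<n>M`) records only; soft-clipped
  primer handling is delegated to upstream alignment.
* Family spans are treated as coinciding within a family in the fast
  counting path; data with heterogeneous read lengths inside one family
  would be counted approximately there (the per-family reference path is
  exact).
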