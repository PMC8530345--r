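# invitroRescue

End-bias quantification and dual-enzyme recovery for *in vitro*
reconstituted nucleosomes.

## The problem

Genome-wide maps of intrinsic nucleosome-DNA affinity are built by
reconstituting histone octamers on protein-free genomic DNA
("invitrosomes"), sequencing the protected 147-bp cores, and mapping the
single-end reads back to the genome. When the input DNA is fragmented,
nucleosomes preferentially assemble **on or very near the fragment
termini** — proximal end bias, a purely experimental artifact. If the
fragments come from a blunt-cutting type II restriction digest the
termini are known exactly, so end-proximal calls can be flagged; the
conventional remedy is to discard every read within some distance *d* of
a fragment end, which can cost most of a library.

This package implements, for analysts of such libraries:

1. **In-silico digestion** — cut-site location for IUPAC-degenerate
   palindromic blunt cutters (built-ins: RsaI `GT^AC`, HincII
   `GTY^RAC`), fragment tables with a 147-bp minimum-length filter, and
   digestion statistics.
2. **Dyad calling** — each read's 5' base marks one footprint end; the
   dyad sits (147 − 1)/2 = 73 bp inward, downstream on `+` reads and
   upstream on `-` reads.
3. **End-bias profiles** over positions *p* = 1..73 from fragment ends:
   the *start ratio* (starts at *p* / all starts in the library) and
   *mean-normalized occupancy* (RPKM-scaled start coverage / window
   mean, so 1 = average occupancy). A spike at *p* = 1 that vanishes at
   the other enzyme's cut sites is the end-bias signature.
4. **The recovery method** — classify each invitrosome as
   *innercut* (an own-enzyme cut site strictly inside the footprint: an
   under-digested template, always rescued), *suspect* (footprint start
   inside a suspect start region or footprint end inside a suspect end
   region, regions of width *d* at each fragment terminus), or *passed*;
   then rescue suspects whose position is corroborated by a passed or
   innercut invitrosome in the alternate-enzyme library
   (dyad distance ≤ tolerance, default 0). Full accounting with
   passed/suspect/innercut/recovered/biased counts and one-decimal
   percentages, plus Raw / PreRecovery / PostRecovery sub-libraries.
5. **Composition stability** — position-specific 4-mer frequency
   matrices (4ᵏ × 144 for 147-nt footprints) and Pearson/Spearman
   correlations between sub-libraries and against end-free reference
   libraries, over all positions or only the 7 terminal positions at
   each end.
6. **A truth-tracked simulator** — i.i.d. genomes with hard-masking,
   enzyme-digest / sheared (600–800 bp) / uniform read libraries with a
   tunable terminal-placement enrichment factor β, emitting 25-nt reads
   plus a complete truth table, so the whole pipeline is testable with
   no external data.

## Worked example

A 1-Mb synthetic genome, a HincII-digest library of 200,000 molecules
with 4-fold terminal enrichment confined to the terminal base, and the
full quantify–classify–recover loop:

```r
library(invitroRescue)
library(Biostrings)

genome <- simulateGenome(1e6, gc = 0.36, seed = 1)
sim <- simulateEnzymeLibrary(genome, "HincII", n = 200000,
                             beta = 4, seed = 2)
inv <- callDyads(sim$reads,
                 seqlengths = setNames(width(genome), names(genome)),
                 library = "HincII")

prof <- startRatioProfile(inv, sim$fragments, library = "HincII")
prof
#> EndBiasProfile: HincII vs HincII cut sites (start_ratio, window 73, n = 200000)
#>   value(1) = 0.00333; window mean = 0.0008168
v <- profileValues(prof)
round(v[1] / median(v[2:73]), 2)
#> [1] 4.26
```

The terminal base carries ~4× the baseline start ratio — the planted
enrichment factor, read straight off the profile. Classification and
recovery against an RsaI-digest library of the same genome:

```r
cs  <- findCutSites(genome, "HincII")
cls <- classifyInvitrosomes(inv, buildSuspectRanges(sim$fragments, 200), cs)
table(cls$label)
#>  passed suspect
#>  144114   55886

simR <- simulateEnzymeLibrary(genome, "RsaI", n = 200000, beta = 4, seed = 3)
invR <- callDyads(simR$reads,
                  seqlengths = setNames(width(genome), names(genome)),
                  library = "RsaI")
clsR <- classifyInvitrosomes(invR, buildSuspectRanges(simR$fragments, 200),
                             findCutSites(genome, "RsaI"))
final <- crossRecover(cls, clsR[clsR$label %in% c("passed", "innercut")],
                      tolerance = 0)
tabulateRecovery(final, library = "HincII", suspectRange = 200)
#> RecoveryReport: HincII at 200-bp suspect range
#>  library suspectRange        category   count percent
#>   HincII          200      totalReads 200,000      NA
#>   HincII          200     mappedReads 200,000   100.0
#>   HincII          200          passed 144,114    72.1
#>   HincII          200 positionSuspect  55,886    27.9
#>   HincII          200    innerCutSite       0     0.0
#>   HincII          200      allSuspect  55,886    27.9
#>   HincII          200       recovered   2,365     1.2
#>   HincII          200  totalRecovered   2,365     1.2
#>   HincII          200 remainingBiased  53,521    26.8
#>   HincII          200    postRecovery 146,479    73.2
```

27.9% of the library sits within 200 bp of a HincII fragment end;
2,365 of those reads share an exact dyad with a passed RsaI-library
invitrosome and are rescued. (Recovery rates are low here because at
this sequencing depth exact-dyad coincidences are rare; real libraries
are an order of magnitude deeper. The simulator's digestion is also
complete, so no innercut reads arise.) `runPipeline()` drives the same
loop end to end from a YAML/list config, writing BED/TSV/JSON at every
stage, and `inst/scripts/invitrorescue.R` exposes each stage as a shell
subcommand (`digest`, `dyads`, `endbias`, `recover`, `kmer`,
`simulate`, `run`).

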