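# chosda

Chitooligosaccharide deacetylation analysis and CE4 deacetylase
screening.

Chitin deacetylases (CDAs, CAZy family CE4, EC 3.5.1.41) convert
N-acetylglucosamine (**A**) units of chitooligosaccharides (CHOS) into
glucosamine (**D**), and *where* along the chain they act — the pattern
of acetylation P_A, on top of the fraction F_A = nA/DP — determines the
biological activity of the product.  `chosda` implements the
computational workflow of a CDA characterization study for researchers
mining sequence collections for deacetylases and sequencing their
reaction products by mass spectrometry:

* **Mass arithmetic** for CHOS with an optional 2-aminoacridone (AMAC)
  reducing-end label.  Reductive amination replaces the reducing-end
  water and adds H2, so a labeled oligomer's neutral mass is
  Σ residues + AMAC + H2, and the protonated ion is (M + z·H⁺)/z.
* **MS2 pattern sequencing**: Y/B fragment-ladder enumeration, peak
  matching, exhaustive ranking of positional isomers by
  explained-intensity fraction, per-position deacetylation support
  f_i = Σ_p w_p·[p_i = D] with w_p ∝ score_p^γ, and chain-end
  diagnostics (GlcNAc-AMAC m/z 416.18 vs GlcN-AMAC 374.17).
* **Candidate screening**: the five conserved CE4 motifs (T(F/Y)DD,
  H(S/T)xxH, RxPY, DxxD(W/Y), LxH) plus gene-completeness,
  signal-peptide and single-domain filters, applied as an auditable
  funnel with per-stage counts.
* **Activity metrics**: ASAR (substrate as acetyl-group concentration),
  deacetylation degree = 100·acetate/ASAR, release rate (nmol/min) and
  apparent rate constant k_app = acetate/(t·[E]) (s⁻¹) from raw
  acetate-release assays, including the built-in ten-substrate
  reference panel.
* **Synthetic data**: a continuous-time Markov simulator of
  position-biased sequential deacetylation (exponential clocks, optional
  Gillespie neighbor penalty), synthetic MS2 spectra, and protein
  collections with planted ground truth.

## Worked example

Sequencing a mixed mono-deacetylated pentamer pool from a synthetic MS2
spectrum:

```r
library(chosda)

p <- chosPattern("AADAA", label = "AMAC")
p
#> ChosPattern (non-reducing end -> reducing end): AADAA+AMAC
#>   DP 5 | nA 4 | nD 1 | F_A 0.8
ionMz(p)
#> [1] 1186.489      # the printed ion-trap value is 1186.6

sp <- synthSpectrum(c(AADAA = 0.85, ADAAA = 0.15),
                    noise = spectrumNoise(mzJitterSd = 0.1,
                                          nNoisePeaks = 8, seed = 42))
rk <- rankPatterns(sp, nA = 4, nD = 1)
head(rk, 3)
#>   pattern     score explainedFraction nMatched
#> 1   AADAA 0.8022628         0.9375019        9
#> 2   ADAAA 0.6847823         0.7954325        9
#> 3   AAADA 0.6344335         0.7345456        7

round(positionalSupport(rk)$f, 3)
#>  pos1  pos2  pos3  pos4  pos5
#> 0.078 0.240 0.453 0.177 0.052
```

The dominant mixture component is recovered at rank 1 and the
positional support concentrates on the internal positions (the minority
isomer ADAAA lifts pos2), with little support at either chain end.

Screening a synthetic 64-protein collection and reconstructing the
activity table:

```r
coll <- synthProteinCollection(seed = 1)
runCascade(coll$proteins, coll$truth[, c("id", "family")])
#> ScreenReport: 64 proteins
#>   funnel: input=64 -> familyCE4=48 -> motifsPresent=24 -> complete=16
#>           -> signalPeptide=5 -> singleDomain=1
#>   candidates: prot064

head(reproduceTable(chitinDeacetylaseAssays())[,
       c("substrate", "asarUM", "degreeFmt", "kAppFmt")], 3)
#>   substrate asarUM degreeFmt kAppFmt
#> 1    GlcNAc   2000     0.000    0.00
#> 2 (GlcNAc)2   4000     0.003    0.00
#> 3 (GlcNAc)3   6000      0.20    0.02
```

File-based workflows go through `runScreenReport()` (FASTA +
annotation TSV → funnel/verdict TSVs) and `runMsReport()` (MGF →
pattern scores, positional-support JSON); see the methods vignette
(`vignettes/chos-deacetylation.Rmd`) for the model, parameter defaults
and their rationale.

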