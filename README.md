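# aptamin

In-silico minimization of single-stranded DNA aptamers.

Aptamers selected by SELEX are often much longer than the structural
element that actually recognizes their target. Trimming them is attractive
(cheaper synthesis, fewer off-target structures) but dangerous: deleting
residues from a drawn secondary structure "on paper" says nothing about
what the shortened molecule will actually fold into. `aptamin` makes the
whole minimization loop computational and verifiable:

1. **Fold** — minimum-free-energy (MFE) secondary structure of ssDNA under
   the nearest-neighbor thermodynamic model, computed by Zuker-style
   dynamic programming over pseudoknot-free structures:

   *E(S) = Σ over loop faces of* `E_face`, with stacking, hairpin, bulge,
   interior and multiloop terms read from the bundled DNA Mathews-2004
   tables (37 °C, energies in kcal/mol, integer hundredths internally).
   The multiloop term is the standard affine `a + b·k + c·u` (closing
   penalty, per-helix, per-unpaired-base); dangles follow the common
   both-sides ("d2") convention.

2. **Truncate** — a sliding-window scan over 5′/3′ end trims refolds every
   candidate and keeps those whose MFE structure still contains the
   designated multiloop recognition motif (dot-bracket fragment, minimum
   junction branching, required-unpaired segments).

3. **Design** — constrained inverse folding: repeated seeded adaptive
   walks search for sequences whose MFE structure equals the minimized
   target (objective: base-pair distance 0), under positional IUPAC
   constraints. Batches deduplicate successes and rank them by MFE.

4. **Restore & vary** — functional loop sequences are written back into
   the best design; multiloop junction composition variants (e.g. `AAAA`,
   `TTTT`, `ATAT`) are generated for downstream modeling.

5. **Screen** — designs carrying canonical G-quadruplex motifs
   (≥4 G-runs of ≥3, loops 1–7) are flagged and excluded from the ranking;
   pseudoknots are excluded by the folding model itself.

## Worked example

```r
library(aptamin)

# fold the bundled 64-nt Gol1 aptamer
gol1 <- read_fasta(system.file("extdata", "gol1.fasta", package = "aptamin"))[[1]]
mfe_fold(gol1)
#> >Gol1
#> GCCGGCGGCATTTTGACGCCGCCGCCGGCCGGCTGCTTATGCTGCTCCGGGGGGCATATATGGC
#> ..(((((.((...)).)))))((.((((..(((.((....)).))))))).))........... (-17.90)
```

The three lines are the Vienna plain-text convention: identifier,
sequence, and the MFE structure in dot-bracket notation with its free
energy of formation in kcal/mol. (The study that proposed Gol1 printed
−24.7 "AU" for this fold; the value computed here, −17.90, is what the
named parameterization actually yields — the reference folding engine
RNAfold with `dna_mathews2004.par` prints the identical structure and
energy.)

A synthetic three-way-junction parent makes the whole pipeline
demonstrable with known ground truth:

```r
fx <- make_synthetic_aptamer(synthetic_aptamer_spec(seed = 3))
land <- truncation_scan(fx$sequence, fx$motif)
attr(land, "selected")[, 1:4]
#>   trim5 trim3 length energy_kcal_mol
#> 1     5     7     48           -20.2
```

The scan recovers exactly the 5 nt of 5′ and 7 nt of 3′ padding the
generator inserted — trimming any deeper cuts into the outer stem and the
refolded molecule loses its junction. Designing against the minimized
structure and ranking by energy:

```r
target <- parse_dotbracket(attr(land, "selected")$dotbracket)
batch  <- run_design_batch(target, n_runs = 20, master_seed = 1)
summary(batch)
```

`run_pipeline(pipeline_config(...))` chains all stages and writes the
landscape TSV, design-batch JSON, ranked FASTA, screen TSV and the
resolved configuration (with the parameter-table checksum and master
seed) to an output directory. A thin command-line front end lives at
`inst/cli/aptamin.R`.

## Scope

Pseudoknots, G-quadruplex thermodynamics, partition-function (ensemble)
design objectives, RNA parameters, temperature rescaling, co-folding and
3D structure modeling are out of scope. See the methods vignette
(`vignettes/aptamer-minimization.Rmd`) for the model, its assumptions and
the design decisions.
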