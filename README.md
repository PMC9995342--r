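# episial

Targeted detection of tetra-sialylated erythropoietin N-glycopeptides in
LC–HRMS data.

## The problem

Recombinant erythropoietin (rEPO) is a prohibited performance-enhancing
drug. Endogenous urinary EPO carries mono- to tri-sialylated N-glycans;
N-glycans terminating in **four** sialic acids occur only on the
recombinant products, so an intact tetra-sialylated N-glycopeptide is an
exogenous marker whose presence in urine implies drug administration.
`episial` is for analytical and anti-doping scientists building or
evaluating such targeted glycopeptide assays: it provides the in-silico
assay design (digestion, masses, transitions), the detection logic for
centroided runs, the bioanalytical validation battery, and a synthetic-run
generator with known ground truth so every estimator can be verified
without instrument data.

## The core computation

The assay monitors the EPO Asn38 glycopeptide `HCSLNENITVPDTK` (mature
chain residues 32–45, carbamidomethyl-Cys) carrying
HexNAc(6)Hex(7)Fuc(1)NeuAc(4). Masses are monoisotopic and additive:

    M(glycopeptide) = Σ residue masses + H2O + mods + Σ glycan residue masses
    m/z(z, k)       = (M + k·1.003355 + z·1.007276) / z

where `k` is the monitored ¹³C isotopologue. For this ~5.3 kDa analyte the
isotope envelope peaks at M+2, so the SIM precursor is monitored at
`m/z(4, 2) = 1324.0221` rather than the monoisotopic 1323.5205. Identity is
confirmed by the diagnostic oxonium series (HexNAc 204.087, NeuAc−H₂O
274.092, NeuAc 292.103, HexNAc+Hex 366.139, HexNAc+Hex+NeuAc 657.235), and
a detection call requires chromatographic S/N > 3 plus ≥ 4 matched product
ions in a covering MS2 scan.

## Worked example

```r
library(episial)

gp <- glycopeptide(peptide("HCSLNENITVPDTK", start = 32L, end = 45L),
                   site = 38L, glycan = "_6_7_1_4")
gp
#> <glycopeptide> HCSLNENITVPDTK_6_7_1_4 (site 38)
glycopeptide_mass(gp)
#> [1] 5290.053
glycopeptide_mz(gp, charge = 4, isotopologue = 2)   # the SIM target
#> [1] 1324.022
oxonium_ions(gp$glycan)
#>      kind            label       mz charge index
#> 1 oxonium           HexNAc 204.0866      1    NA
#> 2 oxonium              Hex 163.0601      1    NA
#> 3 oxonium              Fuc 147.0652      1    NA
#> 4 oxonium            NeuAc 292.1027      1    NA
#> 5 oxonium        NeuAc-H2O 274.0921      1    NA
#> 6 oxonium       HexNAc+Hex 366.1395      1    NA
#> 7 oxonium HexNAc+Hex+NeuAc 657.2349      1    NA

# a synthetic spiked run (10 ng/mL) and a blank, same noise seed
run   <- simulate_run(synthetic_run_config(concentration = 10, seed = 42))
blank <- simulate_run(synthetic_run_config(concentration = 0,  seed = 42))
detect_target(run, target_transition())
#> <detection> HCSLNENITVPDTK  detected=TRUE  S/N=165.54  rt=14.99  area=514.7  products=7
detect_target(blank, target_transition())
#> <detection> HCSLNENITVPDTK  detected=FALSE  S/N=1.50  rt=14.33  area=2.5  products=0
```

The spiked run is called positive (S/N far above 3, all products matched);
the blank fails both the S/N threshold and the product requirement. The
peak area (intensity × minutes, baseline-corrected) is the quantitative
response used by the validation battery: with the default response factor
of 100 area units per ng/mL, ~515 at 10 ng/mL reflects the ~51% of the
Gaussian peak inside the apex ± 3-scan integration region reported by
`detect_target()` (full-window areas from `measure_peak_area()` recover
concentration × response).

In-silico assay design from the packaged mature EPO chain:

```r
find_sequons(epo_mature_sequence())
#>   position sequon
#> 1       24    NIT
#> 2       38    NIT
#> 3       83    NSS
tab <- peptide_table(digest(epo_mature_sequence(),
                            enzyme_preset("gluc+trypsin", max_missed = 2)))
subset(tab, sequence == "HCSLNENITVPDTK")
#>          sequence start end missed_cleavages     mass
#> 33 HCSLNENITVPDTK    32  45                2 1626.767
```

A command-line interface (`exec/episial`) exposes the same functionality:
`digest`, `transitions`, `detect`, `validate`, `simulate`.

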