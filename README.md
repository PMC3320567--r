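# mdcontacts

Interaction fingerprinting of protein–peptide molecular-dynamics
trajectories, built for the analysis of SH2-domain/phosphopeptide
recognition.

SH2 domains read short phosphotyrosine (pY) motifs: the phosphotyrosine
docks into a basic pocket, the residue at pY+3 into a second surface
pocket, and the residues further C-terminal tune affinity and specificity.
Given an MD trajectory of such a complex (a multi-model PDB, one MODEL per
frame), `mdcontacts` answers the standard questions of this analysis:

- **Which atomic contacts form in each frame?** Salt bridges (anionic O to
  cationic N at ≤ 3.2 Å), hydrogen bonds (donor–acceptor heavy atoms at
  ≤ 3.0 Å with a D–H–A angle ≥ 120° when hydrogens are present), and
  hydrophobic contacts (apolar heavy atoms at ≤ 5.0 Å). All cutoffs are
  inclusive and configurable.
- **Which residue pairs are stable?** Per residue pair, the *occupancy* of a
  contact kind is the fraction of frames in which it occurs; only pairs
  occupied in strictly more than 30 % of the frames (default) are reported.
- **How does each side interact?** Each record carries a class label such as
  `s-s`, `m-s` or `hs-s`: main-chain (`m`), side-chain (`s`), or
  hydrophobic-only involvement of a side chain that also has a polar part
  (`hs`), ligand side first.
- **Where on the interface?** Ligand residues map to interface regions by pY
  offset: region I (pY, pY+1), region II (pY+2, pY+3), region III (pY+4
  onward); pY−1 reports as flank.

Everything is tidyverse-native: functions take data frames and return
tibbles, results chain with the pipe, and fitted result types have
`tidy()`, `glance()` and `autoplot()` methods. A synthetic-trajectory
generator plants schedule-controlled contacts with exact ground truth, so
the whole pipeline is testable without external data. Small helpers
quantify reporter-assay and immunoblot measurements (relative response
ratio, renilla normalisation, GAPDH-normalised phospho ratios).

## Worked example

The shipped fixture plants a strong three-region binder: a 9-residue
`GyRPQNVLT` phosphopeptide (residues 113–121, pY at 114) with a
pY–lysine salt bridge (region I), a Gln–Tyr hydrogen bond at pY+3
(region II) and a Val–Met hydrophobic contact at pY+5 (region III):

```r
library(mdcontacts)
library(dplyr)

fx <- three_region_fixture(n_frames = 50, seed = 42)
tab <- detect_all(fx$trajectory, "B", "A") |>
  accumulate(fx$trajectory) |>
  stable_interactions(fx$peptide, threshold = 0.30)
tidy(tab)
#> # A tibble: 3 × 8
#>   ligand_resname ligand_resnum offset region receptor_resnum kind    class_label
#>   <chr>                  <int>  <int> <chr>            <int> <chr>   <chr>
#> 1 PTR                      114      0 I                  591 saltbr… s-s
#> 2 GLN                      117      3 II                 640 hbond   s-s
#> 3 VAL                      119      5 III                648 hydrop… s-s

cat(render_table(tab, "text"), sep = "\n")
#> Region   flank  I         I     II    II        III   III       III   III
#> Ligand   G113  pY114     R115  P116  Q117      N118  V119      L120  T121
#>                K591 s-s              Y640 s-s        M648 s-s

glance(tab)
#> # A tibble: 1 × 7
#>   n_records n_region_I n_region_II n_region_III n_flank n_frames threshold
#> 1         3          1           1            1       0       50       0.3
```

The three records recover the planted occupancies (0.80, 0.60, 0.50)
exactly, each in its planted region with its planted side-chain/side-chain
class. `autoplot(tab)` draws the occupancy profile;
`distance_timeseries()` extracts per-frame minimum heavy-atom distances for
any residue pair, e.g. over the final stretch of a run.

A thin command-line wrapper over the same functions ships at
`inst/cli/mdcontacts.R` with subcommands `profile`, `timeseries`,
`fixtures` and `quant`; flags mirror the parameter names
(`--hbond-cutoff`, `--threshold`, ...), and a flat YAML config file can
record a full run.

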