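# icodiff

Difference mapping and occupancy analysis for icosahedral cryo-EM density
maps.

## The problem

Double-stranded RNA bacteriophages assemble an empty, unexpanded procapsid
before packaging their genome. The procapsid of cystoviruses is built from
120 copies of the shell protein P1, with three further proteins at
substoichiometric occupancy: the RNA-dependent RNA polymerase P2, the
packaging NTPase P4 at the twelve five-fold vertices, and the packaging
cofactor P7. Where P2 and P7 sit inside the shell — and how strongly each
site is occupied — can be read out of icosahedrally averaged single-particle
reconstructions by comparing the complete particle (P1247) with deletion
mutants lacking one protein (P124 = P7-minus, P147 = P2-minus).

`icodiff` implements that comparison as a reusable, tested analysis for
people working with icosahedral reconstructions: map normalization,
difference mapping, symmetry-axis site detection, and occupancy estimation,
together with a synthetic phantom generator that provides ground truth for
validating every stage.

## The method

Given three reconstructions on a common grid, the pipeline

1. **low-pass filters** each map to a common resolution (default 16 Å) to
   suppress resolution-difference artifacts;
2. **thresholds** each map at the density level *t* whose enclosed volume
   matches the expected protein volume of the shell,
   *V = n·m/(N_A·ρ)* (default 120 copies × 84 kDa at ρ = 1.41 g/cm³,
   ≈ 1.19 × 10⁴ nm³), giving a shell mask per map;
3. **standardizes** each map to mean 0 and standard deviation 1 over the
   union of a background annulus and its own shell mask, then applies
   per-shell **radial scale factors** from the masked radial averages;
4. forms the **difference maps** P1247 − P147 (polymerase) and
   P1247 − P124 (cofactor), plus the composite P124 + P147 − P1247, which
   satisfy the exact identity
   (P1247−P124) + (P1247−P147) + (P124+P147−P1247) = P1247;
5. **detects sites** as the peak density inside a search cylinder around
   each three-fold axis direction within a radial band, reported when the
   peak clears a σ-contour threshold (default 2 σ of the difference map);
6. **estimates occupancy** as
   occ = (site − background) / (shell_reference − background), with the
   mean of the top 1% of shell densities as the 100% level and the annulus
   as 0%.

Supporting tools: the 60-element icosahedral rotation group and its
12/20/30 axis direction sets in a fixed 222 orientation, group averaging of
maps, MRC2014 I/O, radial profiles, and Fourier shell correlation with
resolution read at a cutoff (0.5 by convention).

Because site densities are measured only at the nominal symmetry positions,
occupancies are position-conditional: protein present but displaced from
its site does not count, exactly as in the original analysis.

## Worked example

Generate a synthetic mutant triple at the default study conditions
(96³ voxels at 2.9 Å, shell radius 80 Å, polymerase occupancy 0.5, cofactor
occupancy 0.57, noise 0.1 × shell amplitude) and run the full pipeline:

```r
library(icodiff)

spec   <- phantom_spec(seed = 42)
triple <- generate_mutant_triple(spec)
config <- pipeline_config(
  target_volume_nm3 = phantom_target_volume(spec),
  p1_radial_band    = spec$shell_radius + c(-2, 2) * spec$shell_thickness)
report <- run_pipeline(triple$maps, config)

report$site_counts
#> polymerase   cofactor
#>         20         20

print(report$occupancy[, 1:4], digits = 3)
#>      protein   map occupancy site_mean
#> 1 polymerase P1247     0.472     1.381
#> 2 polymerase  P124     0.406     0.639
#> 3   cofactor P1247     0.484     1.415
#> 4   cofactor  P147     0.379     0.473
```

The polymerase difference map shows density at all 20 three-fold axis
directions — the full set of visible polymerase sites in the unexpanded
particle — and the recovered complete-particle occupancies (0.47, 0.48)
track the generator's ground truth (0.50, 0.57). Occupancies read directly
off the mutant maps (rows 2 and 4) are cruder: they inherit shell tails and
displaced density, which is why the estimator is documented as
position-conditional. Since at most 12 of the 20 sites can be occupied
simultaneously, `max_occupancy(12, 20)` = 0.6 bounds the polymerase
occupancy from above.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/icodiff.R` (`simulate`, `pipeline`, and `fsc` subcommands).

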