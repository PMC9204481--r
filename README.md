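# plaqrupt

Quantitative analysis of ruptured coronary plaques from frame-level
intravascular OCT annotations, with desk-scale physiology surrogates on
representative idealized lesion geometries.

## The problem

Plaque rupture causes most acute coronary events. It happens both in native
vessels (PR-NV) and inside previously stented segments where a new
atherosclerotic layer — neoatherosclerosis — has grown within the neointima
(PR-NA). The two lesion types differ morphologically, and those differences
change the local mechanics: the endothelial shear stress (ESS) exerted by
blood on the lumen and the structural stress (PSS) carried by the plaque
wall, both of which drive destabilization. `plaqrupt` is for researchers who
have frame-level OCT annotations (lumen/EEM/stent contours or areas, tissue
arcs, cap-thickness profiles, rupture cavities, thrombus quadrants) and want
the full quantitative pipeline: per-lesion morphometry, group comparison
tables, and idealized-geometry physiology.

## What it computes

**Morphometry.** Culprit lesions are delimited by the group rule (lipid or
plaque burden ≥ 40% in native vessels; mean neointima ≥ 0.5 mm in-stent);
the package then reports the minimum lumen area (MLA), lesion length, area
stenosis `100·(1 − MLA / mean(A_prox, A_dist))`, upstream/downstream radius
gradients `RG = (R_ref − R_MLA)/L`, fibroatheroma phenotype (TCFA when the
minimum fibrous cap ≤ 65 μm over > 90° of lipid), pooled minimum/mean cap
thickness, tissue indices

    index = 100 · (mean arc [deg] × tissue length) / (lesion length × 360°)

for lipid, calcium and lined macrophages, microchannel runs (≤ 300 μm, ≥ 3
consecutive frames), rupture site count/length/depth/arc with upstream /
throat / downstream and center / shoulder location classes, and the thrombus
score (percent of lumen quadrants with thrombus).

**Statistics.** Two-group tables in the clinical-reporting idiom: mean ± SD
with Student/Welch t from summary statistics, Mann–Whitney U after a
normality screen, and the Pearson χ² on 2×2 counts *without* continuity
correction — the variant that reproduces printed p-values from printed
counts.

**Physiology.** From the group-mean lesion specification the package builds
a C¹ cosine-taper stenosis with cap/lipid/EEM layering (remodeling index
1.20 at the MLA) and an optional stent ring lattice, then evaluates a
quasi-1D Poiseuille model `τ = 4μQ/(πR³)` and a steady axisymmetric
Navier–Stokes solver (stream-function/vorticity finite differences,
validated against Poiseuille to < 1%), plus closed-form wall stress: Lamé
thick-walled profiles, the Laplace cap limit `σ = pR/h_cap` over the lipid
pool, Mooney–Rivlin material response, and a stent caging factor for the
stented wall.

**Synthetic cohorts.** `simulate_cohort()` draws per-lesion metrics from
moment-matched truncated normals at the published group means/SDs (n = 56
native, 24 neoatherosclerotic) and `synthesize_pullback()` inverts the
morphometry pipeline into full annotated pullbacks, so everything is
testable without patient data.

## Worked example

```r
library(plaqrupt)

# a synthetic native-vessel cohort at the published group parameters
co <- simulate_cohort(group_params("PR-NV", n = 56, seed = 7))
pb <- synthesize_pullback(co[1, ], seed = 701)

lesion_record(pb)
#> Lesion [PR-NV-001, PR-NV]: frames 6-82 (30.4 mm), MLA 0.87 mm2 at frame 44
#>   area stenosis 76.1%, RG up 0.028 / down 0.044, 1 rupture site(s)

morphometry(pb)
#> Morphometry [PR-NV-001, PR-NV]: TCFA
#>   FCT min/mean 63/91 um; lipid arc 165.4 deg x 1.6 mm (index 2.4)
#>   1 rupture site(s), depth 2.07 mm, thrombus score 3.6%
```

The first lesion of this cohort happens to be a long, severely stenosed
TCFA: a 30.4 mm lesion with MLA 0.87 mm², a 63 μm minimum cap over a 165°
lipid arc, one ruptured site, and thrombus in 3.6% of lumen quadrants.
Running the whole two-group study:

```r
bundle <- run_full_study(run_config(seed = 7))
bundle
#> Study bundle: 56 native + 24 neoatherosclerotic lesions
#>   flow (quasi1d): tau_max 5.3 vs 7.2 Pa; dp 0.56 vs 0.75 mmHg
#>   superficial PSS: 261.7 (native) vs 112.1 (stented) kPa

subset(bundle$comparison, variable %in% c("mla_mm2", "mean_fct_um", "lipid_index"))
#>       variable      group_a      group_b    test_used p_formatted
#> 2      mla_mm2    3.1 ± 1.9    2.5 ± 1.4 mann_whitney       0.233
#> 9  mean_fct_um 183.6 ± 64.2 227.2 ± 81.7    student_t       0.012
#> 12 lipid_index  14.2 ± 11.9  21.3 ± 13.4 mann_whitney       0.015
```

The stented model sees higher peak shear (7.2 vs 5.3 Pa — its MLA is
smaller) and a larger pressure drop, while its superficial cap stress is
lower (112 vs 262 kPa) because the thicker neointimal cap and the stent
caging both unload the wall — the orderings the physiology analysis is
designed to expose. The comparison table recovers the expected group
contrasts (thicker caps and higher lipid index in the stented group) at
one seeded replicate's power.

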