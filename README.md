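# octbias

Catheter-bias morphometry and dissection-risk analysis for intravascular
OCT pullbacks.

## What it is for

During rotational atherectomy (ROTA) of calcified coronary lesions, an
eccentric guidewire ("guidewire bias") steers the burr toward one wall and
can cause iatrogenic dissection. On a segmented OCT cross-section the bias
is directly measurable. `octbias` is for interventional-imaging analysts
who have contour-level OCT data (intima, optionally media/EEM, catheter
pose) and want to:

1. **measure** per-frame bias indices — with vessel center `O` (lumen
   centroid) and catheter center `C`, the bias ray is `O→C`, and

   * `D_cib`, `D_cio` — distance from `C` to the **i**ntima along the
     **b**ias ray / its **o**pposite;
   * `D_cmb`, `D_cmo` — the same to the **m**edia;
   * touch angle — the arc (at `C`) over which the catheter contacts the
     intima;
   * lumen area, min/max lumen diameter, eccentricity
     `LE = (MaxLD − MinLD)/MaxLD`, EEM area, average vessel diameter;
   * the bias quadrant (bias ray ± 45° about `O`);

2. **coregister** pre-/post-ROTA pullbacks by a fiduciary side branch and
   pair frames on a 1-mm grid;

3. **analyze** which pre-ROTA index discriminates frames that dissect:
   Spearman correlation, empirical ROC with DeLong 95% CI, Youden-optimal
   cutoffs (`J = sens + spec − 1`), a DeLong test of the two best AUCs,
   bias-quadrant/dissection coincidence, catheter-entrapment rate, a
   cluster bootstrap for within-patient clustering, and agreement
   statistics (ICC(2,1), Cohen's kappa) for reader studies.

A synthetic paired-pullback generator (≈ 21 patients / 388 frames / 14%
dissection, with dissection mechanistically driven by `D_cmb < 0.72 mm` or
touch angle `> 98.2°`) makes the entire chain testable without image data.
See `vignettes/octbias-methods.Rmd` for the full model description.

## Worked example

```r
library(octbias)

study  <- generate_study(generator_config(seed = 1))  # synthetic paired study
paired <- pair_study(study)                           # align + 1-mm pairing
an     <- run_analysis(paired, meta = study$meta, B = 2000, seed = 1)
an
```

```
Discrimination analysis over 411 paired frames (63 dissected)
        variable      r       p_r   auc ci_low ci_high sensitivity specificity  cutoff youden       direction   n
           D_cib -0.608  7.28e-43 0.987  0.978   0.996       100.0        95.7   0.486  0.957  lower_positive 411
           D_cio  0.348  3.59e-13 0.779  0.723   0.835        85.7        58.3   1.901  0.440 higher_positive 411
           D_cmb -0.638  6.86e-40 0.998  0.995   1.000        98.2        99.6   0.730  0.978  lower_positive 337
           D_cmo  0.386  2.19e-13 0.801  0.744   0.858        90.9        59.9   2.204  0.508 higher_positive 337
 Final burr size  0.008  8.78e-01 0.506  0.431   0.581        79.4        27.0   1.559  0.064 higher_positive 411
     Touch angle  0.902 6.95e-151 0.989  0.973   1.000        98.4        96.6  43.250  0.950 higher_positive 411
           MinLD -0.026  6.02e-01 0.521  0.446   0.595        77.8        35.9   2.526  0.137  lower_positive 411
           MaxLD  0.062  2.09e-01 0.550  0.471   0.629        38.1        74.1   3.089  0.122 higher_positive 411
DeLong D_cmb vs Touch angle: AUC 0.998 vs 0.988, p = 0.282
Bias-quadrant coincidence: 100% of 63 dissected frames; catheter entrapment: 100%
Cluster bootstrap (D_cmb, B=2000): AUC 0.998 (0.994-1.000)
```

Reading it: the catheter-to-media distance at the bias site (`D_cmb`) and
the touch angle dominate (AUC ≈ 0.99–1.00); the recovered `D_cmb` Youden
cutoff (0.730 mm) sits next to the generator's mechanism threshold
(0.72 mm); every dissection arc overlaps the pre-ROTA bias quadrant and
every dissected frame shows the catheter trapped subintimally — the
construction the generator encodes. `n = 337` for the media-based indices
reflects frames whose media was not segmented (a first-class missing
value). Note the touch-angle cutoff (43.2°) is *not* its mechanism
threshold here: under the default OR-rule most dissections are also
short-`D_cmb` contact frames, so a lower angle already separates; the
threshold is recovered cleanly when the angle term drives dissection alone
(acceptance target t8).

## Command line

```sh
Rscript -e 'octbias::cli_main()' reproduce --seed 1 --out run1
Rscript -e 'octbias::cli_main()' generate  --seed 1 --out data
Rscript -e 'octbias::cli_main()' measure   --out meas.csv data/P01_pre.json
Rscript -e 'octbias::cli_main()' pair      --pre data/P01_pre.json --post data/P01_post.json --out paired.csv
Rscript -e 'octbias::cli_main()' analyze   --paired run1/paired.csv --meta data/patients.csv --json report.json
```

Pullbacks travel as a versioned JSON schema (documented in `R/io.R`);
measurements and reports as CSV.

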