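# perfvec

Quantification of myocardial perfusion SPECT by the **perfusion vector**: the
displacement between the anatomical centroid of the left-ventricular
mid-myocardial surface and its perfusion-weighted center of gravity. The
package is for researchers in nuclear cardiology image analysis who want an
objective, fully automatic scalar/vector summary of perfusion homogeneity to
use alongside visual reading and segmental scores, plus a digital phantom to
study its behavior under controlled defect geometry and noise.

## The statistic

The mid-myocardial surface is a grid of rectangles, each with an index *i*, a
center (*x_i*, *y_i*, *z_i*) in mm, an area *A_i* and an intensity weight
*W_i*. The weighted centroid is

    C = ( Σ x_i A_i W_i / Σ A_i W_i ,
          Σ y_i A_i W_i / Σ A_i W_i ,
          Σ z_i A_i W_i / Σ A_i W_i )

With *W_i* = 1 this is the **anatomical centroid** C_A; with *W_i* set to the
measured tracer intensity at each rectangle it is the **perfusion center of
gravity** C_P. The perfusion vector is

    P = C_P − C_A

Uniform perfusion gives P ≈ 0. A perfusion defect removes weight on one side,
so C_P moves away from the defect and **P points away from the defect**, with
a magnitude growing with defect severity and extent. Stress/rest pairs are
summarized by |P_stress| − |P_rest| (reversible-ischemia contrast) and by
|P_stress − P_rest|.

### Coordinate conventions

All coordinates are cardiac-frame millimetres, right-handed:

```
        +z  apex
         |
         |        short-axis (x-y) plane, seen from the apex:
         |
         o-- +x  lateral            anterior (theta = 270 deg)
        /                                  |
      +y  inferior          septal --------+-------- lateral (theta = 0)
                            (180 deg)      |
                                    inferior (theta = 90 deg)
```

theta is measured from +x (lateral) toward +y (inferior). With these signs an
anterior defect increases p_y and a lateral defect decreases p_x.

## Worked example

Simulate a stress study with a 50-degree anterior defect through the phantom
pipeline (rasterize a 148-mL ventricle, 7 mm FWHM Gaussian blur, Poisson
noise at 500 peak counts), sample intensities along the surface normals, and
compute the vector:

```r
library(perfvec)
study <- simulate_study(defect = defect_spec("anterior", alpha = 50),
                        acq = acquisition_spec(seed = 7L))
w <- sample_weights(study$volume, study$surface)
res <- compute_perfusion_vector(study$surface, weights = w, phase = "stress")
res
#> <perfusion_result:stress>
#>   C_A (-0.000, -0.000, 16.974) mm
#>   C_P (-0.013, 3.429, 17.636) mm
#>   P   (-0.013, 3.429, 0.662) mm, |P| = 3.492 mm
```

The vector points toward +y (inferior), i.e. **away from the anterior
defect**, with |P| ≈ 3.5 mm; a defect-free run of the same pipeline gives
|P| ≈ 0.3 mm. Larger opening angles move p_y further (≈ 0.6, 2.0, 3.4,
4.9 mm for 10, 30, 50, 70 degrees, noiseless) while p_x and p_z stay nearly
constant — the simulated defect-size trend.

Cohort-level analysis mirrors a clinical validation study: a synthetic
40-normal / 80-abnormal cohort, Kruskal-Wallis omnibus per metric, pairwise
Mann-Whitney against the normal group at Bonferroni-corrected thresholds
(0.0125 for four location groups, 0.025 for the ischemia/infarction split),
and Spearman correlation of true defect extent with stress |P|:

```r
cohort <- generate_cohort(cohort_spec(seed = 1))
spearman_correlation(cohort$true_extent_fraction, cohort$stress_mag)
compare_groups(cohort, "diff_mag", reference = "normal", group_col = "condition")
```

## Command line

A thin wrapper over the same functions is installed at
`inst/cli/perfvec` (`Rscript inst/cli/perfvec ...` from a source tree):

```sh
perfvec simulate --defect-location anterior --defect-angle 30 --seed 7 \
        --out-volume study.nii.gz --out-surface surface.csv
perfvec vector --surface surface.csv --phase stress --out result.json
perfvec cohort --n-normal 40 --n-per-group 20 --seed 1 --out cohort.csv
perfvec stats --table cohort.csv --metric stress_mag --reference normal
```

All file coordinates are cardiac-frame mm; volumes are NIfTI-1, surfaces and
cohorts CSV, results JSON. Fixed seeds reproduce outputs exactly.

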