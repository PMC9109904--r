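# cwchord

Raytraced translation between the Chang-Waring chord and angle Alpha.

## The problem

Angle Alpha — the angle between an eye's optical axis and its visual axis —
is a recognised risk factor when centring corneal refractive ablations and
premium (toric, EDOF, multifocal) intraocular lenses, but it cannot be
measured in the clinic: neither axis is observable. What every biometer,
topographer and tomographer *can* report is the **Chang-Waring (CW)
chord**: the 2-D offset between the pupil centre and the first corneal
Purkinje reflex (PI) seen under coaxial illumination while the patient
fixates a far target. `cwchord` is for physiological-optics researchers and
anterior-segment imaging engineers who need the quantitative link between
the two: given routine biometry, it raytraces the CW chord produced by a
known incident angle, and it provides (and refits) a bidirectional linear
translation so that a *measured* chord can be converted into an estimate of
angle Alpha.

## The model

Each eye is two coaxial conic corneal surfaces plus a decentred aperture
stop, in a frame with the origin at the corneal front apex and Z towards
the retina (right eyes are mirrored to left-eye geometry, positive X
temporal). With conic sagitta

    z(r) = c r^2 / (1 + sqrt(1 - (1+Q) c^2 r^2)),   c = 1/R,

surfaces `(Ra, Qa)` at z = 0 and `(Rp, Qp)` at z = CCT, and indices
1.0 / 1.376 / 1.336 (Liou-Brennan), two landmark rays of a fixation beam
tilted by `(I_X, I_Y)` degrees are solved per eye:

* the **Purkinje ray**, which meets the corneal front surface
  perpendicularly (collinear with the surface normal, hence unrefracted
  and back-reflected into the instrument), and
* the **pupil-centre ray**, steered so that its traced transverse
  coordinates reach the exported pupil decentration `(Pup_X, Pup_Y)` at
  the pupil reference plane.

Both are read at the apex plane, rotated by quaternions onto the plane
perpendicular to the beam, and differenced:

    CW_X = PupR_X - PurkinjeR_X,   CW_Y = PupR_Y - PurkinjeR_Y.

A Monte-Carlo over a synthetic biometry population (truncated-normal
marginals of a large Casia2 cohort, correlated corneal radii, truncated
normal incident angles) feeds a stepwise-selected multivariable linear
model

    [CW_XM, CW_YM]' = F [1, Ra, Qa, Rp, CCT, ACD, Pup_X, Pup_Y, I_X, I_Y]'

whose exact algebraic inverse predicts the angle from a measured chord:

    [I_XM, I_YM]' = G [1, Ra, Qa, Rp, CCT, ACD, Pup_X, Pup_Y, CW_X, CW_Y]'.

An entrance-pupil module traces collimated ray bundles, marks the rays
passing the stop, and fits the moment-based constraining ellipse of the
footprint (eigen-decomposition of the second central moments, diameters
`4 sqrt(lambda)`), giving the entrance-pupil magnification and distortion.

## Worked example

```r
library(cwchord)

# cohort-mean left eye, cohort-mean fixation angle
m <- eye_model(mean_eye())
compute_cw_chord(m, incident_angle(-5.03, 0.01))
#> <cw_landmarks>
#>   PupC      (-0.3419, -0.1019) mm    PurkinjeC (-0.6836, +0.0014) mm
#>   PupR      (-0.3406, -0.1019) mm    PurkinjeR (-0.6810, +0.0014) mm
#>   CW chord  (+0.3404, -0.1032) mm
```

The pupil centre appears 0.34 mm nasal of the apex, the Purkinje reflex
0.68 mm nasal, so the chord points 0.34 mm temporally — the familiar
clinical picture of PI sitting nasal to the pupil centre. Translating a
*measured* chord back into an angle with the bundled published matrices:

```r
predict_alpha(mean_eye(), c(0.34, -0.10), cw_translation_2022())
#>           I_XM        I_YM
#> [1,] -5.040443 -0.01820872
```

i.e. a 0.34 mm temporal chord on an average eye corresponds to an angle
Alpha of about 5 degrees. Refitting the model on your own (or synthetic)
data:

```r
eyes   <- synthesize_population(population_spec(2000, seed = 1))
angles <- sample_incident_angles(2000, seed = 2)
res    <- run_monte_carlo(eyes, angles)
fit    <- cw_translation(res)       # print/summary/coef/predict/plot
```

A thin command line (`inst/cli/cwchord.R`) wraps the same functions:
`simulate`, `fit`, `translate --direction cw|alpha`, `ellipse`.

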