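# scintQA

Image-based quality assurance of the **binary multileaf collimator (MLC)**
of a helical tomotherapy unit, using nothing but a cylindrical plastic
scintillator and an ordinary camcorder.

In helical tomotherapy a 6 MV accelerator rotates around the patient while a
bank of 64 binary leaves (0.625 cm each, a 40 cm field) chops the fan beam.
The treatment is encoded in a *sinogram*: a P x 64 matrix whose entry
`f[p, j] ∈ [0, 1]` is the fraction of projection `p` (one of 51 equal
angular segments of a rotation; 294.12 ms at the standard 15 s rotation)
for which leaf `j` is open.  Verifying that the delivered leaf motion
matches this file is hard with film or ion chambers because the pattern is
dynamic and synchronized with the gantry.  The method implemented here
films the light a scintillator cylinder emits during the delivery
(8-bit 640 x 480 grayscale frames at 29.97 fps), reconstructs the sinogram
from the video, and scores it against the plan.  It is aimed at medical
physicists who want a cheap, simulation-backed delivery-QA workflow, and at
anyone studying the photometry pipeline itself.

## The measurement model

For ROI `j` (a 5 x 5 pixel box at the centre of leaf `j`'s strip; only
leaves 18-47 fit on the 20 cm scintillator) in frame `i`:

```
q[j,i]  = qraw[j,i] - BG                    # background-subtracted light
Q[j]    = sum_i q[j,i]                      # accumulated light
qc[j,i] = q[j,i] * k1[j] * k2[i]            # lateral + drift corrections
```

`BG` is the dark level (0.36 pv measured over 9000 beam-off frames),
`k1[j]` the inverse single-leaf lateral profile normalized at leaf 32, and
`k2[i]` the inverse windowed beam-output drift normalized at 100 s.
During a rotating delivery each frame is first rotated back to the gantry
0-degree frame by its recorded angle.  Corrected light is accumulated per
projection, a threshold `Th` decides open vs. closed (`qc > Th` is open),
and open bins are converted to leaf open times through the measured linear
relation between `Q` and open time, giving the reconstructed sinogram.
`Th` is chosen by maximizing the Youden index
`J = sensitivity + specificity - 1` over an ROC sweep; agreement is
reported as sensitivity/specificity of the open/closed calls plus the
*leaf open error*, the mean +/- SD of the per-bin relative errors
normalized by each projection's maximum planned fraction.

Because no recorded video of the original measurements exists, the package
ships a forward simulator calibrated to the printed light anchors: one open
leaf yields 29.1 pv/frame at its own ROI (0.48 of the 10 cm field), a
28-leaf field 65.1 pv/frame at the centre, and the field-edge ROIs see
5.6 to 33.7 pv/frame as the aperture grows from 1 to 24 leaves — a
two-sided exponential scatter kernel over leaf offsets reproduces these as
closely as a monotone kernel can.  Pixel noise, 8-bit quantization,
beam-output drift, the lateral profile, attenuation along the beam path and
sporadic transient artifacts (0.2 % of frames) are all modelled.

## Worked example

Simulate a modulated 60-projection delivery, calibrate, and verify it:

```r
library(scintQA)
g   <- tomoGeometry()
m   <- calibrateOpticalModel()       # fit gain + scatter to the light anchors
cal <- simulateCalibrationSession(m, g, seed = 1, driftDuration = 120)

plan  <- clinicalPattern(g, nProjections = 60, seed = 1)   # modulation 1.649
stack <- simulateDelivery(plan, m, g, seed = 2)            # 529 video frames
rec   <- extractLight(stack, bg = m@backgroundMean, backRotate = TRUE)
corr  <- applyCorrections(rec, cal, nProjections = nProjections(plan))

th     <- youdenThreshold(rocAnalysis(corr, plan))         # 18 pv here
recon  <- reconstructSinogram(corr, cal, th, g)
verificationReport(plan, recon, threshold = th)
```

```
VerificationReport
  threshold        : 18 pv
  sensitivity      : 0.937
  specificity      : 0.966
  Youden index     : 0.904
  leaf open error  : -0.0 +/- 15.1 %
  within +/-3%     : 40.9 %
```

Reading the scorecard: 93.7 % of truly open leaf-projection bins were
detected open and 96.6 % of closed bins closed at the Youden-optimal
threshold.  The misses are almost entirely the small openings this plan's
heavy modulation produces (down to the ~20 ms clinical minimum, whose
light sits below the scatter glow of wide neighbouring fields) — the
field-size dependence of the detected light is the method's dominant error
source, and a single global threshold cannot remove it.  A scatter-free,
noise-free simulation round-trips any plan to within 2 % with
sensitivity = specificity = 1 (see the test suite).

The same pipeline is scriptable from a shell via
`inst/scripts/tomomlc.R` with subcommands `simulate`, `calibrate`,
`verify` and `gantry-check`, YAML configs, and exit code 2 when a
verification floor is violated.

A rotational-stability check is included: `simulateRotation()` films a
single open central leaf while the gantry turns, `trackBeamEdge()` follows
the beam-edge angle on a ring around the isocenter, and `fitRotation()`
compares the fitted angular speed with the nominal 360/period line
(24 deg/s at 15 s/rev is recovered to <0.01 % with residuals below 0.2
degrees; a +/-5 % injected speed wobble is flagged).

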