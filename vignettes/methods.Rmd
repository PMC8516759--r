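---
title: "Methods: keypoint-driven face AOIs, gaze timelines and agreement scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: keypoint-driven face AOIs, gaze timelines and agreement scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faceAOI)
```

## The problem

Wearable eye-tracking glasses record a scene video together with the
wearer's gaze point in scene-camera pixel coordinates. To quantify how
long the wearer looks at the faces of the people they interact with,
each 40-ms video frame (the 25 Hz annotation grain) must be labelled:
*is the gaze on a face?* and, when several people are present, *on whose
face?* Doing this by hand is slow and subjective; `faceAOI` automates it
given two inputs that any modern pose/appearance stack produces:

1. per-frame head keypoints — pixel positions and confidences for the
   nose, both eyes and both ears of every detected person; and
2. per-detection appearance embeddings — fixed-length descriptors
   (conventionally 128-dimensional) that cluster by identity.

Everything downstream of those inputs — AOI construction, hit testing,
re-identification, agreement scoring — is implemented here. Running a
pose detector or embedding network is deliberately out of scope.

## From keypoints to a face AOI

A landmark counts as **visible** when its detector confidence reaches
`conf_threshold` (default 0.1; pose detectors emit near-zero confidence
for landmarks they did not find). Visibility drives a three-way
orientation rule:

* 5 visible landmarks → **frontal** face,
* 2–4 visible → **profile** face (head turning hides the far ear/eye),
* ≤ 1 visible → **undetected**: no AOI is produced for that person.

The five landmarks cover only the middle of a face, so the AOI is an
inflated box: with $w$ the largest Euclidean distance between any two
visible landmarks,

$$\text{width} = w\, m_o, \qquad \text{height} = w\, a_o\, m_o,$$

where $a_o$ (aspect ratio, height/width) and $m_o$ (margin scale) depend
on the orientation $o \in \{\text{frontal}, \text{profile}\}$. A profile
face exposes a narrower landmark span for the same physical head, which
is why the two orientations carry separate parameters. The box is
centered on the midpoint of the bounding box of the visible landmarks,
optionally shifted vertically by `offset_frontal` / `offset_profile`
(signed fractions of the height; positive is down-screen, since image
coordinates grow downward).

Two centering candidates were considered: the landmark centroid and the
bounding-box midpoint. Midpoint centering was chosen because it makes a
useful guarantee hold by construction: whenever $m_o \ge 1$, $a_o \ge 1$
and the offset is zero, the AOI contains every visible landmark (each
coordinate extent of the landmarks is at most $w$, and the box spans at
least $w$ in both directions around the midpoint). Centroid centering
breaks that guarantee as soon as the visible landmarks are unevenly
spread. The test suite asserts the containment property directly.

The AOI `shape` is either the rectangle itself or the axis-aligned
ellipse inscribed in it (same center, width and height; area $\pi/4$ of
the rectangle). AOIs are axis-aligned — the keypoint rule gives no
rotational information worth estimating.

**Defaults.** `aspect_frontal = 1.4`, `aspect_profile = 1.2`, both
margins 1.2, offsets 0. These are documented placeholders of plausible
magnitude (a face is taller than the eye–ear span is wide, and a modest
margin absorbs hair and chin). In a real deployment they should be
calibrated against a sample of manual annotations for the specific
camera and recording geometry; every function takes them explicitly, and
all package tests parameterise them rather than relying on the defaults.

## From gaze samples to a 25 Hz timeline

Gaze is consumed raw — screen coordinates per timestamp, no fixation or
attention filtering. Frame $f$ owns the half-open window
$[40f, 40(f{+}1))$ ms; among the valid samples in the window, the one
nearest the midpoint $40f + 20$ ms represents the frame, with exact ties
broken toward the earlier sample so the choice is deterministic at any
sampling rate.

Hit testing is boundary-inclusive (rectangle: $|x-c_x| \le w/2$ and
$|y-c_y| \le h/2$; oval: $\left(\frac{x-c_x}{w/2}\right)^2 +
\left(\frac{y-c_y}{h/2}\right)^2 \le 1$): manual annotators draw face
areas with a little slack, so an edge hit counts. The single-class
timeline labels a frame 1 iff the frame's gaze point hits at least one
AOI. The multiple-class timeline labels the frame with the identity of
the hit AOI; when the point falls inside several overlapping AOIs the
one with the nearest center wins — a rule that is stable under margin
changes, unlike smallest-area. Frames with no valid gaze sample get
label 0 (the spreadsheet convention has no third state); the number of
gaze-missing frames is carried as an attribute so missingness remains
reportable.

Face-gaze duration is simply `0.04 s × (non-zero frames)`, per identity
when requested, so identity durations plus the no-face duration always
reconstruct the video duration exactly.

## Re-identification

Identity assignment is Euclidean nearest neighbour against a labelled
gallery, over individual entries (per-entry minimum, not a per-identity
centroid): one labelled occurrence of a person suffices, and extra
entries — say, after a wardrobe change — can only shrink the minimal
distance for any query (monotone improvement, asserted as a property
test). Exact distance ties resolve to the lexicographically smallest
label, then the earliest entry, making assignment independent of gallery
insertion order. A rejection threshold `max_distance` exists for
robustness but defaults to unlimited, matching the workflow in which
every detection receives an identity.

## Agreement scoring

Two timelines of equal length are compared with:

* **Cohen's kappa** $\kappa = (p_o - p_e)/(1 - p_e)$, with $p_o$ the
  observed frame-wise agreement and $p_e$ the chance agreement from the
  marginal label frequencies — plain unweighted kappa over the full
  label set including 0, for both binary and multi-label timelines. The
  degenerate case $p_e = 1$ (both raters constant and identical) returns
  1 with a warning, since the raters do agree everywhere.
* **Frame-by-frame accuracy**, the percentage of matching frames.
* **Duration difference** $\Delta$ and the **normalized absolute
  difference** $|\Delta|$ / video duration (percent). Two conventions
  are provided: `net` (default) differences the two face-gaze totals, so
  over- and under-identification on different frames cancel; `framewise`
  sums mismatched frames at 0.04 s each, so they do not. The net
  convention is the default because it is the one under which the
  package's bundled reference tables (`reference_agreement()`) are
  internally consistent — every published normalized difference equals
  the net $|\Delta|$ over the video duration to the printed two
  decimals, which the acceptance tests recompute.
* **Confusion matrices** over identity labels (manual rows × algorithm
  columns), with Re-ID accuracy as the diagonal percentage. Collapsing a
  multi-class matrix to 0 vs non-zero reproduces the binary agreement
  counts exactly; this oracle equivalence is asserted over random
  simulated scenes.

## The synthetic scene generator

`simulate_scene()` emulates the recording situation the pipeline is
meant for: a head-worn scene camera (default 1920 × 1080) watching one
to a few interactors for a default 60 s — the one-minute-per-video grain
at which such pipelines are typically validated — at 25 Hz.

* **Heads** follow reflected Gaussian random walks (`motion_step_sd`,
  default 3 px/frame — smooth conversational head motion). Landmarks sit
  at fixed anatomical offsets scaled by `head_scale` (default 120 px
  ear-to-ear, a conversational-distance head).
* **Pose**: each frame is frontal with all five landmarks, or (with
  `profile_prob`, default 0.2) a profile in which the far ear is hidden
  and each eye independently drops out with `dropout_prob` (default
  0.1). The nose and near ear always remain, so a generated head is
  always detectable (2–4 visible landmarks); detector misses are outside
  what this generator emulates.
* **Embeddings** are drawn from identity-specific Gaussian clusters:
  orthogonal centroids scaled by `embedding_centroid_separation`
  (default 10) with per-component noise `embedding_noise_sd` (default 1,
  i.e. clusters well separated relative to their spread, as a
  well-trained embedding network produces). The gallery holds each
  identity's centroid.
* **Gaze**: with `gaze_on_face_prob` (default 0.5, alternating
  dwell-on/dwell-off behaviour) the frame's gaze targets a uniformly
  chosen face, placed strictly inside that face's AOI with a 2-px
  buffer; otherwise strictly outside all AOIs with the same buffer. The
  buffer exists so that boundary-inclusion conventions can never flip a
  ground-truth label. Recorded samples add `gaze_jitter_sd` of Gaussian
  noise on top of the intended point, while ground truth keeps the
  intended label — jitter therefore degrades recovered agreement, which
  is the knob the degradation tests turn.

Ground-truth timelines come from the generative draws, never from
running the annotation pipeline, so recovery checks are genuine round
trips. Each identity's walk is confined to a horizontal band wide enough
for the largest possible AOI, making AOIs of different people disjoint
by construction; together with the gaze buffer this is what makes
noiseless recovery exact (κ = 1, Re-ID accuracy 100 %), the suite's
central oracle-equivalence test. All randomness derives from one master
seed through per-stage substreams, so e.g. adding gaze jitter cannot
shift the head trajectories, and replicates across a noise grid share
their other draws (common random numbers), which is what makes the
degradation-monotonicity tests sharp.

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: pose-detector localisation error
and false/missed detections, embedding drift within an identity,
motion-blur-correlated dropout, overlapping faces (the nearest-center
overlap rule is exercised by constructed unit cases instead), and
eye-tracker latency or drift. Results on real recordings depend on
calibrating the AOI parameters; the synthetic suite validates the
machinery, not any particular parameter set.

## Numerical choices and degenerate inputs

* Durations convert to frames by `round(duration × 25)`; frame windows
  are half-open so every sample belongs to exactly one frame.
* Gaze-to-frame ties break toward the earlier sample; Re-ID distance
  ties break lexicographically; overlap hits break by nearest center.
  Every tie rule is deterministic and tested.
* Undetected heads yield no AOI (`NULL`/dropped row), never an error;
  fewer than two visible landmarks make `head_width()` error only when
  called directly.
* Timelines of length zero, mismatched lengths, empty galleries and
  dimensionality mismatches raise typed errors (`faceaoi_input_error`,
  `faceaoi_format_error`, `faceaoi_config_error`) that the CLI maps to
  exit codes 2 and 3.
* File writers emit full-precision (`%.17g`) numbers so write → read
  round-trips are lossless; timeline CSVs round-trip bit-exactly.

## Problem sizes in the test suite

The suite validates oracle equivalence on 100 random 100-frame scenes,
exact recovery on a 10,000-frame (400 s) scene, and degradation
monotonicity on 4-point jitter and noise grids with 20 replicates of
200-frame scenes each — sizes at which every property under test is
already fully exercised (each scene contains hundreds of
frontal/profile switches, dropouts and dwell transitions) while the
whole suite stays fast enough to run on every change.

## Known limitations

* The frontal/profile dichotomy is visibility-based only; a
  three-quarter view with five visible landmarks is treated as frontal.
* AOIs are axis-aligned; head tilt is absorbed by the margin rather
  than modelled.
* Whether a profile AOI should also shift horizontally toward the
  visible ear is not established; the package exposes only a vertical
  offset per orientation and keeps the horizontal center at the
  landmark-box midpoint.
* Agreement statistics treat frames as exchangeable; no time-series
  correction (runs, autocorrelation) is applied, matching standard
  practice for this validation design.
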