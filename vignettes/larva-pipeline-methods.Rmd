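---
title: "Methods: from tracker contours to screen hits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from tracker contours to screen hits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(etholarva)
```

`etholarva` quantifies how *Drosophila* larvae respond to a mechanosensory
air-puff. The input is the raw output of multi-worm-tracker style software:
for each animal a time series of a closed body contour (variable length,
about 114 points) and an 11-point midline skeleton (the *spine*), sampled
at irregular intervals averaging 82 ms. The output is, per animal, an
*ethogram* — a timeline of mutually exclusive discrete actions (Crawl,
Bend, Stop, Hunch, Back-up, Roll, Small motion) — and, per genotype,
population statistics and screen-scale hit calls. This vignette documents
the models, the conventions behind every tunable constant, and the places
where the design was genuinely open.

## Geometry and kinematics

All positions are in mm and times in seconds; ingestion applies a
`pixel_scale` when the tracker reports pixels. The oriented convention is
tail = spine point 1, head = spine point 11.

Frame-wise geometry follows a small set of robust descriptors: the true
length `l` (sum of the ten segment norms) and modified length
`l_M` (sum of squared norms, bounded by `l^2/10 <= l_M <= l^2`); the
shape order parameter

\[ S = \tfrac12\,(3\langle\cos^2\theta\rangle_s - 1), \]

where \(\theta\) is the angle of each spine segment to the body direction
(lower neck to spine midpoint) — a nematic order parameter equal to 1 for
a straight animal and \(-0.5\) when every segment lies perpendicular to
the axis; and the contour eigen-shape factor
\(\lambda = (\lambda_1-\lambda_2)/(\lambda_1+\lambda_2)\) of the contour
coordinate covariance, 0 for a circle and 1 for a degenerate line.

Kinematic channels are built from convolution kernels with one documented
semantics: "Gaussian averaging over *n* points" means a truncated,
renormalized Gaussian of support about *n* samples with \(\sigma = n/4\)
samples; the derivative-of-Gaussian kernel shares \(\sigma\) and is
normalized to unit response on a unit-slope ramp, so dividing by the frame
interval yields derivatives per second. Irregular frame times are handled
by resampling each track onto a uniform grid at its median dt
(`validate_timebase()`), computing all kernels there, and mapping back to
the original frames by nearest grid time. Edges are padded by reflection;
within half a kernel width of a track end the derivative channels are
attenuated, which the tests account for by asserting steady-state values
on interior frames.

Two conventions deserve a note:

* the agitation velocity is implemented as
  \(v_a = (v_c^2+v_{nu}^2+v_{nd}^2)/(3\alpha_v)\) with \(\alpha_v = 10\);
  the symmetric neck-up/neck-down form treats the duplicated neck-up term
  in the usual way of a typographic slip, and `strict_va = TRUE` restores
  the literal form;
* `axis_direction_25_10`, the feature gating back-up detection at the
  \(-0.8\) threshold, is the direction-alignment family member
  \(\beta_{25,10}\): the dot product of the Gaussian-averaged tail to
  neck-down unit vector (25 frames) with the averaged motion unit vector
  (10 frames). It is the only printed "direction of motion" family with
  two window parameters, and \(-0.8\) corresponds to strong
  anti-alignment of body axis and displacement.

Contour regularization projects \(z(s) = x(s) + i y(s)\) on a truncated
Fourier basis (order 7) and evaluates the signed curvature of the
recomposed curve. For head-tail evidence the curvature sign is normalized
by the traversal winding so that the contrast
\(\delta\kappa = \tanh(\kappa(\mathrm{tip}_1)-\kappa(\mathrm{tip}_2))\)
depends on the shape of the two ends, not on the tracker's polygon
orientation.

## Head-tail disambiguation

At screen magnification the two spine endpoints are interchangeable and
identity must come from dynamics. The decoder is a two-orientation-state
hidden Markov model (head = first vs head = last stored point) with stay
probability 0.9 per step and emission weights \(\exp(-\beta E)\),
\(\beta = 0.01\), where the per-frame energy combines five weighted
evidence channels (\(\alpha = (1, 0.2, 1, 0.5, 0.5)\)): the endpoint
curvature contrast; a direction-alignment term; a step-level
displacement-consistency term that penalizes endpoint assignments
implying teleportation across a frame pair; an endpoint agitation
asymmetry (the head casts more than the tail); and an oriented velocity
term. Each decoded step induces one of the four printed transition states
(T1: head 1→1, T2: 1→11, T3: 11→11, T4: 11→1); the block-diagonal 4×4
transition matrix printed for those states permits chains such as T2→T1
whose arrival and departure orientations disagree, so the
orientation-consistent two-state chain is the default and
`viterbi_orient_4state()` ships as the strict-literal comparison mode.
Three realizations were genuinely open and are fixed as follows:

* the orientation indicator enters each energy term as ±1 per frame
  (the only role consistent with the two-frame structure of the terms);
* the displacement term is the body-length-normalized movement of the
  inferred head and tail endpoints across each step, for the flip and
  no-flip assignments;
* the velocity evidence is the centre velocity projected on the stored
  first-to-last body axis (signed axial speed). An unsigned speed
  multiplied by ±1 is a constant bias toward one label and carries no
  orientation information; `strict_ev = TRUE` restores the literal form.
* the direction evidence uses a symmetrized 10/10 alignment (mean of the
  tail-to-neck-down and negated head-to-neck-up alignments), which is
  exactly antisymmetric under a stored endpoint-order flip; the raw
  \(\beta_{10,10}\) is not, because the two body ends are geometrically
  inequivalent.

With the printed inverse temperature the emission energies are of order
\(10^{-2}\) per frame while a decoded flip costs
\(2\log(0.9/0.1)\approx 4.4\), so the decoder needs on the order of a
hundred consistent frames to accept a flip. It therefore tracks the rare
orientation errors of a real tracker very well (the synthetic default is
one storage flip per ~80 s of tracking) and degrades gracefully, by
design of the printed parameters, when storage flips are made
artificially frequent; the test suite documents both regimes. Ties
resolve to no-flip, then head = first.

## The five-layer action classifier

Layer 1 trains one binary random-forest detector per action plus a
postural classifier (Ball, Curl, Bend, StraightLightBend, Straight;
rule-labeled from `S` and the folded head-tail distance). Back-up is
rule-defined: posture straight or lightly bent, displacement status true,
and `axis_direction_25_10` below \(-0.8\). Displacement status — named
but never quantified upstream — is true when the 5-frame
derivative-of-Gaussian centre speed exceeds 0.1 body lengths/s. Layer 2
resolves co-detections by the printed cascade (conflicts with Stop, then
Roll, Back-up, Bend, Crawl become no-action). Layers 3/4 are a single
multiclass forest over the frame features, the one-hot layer-2 state and
the 5-frame-smoothed layer-1 probabilities; every frame receives a
definite label. Singular events are corrected exactly as printed
(`i j i` → `i i i`, `i j k` → `i k k` for one-frame interlopers), events
are segmented as maximal constant-state runs with amplitude summaries,
detected hunches are re-examined by an event-level forest on length
statistics (head retraction vs other quick motions), Stops and Back-ups
shorter than 2 frames merge into the longer temporal neighbor (ties to
the preceding one), and layer 5 relabels each event by the agreement of a
random forest and an SVM on 14 duration-aggregated features, resolving
disagreements by the higher calibrated probability. The same 14 features
feed the detection-quality heuristic (`quality_heuristic()`), which
cross-validates kNN and forest predictions of the pipeline's own labels.

The exact per-layer feature subsets are this package's choice (the
original inventory lives only in an external repository): a compact set
of shape (S, lambda, angles, normalized head-tail distance), length
dynamics (dl/dt, its square and 10-frame average), speed (per body
length), agitation, direction alignment (several \(\beta\) windows) and
rotation-energy channels.

## The synthetic population

The generator is the package's study-condition model, not a rendering
tool. Frame times follow a truncated normal (mean 0.082 s, sd 0.013 s,
floor 0.028 s). Action sequences are semi-Markov: exponential dwell times
(crawl runs average 10 s, bends about 1 s, matching free locomotion) and
jump transitions from a 7×7 zero-diagonal row-stochastic matrix. The
default pre-stimulus jump matrix was solved once so that its jump-chain
stationary distribution reproduces the baseline event proportions of
unstimulated animals (about half of events crawling, a third bending, the
rest stops, rare hunches and back-ups); the resulting time occupancy is
strongly crawl-dominant, which is what the locomotor-defect filter
expects of a healthy line. At the 45 s air-puff onset the ongoing action
is interrupted and the first response is drawn from a configurable
distribution (default: hunch- and bend-dominated, the canonical response
mix); subsequent transitions use the post-stimulus matrix. Kinematics per
action: crawl displaces the centre of mass along the tail-to-head axis
with peristaltic length oscillation (8% amplitude, 1 s period); back-up
reverses the displacement; hunch shortens the body by a configured 30%
(beyond peristaltic amplitude) and recovers; bend deviates the head axis
by 1.6 rad with a casting profile; stop freezes the midline; small
motions replay bend/hunch at a 0.25 amplitude scale, a deliberately
sub-threshold class (no quantitative upstream definition exists). The
contour offsets the midline with a tapered width profile whose head end
is sharper than the tail end; the point count is drawn per track from
Normal(114, 23), floored at 40. Tracker noise is 5 µm per spine point,
and endpoint-order corruption is a two-state Markov process with
stay-probability 0.999 by default (orientation errors in real trackers
are rare discrete events, roughly one per minute).

What the generator does not emulate — rolling kinematics, collisions,
segmentation artifacts, optical blur, the amplitude heterogeneity of real
populations — bounds what green tests mean: they certify the pipeline's
internal correctness and its recovery of known structure, not
field performance on real plates.

## Statistics and the screen

Ethogram statistics follow the printed definitions: behavior
probabilities over 0.2 s windows among active larvae (active = tracked at
the window midpoint); dominant/second-dominant behaviors with ties broken
in the fixed order Crawl, Bend, Stop, Hunch, Backup, Roll, Small;
fraction-of-time and at-least-once window statistics over 1/5/15 s after
stimulus onset and offset; transition matrices as row-normalized counts
of event adjacencies whose switch instant falls in the window (default
first 3 s post-onset), zero diagonal by construction; first-response
sequences capped at four actions with a 0.5 s perception-uncertainty rule
(the pre-onset action counts as the response only if it persists at least
that long past onset); hunch amplitudes \(\delta(l)=(l_{max}-l_{min})/l_{max}\)
and \(r(l)=l_{min}/l_{max}\); bend amplitude as the mean minimal S; and
angle-to-wind CDFs (wind at \(3\pi/2\)) compared across first-action
groups by two-sample Kolmogorov-Smirnov tests.

Hit detection compares each line to the control by generalized
likelihood-ratio tests: per behavior a binomial GLR with pooled
proportion (\(\chi^2\), df 1; direction from the sign of the proportion
difference), and a multinomial GLR over the full 7-behavior distribution
(df 6; zero-count categories drop via \(0\log 0 = 0\)). A line is counted
into behavior *k* by its first response within the 1 s post-onset window
(an any-occurrence mode is provided). Lines whose pre-stimulus population
is not crawl-dominant with bend second-dominant in strictly more than 97%
of windows over [0, 44.75 s) are excluded as locomotor-defective before
any testing. The competitive-interaction call requires the multinomial
test significant at 0.05 plus two called behaviors (Hunch, Bend, Back-up)
moving in opposite directions with p-values below 0.01 and 0.1.

A calibration fact worth knowing when interpreting screen output: these
are uncorrected planned comparisons, so across several hundred tested
lines the joint competitive condition still admits occasional false
competitive calls (and, conversely, the df-6 multinomial gate can
withhold a genuine moderate two-behavior shift), which the package's
screen-level tests quantify under known synthetic truth. The Bonferroni
helper (`bonferroni()`, threshold \(\alpha/m\)) is available when a
conservative hit list is preferred.

## Numerical choices and problem sizes

Degenerate cases are handled explicitly: zero-length body direction makes
S missing for the frame; motion unit vectors are zero below 1 nm/s so
stationary frames contribute no direction evidence; log-derivative
channels use a \(10^{-9}\) floor; \(0\log 0 = 0\) throughout the GLR
algebra; segment angles use the atan2 form, stable where acos is not.
Event frame indices are 0-based half-open intervals; all window logic is
half-open. Cleaning removes the first 5 and last 10 frames once
(idempotent by construction) and then rejects tracks shorter than 5 s,
displacing less than one body length net, retaining fewer than 250
frames, or whose centre-of-mass trajectory hull is under 1 mm².

The test suite exercises the classifier on a 200-train / 100-test larva
corpus of 60 s tracks (the stimulus at 45 s provides both baseline and
response regimes in every track), the orientation decoder on 165 s tracks
(about 2000 frames), occupancy and transition fidelity on \(10^4\)
events/transitions, GLR calibration on \(10^4\) null replicates, and the
screen on twenty 50-line × 300-larva replicates simulated at ethogram
level — the hit statistics consume only labels, so geometric synthesis
there would add runtime without information.

## Known limitations

The trained forests are this package's own (the original training corpus
of human-tagged larvae is not distributable), so per-action operating
points differ from any particular historical run. Roll is a legal label
that the generator never produces and the classifier therefore never
learns. The Small class is defined only through the generator's
sub-threshold amplitudes. The strict four-state orientation mode cannot
chain a head flip (its printed block-diagonal transition matrix forbids
the consistent T2→T3 succession) and exists for comparison, not use.
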