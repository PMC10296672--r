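---
title: "Simulated microwave colonoscopy: forward model, imaging and polyp detection"
author: "mwcolon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated microwave colonoscopy: forward model, imaging and polyp detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwcolon)
```

## The measurement principle

Colorectal lesions differ from healthy mucosa in their dielectric
properties: relative permittivity $\varepsilon_r$ and conductivity
$\sigma$, combined at working frequency $f$ into the complex relative
permittivity

$$\varepsilon^*(\omega) = \varepsilon_r - j\,\frac{\sigma}{\omega
\varepsilon_0}, \qquad \omega = 2\pi f .$$

The package uses the $e^{+j\omega t}$ time convention throughout, so
conductive loss appears as a negative imaginary part and the background
wavenumber $k = (2\pi f/c)\sqrt{\varepsilon^*}$ lies on the branch with
$\mathrm{Im}(k) \le 0$ (outgoing waves decay). A single shared convention is
deliberate: mixed conventions are the classic source of sign errors in
Green's-function codes.

The simulated instrument is a ring-shaped colonoscope accessory: eight
transmitting and eight receiving antennas on a 10 mm-radius ring, operating
at 7.5 GHz. For each transmitter, the field is recorded at the adjacent
receiver and the two closest diagonal receivers, giving $8 \times 3 = 24$
complex channels per cross-sectional *frame*. As the scope is withdrawn,
frames sweep the lumen longitudinally; the frame index is the longitudinal
coordinate (no pull-back speed is modelled, because none is published — a
frame *is* the longitudinal unit here).

What the channels carry is the contrast between an inclusion and the
background,

$$\chi = \frac{\varepsilon^*_{\mathrm{inc}} -
\varepsilon^*_{\mathrm{bg}}}{\varepsilon^*_{\mathrm{bg}}},$$

which is zero exactly when the tissue is homogeneous and invariant under a
common rescaling of both permittivities.

### Tissue table

The default tissue values are **configurable placeholders**, not measured
porcine or human values (none are published with the study design this
package replicates): mucosa $\varepsilon_r = 50$, $\sigma = 6$ S/m;
adenoma $60$, $8$ S/m; stool $40$, $4$ S/m. They are plausible
high-water-content values whose lesion/background contrast magnitude
($|\chi| \approx 0.21$) is comfortably imageable. Override them in the
pipeline configuration (`tissues.<name>.eps_r`, `tissues.<name>.sigma`).

## Forward model

Each frame is treated as an independent 2D cross-section in a homogeneous
lossy background (the mucosa class); the 30 mm axial extent of the physical
device is ignored because the axial arrangement is unpublished and the
frame is defined as a cross-sectional slice. Propagation uses the 2D
outgoing-wave Green's function

$$G(r) = -\tfrac{j}{4}\,H_0^{(2)}(kr),$$

with $H_0^{(2)}$ evaluated for complex argument by an in-package kernel
(power series below $|z| = 16$, Hankel's asymptotic expansion above; the
two branches agree to $\sim 10^{-9}$ at the seam).

Scattering is Born-linearised: an inclusion is a point scatterer of
strength $a\chi$ at its cross-sectional position, and the measured channel
is

$$d_{(t,r)} = \underbrace{G(|\mathbf{x}_t - \mathbf{x}_r|)}_{\text{direct
coupling baseline}} + \sum_{s} a_s \chi_s\, G(\mathbf{x}_t,
\mathbf{x}_s)\,G(\mathbf{x}_s, \mathbf{x}_r) + n,$$

with $n$ circular complex Gaussian noise of standard deviation
`noise_rel` $\times$ the median baseline magnitude (default $10^{-3}$).
Single scattering keeps the model analytically checkable: linearity in the
scatterer set, rotation equivariance of the 24-channel vector under
$45^\circ$ scene rotations, and monotonicity in $|\chi|$ are all exact
properties that the test suite asserts.

Two geometric choices deserve a note:

* **Receive ring offset.** The transmit and receive rings are co-indexed
  but the receive ring is rotated half an antenna pitch ($22.5^\circ$), so
  "the receiver adjacent to transmitter $i$" (receiver $i$) sits between
  transmitters $i$ and $i+1$, and receivers $i \pm 1$ are its diagonals.
  This is the minimal symmetric reading of the published switching rule,
  and it keeps every transmitter--receiver pair at a finite separation so
  the direct-coupling baseline is well defined.
* **Point scatterers.** Extended polyps are represented by the amplitude
  scale $a$ rather than by meshed regions. The Born sum only needs
  $a\chi$ at a location, and point targets keep an analytic oracle for
  every downstream test. The default $a = 1$ produces a maximum
  per-channel relative deviation of about $10^{-2}$ — an order of
  magnitude above the default noise floor and more than an order of
  magnitude below the contact-detection threshold, so lesions are clearly
  imageable yet never mistaken for antenna mismatch.

## Scenes, contacts and ground truth

A `scene_timeline` holds the pull-back: polyp and stool inclusions (each a
point scatterer persisting over a run of frames) and wall-contact events.
Defaults encode the one discriminant the replicated study states — polyps
are *wide* bright runs (15–40 frames), stool remnants *short* ones (2–6
frames).

Contact events model antenna mismatch: while the accessory touches the
wall or stool, all schedule channels involving one or two touched antennas
are multiplied by a severity factor (default 10) with a random phase.
`random_timeline` marks frames for contact independently with probability
`contact_fraction`, then merges marked runs into events, so the realised
contact fraction fluctuates binomially around the request — exactly the
statistics the discard-rate recovery experiment assumes.

`ground_truth` labels every frame with priority
`contact > cluster > polyp > stool > healthy`: contact frames are unusable
whatever they contain, and frames covered by two or more polyps are
`cluster` (excluded from scoring — in the replicated study densely
clustered polyp stretches were excluded from annotation, and no
declustering algorithm is claimed here). Intervals are 0-based and
half-open everywhere, including on disk.

`replica_sequence_timeline` pins the study's valid sequence: 600 frames, three
isolated polyps separated by four healthy stretches (each at least 60
frames, so the leading calibration window is always clean), no contacts.
Seeds move positions and extents, never the segment composition.

## Imaging

The instrument's own reconstruction algorithm is proprietary; the package
uses the standard real-time-capable stand-in, the **adjoint** (matched
filter / backprojection) of the Born operator:

$$I(p) = \Bigl|\sum_{(t,r)} \overline{G(\mathbf{x}_t, p)\,G(p,
\mathbf{x}_r)}\; \bigl(d_{(t,r)} - \hat b_{(t,r)}\bigr)\Bigr|,$$

where $\hat b$ is the per-channel baseline estimated as the component-wise
median over the first `calib_frames` (default 50) frames — assumed healthy,
an operator responsibility. The simulator's exact baseline is never handed
to the imaging chain. No regularised inversion is attempted; the images
are a qualitative contrast-magnitude map, which is all the detection
logic needs (homogeneous $\to$ dark, lesion $\to$ bright).

Pixels live on a polar annulus: 20 radial bins over $(10.5, 25]$ mm and
64 angular bins. Two numerical choices matter:

* **The annulus, not the disc.** The region $r <$ ring radius is inside
  the accessory itself — tissue cannot be there — and, with an
  unnormalised adjoint in a lossy background, interior pixels host a
  mirror lobe of the point-spread function that can out-shine the true
  lobe and drag the angular argmax several bins off when a lesion aligns
  with an antenna. Starting the grid 0.5 mm outside the ring (the device
  shell) removes the artefact: measured over 96 scatterer angles, the
  angular argmax error drops from up to 3.5 bins (full disc) to at most
  0.5 bins (annulus).
* **No radial localisation is claimed.** At a single frequency the
  two-way weight magnitude decays monotonically from the ring, so the
  radial argmax of the adjoint image sits at the innermost shell
  regardless of the scatterer radius. The package therefore aggregates
  over radius — `aggregate_frame` takes the maximum over $r$ per angular
  bin (a peak statistic, because lesion evidence is a localised bright
  spot), and the per-frame scalar is the maximum of that profile.
  Angular position and frame extent, not radius, carry the detection
  information.

`build_contrast_map` stacks the angular profiles over frames into the
longitudinal B-scan on which detection operates; with `n_theta` divisible
by 8, a $45^\circ$ scene rotation shifts the profile by exactly
`n_theta`/8 bins, a symmetry the tests exploit.

## Frame validity

Contact corrupts specific antennas far beyond anything a lesion echo
produces, so validity scoring is a **count, not a norm**: channel $c$ is
deviant when $|d_c - \hat b_c| / |\hat b_c| > \tau_{\mathrm{chan}}$
(default 0.5), and a frame is invalid when at least $m_{\min}$ (default 2)
channels deviate. A count is robust to one strong lesion echo on a single
channel; the defaults sit two orders of magnitude above simulated polyp
deviations ($\sim 10^{-2}$) and far below contact severities
($e_c \ge 9$ at severity 10), so the classifier separates the two
populations without error on simulated streams.

## Detection and alerts

Detection runs on the per-frame scalar aggregate:

1. **Threshold.** $\theta = \mu + k_\sigma \sigma$ over the first
   `calib_frames` *valid* frames (default $k_\sigma = 5$: essentially
   zero false-alarm probability per frame under Gaussian noise).
2. **Runs.** Maximal intervals of valid frames above $\theta$, bridging
   gaps up to `gap_bridge` frames (default 3) so a brief dip or an
   isolated invalid frame does not split one lesion into two alerts;
   runs never start or end on invalid frames.
3. **Width classification.** Runs of at least `L_min` frames (default
   10, inclusive) are polyps, shorter runs stool. The default sits
   between the stool ($\le 6$) and polyp ($\ge 15$) extent defaults with
   margin on both sides — the study quantifies "wider" versus "shorter"
   no further, so the boundary is a configuration value, not a published
   one.

Each run becomes one alert event carrying its frame interval, the angular
bin and magnitude of its contrast peak, and the label. Events are the
testable contract standing in for the device's acoustic polyp signal;
rendering audio is out of scope.

## Evaluation

`score_segments` works at the segment level, mirroring how the study
reports its result: a polyp segment is detected when at least one
polyp-labelled alert overlaps it by one frame or more (the study's
correlation of microwave and endoscopic timelines states no stricter
overlap criterion); a healthy segment overlapped by a polyp alert is a
false-positive segment; cluster and contact segments are excluded from
every count.

Two bundled experiments reproduce the study design at desk scale:

* `run_replica_sequence`: the 600-frame valid sequence — the detector must
  alert on all three polyp segments and on no healthy segment.
* `run_trial2_recovery`: a 7087-frame stream with 14% per-frame contact
  corruption — the validity classifier's invalid fraction must recover
  the generator rate within binomial error
  ($3\,\mathrm{SD} \approx 1.2$ percentage points at this length).

The in-vivo recording behind those numbers (histology, the 59% cluster
discard, the raw 7087 frames) is real data and is not claimed as a
computational output; what the experiments test is that the pipeline's
statistical behaviour matches the study's printed design numbers under
the simulator's conditions.

```{r replica, eval = FALSE}
r <- run_replica_sequence(seed = 1)
r$polyp_detected            # 3 of 3
r$healthy_with_false_polyp  # 0
plot(r$detection)
```

## Problem sizes, determinism and limitations

The shipped experiments use the study-design sizes directly: 600-frame
replica sequences (the suite and the acceptance script run 20 seeds) and
the full 7087-frame discard-rate stream; a replica run takes well under a
second of imaging because the adjoint reduces to one
$600 \times 24$-by-$24 \times 1280$ complex product with precomputed
weights. All randomness flows from explicit integer seeds through a
private RNG stream (the caller's RNG state is restored), so identical
seeds give byte-identical stream archives, maps and event tables.

What the simulator does *not* emulate bounds what green tests mean:
haustral folds and realistic lumen geometry, mucosal clutter, antenna
element patterns, mutual coupling beyond the direct baseline term,
multiple scattering (the Born approximation is exact here by
construction, not an approximation error), frequency dispersion, and the
proprietary reconstruction algorithm. Passing the replica experiments
shows the pipeline reproduces the study's segment-level detection
behaviour under these idealised conditions; it is not evidence about
animal or patient data.
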