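---
title: "Parallel-transmit pulses in standard Pulseq files: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parallel-transmit pulses in standard Pulseq files: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptxseq)
```

# The problem

Pulseq is a vendor-neutral text format that describes an MRI pulse sequence
as a list of blocks referencing tables of RF, gradient and ADC events, with
sampled waveforms ("shapes") stored once and shared. The format defines a
single RF waveform per event, yet high-field systems drive many transmit
channels at once (parallel transmission, pTx) to counter the inhomogeneous
transmit field $\tilde B_1^+$ at 7 T. `ptxseq` implements a packing scheme
that stores one complex waveform **per channel** inside a single, fully
spec-compliant RF event, plus the surrounding machinery a pulse needs to
travel between scanner platforms: channel reordering, B0-direction reversal,
gradient-axis remapping, raster regridding, hardware-limit validation, and a
multi-channel Bloch verification stack.

# Packing pTx pulses into standard RF events

A Pulseq RF event references three shapes: magnitude (normalized to
$[0,1]$), phase (stored as radians$/2\pi$) and sample-time indices (RF
raster units). Time shapes exist to store sparse pulses cheaply, but nothing
in the format forbids *repeated* time points. The packing exploits exactly
that: the per-channel magnitude and phase waveforms are concatenated in
channel order, and the time shape repeats each channel's time range. A
decoder that knows the convention splits the shapes wherever the time index
fails to increase strictly (`infer_channel_count()` returns one plus the
number of non-increasing steps); a decoder that does not simply sees a legal
RF event whose duration is the final time point times the raster — which is
also why every channel must end at the latest time point used by any
channel (`pad_channels()` appends one zero-magnitude sample where needed;
because a sample covers the raster cells since the previous time index, one
terminal zero fills the whole gap). A one-channel pulse packs to bytes
identical to its plain encoding, so the scheme is backward compatible by
construction.

Two semantic choices are worth stating. The per-event frequency and phase
offsets are scalars in the format, so they apply uniformly to all channels.
Zero-magnitude padding carries phase 0: magnitude zero makes the phase
physically irrelevant, and a canonical value keeps round-trips exact.

# File I/O and the shape codec

Shapes are stored either literally or as a run-length encoding of first
differences, where two equal consecutive stored values announce a
repetition count. The writer targets 9 significant decimal digits. Instead
of quantizing samples independently, the compressor quantizes each
derivative *against the reconstructed running value* (feedback
quantization), so quantization error is bounded by one quantum per sample
and never accumulates along a 4096-sample shape. The quantized doubles are
exactly the doubles the printed decimals parse back to, which makes the
text round-trip bit-exact and the in-memory round-trip exact at the stated
precision. Times are stored as integer microseconds (ADC dwell in
nanoseconds), so constructors keep event timing on the raster grids.

Files carry an optional `[SIGNATURE]` section with the MD5 hash of
everything preceding it. On read, the raw body text is retained so
verification detects any single-byte change to the stored file;
`verify_signature()` distinguishes a failed check (`FALSE`) from an
unsigned document (`NA`). Offline safety-prediction results (and the
scanner-specific parameters used to compute them) can be carried in the
definitions header under a fixed `safety_` prefix that cannot collide with
core keys such as the raster times; combined with the signature this makes
the predictions tamper-evident. Sequences are read tolerant of v1.4.x and
normalized to the v1.5.0 model; writing always emits v1.5.0. Sections the
model does not interpret are preserved opaquely.

# B0-direction reversal

Moving a pTx pulse between platforms whose main fields point in opposite
directions changes the sense of Larmor precession. Writing the Bloch
equation $\dot{\mathbf M} = \mathbf M \times \boldsymbol\omega$ with
transverse drive $\omega_{xy} = 2\pi \sum_c S_c(\mathbf r)\, b_c(t)$ and
gradient term $\omega_z = 2\pi\, \mathbf G(t)\cdot\mathbf r$, two exact
reflection identities of the rotation group give

$$\alpha(\text{drive } f,\ \omega_z)
  \;=\; \alpha(\text{drive } \bar f,\ -\omega_z),$$

and a reversed main field is equivalent (by a proper $\pi$ rotation of the
lab frame about the x axis) to the normal field with the transverse drive
conjugated and the gradient term negated. For coils whose 3D profile is
mirror-symmetric across the transverse plane (magnitude even, phase odd in
z) the effective per-channel sensitivities under the reversed field are the
conjugates $\bar S_c$ of the stored maps — this is the symmetry assumption,
and it is how the simulator models `b0_sign = -1`. Combining the two facts,
the hardware-realizable conversion

* negate every RF phase (conjugate the waveforms), and
* flip the sign of the z gradient axis (`gradient_transform = diag(1, 1, -1)`)

reproduces the original flip-angle map exactly on the central transverse
plane, for *any* pulse. The package verifies this end to end: the converted
pulse simulated with `b0_sign = -1` matches the original map to better than
$10^{-6}$ relative, and applying the conversion twice is bit-exact (phase
negation and gradient sign flips are exact floating-point operations).

Channel-to-hardware orderings are site- and coil-specific, so the shipped
Siemens/Philips conversion configs carry the axis transform and conjugation
flag but an identity channel permutation; users edit
`channel_permutation` in the config to match their coil plug mapping. The
conversion operators (reordering, conjugation, axis transform) are factored
and individually testable. Only the XYZ frame is handled; oblique
native-frame (MPS) transforms are out of scope.

# Raster regridding

Arbitrary (shape-sampled) gradients are tied to a platform time grid —
commonly 10 µs, but 6.4 µs on the hardware this packing targets — so
`regrid_waveform()` moves center-sampled waveforms between grids by linear
interpolation. Linear interpolation (rather than Fourier resampling) is
deliberate: it matches interpreter-style upsampling, cannot ring, and
preserves endpoint values whenever the duration is representable on the
target grid. When it is not, the grid gains one cell and the cell straddling
the waveform end carries the cell-averaged value, so the zeroth moment (the
gradient area, hence the k-space displacement) is preserved: exactly for
constants, and to better than $10^{-4}$ relative for trapezoids (the only
residual error is the midpoint rule across the ramp corners). The sub-raster
remainder is reported so callers can account for the timing pad.

# Hardware validation and switch-count analysis

`validate_sequence()` mirrors a scanner's pre-scan checks: per-block
gradient amplitude, slew rate (forward difference over the raster, the
first sample slewing from zero; for trapezoids amplitude/ramp-time), ADC
bandwidth, shape range, raster alignment and block timing. Violations are
report rows, not exceptions, and any hard violation flags the sequence
`rejected`, mirroring the safe abort of an intentionally over-spec
sequence. A gradient-raster mismatch is a separate `needs_regrid` flag
because it is fixable.

Transmit/receive hardware mode switches need guard time on real systems.
Rather than modeling vendor timing, `count_hw_switches()` reports how many
switch windows a sequence needs when an interpreter coalesces blocks: a
receive window continues across consecutive ADC blocks (and neutral blocks
carrying only gradients or delays) and is broken by a transmit block. An
EPI-style train of 64 readout blocks thus needs one receive window instead
of 64, which is the property that makes dead-time-free execution of such
trains possible.

# The simulation stack

Units follow Pulseq: RF amplitudes are $\gamma B_1$ in Hz, gradients
$\gamma G$ in Hz/m, so the gyromagnetic ratio is folded into the sequence
and `GAMMA_PROTON` is only needed to convert hardware units. The full Bloch
simulation applies per-voxel Rodrigues rotations of the effective field
with step size $\min(\text{RF raster}, \text{gradient raster})$ and no
relaxation (the pulses of interest last a few milliseconds at most); the
rotation form conserves the magnetization norm to machine precision, which
the tests check via $|M_{xy}| = \sin\alpha$. The small-tip model evaluates
the Fourier-weighted integral of the drive along the excitation k-space
trajectory (remaining gradient area after each sample, midpoint-corrected).
A constant hard pulse gives $\alpha = 360\,A\,T$ degrees in closed form and
is reproduced to $10^{-9}$; random kT-points pulses at $\le 10^\circ$ agree
between the two models to well under 2% pointwise, consistent with the
$O(\alpha^2)$ linearization error.

k-space trajectories are running integrals of the gradient samples. Because
center samples are cell averages for piecewise-linear waveforms, the
cumulative rectangle sum at cell boundaries is *exact* for trapezoids;
constant-gradient and balanced-train closed forms are matched exactly and an
Archimedean spiral's analytic endpoint to well under 1% (pure
discretization).

## Synthetic B1 maps and what they do and do not show

`synth_b1_maps()` emulates an 8-channel transmit/receive head array on a 2D
grid through the isocenter: smooth Gaussian magnitude lobes on a coil ring,
rotated by $2\pi/C$ per channel; a constant channel phase of
$-2\pi(c-1)/C$ so the circularly polarized combination adds coherently at
the center (asserted as center-bright in the tests); and a mild linear
phase ramp along each channel's direction, with seeded per-channel jitter.
`symmetric = TRUE` designates the construction as the central plane of a
mirror-symmetric 3D profile, the regime in which the conjugate-map model of
reversed B0 is exact; `symmetric = FALSE` adds smooth phase asymmetries
that break it. These maps are deliberately idealized: no electromagnetic
field computation, no coil coupling, no subject-dependent loading, no local
SAR tensors. Tests passing on them show the *algebra* (packing, conversion,
simulation) is right; they say nothing about the accuracy of any specific
coil model on real anatomy.

## Simulated GRE acquisition

`simulate_gre()` runs a Cartesian 2D gradient-echo document end to end: the
slice excitation (possibly a packed pTx pulse) is Bloch-simulated on the
maps, the k-space location of every ADC sample is integrated from the
gradient events (phase resets at each excitation), each line is the exact
discrete Fourier transform of phantom x transverse magnetization x receive
sensitivity at those locations, and reconstruction inverts the encoding
with the conjugate kernels (exact for fully sampled Cartesian data) before
root-sum-of-squares combination. Receive sensitivities default to the
transmit map magnitudes, as for a transmit/receive array. Steady-state
longitudinal evolution across TRs is not modeled — images are proportional
to $\rho \sin\alpha$ — which is the regime the per-channel verification
needs. The per-channel check reproduces its target: with each of eight
slices transmitting on one channel, each slice image correlates with
$|\tilde B_1^+_c| \times$ phantom at better than 0.99 inside the phantom
(the 0.99 threshold is this package's choice of "nearly identical";
measured values are ≈ 0.9998 at 64x64). Non-Cartesian documents are
rejected; for those the trajectory tools apply.

## Power monitoring

Instantaneous per-channel power is $|A \cdot m_c(t)|^2$ times an arbitrary
but fixed calibration constant (default $10^{-3}$ W/Hz²) — true watt
levels are hardware calibrations the package cannot know, so limits are
interpreted on the same scale. Contiguous windows tile the waveform, so the
reported energy equals the sum of window averages times window length
identically. Sequence-level reports place each RF event into global
windows, which reproduces the expected signature of per-channel activation
scans: time-averaged power rises only on the active channel's trace while
it transmits.

# Fixture generators

`make_gre_fixture()` builds the phantom verification protocol
(FOV 256 mm, 1 mm, TE/TR/flip/BW = 6 ms/15 ms/6°/900 Hz/px by default, 256
phase-encode lines per slice) with excitation / encode / readout / spoiler
blocks whose ADC samples land exactly on the k-space grid; per-channel
activation makes each slice's excitation a packed single-channel pTx
pulse. `make_ktpoints_block()` emits an insertable fragment of hard
subpulses (per-channel complex weights) alternating with slew-limited
gradient blips; `make_mprage_template()` is a deliberately simplified
MPRAGE-like loop (inversion, delay, low-flip echo train) that serves as a
hybrid-sequence merge target for `merge_excitation()`. Every fixture passes
the default hardware profile and round-trips through the file format;
generation is deterministic given parameters and seed. kT-points weights
are user-supplied — pulse *design* (universal-pulse optimization) is prior
work and out of scope.

Default problem sizes are chosen to keep the whole verification suite fast
on one core: unit tests run 16-32 voxel grids and the acceptance checks a
64x64 eight-slice acquisition, 1000-shape codec sweeps and 32 randomized
packing round-trips — small enough to finish in seconds while exercising
every code path at the tolerances stated above.

# Known limitations

* Flip-angle simulation is 2D (central transverse plane); the B0-conversion
  identity is exact there and holds as a mirror relation in 3D.
* No relaxation, no steady-state signal model, no off-resonance beyond
  gradient-induced terms.
* Extension events (triggers, labels) are preserved opaquely, not
  interpreted.
* Power is monitored on an arbitrary calibration scale; vendor SAR, nerve
  stimulation and acoustic-resonance prediction algorithms are proprietary
  and not reproduced.
* The shipped cross-platform configs use identity channel ordering; the
  true ordering depends on the site's coil wiring and must be configured.
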