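# ptxseq

Parallel-transmit (pTx) RF pulses inside unmodified Pulseq v1.5.0 sequence
files: packing, cross-platform conversion, validation, and simulation-based
verification.

## The problem

Pulseq is the open, vendor-neutral text format for MRI pulse sequences, but
it defines a single RF waveform per event, while high-field (7 T) systems
drive several independent transmit channels to counter the inhomogeneous
transmit field B1+. `ptxseq` is a toolbox for researchers who want to move
multi-channel pulses — for example kT-points or universal-pulse excitations
— between scanner platforms through plain `.seq` files:

* **Packing.** Per-channel complex envelopes are concatenated into one
  spec-compliant RF event by repeating the time shape's range once per
  channel; decoders split the shapes where the time index stops increasing
  (`pack_ptx()`, `unpack_ptx()`, `infer_channel_count()`,
  `pad_channels()`). A one-channel pulse packs byte-identically to its
  plain encoding, so the scheme is fully backward compatible.
* **File I/O.** A complete Pulseq v1.5.0 reader/writer (`read_seq()`,
  `write_seq()`) with the derivative run-length shape codec
  (`compress_shape()`, `decompress_shape()`), MD5 signatures
  (`compute_signature()`, `verify_signature()`), and namespaced safety
  metadata in the definitions header (`set_safety_definitions()`).
* **Cross-platform conversion.** Channel reordering, B0-direction reversal
  (RF conjugation + z-gradient sign flip, derived from Bloch-equation
  reflection symmetry), gradient-axis remapping and 10 µs ↔ 6.4 µs raster
  regridding (`conversion_spec()`, `convert_seq()`, `regrid_waveform()`).
* **Validation.** Hardware-limit checks mirroring a scanner's safe abort
  (`validate_sequence()`), transmit/receive switch-window coalescing
  (`count_hw_switches()`), per-channel power monitoring (`power_report()`),
  and hybrid-sequence block replacement (`merge_excitation()`).
* **Physics.** A multi-channel Bloch simulator with a small-tip-angle
  cross-check (`simulate_flip()`), synthetic coil maps (`synth_b1_maps()`),
  k-space trajectory integration (`compute_ktrajectory()`), and a simulated
  Cartesian 2D GRE acquisition with root-sum-of-squares reconstruction
  (`simulate_gre()`), so every transformation can be verified by its effect
  on the flip-angle map rather than by eye.

The central physical statement behind the converter: for transmit arrays
whose sensitivities are mirror-symmetric across the transverse plane,
reversing the main field is equivalent to conjugating the per-voxel drive
and negating the through-plane gradient phase — realizable on any hardware
as phase negation plus a z-gradient sign flip, and exact on the central
plane. The package proves this numerically to 1e-6 on every run.

## Worked example

```r
library(ptxseq)

# two-channel pulse: channel 1 a full-amplitude rectangle, channel 2 at
# half amplitude with a 90 degree phase offset
rf <- multichannel_rf(
  mag   = list(rep(1, 100), rep(0.5, 100)),
  phase = list(numeric(100), rep(pi / 2, 100)),
  amplitude = 250)            # Hz (gamma * B1)

packed <- pack_ptx(rf)
packed
#> <ptx_packed> 2 channel(s) in 200 samples, duration 0.1 ms
infer_channel_count(packed$time)
#> [1] 2

# store it in a sequence file and check the signature survives
doc <- new_seq(name = "demo")
r <- seq_add_rf(doc, packed); doc <- r$doc
verify_signature(read_seq(write_seq(doc)))
#> [1] TRUE

# simulate the excitation on synthetic 2-channel coil maps
maps <- synth_b1_maps(2, grid = list(n = 32, fov = 0.256), seed = 1)
fl <- simulate_flip(rf, grads = NULL, maps = maps)
range(fl[maps$mask])
#> [1] 3.15 8.70   # degrees

# convert for a reversed B0 and re-simulate: the flip map is unchanged
conv <- convert_b0_direction(rf, NULL, conversion_spec(b0_flip = TRUE))
maps$b0_sign <- -1L
max(abs(simulate_flip(conv$rf, NULL, maps) - fl))
#> [1] 0

power_report(rf, limits = list(peak = 100, avg = 100), window = 5e-5)
#> <power_report> window 0.05 ms, overall PASS
#>  channel   peak avg_max    energy pass
#>        1 62.500  62.500 0.0062500 TRUE
#>        2 15.625  15.625 0.0015625 TRUE
```

The flip angles are in degrees (a 250 Hz rectangle for 0.1 ms would tip a
uniform unit sensitivity by 360 × 250 × 1e-4 = 9°; the map modulates that
spatially). Peak power and energy are on the package's fixed arbitrary
calibration scale (see the methods vignette).

A command-line front end wrapping the same functions is installed as
`exec/ptxseq`:

```sh
ptxseq fixture gre --default-protocol --out gre.seq
ptxseq validate gre.seq
ptxseq convert --spec inst/extdata/spec_siemens_to_philips.cfg gre.seq out.seq
ptxseq merge --template mprage.seq --block ktpoints.seq --at use=e hybrid.seq
```

## Package layout

* `R/shapes.R`, `R/seqio.R`, `R/doc.R` — Pulseq model, codec, reader/writer,
  signatures, safety definitions
* `R/ptx.R` — pTx packing/unpacking
* `R/convert.R`, `R/config.R` — conversion specs, regridding, config files
* `R/validate.R`, `R/merge.R` — hardware validation, switch analysis,
  hybrid-sequence merging
* `R/physics.R`, `R/gre.R` — Bloch/small-tip simulation, B1 maps,
  trajectories, power, GRE acquisition
* `R/fixtures.R`, `R/cli.R`, `exec/ptxseq` — fixture generators and CLI
* `vignettes/ptx-pulseq-methods.Rmd` — models, assumptions, parameter
  choices and limitations
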