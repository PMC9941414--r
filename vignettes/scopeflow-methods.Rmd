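---
title: "File-watcher microscopy automation: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{File-watcher microscopy automation: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scopeflow)
```

## The synchronization model

`scopeflow` couples an acquisition unit, a reconstruction unit and an
orchestrator through a shared filesystem and nothing else. Each unit
runs a polling watcher: every `poll_interval_s` seconds (default 1 s,
chosen as a comfortable compromise between latency and filesystem
traffic on network shares) it lists its folder, filters by suffix, and
delivers new, fully written files to the unit's handler as an ordered
batch. Three properties define correctness, and each is enforced by a
property-style test:

* **exactly-once** — a per-session *seen* set guarantees no path is
  delivered twice;
* **completeness** — every matching stable file is eventually
  delivered (within two poll intervals of settling);
* **stability** — a file is delivered only after its size and
  modification time are unchanged across two consecutive polls.
  Directory datasets (Zarr stores) are judged by their recursive file
  count and total byte size instead, since their mtimes only reflect
  the top level.

The stability rule needs no cooperation from the writer — essential
when the writer is a different program on a different machine — at the
price of one poll interval of extra latency per file. Writers inside
the package additionally stage every output under a temporary name and
rename it into place, so partially written files are never visible
under their final names at all.

Batches are ordered lexicographically by filename with an mtime
tie-break. The ordering must merely be deterministic and shared by all
units; lexicographic order has the convenient side effect that
zero-padded sequential names process in drop order.

Files already present when a session starts are marked seen without
delivery by default ("watch from now on"); `process_preexisting = TRUE`
opts into batch reprocessing of an existing folder. The seen set is
in-memory and per-session: restarting a unit over the same folder
reprocesses it unless started with the default policy, which simply
watches onward from the restart. Reconstruction is idempotent (outputs
are overwritten deterministically), so reprocessing is safe.

## The experiment log

Every unit appends one record per handled item — path, arrival time,
finish time, latency, ok/failed — and writes a plain-text log
(`<role>_<host>_<ISO start>.log`, never overwriting an existing file)
into its watched folder when the session ends. `parse_log()` is the
exact inverse of `write_log()` at millisecond timestamp precision and
validates each line, including that the stored latency matches the
stored timestamps within 2 ms. `latency_summary()` reports statistics
over the ok records only, counting failures separately, which is how
per-computer reconstruction performance is evaluated offline.

## The virtual microscope

The simulator exists so that every downstream stage can be verified
against ground truth. A `virtual_sample` is a non-negative intensity
image on a micrometer grid; three families cover the test needs:
`constant` (invertibility checks), `spots` (Gaussian puncta,
mitochondria-like), `filaments` (random-walk curves, actin-like). All
are deterministic in their seed.

`acquire_stack()` implements the grid-scan forward model. With scan
steps $s$ per axis and foci pitch $p$ pixels, frame
$k = k_y s + k_x$ records

$$F_k(y, x) = \begin{cases} b + a\,S(y, x) & x \bmod p = k_x \text{ and } y \bmod p = k_y \\ b & \text{otherwise,}\end{cases}$$

optionally followed by per-pixel Poisson noise, then rounding and
clipping into the unsigned 16-bit camera range. Design choices worth
stating explicitly:

* **Scan order** is row-major and non-serpentine — the simplest
  invertible mapping between frame index and scan step; it is a
  convention shared with the reconstruction, not a physical claim.
* **Defaults** are $s = p = 18$ and 8 ms per frame: 324 frames and
  2.592 s per stack, the stack geometry of the tiling experiments this
  framework was built around. With $p = s$ the $s^2$ steps tile the
  pitch exactly, so every pixel is a focus pixel in exactly one frame
  (a tested partition property) and reconstruction is exactly
  invertible. $p > s$ (sparser foci) is allowed and leaves unvisited
  pixels at background.
* **Optics blur is off by default.** The framework, not image
  formation, is the contribution; an optional Gaussian blur
  (`blur_sigma_px`) exists for qualitative realism but would break the
  exact-identity tests, so the default model omits it.
* **Stage snapping**: stage positions are continuous micrometers; the
  sample crop snaps to the nearest pixel via `round(position /
  pixel_size)`. The mosaic layout applies the *same* rounding, which is
  why nominal-offset stitching of noiseless simulated tiles is exact.

What the simulator deliberately does not emulate: photoswitching
kinetics, drift, stage imprecision, read noise, 3D structure and
spectral channels. Passing tests therefore demonstrate the correctness
of the framework's bookkeeping (delivery, ordering, formats, geometry,
reconstruction algebra), not robustness to real optical imperfections.

## Raw data formats

Raw stacks are stored as `n × H × W` unsigned 16-bit arrays with the
complete acquisition metadata serialized as one JSON string under the
attribute `ImSwitchData` — stage position, tile and lapse indices, scan
geometry and timing, detector shape, pixel size, laser settings,
timestamp, writer version. Two interchangeable backends:

* **Zarr v2 directory store**, uncompressed, C-order, chunked one
  frame per chunk, so a consumer on a shared filesystem fetches frames
  independently while the producer is still writing elsewhere. The
  reader/writer is implemented in the package (no R Zarr library is
  available) and its stores are verified against the reference Python
  `zarr` implementation in the test suite.
* **HDF5** file with a single dataset `data`, via a small bundled C
  binding to libhdf5; verified against `h5py` in the same test.

`load_raw(save_raw(x))` is bit-exact for frames and field-equal for
metadata in both formats, and loading the same stack from both formats
yields identical objects — the property the reconstruction unit's
format-agnostic ingest relies on.

## Reconstruction

The default algorithm is focus reassignment: for each frame and each
of its focus positions, sum the background-subtracted signal over a
$(2w+1)^2$ window clipped at the frame border and place it at the
focus pixel. `window_halfwidth_px` must satisfy $2w + 1 \le p$; a
larger window would overlap a neighboring focus and is rejected.
Background is either none or the stack's global minimum — which of
these (if either) a given instrument needs is sample-dependent, so it
is a parameter rather than a guess. The implementation uses a
summed-area table per frame for $w > 0$ and is tested for exact
equality against a naive triple-loop oracle on random stacks.

The algorithm is registered under `algorithm_id =
"focus_reassignment"` in a registry (`register_recon_algorithm()`), so
an instrument-specific reconstruction can replace it without touching
the unit's watch/queue/output contract — the framework's guarantee is
"n frames in, one image out", not a particular inverse.

Outputs are written twice: a float32 TIFF (single strip, with the
metadata and reconstruction parameters in the ImageDescription JSON)
and a single-scale OME-Zarr group with NGFF 0.4 `multiscales` metadata
(axes y, x in micrometers; scale from the recorded pixel size). NGFF
0.4 was chosen as the current widely read revision of the spec. The
TIFF writer is implemented in the package because the available TIFF
binding clamps float samples to [0, 1], which cannot represent
reconstruction values; `tiff::readTIFF` reads the files back verbatim
and acts as the independent format check. TIFF pixels and OME-Zarr
pixels are asserted identical.

## Planner geometry

`plan_grid(nx, ny, fov_um, overlap_frac)` places tile $(i, j)$ at
$(x_0 + i\,f(1-o),\; y_0 + j\,f(1-o))$, visited row-major. Axes follow
the image convention — x rightward along columns, y downward along
rows — fixed in one place and asserted in tests, because a silent flip
here is the classic source of mirrored mosaics. The registration table
(`apply_registration()`) replaces the interactive focus/skip step of a
GUI workflow: per-tile z offsets (e.g. from a measured sample tilt
plane) and skip flags, with skipped tiles excluded from all visit
sequences. Automatic focus finding is deliberately out of scope.
`plan_timelapse()` repeats the (skip-filtered) tile order $N$ times and
budgets a settle time (default 1 s) after every stage move to let
drift die down.

Plans serialize to JSON; experiment scripts retrieve the visit table
through the control API (`api$imcontrol$load_plan()`), so the planner
— not the script — owns the geometry.

## Scripts and the control API

Experiment scripts are R programs executed in a sandbox whose parent
environment is `baseenv()`: the base language is available, package
namespaces and attached globals are not, and the only injected binding
is `api`. The `api$imcontrol` namespace is the whole instrument
surface: `move_stage`, `get_stage_position`, `run_scan`,
`wait_for_scan_end`, `set_recording_folder`, `set_save_format`,
`set_param`/`get_param`, `load_plan`, `log_message`. Calls are
synchronous — `run_scan` returns only after the raw file is fully
written — so scripts read as straight-line experimental protocols. A
script error marks that job failed and the queue proceeds; a failed
experiment must never wedge the instrument.

The backend keeps a virtual experiment clock: each scan advances it by
`n_frames × frame_period` and each stage move by the configured settle
time, so experiment durations are modelled faithfully without real
sleeping (wall-clock pacing is available via `realtime = TRUE` where
realistic timing matters).

## Mosaicking

`compute_layout()` places tiles at their nominal stage offsets
(rounded as above); `assemble_mosaic()` blends with `average`
(default; conserves perfectly consistent overlaps exactly),
`overwrite`, or `feather` (border-distance weights). Correlation-based
alignment refinement is deliberately not implemented: stitching
refinement is a well-served post-processing problem, and
`overlap_consistency()` — the per-pair RMS over shared regions — tells
the user when it is actually needed. Under independent Gaussian noise
of standard deviation $\sigma$ per tile the expected RMS is
$\sigma\sqrt{2}$, a closed form the tests verify to 10 % on
$\ge 10^4$ overlap pixels; misplacement inflates it above that floor.

## The single-machine demo

`cmd_demo()` wires all three units over one folder tree inside one R
process. R is single-threaded, so "simultaneous" units are cooperative:
the three watch sessions are stepped round-robin, which preserves every
observable contract (file-based coupling, FIFO queues, exactly-once
delivery, per-unit logs) while remaining deterministic enough to assert
bit-reproducibility of the final mosaic for a fixed seed. Multi-process
or multi-machine operation uses the same `cmd_watch_*` commands pointed
at a shared folder.

Termination is inferred, since the filesystem is the only channel
between units: the demo stops when the script has run, raw/
reconstruction/layer counts agree, and two full scheduler rounds
discover no work — the demo's quiescence condition. A round limit turns
a wedged pipeline into an error rather than a hang.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full timelapse
schedule (2×2 tiles × 10 lapses, 324-frame stacks, 64×64 px tiles) and
scale the remaining end-to-end checks to small grids (3×3 tiles,
16–50 px tiles, 9–36 frame stacks) — sizes chosen so the whole suite
exercises every code path in well under a minute while the identity
properties it checks are size-independent. Oracle comparisons on
integer data use exact equality; floating-point comparisons use
tolerances at least six orders of magnitude below the quantities
compared, except where a statistical bound is the point (Poisson
convergence at 3σ of the standard error; overlap RMS at 10 %).

Known limitations: no OS-native filesystem event APIs (polling is the
point — it works on any share); no authentication or transport
security (units are assumed to live on a trusted share); single-scale
OME-Zarr only; 2D single-channel stacks; the seen-set does not persist
across unit restarts.
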