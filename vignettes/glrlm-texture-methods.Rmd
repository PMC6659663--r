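---
title: "Run-length texture features over sliding windows: models and methods"
author: "GLRLMtexture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Run-length texture features over sliding windows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GLRLMtexture)
```

## The model

A gray level run is a maximal set of consecutive, collinear pixels that
share one intensity along a given direction; the number of pixels in the
set is its run length. The gray level run length matrix (GLRLM) of a
region of interest (ROI) is the 2-D histogram $P$ whose entry $P_{ij}$
counts the runs of gray level $i$ and length $j$ inside the ROI along one
direction. Four principal directions are considered, expressed as unit
steps $(dx, dy)$ with the origin at the top-left pixel, $x$ growing
rightwards (columns) and $y$ growing downwards (rows): horizontal
$0^\circ = (1, 0)$, anti-diagonal $45^\circ = (1, -1)$, vertical
$90^\circ = (0, -1)$ and diagonal $135^\circ = (-1, -1)$.

Because every ROI pixel belongs to exactly one run, the run-length mass
identity
$$N = \sum_{i \in N_g} \sum_{j \in N_r} j\, P_{ij}$$
holds, with $N$ the ROI pixel count and $N_g$, $N_r$ the sets of occurring
gray levels and run lengths. The package verifies this identity for every
ROI it ever produces — it is part of the validity of the `GLRLMBatch`
class, and the command-line driver re-checks and logs it on every run.

From $P$ the eleven classical run-length features are computed, all
normalized by the total run count $S = \sum_{ij} P_{ij}$: SRE and LRE
($\sum P_{ij}/j^2$ and $\sum j^2 P_{ij}$, over $S$), GLN and RLN (squared
row and column marginals over $S$), RP ($S/N$), LGRE and HGRE (inverse and
direct square gray-level weights), and the four joint features SRLGE,
SRHGE, LRLGE, LRHGE ($1/(i^2 j^2)$, $i^2/j^2$, $j^2/i^2$ and $i^2 j^2$
weights). Here $j$ is the run length and $i$ the *level*, i.e. the raw
intensity plus a configurable `levelOffset` (below).

The analysis is windowed: a `roiSpec(w, h)` window is glided one pixel at
a time over the image, and only fully contained windows are enumerated —
no padding and no partial windows, so the mass identity stays exact. The
window with top-left pixel $(i, j)$ (0-based) has ROI index
$i \times \mathrm{width} + j$; indices therefore use the full image width
as stride and are sparse. Feature tables are keyed by this index, and
`featureMaps()` lays the values out densely on the
$(\mathrm{height}-h+1) \times (\mathrm{width}-w+1)$ grid of window
positions.

## Three engines, one contract

`glrlm()` exposes three engines that must produce *identical* sparse
output, and the test suite enforces exact equality among them across
randomized images, window sizes, directions and gray resolutions:

* **oracle** — per-ROI brute force: each window line is scanned directly
  and its runs tallied. Quadratic in the window overlap and deliberately
  simple; this is the ground truth.
* **sequential** — an optimized single-pass formulation. A whole-image
  *run length array* is computed once per direction: entry $RL[p]$ is the
  length of the run starting at $p$, obtained by visiting pixels
  reversely to the direction (anchored at the *ending pixels*, those with
  no in-image successor) with the recurrence $RL[p] = 1 + RL[p+(dx,dy)]$
  when the successor shares $p$'s intensity, else $1$. Each window line is
  then walked by jumps: at pixel $p$ the run is
  $\min(RL[p], \text{remaining in-window length})$ and the walk skips
  ahead by that many pixels. Runs are truncated at the window boundary;
  the entries of $RL$ itself are unbounded by any window.
* **batch** — all ROIs at once through array primitives, mirroring how
  one would phrase the computation for a massively parallel device while
  remaining plain vectorized R here:
  1. *scatter* (`expandROIs()`): every pixel copy is written to the
     address $N_k \cdot \mathrm{numROIs} + R_k \cdot r + l$ for the
     $(l+1)$-th entry of the $(k+1)$-th line of the ROI with dense rank
     $r$ ($R_k$ line sizes, $N_k$ their prefix sums), tagged as
     `key_IG = roi_index * G + gray`;
  2. *reduce-by-key* (`reduceRuns()`): adjacent equal keys collapse, the
     block length being the run length;
  3. *key packing* (`combineKeys()`):
     `key_IGL = key_IG * roiLength + run - 1`, with
     `roiLength = max(w, h)`;
  4. *sort and count* (`sortAndCount()`): sorting clusters each ROI's
     keys (the ROI index occupies the most significant digits) and a
     second reduce-by-key yields the strictly increasing unique keys and
     counts — the sparse GLRLMs of all ROIs with only non-null entries.

Two addressing decisions in the scatter deserve a note. First, the
scatter address uses the *dense rank* of the ROI, not its sparse index:
only with the rank is the address map a bijection onto
$[0, \mathrm{numROIs} \times N)$ for windows spanning several image rows;
since ranks are ordered exactly like sparse indices, the sorted output is
unaffected, and the keys themselves keep the sparse index. Second, the
interleaved layout separates the $k$-th lines of different ROIs, but with
a single ROI consecutive lines of that ROI become adjacent, and a purely
adjacency-based reduce could fuse a run across a line boundary whenever a
line ends with the intensity the next one starts with (the bundled worked
example triggers this along the horizontal direction). `expandROIs()`
therefore also emits a line-segment id per element, and the pipeline's
reduce never merges across segment boundaries. Called without a segment
vector, `reduceRuns()` keeps pure adjacency semantics.

Feature extraction works directly on the sorted keys in three summation
categories: the shared denominator $S$ (one reduce by ROI); the eight
$i/j$-weighted sums (transform each non-null entry, reduce by ROI); and
the squared marginals GLN and RLN. For GLN, dropping the run length from
the key (`key %/% roiLength`) leaves keys grouped, so an adjacency reduce
suffices; for RLN, dropping the gray level intermingles the order, so the
(ROI, run) keys are re-sorted — a segmented sort, the ROI being the most
significant digit — before the inner reduce, square and per-ROI reduce.

## Parameters

* `roiWidth`, `roiHeight` (pixels): window size; typical radiomics maps
  use small windows (4–12 px). `roiLength = max(roiWidth, roiHeight)` is
  the key multiplier. For the diagonal directions the longest possible
  run is `min(roiWidth, roiHeight)`, so `roiLength` is a strict upper
  bound there; it is used unchanged because the packing only requires a
  bound, and a uniform multiplier keeps keys decodable without knowing
  the direction.
* `glResolution` $G$ (levels): the number of gray levels, default 256 for
  8-bit imagery. Intensities must lie in $[0, G-1]$; the package performs
  no re-binning.
* `levelOffset` (levels, default 1): added to the raw intensity wherever
  a feature weights by the gray level, so level 0 never meets a $1/i^2$
  weight. With `levelOffset = 0` the formulas apply to raw intensities
  and the package raises an explicit domain error, naming the ROI, if a
  zero intensity occurs under an inverse-square gray weight — it never
  silently produces infinities.
* `engine`: `"batch"` (default), `"sequential"`, `"oracle"`. Output is
  identical; only speed differs.

## Numerical choices

Keys are IEEE doubles holding exact integers. Before any engine runs the
package asserts
$\mathrm{width} \times \mathrm{height} \times G \times \mathrm{roiLength} < 2^{53}$,
the exact-integer capacity of a double, and fails loudly otherwise; for
perspective, an 8-bit 4096×4096 image with 64-pixel windows sits near
$2^{48}$. All feature arithmetic is double precision. The engines'
equality is asserted exactly (integer keys and counts); feature
agreement between the key-reduction path and a dense double-loop oracle
is asserted to $10^{-12}$ relative. The sort need not be stable: after
packing, all information lives inside the key, so equal keys are
interchangeable. Degenerate inputs are handled by construction: 1×1
images and windows are valid (every direction yields single-pixel
lines), and empty key vectors reduce to empty batches.

## The synthetic generators

`synthConstant()`, `synthStripes()` and `synthCheckerboard()` produce
patterns with closed-form matrices used as exact regressions: a constant
$w \times h$ window scanned horizontally has one length-$w$ run per row
($S = h$, SRE $= 1/w^2$, LRE $= w^2$, RP $= 1/w$, GLN $=$ RLN $= S$); a
two-color checkerboard has all runs of length 1 along the horizontal and
vertical directions (RP $=$ SRE $=$ LRE $= 1$, RLN $= N$). Note the
diagonal caveat: diagonal neighbors of a checkerboard share
$(\mathrm{row}+\mathrm{col})$ parity and hence color, so along the two
diagonal directions checkerboard runs span whole diagonals — the
all-runs-one closed form is a horizontal/vertical property, and the
package's tests assert it only there.

`synthRandom(h, w, G, seed)` draws i.i.d. uniform intensities with R's
Mersenne-Twister generator, seeded locally (the caller's RNG state is
saved and restored, so drawing a fixture never perturbs an enclosing
simulation). Uniform i.i.d. pixels are a deliberately structureless
stress case: they exercise every code path (all gray levels, boundary
truncation, run skipping) but contain none of the spatial correlation,
noise texture or intensity non-uniformity of real MR images. Passing the
cross-engine equality and conservation tests on such images demonstrates
*combinatorial correctness* of the construction for arbitrary pixel
content — it says nothing about the discriminative value of the features
on any particular tissue, which is a property of the data, not of this
implementation.

The bundled `workedExample()` is a 5×5 window with 5 distinct intensities
whose four direction matrices are known exactly and are stored alongside
the pixels; it doubles as the end-to-end regression for all three engines
and for the feature values (e.g. $S = 22$, RP $= 0.88$,
SRE $= 19.75/22$, LRE $= 31/22$, GLN $= 100/22$, RLN $= 370/22$, and with
the default offset HGRE $= 451832/22$).

Test and acceptance runs keep problem sizes modest by choice — 32×48
random images across $G \in \{8, 256\}$ and square windows of 2–12
pixels, 25 seeded replicates — because the engines' exact-equality
contract makes larger sizes add runtime, not evidence: every code path
(line shapes, truncation, key packing) is already exercised at these
sizes, and all quantities compared are exact integers or closed-form
rationals.

## Design choices and limitations

* Feature map cells are anchored at the window's *top-left* pixel, the
  same anchor the ROI index uses; center anchoring (`anchor = "center"`)
  is available and pads with `NA` to the full image shape.
* The natural-log display transform for the four wide-dynamic-range
  features (LGRE, SRLGE, LRLGE, LRHGE) is an explicit display option for
  maps and PNG export, never a default, and never touches CSV output.
* CSV is the normative output format (written with `%.17g`, so finite
  doubles round-trip bit-exactly); PNG feature images are 8-bit min-max
  normalized display artifacts.
* Scope: 2-D images only, the four principal directions only, no gray
  level re-binning, no direction-averaged feature aggregation, and no
  incremental updates between overlapping windows. PGM input is limited
  to 8-bit (maxval ≤ 255); PNG input must be grayscale.
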