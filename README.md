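# GLRLMtexture

Run-length texture features for grayscale images, computed for **every
sliding rectangular window** of the image along the four principal
directions — the preprocessing step behind run-length-based radiomics
feature maps for medical imagery (e.g. MR slices), where thousands of
small, heavily overlapping regions of interest must be summarized per
image.

## What it computes

The gray level run length matrix (GLRLM) of a region of interest (ROI)
is the 2-D histogram *P* whose entry *P<sub>ij</sub>* counts the maximal
runs of gray level *i* with length *j* along one direction (0°, 45°, 90°
or 135°). Since every ROI pixel belongs to exactly one run,

&nbsp;&nbsp;&nbsp;&nbsp;*N* = Σ<sub>i</sub> Σ<sub>j</sub> *j P<sub>ij</sub>*,

with *N* the ROI pixel count — an identity the package verifies for every
ROI it produces. From *P* the eleven classical run-length features are
derived (all normalized by the run total *S* = Σ *P<sub>ij</sub>*): SRE,
LRE, GLN, RLN, RP, LGRE, HGRE, SRLGE, SRHGE, LRLGE and LRHGE.

Three engines produce **bit-identical** sparse output and cross-validate
each other:

* `oracle` — per-ROI brute-force line scans (ground truth);
* `sequential` — a whole-image *run length array* (one linear reverse
  pass per direction) plus per-window walks that skip ahead run by run,
  truncating at the window boundary;
* `batch` — all ROIs at once via array primitives: scatter every pixel
  copy into an interleaved layout, tag it with `roi_index * G + gray`,
  collapse adjacent equal keys into run lengths (reduce-by-key), pack
  `key = (roi * G + gray) * roiLength + run - 1`, then sort and count —
  the sorted unique keys with their counts *are* the sparse GLRLMs of
  all ROIs.

## Worked example

The package embeds a canonical 5×5 window with known matrices:

```r
library(GLRLMtexture)
fx <- workedExample()
pixels(fx$image)
#>      [,1] [,2] [,3] [,4] [,5]
#> [1,]    0  255  113  113   42
#> [2,]  255   42  113  113    0
#> [3,]  128  113  255    0   42
#> [4,]  113  255    0  128   42
#> [5,]   42  113  128  255  255

b <- glrlm(fx$image, roiSpec(5, 5), "H0")
b
#> GLRLMBatch: 7 non-null entries over 1 ROIs (5 x 5 windows), direction H0, G = 256
decodeKeys(b)
#>   roi_index gray_level run_length count
#> 1         0          0          1     4
#> 2         0         42          1     5
#> 3         0        113          1     3
#> 4         0        113          2     2
#> 5         0        128          1     3
#> 6         0        255          1     4
#> 7         0        255          2     1
```

Reading: scanning the five rows horizontally, intensity 42 occurs as
five isolated pixels (five runs of length 1), intensity 113 forms three
single runs and two runs of length 2, and so on; the run-length mass is
4+5+3+2·2+3+4+2 = 25 = *N*. The features:

```r
round(featureValues(extractFeatures(b)), 6)
#>           SRE      LRE      GLN      RLN   RP    LGRE     HGRE    SRLGE
#> [1,] 0.897727 1.409091 4.545455 16.81818 0.88 0.18197 20537.82 0.181964
#>         SRHGE    LRLGE    LRHGE
#> [1,] 17417.55 0.181993 33018.91
```

SRE near 1 and RP = 22/25 say the texture is dominated by short runs
(22 runs cover 25 pixels); HGRE is large because runs sit at high
levels (up to 256 with the default `levelOffset = 1`).

For a feature map over all sliding windows of a real image:

```r
img <- readGrayImage("slice.png")             # PNG, PGM or CSV
tab <- extractFeatures(glrlm(img, roiSpec(4, 4), "H0"))
maps <- featureMaps(tab)                      # 11 dense matrices
```

or from a shell:

```sh
Rscript inst/scripts/glrlm-features.R --image slice.png \
  --roi-width 4 --roi-height 4 --directions 0,45,90,135 --out results/
```

which writes per-direction sparse triplet CSVs and per-feature map CSVs
(optionally normalized PNGs), logging the number of ROIs and the mass
identity check for each direction.

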