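---
title: "Methods: how herbsheet reads a herbarium sheet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how herbsheet reads a herbarium sheet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbsheet)
```

`herbsheet` turns a digitised herbarium sheet into structured specimen
metadata in three chained workflows. This vignette explains the model behind
each stage, the parameters that matter, the numerical choices, and what the
synthetic test bed does and does not establish about real collections.

## The Specimen Description File

All stages communicate through one accumulating record per specimen, the
SDF. It is a nested document — specimen reference, matched scale region,
derived DPI, text regions, recognised texts, per-category entity lists, and
a provenance log with one entry per service call — serialized as canonical
JSON: sorted keys, schema version, image-derived floats at 6 significant
digits. Canonical form makes `serialize → parse → serialize` byte-stable,
so pipeline runs can be compared with `diff`.

Two deliberate choices:

* **Re-run semantics.** Re-invoking a service replaces that service's field
  and appends to the history; nothing else is touched. Results therefore
  accumulate monotonically and iterative workflows need no delete
  operation.
* **Reproducible provenance timestamps.** A provenance entry carries an
  ISO-8601 timestamp, but a wall-clock default would make two identical
  runs differ byte-wise. `record_result()` defaults to a fixed epoch
  string; callers that want wall-clock provenance pass `timestamp =`
  explicitly. Determinism is the default because diffable outputs are worth
  more in a batch pipeline than implicit timing.

Entity coordinate payloads are the one exception to the 6-digit float rule:
latitudes and longitudes serialize at full double precision so the
`deg + min/60 + sec/3600` identity survives a round trip to 1e-9.

## Scale matching and DPI

The scale bar mounted on each sheet is located by zero-mean normalised
cross-correlation (NCC) against the Scale Reference Image. NCC is bounded in
[−1, 1], invariant to affine intensity changes, and therefore thresholdable
across scans; the numerator is computed via one FFT of the image reused
across all template sizes, the window means and variances via integral
images. The specimen's resolution is unknown before this step, so the
template is rescaled over a geometric grid (default 0.5–2.0 at ratio
2^(1/4)); the best score wins, with ties broken toward magnification 1.0 and
then the smallest (y, x). Rescaling is nearest-neighbour, shared with the
synthetic generator, so an exact-magnification paste is recovered exactly.

A best score below 0.6 is *flagged*, not raised: the DPI computed from a
dubious match is recorded as low-confidence and text detection proceeds with
a configurable fallback (default 300 dpi). This mirrors how production
digitisation lines route uncertain sheets to manual handling rather than
halting the batch.

DPI itself is arithmetic: the SRI's physical length is its pixel width over
its resolution, and the sheet's DPI is the matched pixel width divided by
that length. It is exactly linear in the matched width, which the tests
exploit.

## Text-region detection

Printed text shows high horizontal contrast with dark and bright runs
alternating quickly; isolated plant material does not. The detector:

1. computes the horizontal gradient and binarizes it at 40/255 *keeping the
   sign* (−1 entering a dark run, +1 leaving);
2. counts **sign alternations** between consecutive strong gradients along
   each row. This is the discriminating step: a lone stem crossing a row
   produces one alternation, whereas each glyph produces several. Counting
   unsigned edge pixels instead would let any two nearby strokes imitate
   text;
3. averages alternations in a sliding window of 0.25 in × 0.083 in
   (dpi-scaled; about one text line high) and keeps windows above
   0.08 transitions/pixel;
4. merges accepted windows by morphological closing with a 0.1 in disc —
   lines of one label fuse, labels further apart than twice the radius stay
   separate;
5. drops components whose smaller dimension is below 0.07 in.

All lengths are physical and scale through the DPI, so one parameter set
(`text_detect_params()`) serves 150 and 600 dpi scans alike. Detected boxes
hug the ink, so they sit slightly inside the painted label rectangle;
against planted labels this yields IoU ≈ 0.8 with defaults.

One boundary subtlety: adding margin to an image shifts detections by
exactly the margin *when the margin matches the sheet border tone* (the
usual case for scan crops, and what the tests assert). A pure-white margin
around a darker paper tone creates a genuine contrast seam that can move
region bounds by a few pixels — a property of the data, not a detector bug.

## OCR over regions

Recognition is restricted to the detected regions: `recognize_regions()`
crops each rectangle (half-open pixel convention, no padding) and hands only
the crop to the engine, so plant material outside labels can never leak
characters into the transcript. Engines are pluggable behind a two-field
interface (`name`, `recognize`); an engine exception on one crop records
empty text with an error flag and the specimen continues.

The test suite runs entirely on a **fixture engine** that looks up the
planted text of the ground-truth label with maximal IoU (≥ 0.3) to the
crop's source region, optionally corrupted by a seeded per-character
substitution model. This isolates the pipeline logic from any OCR binary; a
thin `tesseract` CLI adapter is included for real use but never required.

## Entity extraction

Five services, order-independent and aggregated canonically (sorted by
offset, then category), each returning mentions with verbatim surfaces and
half-open character offsets:

* **Scientific names** — candidate genus (+ optional epithet) token windows
  matched against a dictionary; authorship tokens after the name are
  captured in the payload but excluded from the surface. Fuzzy matching
  allows edit distance 1 per token of ≥ 5 characters (single OCR
  substitutions), exact matching below that — short tokens would otherwise
  flood false positives.
* **Botanist names** — dictionary surnames extended leftward over initial
  tokens; a cue ending within 12 characters before the mention assigns the
  role (`leg.`/`legit`/`coll.` → collector, `det.`/`rev.` → determiner).
  The separator following the cue is not counted against the window,
  otherwise `leg. A. Humboldt …` (gap 13 with the space) would lose its
  cue.
* **Dates** — grammars `d.m.yyyy`, `d.R.yyyy` (Roman-numeral month, a
  herbarium convention), `yyyy-mm-dd`/`yyyy-mm`, `d/m/yyyy` (day-first by
  default, the continental label convention), `d Month yyyy`
  (English + Latin abbreviations) and bare years; everything normalises to
  ISO-8601, calendar-invalid near-matches are skipped, overlaps resolve
  longest-first (so `12.4.1987` is one day-precise date, not also a year).
  The same 12-character cue window classifies collection / determination /
  accession dates.
* **Coordinates** — DMS, degrees-decimal-minutes, hemisphere-letter and
  signed decimal atoms; a latitude pairs with the nearest following
  longitude starting within 40 characters (latitude first, the dominant
  label layout). Conversion is `deg + min/60 + sec/3600`, negated for S/W;
  out-of-range pairs are dropped. Unsigned bare numbers are never
  coordinate atoms, so altitudes and collection numbers cannot pair.
* **Locations** — case-insensitive longest match of gazetteer place names
  at token boundaries, carrying the gazetteer country.

## The synthetic test bed

`generate_sheet()` emulates what the pipeline needs to see: a light paper
background, dark plant-like clutter, printed labels at known positions, and
the SRI pasted at a known magnification. Choices worth knowing:

* **Label grammar.** Each label is one entity per line — scientific name
  with author, `leg.` + initials + surname, gazetteer place, optionally a
  coordinate pair in one of five formats, and a (possibly cue-prefixed)
  date in one of five formats. The generator computes the exact expected
  payloads from its own sampling, so extractor tests compare two
  independent routes. Lines stay under ~22 characters because real labels
  wrap; long sparse lines are also exactly what line-contrast windows
  undercover.
* **Typography.** Text renders from a bundled 5×7 bitmap font (lowercase
  reuses uppercase shapes) at a physical glyph height of 0.08 in, scaled by
  the sheet DPI like real print. The rendering is schematic — legible to a
  contrast profile, not to a human-grade OCR engine — which is sufficient
  because the fixture engine reads the ground-truth sidecar, not pixels.
* **Clutter.** `clutter_density` d draws about 100·d constant-curvature
  arcs (stems/twigs), continuously rasterized at unit steps and kept
  0.12 in clear of labels and scale. Continuous rasterization matters: a
  dashed stroke alternates dark/bright along rows exactly like text.
* **Reproducibility.** Every artifact (image bytes, sidecar, label text)
  is a pure function of the seed; the generator saves and restores the
  global RNG state.

Default study sizes: 1000×1400 px canvases, 20-sheet benchmarks, 200 label
texts, three magnifications {0.5, 1, 2} (the DPI benchmark plants no labels
so one canvas size serves all magnifications). The acceptance script runs
all of it in a few minutes on one CPU.

**What passing does not show.** The generator has no handwriting, no
photographic noise or illumination gradients, no barcode/colour-chart
confusables, schematic glyphs, and dictionaries that are synthetic and
collision-free by construction. Results on it validate the pipeline's
logic — contracts, chaining, geometry, grammars, noise tolerance of the
matchers — not field performance on historical handwritten labels, which
the underlying approach explicitly leaves to future handwriting services.

## Known limitations

* The scale matcher assumes the mounted scale resembles the SRI up to
  scaling; rotation and perspective are out of scope.
* Line-contrast detection targets printed text; faint or cursive
  handwriting falls below the transition-density threshold.
* Date interpretation of ambiguous slash forms is a configuration
  (`day_first`), not an inference.
* Location assignment is dictionary lookup with country attribution; no
  geocoding or disambiguation between homonymous places.
* The coordinator is an in-process engine: service implementations can be
  swapped freely while contracts hold (`rebind_service()`), but there is no
  distributed execution, message broker or human-review loop.
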