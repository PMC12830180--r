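---
title: "Serving pyramidal whole-slide images: design and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serving pyramidal whole-slide images: design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iristiles)
```

## The problem

A whole-slide image is a gigapixel scan stored as a resolution pyramid:
each layer is the same scene at a different linear scale, cut into square
tiles (here 256 px, JPEG-compressed). A viewer shows a viewport at some
magnification by fetching just the tiles it needs. Static HTTP file servers
can only hand out whole files, so single-file WSI containers need a
dedicated service that understands the container's structure and streams
individual tiles on request. `iristiles` implements that service, the
container it serves, the client logic a tiled viewer needs, and the
synthetic-data and load-test tooling to verify all of it.

## The container and its validation

A slide is one binary file: magic bytes `IRST`, a format version, a tile
count, a JSON metadata block, a per-tile table of `(offset, length)` pairs
in storage order, the concatenated compressed tile payloads, and a trailing
CRC32 of every preceding byte. Layers are stored lowest resolution first;
`scale` is defined relative to the highest-resolution layer, whose scale is
exactly 1. Grids obey `x_tiles = ceil(scale * width / tile_size)`.

Validation runs in full before any tile is served, and each failure has its
own condition class: bad magic, unsupported version, malformed or
inconsistent metadata, a header/metadata tile-count mismatch, a table entry
pointing outside the payload region (or overlapping another), and a
checksum failure. The checksum is checked last, so structural errors are
reported as such rather than as generic corruption. Detection is the goal;
corruption *recovery* is out of scope.

Edge tiles are stored at full tile size with right/bottom replicate
padding, so every stored tile has identical pixel geometry; clients crop
using the layer pixel extent `ceil(scale * extent)`. Using the ceiling here
(rather than rounding) is deliberate: it is the only definition consistent
with the tile-grid invariant above for fractional scaled extents, and it
matches the DeepZoom level-size convention, which keeps the DZI export
comparable tile-for-tile.

## Tile addressing

Within a layer, a tile at column `x`, row `y` (0-based, y growing downward
in image convention) has raster index `t = y * x_tiles + x`; the inverse is
`x = t mod x_tiles`, `y = t div x_tiles`. Layer indices are 0-based with
layer 0 the lowest resolution, matching the metadata's ascending-scale
order. The test suite proves the index/coordinate pair is an exact
bijection for every layer shape up to 32×32 by exhaustive enumeration.

The WADO-RS dialect maps its 1-based numbering onto this scheme: instance
`i` is layer `i - 1`, frame `f` is tile `t = f - 1`. Only single-frame
retrieval is supported; a comma-separated frame list is rejected with a
narrative naming the restriction. The study segment is accepted and ignored
for resolution — the container has no DICOM hierarchy.

## Request parsing and the error taxonomy

Both URL grammars are parsed strictly and without touching the file system:
ids are restricted to a conservative character set, indices must be plain
decimal, and any `..`, percent-encoding or backslash in a target is
rejected outright. The taxonomy is: 400 for malformed targets and
out-of-range indices ("request range violations"), 403 for traversal
attempts and prohibited files, 404 for unknown slides or files, 405 for
verbs other than GET/OPTIONS, and 500 for internal failures including a
container that fails validation. Every error body is the narrative in plain
text for ease of parsing. Rejecting all percent-encoding is stricter than
RFC 3986 requires, but no legitimate target in either grammar needs it and
it closes the encoded-separator class of traversal bugs entirely.

## The two-stack server

The live server separates a network stack from a file-system stack. The
network side accepts connections, reads buffers, parses request heads and
answers everything that needs no container bytes — errors, preflights,
introspection — immediately. Requests that do need container or
document-root bytes are appended to a FIFO queue drained into `fs_workers`
concurrency slots; a slot is occupied from dispatch until the job
completes, and completions are delivered in submission order.

R is single-threaded, so the stacks are cooperative phases of one event
loop rather than OS thread pools; "lockless" concurrency is treated as a
performance note of the original design, not a testable contract. The
contracts that *are* testable — FIFO completion order, and connection
acceptance plus request rejection remaining live while every worker slot is
stalled — hold and are asserted with a per-tile delay hook
(`tile_delay`), which occupies a worker slot via deadline scheduling
instead of a blocking sleep. With one worker stalled for 2 s, a malformed
request on a fresh connection is still answered within 100 ms.

A session is one HTTP connection (keep-alive); this is the natural analogue
of counting TCP socket sessions. The first request a connection makes
against a slide validates and opens the container (lazily, not at startup)
and takes one reference on the shared per-path handle; repeat requests on
the same connection take no further reference. When the connection closes,
its references are dropped and a handle reaching zero is evicted and its
byte view released. Base R has no memory mapping, so a handle holds the
container's bytes read once into memory — the operative contract
(no re-parse on reads; at most one open view per path; release exactly at
refcount zero) is unchanged. The `GET /internal/handles` route (only with
`debug = TRUE`) exposes the cache for tests; it is not part of the public
API.

Static-file mode serves only allow-listed extensions (`.html .htm .js .css
.json .xml .dzi .png .jpg .jpeg .ico .svg .wasm`) from inside the document
root, with symlink resolution checked against the root; slide containers
are never downloadable even when they live inside the root, so slides and
viewer assets can safely share a directory.

With `tls = "self-signed"` the server generates a 2048-bit RSA key and
self-signed certificate at startup (skipped when a pair is supplied). A
limitation: no package in the available R stack can terminate TLS on a
listening socket, so the listener itself stays plaintext and the generated
pair is written for a fronting load balancer — the deployment model the
two-stack design targets anyway. Consequently "rejects plaintext on the
TLS port" is not a behaviour this implementation can exhibit.

## Synthetic slides: what they do and do not establish

The generator's defaults describe a small but structurally complete
pyramid: 1024×1024 px, 256-px tiles, three layers at 2× downsampling
(scales 0.25/0.5/1), JPEG quality 90. That is large enough for multi-tile
rows (so raster addressing is actually exercised) and small enough for
exhaustive per-tile verification within test budgets.

*Identity mode* makes every tile a solid colour encoding its own address:
`R = 8((t div 32) mod 32)`, `G = 8(t mod 32)`, `B = 8(layer mod 32)`.
Multiples of 8 survive JPEG quantization of flat blocks, so a decoded tile
(channels rounded to the 8-step grid, tolerance 3 gray levels, robust at
quality ≥ 75) testifies to which tile the server really returned — the
oracle behind the API-equivalence and cross-format checks. The encoding
caps identity slides at 1024 tiles per layer and 32 layers.

*Pyramid mode* builds a seeded smooth texture (a sum of low-frequency plane
waves per channel) at full resolution and derives lower layers by
block-mean downsampling, which conserves the global pixel mean across
layers to within a gray level — a property the tests assert. Smoothness
keeps JPEG reconstruction error well under the mean-absolute-error
tolerance of 2 gray levels used in stitching and DZI comparisons.

Neither mode emulates real tissue statistics, scanner noise, or realistic
JPEG size distributions; a green suite establishes protocol, addressing and
byte-level correctness, not rendering quality or compression behaviour on
clinical data.

The DZI export places container layer `l` at DeepZoom level
`ceil(log2(max(width, height))) - (n_layers - 1 - l)` and requires an exact
2× pyramid. Interior tiles are byte-identical copies of the stored JPEGs,
so served tiles and exported files can be compared without decoding; only
cropped edge tiles are re-encoded.

## Load harness

The load harness mirrors the ramped virtual-user protocol of common load
tools: users start at a fixed ramp rate, each fetches the metadata once,
then loops uniformly random in-bounds tile requests with a uniform think
time — by default 1–2 ms, the reference protocol's pacing — with no
client-side caching. Sampling is seeded per user, so a fixed seed
reproduces the identical request sequence. The report is the conventional
CSV shape (per-second window, request count, failures, p50/p75/p95 latency
in ms). Absolute throughput and latency are hardware- and network-bound and
are never asserted; the suite asserts only clean completion and report
well-formedness.

## Numerical and design choices

* Offsets and lengths are stored as unsigned 64-bit little-endian and
  handled as R doubles (exact below 2^53).
* Metadata JSON is emitted canonically (fixed key order, maximal digits),
  so serialize–parse–serialize is byte-stable; scales in 2×/4× pyramids are
  exact binary fractions and round-trip exactly.
* `ceiling` is used for layer pixel extents (see above); tile grids use
  `ceil(scale * extent / tile_size)`.
* The container format is repo-defined (documented in `R/container.R`);
  bit-compatibility with any external WSI container is a non-goal.
* Containers are validated lazily at first request, not at server startup,
  so a directory of many slides starts serving immediately.
* `fs_workers` defaults to the CPU count; the per-tile delay default is 0
  (the hook exists only for liveness/FIFO tests).

## Known limitations

* No TLS termination in-process (see above); plaintext HTTP/1.1 only, no
  HTTP/2, no multipart WADO-RS responses, no authentication.
* Handles hold container bytes in memory rather than a true memory map;
  fine at fixture scale, not for multi-gigabyte archives.
* The single-process event loop serves hundreds of requests per second, not
  the thousands a compiled implementation reaches; the load harness is for
  protocol validation, not benchmarking hardware.
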