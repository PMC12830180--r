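# iristiles

A lightweight RESTful tile server and tile-source client for pyramidal
whole-slide images (WSI), written in R.

Digital pathology viewers render gigapixel slide scans as multi-resolution
pyramids of small square tiles. Static HTTP file servers cannot stream
subregions of a single large container file, which is why browser viewers
have historically relied on DeepZoom (DZI) trees — one file per tile, at the
cost of millions of files and lossy conversion. `iristiles` implements the
alternative: a single validated binary container of JPEG-compressed 256×256
tiles, streamed by a dedicated slide-serving microservice over two HTTP GET
dialects —

* a native RESTful grammar:
  `GET /slides/{slide}/metadata` and `GET /slides/{slide}/layers/{l}/tiles/{t}`
* a DICOMweb WADO-RS-compatible mapping:
  `GET /studies/{s}/series/{slide}/metadata` and
  `GET /studies/{s}/series/{slide}/instances/{i}/frames/{f}`
  with 1-based instances/frames mapped onto layers/tiles.

Tiles within a layer are addressed by a single raster-order index

```
t = y * tiles_x + x
```

where `tiles_x` is the number of tile columns of the layer; the client half
of the package (`configure_from_metadata()`, `tile_url()`, `fetch_region()`)
mirrors what a tiled viewer's tile source does: parse the served metadata,
derive one level per layer, and turn `(level, x, y)` into tile URLs.

The server follows a two-stack design: the network stack accepts, parses and
— for anything that does not adhere strictly to either API grammar — rejects
requests immediately, while all container access runs through a FIFO
file-system queue with a configurable number of worker slots. Open slides are
held in a reference-counted handle cache shared between client sessions; a
slide's byte view is released exactly when its last referencing connection
closes. A restricted static-file mode (allow-listed extensions, document-root
containment, slide containers never downloadable) can host a viewer
application next to the tiles, and CORS headers are emitted when an origin is
configured. With `--tls self-signed`, a 2048-bit RSA key and self-signed
certificate are generated at startup for a fronting TLS terminator.

It is aimed at people building or testing WSI viewer infrastructure who want
a fully scriptable, dependency-light reference stack: every slide is
generated deterministically in code (no sample data needed), and the served
pyramid can be cross-checked against a DZI export tile by tile.

## Worked example

```r
library(iristiles)

# a deterministic synthetic slide: 1024x1024 px, 3 layers, 2x downsampling
dir.create(sd <- tempfile("slides"))
gen <- generate_slide(synthetic_slide_spec(), file.path(sd, "demo.iris"))
validate_container(gen$path)
#> <slide_metadata> 1024 x 1024 px, 256-px jpeg tiles, 3 layer(s)
#> # A tibble: 3 × 3
#>   x_tiles y_tiles scale
#>     <int>   <int> <dbl>
#> 1       1       1  0.25
#> 2       2       2  0.5
#> 3       4       4  1
```

The three rows are the pyramid layers, lowest resolution first: layer 0 is a
single 256-px thumbnail at 1/4 scale, layer 2 the full-resolution 4×4 tile
grid. Serve it and read it back like a viewer would:

```r
srv <- callr::r_bg(function(sd) iristiles::iris_serve(sd, port = 8080),
                   args = list(sd = sd))
Sys.sleep(1)

levels <- fetch_levels("http://127.0.0.1:8080", "demo")
tile_url("http://127.0.0.1:8080", "demo", level = 2, x = 3, y = 2, levels)
#> [1] "http://127.0.0.1:8080/slides/demo/layers/2/tiles/11"

region <- fetch_region("http://127.0.0.1:8080", "demo",
                       level = 2, x0 = 100, y0 = 200,
                       width = 300, height = 250, levels = levels)
dim(region)
#> [1] 250 300   3
```

`tiles/11` is the raster index `2 * 4 + 3` for the 4-column top layer;
`region` is the exact requested pixel block, stitched from the covering
tiles with edge padding cropped. The same slide can be started from a shell
via the installed scripts:

```sh
Rscript inst/exec/iris-restful -d <slide_dir> -o anonymous -p 8080
Rscript inst/exec/iris-fixtures generate --out demo.iris
Rscript inst/exec/iris-fixtures loadtest --url http://127.0.0.1:8080 --slide demo
```

## Acceptance script

`scripts/acceptance.R` regenerates the default synthetic slide from the
given seed, serves it over HTTP, fetches every tile through both API
dialects, and verifies each response byte-for-byte against a direct
container read (and against the tile's self-identifying colour encoding)
before writing its JSON summary:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
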