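# Seeded generator of synthetic vasculogenesis-like binary vessel masks.
#
# Real network diversity arises from wet-lab determinants (endothelial cell
# source and density, matrix stiffness, growth-factor supplementation). The
# generator maps each determinant onto one knob: cell density ->
# n_seed_points, stiffness -> dropout_frac / diameter, growth factors ->
# connect_prob, media access -> spanning_bias. Segments are drawn between
# seed points on a k-nearest-neighbour proximity graph (k = 3), rasterized
# as hard binary strokes of normally distributed diameter.

#' Configuration of the synthetic vessel-network generator
#'
#' @param image_shape Integer vector `(rows, cols)` in pixels.
#' @param pixel_pitch Physical pixel size, micrometres per pixel. The default
#'   256 x 256 grid at 4 um/pixel covers a 1 x 1 mm field of view.
#' @param n_seed_points Number of scattered seed points (endothelial-density
#'   analog). Zero is valid and yields an empty mask.
#' @param connect_prob Probability in `[0, 1]` of keeping each proximity-graph
#'   edge (network-connectivity analog).
#' @param diameter_mean,diameter_sd Mean and standard deviation of per-segment
#'   stroke diameter, micrometres. Diameters are truncated below at one pixel.
#' @param spanning_bias Dimensionless `>= 0`; scales the number of anchor
#'   points placed on the two lateral image boundaries, biasing the network
#'   toward spanning the media channels.
#' @param dropout_frac Fraction in `[0, 1)` of surviving segments deleted
#'   before rasterization (sparse-network analog).
#' @param rng_seed Integer seed; identical config implies a bit-identical mask.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(image_shape = c(256L, 256L),
                             pixel_pitch = 4,
                             n_seed_points = 120,
                             connect_prob = 0.8,
                             diameter_mean = 16,
                             diameter_sd = 4,
                             spanning_bias = 1,
                             dropout_frac = 0.1,
                             rng_seed = 1L) {
  cfg <- list(
    image_shape = as.integer(image_shape),
    pixel_pitch = as.numeric(pixel_pitch),
    n_seed_points = as.integer(round(n_seed_points)),
    connect_prob = as.numeric(connect_prob),
    diameter_mean = as.numeric(diameter_mean),
    diameter_sd = as.numeric(diameter_sd),
    spanning_bias = as.numeric(spanning_bias),
    dropout_frac = as.numeric(dropout_frac),
    rng_seed = as.integer(rng_seed)
  )
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  if (length(cfg$image_shape) != 2 || any(cfg$image_shape < 1))
    stopf("image_shape must be two positive integers")
  if (cfg$pixel_pitch <= 0) stopf("pixel_pitch must be > 0")
  if (cfg$n_seed_points < 0) stopf("n_seed_points must be >= 0")
  if (cfg$connect_prob < 0 || cfg$connect_prob > 1)
    stopf("connect_prob must be in [0, 1]")
  if (cfg$dropout_frac < 0 || cfg$dropout_frac >= 1)
    stopf("dropout_frac must be in [0, 1)")
  if (cfg$diameter_mean <= 0) stopf("diameter_mean must be > 0")
  if (cfg$diameter_sd < 0) stopf("diameter_sd must be >= 0")
  if (cfg$spanning_bias < 0) stopf("spanning_bias must be >= 0")
  invisible(cfg)
}

#' Construct a vessel mask object
#'
#' @param pixels Strictly binary (0/1 or logical) matrix; 1 marks vessel lumen.
#' @param pixel_pitch Micrometres per pixel, `> 0`.
#' @param provenance Free text or the [generator_config()] that produced the
#'   mask.
#' @return An object of class `vessel_mask` with integer `pixels`.
#' @export
vessel_mask <- function(pixels, pixel_pitch, provenance = "unspecified") {
  if (is.logical(pixels)) storage.mode(pixels) <- "integer"
  if (!is.matrix(pixels) || anyNA(pixels) ||
      any(pixels != 0L & pixels != 1L))
    stopf("mask not binary")
  if (!is.numeric(pixel_pitch) || pixel_pitch <= 0)
    stopf("pixel_pitch must be > 0")
  structure(
    list(pixels = pixels, pixel_pitch = as.numeric(pixel_pitch),
         provenance = provenance),
    class = "vessel_mask"
  )
}

#' @export
print.vessel_mask <- function(x, ...) {
  cat(sprintf("<vessel_mask> %d x %d px @ %.3g um/px, coverage %.3f\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_pitch,
              mean(x$pixels)))
  invisible(x)
}

#' Generate one synthetic binary vessel-network mask
#'
#' Seed points (plus lateral boundary anchors controlled by `spanning_bias`)
#' are scattered uniformly, joined by a k-nearest-neighbour graph (k = 3),
#' thinned by `connect_prob`, further thinned by deleting a `dropout_frac`
#' fraction of segments, and the survivors rasterized as hard binary strokes
#' with per-segment diameters drawn from
#' `Normal(diameter_mean, diameter_sd)` truncated at one pixel. No
#' anti-aliasing is applied, so downstream morphometrics stay well defined.
#'
#' @param config A [generator_config()].
#' @return A [vessel_mask()]; deterministic given `config` (including its
#'   `rng_seed`).
#' @export
generate_mask <- function(config) {
  validate_generator_config(config)
  nr <- config$image_shape[1]
  nc <- config$image_shape[2]
  pix <- matrix(0L, nr, nc)
  if (config$n_seed_points == 0) {
    return(vessel_mask(pix, config$pixel_pitch, provenance = config))
  }
  with_seed(config$rng_seed, {
    pts_r <- runif(config$n_seed_points, 1, nr)
    pts_c <- runif(config$n_seed_points, 1, nc)
    n_anchor <- as.integer(round(3 * config$spanning_bias))
    if (n_anchor > 0) {
      pts_r <- c(pts_r, runif(n_anchor, 1, nr), runif(n_anchor, 1, nr))
      pts_c <- c(pts_c, rep(1, n_anchor), rep(nc, n_anchor))
    }
    edges <- knn_edges(pts_r, pts_c, k = 3L)
    if (nrow(edges) > 0) {
      keep <- runif(nrow(edges)) < config$connect_prob
      edges <- edges[keep, , drop = FALSE]
    }
    if (nrow(edges) > 0 && config$dropout_frac > 0) {
      n_drop <- floor(config$dropout_frac * nrow(edges))
      if (n_drop > 0) {
        drop <- sample.int(nrow(edges), n_drop)
        edges <- edges[-drop, , drop = FALSE]
      }
    }
    if (nrow(edges) > 0) {
      diam_um <- pmax(rnorm(nrow(edges), config$diameter_mean,
                            config$diameter_sd),
                      config$pixel_pitch)
      radius_px <- diam_um / (2 * config$pixel_pitch)
      for (e in seq_len(nrow(edges))) {
        pix <- draw_stroke(pix,
                           pts_r[edges[e, 1]], pts_c[edges[e, 1]],
                           pts_r[edges[e, 2]], pts_c[edges[e, 2]],
                           radius_px[e])
      }
    }
  })
  vessel_mask(pix, config$pixel_pitch, provenance = config)
}

# Undirected k-nearest-neighbour edge list over points; two-column matrix of
# point indices, deduplicated.
knn_edges <- function(r, c, k = 3L) {
  n <- length(r)
  if (n < 2) return(matrix(integer(), 0, 2))
  d <- as.matrix(stats::dist(cbind(r, c)))
  diag(d) <- Inf
  k <- min(k, n - 1L)
  nb <- apply(d, 1, function(row) order(row)[seq_len(k)])
  nb <- matrix(nb, nrow = k)
  from <- rep(seq_len(n), each = k)
  to <- as.vector(nb)
  e <- cbind(pmin(from, to), pmax(from, to))
  unique(e)
}

# Stamp one thick line segment (capsule of given radius, in pixels) into a
# binary matrix. Distance test on pixel centres; hard threshold, no AA.
draw_stroke <- function(pix, r1, c1, r2, c2, radius_px) {
  nr <- nrow(pix); nc <- ncol(pix)
  rad <- max(radius_px, 0.5)
  rlo <- max(1L, floor(min(r1, r2) - rad)); rhi <- min(nr, ceiling(max(r1, r2) + rad))
  clo <- max(1L, floor(min(c1, c2) - rad)); chi <- min(nc, ceiling(max(c1, c2) + rad))
  if (rlo > rhi || clo > chi) return(pix)
  rr <- rlo:rhi; cc <- clo:chi
  gr <- matrix(rr, length(rr), length(cc))
  gc <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  vr <- r2 - r1; vc <- c2 - c1
  len2 <- vr * vr + vc * vc
  if (len2 == 0) {
    d2 <- (gr - r1)^2 + (gc - c1)^2
  } else {
    t <- ((gr - r1) * vr + (gc - c1) * vc) / len2
    t <- pmin(pmax(t, 0), 1)
    d2 <- (gr - (r1 + t * vr))^2 + (gc - (c1 + t * vc))^2
  }
  sub <- pix[rr, cc, drop = FALSE]
  sub[d2 <= rad * rad] <- 1L
  pix[rr, cc] <- sub
  pix
}

#' Default per-field jitter ranges for cohort generation
#'
#' Uniform sampling ranges over the generator knobs used to emulate a diverse
#' cohort spanning sparse, barely connected networks up to dense spanning
#' ones. Ranges were fixed once so that a default cohort spans vessel
#' coverages from below 0.05 to above 0.4.
#'
#' @return Named list of `c(lo, hi)` ranges over [generator_config()] fields.
#' @export
default_cohort_jitter <- function() {
  list(
    n_seed_points = c(25, 350),
    connect_prob = c(0.35, 1),
    diameter_mean = c(8, 32),
    diameter_sd = c(1, 6),
    spanning_bias = c(0, 3),
    dropout_frac = c(0, 0.45)
  )
}

#' Generate a cohort of synthetic vessel masks
#'
#' Draws `n` generator configurations by sampling each field named in
#' `jitter_spec` uniformly from its range (integer fields are rounded), all
#' other fields taken from `base`, and generates one mask per configuration.
#' The whole cohort is a pure function of `(base, jitter_spec, master_seed)`.
#'
#' @param base A [generator_config()] supplying non-jittered fields.
#' @param n Number of masks, `>= 1`.
#' @param jitter_spec Named list of `c(lo, hi)` ranges over config fields;
#'   zero-width ranges (or an empty list) give a single-condition cohort.
#' @param master_seed Integer; per-mask seeds are derived with [derive_seed()].
#' @return List with `masks` (list of [vessel_mask()]) and `manifest`
#'   (data frame, one row per mask recording the sampled config and seed).
#' @export
generate_cohort <- function(base = generator_config(), n = 500,
                            jitter_spec = default_cohort_jitter(),
                            master_seed = 1L) {
  if (!is_count(n) || n < 1) stopf("n must be a positive integer")
  validate_generator_config(base)
  int_fields <- "n_seed_points"
  bad <- setdiff(names(jitter_spec), names(base))
  if (length(bad)) stopf("unknown jitter fields: %s", paste(bad, collapse = ", "))
  masks <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cfg_seed <- derive_seed(master_seed, i)
    cfg <- unclass(base)
    with_seed(cfg_seed, {
      for (f in names(jitter_spec)) {
        rng <- jitter_spec[[f]]
        val <- runif(1, min(rng), max(rng))
        if (f %in% int_fields) val <- as.integer(round(val))
        cfg[[f]] <- val
      }
    })
    cfg$rng_seed <- derive_seed(master_seed, n + i)
    cfg <- do.call(generator_config, cfg)
    masks[[i]] <- generate_mask(cfg)
    rows[[i]] <- data.frame(
      sample_id = sprintf("mask_%04d", i),
      rows = cfg$image_shape[1], cols = cfg$image_shape[2],
      pixel_pitch = cfg$pixel_pitch,
      n_seed_points = cfg$n_seed_points,
      connect_prob = cfg$connect_prob,
      diameter_mean = cfg$diameter_mean,
      diameter_sd = cfg$diameter_sd,
      spanning_bias = cfg$spanning_bias,
      dropout_frac = cfg$dropout_frac,
      rng_seed = cfg$rng_seed
    )
  }
  list(masks = masks, manifest = do.call(rbind, rows))
}

#' Read or write a vessel mask as an 8-bit PNG or TIFF
#'
#' Masks are stored single-channel with vessel pixels at full intensity
#' (255) and tissue at 0. The pixel pitch is not stored in the image file and
#' must be supplied on read.
#'
#' @param mask A [vessel_mask()].
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @return `write_mask()` returns `path` invisibly; `read_mask()` returns a
#'   [vessel_mask()].
#' @export
write_mask <- function(mask, path) {
  img <- mask$pixels * 1.0  # matrix rows = image rows, origin top-left
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img, target = path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, where = path, bits.per.sample = 8L)
  } else stopf("unsupported mask format: .%s", ext)
  invisible(path)
}

#' @rdname write_mask
#' @param path File path to read.
#' @param pixel_pitch Micrometres per pixel of the stored image.
#' @export
read_mask <- function(path, pixel_pitch) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") png::readPNG(path) else
    if (ext %in% c("tif", "tiff")) tiff::readTIFF(path) else
      stopf("unsupported mask format: .%s", ext)
  if (length(dim(img)) == 3) img <- img[, , 1]
  vessel_mask((img > 0.5) * 1L, pixel_pitch, provenance = path)
}
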