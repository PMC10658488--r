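# Programmatic mask fixtures with closed-form expected morphometrics, plus
# tiny brute-force oracles used to freeze expected values.

blank_mask <- function(nr = 64, nc = 64, pitch = 1) {
  vessel_mask(matrix(0L, nr, nc), pitch, provenance = "fixture")
}

# axis-aligned filled rectangle: rows r1:r2, cols c1:c2
rect_mask <- function(nr, nc, r1, r2, c1, c2, pitch = 1) {
  m <- matrix(0L, nr, nc)
  m[r1:r2, c1:c2] <- 1L
  vessel_mask(m, pitch, provenance = "fixture")
}

# horizontal bar of given width (rows) and length (cols), centred
bar_mask <- function(nr = 200, nc = 200, width = 3, len = 100, pitch = 1) {
  r0 <- floor((nr - width) / 2) + 1
  c0 <- floor((nc - len) / 2) + 1
  rect_mask(nr, nc, r0, r0 + width - 1, c0, c0 + len - 1, pitch)
}

# plus sign: two crossing bars through the image centre
plus_mask <- function(nr = 200, nc = 200, width = 3, len = 120, pitch = 1) {
  m <- matrix(0L, nr, nc)
  rc <- floor(nr / 2); cc <- floor(nc / 2)
  hw <- floor(width / 2); hl <- floor(len / 2)
  m[(rc - hw):(rc + hw), (cc - hl):(cc + hl)] <- 1L
  m[(rc - hl):(rc + hl), (cc - hw):(cc + hw)] <- 1L
  vessel_mask(m, pitch, provenance = "fixture")
}

# comb: one horizontal spine with n vertical teeth
comb_mask <- function(n_teeth = 3, width = 3, pitch = 1) {
  nr <- 120; nc <- 40 * n_teeth + 40
  m <- matrix(0L, nr, nc)
  spine_r <- 20
  m[spine_r:(spine_r + width - 1), 20:(nc - 20)] <- 1L
  for (i in seq_len(n_teeth)) {
    c0 <- 20 + i * 40 - 20
    m[spine_r:(spine_r + 80), c0:(c0 + width - 1)] <- 1L
  }
  vessel_mask(m, pitch, provenance = "fixture")
}

# brute-force skeleton degree census (independent of the graph extractor):
# counts of skeleton pixels by 8-neighbour degree
degree_census <- function(mask, spur_len_px = 5) {
  g <- skeletonize_and_graph(mask, spur_len_px)
  S <- g$skeleton
  nr <- nrow(S)
  deg <- matrix(0L, nr, ncol(S))
  P <- matrix(0L, nr + 2, ncol(S) + 2)
  P[2:(nr + 1), 2:(ncol(S) + 1)] <- S
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    deg <- deg + P[(2 + dr):(nr + 1 + dr), (2 + dc):(ncol(S) + 1 + dc)]
  }
  table(factor(deg[S], levels = 0:8))
}

# brute-force regression metrics from first principles
brute_metrics <- function(y, p) {
  res <- y - p
  list(r2 = 1 - sum(res^2) / sum((y - mean(y))^2),
       mae = sum(abs(res)) / length(res),
       mse = sum(res^2) / length(res),
       rmse = sqrt(sum(res^2) / length(res)))
}
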