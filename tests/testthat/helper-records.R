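# Tabular fixtures for the model harness, built in code: fast to generate
# and with known ground-truth structure.

# records whose labels are smooth deterministic functions of the metrics;
# optional gaussian noise on the labels
make_records <- function(n, seed, noise = 0) {
  with_seed(seed, {
    cov <- runif(n, 0.02, 0.5)
    len <- cov * 40000 + rnorm(n, 0, 500)
    nseg <- pmax(1, round(cov * 900 + rnorm(n, 0, 10)))
    nbr <- pmax(0, round(nseg * 0.7 + rnorm(n, 0, 5)))
    msl <- len / nseg
    dia <- runif(n, 8, 26)
    oxy_v <- clip01(0.35 + 1.1 * cov + rnorm(n, 0, noise))
    oxy_t <- clip01(0.30 + 1.2 * cov + rnorm(n, 0, noise))
    data.frame(
      sample_id = sprintf("s%04d", seq_len(n)),
      vessel_coverage = cov, total_vessel_length = len,
      segment_count = nseg, branchpoint_count = nbr,
      mean_segment_length = msl, mean_segment_diameter = dia,
      oxy_v = oxy_v, oxy_t = oxy_t
    )
  })
}

# records where both labels are constant
make_constant_records <- function(n, seed, value = 0.5) {
  r <- make_records(n, seed)
  r$oxy_v <- value
  r$oxy_t <- value
  r
}
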