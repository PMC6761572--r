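# Shared fixtures built in code.

frame_times <- function(total = 24, dt = 1 / 3) seq(0, total, by = dt)

# noiseless, deterministic pulse-train trace set
noiseless_p53 <- function(regimen_name = "natural", n_cells = 1, dt = 1 / 3,
                          total_time = 24) {
  generate_p53_traces(
    make_regimen(regimen_name, total_time = total_time),
    generator_config(n_cells = n_cells, amp_cv = 0, noise_sd = 0, seed = 1,
                     dt = dt))
}

# four well-separated template shapes for clustering tests
cluster_templates <- function(n_frames = 73) {
  tt <- seq(0, 1, length.out = n_frames)
  rbind(ramp_up = tt,
        ramp_down = 1 - tt,
        bump = exp(-((tt - 0.5) / 0.15)^2),
        sigmoid = 1 / (1 + exp(-12 * (tt - 0.3))))
}

# brute-force histogram mode used as an independent oracle
oracle_hist_mode <- function(v, bins) {
  r <- range(v)
  w <- diff(r) / bins
  centers <- seq(r[1], r[2], by = w)
  counts <- vapply(centers, function(c0)
    sum(v >= c0 - w / 2 & v < c0 + w / 2), numeric(1))
  counts[length(counts)] <- counts[length(counts)] +
    sum(v == r[2] & r[2] >= centers[length(centers)] + w / 2)
  centers[which.max(counts)]
}
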