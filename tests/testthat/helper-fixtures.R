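# shared small fixtures, built in code

# frame sequence with a white square translating rightwards by `step` px
# per frame
square_frames <- function(n_frames = 6, size = 10, step = 3,
                          frame = c(40, 60), y0 = 10, x0 = 5) {
  a <- array(0, dim = c(frame[1L], frame[2L], n_frames))
  for (t in seq_len(n_frames)) {
    x <- x0 + (t - 1L) * step
    a[y0:(y0 + size - 1L), x:(x + size - 1L), t] <- 255
  }
  a
}

# quick uncoupled / coupled segment generators at test scale
sim_segment <- function(alpha = 0, delta_s = 0, seed = NULL, duration_s = 120,
                        phase = "pretalk", dyad_id = "T") {
  gen_dyad(coupling_spec(alpha = alpha, delta_s = delta_s,
                         duration_s = duration_s, seed = seed),
           phase = phase, dyad_id = dyad_id)
}

# minimal pool for combinatorial checks: short random recordings,
# one per (dyad, phase)
toy_acc_pool <- function(m, phases = "pretalk") {
  segs <- list()
  for (ph in phases) for (i in seq_len(m)) {
    set.seed(2000 + i + 100 * match(ph, phases))
    segs <- c(segs, list(dyad_segment(rnorm(300) + 2, rnorm(300) + 2,
                                      fps = 30, phase = ph,
                                      dyad_id = sprintf("D%02d", i))))
  }
  segment_pool(segs)
}

# a pool of n uncoupled recordings of one phase
sim_pool <- function(n, alpha = 0, phase = "posttalk", duration_s = 60) {
  segment_pool(lapply(seq_len(n), function(i)
    sim_segment(alpha = alpha, duration_s = duration_s, phase = phase,
                dyad_id = sprintf("D%02d", i))))
}
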