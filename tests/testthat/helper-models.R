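# shared small model objects for the solver tests
ref_wall <- function(E = 4e5, r0 = 3, h0 = 0.3, sigma = 0.5)
  wall_model(E = E, r0 = r0, h0 = h0, sigma = sigma)

ref_fluid <- function(...) fluid_props(...)

# single straight-segment network: inlet at start, RCR terminal at end
single_tube_network <- function(length_mm = 100, radius_mm = 3,
                                R1 = 2e8, R2 = 1.8e9, C = NULL,
                                Pout = mmHg_to_Pa(5), E = 4e5,
                                tau = 0.05) {
  if (is.null(C)) C <- tau / R2
  seg <- straight_segment(c(0, 0, 0), c(0, 0, length_mm), radius_mm, dl = 2,
                          index = 1)
  assemble_network(
    list(seg), junctions = list(),
    inlet = list(segment = 1, end = "start"),
    terminals = list(list(segment = 1, end = "end", R1 = R1, R2 = R2, C = C,
                          Pout = Pout)),
    wall = list(E = E, h0_ratio = 0.1, sigma = 0.5, P0 = mmHg_to_Pa(85)))
}

constant_inflow <- function(Q0, T_period = 1)
  data.frame(t = c(0, T_period), Q = c(Q0, Q0))

# brute-force nearest-background radius oracle (out-of-volume = background)
brute_force_radii <- function(sk, volume) {
  d <- dim(volume$data)
  bg <- which(!volume$data, arr.ind = TRUE)
  # virtual background just outside every face of the domain
  faces <- rbind(
    cbind(0, seq_len(d[2] + 2) - 1, rep(seq_len(d[3] + 2) - 1, each = d[2] + 2)),
    cbind(d[1] + 1, seq_len(d[2] + 2) - 1, rep(seq_len(d[3] + 2) - 1, each = d[2] + 2)),
    cbind(seq_len(d[1] + 2) - 1, 0, rep(seq_len(d[3] + 2) - 1, each = d[1] + 2)),
    cbind(seq_len(d[1] + 2) - 1, d[2] + 1, rep(seq_len(d[3] + 2) - 1, each = d[1] + 2)),
    cbind(seq_len(d[1] + 2) - 1, rep(seq_len(d[2] + 2) - 1, each = d[1] + 2), 0),
    cbind(seq_len(d[1] + 2) - 1, rep(seq_len(d[2] + 2) - 1, each = d[1] + 2), d[3] + 1))
  allbg <- rbind(as.matrix(bg), faces)
  bgw <- sweep(sweep(allbg - 1, 2, volume$spacing, "*"), 2, volume$origin, "+")
  pos <- as.matrix(sk$nodes[, c("x", "y", "z")])
  vapply(seq_len(nrow(pos)), function(i) {
    dd <- sweep(bgw, 2, pos[i, ], "-")
    sqrt(min(rowSums(dd * dd)))
  }, numeric(1))
}

mid_segment_mean_flow <- function(solution, id) {
  q <- solution$segments[[as.character(id)]]$Q
  mean(q[, ceiling(ncol(q) / 2)])
}
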