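# Shared lazily-built fixtures: expensive objects are built once per test run
# and memoized in this environment.
.fix <- new.env(parent = emptyenv())

fix_get <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

fix_template <- function() fix_get("template", build_template)

fix_network <- function() fix_get("network", function()
  reduce_to_network(fix_template()))

# homogeneous discrete strips used by CV and equivalence checks
fix_strip_lp <- function() fix_get("strip_lp", function()
  reduce_to_network(tile_template(fix_template(), 10L, 1L)))

fix_strip_tp <- function() fix_get("strip_tp", function()
  reduce_to_network(tile_template(fix_template(), 1L, 24L)))

# interior probe pair along an axis of a network, at fractions f1 < f2 of
# the extent, near the orthogonal midline
probe_pair <- function(nw, axis = c("x", "y"), f1 = 0.4, f2 = 0.8) {
  axis <- match.arg(axis)
  nd <- nw$nodes
  a <- if (axis == "x") nd$cx else nd$cy
  o <- if (axis == "x") nd$cy else nd$cx
  span <- range(a)
  pick <- function(f) which.min(abs(a - (span[1] + f * diff(span))) +
                                  abs(o - mean(o)))
  c(pick(f1), pick(f2))
}

expect_close <- function(got, want, rel) {
  expect_lt(abs(got - want), rel * abs(want))
}

# heavy shared runs for the conduction-velocity and model-equivalence
# checks (Bondarenko kinetics, dt_p = 0.01 ms)

# discrete LP run on a 10-unit strip, with interior probes
bdk_lp_run <- function() fix_get("bdk_lp", function() {
  nw <- fix_strip_lp()
  simulate_discrete(nw, bondarenko_model(), monodomain_params(dt_p = 0.01),
                    stimulus_protocol("left_edge"), T_end = 16)
})

# discrete TP run on a 24-unit-tall strip
bdk_tp_run <- function() fix_get("bdk_tp", function() {
  nw <- fix_strip_tp()
  simulate_discrete(nw, bondarenko_model(), monodomain_params(dt_p = 0.01),
                    stimulus_protocol("bottom_edge"), T_end = 40)
})

# microscopic vs discrete pair on the same 4-unit strip, probed at the
# reference volume of one mid-strip cell
bdk_micro_pair <- function() fix_get("bdk_micro", function() {
  tis <- tile_template(fix_template(), 4L, 1L)
  nw <- reduce_to_network(tis)
  ion <- bondarenko_model()
  cell <- nw$nodes$id[which.min(abs(nw$nodes$cx - 0.6 * tis$nx * tis$h) +
                                  abs(nw$nodes$cy - tis$ny * tis$h / 2))]
  vol <- which(row(tis$cell_id) == nw$nodes$pr_x[cell] &
                 col(tis$cell_id) == nw$nodes$pr_y[cell])
  micro <- simulate_microscopic(tis, ion, monodomain_params(dt_p = 0.01),
                                stimulus_protocol("left_edge"), T_end = 20,
                                probes = vol)
  disc <- simulate_discrete(nw, ion, monodomain_params(dt_p = 0.01),
                            stimulus_protocol("left_edge"), T_end = 20,
                            probes = cell)
  list(micro = micro, disc = disc, cell = cell, vol = vol, mesh = tis,
       network = nw)
})

# anatomical-reentry oracle: a slow 60-cell ring started from a prepared
# circulating excitation (depolarized head at cells 1-6, graded refractory
# tail behind it); the lap time (~110 ms) exceeds the refractory period, so
# the wave circulates indefinitely
ring_reentry_run <- function(ion) {
  fix_get("ring_run", function() {
    n <- 60L
    ring <- fixture_ring_network(n = n, G = 0.01, G_slow = 0.01)
    V0 <- rep(ion$V_rest, n); h0 <- rep(1, n)
    V0[1:3] <- 30;  h0[1:3] <- 0.4
    V0[4:6] <- -20; h0[4:6] <- 0.9
    tail <- 45:60
    V0[tail] <- -80
    h0[tail] <- seq(0.02, 0.6, length.out = length(tail))
    prot <- stimulus_protocol("custom", pulses = list(
      list(region = 10L, start = 0, duration = 1, amplitude = 0)))
    simulate_discrete(ring, ion, monodomain_params(dt_p = 0.02), prot,
                      T_end = 500, stop_when_quiescent = TRUE,
                      V0 = V0, eta0 = matrix(h0, 1))
  })
}
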