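test_that("diffusion rows sum to alpha and membranes decouple", {
  params <- monodomain_params(dt_p = 0.01)
  # 1 x 2 volumes joined by membrane: block-diagonal, independent evolution
  cid <- matrix(c(1L, 2L), 2, 1)
  fe <- matrix(c(face_types()[["MEMBRANE"]], NA), 2, 1)
  fn <- matrix(NA_integer_, 2, 1)
  mesh <- cardiomaze:::.new_mesh(cid, fe, fn, h = 8, d = 10)
  sys <- assemble_diffusion_system(mesh, params)
  M <- as.matrix(sys$M)
  expect_equal(M[1, 2], 0)
  v <- diffusion_step(sys, c(-80, 20))
  expect_equal(v, c(-80, 20)) # fully decoupled volumes keep their values

  # cytoplasm-joined pair: off-diagonal -sigma_c, rows sum to alpha
  fe[1, 1] <- face_types()[["CYTOPLASM"]]
  mesh2 <- cardiomaze:::.new_mesh(cid, fe, fn, h = 8, d = 10)
  sys2 <- assemble_diffusion_system(mesh2, params)
  M2 <- as.matrix(sys2$M)
  alpha <- params$beta * params$C_m * 64 / params$dt_p
  expect_equal(M2[1, 2], -0.4)
  expect_equal(rowSums(M2), rep(alpha, 2))
  # implicit-Euler relaxation toward the mean, closed form:
  # difference shrinks by alpha / (alpha + 2 sigma_c)
  v2 <- diffusion_step(sys2, c(0, 1))
  shrink <- alpha / (alpha + 2 * 0.4)
  expect_equal(v2[2] - v2[1], shrink, tolerance = 1e-12)
  expect_equal(mean(v2), 0.5, tolerance = 1e-12)

  # template system: every row (interior and boundary) sums to alpha
  sys3 <- assemble_diffusion_system(fix_template(), params)
  expect_equal(range(Matrix::rowSums(sys3$M)), rep(alpha, 2),
               tolerance = 1e-12)
})

test_that("uniform fields are exact fixed points of the diffusion step", {
  sys <- assemble_diffusion_system(fix_template())
  v <- rep(-82, sys$n)
  expect_equal(diffusion_step(sys, v), v, tolerance = 1e-12)
})

test_that("diffusion matches a dense direct solve on a random toy", {
  set.seed(11)
  # random 5 x 5 single-cell cytoplasmic mesh
  cid <- matrix(1L, 5, 5)
  fe <- matrix(face_types()[["CYTOPLASM"]], 5, 5); fe[5, ] <- NA
  fn <- matrix(face_types()[["CYTOPLASM"]], 5, 5); fn[, 5] <- NA
  mesh <- cardiomaze:::.new_mesh(cid, fe, fn, h = 8, d = 10)
  sys <- assemble_diffusion_system(mesh)
  v <- rnorm(25, -60, 30)
  got <- diffusion_step(sys, v)
  dense <- solve(as.matrix(sys$M), sys$alpha * v)
  expect_lt(max(abs(got - dense)), 1e-10)
})

test_that("pure diffusion conserves the voltage sum and obeys the maximum principle", {
  mesh <- tile_template(fix_template(), 2, 1)
  sys <- assemble_diffusion_system(mesh)
  set.seed(3)
  for (rep in 1:5) {
    v <- runif(sys$n, -90, 30)
    v1 <- diffusion_step(sys, v)
    expect_lt(abs(sum(v1) - sum(v)) / abs(sum(v)), 1e-8)
    expect_gte(min(v1), min(v) - 1e-9)
    expect_lte(max(v1), max(v) + 1e-9)
  }
})

test_that("weighted conservation holds for the discrete network solve", {
  nw <- fix_network()
  sys <- assemble_network_system(nw)
  set.seed(4)
  v <- runif(nw$n, -90, 30)
  v1 <- as.numeric(Matrix::solve(sys$chol, sys$alpha * v, system = "A"))
  a <- nw$nodes$area
  expect_lt(abs(sum(a * v1) - sum(a * v)) / abs(sum(a * v)), 1e-8)
})

test_that("no stimulus means no activation anywhere, for both models", {
  u <- fix_template()
  prot <- stimulus_protocol("custom", pulses = list(
    list(region = "left_edge", start = 0, duration = 1, amplitude = 0)))
  for (ion in list(surrogate_model(), bondarenko_model())) {
    sim <- simulate_microscopic(u, ion, monodomain_params(dt_p = 0.05),
                                prot, T_end = 5)
    expect_true(all(is.na(sim$activation)))
    expect_lt(max(abs(sim$V_final - ion$V_rest)), 0.5)
  }
})

test_that("microscopic stimulation produces a propagating wave", {
  u <- fix_template()
  ion <- surrogate_model()
  sim <- simulate_microscopic(u, ion, monodomain_params(dt_p = 0.05),
                              stimulus_protocol("left_edge"), T_end = 10,
                              snapshot_times = c(5, 10))
  act <- matrix(sim$activation, u$nx, u$ny)
  expect_true(all(!is.na(act)))
  # activation time increases with x on average (plane wave moving right)
  prof <- rowMeans(act)
  expect_gt(cor(seq_len(u$nx), prof), 0.9)
  expect_length(sim$snapshots, 2L)
})

test_that("refinement in dt_p leaves probe traces consistent", {
  nw <- fix_strip_lp()
  ion <- surrogate_model()
  p <- probe_pair(nw, "x")[1]
  tr <- lapply(c(0.04, 0.02), function(dtp)
    simulate_discrete(nw, ion, monodomain_params(dt_p = dtp),
                      stimulus_protocol("left_edge"), T_end = 20,
                      probes = p))
  v1 <- tr[[1]]$probe_V[, 1]
  v2 <- tr[[2]]$probe_V[seq(1, length(tr[[2]]$times), by = 2), 1]
  expect_lt(max(abs(v1 - v2)), 1.5) # sup-norm under halving dt_p (mV)
})

test_that("T_end must be a multiple of dt_p and params validate", {
  expect_error(monodomain_params(beta = -1), "positive")
  expect_error(monodomain_params(dt_o = 0.004, dt_p = 0.01), "multiple")
  expect_error(
    simulate_microscopic(fix_template(), surrogate_model(),
                         monodomain_params(dt_p = 0.05),
                         stimulus_protocol("left_edge"), T_end = 0.07),
    "multiple")
})
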