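test_that("occluder visibility implements the hard window and soft edges", {
  geom <- occluder_geometry(0, 0.8, softness = 0)
  expect_equal(occluder_visibility(c(0.4, -0.5, 0.9), geom), c(0, 1, 1))
  expect_error(occluder_visibility(NaN, geom), "finite")
  expect_error(occluder_geometry(1, 0), "strictly below")

  # soft edges: bounded, monotone in distance from the window, and
  # converging pointwise to the hard window off the edges
  xs <- seq(-1.5, 1.5, by = 0.01)
  for (s in c(0.2, 0.05, 0.01, 0.002)) {
    v <- occluder_visibility(xs, occluder_geometry(0, 0.8, s))
    expect_true(all(v >= 0 & v <= 1))
  }
  off_edge <- xs[abs(xs - 0) > 0.1 & abs(xs - 0.8) > 0.1]
  v_soft <- occluder_visibility(off_edge, occluder_geometry(0, 0.8, 1e-4))
  v_hard <- occluder_visibility(off_edge, geom)
  expect_equal(v_soft, v_hard, tolerance = 1e-6)

  # analytic gradient against finite differences
  g2 <- occluder_geometry(-0.8, 0, softness = 1 / 32)
  x0 <- c(-0.85, -0.79, -0.4, -0.02, 0.02)
  fd <- (occluder_visibility(x0 + 1e-6, g2) -
           occluder_visibility(x0 - 1e-6, g2)) / 2e-6
  expect_equal(pursuitdcm:::occluder_visibility_grad(x0, g2), fd,
               tolerance = 1e-4)
})

test_that("joint visibility is the inclusive disjunction of the two sites", {
  geom <- occluder_geometry(0, 0.8, softness = 0)
  expect_equal(joint_visibility(-0.5, 0.4, geom), 1) # attractor visible
  expect_equal(joint_visibility(0.2, 0.4, geom), 0)  # both occluded
  expect_equal(joint_visibility(-0.5, 0.9, geom), 1) # both visible
  # soft case: max of the two single-site visibilities
  gs <- occluder_geometry(0, 0.8, softness = 0.05)
  v <- runif(20, -1, 1); xt <- runif(20, -1, 1)
  expect_equal(joint_visibility(v, xt, gs),
               pmax(occluder_visibility(v, gs), occluder_visibility(xt, gs)))
})

test_that("coupling strengths follow the occlusion-dependent form", {
  k <- kinetic_parameters()
  vis1 <- coupling_strengths(1, k)
  expect_equal(vis1$kappa_v, 1 / 4 - 1 / 32) # 0.21875
  expect_equal(vis1$kappa_t, 1 / 2 + 1 / 32) # 0.53125
  vis0 <- coupling_strengths(0, k)
  expect_equal(vis0$kappa_v, 0.25)
  expect_equal(vis0$kappa_t, 0.5)
  # occluder-independent limit
  k0 <- kinetic_parameters(theta4 = 0, theta5 = 0)
  for (v in c(0, 0.3, 1)) {
    cs <- coupling_strengths(v, k0)
    expect_equal(cs$kappa_v, k0$theta1)
    expect_equal(cs$kappa_t, k0$theta3)
  }
  # the anticipatory design: attraction to the hidden location is stronger
  # when occluded, attraction to the target stronger when visible
  expect_gt(vis0$kappa_v, vis1$kappa_v)
  expect_lt(vis0$kappa_t, vis1$kappa_t)
})

test_that("sensory mapping produces gated Gaussian channel responses", {
  sg <- sensory_geometry()
  expect_length(sg$channel_centres, 17)
  far <- occluder_geometry(5, 6) # everything visible
  sp <- sensory_prediction(0.3, 0.3, sg, far)
  expect_equal(sp$proprio, 0.3)
  expect_equal(sp$visual[sg$channel_centres == 0], 1)
  expect_equal(sp$visual[abs(sg$channel_centres) == 1], rep(exp(-1), 2))
  # occluded target: all channels dark
  occ <- occluder_geometry(0, 0.8, softness = 0)
  expect_equal(sensory_prediction(0, 0.4, sg, occ)$visual, rep(0, 17))
  # displaced target excites the channel at its retinal position
  sp1 <- sensory_prediction(0, 1, sg, far)
  expect_equal(which.max(sp1$visual), which(sg$channel_centres == 1))
  expect_equal(max(sp1$visual), 1)
  # bounded responses; total excitation is maximal when the response bump
  # lies on the array (i.e. near fixation) and decays once it slides off
  grid <- seq(-15, 15, by = 1.5) + 0.3
  tot <- vapply(grid, function(xo)
    sum(sensory_prediction(xo, 0.3, sg, far)$visual), numeric(1))
  expect_true(all(tot >= 0 & tot <= 17))
  tot_fix <- sum(sensory_prediction(0.3, 0.3, sg, far)$visual)
  expect_gte(tot_fix + 1e-6, max(tot))
  expect_gt(tot_fix, sum(sensory_prediction(0.3 + 10, 0.3, sg, far)$visual))
})

test_that("attractor prior is a scaled, phase-led sinusoid", {
  pb <- prior_belief_parameters(amplitude = 1, phase_lead = 2 * pi / 32)
  expect_equal(attractor_prior(0, pb), cos(2 * pi / 32))
  expect_equal(attractor_prior(0, prior_belief_parameters(1, 1e-9)), 1,
               tolerance = 1e-9)
  t <- seq(0, 2, by = 0.05)
  expect_equal(attractor_prior(t, prior_belief_parameters(2, 0.1)),
               2 * attractor_prior(t, prior_belief_parameters(1, 0.1)))
  expect_error(prior_belief_parameters(amplitude = -1))
})

test_that("model flow implements the coupled pursuit dynamics", {
  p <- full_parameter_set()
  far <- occluder_geometry(5, 6)
  # fixed point
  expect_equal(model_flow(c(0.3, 0, 0.3, 0), 0.3, p, far), rep(0, 4))
  # worked substitution: v = 1, states at 0, fully visible
  fl <- model_flow(c(0, 0, 0, 0), 1, p, far)
  expect_equal(fl[2], 1 / 4 - 1 / 32) # kappa_v * (v - xo)
  expect_equal(fl[4], 0.25)           # (v - xt) / 4
  # pure viscous decay of target velocity
  fl2 <- model_flow(c(0, 0, 0.5, 1), 0.5, p, far)
  expect_equal(fl2[4], -p$kinetic$theta6)
  # continuity across the occluder edge when softness > 0
  gs <- occluder_geometry(-0.8, 0, softness = 1 / 32)
  xs <- seq(-0.1, 0.1, by = 1e-3)
  acc <- vapply(xs, function(x) model_flow(c(0, 0, x, 0), x, p, gs)[2],
                numeric(1))
  expect_lt(max(abs(diff(acc))), 0.02)
})

test_that("oculomotor plant integrates action with unit viscosity", {
  expect_equal(process_flow(c(0, 0), 0), c(0, 0))
  expect_equal(process_flow(c(0.2, 0.5), 0.5)[2], 0) # equilibrium velocity
  expect_equal(process_flow(c(0, 0), 1), c(0, 1))
})

test_that("parameter sets round-trip through the flat vector form", {
  p <- full_parameter_set(
    kinetic = kinetic_parameters(0.3, 0.4, 0.6, 0.01, 0.02, 0.2),
    prior_beliefs = prior_belief_parameters(1.4, 0.3),
    precisions = precision_parameters(3, 5, 2))
  v <- as_param_vector(p)
  expect_named(v, param_names())
  expect_equal(param_set_from_vector(v), p)
  expect_equal(param_set_from_vector(rev(v)), p) # named reordering
  expect_equal(precision_sd(4), exp(-2))
})
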