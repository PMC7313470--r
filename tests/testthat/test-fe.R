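## geometry used for closed-form benchmarks
soft_E <- 1000
soft_nu <- 0.49

## all element edge lengths positive (no inverted elements)
elem_dims_positive <- function(mesh) {
  sz <- cbind(mesh$nodes[mesh$elems[, 7], 1] - mesh$nodes[mesh$elems[, 1], 1],
              mesh$nodes[mesh$elems[, 7], 2] - mesh$nodes[mesh$elems[, 1], 2],
              mesh$nodes[mesh$elems[, 7], 3] - mesh$nodes[mesh$elems[, 1], 3])
  sz > 0
}

test_that("element stiffness is symmetric with a rigid-body nullspace", {
  Ke <- hex8_stiffness(1e-3, 2e-3, 0.5e-3, soft_E, soft_nu)
  expect_equal(Ke, t(Ke), tolerance = 1e-12)
  ## translations in x, y, z produce no force
  for (dof in 1:3) {
    t_vec <- rep(0, 24)
    t_vec[seq(dof, 24, by = 3)] <- 1
    expect_lt(max(abs(Ke %*% t_vec)), 1e-9 * max(abs(Ke)))
  }
  expect_gte(min(eigen(Ke, symmetric = TRUE, only.values = TRUE)$values),
             -1e-9 * max(abs(Ke)))
})

test_that("patch test: uniform uniaxial stress is reproduced exactly", {
  lx <- 10e-3; ly <- 4e-3; lz <- 2e-3
  F <- 1e-3
  mesh <- hex_grid_mesh(seq(0, lx, length.out = 5),
                        seq(0, ly, length.out = 4),
                        seq(0, lz, length.out = 3))
  K <- fe_assemble(mesh, data.frame(region = 1L, E = soft_E, nu = soft_nu))
  x <- mesh$nodes[, 1]
  left <- which(x < 1e-12)
  right <- which(abs(x - lx) < 1e-12)
  ## roller on the left face (normal component only) plus minimal rigid-body
  ## pins so lateral contraction stays free
  fixed <- c(3 * left - 2, 3 * left[1] - 1, 3 * left[1],
             3 * left[length(left)])
  f <- fe_face_load(mesh, right, F, dof = 1L, normal = 1L)
  sol <- fe_solve(K, f, fixed)
  u_end <- mean(matrix(sol$u, ncol = 3, byrow = TRUE)[right, 1])
  expect_lt(abs(u_end / (F * lx / (soft_E * ly * lz)) - 1), 1e-6)
})

test_that("simple shear of a bonded thin layer matches F t / (G A)", {
  lx <- 20e-3; ly <- 20e-3; t_lay <- 0.5e-3
  F <- 1e-3
  G <- soft_E / (2 * (1 + soft_nu))
  mesh <- hex_grid_mesh(seq(0, lx, length.out = 13),
                        seq(0, ly, length.out = 13),
                        seq(0, t_lay, length.out = 5)) # 4 through thickness
  K <- fe_assemble(mesh, data.frame(region = 1L, E = soft_E, nu = soft_nu))
  z <- mesh$nodes[, 3]
  bot <- which(z < 1e-12)
  top <- which(abs(z - t_lay) < 1e-12)
  nn <- nrow(mesh$nodes)
  fixed <- c(3 * bot - 2, 3 * bot - 1, 3 * bot, 3 * top - 1, 3 * top)
  couple <- integer(3 * nn)
  couple[3 * top - 2] <- 1L # rigid plate: shared tangential translation
  f <- numeric(3 * nn)
  f[3 * top[1] - 2] <- F
  sol <- fe_solve(K, f, fixed, couple)
  u_top <- sol$u[3 * top[1] - 2]
  expect_lt(abs(u_top / (F * t_lay / (G * lx * ly)) - 1), 0.02)
})

test_that("stretcher config validates geometry and materials", {
  expect_error(stretcher_config(retina_size = c(5e-3, 10e-3, 0.22e-3)),
               "retina width")
  expect_error(stretcher_config(nu_retina = 0.5), "nu_retina")
  expect_error(stretcher_config(E_retina = -5), "positive")
  expect_warning(stretcher_config(E_scaffold = 1e6), "ratio")
  ## gap enters the width invariant
  expect_silent(stretcher_config(gap = 1e-4,
                                 retina_size = c(6.1e-3, 10e-3, 0.22e-3)))
  cfg <- stretcher_config()
  expect_equal(cfg$retina_size[1], 2 * cfg$scaffold_size[1])
})

test_that("the stretcher mesh duplicates interface nodes at gap zero", {
  cfg <- stretcher_config()
  mod <- build_model(cfg, resolution = 1)
  mesh <- mod$mesh
  ws <- cfg$scaffold_size[1]
  ## no node is shared between the two scaffolds
  left_nodes <- unique(as.integer(mesh$elems[mesh$region == 1L, ]))
  right_nodes <- unique(as.integer(mesh$elems[mesh$region == 2L, ]))
  expect_length(intersect(left_nodes, right_nodes), 0)
  ## and the scaffold-only stiffness carries no cross coupling
  Ks <- fe_assemble(mesh, data.frame(region = c(1L, 2L), E = 1e9, nu = 0.3),
                    regions = c(1L, 2L))
  ldof <- sort(c(3 * left_nodes - 2, 3 * left_nodes - 1, 3 * left_nodes))
  rdof <- sort(c(3 * right_nodes - 2, 3 * right_nodes - 1, 3 * right_nodes))
  expect_equal(max(abs(Ks[ldof, rdof])), 0)
  ## element count and dof bookkeeping
  expect_equal(mod$dof_count, 3L * nrow(mesh$nodes))
  expect_true(all(elem_dims_positive(mesh)))
})

test_that("medium resolution lands in the documented dof band", {
  mod <- build_model(stretcher_config(), resolution = 3)
  expect_gte(mod$dof_count, 5e4)
  expect_lte(mod$dof_count, 3e5)
})

test_that("forward solutions are linear in load and inverse in modulus", {
  cfg <- stretcher_config()
  mod <- build_model(cfg, resolution = 1)
  s1 <- solve_forward(mod, cfg)
  expect_gt(s1$u_x, 0)
  expect_lt(s1$residual, 1e-4)

  ## zero load: identically zero field
  cfg0 <- cfg; cfg0$load <- 0
  expect_equal(max(abs(solve_forward(mod, cfg0)$u)), 0)

  ## doubling the load doubles the displacement exactly
  cfg2 <- cfg; cfg2$load <- 2 * cfg$load
  s2 <- solve_forward(mod, cfg2)
  expect_equal(s2$u_x, 2 * s1$u_x, tolerance = 1e-9)

  ## E * u_x constant across decades of tissue modulus (rigid scaffolds)
  prods <- vapply(c(100, 760, 5000), function(E) {
    E * solve_forward(mod, cfg, E_retina = E)$u_x
  }, numeric(1))
  expect_lt(diff(range(prods)) / mean(prods), 0.005)

  ## effective stiffness is load / u_x and independent of load
  k1 <- effective_stiffness(mod, cfg)
  expect_equal(k1, cfg$load / s1$u_x, tolerance = 1e-12)
  expect_equal(effective_stiffness(mod, cfg2), k1, tolerance = 1e-9)
})

test_that("the loaded-face displacement is uniform along the depth", {
  cfg <- stretcher_config()
  mod <- build_model(cfg, resolution = 1)
  sol <- solve_forward(mod, cfg)
  ux <- matrix(sol$u, ncol = 3, byrow = TRUE)[mod$loaded_face, 1]
  expect_lt(diff(range(ux)) / mean(ux), 0.01)
})

test_that("external work balances stored strain energy", {
  cfg <- stretcher_config()
  mod <- build_model(cfg, resolution = 1)
  sol <- solve_forward(mod, cfg)
  parts <- retmech:::model_stiffness_parts(mod, cfg)
  K <- parts$K_scaffold + cfg$E_retina * parts$K_tissue_unit
  f <- fe_face_load(mod$mesh, mod$loaded_face, cfg$load, dof = 1L,
                    normal = 1L, elems = mod$loaded_elems)
  work <- 0.5 * sum(f * sol$u)
  energy <- 0.5 * sum(sol$u * as.numeric(K %*% sol$u))
  expect_lt(abs(work / energy - 1), 1e-6)
})

test_that("rigid-scaffold mode agrees with the full elastic model", {
  g <- 47e-6
  cfg <- stretcher_config(gap = g, retina_size = c(6e-3 + g, 10e-3, 0.22e-3))
  mod <- build_model(cfg, resolution = 1)
  s_full <- solve_forward(mod, cfg)
  s_rigid <- solve_forward_rigid(cfg, resolution = 1)
  expect_lt(abs(s_rigid$u_x / s_full$u_x - 1), 0.01)
})

test_that("displacement converges under mesh refinement at finite gap", {
  ## the touching-scaffold limit is singular (displacement-jump boundary
  ## data), so convergence is assessed on the regular finite-gap problem;
  ## refinement is in the deformation plane (x, z), the solution being
  ## uniform along the depth
  g <- 47e-6
  cfg <- stretcher_config(gap = g, retina_size = c(6e-3 + g, 10e-3, 0.22e-3))
  u <- vapply(c(16, 32, 64), function(nx) {
    solve_forward_rigid(cfg, resolution = 2, nxs = nx, ny = 4,
                        nzr = nx %/% 2)$u_x
  }, numeric(1))
  expect_lt(abs(u[3] / u[2] - 1), 0.03)
  expect_lt(abs(u[2] / u[1] - 1), 0.06)
})

test_that("invalid meshes and degenerate solves raise errors", {
  cfg <- stretcher_config()
  expect_error(build_model(cfg, resolution = -1), "positive")
  mesh <- hex_grid_mesh(c(0, 1e-3), c(0, 1e-3), c(0, 1e-3))
  K <- fe_assemble(mesh, data.frame(region = 1L, E = 1e3, nu = 0.3))
  f <- numeric(24); f[1] <- 1
  ## no constraints at all: singular system
  expect_error(suppressWarnings(fe_solve(K, f, integer(0))), "solver error")
})

test_that("VTU export writes a well-formed unstructured grid", {
  tmp <- withr::local_tempdir()
  cfg <- stretcher_config()
  mod <- build_model(cfg, resolution = 1)
  sol <- solve_forward(mod, cfg)
  path <- file.path(tmp, "field.vtu")
  write_vtu(mod$mesh, sol$u, path)
  txt <- readLines(path)
  expect_true(any(grepl("<VTKFile", txt)))
  expect_true(any(grepl(sprintf('NumberOfPoints="%d"', nrow(mod$mesh$nodes)),
                        txt)))
  expect_true(any(grepl('Name="displacement"', txt)))
  expect_equal(sum(grepl("^12$", txt)), nrow(mod$mesh$elems))
})
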