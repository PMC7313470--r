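#' Stretcher geometry and material configuration
#'
#' Dimensions, materials and load of the two-scaffold tissue stretcher: two
#' stiff scaffolds side by side (one fixed, one pulled in x), with the soft
#' near-incompressible retina bonded on top across both.
#'
#' Default dimensions are the experimental ones: each scaffold 3 mm wide
#' (x) by 10 mm deep (y) by 0.1 mm high (z); retina 6 mm x 10 mm x 0.22 mm.
#' The scaffolds are titanium (E = 105 GPa, nu = 0.33, standard handbook
#' values); their exact stiffness is immaterial because they are ~1e8 times
#' stiffer than the tissue. The retina carries a Poisson ratio of 0.49
#' (near-incompressible hydrated tissue) and a density of 1017 kg/m^3; the
#' density is configuration metadata only - the solve is static with no
#' gravity.
#'
#' @param scaffold_size c(width, depth, height) \[m\] of each scaffold
#' @param retina_size c(width, depth, height) \[m\] of the tissue slab
#' @param E_scaffold scaffold Young's modulus \[Pa\]
#' @param nu_scaffold scaffold Poisson ratio
#' @param E_retina tissue Young's modulus \[Pa\]
#' @param nu_retina tissue Poisson ratio, in (0, 0.5)
#' @param rho_retina tissue density \[kg/m^3\] (metadata)
#' @param load total x-force on the moving scaffold's outer sidewall \[N\]
#' @param gap initial scaffold separation \[m\] (0 = touching)
#' @return An object of class `stretcher_config`.
#' @export
stretcher_config <- function(scaffold_size = c(3e-3, 10e-3, 0.1e-3),
                             retina_size = c(6e-3, 10e-3, 0.22e-3),
                             E_scaffold = 105e9, nu_scaffold = 0.33,
                             E_retina = 760, nu_retina = 0.49,
                             rho_retina = 1017, load = 1.0e-3, gap = 0) {
  stopifnot(length(scaffold_size) == 3, length(retina_size) == 3)
  if (any(c(scaffold_size, retina_size) <= 0)) {
    stop("all dimensions must be positive", call. = FALSE)
  }
  if (nu_retina <= 0 || nu_retina >= 0.5) {
    stop("nu_retina must lie in (0, 0.5)", call. = FALSE)
  }
  if (E_retina <= 0 || E_scaffold <= 0) {
    stop("moduli must be positive", call. = FALSE)
  }
  if (gap < 0) stop("gap must be >= 0", call. = FALSE)
  if (abs(retina_size[1] - (2 * scaffold_size[1] + gap)) >
      1e-9 * retina_size[1]) {
    stop("retina width must equal 2 x scaffold width + gap", call. = FALSE)
  }
  if (abs(retina_size[2] - scaffold_size[2]) > 1e-9 * retina_size[2]) {
    stop("retina and scaffold depth must match", call. = FALSE)
  }
  if (E_scaffold / E_retina < 1e4) {
    warning("scaffold/tissue stiffness ratio below 1e4: scaffold compliance ",
            "may no longer be negligible")
  }
  structure(
    list(scaffold_size = scaffold_size, retina_size = retina_size,
         E_scaffold = E_scaffold, nu_scaffold = nu_scaffold,
         E_retina = E_retina, nu_retina = nu_retina,
         rho_retina = rho_retina, load = load, gap = gap),
    class = "stretcher_config"
  )
}

#' @export
print.stretcher_config <- function(x, ...) {
  cat("Stretcher configuration:\n")
  cat(sprintf("  scaffolds: 2 x (%.3g x %.3g x %.3g) mm, E = %.3g GPa, gap %.3g mm\n",
              x$scaffold_size[1] * 1e3, x$scaffold_size[2] * 1e3,
              x$scaffold_size[3] * 1e3, x$E_scaffold / 1e9, x$gap * 1e3))
  cat(sprintf("  retina:    %.3g x %.3g x %.3g mm, E = %.4g Pa, nu = %.3g\n",
              x$retina_size[1] * 1e3, x$retina_size[2] * 1e3,
              x$retina_size[3] * 1e3, x$E_retina, x$nu_retina))
  cat(sprintf("  load:      %.3g mN in x on the moving scaffold sidewall\n",
              x$load * 1e3))
  invisible(x)
}

#' Read/write a stretcher configuration as YAML
#'
#' @param config a [stretcher_config]
#' @param path YAML file path
#' @return `write_stretcher_config` returns `path` invisibly;
#'   `read_stretcher_config` returns a [stretcher_config].
#' @export
write_stretcher_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_stretcher_config
#' @export
read_stretcher_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(stretcher_config, x)
}

## region ids of the stretcher mesh
.REG_FIXED <- 1L
.REG_MOVING <- 2L
.REG_RETINA <- 3L

#' Build the finite-element model of the stretcher
#'
#' Structured hexahedral mesh of the two scaffolds and the tissue slab on
#' top, with geometric grading of the element sizes toward the
#' scaffold-scaffold interface line (where the deformation localizes) and
#' toward the bottom of the tissue. When the scaffolds touch (`gap = 0`),
#' nodes on the coincident interface plane are duplicated so that the two
#' scaffolds carry no direct stiffness coupling - they interact only through
#' the tissue bonded to their top faces. Tissue nodes are shared with the
#' scaffold top-face nodes (perfect bonding); the single tissue node line
#' directly above the interface is bonded to neither scaffold.
#'
#' Boundary conditions: the fixed scaffold is clamped in all directions; all
#' nodes of the moving scaffold are constrained to `u_z = 0`; the outer x
#' sidewall of the moving scaffold is tagged for a uniform x traction.
#'
#' @param config a [stretcher_config]
#' @param resolution positive mesh-density multiplier; 1 is coarse (quick
#'   checks), 3 gives roughly 1e5 degrees of freedom
#' @return An object of class `stretcher_model`: the `hex_mesh`, dof count,
#'   node index sets (`clamped`, `uz_only`, `loaded_face`) and the element
#'   subset owning the loaded faces.
#' @export
build_model <- function(config, resolution = 3) {
  stopifnot(inherits(config, "stretcher_config"))
  if (resolution <= 0) stop("resolution must be positive", call. = FALSE)
  ws <- config$scaffold_size[1]; dep <- config$scaffold_size[2]
  hs <- config$scaffold_size[3]
  hr <- config$retina_size[3]
  gp <- config$gap

  nzr <- max(4L, round(6 * resolution))
  if (nzr < 2L) stop("resolution too coarse for the tissue layer", call. = FALSE)
  nxs <- max(6L, round(12 * resolution))
  ny <- max(4L, round(5 * resolution))
  nzs <- max(2L, round(2 * resolution))

  xl_left <- graded_levels(0, ws, nxs, toward = "end")
  xl_right <- graded_levels(ws + gp, 2 * ws + gp, nxs, toward = "start")
  xlev <- sort(unique(c(xl_left, xl_right,
                        if (gp > 0) seq(ws, ws + gp,
                                        length.out = max(2L, round(2 * resolution))))))
  ylev <- seq(0, dep, length.out = ny + 1L)
  zlev <- c(seq(0, hs, length.out = nzs + 1L),
            graded_levels(hs, hs + hr, nzr, toward = "start")[-1])

  classify <- function(xc, yc, zc) {
    reg <- rep(NA_integer_, length(xc))
    below <- zc < hs
    reg[below & xc < ws] <- .REG_FIXED
    reg[below & xc > ws + gp] <- .REG_MOVING
    reg[!below] <- .REG_RETINA
    reg
  }
  mesh <- hex_grid_mesh(xlev, ylev, zlev, classify)

  if (gp == 0) {
    mesh <- split_interface_nodes(mesh, x_plane = ws, z_top = hs)
  }

  nodes <- mesh$nodes
  xmax <- 2 * ws + gp
  tol <- 1e-9
  owner <- node_owner(mesh)
  clamped <- which(owner == .REG_FIXED)
  uz_only <- which(owner == .REG_MOVING)
  loaded_face <- which(abs(nodes[, 1] - xmax) < tol * xmax &
                         nodes[, 3] <= hs + tol)
  loaded_elems <- which(mesh$region == .REG_MOVING)

  structure(
    list(mesh = mesh, dof_count = 3L * nrow(nodes),
         clamped = clamped, uz_only = uz_only, loaded_face = loaded_face,
         loaded_elems = loaded_elems, resolution = resolution,
         config = config, cache = new.env(parent = emptyenv())),
    class = "stretcher_model"
  )
}

#' @export
print.stretcher_model <- function(x, ...) {
  cat(sprintf("Stretcher FE model: %d nodes, %d elements, %d dofs (resolution %.3g)\n",
              nrow(x$mesh$nodes), nrow(x$mesh$elems), x$dof_count,
              x$resolution))
  invisible(x)
}

## region id that "owns" each node for boundary conditions: scaffold regions
## claim their nodes (shared scaffold-top/tissue nodes are bonded to the
## scaffold and inherit its constraint), remaining nodes belong to the tissue
node_owner <- function(mesh) {
  owner <- rep(NA_integer_, nrow(mesh$nodes))
  for (reg in c(.REG_RETINA, .REG_MOVING, .REG_FIXED)) {
    ids <- unique(as.integer(mesh$elems[mesh$region == reg, ]))
    owner[ids] <- reg
  }
  owner
}

## Duplicate the nodes of the coincident scaffold-scaffold plane so the two
## plates are disconnected below the tissue. The right (moving) scaffold
## gets duplicates at every interface node it touches; at the scaffold-top
## level the left scaffold gets its own duplicate as well, leaving the
## original node to the tissue alone (bonded to neither plate on that line).
split_interface_nodes <- function(mesh, x_plane, z_top) {
  tol <- 1e-12 + 1e-9 * x_plane
  on_plane <- abs(mesh$nodes[, 1] - x_plane) < tol
  below <- mesh$nodes[, 3] < z_top - 1e-12
  at_top <- abs(mesh$nodes[, 3] - z_top) < 1e-12
  iface <- which(on_plane & (below | at_top))
  if (!length(iface)) return(mesh)

  nodes <- mesh$nodes
  elems <- mesh$elems
  new_id <- function(coords) {
    nodes <<- rbind(nodes, coords)
    nrow(nodes)
  }
  ## duplicates for the moving scaffold
  dup_right <- setNames(vapply(iface, function(i) new_id(nodes[i, ]),
                               numeric(1)), iface)
  mov <- which(mesh$region == .REG_MOVING)
  for (e in mov) {
    hit <- elems[e, ] %in% iface
    if (any(hit)) {
      elems[e, hit] <- dup_right[as.character(elems[e, hit])]
    }
  }
  ## duplicates for the fixed scaffold at the top level only
  iface_top <- which(on_plane & at_top)
  if (length(iface_top)) {
    dup_left <- setNames(vapply(iface_top, function(i) new_id(nodes[i, ]),
                                numeric(1)), iface_top)
    fixd <- which(mesh$region == .REG_FIXED)
    for (e in fixd) {
      hit <- elems[e, ] %in% iface_top
      if (any(hit)) {
        elems[e, hit] <- dup_left[as.character(elems[e, hit])]
      }
    }
  }
  mesh$nodes <- nodes
  mesh$elems <- elems
  mesh
}

#' Solve the forward stretcher problem
#'
#' Static small-strain linear elasticity with isotropic Hooke's law per
#' region (no gravity or inertia), trilinear hexahedra and selective reduced
#' integration of the dilatational term. Returns the full displacement field
#' and the mean x-displacement of the loaded sidewall.
#'
#' The global stiffness splits as `K = K_scaffold + E_retina * K_tissue(E=1)`;
#' both parts are assembled once and cached on the model, so repeated solves
#' at different tissue moduli (as in the inverse identification) only
#' refactorize.
#'
#' @param model a [build_model()] result
#' @param config a [stretcher_config]; geometry must be the one the model
#'   was built from
#' @param E_retina optional override of `config$E_retina` \[Pa\]
#' @return An object of class `fe_solution`: displacement field `u`
#'   (3 N vector), scalar `u_x` \[m\], solver `residual`, `dof_count`.
#' @examples
#' \donttest{
#' cfg <- stretcher_config()
#' mod <- build_model(cfg, resolution = 1)
#' sol <- solve_forward(mod, cfg)
#' sol$u_x * 1e6 # displacement of the moving scaffold in micrometres
#' }
#' @export
solve_forward <- function(model, config = model$config,
                          E_retina = config$E_retina) {
  stopifnot(inherits(model, "stretcher_model"))
  if (E_retina <= 0) stop("E_retina must be positive", call. = FALSE)
  parts <- model_stiffness_parts(model, config)
  K <- parts$K_scaffold + E_retina * parts$K_tissue_unit
  f <- fe_face_load(model$mesh, model$loaded_face, config$load, dof = 1L,
                    normal = 1L, elems = model$loaded_elems)
  fixed <- c(3L * model$clamped - 2L, 3L * model$clamped - 1L,
             3L * model$clamped, 3L * model$uz_only)
  sol <- fe_solve(K, f, fixed)
  ux_nodes <- matrix(sol$u, ncol = 3, byrow = TRUE)[model$loaded_face, 1]
  structure(
    list(u = sol$u, u_x = mean(ux_nodes), residual = sol$residual,
         dof_count = model$dof_count, E_retina = E_retina,
         load = config$load),
    class = "fe_solution"
  )
}

#' @export
print.fe_solution <- function(x, ...) {
  cat(sprintf("FE solution: u_x = %.4g um at E = %.4g Pa, load %.3g mN (residual %.2g)\n",
              x$u_x * 1e6, x$E_retina, x$load * 1e3, x$residual))
  invisible(x)
}

## assemble the E-independent stiffness parts once per model, cached in the
## model's environment; keyed by the material parameters so config tweaks
## refresh the cache
model_stiffness_parts <- function(model, config) {
  key <- paste(config$E_scaffold, config$nu_scaffold, config$nu_retina)
  cache <- get0("stiffness", envir = model$cache, inherits = FALSE)
  if (!is.null(cache) && identical(cache$key, key)) return(cache)
  K_scaffold <- fe_assemble(
    model$mesh,
    data.frame(region = c(.REG_FIXED, .REG_MOVING),
               E = config$E_scaffold, nu = config$nu_scaffold),
    regions = c(.REG_FIXED, .REG_MOVING))
  K_tissue_unit <- fe_assemble(
    model$mesh,
    data.frame(region = .REG_RETINA, E = 1, nu = config$nu_retina),
    regions = .REG_RETINA)
  cache <- list(key = key, K_scaffold = K_scaffold,
                K_tissue_unit = K_tissue_unit)
  assign("stiffness", cache, envir = model$cache)
  cache
}

#' Effective structural stiffness of the stretcher
#'
#' Ratio of the applied load to the resulting scaffold displacement,
#' `load / u_x` \[N/m\] - the quantity that corresponds to the regime-1
#' elastic constant measured in a stretching experiment.
#'
#' @inheritParams solve_forward
#' @return Stiffness \[N/m\].
#' @export
effective_stiffness <- function(model, config = model$config,
                                E_retina = config$E_retina) {
  sol <- solve_forward(model, config, E_retina)
  if (sol$u_x <= 0) {
    stop("degenerate result: non-positive scaffold displacement",
         call. = FALSE)
  }
  config$load / sol$u_x
}

#' Forward solve with rigid scaffolds
#'
#' Fast variant in which only the tissue is meshed: the fixed scaffold
#' becomes a clamped boundary for the tissue bottom on its side, and the
#' moving scaffold a rigid in-plane constraint (all its bonded tissue nodes
#' share one x-translation, with `u_y = u_z = 0`) that carries the load.
#' Agrees with the full elastic model to well within 1% because the
#' scaffolds are ~1e8 times stiffer than the tissue.
#'
#' @inheritParams solve_forward
#' @param resolution mesh-density multiplier as in [build_model()]
#' @param nxs,ny,nzr optional per-axis element-count overrides (x elements
#'   per scaffold side, y elements, z elements through the tissue); useful
#'   for anisotropic refinement studies
#' @return An `fe_solution` (the displacement field covers only the tissue).
#' @export
solve_forward_rigid <- function(config, resolution = 3,
                                E_retina = config$E_retina,
                                nxs = NULL, ny = NULL, nzr = NULL) {
  stopifnot(inherits(config, "stretcher_config"))
  ws <- config$scaffold_size[1]; dep <- config$scaffold_size[2]
  hs <- config$scaffold_size[3]; hr <- config$retina_size[3]
  gp <- config$gap
  if (is.null(nzr)) nzr <- max(4L, round(6 * resolution))
  if (is.null(nxs)) nxs <- max(6L, round(12 * resolution))
  if (is.null(ny)) ny <- max(4L, round(5 * resolution))
  xl_left <- graded_levels(0, ws, nxs, toward = "end")
  xl_right <- graded_levels(ws + gp, 2 * ws + gp, nxs, toward = "start")
  xlev <- sort(unique(c(xl_left, xl_right,
                        if (gp > 0) seq(ws, ws + gp,
                                        length.out = max(2L, round(2 * resolution))))))
  ylev <- seq(0, dep, length.out = ny + 1L)
  zlev <- graded_levels(hs, hs + hr, nzr, toward = "start")
  mesh <- hex_grid_mesh(xlev, ylev, zlev)
  K <- fe_assemble(mesh, data.frame(region = 1L, E = E_retina,
                                    nu = config$nu_retina))
  nodes <- mesh$nodes
  tol <- 1e-12 + 1e-9 * ws
  bottom <- abs(nodes[, 3] - hs) < 1e-12
  if (gp > 0) {
    ## bonded up to and including the plate edges
    on_fixed <- which(bottom & nodes[, 1] < ws + tol)
    on_moving <- which(bottom & nodes[, 1] > ws + gp - tol)
  } else {
    ## touching plates: the single node line above the interface stays free,
    ## matching the duplicated-node treatment of the full elastic model
    on_fixed <- which(bottom & nodes[, 1] < ws - tol)
    on_moving <- which(bottom & nodes[, 1] > ws + tol)
  }
  nn <- nrow(nodes)
  fixed <- c(3L * on_fixed - 2L, 3L * on_fixed - 1L, 3L * on_fixed,
             3L * on_moving - 1L, 3L * on_moving)
  couple <- integer(3L * nn)
  couple[3L * on_moving - 2L] <- 1L
  f <- numeric(3L * nn)
  f[3L * on_moving[1] - 2L] <- config$load
  sol <- fe_solve(K, f, fixed, couple)
  u_x <- sol$u[3L * on_moving[1] - 2L]
  structure(
    list(u = sol$u, u_x = u_x, residual = sol$residual,
         dof_count = 3L * nn, E_retina = E_retina, load = config$load),
    class = "fe_solution"
  )
}
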