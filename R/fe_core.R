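## Small-strain linear-elasticity FE core on axis-aligned 8-node hexahedra.
##
## Near-incompressible materials (nu -> 0.5) lock with fully integrated
## trilinear elements, so the element stiffness uses selective reduced
## integration: the shear/deviatoric (mu) part with the full 2x2x2 Gauss
## rule, the dilatational (lambda) part with the 1-point rule.

## trilinear shape-function derivatives on the reference cube [-1,1]^3
hex8_dshape <- function(xi, eta, zeta) {
  s <- matrix(c(-1, -1, -1,
                 1, -1, -1,
                 1,  1, -1,
                -1,  1, -1,
                -1, -1,  1,
                 1, -1,  1,
                 1,  1,  1,
                -1,  1,  1), ncol = 3, byrow = TRUE)
  dN <- matrix(0, 8, 3)
  for (a in 1:8) {
    dN[a, 1] <- s[a, 1] * (1 + s[a, 2] * eta) * (1 + s[a, 3] * zeta) / 8
    dN[a, 2] <- s[a, 2] * (1 + s[a, 1] * xi) * (1 + s[a, 3] * zeta) / 8
    dN[a, 3] <- s[a, 3] * (1 + s[a, 1] * xi) * (1 + s[a, 2] * eta) / 8
  }
  dN
}

hex8_bmat <- function(dNdx) {
  B <- matrix(0, 6, 24)
  for (a in 1:8) {
    c0 <- 3 * (a - 1)
    B[1, c0 + 1] <- dNdx[a, 1]
    B[2, c0 + 2] <- dNdx[a, 2]
    B[3, c0 + 3] <- dNdx[a, 3]
    B[4, c0 + 1] <- dNdx[a, 2]; B[4, c0 + 2] <- dNdx[a, 1]
    B[5, c0 + 2] <- dNdx[a, 3]; B[5, c0 + 3] <- dNdx[a, 2]
    B[6, c0 + 1] <- dNdx[a, 3]; B[6, c0 + 3] <- dNdx[a, 1]
  }
  B
}

#' Element stiffness of an axis-aligned hexahedron
#'
#' 24x24 stiffness of a rectangular 8-node hexahedron of edge lengths
#' `dx, dy, dz` for an isotropic material, using selective reduced
#' integration of the dilatational term (full 2x2x2 rule on the shear part,
#' 1-point rule on the lambda part) to avoid volumetric locking at Poisson
#' ratios close to 0.5.
#'
#' @param dx,dy,dz element edge lengths \[m\]
#' @param E Young's modulus \[Pa\]
#' @param nu Poisson ratio
#' @param sri use selective reduced integration (default `TRUE`)
#' @return 24x24 numeric matrix; node order: bottom face counter-clockwise
#'   then top face, dofs (ux, uy, uz) per node.
#' @export
hex8_stiffness <- function(dx, dy, dz, E, nu, sri = TRUE) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D_mu <- diag(c(2, 2, 2, 1, 1, 1) * mu)
  D_lam <- matrix(0, 6, 6)
  D_lam[1:3, 1:3] <- lam
  Jdiag <- c(dx, dy, dz) / 2
  detJ <- prod(Jdiag)
  gp <- 1 / sqrt(3)
  K <- matrix(0, 24, 24)
  for (xi in c(-gp, gp)) for (eta in c(-gp, gp)) for (zeta in c(-gp, gp)) {
    dNdx <- sweep(hex8_dshape(xi, eta, zeta), 2, Jdiag, "/")
    B <- hex8_bmat(dNdx)
    D <- if (sri) D_mu else D_mu + D_lam
    K <- K + detJ * t(B) %*% D %*% B
  }
  if (sri) {
    dNdx0 <- sweep(hex8_dshape(0, 0, 0), 2, Jdiag, "/")
    B0 <- hex8_bmat(dNdx0)
    K <- K + 8 * detJ * t(B0) %*% D_lam %*% B0
  }
  (K + t(K)) / 2
}

#' Structured hexahedral mesh from grid levels
#'
#' Builds a tensor-product mesh of axis-aligned hexahedra from coordinate
#' levels along each axis. Cells for which `classify` returns `NA` are
#' omitted (voids); otherwise its return value is stored as the element's
#' region id.
#'
#' @param xlev,ylev,zlev strictly increasing coordinate levels \[m\]
#' @param classify `function(xc, yc, zc)` of cell centres returning an
#'   integer region id or `NA` (vectorized)
#' @return A `hex_mesh`: `nodes` (N x 3), `elems` (M x 8 node indices),
#'   `region` (length M), and the grid levels.
#' @export
hex_grid_mesh <- function(xlev, ylev, zlev,
                          classify = function(xc, yc, zc) rep(1L, length(xc))) {
  stopifnot(all(diff(xlev) > 0), all(diff(ylev) > 0), all(diff(zlev) > 0))
  nx <- length(xlev); ny <- length(ylev); nz <- length(zlev)
  nid <- function(ix, iy, iz) ix + nx * (iy - 1L) + nx * ny * (iz - 1L)
  nodes <- cbind(rep(xlev, times = ny * nz),
                 rep(rep(ylev, each = nx), times = nz),
                 rep(zlev, each = nx * ny))
  cells <- expand.grid(ix = seq_len(nx - 1L), iy = seq_len(ny - 1L),
                       iz = seq_len(nz - 1L))
  xc <- (xlev[cells$ix] + xlev[cells$ix + 1L]) / 2
  yc <- (ylev[cells$iy] + ylev[cells$iy + 1L]) / 2
  zc <- (zlev[cells$iz] + zlev[cells$iz + 1L]) / 2
  reg <- classify(xc, yc, zc)
  keep <- !is.na(reg)
  cells <- cells[keep, , drop = FALSE]
  reg <- reg[keep]
  ix <- cells$ix; iy <- cells$iy; iz <- cells$iz
  elems <- cbind(nid(ix, iy, iz),       nid(ix + 1L, iy, iz),
                 nid(ix + 1L, iy + 1L, iz), nid(ix, iy + 1L, iz),
                 nid(ix, iy, iz + 1L),  nid(ix + 1L, iy, iz + 1L),
                 nid(ix + 1L, iy + 1L, iz + 1L), nid(ix, iy + 1L, iz + 1L))
  structure(list(nodes = nodes, elems = elems, region = as.integer(reg),
                 xlev = xlev, ylev = ylev, zlev = zlev),
            class = "hex_mesh")
}

#' @export
print.hex_mesh <- function(x, ...) {
  cat(sprintf("Hexahedral mesh: %d nodes, %d elements, %d region(s)\n",
              nrow(x$nodes), nrow(x$elems), length(unique(x$region))))
  invisible(x)
}

## element sizes (dx, dy, dz) per element, from node coordinates
elem_sizes <- function(mesh) {
  n1 <- mesh$elems[, 1]; n7 <- mesh$elems[, 7]
  cbind(mesh$nodes[n7, 1] - mesh$nodes[n1, 1],
        mesh$nodes[n7, 2] - mesh$nodes[n1, 2],
        mesh$nodes[n7, 3] - mesh$nodes[n1, 3])
}

#' Assemble the global stiffness matrix
#'
#' Sums selective-reduced-integration element stiffnesses into a sparse
#' symmetric global matrix. Elements are grouped by (size, material) so each
#' distinct element stiffness is computed once.
#'
#' @param mesh a `hex_mesh`
#' @param materials data.frame with columns `region`, `E`, `nu`
#' @param regions optional subset of region ids to assemble (others skipped);
#'   used to split the stiffness into per-material parts
#' @return A `dgCMatrix` of size (3 N) x (3 N), dof order (ux, uy, uz) per
#'   node.
#' @export
fe_assemble <- function(mesh, materials, regions = NULL) {
  stopifnot(inherits(mesh, "hex_mesh"))
  ndof <- 3L * nrow(mesh$nodes)
  sel <- if (is.null(regions)) seq_len(nrow(mesh$elems)) else
    which(mesh$region %in% regions)
  if (!length(sel)) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(ndof, ndof)))
  }
  sz <- elem_sizes(mesh)[sel, , drop = FALSE]
  reg <- mesh$region[sel]
  mat_idx <- match(reg, materials$region)
  if (anyNA(mat_idx)) stop("material missing for some region", call. = FALSE)
  key <- paste(signif(sz[, 1], 12), signif(sz[, 2], 12), signif(sz[, 3], 12),
               mat_idx)
  groups <- split(seq_along(sel), key)
  ilist <- vector("list", length(groups))
  jlist <- vector("list", length(groups))
  xlist <- vector("list", length(groups))
  g <- 0L
  for (grp in groups) {
    g <- g + 1L
    e1 <- grp[1]
    Ke <- hex8_stiffness(sz[e1, 1], sz[e1, 2], sz[e1, 3],
                         E = materials$E[mat_idx[e1]],
                         nu = materials$nu[mat_idx[e1]])
    conn <- mesh$elems[sel[grp], , drop = FALSE]
    ## dof indices per element: 24 columns
    edof <- matrix(0L, nrow(conn), 24L)
    edof[, seq(1, 24, by = 3)] <- 3L * conn - 2L
    edof[, seq(2, 24, by = 3)] <- 3L * conn - 1L
    edof[, seq(3, 24, by = 3)] <- 3L * conn
    ii <- edof[, rep(seq_len(24), times = 24), drop = FALSE]
    jj <- edof[, rep(seq_len(24), each = 24), drop = FALSE]
    ilist[[g]] <- as.integer(ii)
    jlist[[g]] <- as.integer(jj)
    xlist[[g]] <- rep(as.numeric(Ke), each = nrow(conn))
  }
  Matrix::sparseMatrix(i = unlist(ilist), j = unlist(jlist),
                       x = unlist(xlist), dims = c(ndof, ndof))
}

#' Consistent nodal forces for a uniform traction on a boundary face set
#'
#' Distributes a total force over the bilinear faces spanned by a set of
#' boundary nodes (each face contributes a quarter of its area to each of
#' its nodes), i.e. uniform traction.
#'
#' @param mesh a `hex_mesh`
#' @param face_nodes node indices on the loaded plane
#' @param total_force total force \[N\]
#' @param dof loaded direction: 1 = x, 2 = y, 3 = z
#' @param normal axis perpendicular to the face plane (1, 2 or 3)
#' @param elems optional element subset owning the loaded faces
#' @return Force vector of length 3 N.
#' @export
fe_face_load <- function(mesh, face_nodes, total_force, dof = 1L,
                         normal = 1L, elems = NULL) {
  ndof <- 3L * nrow(mesh$nodes)
  f <- numeric(ndof)
  on_face <- rep(FALSE, nrow(mesh$nodes))
  on_face[face_nodes] <- TRUE
  esel <- if (is.null(elems)) seq_len(nrow(mesh$elems)) else elems
  tang <- setdiff(1:3, normal)
  w <- numeric(nrow(mesh$nodes))
  sz <- elem_sizes(mesh)
  for (e in esel) {
    conn <- mesh$elems[e, ]
    hit <- conn[on_face[conn]]
    if (length(hit) != 4L) next
    area <- sz[e, tang[1]] * sz[e, tang[2]]
    w[hit] <- w[hit] + area / 4
  }
  if (sum(w) == 0) stop("no loaded faces found", call. = FALSE)
  w <- w / sum(w)
  f[3L * (which(w > 0)) - (3L - dof)] <- total_force * w[w > 0]
  f
}

#' Solve the constrained static system
#'
#' Applies homogeneous Dirichlet constraints (and optional master-slave
#' couplings) to the assembled system and solves by sparse Cholesky
#' factorization.
#'
#' @param K global stiffness (`dgCMatrix`)
#' @param f global force vector
#' @param fixed integer or logical index of constrained (zero) dofs
#' @param couple optional integer vector, length = ndof: for each dof either
#'   0 (ordinary) or a group id; all dofs sharing a group id are forced equal
#'   (their rows/columns are summed onto one unknown)
#' @return List with the full displacement vector `u` \[m\] and the relative
#'   residual `residual` of the reduced solve.
#' @export
fe_solve <- function(K, f, fixed, couple = NULL) {
  ndof <- length(f)
  isfix <- rep(FALSE, ndof)
  isfix[fixed] <- TRUE
  ## dofs never touched by any element (void-region grid nodes) are inert
  isfix[Matrix::diag(K) == 0] <- TRUE
  map <- integer(ndof) # reduced index per dof; 0 = eliminated
  if (is.null(couple)) couple <- integer(ndof)
  free <- which(!isfix & couple == 0L)
  map[free] <- seq_along(free)
  nred <- length(free)
  gids <- unique(couple[couple != 0L & !isfix])
  for (gid in gids) {
    nred <- nred + 1L
    map[couple == gid & !isfix] <- nred
  }
  Kt <- methods::as(K, "TsparseMatrix")
  ii <- map[Kt@i + 1L]; jj <- map[Kt@j + 1L]
  keep <- ii > 0L & jj > 0L
  Kred <- Matrix::sparseMatrix(i = ii[keep], j = jj[keep], x = Kt@x[keep],
                               dims = c(nred, nred), symmetric = FALSE)
  idx <- which(map > 0L)
  fred <- numeric(nred)
  acc <- rowsum(f[idx], map[idx]) # grouped sums, rows ordered by group id
  fred[as.integer(rownames(acc))] <- acc[, 1]
  Ksym <- Matrix::forceSymmetric(Kred)
  ured <- tryCatch(
    as.numeric(Matrix::solve(Matrix::Cholesky(Ksym, LDL = FALSE), fred,
                             system = "A")),
    error = function(e) stop("solver error: ", conditionMessage(e),
                             call. = FALSE))
  res <- sqrt(sum((as.numeric(Kred %*% ured) - fred)^2)) /
    max(sqrt(sum(fred^2)), .Machine$double.eps)
  u <- numeric(ndof)
  u[map > 0L] <- ured[map[map > 0L]]
  list(u = u, residual = res)
}

#' Export a mesh and displacement field as VTK unstructured grid (VTU)
#'
#' Plain-XML ascii VTU with the displacement as a point-data vector and the
#' region id as cell data, viewable in ParaView.
#'
#' @param mesh a `hex_mesh`
#' @param u displacement vector (length 3 N) or NULL
#' @param path output file
#' @return `path`, invisibly.
#' @export
write_vtu <- function(mesh, u = NULL, path) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$elems)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid><Piece NumberOfPoints="', n,
    '" NumberOfCells="', m, '">')
  w('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(apply(mesh$nodes, 1, paste, collapse = " "), con)
  w('</DataArray></Points>')
  w('<Cells><DataArray type="Int32" Name="connectivity" format="ascii">')
  writeLines(apply(mesh$elems - 1L, 1, paste, collapse = " "), con)
  w('</DataArray><DataArray type="Int32" Name="offsets" format="ascii">')
  writeLines(paste(seq_len(m) * 8L), con)
  w('</DataArray><DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(rep("12", m), con)
  w('</DataArray></Cells>')
  if (!is.null(u)) {
    um <- matrix(u, ncol = 3, byrow = TRUE)
    w('<PointData Vectors="displacement">')
    w('<DataArray type="Float64" Name="displacement" NumberOfComponents="3" format="ascii">')
    writeLines(apply(um, 1, paste, collapse = " "), con)
    w('</DataArray></PointData>')
  }
  w('<CellData Scalars="region">')
  w('<DataArray type="Int32" Name="region" format="ascii">')
  writeLines(paste(mesh$region), con)
  w('</DataArray></CellData>')
  w('</Piece></UnstructuredGrid></VTKFile>')
  invisible(path)
}

## geometric grading of n intervals over [a, b]; smallest interval at the
## `toward` end, neighbouring sizes in ratio `ratio`
graded_levels <- function(a, b, n, toward = c("end", "start"), ratio = 1.25) {
  toward <- match.arg(toward)
  r <- ratio^(seq_len(n) - 1L)
  if (toward == "end") r <- rev(r)
  widths <- r / sum(r) * (b - a)
  c(a, a + cumsum(widths))
}
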