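#' Element stiffness matrix of a cubic trilinear hexahedron
#'
#' Standard 8-node isoparametric hexahedral stiffness for a cube of edge
#' `h_m` and isotropic elasticity `(E_pa, nu)`, integrated with 2x2x2 Gauss
#' quadrature.  Node order: x fastest, then y, then z; three displacement
#' dofs per node.
#'
#' @param E_pa Young's modulus in Pa.
#' @param nu Poisson's ratio.
#' @param h_m element edge in metres.
#' @return 24 x 24 symmetric stiffness matrix (N/m).
#' @keywords internal
hex_stiffness <- function(E_pa, nu, h_m) {
  D <- elasticity_matrix(E_pa, nu)
  g <- 1 / sqrt(3)
  corners <- as.matrix(expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1)))
  Ke <- matrix(0, 24, 24)
  detJ <- (h_m / 2)^3
  for (gz in c(-g, g)) for (gy in c(-g, g)) for (gx in c(-g, g)) {
    B <- hex_bmat(c(gx, gy, gz), corners, h_m)
    Ke <- Ke + t(B) %*% D %*% B * detJ
  }
  (Ke + t(Ke)) / 2
}

# isotropic elasticity matrix, engineering shear strains,
# order (xx, yy, zz, xy, yz, xz)
elasticity_matrix <- function(E_pa, nu) {
  lam <- E_pa * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E_pa / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  D
}

# strain-displacement matrix (6 x 24) at natural coordinates xi
hex_bmat <- function(xi, corners, h_m) {
  # dN/dxi for N_a = prod (1 + xi_a * xi)/2 ; then dN/dx = dN/dxi * 2/h
  dN <- matrix(0, 8, 3)
  for (a in 1:8) {
    s <- corners[a, ]
    dN[a, 1] <- s[1] / 2 * (1 + s[2] * xi[2]) / 2 * (1 + s[3] * xi[3]) / 2 * 4
    dN[a, 2] <- (1 + s[1] * xi[1]) / 2 * s[2] / 2 * (1 + s[3] * xi[3]) / 2 * 4
    dN[a, 3] <- (1 + s[1] * xi[1]) / 2 * (1 + s[2] * xi[2]) / 2 * s[3] / 2 * 4
  }
  dN <- dN / 2 * (2 / h_m) / 2  # d/dxi -> d/dx with x = h*xi/2
  B <- matrix(0, 6, 24)
  for (a in 1:8) {
    c0 <- 3 * (a - 1)
    B[1, c0 + 1] <- dN[a, 1]
    B[2, c0 + 2] <- dN[a, 2]
    B[3, c0 + 3] <- dN[a, 3]
    B[4, c0 + 1] <- dN[a, 2]; B[4, c0 + 2] <- dN[a, 1]
    B[5, c0 + 2] <- dN[a, 3]; B[5, c0 + 3] <- dN[a, 2]
    B[6, c0 + 1] <- dN[a, 3]; B[6, c0 + 3] <- dN[a, 1]
  }
  B
}

#' Assemble the voxel finite-element elasticity operator
#'
#' Builds the sparse symmetric stiffness matrix of the solid phase using one
#' trilinear hexahedral element per solid voxel.  The operator is reusable
#' across time steps: boundary conditions are applied separately by
#' [apply_solid_bcs()].
#'
#' @param domain a [voxel_domain()]; the solid phase must be non-empty and
#'   face-connected (see [cleanup_connectivity()]).
#' @param mat a [material_spec()].
#' @return an elasticity system handle (class `solid_system`) holding the
#'   stiffness matrix, node numbering and element table.
#' @export
assemble_elasticity <- function(domain, mat) {
  stopifnot(inherits(domain, "voxel_domain"), inherits(mat, "material_spec"))
  lab <- domain$labels
  d <- dim(lab)
  solid_cells <- which(lab == 1L)
  if (!length(solid_cells)) stop("solid phase is empty")
  comp <- label_components(lab == 1L)
  if (comp$ncomp != 1L)
    stop("solid phase is not a single connected component; run cleanup_connectivity() first")
  h_m <- domain$pitch_um * 1e-6
  Ke <- hex_stiffness(mat$E_gpa * 1e9, mat$nu, h_m)

  nd <- d + 1L  # node grid dims
  ci <- arrayInd(solid_cells, d)
  bits <- as.matrix(expand.grid(bx = 0:1, by = 0:1, bz = 0:1))
  # full-grid node index for the 8 corners of every element
  enodes <- matrix(0L, nrow = length(solid_cells), ncol = 8L)
  for (a in 1:8) {
    enodes[, a] <- (ci[, 1] + bits[a, 1]) +
      nd[1] * ((ci[, 2] + bits[a, 2] - 1L) +
                 nd[2] * (ci[, 3] + bits[a, 3] - 1L))
  }
  nodes <- sort(unique(as.vector(enodes)))
  nmap <- integer(prod(nd))
  nmap[nodes] <- seq_along(nodes)
  enodes_c <- matrix(nmap[enodes], nrow = nrow(enodes))

  # element dof table (E x 24): dofs (3*(node-1)+1..3) in node order
  dofmat <- matrix(0L, nrow = nrow(enodes_c), ncol = 24L)
  for (a in 1:8)
    for (c0 in 1:3)
      dofmat[, 3L * (a - 1L) + c0] <- 3L * (enodes_c[, a] - 1L) + c0

  aidx <- rep(1:24, times = 24)
  bidx <- rep(1:24, each = 24)
  ii <- dofmat[, aidx]
  jj <- dofmat[, bidx]
  xx <- rep(as.vector(Ke), each = nrow(dofmat))
  ndof <- 3L * length(nodes)
  K <- Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj), x = xx,
                            dims = c(ndof, ndof))
  rm(ii, jj, xx)

  nai <- arrayInd(nodes, nd)
  structure(
    list(K = K, domain = domain, mat = mat, h_m = h_m,
         nodes = nodes, node_ijk = nai, nmap = nmap, node_grid = nd,
         elem_cells = solid_cells, elem_ijk = ci, enodes = enodes_c,
         dofmat = dofmat, Ke = Ke,
         cache = new.env(parent = emptyenv())),
    class = "solid_system")
}

#' Apply the loading-cycle boundary conditions to the solid system
#'
#' Fixes the bottom core face (all components zero), prescribes the
#' displacement waveform on the top core face along the loading axis
#' (in-plane components left free), and adds the spring-foundation (Robin)
#' stiffness to the normal displacement component of the four lateral core
#' faces.
#'
#' @param system a `solid_system` from [assemble_elasticity()].
#' @param t time in seconds at which to evaluate the displacement waveform.
#' @param load a [load_spec()].
#' @param u_top_um optional explicit top-face displacement (micrometres),
#'   overriding the waveform; used for unit solves.
#' @return a constrained system (class `solid_system_bc`) ready for
#'   [solve_solid()].
#' @export
apply_solid_bcs <- function(system, t, load = load_spec(), u_top_um = NULL) {
  stopifnot(inherits(system, "solid_system"))
  dom <- system$domain
  a <- dom$loading_axis
  m <- dom$margin_vox
  nc <- dom$core_dim
  nij <- system$node_ijk
  bottom_nodes <- which(nij[, a] == m + 1L)
  top_nodes <- which(nij[, a] == m + nc[a] + 1L)
  if (!length(bottom_nodes) || !length(top_nodes))
    stop("solid phase does not reach the top/bottom loading faces")
  if (is.null(u_top_um)) u_top_um <- displacement_waveform(t, load)

  ndof <- nrow(system$K)
  fixed <- c(outer(3L * (bottom_nodes - 1L), 1:3, `+`))
  top_dof <- 3L * (top_nodes - 1L) + a
  fixed_val <- c(rep(0, length(fixed)), rep(u_top_um * 1e-6, length(top_dof)))
  fixed <- c(fixed, top_dof)

  spring <- spring_diagonal(system, load)
  structure(
    list(base = system, t = t, load = load, u_top_um = u_top_um,
         fixed = fixed, fixed_val = fixed_val, spring = spring),
    class = "solid_system_bc")
}

# diagonal spring-foundation contribution (N/m per dof): each solid voxel
# face on a lateral core boundary contributes k*h^2/4 to the face-normal
# dof of its four nodes
spring_diagonal <- function(system, load) {
  dom <- system$domain
  ndof <- nrow(system$K)
  diagv <- numeric(ndof)
  if (load$k_pa_per_m == 0) return(diagv)
  a_load <- dom$loading_axis
  m <- dom$margin_vox
  nc <- dom$core_dim
  d <- dim(dom$labels)
  nd <- system$node_grid
  kface <- load$k_pa_per_m * system$h_m^2 / 4
  ci <- system$elem_ijk
  for (a in setdiff(1:3, a_load)) {
    for (side in c("lo", "hi")) {
      cell_layer <- if (side == "lo") m + 1L else m + nc[a]
      sel <- which(ci[, a] == cell_layer)
      if (!length(sel)) next
      # the 4 nodes of the boundary face of each selected element; a node
      # shared by f faces receives f * k h^2 / 4
      face_bits <- if (side == "lo") 0L else 1L
      bits <- as.matrix(expand.grid(bx = 0:1, by = 0:1, bz = 0:1))
      keep <- which(bits[, a] == face_bits)
      cnt <- table(as.vector(system$enodes[sel, keep]))
      diagv[3L * (as.integer(names(cnt)) - 1L) + a] <-
        diagv[3L * (as.integer(names(cnt)) - 1L) + a] +
        kface * as.integer(cnt)
    }
  }
  diagv
}

#' Solve the constrained elasticity system
#'
#' Sparse Cholesky solve of the free degrees of freedom given the prescribed
#' displacements; the factorisation is cached on the system handle and
#' reused across time steps (the constrained dof pattern and spring
#' stiffness do not change within a cycle).  Element stresses are evaluated
#' from the strain-displacement matrix at element centroids.
#'
#' @param system a `solid_system_bc` from [apply_solid_bcs()].
#' @return a `solid_solution`: nodal displacements (micrometres), element
#'   centroid stresses and von Mises stress (MPa), solve residual.
#' @export
solve_solid <- function(system) {
  stopifnot(inherits(system, "solid_system_bc"))
  base <- system$base
  K <- base$K
  ndof <- nrow(K)
  fixed <- system$fixed
  free <- setdiff(seq_len(ndof), fixed)
  u <- numeric(ndof)
  u[fixed] <- system$fixed_val

  cache <- base$cache
  key <- paste0("chol_", length(fixed), "_", sum(system$spring))
  Ks <- K + Matrix::Diagonal(ndof, system$spring)
  if (is.null(cache[[key]])) {
    Kff <- Ks[free, free]
    cache[[key]] <- list(chol = Matrix::Cholesky(Matrix::forceSymmetric(Kff),
                                                 LDL = FALSE, super = TRUE),
                         free = free)
  }
  ch <- cache[[key]]
  rhs <- -(Ks[free, fixed] %*% u[fixed])
  uf <- as.numeric(Matrix::solve(ch$chol, rhs, system = "A"))
  u[free] <- uf

  resid_vec <- Ks[free, , drop = FALSE] %*% u
  rel_res <- sqrt(sum(resid_vec^2)) / max(sqrt(sum(rhs^2)), 1e-300)
  if (!is.finite(rel_res) || rel_res > 1e-6)
    stop(sprintf("solid solve failed to converge (relative residual %.3e)",
                 rel_res))

  stress <- element_stress(base, u)
  vm <- von_mises(stress)
  cent <- (base$elem_ijk - 0.5) * base$domain$pitch_um
  structure(
    list(u_um = matrix(u, ncol = 3, byrow = TRUE) * 1e6,
         node_ijk = base$node_ijk,
         node_xyz_um = (base$node_ijk - 1) * base$domain$pitch_um,
         stress_mpa = stress / 1e6,
         von_mises_mpa = vm / 1e6,
         elem_centroid_um = cent,
         time = system$t,
         u_top_um = system$u_top_um,
         residual = rel_res),
    class = "solid_solution")
}

# element centroid stresses (Pa), rows (xx, yy, zz, xy, yz, xz)
element_stress <- function(base, u) {
  D <- elasticity_matrix(base$mat$E_gpa * 1e9, base$mat$nu)
  corners <- as.matrix(expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1)))
  B0 <- hex_bmat(c(0, 0, 0), corners, base$h_m)
  DB <- D %*% B0  # 6 x 24
  ue <- matrix(u[t(base$dofmat)], nrow = 24L)
  t(DB %*% ue)
}

#' Von Mises equivalent stress
#'
#' `sqrt(0.5 * ((s11-s22)^2 + (s22-s33)^2 + (s33-s11)^2) + 3*(s12^2 + s23^2
#' + s13^2))`.
#'
#' @param stress either a symmetric 3x3 stress tensor, a length-6 vector, or
#'   an N x 6 matrix with columns `(xx, yy, zz, xy, yz, xz)`.
#' @return non-negative scalar (or vector of length N), same units as the
#'   input.
#' @export
von_mises <- function(stress) {
  if (is.matrix(stress) && all(dim(stress) == c(3, 3))) {
    stress <- c(stress[1, 1], stress[2, 2], stress[3, 3],
                stress[1, 2], stress[2, 3], stress[1, 3])
  }
  if (is.null(dim(stress))) stress <- matrix(stress, nrow = 1)
  s11 <- stress[, 1]; s22 <- stress[, 2]; s33 <- stress[, 3]
  s12 <- stress[, 4]; s23 <- stress[, 5]; s13 <- stress[, 6]
  out <- sqrt(0.5 * ((s11 - s22)^2 + (s22 - s33)^2 + (s33 - s11)^2) +
                3 * (s12^2 + s23^2 + s13^2))
  if (length(out) == 1L) out[[1]] else out
}

#' Strain energy of a solid solution
#'
#' `0.5 * u' K u`, useful for mesh-convergence and work-balance checks.
#'
#' @param system a `solid_system_bc`.
#' @param sol the corresponding `solid_solution`.
#' @return energy in joules.
#' @export
strain_energy <- function(system, sol) {
  u <- as.vector(t(sol$u_um)) * 1e-6
  Ks <- system$base$K + Matrix::Diagonal(length(u), system$spring)
  0.5 * sum(u * as.numeric(Ks %*% u))
}
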