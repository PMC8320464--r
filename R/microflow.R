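#' Parameters for the micro-scale Stokes flow solve
#'
#' @param air_density air density rho_a (kg/m^3).
#' @param air_viscosity dynamic viscosity mu_a (kg/(m s)).
#' @param slip_length Navier slip length at fiber surfaces (m); 0 means
#'   no-slip. First-order slip: the tangential velocity extrapolates to zero
#'   a distance `slip_length` behind the wall, which lowers the pressure drop
#'   relative to no-slip for the same mass flux.
#' @param convergence_tol dimensionless tolerance on the divergence residual
#'   (max cell divergence times h over the face velocity).
#' @param max_iter cap on pressure conjugate-gradient iterations.
#' @return an object of class `flow_params`.
#' @export
flow_params <- function(air_density = 1.204, air_viscosity = 1.834e-5,
                        slip_length = 0, convergence_tol = 1e-6,
                        max_iter = 1500) {
  stopifnot(air_viscosity > 0, slip_length >= 0)
  structure(list(rho = air_density, mu = air_viscosity,
                 slip_length = slip_length, tol = convergence_tol,
                 max_iter = max_iter),
            class = "flow_params")
}

# circular shift of a 3-D array along one axis: element i of the result is
# a[i - by] (periodic), so by = -1 fetches the i+1 neighbour
shift3 <- function(a, axis, by) {
  dm <- dim(a)
  idx <- ((seq_len(dm[axis]) - 1 + by) %% dm[axis]) + 1
  switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

# non-periodic shift along z, filling vacated slices with `fill`
shiftz_fill <- function(a, by, fill) {
  dm <- dim(a); nz <- dm[3]
  out <- array(fill, dm)
  if (by == 1) {
    if (nz > 1) out[, , 1:(nz - 1)] <- a[, , 2:nz]
  } else {
    if (nz > 1) out[, , 2:nz] <- a[, , 1:(nz - 1)]
  }
  out
}

# fluid cells reachable from the inlet slice through 6-connected fluid
reach_from_inlet <- function(solid) {
  fluid <- !solid
  nz <- dim(fluid)[3]
  reach <- array(FALSE, dim(fluid))
  reach[, , 1] <- fluid[, , 1]
  if (!any(reach[, , 1])) return(reach)
  repeat {
    nb <- reach |
      shift3(reach, 1, 1) | shift3(reach, 1, -1) |
      shift3(reach, 2, 1) | shift3(reach, 2, -1) |
      shiftz_fill(reach, 1, FALSE) | shiftz_fill(reach, -1, FALSE)
    nb <- nb & fluid
    if (sum(nb) == sum(reach)) return(reach)
    reach <- nb
  }
}

# TRUE if an open fluid path connects inlet to outlet slice (6-connectivity)
percolates_z <- function(solid) {
  nz <- dim(solid)[3]
  any(reach_from_inlet(solid)[, , nz])
}

#' Solve steady Stokes flow through a voxel structure
#'
#' Marker-and-cell staggered discretization on the voxel grid; laterally
#' periodic; uniform velocity prescribed on empty padding slabs up- and
#' downstream of the web. Velocity unknowns live on faces between two fluid
#' cells; faces touching solid carry zero normal velocity, and tangential
#' stencil legs ending in solid use a half-cell wall ghost (no-slip or Navier
#' slip). The saddle-point system is reduced to the pressure Schur complement
#' and solved by conjugate gradients; the three viscous blocks are factorized
#' once with sparse Cholesky (CHOLMOD).
#'
#' @param structure a `voxel_structure`; must percolate in z.
#' @param face_velocity superficial (approach) velocity (m/s), > 0.
#' @param params a [flow_params()].
#' @param pad empty padding slices added on each z side of the web.
#' @return object of class `micro_flow_field` with cell-centred velocities
#'   `ucc, vcc, wcc` (m/s), staggered z-face velocities `wfaces`, pressure `p`
#'   (Pa, `NA` in solid), the padded `solid` mask, `z_structure` (index range
#'   of the web inside the padded grid), `face_velocity`, `residual`,
#'   `converged` and grid metadata.
#' @export
solve_stokes <- function(structure, face_velocity, params = flow_params(),
                         pad = 8L) {
  stopifnot(inherits(structure, "voxel_structure"), face_velocity > 0)
  h <- structure$voxel_size
  mu <- params$mu
  dm <- structure$dims
  nx <- dm[1]; ny <- dm[2]; nzs <- dm[3]
  pad <- as.integer(pad)
  nz <- nzs + 2L * pad
  solid <- array(FALSE, c(nx, ny, nz))
  solid[, , (pad + 1L):(pad + nzs)] <- structure$occupancy
  if (any(solid)) {
    reach <- reach_from_inlet(solid)
    if (!any(reach[, , nz])) {
      stop("blocked-medium error: no open percolating path in z")
    }
    # enclosed fluid pockets carry no flow; masking them keeps the pressure
    # Schur complement non-singular (up to its constant nullspace)
    solid <- solid | (!reach & !solid)
  }

  fluid <- !solid
  ncf <- sum(fluid)
  cellId <- array(NA_integer_, dim(fluid))
  cellId[fluid] <- seq_len(ncf)

  uSolid <- solid | shift3(solid, 1, 1)    # u face between cells i and i+1
  vSolid <- solid | shift3(solid, 2, 1)
  wSolid3 <- solid | shiftz_fill(solid, 1, TRUE) # face between k and k+1; k=nz col unused
  wSolid <- wSolid3[, , 1:(nz - 1), drop = FALSE]

  uUnk <- !uSolid; vUnk <- !vSolid; wUnk <- !wSolid
  nu <- sum(uUnk); nv <- sum(vUnk); nw <- sum(wUnk)
  uId <- array(NA_integer_, dim(uUnk)); uId[uUnk] <- seq_len(nu)
  vId <- array(NA_integer_, dim(vUnk)); vId[vUnk] <- nu + seq_len(nv)
  wId <- array(NA_integer_, dim(wUnk)); wId[wUnk] <- nu + nv + seq_len(nw)
  ntot <- nu + nv + nw

  lam <- params$slip_length
  cWall <- 2 * h / (2 * lam + h)  # tangential wall diagonal weight (2 if no-slip)
  s <- mu / h^2
  vface <- face_velocity

  trI <- vector("list", 32); trJ <- vector("list", 32); trX <- vector("list", 32)
  ntr <- 0L
  diagv <- numeric(ntot)
  rhs <- numeric(ntot)

  # one stencil leg for component faces `fid` (NA = not an unknown):
  #  nbId / nbSolid / nbBC describe the neighbour in that direction;
  #  nbBC codes 0 none, 1 Dirichlet(face_velocity), 2 tangential Dirichlet-0
  #  ghost at the inflow/outflow planes (uniform axial flow there)
  leg <- function(fid, nbId, nbSolid, nbBC, tangential) {
    here <- !is.na(fid)
    f <- fid[here]; n <- nbId[here]; sn <- nbSolid[here]; bc <- nbBC[here]
    unk <- !is.na(n)
    ntr <<- ntr + 1L
    trI[[ntr]] <<- f[unk]; trJ[[ntr]] <<- n[unk]
    trX[[ntr]] <<- rep(-s, sum(unk))
    add <- numeric(length(f))
    add[unk] <- s
    wall <- !unk & sn
    add[wall] <- if (tangential) cWall * s else s
    dir <- !unk & !sn & bc == 1
    add[dir] <- s
    rhs[f[dir]] <<- rhs[f[dir]] + s * vface
    ghost <- !unk & !sn & bc == 2
    add[ghost] <- 2 * s
    diagv[f] <<- diagv[f] + add
    invisible(NULL)
  }

  none <- function(fid) array(0L, dim(fid))

  # ---- u and v faces (tangential z legs see zero-gradient ghosts) ---------
  for (comp in 1:2) {
    fid <- if (comp == 1) uId else vId
    fS <- if (comp == 1) uSolid else vSolid
    for (ax in 1:2) {
      tang <- ax != comp
      for (by in c(-1L, 1L)) {
        leg(fid, shift3(fid, ax, by), shift3(fS, ax, by), none(fid), tang)
      }
    }
    for (by in c(-1L, 1L)) {
      nbId <- shiftz_fill(fid, by, NA_integer_)
      nbS <- shiftz_fill(fS, by, FALSE)
      nbBC <- array(0L, dim(fid))
      if (by == -1L) nbBC[, , 1] <- 2L else nbBC[, , nz] <- 2L
      # mark ghost only where neighbour slice was vacated
      leg(fid, nbId, nbS, nbBC, TRUE)
    }
  }

  # ---- w faces -------------------------------------------------------------
  nzw <- nz - 1L
  for (ax in 1:2) {
    for (by in c(-1L, 1L)) {
      leg(wId, shift3(wId, ax, by), shift3(wSolid, ax, by), array(0L, dim(wId)), TRUE)
    }
  }
  for (by in c(-1L, 1L)) {
    nbId <- array(NA_integer_, dim(wId))
    nbS <- array(FALSE, dim(wId))
    nbBC <- array(0L, dim(wId))
    if (by == -1L) {
      if (nzw > 1) { nbId[, , 2:nzw] <- wId[, , 1:(nzw - 1)]
                     nbS[, , 2:nzw] <- wSolid[, , 1:(nzw - 1)] }
      nbBC[, , 1] <- 1L
    } else {
      if (nzw > 1) { nbId[, , 1:(nzw - 1)] <- wId[, , 2:nzw]
                     nbS[, , 1:(nzw - 1)] <- wSolid[, , 2:nzw] }
      nbBC[, , nzw] <- 1L
    }
    leg(wId, nbId, nbS, nbBC, FALSE)
  }

  A <- Matrix::sparseMatrix(
    i = c(unlist(trI[seq_len(ntr)]), seq_len(ntot)),
    j = c(unlist(trJ[seq_len(ntr)]), seq_len(ntot)),
    x = c(unlist(trX[seq_len(ntr)]), diagv),
    dims = c(ntot, ntot), symmetric = FALSE)
  A <- Matrix::forceSymmetric((A + Matrix::t(A)) / 2, uplo = "U")

  # ---- gradient operator G (faces x fluid cells) ---------------------------
  gi <- integer(0); gj <- integer(0); gx <- numeric(0)
  addG <- function(fid, leftCell, rightCell) {
    here <- !is.na(fid)
    f <- fid[here]; cl <- leftCell[here]; cr <- rightCell[here]
    gi <<- c(gi, f, f); gj <<- c(gj, cr, cl)
    gx <<- c(gx, rep(1 / h, length(f)), rep(-1 / h, length(f)))
  }
  addG(uId, cellId, shift3(cellId, 1, 1))
  addG(vId, cellId, shift3(cellId, 2, 1))
  addG(wId, cellId[, , 1:(nz - 1), drop = FALSE], cellId[, , 2:nz, drop = FALSE])
  G <- Matrix::sparseMatrix(i = gi, j = gj, x = gx, dims = c(ntot, ncf))

  # continuity right-hand side from the prescribed inlet/outlet faces
  cc <- numeric(ncf)
  bot <- cellId[, , 1]; bot <- bot[!is.na(bot)]
  top <- cellId[, , nz]; top <- top[!is.na(top)]
  cc[bot] <- cc[bot] - vface / h
  cc[top] <- cc[top] + vface / h

  ch <- Matrix::Cholesky(A, LDL = FALSE, perm = TRUE, super = TRUE)
  Ainv <- function(x) as.numeric(Matrix::solve(ch, x))

  bvec <- rhs
  rhsS <- as.numeric(Matrix::crossprod(G, Ainv(bvec))) - cc
  rhsS <- rhsS - mean(rhsS)

  # CG on the pressure Schur complement, constants projected out
  p <- numeric(ncf)
  r <- rhsS
  z <- r
  d <- z
  rz <- sum(r * z)
  nrm0 <- sqrt(sum(rhsS^2))
  it <- 0L
  cgtol <- max(params$tol * 1e-2, 1e-12)
  if (nrm0 > 0) {
    repeat {
      it <- it + 1L
      q <- as.numeric(Matrix::crossprod(G, Ainv(as.numeric(G %*% d))))
      q <- q - mean(q)
      alp <- rz / sum(d * q)
      p <- p + alp * d
      r <- r - alp * q
      if (sqrt(sum(r^2)) <= cgtol * nrm0 || it >= params$max_iter) break
      rzn <- sum(r * r)
      d <- r + (rzn / rz) * d
      rz <- rzn
    }
  }
  p <- p - mean(p)
  U <- Ainv(bvec - as.numeric(G %*% p))

  # ---- reconstruct fields --------------------------------------------------
  uarr <- array(0, c(nx, ny, nz)); uarr[uUnk] <- U[uId[uUnk]]
  varr <- array(0, c(nx, ny, nz)); varr[vUnk] <- U[vId[vUnk]]
  wfaces <- array(0, c(nx, ny, nz + 1L))
  wfaces[, , 1] <- vface; wfaces[, , nz + 1L] <- vface
  wi <- array(0, c(nx, ny, nzw)); wi[wUnk] <- U[wId[wUnk]]
  wfaces[, , 2:nz] <- wi

  div <- (uarr - shift3(uarr, 1, -1) + varr - shift3(varr, 2, -1) +
            wfaces[, , 2:(nz + 1), drop = FALSE] -
            wfaces[, , 1:nz, drop = FALSE]) / h
  res <- max(abs(div[fluid])) * h / vface

  parr <- array(NA_real_, c(nx, ny, nz))
  parr[fluid] <- p

  ucc <- (uarr + shift3(uarr, 1, -1)) / 2
  vcc <- (varr + shift3(varr, 2, -1)) / 2
  wcc <- (wfaces[, , 1:nz, drop = FALSE] + wfaces[, , 2:(nz + 1), drop = FALSE]) / 2

  structure(list(ucc = ucc, vcc = vcc, wcc = wcc, wfaces = wfaces, p = parr,
                 solid = solid, voxel_size = h, dims = c(nx, ny, nz),
                 z_structure = c(pad + 1L, pad + nzs), pad = pad,
                 face_velocity = vface, params = params,
                 residual = res, cg_iterations = it,
                 converged = res <= max(params$tol, 1e-9)),
            class = "micro_flow_field")
}

#' @method print micro_flow_field
#' @export
print.micro_flow_field <- function(x, ...) {
  cat(sprintf("<micro_flow_field> %d x %d x %d, v = %.3g m/s, residual %.2e (%s, %d CG its)\n",
              x$dims[1], x$dims[2], x$dims[3], x$face_velocity, x$residual,
              if (x$converged) "converged" else "NOT converged", x$cg_iterations))
  invisible(x)
}

#' Pressure drop across the slab
#'
#' Plane-averaged pressure on the planes immediately bounding the web
#' (inside the empty padding, when padding exists), upstream minus
#' downstream; positive for forward flow. Measuring at the bounding planes
#' rather than the Dirichlet inflow plane keeps the prescribed plug profile
#' from contaminating the reading. The Darcy-law sign convention is absorbed
#' in [darcy_permeability()].
#' @param field a converged `micro_flow_field`.
#' @param structure the `voxel_structure` it was solved on (unused beyond a
#'   sanity check; kept for the natural call signature).
#' @return pressure drop in Pa.
#' @export
pressure_drop <- function(field, structure = NULL) {
  stopifnot(inherits(field, "micro_flow_field"))
  if (!field$converged) {
    stop("unconverged flow field (residual ", signif(field$residual, 3),
         "); refusing to report a pressure drop")
  }
  nz <- field$dims[3]
  k1 <- if (field$pad >= 1L) field$z_structure[1] - 1L else 1L
  k2 <- if (field$pad >= 1L) field$z_structure[2] + 1L else nz
  mean(field$p[, , k1], na.rm = TRUE) - mean(field$p[, , k2], na.rm = TRUE)
}

#' Plane-averaged pressure profile along the flow axis
#'
#' Average over fluid cells in each z slice; useful for inspecting entrance
#' effects and for fixture checks against fully developed closed forms.
#' @param field a `micro_flow_field`.
#' @return numeric vector of length `dims[3]` (Pa).
#' @export
pressure_profile <- function(field) {
  apply(field$p, 3, mean, na.rm = TRUE)
}

#' Darcy permeability from a measured pressure drop
#'
#' `k = v * mu_a * t_f / dP` with `dP` defined positive upstream-minus-
#' downstream.
#' @param face_velocity superficial velocity v (m/s).
#' @param pressure_drop positive pressure drop (Pa).
#' @param thickness slab thickness t_f (m).
#' @param viscosity dynamic viscosity mu_a (kg/(m s)).
#' @return permeability in m^2.
#' @export
darcy_permeability <- function(face_velocity, pressure_drop, thickness,
                               viscosity = 1.834e-5) {
  if (pressure_drop <= 0) stop("domain error: pressure_drop must be > 0")
  if (thickness <= 0) stop("domain error: thickness must be > 0")
  face_velocity * viscosity * thickness / pressure_drop
}

# plane-averaged z velocity per slice (mass-conservation diagnostic)
plane_mean_w <- function(field) {
  apply(field$wfaces, 3, mean)
}
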