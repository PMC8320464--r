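#' Specification of one nonwoven fiber layer
#'
#' Describes a single spunbond or meltblown web by its fiber diameter
#' distribution, packing fraction (solidity) and thickness. Fiber geometry is
#' not published for the reference webs, so these are tunable proxies;
#' [calibrate_layer()] adjusts the solidity against a measured single-layer
#' filtration efficiency.
#'
#' @param fiber_diameter_um mean fiber diameter (micrometres).
#' @param solidity target solid volume fraction, in `[0, 0.5)`.
#' @param thickness_um layer thickness (micrometres).
#' @param fiber_diameter_sd_um standard deviation of the fiber diameter.
#' @param orientation_anisotropy 0 for isotropic in-plane orientation, up to 1
#'   for fibers aligned with the x axis.
#' @param label free-text label, e.g. `"spunbond"`.
#' @return an object of class `fiber_layer_spec`.
#' @export
fiber_layer_spec <- function(fiber_diameter_um, solidity, thickness_um,
                             fiber_diameter_sd_um = 0.1 * fiber_diameter_um,
                             orientation_anisotropy = 0, label = "web") {
  stopifnot(fiber_diameter_um > 0, thickness_um > 0,
            solidity >= 0, solidity < 0.5,
            orientation_anisotropy >= 0, orientation_anisotropy <= 1)
  structure(list(fiber_diameter_um = fiber_diameter_um,
                 fiber_diameter_sd_um = fiber_diameter_sd_um,
                 solidity = solidity,
                 thickness_um = thickness_um,
                 orientation_anisotropy = orientation_anisotropy,
                 label = label),
            class = "fiber_layer_spec")
}

#' @method print fiber_layer_spec
#' @export
print.fiber_layer_spec <- function(x, ...) {
  cat(sprintf("<fiber_layer_spec '%s'> d_f = %.2g um, solidity = %.3f, t = %g um\n",
              x$label, x$fiber_diameter_um, x$solidity, x$thickness_um))
  invisible(x)
}

#' Default spunbond layer (coarse fibers, low efficiency)
#'
#' Literature-typical values; the solidity is the calibration handle. The
#' 12 um default fiber is at the fine end of the spunbond range, chosen so
#' that the measured single-layer efficiency is reachable by solidity
#' calibration inside the (0, 0.3) domain where the layer capture model is
#' valid.
#' @param solidity target solidity.
#' @return a [fiber_layer_spec()].
#' @export
spunbond_spec <- function(solidity = 0.10) {
  fiber_layer_spec(12, solidity, 250, label = "spunbond")
}

#' Default meltblown layer (fine fibers, high efficiency)
#' @param solidity target solidity.
#' @return a [fiber_layer_spec()].
#' @export
meltblown_spec <- function(solidity = 0.08) {
  fiber_layer_spec(3, solidity, 470, label = "meltblown")
}

#' Layer compositions of the two virtual masks
#'
#' Type A is two spunbond layers (0.5 mm total); Type B is
#' spunbond/meltblown/spunbond (0.97 mm total, dense middle layer).
#' @param type `"A"` or `"B"`.
#' @param spunbond,meltblown layer specs to compose.
#' @return list of [fiber_layer_spec()]s, outermost first.
#' @export
mask_layer_specs <- function(type = c("A", "B"), spunbond = spunbond_spec(),
                             meltblown = meltblown_spec()) {
  type <- match.arg(type)
  if (type == "A") list(spunbond, spunbond)
  else list(spunbond, meltblown, spunbond)
}

#' Generate a voxelized virtual fiber web
#'
#' Lays down straight cylindrical fibers with random in-plane orientation and
#' random depth until the occupied-voxel fraction reaches the spec's target
#' solidity within +/- 0.01. Fibers wrap across the lateral faces so the
#' structure is periodic-compatible; overlaps are allowed. Near the target the
#' generator switches to shorter chords so the tolerance can always be met.
#'
#' @param spec a [fiber_layer_spec()].
#' @param domain_xy lateral physical size, length-2 numeric (m).
#' @param voxel_size voxel edge length (m); must resolve the fiber diameter
#'   with at least 3 voxels.
#' @param seed integer seed; the same seed and spec give a bit-identical web.
#' @param max_fibers safety cap before a convergence error is raised.
#' @return an object of class `voxel_structure` with fields `occupancy`
#'   (logical 3-D array, z = through-thickness), `voxel_size`, `dims`,
#'   `layer_boundaries` and `layers`.
#' @export
generate_layer <- function(spec, domain_xy, voxel_size, seed,
                           max_fibers = 10000) {
  stopifnot(inherits(spec, "fiber_layer_spec"), length(domain_xy) == 2)
  d_f <- spec$fiber_diameter_um * 1e-6
  h <- voxel_size
  if (h > d_f / 3 + 1e-15) {
    stop("resolution error: voxel_size must be <= fiber_diameter/3 (got ",
         signif(h, 3), " m for a ", signif(d_f, 3), " m fiber)")
  }
  if (any(domain_xy <= 2 * d_f)) {
    stop("domain_xy must exceed twice the fiber diameter")
  }
  nx <- max(2L, as.integer(round(domain_xy[1] / h)))
  ny <- max(2L, as.integer(round(domain_xy[2] / h)))
  nz <- max(1L, as.integer(round(spec$thickness_um * 1e-6 / h)))
  occ <- array(FALSE, dim = c(nx, ny, nz))

  target <- spec$solidity
  if (target > 0) {
    occ <- with_seed(seed, {
      lay_fibers(occ, spec, h, max_fibers)
    })
    ach <- mean(occ)
    if (abs(ach - target) > 0.01) {
      stop(sprintf(
        "convergence error: achieved solidity %.4f not within 0.01 of %.4f",
        ach, target))
    }
  }
  structure(list(occupancy = occ, voxel_size = h, dims = c(nx, ny, nz),
                 layer_boundaries = list(c(1L, nz)), layers = list(spec),
                 seed = seed),
            class = "voxel_structure")
}

# fiber laydown inner loop: paints spheres along straight wrapped chords
lay_fibers <- function(occ, spec, h, max_fibers) {
  dm <- dim(occ)
  nx <- dm[1]; ny <- dm[2]; nz <- dm[3]
  Lx <- nx * h; Ly <- ny * h
  target <- spec$solidity
  nvox <- length(occ)
  full_len <- 2 * (Lx + Ly)
  # solid volume added per unit chord length, updated from actual painting
  eff <- 1.3 * pi * (spec$fiber_diameter_um * 1e-6 / 2)^2

  for (nf in seq_len(max_fibers)) {
    ach <- sum(occ) / nvox
    if (ach >= target - 0.004) break
    d_fib <- -1
    while (d_fib < spec$fiber_diameter_um / 3) {
      d_fib <- stats::rnorm(1, spec$fiber_diameter_um, spec$fiber_diameter_sd_um)
    }
    r <- d_fib * 1e-6 / 2
    # approach the target geometrically with ever-shorter chords so the
    # +/-0.01 band is always reachable despite overlap/voxelization noise
    need <- (target - ach) * nvox * h^3
    len <- min(full_len, max(2 * d_fib * 1e-6, 0.7 * need / eff))
    theta <- if (spec$orientation_anisotropy <= 0) {
      stats::runif(1, 0, pi)
    } else {
      stats::rnorm(1, 0, (1 - spec$orientation_anisotropy) * pi / 2) %% pi
    }
    p0 <- c(stats::runif(1, 0, Lx), stats::runif(1, 0, Ly),
            stats::runif(1, r, max(nz * h - r, r)))
    u <- c(cos(theta), sin(theta), 0)

    step <- h / 3
    np <- max(2L, ceiling(len / step))
    tt <- seq(0, len, length.out = np)
    px <- (p0[1] + tt * u[1]) %% Lx
    py <- (p0[2] + tt * u[2]) %% Ly
    pz <- p0[3]
    # sphere stamp offsets (voxel units) covering radius r
    rv <- ceiling(r / h + 0.5)
    og <- expand.grid(ox = -rv:rv, oy = -rv:rv, oz = -rv:rv)
    keep <- (og$ox^2 + og$oy^2 + og$oz^2) * h^2 <= (r + 0.25 * h)^2
    og <- og[keep, , drop = FALSE]

    ix <- floor(px / h); iy <- floor(py / h)
    iz <- floor(pz / h)
    IX <- outer(ix, og$ox, "+") %% nx
    IY <- outer(iy, og$oy, "+") %% ny
    IZ <- outer(rep(iz, np), og$oz, "+")

    # paint in chunks along the chord, re-checking solidity between chunks,
    # so a single chord can never overshoot the tolerance band
    chunk_len <- max(0.002 * nvox * h^3 / eff, 2 * h)
    chunk_pts <- max(2L, ceiling(chunk_len / step))
    p0i <- 1L
    total_added <- 0
    while (p0i <= np) {
      p1i <- min(np, p0i + chunk_pts - 1L)
      sel <- p0i:p1i
      IZc <- IZ[sel, , drop = FALSE]
      ok <- IZc >= 0 & IZc < nz
      lin <- 1 + IX[sel, , drop = FALSE][ok] + IY[sel, , drop = FALSE][ok] * nx +
        IZc[ok] * nx * ny
      before <- sum(occ)
      occ[lin] <- TRUE
      total_added <- total_added + (sum(occ) - before) * h^3
      if (sum(occ) / nvox >= target - 0.002) break
      p0i <- p1i + 1L
    }
    painted_len <- min(p0i + chunk_pts - 1L, np) / np * len
    if (total_added > 0 && painted_len > 0) {
      eff <- 0.5 * eff + 0.5 * total_added / painted_len
    }
  }
  ach <- sum(occ) / nvox
  if (ach < target - 0.01) {
    stop(sprintf("convergence error: solidity %.4f below target %.4f after %d fibers",
                 ach, target, max_fibers))
  }
  occ
}

#' Stack voxel layers along the flow (z) axis
#'
#' @param layers ordered list of `voxel_structure`s sharing voxel size and
#'   lateral dims; the first layer is upstream.
#' @return a combined `voxel_structure` with `layer_boundaries` recorded.
#' @export
stack_layers <- function(layers) {
  stopifnot(length(layers) >= 1)
  h <- layers[[1]]$voxel_size
  latd <- layers[[1]]$dims[1:2]
  for (l in layers) {
    if (abs(l$voxel_size - h) > 1e-12 * h) {
      stop("shape error: layers must share voxel_size")
    }
    if (!all(l$dims[1:2] == latd)) {
      stop("shape error: layers must share lateral dims")
    }
  }
  nzs <- vapply(layers, function(l) l$dims[3], integer(1))
  occ <- array(FALSE, dim = c(latd, sum(nzs)))
  bounds <- list(); specs <- list()
  z0 <- 0L
  for (l in layers) {
    nz <- l$dims[3]
    occ[, , (z0 + 1L):(z0 + nz)] <- l$occupancy
    bounds[[length(bounds) + 1L]] <- c(z0 + 1L, z0 + nz)
    specs <- c(specs, l$layers)
    z0 <- z0 + nz
  }
  structure(list(occupancy = occ, voxel_size = h, dims = c(latd, z0),
                 layer_boundaries = bounds, layers = specs,
                 seed = layers[[1]]$seed),
            class = "voxel_structure")
}

#' Solid volume fraction of a voxel structure
#' @param structure a `voxel_structure`.
#' @return occupied voxels / total voxels, in `[0, 1]`.
#' @export
solidity <- function(structure) {
  stopifnot(inherits(structure, "voxel_structure"))
  mean(structure$occupancy)
}

#' Physical thickness of a voxel structure (m)
#' @param structure a `voxel_structure`.
#' @export
thickness <- function(structure) {
  structure$dims[3] * structure$voxel_size
}

#' @method print voxel_structure
#' @export
print.voxel_structure <- function(x, ...) {
  cat(sprintf("<voxel_structure> %d x %d x %d voxels @ %.3g um, solidity %.3f, %d layer(s)\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel_size * 1e6,
              mean(x$occupancy), length(x$layer_boundaries)))
  invisible(x)
}

#' Persist a voxel structure as a JSON sidecar plus occupancy RLE text file
#'
#' Plain-text container: run-length-encoded occupancy with a JSON header, so
#' structures can be archived and diffed without binary formats.
#' @param structure a `voxel_structure`.
#' @param path output file path.
#' @export
write_voxel_structure <- function(structure, path) {
  r <- rle(as.vector(structure$occupancy))
  meta <- list(voxel_size_m = structure$voxel_size, dims = structure$dims,
               layers = lapply(structure$layers, unclass),
               seed = structure$seed,
               layer_boundaries = structure$layer_boundaries,
               rle_values = as.integer(r$values), rle_lengths = r$lengths)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a voxel structure written by [write_voxel_structure()]
#' @param path file path.
#' @export
read_voxel_structure <- function(path) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  occ <- array(inverse.rle(list(values = as.logical(meta$rle_values),
                                lengths = meta$rle_lengths)),
               dim = meta$dims)
  layers <- lapply(seq_len(nrow(meta$layers)), function(i) {
    s <- as.list(meta$layers[i, ])
    class(s) <- "fiber_layer_spec"
    s
  })
  structure(list(occupancy = occ, voxel_size = meta$voxel_size_m,
                 dims = as.integer(meta$dims),
                 layer_boundaries = lapply(seq_len(length(meta$layer_boundaries)),
                                           function(i) as.integer(meta$layer_boundaries[[i]])),
                 layers = layers, seed = meta$seed),
            class = "voxel_structure")
}
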