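#' Lattice geometry for the simulation domain
#'
#' The model lives on a regular 3D grid of voxel-centred sites. Sites are
#' addressed by 0-based integer coordinates \code{(i, j, k)} with
#' \code{0 <= i < Nx} etc. Each axis carries its own boundary condition:
#' \code{"reflecting"} (zero-flux; out-of-range moves are simply not offered)
#' or \code{"periodic"} (coordinates wrap modulo the axis extent).
#'
#' @param dims integer vector of length 3, number of sites per axis
#'   \code{(Nx, Ny, Nz)}; each must be >= 1.
#' @param spacing lattice spacing in micrometres (> 0). Default 40.
#' @param bc character vector of length 3 giving the boundary condition per
#'   axis, each \code{"reflecting"} or \code{"periodic"}. A single value is
#'   recycled to all three axes.
#'
#' @return An object of class \code{"lattice_spec"}: a list with elements
#'   \code{dims}, \code{spacing}, \code{bc} and \code{n} (total site count).
#' @examples
#' spec <- lattice_spec(c(10, 10, 10), spacing = 40)
#' site_neighbours(c(0, 0, 0), spec)
#' @export
lattice_spec <- function(dims, spacing = 40, bc = "reflecting") {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(is.na(dims)) || any(dims < 1L))
    stop("dims must be three integers >= 1")
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0)
    stop("spacing must be a single positive number")
  if (length(bc) == 1L) bc <- rep(bc, 3L)
  if (length(bc) != 3L || !all(bc %in% c("reflecting", "periodic")))
    stop("bc must give 'reflecting' or 'periodic' for each of the 3 axes")
  spec <- structure(list(dims = dims, spacing = as.numeric(spacing), bc = bc,
                         n = prod(dims)),
                    class = "lattice_spec")
  # cached face-neighbour table (n x 6, NA where a reflecting boundary
  # removes the neighbour): the random-walk hot path is a table lookup
  spec$nb_face <- vapply(
    list(c(1, -1), c(1, 1), c(2, -1), c(2, 1), c(3, -1), c(3, 1)),
    function(ad) {
      if (spec$dims[ad[1]] == 1L) return(rep(NA_integer_, spec$n))
      as.integer(neighbour_lin(spec, as.integer(ad[1]), as.integer(ad[2])))
    }, integer(spec$n))
  if (is.null(dim(spec$nb_face)))
    spec$nb_face <- matrix(spec$nb_face, nrow = spec$n)
  spec
}

#' @export
print.lattice_spec <- function(x, ...) {
  cat(sprintf("lattice_spec: %d x %d x %d sites, spacing %g um, bc [%s]\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              paste(x$bc, collapse = ", ")))
  invisible(x)
}

# Linear (1-based) index of 0-based sites; sites is an n x 3 matrix or a
# length-3 vector. Inverse of site_from_lin.
site_lin <- function(sites, spec) {
  if (is.null(dim(sites))) sites <- matrix(sites, ncol = 3L)
  d <- spec$dims
  1L + sites[, 1L] + d[1L] * (sites[, 2L] + d[2L] * sites[, 3L])
}

site_from_lin <- function(lin, spec) {
  d <- spec$dims
  lin0 <- as.integer(lin) - 1L
  i <- lin0 %% d[1L]
  j <- (lin0 %/% d[1L]) %% d[2L]
  k <- lin0 %/% (d[1L] * d[2L])
  cbind(i = i, j = j, k = k)
}

#' Canonicalise a site under the lattice boundary conditions
#'
#' Periodic axes wrap the coordinate modulo the axis extent; on reflecting
#' axes an out-of-range coordinate is a caller error.
#'
#' @param site integer vector \code{(i, j, k)} or an n x 3 matrix.
#' @param spec a [lattice_spec()].
#' @return canonical site(s), same shape as the input.
#' @export
canonical_site <- function(site, spec) {
  vec <- is.null(dim(site))
  s <- if (vec) matrix(as.integer(site), ncol = 3L) else
    matrix(as.integer(site), ncol = 3L)
  for (ax in 1:3) {
    if (spec$bc[ax] == "periodic") {
      s[, ax] <- s[, ax] %% spec$dims[ax]
    } else if (any(s[, ax] < 0L | s[, ax] >= spec$dims[ax])) {
      stop(sprintf("site out of range on reflecting axis %d", ax))
    }
  }
  if (vec) s[1L, ] else s
}

is_canonical <- function(site, spec) {
  s <- if (is.null(dim(site))) matrix(site, ncol = 3L) else site
  all(s >= 0L) && all(sweep(s, 2L, spec$dims, "<"))
}

# Offsets for the two connectivities (rows are displacement vectors).
.face_offsets <- rbind(c(1L, 0L, 0L), c(-1L, 0L, 0L),
                       c(0L, 1L, 0L), c(0L, -1L, 0L),
                       c(0L, 0L, 1L), c(0L, 0L, -1L))
.full_offsets <- {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g[rowSums(abs(g)) > 0L, , drop = FALSE]
}

#' Lattice neighbours of a site under the boundary conditions
#'
#' Periodic axes wrap; on reflecting axes the out-of-range neighbour is
#' dropped, so boundary sites simply offer fewer move options.
#'
#' @param site canonical site \code{(i, j, k)} (0-based).
#' @param spec a [lattice_spec()].
#' @param connectivity \code{"face"} (von Neumann, up to 6 neighbours,
#'   default) or \code{"full"} (Moore, up to 26).
#' @return integer matrix with one canonical neighbour per row.
#' @export
site_neighbours <- function(site, spec, connectivity = c("face", "full")) {
  connectivity <- match.arg(connectivity)
  site <- as.integer(site)
  if (!is_canonical(site, spec)) stop("site is not canonical for this lattice")
  off <- if (connectivity == "face") .face_offsets else .full_offsets
  nb <- sweep(off, 2L, site, "+")
  keep <- rep(TRUE, nrow(nb))
  for (ax in 1:3) {
    if (spec$bc[ax] == "periodic") {
      nb[, ax] <- nb[, ax] %% spec$dims[ax]
    } else {
      keep <- keep & nb[, ax] >= 0L & nb[, ax] < spec$dims[ax]
    }
  }
  nb[keep, , drop = FALSE]
}

#' Minimal-image displacement between two sites
#'
#' Per-axis displacement \code{b - a} in micrometres: the minimal image on
#' periodic axes, the plain difference on reflecting axes.
#'
#' @param a,b canonical sites (0-based integer triples).
#' @param spec a [lattice_spec()].
#' @return numeric length-3 displacement in micrometres.
#' @export
wrapped_displacement <- function(a, b, spec) {
  a <- as.integer(a); b <- as.integer(b)
  if (!is_canonical(a, spec) || !is_canonical(b, spec))
    stop("sites must be canonical")
  d <- b - a
  for (ax in 1:3) {
    if (spec$bc[ax] == "periodic") {
      n <- spec$dims[ax]
      d[ax] <- d[ax] - n * round(d[ax] / n)
    }
  }
  d * spec$spacing
}

#' Minimal-image Euclidean distance between sites, in micrometres
#'
#' Vectorised over rows of \code{a} (an n x 3 matrix); \code{b} is one site.
#'
#' @param a n x 3 matrix of canonical sites (or a length-3 vector).
#' @param b canonical site.
#' @param spec a [lattice_spec()].
#' @return numeric vector of distances (um).
#' @export
site_distance <- function(a, b, spec) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 3L)
  d <- sweep(a, 2L, as.integer(b), function(x, y) y - x)
  for (ax in 1:3) {
    if (spec$bc[ax] == "periodic") {
      n <- spec$dims[ax]
      d[, ax] <- d[, ax] - n * round(d[, ax] / n)
    }
  }
  sqrt(rowSums(d * d)) * spec$spacing
}

#' Occupancy bookkeeping for the lattice
#'
#' Tracks per-site counts of normal cells, cancer cells, and whether a site
#' is vessel-occupied. Normal + cancer counts at a site never exceed the
#' carrying capacity; endothelial tip cells and vessels do not count against
#' it.
#'
#' @param spec a [lattice_spec()].
#' @param capacity integer >= 1, cells a site can hold (default 1: at most
#'   one normal or cancer cell per site, the loosely packed default).
#' @return an environment of class \code{"occupancy"} with integer arrays
#'   \code{normal}, \code{cancer} and logical array \code{vessel}, each of
#'   dim \code{spec$dims}.
#' @export
new_occupancy <- function(spec, capacity = 1L) {
  capacity <- as.integer(capacity)
  if (is.na(capacity) || capacity < 1L) stop("capacity must be >= 1")
  occ <- new.env(parent = emptyenv())
  occ$spec <- spec
  occ$capacity <- capacity
  occ$normal <- array(0L, dim = spec$dims)
  occ$cancer <- array(0L, dim = spec$dims)
  occ$vessel <- array(FALSE, dim = spec$dims)
  class(occ) <- "occupancy"
  occ
}

# total normal+cancer count as a flat vector (linear site order)
occ_counts <- function(occ) as.vector(occ$normal) + as.vector(occ$cancer)

occ_add <- function(occ, lin, kind, delta = 1L) {
  if (kind == "normal") occ$normal[lin] <- occ$normal[lin] + delta
  else occ$cancer[lin] <- occ$cancer[lin] + delta
  if (occ$normal[lin] < 0L || occ$cancer[lin] < 0L)
    stop("occupancy count went negative: bookkeeping bug")
  invisible(occ)
}

#' Volume fraction of occupied sites
#'
#' The fraction of lattice sites occupied by at least one entity of the
#' requested kind, relative to the total number of lattice sites.
#'
#' @param occ an [new_occupancy()] object.
#' @param kind one of \code{"tumour"}, \code{"normal"}, \code{"vessel"}.
#' @return a fraction in \[0, 1\].
#' @export
volume_fraction <- function(occ, kind = c("tumour", "normal", "vessel")) {
  kind <- match.arg(kind)
  arr <- switch(kind,
                tumour = occ$cancer > 0L,
                normal = occ$normal > 0L,
                vessel = occ$vessel)
  sum(arr) / length(arr)
}

# Vectorised neighbour linear indices for every site, one direction at a
# time: axis in 1:3, delta in {-1, +1}. Returns an integer vector of length
# spec$n with NA where a reflecting boundary removes the neighbour.
neighbour_lin <- function(spec, axis, delta) {
  d <- spec$dims
  i <- rep_len(0:(d[1] - 1L), spec$n)
  j <- rep(rep(0:(d[2] - 1L), each = d[1]), times = d[3])
  k <- rep(0:(d[3] - 1L), each = d[1] * d[2])
  co <- list(i, j, k)
  co[[axis]] <- co[[axis]] + delta
  if (spec$bc[axis] == "periodic") {
    co[[axis]] <- co[[axis]] %% d[axis]
  } else {
    co[[axis]][co[[axis]] < 0L | co[[axis]] >= d[axis]] <- NA_integer_
  }
  1L + co[[1]] + d[1] * (co[[2]] + d[2] * co[[3]])
}

# TRUE per site if the logical array `mask` is TRUE at the site or at any
# face neighbour (boundary-condition aware). Used for the p53 threshold
# switch ("cancer nearby") and milestone diagnostics.
neighbourhood_any <- function(mask, spec) {
  out <- as.vector(mask)
  v <- as.vector(mask)
  for (axis in 1:3) for (delta in c(-1L, 1L)) {
    nb <- neighbour_lin(spec, axis, delta)
    ok <- !is.na(nb)
    out[ok] <- out[ok] | v[nb[ok]]
  }
  array(out, dim = spec$dims)
}
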