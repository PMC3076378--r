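#' Quasi-steady reaction-diffusion fields (oxygen, VEGF)
#'
#' Oxygen and VEGF obey elliptic reaction-diffusion equations on the cell
#' lattice,
#' \deqn{0 = D \nabla^2 c - (\lambda + s(x))\,c + q(x),}
#' discretised with the 7-point finite-difference stencil. Reflecting axes
#' get a zero-flux closure (the missing neighbour term is dropped from the
#' Laplacian), periodic axes couple across the wrap seam. \code{s(x) >= 0}
#' collects per-site linear sinks (cell consumption, vessel VEGF uptake,
#' the linearised vessel-exchange term) and \code{q(x) >= 0} the constant
#' sources (vessel oxygen delivery, VEGF secretion by hypoxic cells).
#'
#' @param spec a [lattice_spec()].
#' @param D diffusivity (um^2 / min, > 0).
#' @param decay uniform first-order decay rate (1/min, >= 0).
#' @param sink per-site additional linear sink coefficients (1/min, >= 0):
#'   vector of length \code{spec$n} in linear site order, or a scalar.
#' @param source per-site constant source (conc/min, >= 0), same shape.
#' @return list with the sparse system matrix \code{A} (\code{dgCMatrix},
#'   positive definite when \code{decay + sink > 0} somewhere on every
#'   periodic component) and right-hand side \code{b}, so that the solved
#'   concentrations satisfy \code{A c = b}.
#' @export
assemble_elliptic_system <- function(spec, D, decay, sink = 0, source = 0) {
  n <- spec$n
  sink <- rep_len(as.numeric(sink), n)
  source <- rep_len(as.numeric(source), n)
  if (!is.finite(D) || D <= 0) stop("D must be a positive finite number")
  if (!is.finite(decay) || decay < 0) stop("decay must be >= 0")
  if (any(!is.finite(sink)) || any(sink < 0))
    stop("negative or non-finite sink coefficient")
  if (any(!is.finite(source)) || any(source < 0))
    stop("negative or non-finite source")
  w <- D / spec$spacing^2
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  diag_lap <- numeric(n)
  for (axis in 1:3) {
    if (spec$dims[axis] == 1L) next  # degenerate axis: no flux either way
    for (delta in c(-1L, 1L)) {
      nb <- neighbour_lin(spec, axis, delta)
      ok <- which(!is.na(nb))
      ii <- c(ii, ok); jj <- c(jj, nb[ok]); xx <- c(xx, rep(-w, length(ok)))
      diag_lap[ok] <- diag_lap[ok] + w
    }
  }
  ii <- c(ii, seq_len(n))
  jj <- c(jj, seq_len(n))
  xx <- c(xx, diag_lap + decay + sink)
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  list(A = A, b = source, spec = spec)
}

# Matrix-free stencil operator for the same elliptic system that
# assemble_elliptic_system builds explicitly: y = A x evaluated with six
# vectorised neighbour gathers from the cached face-neighbour table. Used on
# the engine's hot path; the explicit sparse form remains the reference
# (their agreement is pinned by tests).
field_operator <- function(spec, D, decay, sink = 0) {
  n <- spec$n
  sink <- rep_len(as.numeric(sink), n)
  if (any(!is.finite(sink)) || any(sink < 0))
    stop("negative or non-finite sink coefficient")
  w <- D / spec$spacing^2
  nb <- spec$nb_face
  valid <- !is.na(nb)
  deg <- rowSums(valid)
  adiag <- w * deg + decay + sink
  # ghost-site trick: out-of-range neighbours point at a zero-valued ghost
  nbg <- nb; nbg[!valid] <- n + 1L
  n1 <- nbg[, 1L]; n2 <- nbg[, 2L]; n3 <- nbg[, 3L]
  n4 <- nbg[, 4L]; n5 <- nbg[, 5L]; n6 <- nbg[, 6L]
  f <- function(x) {
    xg <- c(x, 0)
    adiag * x - w * (xg[n1] + xg[n2] + xg[n3] + xg[n4] + xg[n5] + xg[n6])
  }
  attr(f, "diag") <- adiag
  f
}

#' Restarted GMRES with Jacobi preconditioning
#'
#' Solves \code{A x = b} iteratively. Used for the diffusible fields, where
#' moderate accuracy suffices and the previous time-step's solution is an
#' excellent initial guess; the blood-flow systems use a direct sparse solve
#' instead (see [solve_flow()]) because perfusion decisions need
#' near-machine-precision flows.
#'
#' @param A square sparse matrix.
#' @param b right-hand side.
#' @param x0 initial guess (default zero).
#' @param rtol relative residual tolerance on \code{||b - A x|| / ||b||}.
#' @param restart Krylov subspace size before restart.
#' @param maxit total iteration cap (default \code{10 * length(b)}).
#' @return list \code{x} (solution), \code{residual} (relative), \code{iters}.
#' @export
gmres_solve <- function(A, b, x0 = NULL, rtol = 1e-8, restart = 30L,
                        maxit = NULL) {
  n <- length(b)
  if (is.function(A)) {
    amul <- A
    adiag <- attr(A, "diag")
    if (is.null(adiag)) stop("operator form needs a 'diag' attribute")
  } else {
    amul <- function(x) as.numeric(A %*% x)
    adiag <- Matrix::diag(A)
  }
  if (is.null(maxit)) maxit <- 10L * n
  if (is.null(x0)) x0 <- numeric(n)
  bn <- sqrt(sum(b * b))
  if (bn == 0) return(list(x = numeric(n), residual = 0, iters = 0L))
  dinv <- 1 / adiag
  if (any(!is.finite(dinv))) stop("zero diagonal entry: system is singular")
  x <- x0
  iters <- 0L
  m <- as.integer(restart)
  repeat {
    r <- b - amul(x)
    beta <- sqrt(sum(r * r))
    if (beta / bn <= rtol)
      return(list(x = x, residual = beta / bn, iters = iters))
    V <- matrix(0, n, m + 1L)
    H <- matrix(0, m + 1L, m)
    cs <- numeric(m); sn <- numeric(m)
    g <- numeric(m + 1L); g[1L] <- beta
    V[, 1L] <- r / beta
    k <- 0L
    for (j in seq_len(m)) {
      iters <- iters + 1L
      w <- amul(dinv * V[, j])
      # classical Gram-Schmidt with one reorthogonalisation (CGS2): BLAS-3
      Vj <- V[, seq_len(j), drop = FALSE]
      h1 <- crossprod(Vj, w)
      w <- w - as.numeric(Vj %*% h1)
      h2 <- crossprod(Vj, w)
      w <- w - as.numeric(Vj %*% h2)
      H[seq_len(j), j] <- h1 + h2
      H[j + 1L, j] <- sqrt(sum(w * w))
      if (H[j + 1L, j] > 0) V[, j + 1L] <- w / H[j + 1L, j]
      # apply accumulated Givens rotations, then form a new one
      for (i2 in seq_len(j - 1L)) {
        t <- cs[i2] * H[i2, j] + sn[i2] * H[i2 + 1L, j]
        H[i2 + 1L, j] <- -sn[i2] * H[i2, j] + cs[i2] * H[i2 + 1L, j]
        H[i2, j] <- t
      }
      dd <- sqrt(H[j, j]^2 + H[j + 1L, j]^2)
      cs[j] <- H[j, j] / dd; sn[j] <- H[j + 1L, j] / dd
      H[j, j] <- dd; H[j + 1L, j] <- 0
      g[j + 1L] <- -sn[j] * g[j]
      g[j] <- cs[j] * g[j]
      k <- j
      if (abs(g[j + 1L]) / bn <= rtol || iters >= maxit) break
    }
    y <- backsolve(H[seq_len(k), seq_len(k), drop = FALSE], g[seq_len(k)])
    x <- x + dinv * as.numeric(V[, seq_len(k), drop = FALSE] %*% y)
    if (iters >= maxit) {
      r <- b - amul(x)
      res <- sqrt(sum(r * r)) / bn
      if (res <= rtol) return(list(x = x, residual = res, iters = iters))
      stop(sprintf(
        "GMRES did not converge in %d iterations (relative residual %.3e)",
        iters, res))
    }
  }
}

#' Preconditioned conjugate-gradient solver
#'
#' Krylov iteration specialised to the symmetric positive definite systems
#' produced by the field discretisation (Jacobi preconditioning, relative
#' residual stopping rule). Mathematically an unrestarted Krylov method like
#' [gmres_solve()], but with short recurrences: the natural choice for SPD
#' systems.
#'
#' @inheritParams gmres_solve
#' @return list \code{x}, \code{residual} (relative), \code{iters}.
#' @export
cg_solve <- function(A, b, x0 = NULL, rtol = 1e-8, maxit = NULL) {
  n <- length(b)
  if (is.function(A)) {
    amul <- A; adiag <- attr(A, "diag")
    if (is.null(adiag)) stop("operator form needs a 'diag' attribute")
  } else {
    amul <- function(x) as.numeric(A %*% x)
    adiag <- Matrix::diag(A)
  }
  if (is.null(maxit)) maxit <- 10L * n
  bn <- sqrt(sum(b * b))
  if (bn == 0) return(list(x = numeric(n), residual = 0, iters = 0L))
  dinv <- 1 / adiag
  if (any(!is.finite(dinv)) || any(adiag <= 0))
    stop("non-positive diagonal entry: system is not SPD")
  x <- if (is.null(x0)) numeric(n) else x0
  r <- b - amul(x)
  z <- dinv * r
  p <- z
  rz <- sum(r * z)
  iters <- 0L
  while (iters < maxit) {
    rn <- sqrt(sum(r * r))
    if (rn / bn <= rtol) return(list(x = x, residual = rn / bn, iters = iters))
    iters <- iters + 1L
    Ap <- amul(p)
    alpha <- rz / sum(p * Ap)
    if (!is.finite(alpha))
      stop("CG breakdown: system is singular or not positive definite")
    x <- x + alpha * p
    r <- r - alpha * Ap
    z <- dinv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  rn <- sqrt(sum(r * r))
  if (rn / bn <= rtol) return(list(x = x, residual = rn / bn, iters = iters))
  stop(sprintf("CG did not converge in %d iterations (relative residual %.3e)",
               iters, rn / bn))
}

#' Solve an assembled elliptic field system
#'
#' The discretised field systems are symmetric positive definite, so the
#' default Krylov method is conjugate gradients; \code{method = "gmres"}
#' runs the restarted general-purpose iteration instead (both share the
#' tolerance contract and agree to solver tolerance).
#'
#' @param system output of [assemble_elliptic_system()].
#' @param x0 optional initial guess (previous time-step's field).
#' @param rtol relative residual tolerance (default 1e-8).
#' @param method \code{"cg"} (default) or \code{"gmres"}.
#' @return numeric vector of concentrations (linear site order), >= 0.
#'   Negative values below solver tolerance are clamped to zero; anything
#'   more negative signals a modelling error and aborts.
#' @export
solve_field <- function(system, x0 = NULL, rtol = 1e-8,
                        method = c("cg", "gmres")) {
  method <- match.arg(method)
  res <- if (method == "cg") cg_solve(system$A, system$b, x0 = x0,
                                      rtol = rtol)
    else gmres_solve(system$A, system$b, x0 = x0, rtol = rtol)
  x <- res$x
  tol <- rtol * max(1, max(abs(x)))
  if (any(x < -tol))
    stop("field solution has significantly negative concentrations")
  pmax(x, 0)
}

#' Transmural oxygen exchange rate for one vessel segment
#'
#' Oxygen crosses the vessel wall at a rate proportional to the permeability,
#' the wall surface, and the blood-tissue concentration difference:
#' \deqn{rate = P_{O2}\, k_A\, (c_{blood} - c_{tissue}),}
#' with \eqn{c_{blood} = H / H_{ref}} (haematocrit as the oxygen-carrying
#' proxy, normalised so inlet blood has concentration ~1) and
#' \eqn{k_A = \sigma\, 2\pi R L / V_{site}} the per-site surface factor.
#' Unperfused segments exchange nothing. In the field solve the same term
#' enters implicitly: coefficient \code{P_O2 * kA} as a linear sink and
#' \code{P_O2 * kA * c_blood} as a constant source, which keeps the system
#' diagonally dominant.
#'
#' @param radius segment radius (um).
#' @param length segment length (um).
#' @param haematocrit segment haematocrit in \[0, 1\].
#' @param c_tissue local tissue oxygen concentration (model units).
#' @param perfused logical; unperfused segments exchange nothing.
#' @param P_O2 oxygen permeability coefficient (model units; the growth and
#'   elimination studies use the printed pairing 3800 vs 3116).
#' @param site_volume voxel volume (um^3).
#' @param h_ref haematocrit giving blood concentration 1 (default 0.45).
#' @param perm_scale dimensionless constant fixing the permeability unit of
#'   \code{P_O2} (default 1/15; see the methods vignette).
#' @return net source rate (conc/min) delivered to the tissue site.
#' @export
vessel_oxygen_exchange <- function(radius, length, haematocrit, c_tissue,
                                   perfused = TRUE, P_O2 = 3800,
                                   site_volume = 40^3, h_ref = 0.45,
                                   perm_scale = 1 / 15) {
  if (any(haematocrit < 0)) stop("negative haematocrit")
  if (any(haematocrit > 1)) stop("haematocrit above 1")
  kA <- perm_scale * 2 * pi * radius * length / site_volume
  c_blood <- haematocrit / h_ref
  rate <- P_O2 * kA * (c_blood - c_tissue)
  rate * as.numeric(perfused)
}

# Per-site (sink coefficient, source) contributions of the vessel network's
# oxygen exchange, in linear site order. Each perfused segment spreads its
# wall surface over its two endpoint sites.
vessel_exchange_coefficients <- function(net, spec, P_O2, h_ref = 0.45,
                                         perm_scale = 1 / 15) {
  n <- spec$n
  sink <- numeric(n); src <- numeric(n)
  if (nrow(net$segments) == 0L) return(list(sink = sink, source = src))
  seg <- net$segments[net$segments$perfused, , drop = FALSE]
  if (nrow(seg) == 0L) return(list(sink = sink, source = src))
  vsite <- spec$spacing^3
  kA <- perm_scale * 2 * pi * seg$radius * seg$length / vsite / 2  # per endpoint
  cb <- pmin(seg$haematocrit, 1) / h_ref
  for (end in c("a", "b")) {
    lin <- net$nodes$lin[match(seg[[end]], net$nodes$id)]
    sink_add <- P_O2 * kA
    src_add <- P_O2 * kA * cb
    agg_s <- rowsum(sink_add, lin)
    agg_q <- rowsum(src_add, lin)
    idx <- as.integer(rownames(agg_s))
    sink[idx] <- sink[idx] + agg_s[, 1L]
    src[idx] <- src[idx] + agg_q[, 1L]
  }
  list(sink = sink, source = src)
}
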