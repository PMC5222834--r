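# Eigenmodes of the conical Euler-Bernoulli beam: (s^4 V'')'' = lambda^2 s^2 V
# on [a, 1], clamped at the base s = 1, with either a pinned contact at s = a
# (V = V'' = 0) or a free tip (V'' = V''' = 0). Two independent numerical
# routes are provided: Chebyshev spectral collocation of the strong ODE, and
# a Rayleigh-Ritz projection on the eigenmodes of the equivalent cylindrical
# rod (same L, E, rho, radius b).

# --- Chebyshev machinery (Trefethen-style, points descending on [-1,1]) ----

cheb_diff <- function(N) {
  x <- cos(pi * (0:N) / N)
  c <- c(2, rep(1, N - 1), 2) * (-1)^(0:N)
  X <- matrix(rep(x, N + 1), N + 1)
  dX <- X - t(X)
  D <- outer(c, 1 / c) / (dX + diag(N + 1))
  D <- D - diag(rowSums(D))
  list(D = D, x = x)
}

clencurt <- function(N) {
  theta <- pi * (0:N) / N
  w <- rep(0, N + 1); ii <- 2:N; v <- rep(1, N - 1)
  if (N %% 2 == 0) {
    w[1] <- w[N + 1] <- 1 / (N^2 - 1)
    if (N / 2 >= 2)
      for (m in 1:(N / 2 - 1)) v <- v - 2 * cos(2 * m * theta[ii]) / (4 * m^2 - 1)
    v <- v - cos(N * theta[ii]) / (N^2 - 1)
  } else {
    w[1] <- w[N + 1] <- 1 / N^2
    for (m in 1:((N - 1) / 2)) v <- v - 2 * cos(2 * m * theta[ii]) / (4 * m^2 - 1)
  }
  w[ii] <- 2 * v / N
  w
}

# --- mode_set container ----------------------------------------------------

new_mode_set <- function(spec, boundary_kind, method, a, lambda, s, V,
                         d2V_base, D1, D2, weights, Vpp = NULL,
                         d3V_end = NULL) {
  k <- timescale_k(spec)
  structure(list(boundary_kind = boundary_kind, method = method,
                 domain = c(a, 1), lambda = lambda, omega = lambda / k,
                 k = k, s = s, V = V, Vpp = Vpp, d2V_base = d2V_base,
                 d3V_end = d3V_end, D1 = D1, D2 = D2, weights = weights,
                 normalization = "mass", spec = spec),
            class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf("<mode_set> %s (%s), domain [%.3g, 1], %d mode(s)\n",
              x$boundary_kind, x$method, x$domain[1], length(x$lambda)))
  cat("  f_i [Hz]:", paste(sprintf("%.5g", x$omega / (2 * pi)), collapse = " "), "\n")
  invisible(x)
}

# mass-weighted projection  int s^2 f(s) V_i(s) ds  for all modes
modeset_project <- function(modes, f) {
  fv <- if (is.function(f)) f(modes$s) else f
  as.numeric(crossprod(modes$V, modes$weights * modes$s^2 * fv))
}

# evaluate mode shapes at arbitrary s (barycentric interpolation from the
# Chebyshev sample)
modeset_eval <- function(modes, s_out) {
  if (any(s_out < modes$domain[1] - 1e-12) || any(s_out > 1 + 1e-12))
    stop("s_out outside the mode domain", call. = FALSE)
  apply(modes$V, 2, function(v) pracma::barylag(modes$s, v, s_out))
}

normalize_modes <- function(s, V, w, D1) {
  n <- ncol(V)
  for (i in seq_len(n)) {
    V[, i] <- V[, i] / sqrt(sum(w * s^2 * V[, i]^2))
    # sign convention: positive slope at the non-base end (last grid point)
    if ((D1 %*% V[, i])[length(s)] < 0) V[, i] <- -V[, i]
  }
  V
}

# --- direct spectral solver ------------------------------------------------

# Chebyshev antiderivative: values -> values of int_a^s f ds on the mapped
# grid [a, 1] (points descending in s). Built in coefficient space, so the
# operator is well conditioned — unlike 4th-order differentiation, whose
# conditioning grows as N^8 and corrupts eigenvectors near the degenerate
# (s^4 -> 0) tip.
cheb_int_mat <- function(N, a) {
  j <- 0:N
  C <- cos(pi * outer(j, j) / N)              # coefficients -> values
  V2C <- (2 / N) * C %*% diag(c(0.5, rep(1, N - 1), 0.5))
  V2C[1, ] <- V2C[1, ] / 2
  V2C[N + 1, ] <- V2C[N + 1, ] / 2
  A <- matrix(0, N + 1, N + 1)                # antidifferentiation of T_k
  A[2, 1] <- 1
  if (N >= 2) A[2, 3] <- -0.5
  for (k in 2:N) {
    A[k + 1, k] <- 1 / (2 * k)
    if (k + 2 <= N + 1) A[k + 1, k + 2] <- -1 / (2 * k)
  }
  S <- C %*% A %*% V2C
  S <- S - matrix(rep(S[N + 1, ], each = N + 1), N + 1)  # zero at s = a
  S * (1 - a) / 2
}

# Solves the expanded form s^2 V'''' + 8 s V''' + 12 V'' = lambda^2 V with
# u = V'''' as the unknown: all four boundary conditions are absorbed into
# exact integration constants, so V, V', V'' come out with machine-accurate
# boundary values and the generalized eigenproblem is well conditioned.
solve_modes_direct <- function(spec, a, boundary_kind, n_modes, n_grid = 140) {
  n <- n_grid + 1
  x <- cos(pi * (0:n_grid) / n_grid)
  s <- a + (x + 1) * (1 - a) / 2            # descending: s[1] = 1, s[n] = a
  S1 <- cheb_int_mat(n_grid, a)
  S2 <- S1 %*% S1; S3 <- S2 %*% S1; S4 <- S2 %*% S2
  one <- rep(1, n)
  if (boundary_kind == "free_tip") {
    # V''(a) = V'''(a) = 0 are automatic; V(1) = V'(1) = 0 fix the constants
    rc1 <- -S3[1, ]
    rc0 <- -S4[1, ] - (1 - a) * rc1
    Vmat <- S4 + outer(s - a, rc1) + outer(one, rc0)
    Dmat <- S3 + outer(one, rc1)
    Wmat <- S2
    Tmat <- S1
  } else {
    # V(a) = V''(a) = 0 automatic; V(1) = V'(1) = 0 give a 2x2 system
    h <- 1 - a
    Mc <- matrix(c(h^3 / 6, h, h^2 / 2, 1), 2, 2, byrow = TRUE)
    R <- -solve(Mc) %*% rbind(S4[1, ], S3[1, ])
    rc3 <- R[1, ]; rc1 <- R[2, ]
    Vmat <- S4 + outer((s - a)^3 / 6, rc3) + outer(s - a, rc1)
    Dmat <- S3 + outer((s - a)^2 / 2, rc3) + outer(one, rc1)
    Wmat <- S2 + outer(s - a, rc3)
    Tmat <- S1 + outer(one, rc3)
  }
  L <- diag(s^4) + 8 * s^3 * Tmat + 12 * s^2 * Wmat
  B <- s^2 * Vmat
  E <- tryCatch(eigen(solve(L, B)),
                error = function(e)
                  stop(sprintf(
                    "eigen solve failed (n_grid = %d, end coordinate = %.3g): %s",
                    n_grid, a, conditionMessage(e)), call. = FALSE))
  theta <- E$values
  ok <- abs(Im(theta)) < 1e-8 * Mod(theta) & Re(theta) > 1e-12
  if (sum(ok) < n_modes)
    stop(sprintf(
      "solver returned %d usable eigenvalues < n_modes = %d (n_grid = %d, end = %.3g)",
      sum(ok), n_modes, n_grid, a), call. = FALSE)
  theta_r <- Re(theta[ok]); vec <- Re(E$vectors[, ok, drop = FALSE])
  ord <- order(1 / theta_r)[seq_len(n_modes)]
  mu <- (1 / theta_r)[ord]
  u <- vec[, ord, drop = FALSE]
  V <- Vmat %*% u
  Vp <- Dmat %*% u
  Vpp <- Wmat %*% u
  Vppp <- Tmat %*% u
  w <- clencurt(n_grid) * (1 - a) / 2
  nrm <- sqrt(colSums(w * s^2 * V^2))
  sgn <- ifelse(Vp[n, ] / nrm > 0, 1, -1)   # V' > 0 at the non-base end
  V <- sweep(V, 2, nrm * sgn, "/")
  Vpp <- sweep(Vpp, 2, nrm * sgn, "/")
  cb <- cheb_diff(n_grid)
  D1 <- cb$D * (2 / (1 - a))
  new_mode_set(spec, boundary_kind, "direct", a, sqrt(mu), s, V,
               d2V_base = Vpp[1, ], D1 = D1, D2 = D1 %*% D1,
               weights = w, Vpp = Vpp,
               d3V_end = sweep(Vppp, 2, nrm * sgn, "/")[n, ])
}

#' Conical eigenmodes with a pinned contact
#'
#' Solves `(s^4 V'')'' = lambda^2 s^2 V` on `[epsilon, 1]`, clamped at the
#' base (`V(1) = V'(1) = 0`) and pinned at the contact point
#' (`V(eps) = V''(eps) = 0`), by Chebyshev spectral collocation. The problem
#' is posed on `[epsilon, 1]` only: deflections distal to the contact do not
#' load the base in this model. Mode shapes are normalised to
#' `int s^2 V_i^2 ds = 1` (the cone's mass weighting, required for the modal
#' projection formulas) with sign fixed by `V'(epsilon) > 0`.
#'
#' @param spec A [whisker_spec()].
#' @param epsilon Contact coordinate in `(0, 0.97]`.
#' @param n_modes Number of modes (default 3).
#' @param n_grid Chebyshev polynomial degree (default 140).
#' @return A `mode_set` with dimensionless eigenvalues `lambda`, angular
#'   frequencies `omega = lambda / k`, sampled shapes `V`, base curvatures
#'   `d2V_base` and quadrature `weights`.
#' @export
solve_modes_pinned <- function(spec, epsilon, n_modes = 3, n_grid = 140) {
  stop_if_not_spec(spec)
  if (!is.finite(epsilon) || epsilon <= 0 || epsilon > 0.97)
    stop("epsilon must lie in (0, 0.97]", call. = FALSE)
  if (n_modes < 1) stop("n_modes >= 1 required", call. = FALSE)
  solve_modes_direct(spec, epsilon, "contact_pinned", n_modes, n_grid)
}

#' Conical eigenmodes with a free tip
#'
#' Solves the same eigenproblem on `[s_tip, 1]` with the tip free of force
#' and torque: `V''(s_tip) = V'''(s_tip) = 0`. Used for free whisking in air.
#'
#' @inheritParams solve_modes_pinned
#' @param n_modes Number of modes (default 5).
#' @export
solve_modes_free <- function(spec, n_modes = 5, n_grid = 140) {
  stop_if_not_spec(spec)
  if (spec$tip_coord < 0.01 || spec$tip_coord > 0.3)
    stop("free-tip solver requires s_tip in [0.01, 0.3]", call. = FALSE)
  solve_modes_direct(spec, spec$tip_coord, "free_tip", n_modes, n_grid)
}

# --- cylinder-basis Galerkin route ----------------------------------------

#' Characteristic roots of the uniform-rod eigenproblem
#'
#' Roots `beta` of `cos(beta) cosh(beta) = -1` (clamped-free rod) or
#' `tan(beta) = tanh(beta)` (clamped-pinned rod), each to 1e-10, used to
#' build the cylinder mode basis.
#'
#' @param boundary_kind `"clamped_free"` or `"clamped_pinned"`.
#' @param n Number of roots.
#' @return Numeric vector of roots, asymptotically spaced by `pi`.
#' @export
cylinder_char_roots <- function(boundary_kind = c("clamped_free", "clamped_pinned"),
                                n) {
  boundary_kind <- match.arg(boundary_kind)
  if (n < 1) stop("n >= 1 required", call. = FALSE)
  roots <- numeric(n)
  for (i in seq_len(n)) {
    if (boundary_kind == "clamped_free") {
      # cos b = -sech b, stable for large b
      f <- function(b) cos(b) + 1 / cosh(b)
      ctr <- (i - 0.5) * pi
      br <- if (i == 1) c(1.2, 2.4) else c(ctr - 0.6, ctr + 0.6)
    } else {
      # sin b - cos b tanh b = 0
      f <- function(b) sin(b) - cos(b) * tanh(b)
      ctr <- (i + 0.25) * pi
      br <- c(ctr - 0.4, ctr + 0.4)
    }
    roots[i] <- stats::uniroot(f, br, tol = 1e-12)$root
  }
  roots
}

# stable evaluation of the clamped-(free|pinned) rod mode and derivatives at
# xi in [0,1] (clamped at xi = 0); returns phi, phi', phi''
rod_mode <- function(beta, boundary_kind, xi) {
  if (boundary_kind == "clamped_free") {
    num <- sin(beta) - cos(beta) - exp(-beta)
    den <- sinh(beta) + sin(beta)
  } else {
    num <- cos(beta) - sin(beta) - exp(-beta)
    den <- sinh(beta) - sin(beta)
  }
  oms <- num / den  # 1 - sigma, computed without cancellation
  e <- exp(-beta * xi); shx <- sinh(beta * xi); chx <- cosh(beta * xi)
  list(phi  = e + oms * shx - cos(beta * xi) + (1 - oms) * sin(beta * xi),
       dphi = beta * (-e + oms * chx + sin(beta * xi) + (1 - oms) * cos(beta * xi)),
       d2phi = beta^2 * (e + oms * shx + cos(beta * xi) - (1 - oms) * sin(beta * xi)))
}

#' Conical eigenmodes by cylinder-basis Galerkin projection
#'
#' Rayleigh-Ritz solution of the conical eigenproblem using as trial
#' functions the eigenmodes of a cylindrical rod of the same length, Young's
#' modulus and density, with radius equal to the cone's base radius. Each
#' basis function satisfies all four boundary conditions, so the projected
#' generalized eigenproblem `K c = mu M c` (bending stiffness vs `s^2` mass)
#' gives upper bounds on the true eigenvalues that decrease monotonically as
#' the basis grows. This route remains stable at contact points close to the
#' base where direct collocation degrades.
#'
#' @inheritParams solve_modes_pinned
#' @param end_coord Contact coordinate `epsilon` (pinned) or `s_tip` (free);
#'   defaults to `spec$tip_coord` for the free case.
#' @param boundary_kind `"contact_pinned"` or `"free_tip"`.
#' @param n_basis Number of cylinder modes in the basis (default 24); must be
#'   at least `n_modes + 4`.
#' @param n_quad Gauss-Legendre points for the projection integrals.
#' @return A `mode_set` (method `"cylinder_basis"`), sampled on a Chebyshev
#'   grid for interchangeability with the direct solver.
#' @export
cylinder_basis_modes <- function(spec, end_coord = NULL,
                                 boundary_kind = c("contact_pinned", "free_tip"),
                                 n_basis = 24, n_modes = 3, n_quad = 400,
                                 n_grid = 140) {
  stop_if_not_spec(spec)
  boundary_kind <- match.arg(boundary_kind)
  if (is.null(end_coord)) {
    if (boundary_kind == "free_tip") end_coord <- spec$tip_coord
    else stop("end_coord (epsilon) required for contact_pinned", call. = FALSE)
  }
  a <- end_coord
  if (a <= 0 || a >= 1) stop("end coordinate must lie in (0, 1)", call. = FALSE)
  if (n_basis < n_modes + 4)
    stop("n_basis must be at least n_modes + 4", call. = FALSE)
  rod_kind <- if (boundary_kind == "contact_pinned") "clamped_pinned" else "clamped_free"
  betas <- cylinder_char_roots(rod_kind, n_basis)
  gl <- pracma::gaussLegendre(n_quad, a, 1)
  sq <- gl$x; wq <- gl$w
  xi <- (1 - sq) / (1 - a)
  jac <- 1 / (1 - a)^2        # (dxi/ds)^2
  P <- matrix(0, n_quad, n_basis); Pdd <- matrix(0, n_quad, n_basis)
  for (j in seq_len(n_basis)) {
    bm <- rod_mode(betas[j], rod_kind, xi)
    P[, j] <- bm$phi
    Pdd[, j] <- bm$d2phi * jac
  }
  K <- crossprod(Pdd, Pdd * (wq * sq^4))
  M <- crossprod(P, P * (wq * sq^2))
  K <- (K + t(K)) / 2; M <- (M + t(M)) / 2
  if (rcond(M) < 1e-13)
    stop(sprintf(
      "cylinder basis overlap matrix ill-conditioned (n_basis = %d); reduce n_basis",
      n_basis), call. = FALSE)
  Lc <- chol(M)
  Linv <- backsolve(Lc, diag(n_basis))
  A <- t(Linv) %*% K %*% Linv
  A <- (A + t(A)) / 2
  E <- eigen(A, symmetric = TRUE)
  idx <- rev(seq_len(n_basis))[seq_len(n_modes)]  # ascending eigenvalues
  mu <- E$values[idx]
  coefs <- Linv %*% E$vectors[, idx, drop = FALSE]
  # sample the Ritz modes on a Chebyshev grid of [a, 1]
  cb <- cheb_diff(n_grid)
  s <- a + (cb$x + 1) * (1 - a) / 2
  D1 <- cb$D * (2 / (1 - a))
  D2 <- D1 %*% D1
  xs <- (1 - s) / (1 - a)
  rods <- lapply(seq_len(n_basis), function(j) rod_mode(betas[j], rod_kind, xs))
  Phi <- sapply(rods, `[[`, "phi")
  Phi_dd <- sapply(rods, `[[`, "d2phi") * jac
  V <- Phi %*% coefs
  w <- clencurt(n_grid) * (1 - a) / 2
  # normalisation and sign fixed explicitly so the analytic base curvature
  # (phi''(xi = 0) = 2 beta^2 per rod mode) can be rescaled consistently
  scale_fix <- numeric(n_modes)
  for (i in seq_len(n_modes)) {
    f <- 1 / sqrt(sum(w * s^2 * V[, i]^2))
    if ((D1 %*% (V[, i] * f))[n_grid + 1] < 0) f <- -f
    V[, i] <- V[, i] * f
    scale_fix[i] <- f
  }
  d2V_base <- as.numeric((2 * betas^2 * jac) %*% coefs) * scale_fix
  Vpp <- sweep(Phi_dd %*% coefs, 2, scale_fix, "*")
  ms <- new_mode_set(spec, boundary_kind, "cylinder_basis", a, sqrt(mu), s, V,
                     d2V_base = d2V_base, D1 = D1, D2 = D2, weights = w,
                     Vpp = Vpp)
  ms$n_basis <- n_basis
  ms
}

#' Eigenmode dispatcher used by the dynamics layer
#'
#' Direct collocation for free-tip modes and for pinned contacts at
#' `epsilon <= 0.35`; cylinder-basis Galerkin for pinned contacts closer to
#' the base, where direct solution of the conical problem is numerically
#' fragile.
#'
#' @inheritParams solve_modes_pinned
#' @param boundary_kind `"contact_pinned"` or `"free_tip"`.
#' @export
whisker_modes <- function(spec, epsilon = NULL,
                          boundary_kind = c("contact_pinned", "free_tip"),
                          n_modes = 3, ...) {
  boundary_kind <- match.arg(boundary_kind)
  if (boundary_kind == "free_tip")
    return(solve_modes_free(spec, n_modes = n_modes, ...))
  if (epsilon <= 0.35)
    solve_modes_pinned(spec, epsilon, n_modes = n_modes, ...)
  else
    cylinder_basis_modes(spec, epsilon, "contact_pinned",
                         n_basis = max(24, n_modes + 6), n_modes = n_modes)
}

# --- serialization ---------------------------------------------------------

#' Read and write mode sets as CSV
#'
#' First line: the dimensionless eigenvalues `lambda_i`. Then a CSV table
#' with columns `s, V1, V2, ...`.
#'
#' @param modes A `mode_set`.
#' @param path File path.
#' @export
write_mode_set <- function(modes, path) {
  stopifnot(inherits(modes, "mode_set"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(format(modes$lambda, digits = 17), collapse = ","), con)
  df <- data.frame(s = modes$s, modes$V)
  names(df) <- c("s", paste0("V", seq_len(ncol(modes$V))))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mode_set
#' @export
read_mode_set <- function(path) {
  lines <- readLines(path)
  lambda <- as.numeric(strsplit(lines[1], ",")[[1]])
  df <- utils::read.csv(text = paste(lines[-1], collapse = "\n"))
  list(lambda = lambda, s = df$s,
       V = as.matrix(df[, -1, drop = FALSE]))
}
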