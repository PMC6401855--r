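# Core SCFT machinery: the coupled nonlinear field equations for the lateral
# packing field pi(z) and the electrostatic potential psi(z), their analytic
# Jacobian, the damped-Newton solver and the semi-grand potential.
#
# Reduced units throughout: energies in kT, lengths in nm, charges in e.
# Both fields are bulk-gauged (they vanish in the far field).

.clip_exp <- function(x, lim = 500) pmin(pmax(x, -lim), lim)

#' Assemble an SCFT problem
#'
#' Packages the conformational ensemble, bulk reservoir, binding constants
#' and grafting density into the internal form used by the solver.
#'
#' @param ensemble a [generate_ensemble()] or [manual_ensemble()] object.
#' @param sigma_p grafting density, chains/nm2.
#' @param bulk a [solve_bulk()] reservoir state.
#' @param constants a [binding_constants()] object.
#' @param catalog a [species_catalog()]; defaults to the bulk's catalog.
#' @param polymer_charged set `FALSE` for toy problems with a neutral chain
#'   (no monomer charge and no binding equilibria).
#' @return object of class `scft_system`.
#' @export
scft_system <- function(ensemble, sigma_p, bulk, constants,
                        catalog = bulk$catalog, polymer_charged = TRUE) {
  stopifnot(sigma_p >= 0)
  L <- ensemble$n_layers
  Lc <- ensemble$layers_used
  nA <- matrix(as.numeric(ensemble$nA), nrow(ensemble$nA))
  nG <- matrix(as.numeric(ensemble$nG), nrow(ensemble$nG))
  # bulk monomer-state fractions (gauge reference for the chain weights)
  fbA <- .fractions_one(bulk$a[["H"]], bulk$a[["Na"]], bulk$a[["Mg"]], 0,
                        constants$K[["AH"]], constants$K[["ANa"]],
                        constants$K[["AMg"]], constants$dv)
  fbG <- .fractions_one(bulk$a[["H"]], bulk$a[["Na"]], bulk$a[["Mg"]], 0,
                        constants$K[["GH"]], constants$K[["GNa"]],
                        constants$K[["GMg"]], constants$dv, type = "G")
  lB <- bjerrum_length(catalog$eps_r, bulk$T)
  structure(list(
    L = L, Lc = Lc, dz = ensemble$dz,
    z = (seq_len(L) - 0.5) * ensemble$dz,
    nA = nA, nG = nG, tnA = t(nA), tnG = t(nG), m = ensemble$m,
    n_conformations = ensemble$n_conformations,
    sigma_p = sigma_p, bulk = bulk, constants = constants, catalog = catalog,
    v = catalog$v, zval = catalog$z, vw = catalog$vw,
    vA = catalog$v_A, vG = catalog$v_G,
    fbA = fbA, fbG = fbG,
    lB = lB, eps_eff = 1 / (4 * pi * lB),
    polymer_charged = polymer_charged,
    ensemble_meta = list(seed = ensemble$seed,
                         rotations_per_state = ensemble$rotations_per_state,
                         n_conformations = ensemble$n_conformations)
  ), class = "scft_system")
}

# four-state mass action for one monomer type; activities are rho*vw,
# pi_ enters only through a nonzero reaction volume change
.fractions_one <- function(aH, aNa, aMg, pi_, KH, KNa, KMg, dv, type = "A") {
  sfx <- if (type == "A") c("AH", "ANa", "AMg") else c("GH", "GNa", "GMg")
  xH <- KH * aH * exp(.clip_exp(-pi_ * dv[[sfx[1]]]))
  xNa <- KNa * aNa * exp(.clip_exp(-pi_ * dv[[sfx[2]]]))
  xMg <- KMg * aMg * exp(.clip_exp(-pi_ * dv[[sfx[3]]]))
  fm <- 1 / (1 + xH + xNa + xMg)
  cbind(minus = fm, H = xH * fm, Na = xNa * fm, Mg = xMg * fm)
}

#' Free-species density profiles from the fields
#'
#' rho_g(z) = rho_g^b exp(-pi(z) v_g - z_g psi(z)) in the bulk gauge; the
#' exponent is clipped at +/-500 to guard early iterations.
#'
#' @param fields list with numeric vectors `pi` and `psi` (length L).
#' @param bulk a [solve_bulk()] state.
#' @param catalog a [species_catalog()].
#' @return L x 6 matrix of densities (nm^-3), columns w, H, OH, Na, Mg, Cl.
#' @export
species_density_profiles <- function(fields, bulk, catalog = bulk$catalog) {
  expo <- .clip_exp(-outer(fields$pi, catalog$v) - outer(fields$psi, catalog$z))
  sweep(exp(expo), 2, bulk$rho, "*")
}

#' Monomer state fractions from local ion densities
#'
#' Closed-form solution of the four-state mass-action system at every layer;
#' the four fractions sum to one by construction.
#'
#' @param pi_ packing field, kT/nm3 (enters only with nonzero reaction
#'   volume changes).
#' @param rho_H,rho_Na,rho_Mg local free-ion densities, nm^-3.
#' @param constants a [binding_constants()].
#' @return list of matrices `A` and `G` (layers x minus/H/Na/Mg).
#' @export
monomer_state_fractions <- function(pi_, rho_H, rho_Na, rho_Mg, constants) {
  vw <- constants$vw
  list(
    A = .fractions_one(rho_H * vw, rho_Na * vw, rho_Mg * vw, pi_,
                       constants$K[["AH"]], constants$K[["ANa"]],
                       constants$K[["AMg"]], constants$dv, "A"),
    G = .fractions_one(rho_H * vw, rho_Na * vw, rho_Mg * vw, pi_,
                       constants$K[["GH"]], constants$K[["GNa"]],
                       constants$K[["GMg"]], constants$dv, "G")
  )
}

#' Conformation probabilities from the fields
#'
#' The per-monomer layer weight is w_i(k) = ln f_i-(k) + pi(k) v_i - psi(k)
#' (deprotonated reference state; constant standard potentials drop into the
#' normalization). Probabilities are computed with log-sum-exp and include
#' the multiplicity of each unique occupancy vector, so `sum(P) == 1`.
#'
#' @param fields list with `pi` and `psi`.
#' @param fractions output of [monomer_state_fractions()] (only the `minus`
#'   columns are used).
#' @param ensemble a `conformation_ensemble`.
#' @param catalog a [species_catalog()] (for the monomer volumes).
#' @param charged if `FALSE` the chain is neutral: w_i = pi v_i.
#' @return numeric vector of probabilities per unique conformation class.
#' @export
conformation_weights <- function(fields, fractions, ensemble,
                                 catalog = species_catalog(), charged = TRUE) {
  idx <- seq_len(ensemble$layers_used)
  if (charged) {
    wA <- log(fractions$A[idx, "minus"]) + fields$pi[idx] * catalog$v_A - fields$psi[idx]
    wG <- log(fractions$G[idx, "minus"]) + fields$pi[idx] * catalog$v_G - fields$psi[idx]
  } else {
    wA <- fields$pi[idx] * catalog$v_A
    wG <- fields$pi[idx] * catalog$v_G
  }
  nA <- matrix(as.numeric(ensemble$nA), nrow(ensemble$nA))
  nG <- matrix(as.numeric(ensemble$nG), nrow(ensemble$nG))
  lw <- -(nA %*% wA + nG %*% wG)
  lw <- lw - max(lw)
  pw <- ensemble$m * exp(lw)
  if (!any(pw > 0)) stop("all conformation weights vanished (degenerate fields)")
  drop(pw / sum(pw))
}

#' Ensemble-average monomer number densities
#'
#' rho_i(z_k) = sigma_p * sum_a P(a) n_i(a;k) / dz.
#'
#' @param P conformation probabilities (summing to one).
#' @param ensemble a `conformation_ensemble`.
#' @param sigma_p grafting density, chains/nm2.
#' @param grid a [scft_grid()] (defaults to the ensemble's grid).
#' @return list with vectors `rho_A`, `rho_G` (length `n_layers`, nm^-3).
#' @export
average_monomer_densities <- function(P, ensemble, sigma_p, grid = NULL) {
  L <- if (is.null(grid)) ensemble$n_layers else grid$n_layers
  dz <- if (is.null(grid)) ensemble$dz else grid$dz
  idx <- seq_len(ensemble$layers_used)
  rho_A <- numeric(L); rho_G <- numeric(L)
  rho_A[idx] <- sigma_p * drop(crossprod(matrix(as.numeric(ensemble$nA),
                                                nrow(ensemble$nA)), P)) / dz
  rho_G[idx] <- sigma_p * drop(crossprod(matrix(as.numeric(ensemble$nG),
                                                nrow(ensemble$nG)), P)) / dz
  list(rho_A = rho_A, rho_G = rho_G)
}

#' Ensemble-average charge density
#'
#' rho_q = sum_g z_g rho_g - rho_A (f_A- - f_AMg) - rho_G (f_G- - f_GMg),
#' in e/nm3. Protonated and Na-bound monomer states are neutral.
#'
#' @param rho L x 6 free-species density matrix.
#' @param rho_A,rho_G monomer density profiles.
#' @param fractions output of [monomer_state_fractions()].
#' @param catalog a [species_catalog()] (for the valences).
#' @return numeric vector, e/nm3.
#' @export
charge_density <- function(rho, rho_A, rho_G, fractions,
                           catalog = species_catalog()) {
  free_q <- drop(rho %*% catalog$z)
  free_q - rho_A * (fractions$A[, "minus"] - fractions$A[, "Mg"]) -
    rho_G * (fractions$G[, "minus"] - fractions$G[, "Mg"])
}

# Core evaluation: residuals (and optionally the full profile state) from the
# stacked unknown vector x = c(pi, psi).
.eval_fields <- function(x, sys, full = FALSE) {
  L <- sys$L; dz <- sys$dz; idx <- seq_len(sys$Lc)
  pi_ <- x[seq_len(L)]; psi <- x[L + seq_len(L)]
  expo <- .clip_exp(-outer(pi_, sys$v) - outer(psi, sys$zval))
  a <- sweep(exp(expo), 2, sys$bulk$a, "*")     # dimensionless activities
  rho <- a / sys$vw
  K <- sys$constants$K; dv <- sys$constants$dv
  if (sys$polymer_charged) {
    fA <- .fractions_one(a[, "H"], a[, "Na"], a[, "Mg"], pi_,
                         K[["AH"]], K[["ANa"]], K[["AMg"]], dv, "A")
    fG <- .fractions_one(a[, "H"], a[, "Na"], a[, "Mg"], pi_,
                         K[["GH"]], K[["GNa"]], K[["GMg"]], dv, "G")
    wA <- log(fA[idx, "minus"] / sys$fbA[, "minus"]) + pi_[idx] * sys$vA - psi[idx]
    wG <- log(fG[idx, "minus"] / sys$fbG[, "minus"]) + pi_[idx] * sys$vG - psi[idx]
  } else {
    fA <- cbind(minus = rep(1, L), H = 0, Na = 0, Mg = 0)
    fG <- fA
    wA <- pi_[idx] * sys$vA
    wG <- pi_[idx] * sys$vG
  }
  # conformation probabilities (log-sum-exp, multiplicities included)
  lw <- -(sys$nA %*% wA + sys$nG %*% wG)
  mx <- max(lw)
  pw <- sys$m * exp(lw - mx)
  spw <- sum(pw)
  P <- drop(pw / spw)
  logq <- mx + log(spw)

  rho_A <- numeric(L); rho_G <- numeric(L)
  if (sys$sigma_p > 0) {
    rho_A[idx] <- sys$sigma_p * drop(sys$tnA %*% P) / dz
    rho_G[idx] <- sys$sigma_p * drop(sys$tnG %*% P) / dz
  }
  # bound-state extra volumes per monomer (complex = monomer + ion volume)
  bH <- sys$v[["H"]]; bNa <- sys$v[["Na"]]; bMg <- sys$v[["Mg"]]
  sA <- fA[, "H"] * (bH + dv[["AH"]]) + fA[, "Na"] * (bNa + dv[["ANa"]]) +
        fA[, "Mg"] * (bMg + dv[["AMg"]])
  sG <- fG[, "H"] * (bH + dv[["GH"]]) + fG[, "Na"] * (bNa + dv[["GNa"]]) +
        fG[, "Mg"] * (bMg + dv[["GMg"]])
  phi_p <- rho_A * (sys$vA + sA) + rho_G * (sys$vG + sG)
  phi_free <- sweep(a, 2, sys$v / sys$vw, "*")
  pack <- phi_p + rowSums(phi_free) - 1

  free_q <- drop(rho %*% sys$zval)
  cA <- fA[, "minus"] - fA[, "Mg"]
  cG <- fG[, "minus"] - fG[, "Mg"]
  rho_q <- if (sys$polymer_charged) free_q - rho_A * cA - rho_G * cG
           else rep(0, L)
  psil <- c(psi[1], psi[-L])
  psir <- c(psi[-1], 0)
  pois <- sys$eps_eff * (psil - 2 * psi + psir) / dz^2 + rho_q

  res <- c(pack, pois)
  if (!full) return(res)
  list(res = res, pi = pi_, psi = psi, a = a, rho = rho,
       fA = fA, fG = fG, wA = wA, wG = wG, P = P, logq = logq,
       rho_A = rho_A, rho_G = rho_G, sA = sA, sG = sG, cA = cA, cG = cG,
       phi_p = phi_p, phi_free = phi_free, rho_q = rho_q,
       pack = pack, pois = pois)
}

#' Per-layer residuals of the field equations
#'
#' Block 1: packing, phi_polymer + sum of free-species volume fractions - 1.
#' Block 2: the discrete Poisson equation,
#' eps (psi_(k-1) - 2 psi_k + psi_(k+1)) / dz^2 + rho_q(z_k), with a Neumann
#' ghost node at the wall and a Dirichlet zero beyond the far edge.
#'
#' @param fields list with `pi` and `psi`.
#' @param sys an [scft_system()].
#' @return numeric vector of length 2 * n_layers.
#' @export
residual_vector <- function(fields, sys) {
  .eval_fields(c(fields$pi, fields$psi), sys)
}

# Analytic Jacobian of the stacked residual. The polymer contribution uses
# the conformation-ensemble covariance of the layer occupancies; verified
# against finite differences in the test suite.
.jacobian_analytic <- function(x, sys, st = NULL) {
  L <- sys$L; dz <- sys$dz; idx <- seq_len(sys$Lc)
  if (is.null(st)) st <- .eval_fields(x, sys, full = TRUE)
  v <- sys$v; zv <- sys$zval
  rho <- st$rho
  dPack_dpi_f <- -drop(rho %*% (v * v))
  cross_f     <- -drop(rho %*% (zv * v))   # dPack/dpsi and drq/dpi (free)
  drq_dpsi_f  <- -drop(rho %*% (zv * zv))

  Jpp <- diag(dPack_dpi_f, L)
  Jps <- diag(cross_f, L)
  Jqp <- diag(cross_f, L)
  Jqs <- diag(drq_dpsi_f, L)

  if (sys$sigma_p > 0 || TRUE) {
    dv <- sys$constants$dv
    bH <- v[["H"]]; bNa <- v[["Na"]]; bMg <- v[["Mg"]]
    bA <- c(bH + dv[["AH"]], bNa + dv[["ANa"]], bMg + dv[["AMg"]])
    bG <- c(bH + dv[["GH"]], bNa + dv[["GNa"]], bMg + dv[["GMg"]])
    fA <- st$fA; fG <- st$fG
    tA <- fA[, "H"] + fA[, "Na"] + 2 * fA[, "Mg"]
    tG <- fG[, "H"] + fG[, "Na"] + 2 * fG[, "Mg"]
    if (sys$polymer_charged) {
      WpiA <- sys$vA + st$sA[idx]; WpiG <- sys$vG + st$sG[idx]
      WpsA <- -1 + tA[idx];        WpsG <- -1 + tG[idx]
    } else {
      WpiA <- rep(sys$vA, sys$Lc); WpiG <- rep(sys$vG, sys$Lc)
      WpsA <- rep(0, sys$Lc);      WpsG <- rep(0, sys$Lc)
    }
    if (sys$sigma_p > 0) {
      P <- st$P
      nbarA <- drop(sys$tnA %*% P); nbarG <- drop(sys$tnG %*% P)
      CovAA <- crossprod(sys$nA, P * sys$nA) - tcrossprod(nbarA)
      CovAG <- crossprod(sys$nA, P * sys$nG) - tcrossprod(nbarA, nbarG)
      CovGG <- crossprod(sys$nG, P * sys$nG) - tcrossprod(nbarG)
      CovGA <- t(CovAG)
      fac <- sys$sigma_p / dz
      dRA_dpi <- -fac * (sweep(CovAA, 2, WpiA, "*") + sweep(CovAG, 2, WpiG, "*"))
      dRG_dpi <- -fac * (sweep(CovGA, 2, WpiA, "*") + sweep(CovGG, 2, WpiG, "*"))
      dRA_dps <- -fac * (sweep(CovAA, 2, WpsA, "*") + sweep(CovAG, 2, WpsG, "*"))
      dRG_dps <- -fac * (sweep(CovGA, 2, WpsA, "*") + sweep(CovGG, 2, WpsG, "*"))

      volA <- sys$vA + st$sA[idx]; volG <- sys$vG + st$sG[idx]
      Jpp[idx, idx] <- Jpp[idx, idx] + volA * dRA_dpi + volG * dRG_dpi
      Jps[idx, idx] <- Jps[idx, idx] + volA * dRA_dps + volG * dRG_dps
      if (sys$polymer_charged) {
        Jqp[idx, idx] <- Jqp[idx, idx] - st$cA[idx] * dRA_dpi - st$cG[idx] * dRG_dpi
        Jqs[idx, idx] <- Jqs[idx, idx] - st$cA[idx] * dRA_dps - st$cG[idx] * dRG_dps
      }
    }
    if (sys$polymer_charged) {
      # layer-diagonal terms from the field dependence of the fractions
      dsA_dpi <- st$sA^2 - (fA[, "H"] * bA[1]^2 + fA[, "Na"] * bA[2]^2 + fA[, "Mg"] * bA[3]^2)
      dsG_dpi <- st$sG^2 - (fG[, "H"] * bG[1]^2 + fG[, "Na"] * bG[2]^2 + fG[, "Mg"] * bG[3]^2)
      dsA_dps <- st$sA * tA - (fA[, "H"] * bA[1] + fA[, "Na"] * bA[2] + 2 * fA[, "Mg"] * bA[3])
      dsG_dps <- st$sG * tG - (fG[, "H"] * bG[1] + fG[, "Na"] * bG[2] + 2 * fG[, "Mg"] * bG[3])
      diag(Jpp) <- diag(Jpp) + st$rho_A * dsA_dpi + st$rho_G * dsG_dpi
      diag(Jps) <- diag(Jps) + st$rho_A * dsA_dps + st$rho_G * dsG_dps
      dcA_dpi <- st$cA * st$sA + fA[, "Mg"] * bA[3]
      dcG_dpi <- st$cG * st$sG + fG[, "Mg"] * bG[3]
      dcA_dps <- st$cA * tA + 2 * fA[, "Mg"]
      dcG_dps <- st$cG * tG + 2 * fG[, "Mg"]
      diag(Jqp) <- diag(Jqp) - st$rho_A * dcA_dpi - st$rho_G * dcG_dpi
      diag(Jqs) <- diag(Jqs) - st$rho_A * dcA_dps - st$rho_G * dcG_dps
    }
  }
  if (!sys$polymer_charged) {
    Jqp[, ] <- 0; Jqs[, ] <- 0
  }
  # discrete Laplacian (Neumann ghost at the wall, Dirichlet zero at the top)
  lapc <- sys$eps_eff / dz^2
  Lap <- diag(-2 * lapc, L)
  Lap[1, 1] <- -lapc
  if (L > 1) {
    Lap[cbind(1:(L - 1), 2:L)] <- lapc
    Lap[cbind(2:L, 1:(L - 1))] <- lapc
  }
  rbind(cbind(Jpp, Jps), cbind(Jqp, Jqs + Lap))
}

.jacobian_fd <- function(x, sys, r0 = NULL, h0 = 1e-7) {
  if (is.null(r0)) r0 <- .eval_fields(x, sys)
  n <- length(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- h0 * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + h
    J[, j] <- (.eval_fields(xp, sys) - r0) / h
  }
  J
}

#' Solve the coupled field equations
#'
#' Damped Newton iteration on the stacked residual (packing + Poisson) with
#' an analytic Jacobian, Armijo backtracking line search and a ridge fallback
#' for ill-conditioned steps. Deterministic given the ensemble and the
#' starting fields.
#'
#' @param sys an [scft_system()].
#' @param init optional starting fields (list with `pi`, `psi`), default zero.
#' @param control list: `tol` (max-norm residual, default 1e-8), `max_iter`
#'   (default 200), `jacobian` ("analytic" or "fd"), `verbose`.
#' @return object of class `scft_solution` with converged fields, all
#'   profiles, conformation probabilities, residual history and diagnostics.
#' @export
solve_fields <- function(sys, init = NULL, control = list()) {
  ctl <- utils::modifyList(list(tol = 1e-8, max_iter = 200,
                                jacobian = "analytic", verbose = FALSE),
                           control)
  L <- sys$L
  x <- if (is.null(init)) rep(0, 2 * L) else c(init$pi, init$psi)
  stopifnot(length(x) == 2 * L)
  r <- .eval_fields(x, sys)
  if (any(!is.finite(r))) stop("non-finite residual at the starting fields")
  hist <- max(abs(r))
  iter <- 0
  clip_active <- function(xx) {
    expo <- -outer(xx[seq_len(L)], sys$v) - outer(xx[L + seq_len(L)], sys$zval)
    any(abs(expo) > 500)
  }
  while (max(abs(r)) > ctl$tol && iter < ctl$max_iter) {
    iter <- iter + 1
    J <- if (ctl$jacobian == "fd") .jacobian_fd(x, sys, r0 = r)
         else .jacobian_analytic(x, sys)
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step)) {
      ridge <- 1e-8 * max(abs(diag(J)), 1)
      step <- tryCatch(solve(J + diag(ridge, 2 * L), -r),
                       error = function(e) NULL)
      if (is.null(step)) stop("singular Jacobian; cannot continue")
    }
    ss0 <- sum(r^2)
    t <- 1
    accepted <- FALSE
    while (t > 2^-30) {
      xn <- x + t * step
      rn <- .eval_fields(xn, sys)
      if (all(is.finite(rn)) && sum(rn^2) < ss0 * (1 - 1e-4 * t)) {
        x <- xn; r <- rn; accepted <- TRUE
        break
      }
      t <- t / 2
    }
    if (!accepted) {
      # heavily damped fallback move (Picard-like mixing along the Newton
      # direction) to escape a stagnation point
      xn <- x + 0.05 * step
      rn <- .eval_fields(xn, sys)
      if (all(is.finite(rn))) { x <- xn; r <- rn }
      else break
    }
    hist <- c(hist, max(abs(r)))
    if (ctl$verbose)
      message(sprintf("iter %3d  max|r| = %.3e  (step %.2e)", iter,
                      max(abs(r)), t))
  }
  converged <- max(abs(r)) <= ctl$tol
  st <- .eval_fields(x, sys, full = TRUE)
  structure(list(
    fields = list(pi = st$pi, psi = st$psi),
    grid = list(n_layers = L, dz = sys$dz, z = sys$z),
    rho = st$rho, a = st$a,
    fractions = list(A = st$fA, G = st$fG),
    P = st$P, logq = st$logq,
    rho_A = st$rho_A, rho_G = st$rho_G,
    phi_p = st$phi_p, phi_free = st$phi_free, rho_q = st$rho_q,
    residual = st$res, residual_norm = max(abs(st$res)),
    residual_history = hist, iterations = iter, converged = converged,
    clipping_active = clip_active(x),
    sigma_p = sys$sigma_p, bulk = sys$bulk, constants = sys$constants,
    catalog = sys$catalog, polymer_charged = sys$polymer_charged,
    ensemble_meta = sys$ensemble_meta,
    sys = sys
  ), class = "scft_solution")
}

#' @export
print.scft_solution <- function(x, ...) {
  cat(sprintf(
    "scft_solution: sigma_p = %g chains/nm2, %s in %d iterations (max|r| = %.2e)\n",
    x$sigma_p, if (x$converged) "converged" else "NOT converged",
    x$iterations, x$residual_norm))
  invisible(x)
}

#' Semi-grand thermodynamic potential per unit area
#'
#' Bulk-gauged: beta W / A = -sigma_p ln(q / q_bulk)
#' + sum_k dz (sum_g (rho_g^b - rho_g) - pi)
#' - sum interfaces eps/2 (dpsi/dz)^2, the field-eliminated electrostatic
#' form; W vanishes for the bare reservoir (sigma_p = 0, flat fields) and is
#' a maximum of the fields at the solution.
#'
#' @param sol an `scft_solution`, or an [scft_system()] together with
#'   explicit `fields`.
#' @param fields optional fields at which to evaluate (defaults to the
#'   solution's own).
#' @return scalar, kT/nm2.
#' @export
grand_potential_per_area <- function(sol, fields = NULL) {
  sys <- if (inherits(sol, "scft_system")) sol else sol$sys
  if (is.null(fields) && inherits(sol, "scft_solution")) {
    if (!sol$converged)
      warning("evaluating the grand potential on a non-converged state")
    fields <- sol$fields
  }
  x <- c(fields$pi, fields$psi)
  st <- .eval_fields(x, sys, full = TRUE)
  dz <- sys$dz
  logqb <- log(sum(sys$m))
  chain <- if (sys$sigma_p > 0) -sys$sigma_p * (st$logq - logqb) else 0
  osmotic <- dz * sum(sweep(-st$rho, 2, sys$bulk$rho, "+")) - dz * sum(st$pi)
  dpsi <- diff(c(st$psi, 0))   # Dirichlet ghost above; no wall interface
  elec <- -sys$eps_eff / 2 * sum(dpsi^2) / dz
  chain + osmotic + elec
}
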