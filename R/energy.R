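# Component-wise molecular-mechanics energy and analytic gradient.
# Functional form: harmonic bonds k(r - r0)^2 and angles k(th - th0)^2,
# periodic dihedrals k(1 + cos(n phi - gamma)), harmonic impropers on the
# wrapped dihedral, 12-6 Lennard-Jones and Coulomb with a cubic switching
# function below the cutoff.  Units: kcal/mol, Angstrom, degrees in /
# radians internally.

# cubic switch: 1 below r_on, 0 at r_off, C1-continuous
switch_fn <- function(r, r_on, r_off) {
  s <- rep(1, length(r))
  ds <- rep(0, length(r))
  if (is.finite(r_off)) {
    w <- r > r_on & r < r_off
    x <- (r[w] - r_on) / (r_off - r_on)
    s[w] <- 1 - 3 * x^2 + 2 * x^3
    ds[w] <- (-6 * x + 6 * x^2) / (r_off - r_on)
    s[r >= r_off] <- 0
  }
  list(s = s, ds = ds)
}

# dihedral angles (radians) + per-point derivatives for vectors of quads
dihedral_batch <- function(xyz, qi, qj, qk, ql) {
  b1 <- xyz[qj, , drop = FALSE] - xyz[qi, , drop = FALSE]
  b2 <- xyz[qk, , drop = FALSE] - xyz[qj, , drop = FALSE]
  b3 <- xyz[ql, , drop = FALSE] - xyz[qk, , drop = FALSE]
  cr <- function(u, v) {
    cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
          u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
          u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
  }
  n1 <- cr(b1, b2)
  n2 <- cr(b2, b3)
  nb2 <- sqrt(rowSums(b2^2))
  m1 <- cr(sweep(b2, 1L, nb2, "/"), n1)
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  phi <- atan2(y, x)
  n1sq <- rowSums(n1^2)
  n2sq <- rowSums(n2^2)
  dpdi <- -sweep(n1, 1L, nb2 / n1sq, "*")
  dpdl <- sweep(n2, 1L, nb2 / n2sq, "*")
  f1 <- rowSums(b1 * b2) / nb2^2
  f2 <- rowSums(b3 * b2) / nb2^2
  dpdj <- sweep(dpdi, 1L, -(1 + f1), "*") + sweep(dpdl, 1L, f2, "*")
  dpdk <- -(dpdi + dpdj + dpdl)
  list(phi = phi, di = dpdi, dj = dpdj, dk = dpdk, dl = dpdl)
}

# full energy + gradient; gradient skipped when grad = FALSE
energy_gradient <- function(xyz, topology, grad = TRUE) {
  nat <- nrow(xyz)
  g <- if (grad) matrix(0, nat, 3L) else NULL
  add_grad <- function(idx, contrib) {
    # scatter-add rows of `contrib` into g at rows `idx`
    for (c3 in 1:3) {
      v <- numeric(nat)
      vv <- rowsum(contrib[, c3], idx)
      v[as.integer(rownames(vv))] <- vv[, 1L]
      g[, c3] <<- g[, c3] + v
    }
  }

  e_bond <- e_angle <- e_dih <- e_imp <- e_lj <- e_coul <- 0

  b <- topology$bonds
  if (nrow(b)) {
    d <- xyz[b$i, , drop = FALSE] - xyz[b$j, , drop = FALSE]
    r <- sqrt(rowSums(d^2))
    dr <- r - b$r0
    e_bond <- sum(b$k * dr^2)
    if (grad) {
      f <- 2 * b$k * dr / r
      add_grad(b$i, sweep(d, 1L, f, "*"))
      add_grad(b$j, -sweep(d, 1L, f, "*"))
    }
  }

  an <- topology$angles
  if (nrow(an)) {
    u <- xyz[an$i, , drop = FALSE] - xyz[an$j, , drop = FALSE]
    v <- xyz[an$k, , drop = FALSE] - xyz[an$j, , drop = FALSE]
    nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
    cth <- pmin(1, pmax(-1, rowSums(u * v) / (nu * nv)))
    th <- acos(cth)
    th0 <- an$th0 * DEG
    dth <- th - th0
    e_angle <- sum(an$kth * dth^2)
    if (grad) {
      sth <- sqrt(pmax(1e-12, 1 - cth^2))
      uh <- sweep(u, 1L, nu, "/"); vh <- sweep(v, 1L, nv, "/")
      dthdi <- sweep(sweep(uh, 1L, cth, "*") - vh, 1L, nu * sth, "/")
      dthdk <- sweep(sweep(vh, 1L, cth, "*") - uh, 1L, nv * sth, "/")
      pref <- 2 * an$kth * dth
      add_grad(an$i, sweep(dthdi, 1L, pref, "*"))
      add_grad(an$k, sweep(dthdk, 1L, pref, "*"))
      add_grad(an$j, sweep(-(dthdi + dthdk), 1L, pref, "*"))
    }
  }

  dh <- topology$dihedrals
  if (nrow(dh)) {
    db <- dihedral_batch(xyz, dh$i, dh$j, dh$k, dh$l)
    arg <- dh$n * db$phi - dh$gamma * DEG
    e_dih <- sum(dh$kd * (1 + cos(arg)))
    if (grad) {
      pref <- -dh$kd * dh$n * sin(arg)
      add_grad(dh$i, sweep(db$di, 1L, pref, "*"))
      add_grad(dh$j, sweep(db$dj, 1L, pref, "*"))
      add_grad(dh$k, sweep(db$dk, 1L, pref, "*"))
      add_grad(dh$l, sweep(db$dl, 1L, pref, "*"))
    }
  }

  im <- topology$impropers
  if (nrow(im)) {
    db <- dihedral_batch(xyz, im$i, im$j, im$k, im$l)
    dphi <- db$phi - im$phi0 * DEG
    dphi <- atan2(sin(dphi), cos(dphi))   # wrap to (-pi, pi]
    e_imp <- sum(im$kimp * dphi^2)
    if (grad) {
      pref <- 2 * im$kimp * dphi
      add_grad(im$i, sweep(db$di, 1L, pref, "*"))
      add_grad(im$j, sweep(db$dj, 1L, pref, "*"))
      add_grad(im$k, sweep(db$dk, 1L, pref, "*"))
      add_grad(im$l, sweep(db$dl, 1L, pref, "*"))
    }
  }

  nb <- topology$nb_pairs
  if (nrow(nb)) {
    d <- xyz[nb$i, , drop = FALSE] - xyz[nb$j, , drop = FALSE]
    r2 <- rowSums(d^2)
    if (any(r2 < 1e-12)) {
      w <- which(r2 < 1e-12)[1L]
      stop("overlapping atoms: indices ", nb$i[w], " and ", nb$j[w],
           " are closer than 1e-6 Angstrom")
    }
    r <- sqrt(r2)
    within <- r < topology$cutoff
    if (any(within)) {
      iw <- nb$i[within]; jw <- nb$j[within]
      rw <- r[within]; dw <- d[within, , drop = FALSE]
      p <- topology$params
      rm <- p$rmin2[iw] + p$rmin2[jw]
      epsp <- sqrt(p$eps[iw] * p$eps[jw]) * nb$lj_scale[within]
      qq <- COULOMB_K * p$charge[iw] * p$charge[jw] * nb$coul_scale[within]
      x6 <- (rm / rw)^6
      ulj <- epsp * (x6^2 - 2 * x6)
      uc <- qq / rw
      sw <- switch_fn(rw, topology$cutoff - topology$switch_width,
                      topology$cutoff)
      e_lj <- sum(ulj * sw$s)
      e_coul <- sum(uc * sw$s)
      if (grad) {
        dulj <- epsp * (-12 * x6^2 + 12 * x6) / rw
        duc <- -qq / rw^2
        dtot <- (dulj + duc) * sw$s + (ulj + uc) * sw$ds
        f <- dtot / rw
        add_grad(iw, sweep(dw, 1L, f, "*"))
        add_grad(jw, -sweep(dw, 1L, f, "*"))
      }
    }
  }

  report <- structure(list(
    bond = e_bond, angle = e_angle, dihedral = e_dih, improper = e_imp,
    lj = e_lj, coulomb = e_coul,
    total = e_bond + e_angle + e_dih + e_imp + e_lj + e_coul),
    class = "energy_report")
  list(energy = report, gradient = g)
}

#' Compute the component-wise molecular-mechanics energy
#'
#' @param structure A `pep_structure`.
#' @param topology The matching [build_topology()] output.
#' @return An `energy_report` with components `bond`, `angle`, `dihedral`,
#'   `improper`, `lj`, `coulomb` and their sum `total` (kcal/mol).
#' @export
compute_energy <- function(structure, topology) {
  energy_gradient(coords(structure), topology, grad = FALSE)$energy
}

#' Analytic gradient of the energy
#'
#' Returns dE/dx in kcal/mol/Angstrom (the force is its negative).  The
#' test-suite verifies this against central finite differences.
#'
#' @inheritParams compute_energy
#' @return n x 3 numeric matrix.
#' @export
compute_gradient <- function(structure, topology) {
  energy_gradient(coords(structure), topology, grad = TRUE)$gradient
}

#' @export
print.energy_report <- function(x, ...) {
  cat(sprintf(paste0("<energy_report> total %.4f kcal/mol\n",
                     "  bond %.4f  angle %.4f  dihedral %.4f\n",
                     "  improper %.4f  lj %.4f  coulomb %.4f\n"),
              x$total, x$bond, x$angle, x$dihedral, x$improper, x$lj,
              x$coulomb))
  invisible(x)
}

#' @export
as.data.frame.energy_report <- function(x, ...) {
  data.frame(bond = x$bond, angle = x$angle, dihedral = x$dihedral,
             improper = x$improper, lj = x$lj, coulomb = x$coulomb,
             total = x$total)
}
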