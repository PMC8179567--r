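# Triaxial kinematic closure for head-to-tail macrocycles.
#
# With ideal bond lengths/angles and trans amides, fixing all phi/psi
# except at three pivot residues leaves three rigid segments, each spanning
# the backbone between consecutive pivot C-alphas. The segment shape does
# not depend on the pivot torsions (those rotate about bonds through the
# pivot CA itself), so the three CA...CA virtual distances are fixed and
# the pivot C-alphas form a rigid triangle. Each segment retains one degree
# of freedom: a spin sigma_i about its triangle edge. Ring closure then
# reduces to restoring the ideal N-CA-C angle at each pivot, three
# equations bilinear in (cos sigma, sin sigma) of adjacent segments. Given
# sigma_1, each equation yields up to two branches for the next spin, and
# the remaining scalar residual is root-solved in sigma_1 over a fine grid
# (up to 16 real solutions, the degree bound of the closure polynomial).

rodrigues <- function(axis, theta) {
  e <- axis / sqrt(sum(axis^2))
  ct <- cos(theta); st <- sin(theta)
  K <- matrix(c(0, e[3], -e[2], -e[3], 0, e[1], e[2], -e[1], 0), 3, 3)
  diag(3) * ct + st * K + (1 - ct) * (e %o% e)
}

rotation_between <- function(a, b) {
  # proper rotation taking unit vector a to unit vector b
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- cross3(a, b)
  c_ <- sum(a * b)
  if (sum(v^2) < 1e-20) {
    if (c_ > 0) return(diag(3))
    # opposite: rotate 180 about any perpendicular
    p <- if (abs(a[1]) < 0.9) cross3(a, c(1, 0, 0)) else cross3(a, c(0, 1, 0))
    return(rodrigues(p, pi))
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K * (1 / (1 + c_))
}

# Build one rigid segment from pivot `from` to pivot `to` (cyclic residue
# indices) in a local frame. Returns endpoint CAs, the attachment atoms
# C(from) and N(to), and the interior backbone atoms.
build_kic_unit <- function(from, to, n, phi, psi, omega) {
  th <- .bb$a_NCAC / DEG
  CA <- list(); Cc <- list(); Nn <- list()
  CA[[as.character(from)]] <- c(0, 0, 0)
  Cc[[as.character(from)]] <- c(.bb$b_CAC, 0, 0)
  dummy <- c(0, 1, 0)
  seqres <- from
  r <- from
  repeat {
    nr <- if (r < n) r + 1 else 1
    key <- as.character(nr)
    prevkey <- as.character(r)
    refN <- if (r == from) dummy else Nn[[prevkey]]
    Nn[[key]] <- place_atom(refN, CA[[prevkey]], Cc[[prevkey]],
                            .bb$b_CN, .bb$a_CACN,
                            if (r == from) 0 else psi[r])
    CA[[key]] <- place_atom(CA[[prevkey]], Cc[[prevkey]], Nn[[key]],
                            .bb$b_NCA, .bb$a_CNCA, omega[r])
    seqres <- c(seqres, nr)
    if (nr == to) break
    Cc[[key]] <- place_atom(Cc[[prevkey]], Nn[[key]], CA[[key]],
                            .bb$b_CAC, .bb$a_NCAC, phi[nr])
    r <- nr
  }
  interior <- list()
  add <- function(res, name, xyz) {
    interior[[length(interior) + 1]] <<- list(res = res, name = name,
                                              xyz = xyz)
  }
  add(from, "C", Cc[[as.character(from)]])
  mid <- seqres[-c(1, length(seqres))]
  for (r in mid) {
    k <- as.character(r)
    add(r, "N", Nn[[k]]); add(r, "CA", CA[[k]]); add(r, "C", Cc[[k]])
  }
  add(to, "N", Nn[[as.character(to)]])
  list(from = from, to = to,
       A = CA[[as.character(from)]], B = CA[[as.character(to)]],
       c_atom = Cc[[as.character(from)]],
       n_atom = Nn[[as.character(to)]],
       interior = interior)
}

# Canonically place a unit between triangle vertices and decompose the two
# attachment direction vectors for Rodrigues rotation about the edge axis:
# v(sigma) = par + perp*cos(sigma) + crs*sin(sigma), |v| constant.
place_unit_canonical <- function(unit, v_from, v_to) {
  d_local <- unit$B - unit$A
  e <- (v_to - v_from)
  d <- sqrt(sum(e^2)); e <- e / d
  R0 <- rotation_between(d_local, e)
  tr <- function(x) as.numeric(R0 %*% (x - unit$A)) + v_from
  decomp <- function(v) {
    par <- sum(v * e) * e
    perp <- v - par
    list(par = par, perp = perp, crs = cross3(e, v), norm = sqrt(sum(v^2)))
  }
  c_can <- tr(unit$c_atom)
  n_can <- tr(unit$n_atom)
  list(e = e, v_from = v_from, v_to = v_to, R0 = R0, A = unit$A,
       u = decomp(c_can - v_from),    # CA(from) -> C(from)
       w = decomp(n_can - v_to),      # CA(to)   -> N(to)
       unit = unit)
}

unit_vec_at <- function(dc, sigma) {
  # n x 3 matrix of unit vectors for a vector of sigmas
  (outer(rep(1, length(sigma)), dc$par) +
     outer(cos(sigma), dc$perp) + outer(sin(sigma), dc$crs)) / dc$norm
}

# Solve P cos(s) + Q sin(s) = R for the branch `sgn`; NA when infeasible
solve_cs <- function(P, Q, R, sgn) {
  amp <- sqrt(P^2 + Q^2)
  ratio <- R / amp
  out <- atan2(Q, P) + sgn * acos(pmin(1, pmax(-1, ratio)))
  out[abs(ratio) > 1 | amp < 1e-14] <- NA_real_
  out
}

#' Solve triaxial ring closure for three pivot residues
#'
#' Given full backbone torsions for an n-residue head-to-tail macrocycle
#' with the phi/psi of three pivot residues left free, returns every
#' backbone that closes the ring with ideal bond geometry. Geometrically
#' infeasible torsion sets yield an empty list (not an error).
#'
#' @param phi,psi Numeric length-n torsion vectors (degrees); entries at
#'   `pivots` are ignored and replaced by solved values.
#' @param pivots Integer vector of three distinct residue indices.
#' @param omega Per-residue omega (degrees), default all trans (180).
#' @param topologies Residue topologies for the returned poses (default all
#'   Gly).
#' @param chi Optional per-residue chi list passed to [build_chain()].
#' @param grid Number of sigma grid points for root bracketing.
#' @param build Build a `PeptidePose` (and residual diagnostics) for every
#'   solution (default TRUE). With `build = FALSE` only the solved
#'   torsions are returned; use [solution_pose()] to realize a chosen
#'   solution.
#' @return List of `ClosureSolution` objects: each has `pose` (cyclic
#'   `PeptidePose`, or NULL if `build = FALSE`), `phi`, `psi` (full solved
#'   vectors), `pivots`, `sigma` (the three segment spins, radians) and
#'   `residual` (from [closure_residual()]).
#' @export
solve_closure <- function(phi, psi, pivots, omega = NULL,
                          topologies = NULL, chi = NULL, grid = 1440,
                          build = TRUE) {
  n <- length(phi)
  if (n < 6) stop("ring size must be at least 6 residues")
  pivots <- sort(as.integer(pivots))
  if (length(unique(pivots)) != 3 || any(pivots < 1) || any(pivots > n)) {
    stop("pivots must be three distinct residue indices")
  }
  if (is.null(omega)) omega <- rep(180, n)
  cos_th <- cos(.bb$a_NCAC / DEG)

  p <- pivots
  units <- list(build_kic_unit(p[1], p[2], n, phi, psi, omega),
                build_kic_unit(p[2], p[3], n, phi, psi, omega),
                build_kic_unit(p[3], p[1], n, phi, psi, omega))
  d1 <- sqrt(sum((units[[1]]$B - units[[1]]$A)^2))
  d2 <- sqrt(sum((units[[2]]$B - units[[2]]$A)^2))
  d3 <- sqrt(sum((units[[3]]$B - units[[3]]$A)^2))
  # triangle: V1-V2 = d1, V2-V3 = d2, V3-V1 = d3
  if (d1 + d2 <= d3 || d1 + d3 <= d2 || d2 + d3 <= d1) return(list())
  V1 <- c(0, 0, 0); V2 <- c(d1, 0, 0)
  x3 <- (d1^2 + d3^2 - d2^2) / (2 * d1)
  y3sq <- d3^2 - x3^2
  if (y3sq <= 0) return(list())
  V3 <- c(x3, sqrt(y3sq), 0)

  pl <- list(place_unit_canonical(units[[1]], V1, V2),
             place_unit_canonical(units[[2]], V2, V3),
             place_unit_canonical(units[[3]], V3, V1))

  # residual for a given sigma1 and branch pair; returns list or NULL
  chain_eval <- function(s1, s2sgn, s3sgn) {
    w1 <- unit_vec_at(pl[[1]]$w, s1)
    P <- as.numeric(w1 %*% (pl[[2]]$u$perp / pl[[2]]$u$norm))
    Q <- as.numeric(w1 %*% (pl[[2]]$u$crs / pl[[2]]$u$norm))
    R <- cos_th - as.numeric(w1 %*% (pl[[2]]$u$par / pl[[2]]$u$norm))
    s2 <- solve_cs(P, Q, R, s2sgn)
    w2 <- unit_vec_at(pl[[2]]$w, s2)
    P3 <- as.numeric(w2 %*% (pl[[3]]$u$perp / pl[[3]]$u$norm))
    Q3 <- as.numeric(w2 %*% (pl[[3]]$u$crs / pl[[3]]$u$norm))
    R3 <- cos_th - as.numeric(w2 %*% (pl[[3]]$u$par / pl[[3]]$u$norm))
    s3 <- solve_cs(P3, Q3, R3, s3sgn)
    w3 <- unit_vec_at(pl[[3]]$w, s3)
    u1 <- unit_vec_at(pl[[1]]$u, s1)
    h <- rowSums(w3 * u1) - cos_th
    h[is.na(s2) | is.na(s3)] <- NA_real_
    list(h = h, s2 = s2, s3 = s3)
  }

  sg <- seq(0, 2 * pi, length.out = grid + 1)
  roots <- list()
  for (s2sgn in c(1, -1)) for (s3sgn in c(1, -1)) {
    ev <- chain_eval(sg, s2sgn, s3sgn)
    h <- ev$h
    ok <- !is.na(h)
    for (i in seq_len(grid)) {
      if (!ok[i] || !ok[i + 1]) next
      if (h[i] == 0 || sign(h[i]) * sign(h[i + 1]) > 0) next
      lo <- sg[i]; hi <- sg[i + 1]
      flo <- h[i]
      for (it in 1:60) {
        mid <- (lo + hi) / 2
        fm <- chain_eval(mid, s2sgn, s3sgn)$h
        if (is.na(fm)) break
        if (fm == 0) { lo <- hi <- mid; break }
        if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
      }
      s1 <- (lo + hi) / 2
      e2 <- chain_eval(s1, s2sgn, s3sgn)
      if (is.na(e2$h) || abs(e2$h) > 1e-6) next
      roots[[length(roots) + 1]] <- c(s1, e2$s2, e2$s3)
    }
  }
  if (length(roots) == 0) return(list())
  # deduplicate sigma triples (branch seams can yield the same root twice)
  sig <- do.call(rbind, roots)
  keep <- rep(TRUE, nrow(sig))
  for (i in seq_len(nrow(sig))) {
    if (!keep[i]) next
    if (i < nrow(sig)) for (j in (i + 1):nrow(sig)) {
      dd <- abs(wrap180((sig[j, ] - sig[i, ]) * DEG))
      if (max(dd) < 1e-3) keep[j] <- FALSE
    }
  }
  sig <- sig[keep, , drop = FALSE]

  lapply(seq_len(nrow(sig)), function(k) {
    assemble_solution(sig[k, ], pl, n, phi, psi, omega,
                      topologies, chi, pivots, build)
  })
}

assemble_solution <- function(sigma, pl, n, phi, psi, omega,
                              topologies, chi, pivots, build = TRUE) {
  coords <- list()
  setxyz <- function(res, name, xyz) coords[[paste0(res, ":", name)]] <<- xyz
  for (i in 1:3) {
    p <- pl[[i]]
    Rm <- rodrigues(p$e, sigma[i])
    tr <- function(x_local) {
      can <- as.numeric(p$R0 %*% (x_local - p$A)) + p$v_from
      as.numeric(Rm %*% (can - p$v_from)) + p$v_from
    }
    setxyz(p$unit$from, "CA", p$v_from)
    setxyz(p$unit$to, "CA", p$v_to)
    for (a in p$unit$interior) setxyz(a$res, a$name, tr(a$xyz))
  }
  g <- function(res, name) coords[[paste0(res, ":", name)]]
  phi_out <- phi; psi_out <- psi
  for (i in seq_len(n)) {
    pr <- if (i > 1) i - 1 else n
    nx <- if (i < n) i + 1 else 1
    phi_out[i] <- measure_dihedral(g(pr, "C"), g(i, "N"), g(i, "CA"),
                                   g(i, "C"))
    psi_out[i] <- measure_dihedral(g(i, "N"), g(i, "CA"), g(i, "C"),
                                   g(nx, "N"))
  }
  if (is.null(topologies)) topologies <- rep(list("GLY"), n)
  if (!build) {
    return(structure(list(pose = NULL, phi = phi_out, psi = psi_out,
                          omega = omega, topologies = topologies,
                          pivots = pivots, sigma = sigma,
                          residual = NULL),
                     class = "ClosureSolution"))
  }
  pose <- build_chain(topologies, phi_out, psi_out, omega = omega,
                      chi = chi, cyclic = TRUE)
  structure(list(pose = pose, phi = phi_out, psi = psi_out,
                 omega = omega, topologies = topologies,
                 pivots = pivots, sigma = sigma,
                 residual = closure_residual(pose)),
            class = "ClosureSolution")
}

#' Realize the pose of a closure solution
#'
#' Builds (or returns) the cyclic `PeptidePose` for a solution, filling
#' in its residual diagnostics.
#'
#' @param sol A `ClosureSolution`.
#' @param topologies Optional residue identities overriding the solve-time
#'   ones.
#' @param chi Optional per-residue chi list.
#' @return The completed `ClosureSolution`.
#' @export
solution_pose <- function(sol, topologies = NULL, chi = NULL) {
  if (!is.null(sol$pose) && is.null(topologies) && is.null(chi)) {
    return(sol)
  }
  topo <- if (is.null(topologies)) sol$topologies else topologies
  sol$pose <- build_chain(topo, sol$phi, sol$psi, omega = sol$omega,
                          chi = chi, cyclic = TRUE)
  sol$residual <- closure_residual(sol$pose)
  sol
}

#' @export
print.ClosureSolution <- function(x, ...) {
  cat(sprintf(
    "ClosureSolution: %d residues, pivots %s%s\n",
    length(x$phi), paste(x$pivots, collapse = "/"),
    if (is.null(x$residual)) " (torsions only)" else
      sprintf(", closing-bond error %.2e A", x$residual$bond)))
  invisible(x)
}

#' Validity of a closure solution against geometric tolerances
#'
#' @param sol A `ClosureSolution`.
#' @param bond_tol Closing C-N bond length tolerance (Angstrom).
#' @param angle_tol Closing bond angle tolerance (degrees).
#' @return Logical.
#' @export
closure_valid <- function(sol, bond_tol = 0.01, angle_tol = 1) {
  r <- sol$residual
  r$bond <= bond_tol && r$angle_c <= angle_tol && r$angle_n <= angle_tol
}
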