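# Independent oracle implementations used to cross-check the package.
# These deliberately avoid the code paths they verify.

DEG <- 180 / pi

wrapd <- function(x) {
  y <- ((x + 180) %% 360) - 180
  ifelse(y == -180, 180, y)
}

# dihedral via projection onto the plane perpendicular to the central
# bond (a different formula than the package's atan2-of-cross-products)
oracle_dihedral <- function(p1, p2, p3, p4) {
  b <- p3 - p2
  b <- b / sqrt(sum(b^2))
  u <- (p1 - p2) - sum((p1 - p2) * b) * b
  v <- (p4 - p3) - sum((p4 - p3) * b) * b
  u <- u / sqrt(sum(u^2))
  v <- v / sqrt(sum(v^2))
  cosd <- sum(u * v)
  crs <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
  sgn <- sign(sum(crs * b))
  ang <- acos(min(1, max(-1, cosd))) * DEG
  # IUPAC: cis (eclipsed) is 0; u and v parallel means cis
  out <- if (sgn == 0) ang else sgn * ang
  if (out <= -180) out + 360 else out
}

# brute-force pairwise recomputation of the steric term with the same
# published exclusion rules but independent looping code
oracle_steric_intra <- function(pose, params = energy_params()) {
  a <- pose$atoms[pose$atoms$element != "H", , drop = FALSE]
  a$radius <- vdw_radius(a$element)
  n <- pose_length(pose)
  bb <- c("N", "CA", "C", "O")
  lj <- function(r, r0) {
    x <- max(r / r0, 1e-6)
    eps <- params$lj_eps
    ramp <- params$lj_ramp
    if (x >= ramp) return(eps * (x^-12 - 2 * x^-6))
    e_r <- eps * (ramp^-12 - 2 * ramp^-6)
    slope <- eps * (-12 * ramp^-13 + 12 * ramp^-7)
    e_r + slope * (x - ramp)
  }
  rdist <- function(i, j) {
    d <- abs(i - j)
    if (pose$cyclic) min(d, n - d) else d
  }
  succ <- function(i) if (pose$cyclic) (i %% n) + 1 else i + 1
  total <- 0
  for (i in seq_len(nrow(a) - 1)) {
    for (j in (i + 1):nrow(a)) {
      ri <- a$residue[i]; rj <- a$residue[j]
      if (ri == rj) next
      if (rdist(ri, rj) == 1) {
        if (a$name[i] %in% bb && a$name[j] %in% bb) next
        pair <- sort(c(paste(ri, a$name[i]), paste(rj, a$name[j])))
        if (succ(ri) == rj &&
            ((a$name[i] == "C" && a$name[j] == "CB") ||
             (a$name[i] == "CB" && a$name[j] == "N"))) next
        if (succ(rj) == ri &&
            ((a$name[j] == "C" && a$name[i] == "CB") ||
             (a$name[j] == "CB" && a$name[i] == "N"))) next
      }
      r <- sqrt(sum((as.numeric(a[i, c("x", "y", "z")]) -
                       as.numeric(a[j, c("x", "y", "z")]))^2))
      total <- total + lj(r, a$radius[i] + a$radius[j])
    }
  }
  total
}

# ---------------------------------------------------------------------
# Numerical closure oracle: scans the segment spin angles by explicit
# rigid rotation of actual segment coordinates and numerical
# root-finding, with branch following across a dense outer grid. Fully
# independent of the solver's trigonometric branch algebra.

oracle_closure_solutions <- function(phi, psi, piv, n,
                                     outer_grid = 2161, inner = 360) {
  phi0 <- phi; psi0 <- psi; phi0[piv] <- 0; psi0[piv] <- 0
  ord <- ((piv[1] - 1 + 0:n) %% n) + 1
  po <- build_chain(rep(list("GLY"), n + 1), phi0[ord], psi0[ord])
  allc <- pose_coords(po, "bb3")
  ax <- function(i, nm) as.numeric(allc[paste0(i, ":", nm), ])
  segxyz <- function(pa, pb) {
    ia <- which(ord == pa)[1]
    ib <- which(ord == pb); ib <- ib[ib > ia][1]
    rows <- list(list(res = pa, name = "CA", xyz = ax(ia, "CA")),
                 list(res = pa, name = "C", xyz = ax(ia, "C")))
    if (ib > ia + 1) for (j in (ia + 1):(ib - 1)) {
      for (nm in c("N", "CA", "C")) {
        rows[[length(rows) + 1]] <- list(res = ord[j], name = nm,
                                         xyz = ax(j, nm))
      }
    }
    rows[[length(rows) + 1]] <- list(res = pb, name = "N",
                                     xyz = ax(ib, "N"))
    rows[[length(rows) + 1]] <- list(res = pb, name = "CA",
                                     xyz = ax(ib, "CA"))
    rows
  }
  segs <- list(segxyz(piv[1], piv[2]), segxyz(piv[2], piv[3]),
               segxyz(piv[3], piv[1]))
  dd <- sapply(segs, function(s) {
    sqrt(sum((s[[length(s)]]$xyz - s[[1]]$xyz)^2))
  })
  if (dd[1] + dd[2] <= dd[3] || dd[1] + dd[3] <= dd[2] ||
      dd[2] + dd[3] <= dd[1]) return(list())
  V <- list(c(0, 0, 0), c(dd[1], 0, 0), NULL)
  x3 <- (dd[1]^2 + dd[3]^2 - dd[2]^2) / (2 * dd[1])
  V[[3]] <- c(x3, sqrt(dd[3]^2 - x3^2), 0)
  cross_ <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  dec <- function(p, a, e) {
    v <- p - a
    par <- sum(v * e) * e
    list(par = par + a, perp = v - par, crs = cross_(e, v))
  }
  atm <- function(dc, th) {
    sweep(outer(cos(th), dc$perp) + outer(sin(th), dc$crs), 2, dc$par,
          `+`)
  }
  angv <- function(P, v2, Q) {
    U <- sweep(P, 2, v2); W <- sweep(Q, 2, v2)
    cosang <- rowSums(U * W) / sqrt(rowSums(U^2) * rowSums(W^2))
    acos(pmin(1, pmax(-1, cosang))) * DEG
  }
  canon <- function(s, Va, Vb) {
    A <- s[[1]]$xyz; B <- s[[length(s)]]$xyz
    a <- (B - A) / sqrt(sum((B - A)^2))
    e <- (Vb - Va) / sqrt(sum((Vb - Va)^2))
    v <- cross_(a, e); cc <- sum(a * e)
    R <- if (sum(v^2) < 1e-18) diag(3) else {
      K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
      diag(3) + K + K %*% K / (1 + cc)
    }
    P <- t(apply(do.call(rbind, lapply(s, function(r) r$xyz)), 1,
                 function(x) as.numeric(R %*% (x - A)) + Va))
    list(P = P, names = lapply(s, function(r) c(r$res, r$name)),
         Va = Va, Vb = Vb, e = e,
         dN = dec(P[nrow(P) - 1, ], Va, e), dC = dec(P[2, ], Va, e))
  }
  cs <- list(canon(segs[[1]], V[[1]], V[[2]]),
             canon(segs[[2]], V[[2]], V[[3]]),
             canon(segs[[3]], V[[3]], V[[1]]))
  gin <- seq(0, 2 * pi, length.out = inner + 1)
  Cgrid <- lapply(1:3, function(ci) atm(cs[[ci]]$dC, gin))
  fzeros <- function(Nfix, v2, ci) {
    vals <- angv(matrix(Nfix, inner + 1, 3, byrow = TRUE), v2,
                 Cgrid[[ci]]) - 111.2
    out <- numeric(0)
    idx <- which(sign(vals[-1]) * sign(vals[-length(vals)]) < 0)
    for (i in idx) {
      lo <- gin[i]; hi <- gin[i + 1]; flo <- vals[i]
      f <- function(th) angv(matrix(Nfix, 1, 3), v2,
                             atm(cs[[ci]]$dC, th)) - 111.2
      for (it in 1:52) {
        md <- (lo + hi) / 2; fm <- f(md)
        if (sign(fm) == sign(flo)) { lo <- md; flo <- fm } else hi <- md
      }
      out <- c(out, (lo + hi) / 2)
    }
    out
  }
  Nof <- function(ci, th) as.numeric(atm(cs[[ci]]$dN, th))
  f1res <- function(t3, t1) {
    angv(matrix(Nof(3, t3), 1, 3), V[[1]], atm(cs[[1]]$dC, t1)) - 111.2
  }
  triples <- function(t1) {
    res <- list()
    N1 <- Nof(1, t1)
    for (t2 in fzeros(N1, V[[2]], 2)) {
      N2 <- Nof(2, t2)
      for (t3 in fzeros(N2, V[[3]], 3)) {
        res[[length(res) + 1]] <- c(t1, t2, t3, f1res(t3, t1))
      }
    }
    res
  }
  g1 <- seq(0, 2 * pi, length.out = outer_grid)
  prev <- triples(g1[1]); raw <- list()
  for (i in 2:length(g1)) {
    curr <- triples(g1[i])
    for (pc in prev) {
      if (length(curr) == 0) next
      d2 <- sapply(curr, function(q) {
        max(abs(((q[2:3] - pc[2:3]) + pi) %% (2 * pi) - pi))
      })
      j <- which.min(d2)
      if (d2[j] > 0.5) next
      qc <- curr[[j]]
      if (sign(pc[4]) * sign(qc[4]) < 0) {
        lo <- pc; hi <- qc
        for (it in 1:48) {
          tm <- (lo[1] + hi[1]) / 2
          cand <- triples(tm)
          if (length(cand) == 0) break
          mid23 <- (lo[2:3] + hi[2:3]) / 2
          dd2 <- sapply(cand, function(q) {
            max(abs(((q[2:3] - mid23) + pi) %% (2 * pi) - pi))
          })
          q <- cand[[which.min(dd2)]]
          if (sign(q[4]) == sign(lo[4])) lo <- q else hi <- q
        }
        raw[[length(raw) + 1]] <- (lo[1:3] + hi[1:3]) / 2
      }
    }
    prev <- curr
  }
  out <- list()
  for (r in raw) {
    coord <- list()
    for (ci in 1:3) {
      Vq <- sweep(cs[[ci]]$P, 2, cs[[ci]]$Va)
      e <- cs[[ci]]$e
      par <- outer(as.numeric(Vq %*% e), e)
      perp <- Vq - par
      crs <- cbind(e[2] * Vq[, 3] - e[3] * Vq[, 2],
                   e[3] * Vq[, 1] - e[1] * Vq[, 3],
                   e[1] * Vq[, 2] - e[2] * Vq[, 1])
      P <- sweep(par + perp * cos(r[ci]) + crs * sin(r[ci]), 2,
                 cs[[ci]]$Va, `+`)
      for (k in seq_along(cs[[ci]]$names)) {
        nm <- cs[[ci]]$names[[k]]
        coord[[paste0(nm[1], ":", nm[2])]] <- P[k, ]
      }
    }
    g <- function(res, nm) coord[[paste0(res, ":", nm)]]
    tors <- c()
    for (p in piv) {
      pr <- if (p > 1) p - 1 else n
      nx <- if (p < n) p + 1 else 1
      tors <- c(tors,
                measure_dihedral(g(pr, "C"), g(p, "N"), g(p, "CA"),
                                 g(p, "C")),
                measure_dihedral(g(p, "N"), g(p, "CA"), g(p, "C"),
                                 g(nx, "N")))
    }
    dup <- FALSE
    for (o in out) if (max(abs(wrapd(tors - o))) < 0.01) {
      dup <- TRUE; break
    }
    if (!dup) out[[length(out) + 1]] <- tors
  }
  out
}

# pivot torsions of a solver solution in the oracle's flat layout
solution_pivot_torsions <- function(sol) {
  as.numeric(rbind(sol$phi[sol$pivots], sol$psi[sol$pivots]))
}

anchor_xyz_safe <- function(anchor) {
  i <- which(anchor$atoms$name == "CA")[1]
  as.numeric(anchor$atoms[i, c("x", "y", "z")])
}
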