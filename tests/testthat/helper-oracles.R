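# Independent brute-force oracles: explicit per-voxel loops, no shared code
# with the package's vectorised builders. These are deliberately slow and
# simple so they can be trusted by inspection.

o_in <- function(d3, z, r, c) {
  z >= 1 && z <= d3[1] && r >= 1 && r <= d3[2] && c >= 1 && c <= d3[3]
}

# all valid ordered pairs (a, b) at one offset
o_pairs <- function(lev, off) {
  d3 <- dim(lev)
  a <- c(); b <- c()
  for (z in seq_len(d3[1])) for (r in seq_len(d3[2])) for (cc in seq_len(d3[3])) {
    v1 <- lev[z, r, cc]
    if (is.na(v1)) next
    z2 <- z + off[1]; r2 <- r + off[2]; c2 <- cc + off[3]
    if (!o_in(d3, z2, r2, c2)) next
    v2 <- lev[z2, r2, c2]
    if (is.na(v2)) next
    a <- c(a, v1); b <- c(b, v2)
  }
  list(a = a, b = b)
}

# ---- GLCM ------------------------------------------------------------------

o_glcm_formula <- function(P) {
  Ng <- nrow(P)
  lg <- function(x) log(x) / log(2)
  px <- numeric(Ng)
  for (i in 1:Ng) for (j in 1:Ng) px[i] <- px[i] + P[i, j]
  mu <- 0; for (i in 1:Ng) mu <- mu + i * px[i]
  s2 <- 0; for (i in 1:Ng) s2 <- s2 + (i - mu)^2 * px[i]
  pd <- numeric(Ng); ps <- numeric(2 * Ng - 1)        # |i-j| in 0..Ng-1, i+j in 2..2Ng
  for (i in 1:Ng) for (j in 1:Ng) {
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + P[i, j]
    ps[i + j - 1] <- ps[i + j - 1] + P[i, j]
  }
  mud <- 0; for (k in 0:(Ng - 1)) mud <- mud + k * pd[k + 1]
  ac <- 0; cp <- 0; cs <- 0; ct <- 0; ds <- 0; en <- 0; asm <- 0; hom <- 0
  idmn <- 0; idn <- 0; ssv <- 0; hxy1 <- 0; hxy2 <- 0
  for (i in 1:Ng) for (j in 1:Ng) {
    p <- P[i, j]
    ac <- ac + i * j * p
    cp <- cp + (i + j - 2 * mu)^4 * p
    cs <- cs + (i + j - 2 * mu)^3 * p
    ct <- ct + (i - j)^2 * p
    ds <- ds + abs(i - j) * p
    if (p > 0) en <- en - p * lg(p)
    asm <- asm + p * p
    hom <- hom + p / (1 + abs(i - j))
    idmn <- idmn + p / (1 + (i - j)^2 / Ng^2)
    idn <- idn + p / (1 + abs(i - j) / Ng)
    ssv <- ssv + (i - mu)^2 * p
    if (p > 0 && px[i] > 0 && px[j] > 0) hxy1 <- hxy1 - p * lg(px[i] * px[j])
    if (px[i] > 0 && px[j] > 0) hxy2 <- hxy2 - px[i] * px[j] * lg(px[i] * px[j])
  }
  hx <- 0; for (i in 1:Ng) if (px[i] > 0) hx <- hx - px[i] * lg(px[i])
  de <- 0; for (k in 0:(Ng - 1)) if (pd[k + 1] > 0) de <- de - pd[k + 1] * lg(pd[k + 1])
  dv <- 0; for (k in 0:(Ng - 1)) dv <- dv + (k - mud)^2 * pd[k + 1]
  sa <- 0; se <- 0
  for (k in 2:(2 * Ng)) {
    sa <- sa + k * ps[k - 1]
    if (ps[k - 1] > 0) se <- se - ps[k - 1] * lg(ps[k - 1])
  }
  corr <- if (s2 > 0) (ac - mu * mu) / s2 else NA_real_
  imc1 <- if (hx > 0) (en - hxy1) / hx else NA_real_
  imc2 <- sqrt(max(0, 1 - exp(-2 * log(2) * (hxy2 - en))))
  mp <- 0; for (i in 1:Ng) for (j in 1:Ng) if (P[i, j] > mp) mp <- P[i, j]
  c(glcm_autocorrelation = ac, glcm_cluster_prominence = cp,
    glcm_cluster_shade = cs, glcm_contrast = ct, glcm_correlation = corr,
    glcm_difference_entropy = de, glcm_difference_variance = dv,
    glcm_dissimilarity = ds, glcm_entropy = en, glcm_energy = asm,
    glcm_homogeneity = hom,
    glcm_information_measure_correlation_1 = imc1,
    glcm_information_measure_correlation_2 = imc2,
    glcm_inverse_difference_moment_normalised = idmn,
    glcm_inverse_difference_normalised = idn,
    glcm_maximum_probability = mp, glcm_sum_average = sa,
    glcm_sum_entropy = se, glcm_sum_of_squares_variance = ssv)
}

o_glcm <- function(droi, d = 1L) {
  lev <- droi$levels; Ng <- droi$Ng
  dirs <- direction_set(droi$mode, d)
  acc <- NULL
  for (k in seq_len(nrow(dirs))) {
    pr <- o_pairs(lev, dirs[k, ])
    if (!length(pr$a)) next
    P <- matrix(0, Ng, Ng)
    for (t in seq_along(pr$a)) {
      P[pr$a[t], pr$b[t]] <- P[pr$a[t], pr$b[t]] + 1
      P[pr$b[t], pr$a[t]] <- P[pr$b[t], pr$a[t]] + 1
    }
    acc <- cbind(acc, o_glcm_formula(P / sum(P)))
  }
  rowMeans(acc)
}

# ---- GLDM ------------------------------------------------------------------

o_gldm <- function(droi, d = 1L) {
  lev <- droi$levels; Ng <- droi$Ng
  dirs <- direction_set(droi$mode, d)
  lg <- function(x) log(x) / log(2)
  acc <- NULL
  for (k in seq_len(nrow(dirs))) {
    pr <- o_pairs(lev, dirs[k, ])
    if (!length(pr$a)) next
    p <- numeric(Ng)
    for (t in seq_along(pr$a)) {
      dk <- abs(pr$a[t] - pr$b[t])
      p[dk + 1] <- p[dk + 1] + 1
    }
    p <- p / sum(p)
    mu <- 0; for (kk in 0:(Ng - 1)) mu <- mu + kk * p[kk + 1]
    ent <- 0; va <- 0; ctr <- 0
    for (kk in 0:(Ng - 1)) {
      if (p[kk + 1] > 0) ent <- ent - p[kk + 1] * lg(p[kk + 1])
      va <- va + (kk - mu)^2 * p[kk + 1]
      ctr <- ctr + kk^2 * p[kk + 1]
    }
    acc <- cbind(acc, c(gldm_mean = mu, gldm_entropy = ent,
                        gldm_variance = va, gldm_contrast = ctr))
  }
  rowMeans(acc)
}

# ---- NGTDM -----------------------------------------------------------------

o_ngtdm <- function(droi) {
  lev <- droi$levels; Ng <- droi$Ng
  d3 <- dim(lev)
  half <- direction_set(droi$mode, 1L)
  offs <- rbind(half, -half)
  n_k <- numeric(Ng); s_k <- numeric(Ng)
  for (z in seq_len(d3[1])) for (r in seq_len(d3[2])) for (cc in seq_len(d3[3])) {
    v <- lev[z, r, cc]
    if (is.na(v)) next
    nb <- c()
    for (k in seq_len(nrow(offs))) {
      z2 <- z + offs[k, 1]; r2 <- r + offs[k, 2]; c2 <- cc + offs[k, 3]
      if (!o_in(d3, z2, r2, c2)) next
      v2 <- lev[z2, r2, c2]
      if (!is.na(v2)) nb <- c(nb, v2)
    }
    if (!length(nb)) next
    n_k[v] <- n_k[v] + 1
    s_k[v] <- s_k[v] + abs(v - mean(nb))
  }
  N <- sum(n_k)
  p_k <- n_k / N
  occ <- which(p_k > 0); Ngp <- length(occ)
  eps <- 1e-6
  ps <- sum(p_k * s_k)
  coarse <- 1 / (eps + ps)
  ctr <- 0; busyd <- 0; cmpl <- 0; stren <- 0
  if (Ngp > 1) {
    for (i in occ) for (j in occ) {
      ctr <- ctr + p_k[i] * p_k[j] * (i - j)^2
      if (i != j) {
        busyd <- busyd + abs(i * p_k[i] - j * p_k[j])
        cmpl <- cmpl + abs(i - j) * (p_k[i] * s_k[i] + p_k[j] * s_k[j]) /
          (p_k[i] + p_k[j])
        stren <- stren + (p_k[i] + p_k[j]) * (i - j)^2
      }
    }
    ctr <- ctr / (Ngp * (Ngp - 1)) * sum(s_k) / N
    cmpl <- cmpl / N
    stren <- stren / (eps + sum(s_k))
  }
  busy <- if (busyd > 0) ps / busyd else 0
  c(ngtdm_coarseness = coarse, ngtdm_contrast = ctr, ngtdm_busyness = busy,
    ngtdm_complexity = cmpl, ngtdm_texture_strength = stren)
}

# ---- GLRL ------------------------------------------------------------------

o_glrl_runs <- function(lev, off) {
  d3 <- dim(lev)
  g <- c(); l <- c()
  flush <- function(cur, len) {
    if (len > 0) { g <<- c(g, cur); l <<- c(l, len) }
  }
  for (z in seq_len(d3[1])) for (r in seq_len(d3[2])) for (cc in seq_len(d3[3])) {
    if (o_in(d3, z - off[1], r - off[2], cc - off[3])) next  # not a line start
    cz <- z; cr <- r; ccc <- cc
    cur <- NA_integer_; len <- 0L
    while (o_in(d3, cz, cr, ccc)) {
      v <- lev[cz, cr, ccc]
      if (is.na(v)) {
        flush(cur, len); cur <- NA_integer_; len <- 0L
      } else if (!is.na(cur) && v == cur) {
        len <- len + 1L
      } else {
        flush(cur, len); cur <- v; len <- 1L
      }
      cz <- cz + off[1]; cr <- cr + off[2]; ccc <- ccc + off[3]
    }
    flush(cur, len)
  }
  list(g = g, l = l)
}

o_glrl_formula <- function(g, l, Np) {
  Nr <- length(g)
  sg <- 0; sl <- 0
  for (gv in unique(g)) sg <- sg + sum(g == gv)^2
  for (lv in unique(l)) sl <- sl + sum(l == lv)^2
  c(glrl_run_percentage = Nr / Np,
    glrl_high_grey_level_run_emphasis = sum(g^2) / Nr,
    glrl_short_run_low_grey_level_emphasis = sum(1 / (g^2 * l^2)) / Nr,
    glrl_short_run_high_grey_level_emphasis = sum(g^2 / l^2) / Nr,
    glrl_short_run_emphasis = sum(1 / l^2) / Nr,
    glrl_long_run_emphasis = sum(l^2) / Nr,
    glrl_grey_level_non_uniformity = sg / Nr,
    glrl_run_length_non_uniformity = sl / Nr,
    glrl_low_grey_level_run_emphasis = sum(1 / g^2) / Nr,
    glrl_long_run_low_grey_level_emphasis = sum(l^2 / g^2) / Nr,
    glrl_long_run_high_grey_level_emphasis = sum(l^2 * g^2) / Nr,
    glrl_intensity_variability = sg / Nr^2,
    glrl_run_length_variability = sl / Nr^2)
}

o_glrl <- function(droi) {
  Np <- sum(!is.na(droi$levels))
  dirs <- direction_set(droi$mode, 1L)
  acc <- NULL
  for (k in seq_len(nrow(dirs))) {
    runs <- o_glrl_runs(droi$levels, dirs[k, ])
    acc <- cbind(acc, o_glrl_formula(runs$g, runs$l, Np))
  }
  rowMeans(acc)
}

# ---- GLZSM -----------------------------------------------------------------

o_glzsm_zones <- function(lev, mode) {
  d3 <- dim(lev)
  half <- direction_set(mode, 1L)
  offs <- rbind(half, -half)
  seen <- array(FALSE, d3)
  g <- c(); s <- c()
  for (z in seq_len(d3[1])) for (r in seq_len(d3[2])) for (cc in seq_len(d3[3])) {
    if (seen[z, r, cc] || is.na(lev[z, r, cc])) next
    v <- lev[z, r, cc]
    # breadth-first flood fill with an explicit queue
    queue <- list(c(z, r, cc))
    seen[z, r, cc] <- TRUE
    size <- 0L
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      size <- size + 1L
      for (k in seq_len(nrow(offs))) {
        nz <- cur[1] + offs[k, 1]; nr <- cur[2] + offs[k, 2]
        nc <- cur[3] + offs[k, 3]
        if (!o_in(d3, nz, nr, nc) || seen[nz, nr, nc]) next
        if (is.na(lev[nz, nr, nc]) || lev[nz, nr, nc] != v) next
        seen[nz, nr, nc] <- TRUE
        queue[[length(queue) + 1L]] <- c(nz, nr, nc)
      }
    }
    g <- c(g, v); s <- c(s, size)
  }
  list(g = g, s = s)
}

o_glzsm <- function(droi) {
  zones <- o_glzsm_zones(droi$levels, droi$mode)
  g <- zones$g; s <- zones$s
  Np <- sum(!is.na(droi$levels)); Nz <- length(g)
  sg <- 0; ss <- 0
  for (gv in unique(g)) sg <- sg + sum(g == gv)^2
  for (sv in unique(s)) ss <- ss + sum(s == sv)^2
  c(glzsm_short_zone_emphasis = sum(1 / s^2) / Nz,
    glzsm_short_zone_low_intensity_emphasis = sum(1 / (s^2 * g^2)) / Nz,
    glzsm_short_zone_high_intensity_emphasis = sum(g^2 / s^2) / Nz,
    glzsm_long_zone_low_intensity_emphasis = sum(s^2 / g^2) / Nz,
    glzsm_long_zone_high_intensity_emphasis = sum(s^2 * g^2) / Nz,
    glzsm_long_zone_emphasis = sum(s^2) / Nz,
    glzsm_intensity_non_uniformity = sg / Nz,
    glzsm_zone_length_non_uniformity = ss / Nz,
    glzsm_zone_percentage = Nz / Np,
    glzsm_low_intensity_zone_emphasis = sum(1 / g^2) / Nz,
    glzsm_high_intensity_zone_emphasis = sum(g^2) / Nz,
    glzsm_intensity_variability = sg / Nz^2,
    glzsm_size_zone_variability = ss / Nz^2)
}

# ---- lacunarity ------------------------------------------------------------

o_lacunarity <- function(lev, box_sizes) {
  msk <- !is.na(lev)
  lam <- c()
  for (r in box_sizes) {
    if (r > min(dim(lev))) next
    masses <- c()
    for (i in seq_len(nrow(lev) - r + 1)) for (j in seq_len(ncol(lev) - r + 1)) {
      block <- lev[i:(i + r - 1), j:(j + r - 1)]
      bm <- msk[i:(i + r - 1), j:(j + r - 1)]
      if (all(bm)) masses <- c(masses, sum(block))
    }
    if (length(masses) && mean(masses) > 0)
      lam <- c(lam, mean(masses^2) / mean(masses)^2)
  }
  mean(lam)
}

# direct 2D convolution with replicated edges (smoothing oracle)
o_conv2 <- function(m, w) {
  k <- (nrow(w) - 1) %/% 2
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    acc <- 0
    for (a in -k:k) for (b in -k:k) {
      ii <- min(max(i + a, 1), nrow(m))
      jj <- min(max(j + b, 1), ncol(m))
      acc <- acc + w[a + k + 1, b + k + 1] * m[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}
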