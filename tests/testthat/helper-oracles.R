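# brute-force enumeration oracles, independent of the package's vectorized
# texture implementations; intended for hand-checkable grids (<= 5^3)

all_offsets_26 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

in_grid <- function(p, d) all(p >= 1) && all(p <= d)

oracle_glcm <- function(lv, G) {
  d <- dim(lv)
  m <- matrix(0, G, G)
  offs <- all_offsets_26()
  for (i in which(!is.na(lv))) {
    p <- arrayInd(i, d)
    for (o in seq_len(nrow(offs))) {
      q <- p + offs[o, ]
      if (!in_grid(q, d)) next
      b <- lv[q[1], q[2], q[3]]
      if (is.na(b)) next
      a <- lv[i]
      m[a, b] <- m[a, b] + 1
    }
  }
  m
}

oracle_glrlm <- function(lv, G) {
  d <- dim(lv)
  offs <- all_offsets_26()
  # 13 canonical directions: first nonzero component positive
  canon <- offs[apply(offs, 1, function(r) r[r != 0][1]) > 0, , drop = FALSE]
  runs <- list()
  for (o in seq_len(nrow(canon))) {
    dir <- canon[o, ]
    for (i in seq_along(lv)) {
      a <- lv[i]
      if (is.na(a)) next
      p <- arrayInd(i, d)
      prev <- p - dir
      # only start runs at the first voxel of a maximal run
      if (in_grid(prev, d) && !is.na(lv[prev[1], prev[2], prev[3]]) &&
          lv[prev[1], prev[2], prev[3]] == a) next
      len <- 1
      q <- p + dir
      while (in_grid(q, d) && !is.na(lv[q[1], q[2], q[3]]) &&
             lv[q[1], q[2], q[3]] == a) {
        len <- len + 1
        q <- q + dir
      }
      runs[[length(runs) + 1]] <- c(a, len)
    }
  }
  rmat <- do.call(rbind, runs)
  m <- matrix(0, G, max(rmat[, 2]))
  for (r in seq_len(nrow(rmat)))
    m[rmat[r, 1], rmat[r, 2]] <- m[rmat[r, 1], rmat[r, 2]] + 1
  m
}

oracle_glszm <- function(lv, G) {
  d <- dim(lv)
  offs <- all_offsets_26()
  seen <- array(FALSE, d)
  zones <- list()
  for (i in seq_along(lv)) {
    if (is.na(lv[i]) || seen[i]) next
    a <- lv[i]
    queue <- list(arrayInd(i, d))
    seen[i] <- TRUE
    size <- 0
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (o in seq_len(nrow(offs))) {
        q <- p + offs[o, ]
        if (!in_grid(q, d)) next
        j <- q[1] + (q[2] - 1) * d[1] + (q[3] - 1) * d[1] * d[2]
        if (!seen[j] && !is.na(lv[j]) && lv[j] == a) {
          seen[j] <- TRUE
          queue[[length(queue) + 1]] <- q
        }
      }
    }
    zones[[length(zones) + 1]] <- c(a, size)
  }
  zmat <- do.call(rbind, zones)
  m <- matrix(0, G, max(zmat[, 2]))
  for (r in seq_len(nrow(zmat)))
    m[zmat[r, 1], zmat[r, 2]] <- m[zmat[r, 1], zmat[r, 2]] + 1
  m
}

oracle_ngtdm <- function(lv, G) {
  d <- dim(lv)
  offs <- all_offsets_26()
  s <- numeric(G); n <- numeric(G)
  for (i in which(!is.na(lv))) {
    p <- arrayInd(i, d)
    nb <- c()
    for (o in seq_len(nrow(offs))) {
      q <- p + offs[o, ]
      if (!in_grid(q, d)) next
      b <- lv[q[1], q[2], q[3]]
      if (!is.na(b)) nb <- c(nb, b)
    }
    if (!length(nb)) next
    a <- lv[i]
    s[a] <- s[a] + abs(a - mean(nb))
    n[a] <- n[a] + 1
  }
  list(s = s, n = n)
}

# independent double-sum implementations of the analysis-critical features
oracle_lgze <- function(glszm) {
  tot <- 0; nz <- 0
  for (g in seq_len(nrow(glszm))) for (s in seq_len(ncol(glszm))) {
    tot <- tot + glszm[g, s] / g^2
    nz <- nz + glszm[g, s]
  }
  tot / nz
}

oracle_glcm_correlation <- function(glcm) {
  p <- glcm / sum(glcm)
  G <- nrow(p)
  mu_i <- 0
  for (i in seq_len(G)) for (j in seq_len(G)) mu_i <- mu_i + i * p[i, j]
  mu_j <- 0
  for (i in seq_len(G)) for (j in seq_len(G)) mu_j <- mu_j + j * p[i, j]
  v_i <- 0; v_j <- 0; cv <- 0
  for (i in seq_len(G)) for (j in seq_len(G)) {
    v_i <- v_i + (i - mu_i)^2 * p[i, j]
    v_j <- v_j + (j - mu_j)^2 * p[i, j]
    cv <- cv + (i - mu_i) * (j - mu_j) * p[i, j]
  }
  cv / sqrt(v_i * v_j)
}

# plain-R two-group log-rank statistic for permutation oracles
logrank_stat_oracle <- function(times, events, group) {
  g <- as.integer(factor(group)) - 1L
  ts <- sort(unique(times[events == 1]))
  o_minus_e <- 0; v <- 0
  for (t in ts) {
    at_risk <- times >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g == 1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g == 1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# independent loop-based implementations of all texture features, applied to
# oracle-built matrices; returns the same names as texture_block()
oracle_texture_features <- function(lv, G) {
  out <- c()
  # GLCM family
  cm <- oracle_glcm(lv, G)
  nm <- paste0("glcm_", c("energy", "contrast", "correlation", "homogeneity",
                          "entropy", "dissimilarity", "autocorrelation",
                          "cluster_shade", "cluster_prominence"))
  if (sum(cm) == 0) {
    out <- c(out, setNames(rep(NA_real_, 9), nm))
  } else {
    p <- cm / sum(cm)
    mu_i <- 0; mu_j <- 0
    for (i in 1:G) for (j in 1:G) { mu_i <- mu_i + i * p[i, j]
                                    mu_j <- mu_j + j * p[i, j] }
    vi <- 0; vj <- 0; cv <- 0; en <- 0; ct <- 0; hm <- 0; et <- 0
    ds <- 0; ac <- 0; cs <- 0; cp_ <- 0
    for (i in 1:G) for (j in 1:G) {
      q <- p[i, j]
      vi <- vi + (i - mu_i)^2 * q; vj <- vj + (j - mu_j)^2 * q
      cv <- cv + (i - mu_i) * (j - mu_j) * q
      en <- en + q^2; ct <- ct + (i - j)^2 * q
      hm <- hm + q / (1 + abs(i - j))
      if (q > 0) et <- et - q * log2(q)
      ds <- ds + abs(i - j) * q; ac <- ac + i * j * q
      cs <- cs + (i + j - mu_i - mu_j)^3 * q
      cp_ <- cp_ + (i + j - mu_i - mu_j)^4 * q
    }
    corr <- if (vi * vj > 0) cv / sqrt(vi * vj) else NA_real_
    out <- c(out, setNames(c(en, ct, corr, hm, et, ds, ac, cs, cp_), nm))
  }
  # GLRLM / GLSZM families share the run/zone formulas
  rl_feats <- function(m, np, prefix, names11) {
    nr <- sum(m)
    v <- numeric(11)
    for (g in seq_len(nrow(m))) for (l in seq_len(ncol(m))) {
      c_ <- m[g, l]
      if (c_ == 0) next
      v[1] <- v[1] + c_ / l^2;      v[2] <- v[2] + c_ * l^2
      v[6] <- v[6] + c_ / g^2;      v[7] <- v[7] + c_ * g^2
      v[8] <- v[8] + c_ / (g^2 * l^2); v[9] <- v[9] + c_ * g^2 / l^2
      v[10] <- v[10] + c_ * l^2 / g^2; v[11] <- v[11] + c_ * g^2 * l^2
    }
    for (g in seq_len(nrow(m))) v[3] <- v[3] + sum(m[g, ])^2
    for (l in seq_len(ncol(m))) v[4] <- v[4] + sum(m[, l])^2
    v <- v / nr
    v[5] <- nr / np
    setNames(v, paste0(prefix, names11))
  }
  np <- sum(!is.na(lv))
  out <- c(out, rl_feats(oracle_glrlm(lv, G), np, "glrlm_",
                         c("sre", "lre", "gln", "rln", "rp", "lgre", "hgre",
                           "srlge", "srhge", "lrlge", "lrhge")))
  out <- c(out, rl_feats(oracle_glszm(lv, G), np, "glszm_",
                         c("sze", "lze", "gln", "zsn", "zp", "lgze", "hgze",
                           "szlge", "szhge", "lzlge", "lzhge")))
  # NGTDM family
  nd <- oracle_ngtdm(lv, G)
  nmn <- paste0("ngtdm_", c("coarseness", "contrast", "busyness",
                            "complexity", "strength"))
  N <- sum(nd$n)
  pres <- which(nd$n > 0)
  pp <- nd$n / N; ss <- nd$s
  Ng <- length(pres)
  ps <- sum(pp * ss)
  coar <- if (ps > 0) 1 / ps else NA_real_
  if (Ng > 1) {
    ctn <- 0; bdn <- 0; cx <- 0; stn <- 0
    for (i in pres) for (j in pres) {
      ctn <- ctn + pp[i] * pp[j] * (i - j)^2
      bdn <- bdn + abs(i * pp[i] - j * pp[j])
      cx <- cx + abs(i - j) * (pp[i] * ss[i] + pp[j] * ss[j]) /
        (pp[i] + pp[j])
      stn <- stn + (pp[i] + pp[j]) * (i - j)^2
    }
    contrast <- ctn / (Ng * (Ng - 1)) * sum(ss) / N
    busy <- if (bdn > 0) ps / bdn else NA_real_
    cmplx <- cx / N
    strength <- if (sum(ss) > 0) stn / sum(ss) else NA_real_
  } else contrast <- busy <- cmplx <- strength <- NA_real_
  c(out, setNames(c(coar, contrast, busy, cmplx, strength), nmn))
}
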