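# The 13 unique 3D direction offsets at distance 1 (one of each +/- pair):
# every nonzero (dx,dy,dz) in {-1,0,1}^3 whose first nonzero component is
# positive. Together with their negatives they span the 26-neighborhood.
offsets_13 <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  first_nonzero <- apply(g, 1, function(r) r[r != 0][1])
  as.matrix(g[first_nonzero > 0, , drop = FALSE])
}

crop_levels <- function(lv) {
  w <- which(!is.na(lv), arr.ind = TRUE)
  rg <- apply(w, 2, range)
  lv[rg[1, 1]:rg[2, 1], rg[1, 2]:rg[2, 2], rg[1, 3]:rg[2, 3], drop = FALSE]
}

# valid index range along one axis after shifting by offset o
offset_range <- function(n, o) {
  lo <- max(1, 1 - o); hi <- min(n, n - o)
  if (lo > hi) integer(0) else lo:hi
}

# ordered-pair counts of co-occurring levels for one offset, as a G x G
# count matrix contribution (a -> b direction only)
glcm_offset_counts <- function(lv, off, G) {
  d <- dim(lv)
  xs <- offset_range(d[1], off[1])
  ys <- offset_range(d[2], off[2])
  zs <- offset_range(d[3], off[3])
  if (!length(xs) || !length(ys) || !length(zs)) return(numeric(G * G))
  a <- lv[xs, ys, zs]
  b <- lv[xs + off[1], ys + off[2], zs + off[3]]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(numeric(G * G))
  tabulate((a[ok] - 1L) * G + b[ok], nbins = G * G)
}

build_glcm <- function(lv, G) {
  offs <- offsets_13()
  acc <- numeric(G * G)
  for (i in seq_len(nrow(offs))) acc <- acc + glcm_offset_counts(lv, offs[i, ], G)
  m <- matrix(acc, G, G)
  m + t(m)  # symmetric: each unordered neighbor pair counted twice
}

# run-length counts along one direction: voxels are grouped into lines
# (key constant along a line), ordered by position, and maximal same-level
# runs extracted; out-of-mask voxels break runs
glrlm_direction_counts <- function(lv, off) {
  d <- dim(lv)
  co <- arrayInd(seq_along(lv), d)
  k <- sum(off * off)
  s <- as.numeric(co[, 1] * off[1] + co[, 2] * off[2] + co[, 3] * off[3])
  # line id: (k*c - off*s) is constant along a line and bounded by
  # 2k*(d1+d2+d3) in magnitude, so base B packs the 3 components collision-free
  B <- 8 * k * sum(d) + 1
  key <- (k * co[, 1] - off[1] * s) +
    (k * co[, 2] - off[2] * s) * B +
    (k * co[, 3] - off[3] * s) * B^2
  ord <- order(key, s)
  l <- as.vector(lv)[ord]
  kk <- key[ord]
  n <- length(l)
  lag_l <- c(NA_integer_, l[-n])
  new_line <- c(TRUE, kk[-1] != kk[-n])
  lvl_change <- ifelse(is.na(l) | is.na(lag_l),
                       is.na(l) != is.na(lag_l), l != lag_l)
  grp <- cumsum(new_line | lvl_change)
  keep <- !is.na(l)
  if (!any(keep)) return(NULL)
  r <- rle(grp[keep])
  data.frame(level = l[keep][cumsum(r$lengths)], len = r$lengths)
}

build_glrlm <- function(lv, G) {
  offs <- offsets_13()
  parts <- lapply(seq_len(nrow(offs)),
                  function(i) glrlm_direction_counts(lv, offs[i, ]))
  parts <- do.call(rbind, parts)
  Rmax <- max(parts$len)
  m <- matrix(0, G, Rmax)
  for (r in seq_len(nrow(parts)))
    m[parts$level[r], parts$len[r]] <- m[parts$level[r], parts$len[r]] + 1
  m
}

# 26-connected zones of constant gray level; returns zone level + size.
# Used for the GLSZM and for optional component filtering in segmentation.
label_components_26 <- function(lv) {
  idx <- which(!is.na(lv))
  n <- length(idx)
  if (n == 0L) return(list(index = integer(0), zone_id = integer(0)))
  vid <- array(NA_integer_, dim(lv))
  vid[idx] <- seq_len(n)
  d <- dim(lv)
  offs <- offsets_13()
  efrom <- integer(0); eto <- integer(0)
  for (i in seq_len(nrow(offs))) {
    off <- offs[i, ]
    xs <- offset_range(d[1], off[1])
    ys <- offset_range(d[2], off[2])
    zs <- offset_range(d[3], off[3])
    if (!length(xs) || !length(ys) || !length(zs)) next
    a <- lv[xs, ys, zs]
    b <- lv[xs + off[1], ys + off[2], zs + off[3]]
    va <- vid[xs, ys, zs]
    vb <- vid[xs + off[1], ys + off[2], zs + off[3]]
    ok <- !is.na(a) & !is.na(b) & a == b
    efrom <- c(efrom, va[ok]); eto <- c(eto, vb[ok])
  }
  g <- igraph::make_graph(c(rbind(efrom, eto)), n = n, directed = FALSE)
  comp <- igraph::components(g)
  list(index = idx, zone_id = as.integer(comp$membership))
}

build_glszm <- function(lv, G) {
  lab <- label_components_26(lv)
  nz <- max(lab$zone_id)
  zone_level <- lv[lab$index][match(seq_len(nz), lab$zone_id)]
  zone_size <- tabulate(lab$zone_id, nbins = nz)
  m <- matrix(0, G, max(zone_size))
  for (z in seq_len(nz))
    m[zone_level[z], zone_size[z]] <- m[zone_level[z], zone_size[z]] + 1
  m
}

# per-level absolute deviation from the 26-neighborhood mean; voxels with
# no in-mask neighbor are excluded (their neighborhood mean is undefined)
build_ngtdm <- function(lv, G) {
  d <- dim(lv)
  offs <- offsets_13()
  offs <- rbind(offs, -offs)
  nb_sum <- array(0, d)
  nb_cnt <- array(0L, d)
  for (i in seq_len(nrow(offs))) {
    off <- offs[i, ]
    xs <- offset_range(d[1], off[1])
    ys <- offset_range(d[2], off[2])
    zs <- offset_range(d[3], off[3])
    if (!length(xs) || !length(ys) || !length(zs)) next
    b <- lv[xs + off[1], ys + off[2], zs + off[3]]
    add <- !is.na(b)
    sub_sum <- nb_sum[xs, ys, zs]
    sub_cnt <- nb_cnt[xs, ys, zs]
    sub_sum[add] <- sub_sum[add] + b[add]
    sub_cnt[add] <- sub_cnt[add] + 1L
    nb_sum[xs, ys, zs] <- sub_sum
    nb_cnt[xs, ys, zs] <- sub_cnt
  }
  use <- !is.na(lv) & nb_cnt > 0L
  g <- lv[use]
  dev <- abs(g - nb_sum[use] / nb_cnt[use])
  s <- numeric(G); n <- numeric(G)
  for (lev in unique(g)) {
    sel <- g == lev
    s[lev] <- sum(dev[sel])
    n[lev] <- sum(sel)
  }
  list(s = s, n = n)
}

#' Build the four texture matrices from a discretized volume
#'
#' GLCM: distance-1 co-occurrences over the 13 unique 3D directions,
#' symmetrized and merged into a single matrix. GLRLM: maximal same-level
#' runs over the 13 directions, merged. GLSZM: 26-connected constant-level
#' zones. NGTDM: per-level absolute deviation from the 26-neighborhood
#' mean. All restricted to in-mask voxels.
#'
#' @param disc a [discretize_fixed()] / [discretize_equal_probability()]
#'   result.
#' @return A `texture_matrices` list: `glcm` (G x G counts), `glrlm`
#'   (G x max-run counts), `glszm` (G x max-zone counts), `ngtdm`
#'   (list `s`, `n` of length G), `n_voxels`, `n_levels`.
#' @export
build_matrices <- function(disc) {
  stopifnot(inherits(disc, "discretized_volume"))
  lv <- crop_levels(disc$levels)
  G <- disc$n_levels
  structure(list(glcm = build_glcm(lv, G),
                 glrlm = build_glrlm(lv, G),
                 glszm = build_glszm(lv, G),
                 ngtdm = build_ngtdm(lv, G),
                 n_voxels = sum(!is.na(lv)), n_levels = G),
            class = "texture_matrices")
}
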