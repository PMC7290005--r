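# Independent pure-R oracles used to cross-check the compiled kernels.
# These are deliberately naive implementations kept free of any code from
# the package internals they validate.

# flood-fill connected-component labeling on a logical 3D array
oracle_label <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  ord <- rowSums(abs(offs))
  offs <- offs[ord > 0 & ord <= switch(as.character(connectivity),
                                       "6" = 1, "18" = 2, "26" = 3), ,
               drop = FALSE]
  labels <- array(0L, d)
  cur <- 0L
  for (seed in which(mask)) {
    if (labels[seed] != 0L) next
    cur <- cur + 1L
    stack <- seed
    labels[seed] <- cur
    while (length(stack) > 0) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      vi <- arrayInd(v, d)
      nb <- sweep(offs, 2, as.integer(vi), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + d[1] * (nb[, 2] - 1) + d[1] * d[2] * (nb[, 3] - 1)
      new <- lin[mask[lin] & labels[lin] == 0L]
      labels[new] <- cur
      stack <- c(stack, new)
    }
  }
  labels
}

# same-partition comparison of two labelings (label ids may differ)
same_partition <- function(a, b) {
  if (!all((a > 0) == (b > 0))) return(FALSE)
  idx <- which(a > 0)
  length(unique(paste(a[idx], b[idx]))) == length(unique(a[idx])) &&
    length(unique(paste(a[idx], b[idx]))) == length(unique(b[idx]))
}

# literal greedy measuring-sphere packing per the counting rule:
# repeatedly take the uncovered mask voxel of highest intensity (ties ->
# lowest (z,y,x)), accept iff fit_fraction of the sphere stencil lies on
# uncovered mask and the center is >= diameter from accepted centers.
oracle_pack <- function(intensity, mask, spacing, diameter, fit_fraction) {
  d <- dim(mask)
  r <- diameter / 2
  rng <- floor(r / spacing)
  g <- as.matrix(expand.grid(dz = -rng[1]:rng[1], dy = -rng[2]:rng[2],
                             dx = -rng[3]:rng[3]))
  keep <- (g[, 1] * spacing[1])^2 + (g[, 2] * spacing[2])^2 +
    (g[, 3] * spacing[3])^2 <= r^2 + 1e-9
  stencil <- g[keep, , drop = FALSE]
  m <- nrow(stencil)

  cand <- which(mask)
  ci <- arrayInd(cand, d)
  ord <- order(-intensity[cand], ci[, 1], ci[, 2], ci[, 3])
  cand <- cand[ord]
  ci <- ci[ord, , drop = FALSE]

  covered <- array(FALSE, d)
  accepted <- matrix(numeric(0), 0, 3)
  for (k in seq_along(cand)) {
    v <- cand[k]
    if (covered[v]) next
    vc <- ci[k, ]
    st <- sweep(stencil, 2, as.integer(vc), "+")
    ok <- st[, 1] >= 1 & st[, 1] <= d[1] & st[, 2] >= 1 & st[, 2] <= d[2] &
      st[, 3] >= 1 & st[, 3] <= d[3]
    lin <- st[ok, 1] + d[1] * (st[ok, 2] - 1) + d[1] * d[2] * (st[ok, 3] - 1)
    good <- sum(mask[lin] & !covered[lin])
    if (good / m < fit_fraction) next
    if (nrow(accepted) > 0) {
      dd <- sweep(accepted, 2, vc) %*% diag(spacing)
      if (any(rowSums(dd^2) < diameter^2 - 1e-9)) next
    }
    accepted <- rbind(accepted, vc)
    covered[lin] <- TRUE
  }
  unname(accepted)
}

# random blob mask fixture: a few rasterized balls with random intensity
random_blob_volume <- function(seed, dims = c(20, 24, 20),
                               spacing = c(1, 1, 1), n_blobs = 4,
                               integer_intensity = FALSE) {
  set.seed(seed)
  arr <- array(0, dims)
  ext <- dims * spacing
  for (i in seq_len(n_blobs)) {
    ctr <- runif(3, 0.2, 0.8) * ext
    rad <- runif(1, 1.5, 4) * max(spacing)
    co <- as.matrix(expand.grid(seq_len(dims[1]), seq_len(dims[2]),
                                seq_len(dims[3])))
    cc <- sweep(sweep(co - 0.5, 2, spacing, "*"), 2, ctr)
    sel <- rowSums(cc^2) <= rad^2
    val <- if (integer_intensity) sample(5:9, 1) else runif(1, 100, 1000)
    lin <- co[sel, 1] + dims[1] * (co[sel, 2] - 1) +
      dims[1] * dims[2] * (co[sel, 3] - 1)
    arr[lin] <- pmax(arr[lin], val)
  }
  if (!integer_intensity) arr <- arr + array(runif(length(arr)), dims)
  arr
}
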