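# Independent brute-force oracles for the hot-spot machinery, written as
# plain-R set computations so they share no code with the implementation.

# 26-neighbour index table for a grid: n x 26 matrix of 1-based linear
# indices, NA where out of bounds.
oracle_neighbour_table <- function(dims) {
  key <- paste(dims, collapse = "x")
  cache <- getOption("slndetect.test.nbcache", list())
  if (!is.null(cache[[key]])) return(cache[[key]])
  n <- prod(dims)
  lin0 <- 0:(n - 1)
  i <- lin0 %% dims[1]
  j <- (lin0 %/% dims[1]) %% dims[2]
  k <- lin0 %/% (dims[1] * dims[2])
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  nb <- matrix(NA_integer_, n, nrow(offs))
  for (r in seq_len(nrow(offs))) {
    ii <- i + offs[r, 1]; jj <- j + offs[r, 2]; kk <- k + offs[r, 3]
    ok <- ii >= 0 & jj >= 0 & kk >= 0 &
      ii < dims[1] & jj < dims[2] & kk < dims[3]
    nb[ok, r] <- 1L + ii[ok] + dims[1] * (jj[ok] + dims[2] * kk[ok])
  }
  cache[[key]] <- nb
  options(slndetect.test.nbcache = cache)
  nb
}

# exhaustive scan: qualifying voxels (positive, >= all in-bounds neighbours),
# then one representative per connected equal-valued plateau, at the
# lexicographically smallest (x, y, z)
oracle_find_seeds <- function(arr) {
  dims <- dim(arr)
  v <- as.numeric(arr)
  nb <- oracle_neighbour_table(dims)
  qual <- logical(length(v))
  for (l in which(v > 0)) {
    nbs <- nb[l, ]
    nbs <- nbs[!is.na(nbs)]
    qual[l] <- all(v[nbs] <= v[l])
  }
  if (!any(qual)) {
    return(data.frame(lin = integer(), value = numeric()))
  }
  # group qualifying voxels by connectivity within their equal-value plateau
  # (plain BFS over same-value neighbours)
  plateau_id <- rep(NA_integer_, length(v))
  nextid <- 0L
  for (s in which(qual)) {
    if (!is.na(plateau_id[s])) next
    nextid <- nextid + 1L
    frontier <- s
    plateau_id[s] <- nextid
    while (length(frontier)) {
      nxt <- integer()
      for (l in frontier) {
        nbs <- nb[l, ]
        nbs <- nbs[!is.na(nbs)]
        same <- nbs[v[nbs] == v[l] & is.na(plateau_id[nbs])]
        plateau_id[same] <- nextid
        nxt <- c(nxt, same)
      }
      frontier <- nxt
    }
  }
  reps <- integer()
  for (id in seq_len(nextid)) {
    members <- which(plateau_id == id & qual)
    lin0 <- members - 1L
    x <- lin0 %% dims[1]; y <- (lin0 %/% dims[1]) %% dims[2]
    z <- lin0 %/% (dims[1] * dims[2])
    reps <- c(reps, members[order(x, y, z)][1])
  }
  lin0 <- reps - 1L
  x <- lin0 %% dims[1]; y <- (lin0 %/% dims[1]) %% dims[2]
  z <- lin0 %/% (dims[1] * dims[2])
  o <- order(-v[reps], x, y, z)
  data.frame(lin = reps[o], value = v[reps][o])
}

# monotone-path reachability: voxel claimed by the seed iff a 26-connected
# path of non-increasing positive values leads to it; naive fixpoint
oracle_grow <- function(arr, seed_lin) {
  dims <- dim(arr)
  v <- as.numeric(arr)
  nb <- oracle_neighbour_table(dims)
  inR <- logical(length(v))
  inR[seed_lin] <- TRUE
  repeat {
    valR <- ifelse(inR, v, -Inf)
    best <- rep(-Inf, length(v))
    for (r in seq_len(ncol(nb))) {
      col <- nb[, r]
      ok <- !is.na(col)
      best[ok] <- pmax(best[ok], valR[col[ok]])
    }
    add <- !inR & v > 0 & v <= best
    if (!any(add)) break
    inR[add] <- TRUE
  }
  sort(which(inR))
}

# full construction: seeds, independent claims, shared-voxel deletion
oracle_segment <- function(arr) {
  seeds <- oracle_find_seeds(arr)
  claims <- lapply(seeds$lin, function(s) oracle_grow(arr, s))
  cnt <- integer(length(arr))
  for (cl in claims) cnt[cl] <- cnt[cl] + 1L
  shared <- which(cnt >= 2L)
  out <- list()
  for (q in seq_along(claims)) {
    mem <- setdiff(claims[[q]], shared)
    if (length(mem) == 0L || !(seeds$lin[q] %in% mem)) next
    out[[length(out) + 1L]] <- list(seed = seeds$lin[q],
                                    value = seeds$value[q],
                                    voxels = sort(mem))
  }
  out
}

# random small test volume wrapped in the package's volume class
random_grid_volume <- function(dims = c(6, 6, 6), max_val = 4) {
  arr <- array(sample(0:max_val, prod(dims), replace = TRUE), dim = dims)
  sln_volume(arr, spacing_mm = c(1, 1, 1), modality = "SPECT")
}
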