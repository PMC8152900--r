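# Independent oracles used across the suite: slow, transparent
# implementations that never share code with the package's fast paths.

# flood-fill connected-component labeling (breadth-first, R-level)
oracle_label <- function(fg, connectivity = 26) {
  d <- dim(fg)
  nb <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  nb <- nb[!(nb$dx == 0 & nb$dy == 0 & nb$dz == 0), ]
  if (connectivity == 6)
    nb <- nb[abs(nb$dx) + abs(nb$dy) + abs(nb$dz) == 1, ]
  if (connectivity == 18)
    nb <- nb[abs(nb$dx) + abs(nb$dy) + abs(nb$dz) <= 2, ]
  lab <- array(0L, d)
  cur <- 0L
  for (s in which(fg)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      co <- arrayInd(v, d)
      for (r in seq_len(nrow(nb))) {
        cc <- co + c(nb$dx[r], nb$dy[r], nb$dz[r])
        if (all(cc >= 1) && all(cc <= d)) {
          j <- cc[1] + (cc[2] - 1) * d[1] + (cc[3] - 1) * d[1] * d[2]
          if (fg[j] && lab[j] == 0L) {
            lab[j] <- cur
            queue <- c(queue, j)
          }
        }
      }
    }
  }
  lab
}

# brute-force TFCE: explicit per-threshold component labeling
oracle_tfce <- function(x, E = 0.5, H = 2, n_steps = 100,
                        dh = max(x) / n_steps, connectivity = 26) {
  out <- array(0, dim(x))
  ksteps <- max(n_steps, ceiling(max(x) / dh - 1e-12))
  for (k in seq_len(ksteps)) {
    h <- dh * k
    fg <- !is.na(x) & x >= h
    if (!any(fg)) next
    lab <- oracle_label(fg, connectivity)
    sz <- tabulate(lab)
    out[fg] <- out[fg] + sz[lab[fg]]^E * h^H * dh
  }
  out
}

# direct normal-equations residuals: (I - X (X'X)^-1 X') y
oracle_residuals <- function(y, X) {
  H <- X %*% solve(crossprod(X)) %*% t(X)
  as.vector((diag(length(y)) - H) %*% y)
}

rand_timeseries <- function(dims, n_frames, seed) {
  set.seed(seed)
  array(rnorm(prod(dims) * n_frames), c(dims, n_frames))
}

random_unit_dirs <- function(n, seed) {
  set.seed(seed)
  g <- matrix(rnorm(n * 3), n, 3)
  g / sqrt(rowSums(g^2))
}
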