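# Independent brute-force oracles used to validate the implementation paths.
# These stay deliberately naive: correctness over speed.

# queue-based flood fill labeling (2-D or 3-D)
flood_fill_label <- function(mask, connectivity) {
  dm <- dim(mask)
  ndim <- length(dm)
  offs <- as.matrix(expand.grid(rep(list(-1:1), ndim)))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity %in% c(4, 6)) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  lab <- array(0L, dm)
  nxt <- 0L
  coords <- which(mask == TRUE, arr.ind = TRUE)
  for (s in seq_len(nrow(coords))) {
    start <- coords[s, ]
    if (lab[matrix(start, 1)] != 0L) next
    nxt <- nxt + 1L
    queue <- list(start)
    lab[matrix(start, 1)] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        q <- p + offs[k, ]
        if (any(q < 1) || any(q > dm)) next
        qm <- matrix(q, 1)
        if (mask[qm] && lab[qm] == 0L) {
          lab[qm] <- nxt
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
  }
  lab
}

# partitions agree up to label renaming
same_partition <- function(a, b) {
  if (!identical(a > 0, b > 0)) return(FALSE)
  fg <- a > 0
  length(unique(paste(a[fg], b[fg]))) == length(unique(a[fg])) &&
    length(unique(paste(a[fg], b[fg]))) == length(unique(b[fg]))
}

# textbook two-pass Pearson correlation
pearson_two_pass <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Mann-Whitney U by direct pair counting (midrank-equivalent)
u_count <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) u <- u + (xi > yj) + 0.5 * (xi == yj)
  u
}

# exact two-tailed p by enumeration of all group assignments
mw_enum_p <- function(x, y, tails = "two") {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  uobs <- u_count(x, y)
  mu <- n1 * n2 / 2
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, function(ix) u_count(pooled[ix], pooled[-ix]))
  if (tails == "two") mean(abs(us - mu) >= abs(uobs - mu) - 1e-9)
  else mean(us >= uobs - 1e-9)
}

# tiny noise-free scene defaults shared across tests
quiet_scene <- function(..., seed = 1L) {
  scene_spec(..., noise_rate = 0, read_noise_sd = 0, blur_sd = 0, seed = seed)
}
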