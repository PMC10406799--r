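# Internal helpers shared across modules.

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. All stochastic operations in the package
# funnel through this, so identical (input, seed) pairs are bit-identical.
with_local_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# 8-connectivity labeling of a 2D logical matrix by iterative minimum-label
# propagation: every foreground pixel starts with its own linear index and
# repeatedly takes the minimum over its 8-neighbourhood until a fixed point.
# Labels are then renumbered 1..k in order of first appearance in
# column-major scan order.
label_components_8 <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  d <- dim(mask)
  lbl <- matrix(0L, d[1], d[2])
  if (!any(mask)) return(lbl)
  lbl[mask] <- which(mask)

  pad_shift <- function(m, dy, dx) {
    out <- matrix(Inf, d[1], d[2])
    ys <- max(1, 1 + dy):min(d[1], d[1] + dy)
    xs <- max(1, 1 + dx):min(d[2], d[2] + dx)
    out[ys, xs] <- m[ys - dy, xs - dx]
    out
  }

  cur <- matrix(Inf, d[1], d[2])
  cur[mask] <- lbl[mask]
  repeat {
    nxt <- cur
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0L && dx == 0L) next
      nxt <- pmin(nxt, pad_shift(cur, dy, dx))
    }
    nxt[!mask] <- Inf
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  raw <- ifelse(is.finite(cur), cur, 0)
  ids <- unique(raw[raw > 0])
  out <- matrix(0L, d[1], d[2])
  for (k in seq_along(ids)) out[raw == ids[k]] <- k
  out
}

# Directed nearest-neighbour distances from each row of `x` to the point
# set `y` (exact kd-tree search).
nn_dists <- function(x, y) {
  as.numeric(RANN::nn2(data = y, query = x, k = 1,
                       searchtype = "standard", eps = 0)$nn.dists)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
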