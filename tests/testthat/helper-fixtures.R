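# Shared small fixtures, built in code and cached per test run.

`%||%` <- function(a, b) if (is.na(a)) b else a

fixture_env <- new.env(parent = emptyenv())

small_phantom <- function(seed = 1L, shape = c(48, 48, 16)) {
  key <- paste0("ph_", seed, "_", paste(shape, collapse = "x"))
  if (is.null(fixture_env[[key]]))
    fixture_env[[key]] <- generate_phantom(
      phantom_config(shape = shape, seed = seed))
  fixture_env[[key]]
}

# A random logical matrix with roughly the given foreground density.
random_mask2d <- function(ny, nx, density = 0.3) {
  matrix(runif(ny * nx) < density, ny, nx)
}

# Mask stack with a solid square on every slice, optionally shifted per
# slice; convenient for exact-agreement fixtures.
square_mask <- function(shape, side = 6L, offset = c(0L, 0L),
                        provenance = "fix") {
  arr <- array(FALSE, shape)
  y <- 2L + offset[1]; x <- 2L + offset[2]
  arr[y:(y + side - 1L), x:(x + side - 1L), ] <- TRUE
  mask_stack(arr, provenance = provenance)
}

# Build an observer record whose per-slice Jaccard indices are exactly the
# given values: slice i has truth = 10 columns of row 1 and annotation the
# first round(10 * ji / (1 + ... )) columns chosen so JI comes out exact.
# Works for ji values expressible as o / 10 with the annotation a subset
# (union = 10, intersection = o).
record_with_jis <- function(jis, observer_id = "A") {
  nz <- length(jis)
  a0 <- array(FALSE, c(4, 16, nz))
  a1 <- array(FALSE, c(4, 16, nz))
  for (s in seq_len(nz)) {
    a0[2, 1:10, s] <- TRUE
    o <- round(10 * jis[s])
    stopifnot(abs(o / 10 - jis[s]) < 1e-9)
    if (o > 0) a1[2, 1:o, s] <- TRUE
  }
  observer_record(observer_id,
                  mask_stack(a0, provenance = paste0(observer_id, "/t0")),
                  mask_stack(a1, provenance = paste0(observer_id, "/t1")))
}
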