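# Shared fixtures and small independent oracles used across the test files.

# Noiseless image with Gaussian spots at given (y, x, amplitude).
gauss_image <- function(ny, nx, spots, sigma, offset = 0) {
  img <- matrix(offset, ny, nx)
  yy <- row(img); xx <- col(img)
  for (i in seq_len(nrow(spots))) {
    img <- img + spots[i, 3] *
      exp(-((yy - spots[i, 1])^2 + (xx - spots[i, 2])^2) / (2 * sigma^2))
  }
  img
}

# Small random movie_stack.
random_movie <- function(nt = 4, nc = 2, ny = 32, nx = 32, seed = 1,
                         dt = 1) {
  set.seed(seed)
  movie_stack(array(sample(0:65535, nt * nc * ny * nx, replace = TRUE),
                    c(nt, nc, ny, nx)),
              frame_interval_s = dt)
}

# Exhaustive minimum-total-squared-displacement linking for complete
# point sets (all particles present every frame, no memory): transitions are
# independent, so enumerate all permutations per frame transition.
exhaustive_link <- function(pos) {
  # pos: list of n_frames matrices (n x 2), same n
  n <- nrow(pos[[1]])
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  pp <- perms(seq_len(n))
  ids <- seq_len(n)        # identity of each particle row in current frame
  assign <- list(seq_len(n))
  for (f in seq_along(pos)[-1]) {
    costs <- vapply(pp, function(p)
      sum((pos[[f - 1]] - pos[[f]][p, , drop = FALSE])^2), numeric(1))
    best <- pp[[which.min(costs)]]
    # best[k] = row in frame f matched to row k of frame f-1
    new_ids <- integer(n)
    new_ids[best] <- ids
    ids <- new_ids
    assign[[f]] <- ids
  }
  assign  # per frame: track identity of each row
}

# Exhaustive optimal one-to-one matching with a distance gate: maximizes the
# number of pairs, then minimizes total distance (recursive enumeration).
exhaustive_match <- function(pa, pb, d_max) {
  na <- nrow(pa); nb <- nrow(pb)
  d <- sqrt(outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2)
  best <- list(n = -1, cost = Inf, pairs = matrix(integer(), ncol = 2))
  recurse <- function(i, used_b, pairs, cost) {
    if (i > na) {
      n <- nrow(pairs)
      if (n > best$n || (n == best$n && cost < best$cost))
        best <<- list(n = n, cost = cost, pairs = pairs)
      return(invisible())
    }
    recurse(i + 1, used_b, pairs, cost)            # leave i unmatched
    for (j in seq_len(nb)) {
      if (!used_b[j] && d[i, j] <= d_max) {
        ub <- used_b; ub[j] <- TRUE
        recurse(i + 1, ub, rbind(pairs, c(i, j)), cost + d[i, j])
      }
    }
  }
  recurse(1, rep(FALSE, nb), matrix(integer(), ncol = 2), 0)
  best
}

# Cache for the full-scale benchmark fixture shared by acceptance tests.
.bench_cache <- new.env(parent = emptyenv())
benchmark_cached <- function(seed = 11) {
  key <- paste0("s", seed)
  if (is.null(.bench_cache[[key]]))
    .bench_cache[[key]] <- benchmark_fixture(seed = seed)
  .bench_cache[[key]]
}
clear_benchmark_cache <- function() {
  rm(list = ls(.bench_cache), envir = .bench_cache)
  invisible(gc())
}
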