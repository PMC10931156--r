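# Shared fixtures, computed once per test run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

test_library <- function(seed = 1L) {
  fixture(paste0("lib", seed), function() make_dye_library(seed))
}

# Greedy minimum-SSE-increase agglomeration: the independent Ward oracle.
# Returns merge heights (sqrt of twice the SSE increase) and the partition
# (membership vector) after every merge.
brute_force_ward <- function(X) {
  sse <- function(rows) {
    m <- colMeans(X[rows, , drop = FALSE])
    sum(sweep(X[rows, , drop = FALSE], 2, m)^2)
  }
  cl <- as.list(seq_len(nrow(X)))
  heights <- numeric(0)
  partitions <- list()
  membership <- function(cl) {
    mm <- integer(nrow(X))
    for (i in seq_along(cl)) mm[cl[[i]]] <- i
    mm
  }
  while (length(cl) > 1L) {
    best <- NULL; bestd <- Inf
    for (i in 1:(length(cl) - 1L)) for (j in (i + 1L):length(cl)) {
      d <- sse(c(cl[[i]], cl[[j]])) - sse(cl[[i]]) - sse(cl[[j]])
      if (d < bestd) { bestd <- d; best <- c(i, j) }
    }
    heights <- c(heights, sqrt(2 * bestd))
    cl[[best[1]]] <- c(cl[[best[1]]], cl[[best[2]]])
    cl[[best[2]]] <- NULL
    partitions[[length(partitions) + 1L]] <- membership(cl)
  }
  list(heights = heights, partitions = partitions)
}

same_partition <- function(a, b) {
  identical(outer(a, a, "=="), outer(b, b, "=="))
}

tiny_dcnn <- function(seed = 1L) {
  cfg <- dcnn_config(input_side = 8L, stem_channels = 4L, stem_stride = 1L,
                     num_blocks = 2L, layers_per_block = 2L, growth = 3L,
                     spp_levels = c(1L, 2L), num_classes = 3L)
  build_model(cfg, seed = seed)
}
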