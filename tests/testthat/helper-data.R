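# Seeded random event stream on a small sensor.
random_stream <- function(n, dims = c(8L, 6L), t_max = 1000L, seed = 1L) {
  withr::with_seed(seed, event_stream(
    t = sample(0:t_max, n, replace = TRUE),
    x = sample(0:(dims[1] - 1L), n, replace = TRUE),
    y = sample(0:(dims[2] - 1L), n, replace = TRUE),
    p = sample(c(-1L, 1L), n, replace = TRUE),
    sensor_dims = dims
  ))
}

random_bits <- function(n, seed = 1L) {
  withr::with_seed(seed, sample(c(0L, 1L), n, replace = TRUE))
}

random_bit_matrix <- function(nr, nc, seed = 1L) {
  withr::with_seed(seed,
                   matrix(sample(c(0L, 1L), nr * nc, replace = TRUE), nr, nc))
}

# Generated demo datasets are expensive; cache them for the whole test
# run, keyed by configuration.
.dataset_cache <- new.env(parent = emptyenv())

cached_dataset <- function(key, cfg) {
  if (!exists(key, envir = .dataset_cache)) {
    dir <- file.path(tempdir(), paste0("hdflow-ds-", key))
    unlink(dir, recursive = TRUE)
    manifest <- generate_dataset(cfg, dir)
    assign(key, list(manifest = manifest, dir = dir, cfg = cfg),
           envir = .dataset_cache)
  }
  get(key, envir = .dataset_cache)
}

# A tiny dataset for plumbing tests (2 sessions x 6 samples).
tiny_dataset <- function() {
  cached_dataset("tiny", demo_config(master_seed = 42L, n_sessions = 2L,
                                     samples_per_class_session = 6L))
}

# The default-scale demonstration dataset used by the directional
# acceptance checks (6 sessions x 25 samples per class).
default_demo_dataset <- function() {
  cached_dataset("default", demo_config(master_seed = 1L))
}

# Two-class feature set whose classes differ ONLY in polarity
# structure: class P puts its ring mask in the positive map, class N
# puts the same mask in the negative map. The merged (OR) view of the
# two classes is identically distributed, so discarding polarity
# destroys the class signal by construction.
polarity_only_features <- function(n_per_class = 40, dim = c(8L, 8L),
                                   flip_prob = 0.05, seed = 1L) {
  withr::with_seed(seed, {
    base <- matrix(sample(c(0L, 1L), prod(dim), replace = TRUE,
                          prob = c(0.6, 0.4)), dim[1], dim[2])
    blank <- matrix(0L, dim[1], dim[2])
    noisy <- function(m) {
      flips <- matrix(stats::runif(prod(dim)) < flip_prob, dim[1], dim[2])
      (m + flips) %% 2L
    }
    build <- function(cls) {
      t(vapply(seq_len(n_per_class), function(i) {
        maps <- if (cls == "P") list(pos = noisy(base), neg = noisy(blank))
        else list(pos = noisy(blank), neg = noisy(base))
        class(maps) <- "polarity_maps"
        c(split = list(make_feature(maps, "split")),
          merged = list(make_feature(maps, "merged")))[["split"]]
      }, integer(2L * prod(dim))))
    }
    feats_split <- rbind(build("P"), build("N"))
    labels <- rep(c("P", "N"), each = n_per_class)
    # merged features are the OR of the two halves
    half <- prod(dim)
    feats_merged <- (feats_split[, 1:half] |
                       feats_split[, half + 1:half]) + 0L
    list(split = feats_split, merged = feats_merged, labels = labels)
  })
}
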