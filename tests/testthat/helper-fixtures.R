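# Shared fixtures. Heavy artefacts (the full study-sized dataset and the two
# modality probes, imaged at full 227x227 resolution) are built once per test
# run and reused across files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Study-sized synthetic dataset (96/30/36) with its cached experiment prep.
main_prep <- function() {
  fixture("main_prep", function() {
    grid <- experiment_grid(seed = 42, alphas = c(0, 0.5, 0.7, 1), splits = 0.7)
    prepare_experiment(grid)
  })
}

# Modality-pure probe preps. The scalogram probe uses 50 records per class
# (its low-frequency tone rows need the larger training set for a stable
# linear readout); the binary probe uses 30.
probe_prep <- function(which) {
  fixture(paste0("probe_", which), function() {
    n <- if (which == "scalogram_only") 50L else 30L
    grid <- experiment_grid(seed = 42, alphas = c(0, 1), splits = 0.7,
                            n_per_class = c(ARR = n, CHF = n, NSR = n))
    recs <- generate_modality_probe(which, n_per_class = n, seed = 4242)
    prepare_experiment(grid, records = recs)
  })
}

# Memoized sweep/ablation results on the shared fixtures: several test
# blocks assert different properties of the same experimental cells.
main_sweep <- function() {
  fixture("main_sweep", function() {
    prep <- main_prep()
    run_alpha_sweep(prep$grid, prep)
  })
}

main_ablation <- function() {
  fixture("main_ablation", function() {
    prep <- main_prep()
    run_ablation(prep$grid, prep, split = 0.7)
  })
}

probe_sweep <- function(which) {
  fixture(paste0("probe_sweep_", which), function() {
    prep <- probe_prep(which)
    run_alpha_sweep(prep$grid, prep)
  })
}

# Small toy images for unit tests of the model machinery: random but seeded
# pixel content at a reduced resolution.
toy_images <- function(n = 6, size = 32L, seed = 7) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      sc <- array(sample(0:255, size * size * 3, replace = TRUE),
                  dim = c(size, size, 3))
      class(sc) <- "scalogram_image"
      bi <- matrix(sample(0:1, size * size, replace = TRUE), size, size)
      class(bi) <- "binary_image"
      list(record_id = sprintf("toy_%02d", i),
           label = ECG_CLASSES_TEST[(i - 1) %% 3 + 1],
           scalogram = sc, binary = bi)
    })
  })
}

ECG_CLASSES_TEST <- c("ARR", "CHF", "NSR")

toy_model <- function(size = 32L, alpha = 0.7, seed = 5) {
  build_model(alpha = alpha,
              scalogram_branch = branch_config(input_channels = 3L, input_hw = size),
              binary_branch = branch_config(input_channels = 1L, input_hw = size),
              seed = seed)
}

# Three well-separated 2-D Gaussian blobs, for shallow-head and embedding
# tests where separability must hold by construction.
toy_blobs <- function(n_per_class = 20, sd = 0.1, gap = 100, seed = 3) {
  withr::with_seed(seed, {
    centers <- rbind(c(0, 0), c(gap, 0), c(0, gap))
    X <- do.call(rbind, lapply(1:3, function(k) {
      cbind(rnorm(n_per_class, centers[k, 1], sd),
            rnorm(n_per_class, centers[k, 2], sd))
    }))
    colnames(X) <- c("f0", "f1")
    list(X = X, y = rep(ECG_CLASSES_TEST, each = n_per_class))
  })
}

# Strip class/attribute decoration, keeping only dim: for exact array
# comparisons against undecorated references.
bare <- function(x) {
  d <- dim(x)
  x <- as.vector(x)
  if (!is.null(d)) dim(x) <- d
  x
}
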