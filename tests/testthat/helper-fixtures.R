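# shared fixtures: everything is generated in code at test time

# a random in-memory dataset (no image files) for XML / metrics tests
random_dataset <- function(n_images, n_landmarks, width = 200L,
                           height = 150L, seed = 1L) {
  set.seed(seed)
  anns <- lapply(seq_len(n_images), function(i) {
    image_annotation(
      file = sprintf("img_%03d.png", i),
      width = width, height = height,
      landmarks = cbind(sample.int(width, n_landmarks, TRUE) - 1L,
                        sample.int(height, n_landmarks, TRUE) - 1L))
  })
  landmark_dataset(anns)
}

# small-but-real hyperparameters: trains a 400x300 fixture set in well
# under a second
tiny_hp <- function() {
  hyperparameters(cascade_depth = 4L, tree_depth = 2L,
                  trees_per_cascade = 60L, learning_rate = 0.15,
                  oversampling = 4L, feature_pool_size = 120L,
                  test_splits = 20L, feature_pool_padding = 0.05,
                  regularization = 0.1)
}

# generate a fixture dataset in a fresh temporary directory
fixture_dir <- function(n, params = fixture_params()) {
  d <- tempfile("fixtures_")
  generate_dataset(n, params, d)
  d
}

subset_ds <- function(ds, idx) morphmark:::dataset_subset(ds, idx)

fixture_diag <- function(params = fixture_params())
  sqrt(params$width^2 + params$height^2)
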