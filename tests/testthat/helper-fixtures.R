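# Shared fixtures, built once per test run.

.fixture_env <- new.env()

# Default-scale phantom class-folder dataset (23/4/4 per class, 224x224),
# generated once and reused by the harness and acceptance tests.
fixture_phantom_dataset <- function() {
  if (is.null(.fixture_env$ds)) {
    root <- file.path(tempdir(), "octnss_fixture_ds")
    if (!dir.exists(file.path(root, "train")))
      generate_dataset(phantom_dataset_spec(root = root, seed = 7L))
    .fixture_env$ds <- lapply(stats::setNames(nm = c("train", "val", "test")),
                              function(s) index_dataset(root, s))
  }
  .fixture_env$ds
}

# A small class-folder tree with two classes and a stray non-image file.
fixture_mini_tree <- function() {
  root <- file.path(tempdir(), paste0("tree", sample.int(1e8, 1)))
  for (cl in c("beta", "alpha")) {
    d <- file.path(root, "train", cl)
    dir.create(d, recursive = TRUE)
    for (k in 1:3)
      write_gray(matrix(k * 10, 8, 8), file.path(d, sprintf("img_%d.png", k)))
  }
  writeLines("not an image", file.path(root, "train", "alpha", "notes.txt"))
  root
}

random_raster8 <- function(h, w) matrix(sample(0:255, h * w, replace = TRUE), h, w)
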