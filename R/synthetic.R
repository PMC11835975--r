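#' Synthetic separable image-classification task
#'
#' Generates small grayscale images whose class is carried by a bright square
#' blob at a class-specific location; blob supports are disjoint by
#' construction, so after TTFS encoding the classes are separable by first
#' spike times. Background pixels carry low-level noise. This is the
#' package's self-contained fixture generator: it exercises both encoders and
#' the full training loop without any dataset download.
#'
#' @param n_classes Number of classes (each needs a disjoint blob).
#' @param image_shape `c(H, W)` image size.
#' @param blob_size Side length of the class blob.
#' @param intensity Blob intensity before noise (pixel units, image in
#'   `[0, 1]`).
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param n_samples Total samples (balanced across classes).
#' @param seed Seed; generation is deterministic given it.
#' @return `synthetic_task_spec()`: object of class `synthetic_task_spec`.
#' @export
synthetic_task_spec <- function(n_classes = 3, image_shape = c(8, 8),
                                blob_size = 2, intensity = 1,
                                noise_sd = 0.05, n_samples = 300, seed = 1) {
  stopifnot(is_count(n_classes), is_count(blob_size), is_count(n_samples),
            length(image_shape) == 2L, noise_sd >= 0)
  step <- blob_size + 1L
  need <- (n_classes - 1L) * step + blob_size
  if (need > min(image_shape))
    stop(sprintf(paste0("degenerate spec: %d classes with blob size %d need ",
                        "image side >= %d for disjoint class supports"),
                 n_classes, blob_size, need))
  blobs <- lapply(seq_len(n_classes), function(c) {
    o <- (c - 1L) * step
    list(rows = o + seq_len(blob_size), cols = o + seq_len(blob_size))
  })
  structure(list(n_classes = as.integer(n_classes),
                 image_shape = as.integer(image_shape),
                 blob_size = as.integer(blob_size), intensity = intensity,
                 noise_sd = noise_sd, n_samples = as.integer(n_samples),
                 seed = as.integer(seed), blobs = blobs),
            class = "synthetic_task_spec")
}

#' @rdname synthetic_task_spec
#' @param spec A `synthetic_task_spec`.
#' @return `generate_synthetic_images()`: list with `x` (`(samples, pixels)`
#'   matrix, pixels column-major within the `H x W` image), `y` (factor
#'   labels), `shape`, and the `spec`.
#' @export
generate_synthetic_images <- function(spec) {
  stopifnot(inherits(spec, "synthetic_task_spec"))
  set.seed(spec$seed)
  H <- spec$image_shape[1]; W <- spec$image_shape[2]
  n <- spec$n_samples
  y <- rep(seq_len(spec$n_classes), length.out = n)
  x <- matrix(0, n, H * W)
  for (i in seq_len(n)) {
    img <- matrix(abs(stats::rnorm(H * W, 0, spec$noise_sd)), H, W)
    b <- spec$blobs[[y[i]]]
    img[b$rows, b$cols] <- spec$intensity *
      stats::runif(spec$blob_size^2, 0.85, 1)
    x[i, ] <- pmin(pmax(as.vector(img), 0), 1)
  }
  list(x = x, y = factor(paste0("c", y)), shape = c(H, W), spec = spec)
}
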