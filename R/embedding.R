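#' Image embedding contract
#'
#' Uniform interface for turning a `224 x 224 x 3` image into a
#' 4096-dimensional feature vector (the width of the penultimate
#' fully-connected layer of the VGG family). Three backbones are recognized:
#'
#' * `"stub"` -- deterministic seeded embedding that ships with the package:
#'   the image is block-mean pooled to 32 x 32 x 3, projected through a
#'   fixed Gaussian random matrix (seeded, cached) and half-wave rectified.
#'   It requires no downloads and exercises every downstream shape.
#' * `"vgg16"` / `"vggfaces"` -- pretrained CNN backbones. No weights ship
#'   with this package; constructing one without supplying `embed_fn` fails
#'   with a message naming the stub fallback. An `embed_fn` taking an image
#'   array and returning a 4096-vector plugs an external backbone in.
#'
#' @param name backbone name.
#' @param seed integer seed for the stub projection.
#' @param embed_fn optional function `(image) -> numeric(4096)` implementing
#'   an external backbone.
#' @return object of class `image_embedder` with `name`, `input_shape`,
#'   `output_dim`, `seed`, `embed_fn`.
#' @examples
#' e <- image_embedder("stub", seed = 7)
#' v <- embed(array(0.5, c(224, 224, 3)), e)
#' length(v)
#' @export
image_embedder <- function(name = c("stub", "vgg16", "vggfaces"), seed = 1,
                           embed_fn = NULL) {
  name <- match.arg(name)
  if (name != "stub" && is.null(embed_fn)) {
    stopf(paste0("no pretrained weights are installed for backbone '%s'; ",
                 "supply embed_fn= for an external network or use the ",
                 "deterministic 'stub' embedder"), name)
  }
  structure(list(name = name, input_shape = c(224L, 224L, 3L),
                 output_dim = 4096L, seed = as.integer(seed),
                 embed_fn = embed_fn),
            class = "image_embedder")
}

#' @export
print.image_embedder <- function(x, ...) {
  cat(sprintf("<image_embedder> %s: %s -> %d features (seed %d)\n", x$name,
              paste(x$input_shape, collapse = "x"), x$output_dim, x$seed))
  invisible(x)
}

# stub projection matrix: 4096 x 3072, N(0, 1/3072), cached per seed
# (only the most recent seed is kept to bound memory)
stub_projection <- function(seed) {
  key <- paste0("stub_", seed)
  if (!is.null(.ds_cache$stub_key) && identical(.ds_cache$stub_key, key)) {
    return(.ds_cache$stub_W)
  }
  W <- with_seed(seed, matrix(rnorm(4096L * 3072L), 4096L, 3072L) / sqrt(3072))
  .ds_cache$stub_key <- key
  .ds_cache$stub_W <- W
  W
}

# 224 -> 32 block-mean pooling (7 x 7 blocks) of each channel
pool_image <- function(image, out_n = 32L) {
  d <- dim(image)
  blk <- d[1] %/% out_n
  P <- matrix(0, out_n, d[1])
  for (i in seq_len(out_n)) P[i, ((i - 1) * blk + 1):(i * blk)] <- 1 / blk
  v <- numeric(out_n * out_n * 3L)
  for (ch in 1:3) {
    v[((ch - 1) * out_n^2 + 1):(ch * out_n^2)] <- as.vector(P %*% image[, , ch] %*% t(P))
  }
  v
}

#' Embed an image
#'
#' Applies the embedder's backbone to an image already at the contract's
#' input shape (use [resize_to_input()] first if needed) and returns the
#' 4096-dimensional feature vector. The stub backbone is deterministic for a
#' fixed seed.
#'
#' @param image `224 x 224 x 3` numeric array in [0, 1].
#' @param embedder an [image_embedder()].
#' @return numeric vector of length 4096, all finite.
#' @export
embed <- function(image, embedder) {
  d <- dim(image)
  if (length(d) != 3 || !all(d == embedder$input_shape)) {
    stopf("image dims [%s] do not match the embedder input shape [%s]; resize first",
          paste(d, collapse = ", "), paste(embedder$input_shape, collapse = ", "))
  }
  out <- if (!is.null(embedder$embed_fn)) {
    as.numeric(embedder$embed_fn(image))
  } else {
    W <- stub_projection(embedder$seed)
    as.numeric(pmax(W %*% pool_image(image), 0))
  }
  if (length(out) != embedder$output_dim) {
    stopf("backbone returned %d values, expected %d", length(out), embedder$output_dim)
  }
  if (any(!is.finite(out))) stopf("embedding contains non-finite values")
  out
}
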