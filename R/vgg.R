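## Layer-wise unsupervised activation energy (UAE) from a VGG16-style
## backbone: forward pass over the 13 convolutional layers, post-ReLU
## feature maps, and their per-layer means.

#' Construct a VGG16-style backbone
#'
#' Builds the 13-convolutional-layer VGG configuration. With
#' `source = "random"` the weights are He-initialized Gaussians (zero biases)
#' fully determined by `seed` — a hermetic weight source under which the
#' activation-energy formula behaves identically to a pretrained network.
#' With `source = "file"` a weight list saved with [saveRDS()] is loaded
#' (e.g. ImageNet-pretrained weights exported from another framework as
#' `list(list(W, b), ...)` with 3 x 3 x in x out kernels, cross-correlation
#' convention).
#'
#' @param source `"random"` or `"file"`.
#' @param seed integer seed for `source = "random"`.
#' @param path RDS path for `source = "file"`.
#' @param inputMean,inputStd per-channel centering of the \[0, 1\] RGB input
#'   before the first layer; defaults are the ImageNet convention under which
#'   pretrained activations are meaningful.
#' @return a [VGGBackbone-class].
#' @examples
#' bb <- vggBackbone("random", seed = 11)
#' @export
vggBackbone <- function(source = c("random", "file"), seed = 1L, path = NULL,
                        inputMean = c(0.485, 0.456, 0.406),
                        inputStd = c(0.229, 0.224, 0.225)) {
  source <- match.arg(source)
  ch <- .vggChannels()
  if (source == "random") {
    weights <- .withSeed(seed, lapply(seq_len(13L), function(l) {
      fanIn <- 9 * ch$inC[l]
      W <- array(rnorm(9 * ch$inC[l] * ch$outC[l], sd = sqrt(2 / fanIn)),
                 dim = c(3L, 3L, ch$inC[l], ch$outC[l]))
      list(W = W, b = numeric(ch$outC[l]))
    }))
    src <- sprintf("seeded-random(%d)", as.integer(seed))
  } else {
    if (is.null(path) || !file.exists(path)) stop("weight file not found")
    weights <- readRDS(path)
    src <- paste0("file:", path)
  }
  new("VGGBackbone", weights = weights, weightsSource = src,
      inputMean = inputMean, inputStd = inputStd)
}

.centerInput <- function(rgb, backbone) {
  x <- array(0, dim(rgb))
  for (c in 1:3)
    x[, , c] <- (rgb[, , c] - backbone@inputMean[c]) / backbone@inputStd[c]
  x
}

.imageRGB <- function(image) {
  if (is(image, "TFImage")) image@rgb else image
}

#' Extract post-ReLU feature maps of all 13 convolutional layers
#'
#' Runs a forward pass and returns the rectified activation tensor of each
#' convolutional layer (layer 1 first; spatial size shrinks by the pooling
#' between blocks: 224, 224, 112, 112, 56, 56, 56, 28, 28, 28, 14, 14, 14).
#'
#' @param image a [TFImage-class] or a 224 x 224 x 3 array in \[0, 1\].
#' @param backbone a [VGGBackbone-class].
#' @return list of 13 non-negative arrays (h x w x d).
#' @export
extractFeatureMaps <- function(image, backbone) {
  rgb <- .imageRGB(image)
  if (!identical(dim(rgb), c(224L, 224L, 3L)))
    stop("image must be 224 x 224 x 3")
  validObject(backbone)
  .cppVGGForward(.centerInput(rgb, backbone), backbone@weights, TRUE)$maps
}

#' Unsupervised activation energy of one feature map
#'
#' The mean of the feature map over height, width and channels:
#' UAE = (1/(h w d)) * sum F\[i, j, k\]. Computed on post-ReLU maps it is
#' non-negative, and larger values indicate a more visually complex input
#' image.
#'
#' @param map numeric array (h x w x d), post-ReLU feature map.
#' @return single non-negative number.
#' @export
uae <- function(map) {
  if (!length(map)) stop("empty feature map")
  sum(map) / length(map)
}

#' Per-contact activation-energy vector
#'
#' Computes the 13 per-layer UAE values for each epoch image and averages
#' them across epochs, yielding one 13-element visual-complexity feature
#' vector per iEEG contact.
#'
#' @param images list of [TFImage-class] objects (or 224 x 224 x 3 arrays),
#'   one per 3 s epoch; at least one.
#' @param backbone a [VGGBackbone-class].
#' @return numeric vector of length 13 (names `L1`..`L13`) with attribute
#'   `"nEpochs"`.
#' @export
contactUAE <- function(images, backbone) {
  if (!length(images)) stop("at least one epoch image is required")
  validObject(backbone)
  per <- vapply(images, function(img) {
    rgb <- .imageRGB(img)
    if (!identical(dim(rgb), c(224L, 224L, 3L)))
      stop("each image must be 224 x 224 x 3")
    .cppVGGForward(.centerInput(rgb, backbone), backbone@weights, FALSE)$uae
  }, numeric(13L))
  out <- rowMeans(matrix(per, nrow = 13L))
  names(out) <- paste0("L", 1:13)
  attr(out, "nEpochs") <- length(images)
  out
}
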