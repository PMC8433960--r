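#' Backbone layer descriptors
#'
#' Building blocks for a [backbone_spec()]: 2-D convolution, max pooling,
#' rectifier, and fully connected layers. A backbone is an ordered list of
#' these; the final layer must be fully connected and its `out_dim` is the
#' embedding dimension shared by both Siamese branches.
#'
#' @param out_channels,kernel,stride,padding convolution geometry.
#' @param out_dim fully-connected output width.
#' @return A layer descriptor list with a `type` field.
#' @name layers
NULL

#' @rdname layers
#' @export
conv_layer <- function(out_channels, kernel = 3L, stride = 1L, padding = 1L) {
  list(type = "conv", out_channels = as.integer(out_channels),
       kernel = as.integer(kernel), stride = as.integer(stride),
       padding = as.integer(padding))
}

#' @rdname layers
#' @export
pool_layer <- function(kernel = 2L, stride = 2L) {
  list(type = "pool", kernel = as.integer(kernel), stride = as.integer(stride))
}

#' @rdname layers
#' @export
relu_layer <- function() list(type = "relu")

#' @rdname layers
#' @export
fc_layer <- function(out_dim) list(type = "fc", out_dim = as.integer(out_dim))

#' Backbone specification
#'
#' Describes a small CNN as an ordered list of layer descriptors plus the
#' name of the tap layer whose spatial activations feed the DEEPER
#' dissimilarity construction. Layers are auto-named by type and position
#' (`conv1`, `relu1`, `pool1`, `conv2`, ...). The default tap layer is the
#' layer immediately before the last rectifier, i.e. the deepest
#' convolutional map, chosen to describe patterns by a deep but not final
#' representation and so avoid overfitting the embedding.
#'
#' @param layers list of layer descriptors ([conv_layer()] etc.); the last
#'   layer must be [fc_layer()].
#' @param tap_layer name of the layer whose output feeds DEEPER; `NULL`
#'   selects the default described above.
#' @return An object of class `backbone_spec` with named `layers`,
#'   `tap_layer` and `embedding_dim`.
#' @export
backbone_spec <- function(layers, tap_layer = NULL) {
  if (length(layers) == 0L) stop("backbone needs at least one layer")
  types <- vapply(layers, `[[`, "", "type")
  counts <- stats::ave(seq_along(types), types, FUN = seq_along)
  names(layers) <- paste0(types, counts)
  if (types[length(types)] != "fc")
    stop("the final backbone layer must be fully connected")
  if (is.null(tap_layer)) {
    relu_pos <- which(types == "relu")
    if (length(relu_pos) == 0L || max(relu_pos) <= 1L)
      stop("cannot infer a default tap layer; give `tap_layer` explicitly")
    tap_layer <- names(layers)[max(relu_pos) - 1L]
  }
  if (!tap_layer %in% names(layers))
    stop("tap_layer '", tap_layer, "' does not name a backbone layer")
  structure(
    list(layers = layers, tap_layer = tap_layer,
         embedding_dim = layers[[length(layers)]]$out_dim),
    class = "backbone_spec"
  )
}

#' Default small backbone
#'
#' Three conv/rectifier/pool blocks (8, 16, 32 channels, 3x3 kernels,
#' padding 1) followed by a fully connected embedding. On 32 x 32 x 3 input
#' the tap layer (`conv3`) produces an 8 x 8 x 32 map.
#'
#' @param embedding_dim embedding width (default 64).
#' @return A [backbone_spec()].
#' @export
default_backbone_spec <- function(embedding_dim = 64L) {
  backbone_spec(list(
    conv_layer(8L), relu_layer(), pool_layer(),
    conv_layer(16L), relu_layer(), pool_layer(),
    conv_layer(32L), relu_layer(), pool_layer(),
    fc_layer(embedding_dim)
  ))
}

# Static shape inference: returns a named list mapping layer name to output
# shape (H, W, C) or embedding width; errors mention the offending layer.
infer_shapes <- function(spec, input_shape) {
  shp <- input_shape
  out <- list()
  for (nm in names(spec$layers)) {
    ly <- spec$layers[[nm]]
    shp <- switch(ly$type,
      conv = {
        hw <- conv_out_hw(shp[1L], shp[2L], ly$kernel, ly$stride, ly$padding)
        if (any(hw < 1L))
          stop("layer ", nm, ": output shape collapses below 1 pixel")
        c(hw, ly$out_channels)
      },
      pool = {
        if (length(shp) != 3L)
          stop("layer ", nm, ": pooling requires a spatial input")
        hw <- conv_out_hw(shp[1L], shp[2L], ly$kernel, ly$stride, 0L)
        if (any(hw < 1L))
          stop("layer ", nm, ": output shape collapses below 1 pixel")
        c(hw, shp[3L])
      },
      relu = shp,
      fc = ly$out_dim,
      stop("layer ", nm, ": unknown type '", ly$type, "'")
    )
    out[[nm]] <- shp
  }
  out
}

#' Build a Siamese model from a backbone specification
#'
#' Both branches of the Siamese network share one parameter set (weight
#' tying is structural: there is exactly one copy of the backbone
#' parameters). The head is a single affine map `embedding_dim -> 1`
#' followed by a sigmoid, applied to the element-wise absolute difference
#' `|F1 - F2|` of the two branch embeddings. Weights use seeded He-style
#' fan-in uniform initialization; biases start at zero.
#'
#' @param spec a [backbone_spec()].
#' @param seed integer seed for the parameter initialization.
#' @param input_shape `c(H, W, C)` of the images the model will consume.
#' @return An object of class `siamese_model`: `spec`, `input_shape`,
#'   `shapes` (per-layer output shapes), `params` (flat named list of
#'   tensors, e.g. `conv1.W`, `fc1.b`, `head.w`, `head.b`).
#' @export
build_model <- function(spec, seed = 0L, input_shape = c(32L, 32L, 3L)) {
  stopifnot(inherits(spec, "backbone_spec"))
  shapes <- infer_shapes(spec, input_shape)
  tap_shape <- shapes[[spec$tap_layer]]
  if (length(tap_shape) != 3L)
    stop("tap_layer '", spec$tap_layer, "' does not produce a spatial map")
  local_rng(seed)
  he_unif <- function(n, fan_in) {
    lim <- sqrt(6 / fan_in)
    stats::runif(n, -lim, lim)
  }
  params <- list()
  shp <- input_shape
  for (nm in names(spec$layers)) {
    ly <- spec$layers[[nm]]
    if (ly$type == "conv") {
      fan_in <- ly$kernel^2 * shp[3L]
      params[[paste0(nm, ".W")]] <- array(
        he_unif(ly$kernel^2 * shp[3L] * ly$out_channels, fan_in),
        c(ly$kernel, ly$kernel, shp[3L], ly$out_channels))
      params[[paste0(nm, ".b")]] <- numeric(ly$out_channels)
    } else if (ly$type == "fc") {
      d_in <- prod(shp)
      params[[paste0(nm, ".W")]] <- matrix(
        he_unif(d_in * ly$out_dim, d_in), d_in, ly$out_dim)
      params[[paste0(nm, ".b")]] <- numeric(ly$out_dim)
    }
    shp <- shapes[[nm]]
  }
  e <- spec$embedding_dim
  params[["head.w"]] <- matrix(he_unif(e, e), e, 1L)
  params[["head.b"]] <- 0
  structure(
    list(spec = spec, input_shape = input_shape, shapes = shapes,
         params = params),
    class = "siamese_model"
  )
}

#' @export
print.siamese_model <- function(x, ...) {
  cat(sprintf(
    "<siamese_model> %d layers, input %s, embedding %d, tap '%s' (%s)\n",
    length(x$spec$layers), paste(x$input_shape, collapse = "x"),
    x$spec$embedding_dim, x$spec$tap_layer,
    paste(x$shapes[[x$spec$tap_layer]], collapse = "x")))
  invisible(x)
}

as_batch <- function(images, input_shape) {
  if (inherits(images, "image_dataset")) images <- images$images
  if (length(dim(images)) == 3L) dim(images) <- c(dim(images), 1L)
  if (length(dim(images)) != 4L || !all(dim(images)[1:3] == input_shape))
    stop("images do not match the model input shape ",
         paste(input_shape, collapse = "x"))
  images
}

# Forward pass through the backbone. `upto` stops after the named layer.
# Returns the final output and, when `keep_cache`, the per-layer caches
# needed for the backward pass. `x` is in user layout H x W x C x N;
# spatial intermediates run in the internal channel-last layout (see
# nn-ops.R) and the fc output is an N x out_dim matrix.
backbone_forward <- function(model, x, upto = NULL, keep_cache = FALSE) {
  x <- to_internal(x)
  caches <- list()
  for (nm in names(model$spec$layers)) {
    ly <- model$spec$layers[[nm]]
    step <- switch(ly$type,
      conv = conv_fwd(x, model$params[[paste0(nm, ".W")]],
                      model$params[[paste0(nm, ".b")]],
                      ly$stride, ly$padding),
      pool = pool_fwd(x, ly$kernel, ly$stride),
      relu = relu_fwd(x),
      fc = fc_fwd(x, model$params[[paste0(nm, ".W")]],
                  model$params[[paste0(nm, ".b")]])
    )
    x <- step$out
    if (keep_cache) caches[[nm]] <- step$cache
    if (!is.null(upto) && nm == upto) break
  }
  list(out = x, caches = caches)
}

# Backward pass; d_out matches the output of the last executed layer.
# Returns gradients named like model$params plus `dx`.
backbone_backward <- function(model, caches, d_out) {
  grads <- list()
  for (nm in rev(names(caches))) {
    ly <- model$spec$layers[[nm]]
    step <- switch(ly$type,
      conv = conv_bwd(d_out, caches[[nm]]),
      pool = pool_bwd(d_out, caches[[nm]]),
      relu = relu_bwd(d_out, caches[[nm]]),
      fc = fc_bwd(d_out, caches[[nm]])
    )
    if (!is.null(step$dw)) {
      grads[[paste0(nm, ".W")]] <- step$dw
      grads[[paste0(nm, ".b")]] <- step$db
    }
    d_out <- step$dx
  }
  grads$dx <- d_out
  grads
}

#' Embed a batch of images
#'
#' Runs the shared backbone; row i of the result is the embedding `F` of
#' image i. Purely functional: identical inputs give identical rows.
#'
#' @param model a [build_model()] result.
#' @param images `H x W x C (x N)` array or an [image_dataset()].
#' @return `N x embedding_dim` numeric matrix.
#' @export
embed <- function(model, images) {
  x <- as_batch(images, model$input_shape)
  backbone_forward(model, x)$out
}

#' Tap-layer activations for the DEEPER construction
#'
#' @inheritParams embed
#' @return `H' x W' x C' x N` array of activations at the spec's tap layer.
#' @export
deep_features <- function(model, images) {
  x <- as_batch(images, model$input_shape)
  to_user(backbone_forward(model, x, upto = model$spec$tap_layer)$out)
}

head_forward <- function(model, f1, f2) {
  z <- abs(f1 - f2)
  drop(sigmoid(z %*% model$params[["head.w"]] + model$params[["head.b"]]))
}

#' Network-predicted dissimilarity of image pairs
#'
#' `sigmoid(affine(|F1 - F2|))`, strictly inside (0, 1) and symmetric in its
#' two arguments. Under the package's training convention (pair target 1 =
#' different class) the output is the learned dissimilarity itself.
#'
#' @param model a [build_model()] result.
#' @param images1,images2 equal-sized batches.
#' @return numeric vector of length N with values in (0, 1).
#' @export
pair_dissimilarity <- function(model, images1, images2) {
  x1 <- as_batch(images1, model$input_shape)
  x2 <- as_batch(images2, model$input_shape)
  if (dim(x1)[4L] != dim(x2)[4L]) stop("batch sizes differ")
  head_forward(model, embed(model, x1), embed(model, x2))
}

#' Save / load a Siamese model checkpoint
#'
#' One self-contained RDS file holding the backbone spec, input shape and
#' all parameters, so a checkpoint can be reloaded without the original
#' spec file.
#'
#' @param model a [build_model()] (possibly trained) result.
#' @param path file path (conventionally `.rds`).
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the `siamese_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "siamese_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "siamese_model"))
    stop("file does not contain a siamese model checkpoint")
  model
}

#' Read / write a backbone specification as JSON
#'
#' The JSON round-trips losslessly: `read_backbone_spec(write_backbone_spec(s))`
#' reproduces `s`.
#'
#' @param spec a [backbone_spec()].
#' @param path file path.
#' @export
write_backbone_spec <- function(spec, path) {
  jsonlite::write_json(
    list(layers = lapply(unname(spec$layers), function(l) l),
         tap_layer = spec$tap_layer),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_backbone_spec
#' @export
read_backbone_spec <- function(path) {
  obj <- jsonlite::read_json(path)
  layers <- lapply(obj$layers, function(l) {
    l[setdiff(names(l), "type")] <- lapply(l[setdiff(names(l), "type")],
                                           as.integer)
    l
  })
  backbone_spec(layers, tap_layer = obj$tap_layer)
}
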