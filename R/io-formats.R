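#' Read an IDX (MNIST ubyte) file
#'
#' Parses the IDX format used to distribute MNIST: a big-endian magic
#' number (two zero bytes, a type code, the number of dimensions), the
#' dimension sizes as big-endian 32-bit integers, then the raw payload in
#' C order (last index fastest). Only the unsigned-byte type (0x08) is
#' supported, which covers both the image and the label files.
#'
#' @param path Path to an IDX file.
#' @return A numeric array with the dimensions declared in the header
#'   (a vector for 1-D label files); values in 0..255.
#' @export
read_idx <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4L)
  if (length(magic) < 4L || magic[1] != 0 || magic[2] != 0) {
    stop(sprintf("bad IDX magic number in '%s' (offset 0)", path),
         call. = FALSE)
  }
  if (as.integer(magic[3]) != 0x08L) {
    stop(sprintf("unsupported IDX type code 0x%02x (only ubyte 0x08)",
                 as.integer(magic[3])), call. = FALSE)
  }
  ndim <- as.integer(magic[4])
  dims <- readBin(con, "integer", ndim, size = 4L, endian = "big")
  if (length(dims) < ndim || any(dims < 0)) {
    stop(sprintf("truncated IDX header in '%s' (offset 4)", path),
         call. = FALSE)
  }
  n <- prod(dims)
  payload <- readBin(con, "raw", n)
  if (length(payload) < n) {
    stop(sprintf("truncated IDX payload in '%s': expected %d bytes, got %d (offset %d)",
                 path, n, length(payload), 4L + 4L * ndim + length(payload)),
         call. = FALSE)
  }
  v <- as.numeric(as.integer(payload))
  if (ndim == 1L) return(v)
  # file is C-order (last index fastest); R arrays are column-major
  aperm(array(v, dim = rev(dims)), ndim:1)
}

#' Write an array as an IDX (ubyte) file
#'
#' Inverse of [read_idx()]; values must be integers in 0..255.
#'
#' @param x Numeric array or vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_idx <- function(x, path) {
  v <- as.integer(x)
  if (any(is.na(v)) || any(v < 0) || any(v > 255)) {
    stop("IDX ubyte payload must contain integers in 0..255", call. = FALSE)
  }
  dims <- if (is.null(dim(x))) length(x) else dim(x)
  ndim <- length(dims)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0, 0, 0x08, ndim)), con)
  writeBin(as.integer(dims), con, size = 4L, endian = "big")
  if (ndim > 1L) {
    x_c <- aperm(array(v, dim = dims), ndim:1)
    v <- as.integer(x_c)
  }
  writeBin(as.raw(v), con)
  invisible(path)
}

#' Image dataset container
#'
#' Raw pixel intensities (0..255) with labels; [preprocess_images()]
#' scales to `[0, 1]` and flattens into a [pattern_set()].
#'
#' @param images Array `n x height x width` (grayscale) or
#'   `n x height x width x channels`.
#' @param labels Integer class per image (optional).
#' @param source One of `"mnist_idx"`, `"cifar10_binary"`, `"synthetic"`.
#' @return An object of class `bcm_image_dataset`.
#' @export
image_dataset <- function(images, labels = NULL,
                          source = c("synthetic", "mnist_idx", "cifar10_binary")) {
  source <- match.arg(source)
  d <- dim(images)
  if (is.null(d) || !(length(d) %in% c(3L, 4L))) {
    stop("`images` must be a 3-D or 4-D array", call. = FALSE)
  }
  if (!is.null(labels) && length(labels) != d[1]) {
    stop("one label per image required", call. = FALSE)
  }
  structure(list(images = images, labels = labels, source = source),
            class = "bcm_image_dataset")
}

#' @export
print.bcm_image_dataset <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<bcm_image_dataset: %d images %s, source %s>\n",
              d[1], paste(d[-1], collapse = "x"), x$source))
  invisible(x)
}

#' Read a CIFAR-10 binary batch file
#'
#' Each record is 3073 bytes: one label byte followed by 3072 pixel bytes
#' (channel-major: 1024 red, 1024 green, 1024 blue, each row-major
#' 32 x 32). The file length must be a multiple of 3073.
#'
#' @param path Path to a CIFAR-10 binary batch.
#' @return A [image_dataset()] with images `n x 32 x 32 x 3`
#'   (channel-last) and labels 0..9.
#' @export
read_cifar10_batch <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  rec <- 3073L
  if (length(bytes) %% rec != 0L) {
    stop(sprintf("bad CIFAR-10 batch '%s': %d bytes is not a multiple of %d",
                 path, length(bytes), rec), call. = FALSE)
  }
  n <- length(bytes) %/% rec
  if (n == 0L) {
    return(image_dataset(array(numeric(0), c(0L, 32L, 32L, 3L)),
                         integer(0), source = "cifar10_binary"))
  }
  m <- matrix(as.integer(bytes), rec, n)
  labels <- m[1L, ]
  px <- m[-1L, , drop = FALSE]  # 3072 x n, channel-major then row-major
  # per image: array(row-major 32x32 per channel) -> n x 32 x 32 x 3
  arr <- array(as.numeric(px), dim = c(32L, 32L, 3L, n))  # col, row, ch, img
  images <- aperm(arr, c(4L, 2L, 1L, 3L))                 # img, row, col, ch
  image_dataset(images, labels, source = "cifar10_binary")
}

#' Write images as a CIFAR-10 binary batch
#'
#' Inverse of [read_cifar10_batch()].
#'
#' @param images Array `n x 32 x 32 x 3`, integer values 0..255.
#' @param labels Integer labels 0..9, one per image.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cifar10_batch <- function(images, labels, path) {
  d <- dim(images)
  stopifnot(length(d) == 4L, d[2] == 32L, d[3] == 32L, d[4] == 3L,
            length(labels) == d[1])
  con <- file(path, "wb")
  on.exit(close(con))
  for (i in seq_len(d[1])) {
    writeBin(as.raw(labels[i]), con)
    img <- images[i, , , , drop = TRUE]           # row, col, ch
    px <- aperm(img, c(2L, 1L, 3L))               # col, row, ch -> flatten
    writeBin(as.raw(as.integer(px)), con)
  }
  invisible(path)
}

#' Flatten an image dataset into a pattern set
#'
#' Scales pixel intensities to `[0, 1]` (dividing by 255 when any value
#' exceeds 1) and flattens each image row-major, channel-last: feature
#' index `((r-1) * width + (c-1)) * channels + ch`. Labels are carried
#' through; probabilities are uniform.
#'
#' @param ds A [image_dataset()].
#' @return A [pattern_set()] with `height * width * channels` features.
#' @export
preprocess_images <- function(ds) {
  stopifnot(inherits(ds, "bcm_image_dataset"))
  arr <- ds$images
  if (length(arr) && max(arr) > 1) arr <- arr / 255
  d <- dim(arr)
  X <- if (length(d) == 3L) {
    # (img, row, col) -> features with col fastest, then row
    matrix(aperm(arr, c(3L, 2L, 1L)), d[2] * d[3], d[1])
  } else {
    # (img, row, col, ch) -> ch fastest, then col, then row
    matrix(aperm(arr, c(4L, 3L, 2L, 1L)), d[2] * d[3] * d[4], d[1])
  }
  pattern_set(X, labels = ds$labels)
}

#' Export receptive fields as PNG bitmaps
#'
#' Each neuron's weight vector is min-max scaled to `[0, 1]` on its own
#' (per-neuron contrast keeps each receptive field interpretable),
#' un-flattened to the image dimensions with the same row-major,
#' channel-last convention as [preprocess_images()], and written as one
#' PNG per neuron plus a tiled montage. A constant weight vector renders
#' mid-gray rather than erroring.
#'
#' @param W Weight matrix (`n_neurons x n_features`) or a `bcm_fit`.
#' @param shape Image dimensions `c(height, width)` or
#'   `c(height, width, channels)`; `prod(shape)` must equal `n_features`.
#' @param dir Output directory (created if missing).
#' @param grid Montage layout `c(rows, cols)` (default: near-square).
#' @return Invisibly, the paths of the written files (montage last).
#' @export
export_weight_bitmaps <- function(W, shape, dir, grid = NULL) {
  if (inherits(W, "bcm_fit")) W <- W$network$W
  W <- assert_matrix(W, "W")
  shape <- as.integer(shape)
  stopifnot(length(shape) %in% c(2L, 3L))
  if (prod(shape) != ncol(W)) {
    stop(sprintf("prod(shape) = %d does not match n_features = %d",
                 prod(shape), ncol(W)), call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  N <- nrow(W)
  unflatten <- function(w) {
    if (length(shape) == 2L) {
      # features are col fastest then row -> fill a (col, row) array, transpose
      t(array(w, dim = c(shape[2], shape[1])))
    } else {
      # ch fastest, then col, then row
      aperm(array(w, dim = c(shape[3], shape[2], shape[1])), c(3L, 2L, 1L))
    }
  }
  bitmaps <- vector("list", N)
  paths <- character(N)
  for (i in seq_len(N)) {
    w <- W[i, ]
    rng <- range(w)
    w01 <- if (diff(rng) == 0) rep(0.5, length(w)) else (w - rng[1]) / diff(rng)
    bitmaps[[i]] <- unflatten(w01)
    paths[i] <- file.path(dir, sprintf("neuron_%03d.png", i))
    png::writePNG(bitmaps[[i]], paths[i])
  }
  if (is.null(grid)) {
    gc_ <- ceiling(sqrt(N))
    grid <- c(ceiling(N / gc_), gc_)
  }
  stopifnot(prod(grid) >= N)
  h <- shape[1]; w_ <- shape[2]
  ch <- if (length(shape) == 3L) shape[3] else 1L
  pad <- 1L
  mh <- grid[1] * h + (grid[1] - 1L) * pad
  mw <- grid[2] * w_ + (grid[2] - 1L) * pad
  montage <- array(1, c(mh, mw, ch))
  for (i in seq_len(N)) {
    r <- (i - 1L) %/% grid[2]
    c_ <- (i - 1L) %% grid[2]
    rows <- r * (h + pad) + seq_len(h)
    cols <- c_ * (w_ + pad) + seq_len(w_)
    montage[rows, cols, ] <- bitmaps[[i]]
  }
  if (ch == 1L) montage <- montage[, , 1L]
  montage_path <- file.path(dir, "montage.png")
  png::writePNG(montage, montage_path)
  invisible(c(paths, montage_path))
}

#' Serialize a pattern set to plain text
#'
#' Writes `patterns.csv` (one row per pattern: `pattern`, `label`,
#' `probability`, then feature columns) and `meta.json` (seed and
#' dimensions) into a directory. [read_pattern_set()] restores the set.
#'
#' @param ps A [pattern_set()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_pattern_set <- function(ps, dir) {
  stopifnot(inherits(ps, "bcm_pattern_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as_tibble(ps), file.path(dir, "patterns.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(seed = ps$seed, n_features = n_features(ps),
         n_patterns = n_patterns(ps),
         has_labels = !is.null(ps$labels)),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_pattern_set
#' @param dir Directory written by [write_pattern_set()].
#' @export
read_pattern_set <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  df <- utils::read.csv(file.path(dir, "patterns.csv"))
  ps <- as_pattern_set(df)
  ps$seed <- if (is.null(meta$seed)) NA_integer_ else as.integer(meta$seed)
  ps
}

#' Checkpoint a fit to JSON (and restore it)
#'
#' Stores weights, activation, lateral strength, modification-threshold
#' state, optimizer moments and a config echo as a single JSON document;
#' everything needed to resume a forward pass or audit a run.
#'
#' @param fit A `bcm_fit`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "bcm_fit"))
  cfg <- unclass(fit$config)
  cfg$W0 <- NULL
  obj <- list(
    W = fit$network$W,
    activation = fit$network$activation,
    xi = fit$network$lateral$xi,
    theta = fit$threshold$theta,
    gamma = fit$threshold$gamma,
    theta_floor = fit$threshold$floor,
    optimizer = list(kind = fit$optimizer$kind,
                     learning_rate = fit$optimizer$learning_rate,
                     t = fit$optimizer$t,
                     m = fit$optimizer$m, v = fit$optimizer$v),
    epochs_run = fit$epochs_run,
    converged = fit$converged,
    config = cfg
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_checkpoint
#' @param path Path written by [write_checkpoint()].
#' @export
read_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- as.matrix(obj$W)
  network <- network_state(W, obj$activation,
                           build_lateral(nrow(W), obj$xi))
  ts <- threshold_state(nrow(W), gamma = obj$gamma, floor = obj$theta_floor)
  ts$theta <- as.numeric(obj$theta)
  list(network = network, threshold = ts,
       epochs_run = obj$epochs_run, converged = obj$converged,
       config = obj$config,
       optimizer = obj$optimizer)
}
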