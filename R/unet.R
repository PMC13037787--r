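#' @include containers.R
NULL

# ---------------------------------------------------------------------------
# A miniature 2-D encoder-decoder segmentation network (U-Net style) with
# explicit forward and backward passes written against plain matrices.
# Feature maps are (H*W) x channels matrices in column-major pixel order.
# Convolutions are 3x3 (zero padding 1) via im2col; downsampling is 2x2 max
# pooling; upsampling is nearest-neighbour; skip connections concatenate
# encoder features at equal resolution. Decoder levels carry two
# convolutional blocks each, named Block_<level>-<pair> with level 0 at the
# bottleneck, which is the unit of gradient targeting.
# ---------------------------------------------------------------------------

.gridCaches <- new.env(parent = emptyenv())

# im2col neighbour indices, 2x2 pool member indices and nearest-neighbour
# upsampling map for an H x W grid, built once and cached.
gridCache <- function(H, W) {
  key <- paste0(H, "x", W)
  if (!is.null(.gridCaches[[key]])) return(.gridCaches[[key]])
  n <- H * W
  i <- rep(seq_len(H), times = W)
  j <- rep(seq_len(W), each = H)
  offs <- expand.grid(dy = -1:1, dx = -1:1)
  M <- matrix(0L, n, 9L)
  for (k in seq_len(9L)) {
    ii <- i + offs$dy[k]
    jj <- j + offs$dx[k]
    ok <- ii >= 1L & ii <= H & jj >= 1L & jj <= W
    M[ok, k] <- ii[ok] + (jj[ok] - 1L) * H
  }
  cache <- list(M = M)
  if (H %% 2L == 0L && W %% 2L == 0L) {
    hp <- H %/% 2L
    wp <- W %/% 2L
    a <- rep(seq_len(hp), times = wp)
    b <- rep(seq_len(wp), each = hp)
    P <- matrix(0L, hp * wp, 4L)
    k <- 0L
    for (dj in 0:1) for (di in 0:1) {
      k <- k + 1L
      P[, k] <- (2L * a - 1L + di) + (2L * b - 2L + dj) * H
    }
    up <- ((i + 1L) %/% 2L) + (((j + 1L) %/% 2L) - 1L) * hp
    cache$P <- P
    cache$up <- up
  }
  .gridCaches[[key]] <- cache
  cache
}

im2col <- function(x, H, W) {
  M <- gridCache(H, W)$M
  n <- nrow(x)
  Cin <- ncol(x)
  cols <- matrix(0, n, 9L * Cin)
  for (k in seq_len(9L)) {
    idx <- M[, k]
    ok <- idx > 0L
    block <- matrix(0, n, Cin)
    block[ok, ] <- x[idx[ok], , drop = FALSE]
    cols[, (k - 1L) * Cin + seq_len(Cin)] <- block
  }
  cols
}

col2im <- function(dCols, H, W, Cin) {
  M <- gridCache(H, W)$M
  n <- H * W
  dx <- matrix(0, n, Cin)
  for (k in seq_len(9L)) {
    idx <- M[, k]
    ok <- idx > 0L
    dx[idx[ok], ] <- dx[idx[ok], , drop = FALSE] +
      dCols[ok, (k - 1L) * Cin + seq_len(Cin), drop = FALSE]
  }
  dx
}

# ---------------------------------------------------------------------------
# Construction

#' Construct a ToyModelSpec
#'
#' @param levels number of resolution levels (>= 2). The decoder exposes
#'   `2 * levels` convolutional blocks named `Block_<level>-<pair>`.
#' @param channels base channel count of the first encoder stage.
#' @param classes number of output classes including background (>= 2).
#' @param seed integer seed for weight initialization.
#' @return a [ToyModelSpec-class].
#' @export
toyModelSpec <- function(levels = 2L, channels = 4L, classes = 2L, seed = 1L) {
  new("ToyModelSpec", levels = as.integer(levels), channels = as.integer(channels),
      classes = as.integer(classes), seed = as.integer(seed))
}

encoderChannels <- function(levels, base) {
  pmin(base * 2L^(seq_len(levels) - 1L), base * 4L)
}

#' Build the toy segmentation network
#'
#' Weights use He-normal initialization and are fully determined by the
#' seed. The forward pass z-scores its input image (the standard
#' zero-mean-unit-variance preprocessing), applies the encoder-decoder and
#' returns per-voxel class probabilities that sum to 1.
#'
#' @param spec a [ToyModelSpec-class] from [toyModelSpec()].
#' @return a [ToyUNet-class].
#' @examples
#' model <- buildToyModel(toyModelSpec(levels = 2, channels = 2, seed = 7))
#' listParameterGroups(model)
#' @export
buildToyModel <- function(spec = toyModelSpec()) {
  stopifnot(is(spec, "ToyModelSpec"))
  validObject(spec)
  L <- spec@levels
  enc <- encoderChannels(L, spec@channels)
  params <- list()
  addConv <- function(name, cin, cout, k = 3L) {
    fan <- k * k * cin
    W <- matrix(stats::rnorm(fan * cout, sd = sqrt(2 / fan)), fan, cout)
    params[[paste0(name, ".W")]] <<- W
    params[[paste0(name, ".b")]] <<- numeric(cout)
  }
  withSeed(spec@seed, {
    cin <- 1L
    for (s in seq_len(L)) {
      addConv(sprintf("Enc_%d.c1", s), cin, enc[s])
      addConv(sprintf("Enc_%d.c2", s), enc[s], enc[s])
      cin <- enc[s]
    }
    addConv("Bottleneck.c1", enc[L], enc[L])
    addConv("Bottleneck.c2", enc[L], enc[L])
    prev <- enc[L]
    for (l in 0:(L - 1L)) {
      skip <- enc[L - l]
      addConv(sprintf("Block_%d-0", l), prev + skip, skip)
      addConv(sprintf("Block_%d-1", l), skip, skip)
      prev <- skip
    }
    addConv("Head", prev, spec@classes, k = 1L)
  })
  new("ToyUNet", params = params,
      arch = list(levels = L, channels = spec@channels, classes = spec@classes),
      seed = spec@seed)
}

#' @describeIn listParameterGroups decoder convolutional blocks of the toy
#'   network, ordered bottleneck to output (`Block_0-0` ...
#'   `Block_<levels-1>-1`).
#' @export
setMethod("listParameterGroups", "ToyUNet", function(model) {
  L <- model@arch$levels
  as.vector(vapply(0:(L - 1L), function(l) {
    c(sprintf("Block_%d-0", l), sprintf("Block_%d-1", l))
  }, character(2)))
})

#' Default gradient-target groups of a model
#'
#' The two convolutional blocks of the decoder level closest to the output
#' (for a 5-level decoder, `Block_4-0` and `Block_4-1`), the configuration
#' used for the headline uncertainty measure.
#'
#' @param model a [ToyUNet-class].
#' @return character vector of two group names.
#' @export
defaultTargetGroups <- function(model) {
  L <- model@arch$levels
  c(sprintf("Block_%d-0", L - 1L), sprintf("Block_%d-1", L - 1L))
}

#' Number of learnable parameters
#'
#' @param model a [ToyUNet-class].
#' @param groups optional character vector of parameter-group names; when
#'   given, counts only parameters belonging to those groups.
#' @return integer parameter count.
#' @export
nParameters <- function(model, groups = NULL) {
  nms <- names(model@params)
  if (!is.null(groups)) nms <- nms[parameterGroupOf(nms) %in% groups]
  sum(vapply(model@params[nms], length, integer(1)))
}

# Group (block) name owning each flat parameter name.
parameterGroupOf <- function(paramNames) {
  sub("\\.(c[12]\\.)?(W|b)$", "", paramNames)
}

paramsInGroups <- function(model, groups) {
  nms <- names(model@params)
  nms[parameterGroupOf(nms) %in% groups]
}

# ---------------------------------------------------------------------------
# Forward / backward

reluF <- function(x) {
  x[x < 0] <- 0
  x
}

addBias <- function(x, b) x + rep(b, each = nrow(x))

softmaxRows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Full forward pass. Returns probabilities plus the tape needed to
# backpropagate any scalar seeded at the logits.
unetForward <- function(model, image) {
  stopifnot(is(model, "ToyUNet"))
  v <- if (is(image, "ScanImage")) image@values else as.array(image)
  dims <- dim(v)
  if (length(dims) != 2L) stop("the toy model is 2-D: supply an HxW image", call. = FALSE)
  L <- model@arch$levels
  if (any(dims %% 2L^L != 0L)) {
    stop(sprintf("image dims must be divisible by 2^levels = %d", 2L^L), call. = FALSE)
  }
  mu <- mean(v)
  sdv <- stats::sd(as.vector(v))
  if (!is.finite(sdv) || sdv == 0) sdv <- 1
  x <- matrix((as.vector(v) - mu) / sdv, ncol = 1L)

  P <- model@params
  tape <- list()
  push <- function(op) tape[[length(tape) + 1L]] <<- op

  convRelu <- function(x, name, H, W) {
    Wm <- P[[paste0(name, ".W")]]
    cin <- ncol(x)
    cols <- im2col(x, H, W)
    pre <- addBias(cols %*% Wm, P[[paste0(name, ".b")]])
    push(list(type = "conv", name = name, H = H, W = W, cin = cin,
              cols = cols, mask = pre > 0))
    reluF(pre)
  }

  H <- dims[1L]; W <- dims[2L]
  skips <- vector("list", L)
  sizes <- matrix(0L, L + 1L, 2L)
  for (s in seq_len(L)) {
    sizes[s, ] <- c(H, W)
    x <- convRelu(x, sprintf("Enc_%d.c1", s), H, W)
    x <- convRelu(x, sprintf("Enc_%d.c2", s), H, W)
    skips[[s]] <- x
    g <- gridCache(H, W)
    ncell <- nrow(g$P)
    C <- ncol(x)
    out <- matrix(-Inf, ncell, C)
    arg <- matrix(0L, ncell, C)
    for (k in seq_len(4L)) {
      vals <- x[g$P[, k], , drop = FALSE]
      upd <- vals > out
      idxm <- matrix(g$P[, k], ncell, C)
      out[upd] <- vals[upd]
      arg[upd] <- idxm[upd]
    }
    push(list(type = "pool", nIn = H * W, arg = arg, stage = s))
    x <- out
    H <- H %/% 2L; W <- W %/% 2L
  }
  sizes[L + 1L, ] <- c(H, W)
  x <- convRelu(x, "Bottleneck.c1", H, W)
  x <- convRelu(x, "Bottleneck.c2", H, W)

  for (l in 0:(L - 1L)) {
    Hup <- sizes[L - l, 1L]; Wup <- sizes[L - l, 2L]
    up <- gridCache(Hup, Wup)$up
    push(list(type = "up", up = up, nIn = H * W))
    x <- x[up, , drop = FALSE]
    H <- Hup; W <- Wup
    skip <- skips[[L - l]]
    push(list(type = "concat", c1 = ncol(x), c2 = ncol(skip), skipLevel = L - l))
    x <- cbind(x, skip)
    x <- convRelu(x, sprintf("Block_%d-0", l), H, W)
    x <- convRelu(x, sprintf("Block_%d-1", l), H, W)
  }
  logits <- addBias(x %*% P[["Head.W"]], P[["Head.b"]])
  push(list(type = "head", xIn = x))
  p <- softmaxRows(logits)
  list(p = p, logits = logits, tape = tape, dims = dims, skipGrads = NULL)
}

# Backpropagate dZ (the gradient of a scalar with respect to the logits,
# an (H*W) x C matrix) down the recorded tape. Returns the named list of
# parameter gradients, one entry per entry of model@params. Skip
# connections give the encoder-stage output tensor two consumers (the pool
# below it and the decoder concat); the reverse walk meets the concat
# first, stashes that branch's gradient, and adds it back in when the pool
# op of the same stage is reached.
unetBackward <- function(model, fwd, dZ) {
  P <- model@params
  grads <- vector("list", length(P))
  names(grads) <- names(P)
  skipG <- list()
  d <- dZ
  for (op in rev(fwd$tape)) {
    if (op$type == "head") {
      grads[["Head.W"]] <- crossprod(op$xIn, d)
      grads[["Head.b"]] <- colSums(d)
      d <- d %*% t(P[["Head.W"]])
    } else if (op$type == "conv") {
      d <- d * op$mask
      grads[[paste0(op$name, ".W")]] <- crossprod(op$cols, d)
      grads[[paste0(op$name, ".b")]] <- colSums(d)
      d <- col2im(d %*% t(P[[paste0(op$name, ".W")]]), op$H, op$W, op$cin)
    } else if (op$type == "pool") {
      dx <- matrix(0, op$nIn, ncol(d))
      dx[cbind(as.vector(op$arg), rep(seq_len(ncol(d)), each = nrow(d)))] <-
        as.vector(d)
      stashed <- skipG[[as.character(op$stage)]]
      d <- if (is.null(stashed)) dx else dx + stashed
    } else if (op$type == "up") {
      d <- rowsum(d, op$up, reorder = TRUE)
    } else if (op$type == "concat") {
      key <- as.character(op$skipLevel)
      dSkip <- d[, op$c1 + seq_len(op$c2), drop = FALSE]
      skipG[[key]] <- if (is.null(skipG[[key]])) dSkip else skipG[[key]] + dSkip
      d <- d[, seq_len(op$c1), drop = FALSE]
    }
  }
  for (nm in names(grads)) {
    if (is.null(grads[[nm]])) grads[[nm]] <- P[[nm]] * 0
  }
  grads
}

# ---------------------------------------------------------------------------
# Prediction

#' Per-voxel class probabilities of the toy network
#'
#' @param model a [ToyUNet-class].
#' @param image a [ScanImage-class] (or plain matrix) whose dimensions are
#'   divisible by `2^levels`.
#' @return an `H x W x classes` array of softmax probabilities; each
#'   voxel's probabilities sum to 1.
#' @export
predictProbabilities <- function(model, image) {
  fwd <- unetForward(model, image)
  array(fwd$p, dim = c(fwd$dims, model@arch$classes))
}

#' Predicted label map (argmax class per voxel)
#'
#' Background is class 0; ties are broken towards the lowest class index.
#'
#' @inheritParams predictProbabilities
#' @return a [LabelMap-class] with the spacing of `image` (or 1 mm if a
#'   plain matrix was supplied).
#' @export
predictLabelMap <- function(model, image) {
  fwd <- unetForward(model, image)
  cls <- max.col(fwd$p, ties.method = "first") - 1L
  spacing <- if (is(image, "ScanImage")) image@spacing else rep(1, length(fwd$dims))
  LabelMap(array(cls, dim = fwd$dims), spacing)
}

# ---------------------------------------------------------------------------
# Training (sum of Dice and cross-entropy, Adam, deterministic given seed)

# One-hot truth matrix (nVox x C) from a label map whose labels are
# 0..C-1 (0 = background -> class index 1).
oneHotLabels <- function(truth, nClasses) {
  lab <- as.vector(truth@values) + 1L
  Y <- matrix(0, length(lab), nClasses)
  Y[cbind(seq_along(lab), lab)] <- 1
  Y
}

# Loss value and gradient at the logits for one image.
segLossGrad <- function(p, Y) {
  n <- nrow(p)
  C <- ncol(p)
  eps <- 1e-12
  ce <- -mean(log(rowSums(p * Y) + eps))
  dZce <- (p - Y) / n
  # soft Dice over foreground classes
  smooth <- 1e-5
  diceSum <- 0
  dLdp <- matrix(0, n, C)
  nFg <- C - 1L
  for (cl in 2:C) {
    pc <- p[, cl]
    gc <- Y[, cl]
    inter <- sum(pc * gc)
    den <- sum(pc) + sum(gc) + smooth
    dice <- (2 * inter + smooth) / den
    diceSum <- diceSum + dice
    # d(1 - dice)/dp_c, averaged over foreground classes
    dLdp[, cl] <- dLdp[, cl] - (2 * gc * den - (2 * inter + smooth)) / den^2 / nFg
  }
  diceLoss <- 1 - diceSum / nFg
  # route dL/dp through the softmax Jacobian
  dZdice <- p * (dLdp - rowSums(dLdp * p))
  list(loss = ce + diceLoss, dZ = dZce + dZdice)
}

#' Train the toy segmentation network
#'
#' Minimizes the sum of soft Dice loss (over foreground classes) and
#' cross-entropy with the Adam optimizer, one image per step. Fully
#' deterministic given the seed: the epoch-wise shuffling and the
#' initialization are the only stochastic elements and both are seeded.
#'
#' @param model a freshly built (or partially trained) [ToyUNet-class].
#' @param phantoms a list with elements `images` (list of [ScanImage-class])
#'   and `truth` (list of [LabelMap-class]), e.g. from [generatePhantoms()].
#' @param epochs number of passes over the data.
#' @param lr Adam learning rate.
#' @param seed integer seed for the shuffling.
#' @return the trained model, with the per-epoch mean loss in
#'   `attr(, "lossHistory")`.
#' @export
trainToyModel <- function(model, phantoms, epochs = 10L, lr = 1e-3, seed = 1L) {
  stopifnot(is(model, "ToyUNet"))
  nImg <- length(phantoms$images)
  if (nImg == 0L) stop("no training images supplied", call. = FALSE)
  C <- model@arch$classes
  P <- model@params
  mState <- lapply(P, function(w) w * 0)
  vState <- lapply(P, function(w) w * 0)
  b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8
  step <- 0L
  history <- numeric(epochs)
  Ys <- lapply(phantoms$truth, oneHotLabels, nClasses = C)
  for (ep in seq_len(epochs)) {
    ord <- withSeed(deriveSeed(seed, ep), sample.int(nImg))
    epLoss <- 0
    for (i in ord) {
      mdl <- new("ToyUNet", params = P, arch = model@arch, seed = model@seed)
      fwd <- unetForward(mdl, phantoms$images[[i]])
      lg <- segLossGrad(fwd$p, Ys[[i]])
      if (!is.finite(lg$loss)) stop("training diverged (non-finite loss)", call. = FALSE)
      epLoss <- epLoss + lg$loss
      grads <- unetBackward(mdl, fwd, lg$dZ)
      step <- step + 1L
      corr1 <- 1 - b1^step
      corr2 <- 1 - b2^step
      for (nm in names(P)) {
        g <- grads[[nm]]
        mState[[nm]] <- b1 * mState[[nm]] + (1 - b1) * g
        vState[[nm]] <- b2 * vState[[nm]] + (1 - b2) * g^2
        P[[nm]] <- P[[nm]] - lr * (mState[[nm]] / corr1) /
          (sqrt(vState[[nm]] / corr2) + epsA)
      }
    }
    history[ep] <- epLoss / nImg
  }
  out <- new("ToyUNet", params = P, arch = model@arch, seed = model@seed)
  attr(out, "lossHistory") <- history
  out
}

#' Dice coefficient between the foreground of two label maps
#'
#' @param a,b `LabelMap`s on the same grid; all nonzero labels count as
#'   foreground.
#' @return scalar in `[0, 1]` (1 if both are empty).
#' @export
diceCoefficient <- function(a, b) {
  stopifnot(is(a, "LabelMap"), is(b, "LabelMap"))
  av <- as.vector(a@values) != 0L
  bv <- as.vector(b@values) != 0L
  if (!any(av) && !any(bv)) return(1)
  2 * sum(av & bv) / (sum(av) + sum(bv))
}

# Serialize model weights to a plain-text JSON checkpoint with a sidecar
# group registry, so no binary artifacts are needed.

#' Write a toy model checkpoint (JSON)
#' @param model a [ToyUNet-class].
#' @param path output `.json` path.
#' @export
writeToyModel <- function(model, path) {
  out <- list(
    arch = model@arch, seed = model@seed,
    parameter_groups = listParameterGroups(model),
    params = lapply(model@params, function(w) {
      list(dim = if (is.matrix(w)) dim(w) else length(w), values = as.vector(w))
    })
  )
  # 17 significant digits round-trips IEEE doubles exactly
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a toy model checkpoint written by [writeToyModel()]
#' @param path input `.json` path.
#' @return a [ToyUNet-class].
#' @export
readToyModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(j$params, function(p) {
    d <- as.integer(unlist(p$dim))
    v <- as.numeric(unlist(p$values))
    if (length(d) == 2L) matrix(v, d[1L], d[2L]) else v
  })
  new("ToyUNet", params = params,
      arch = list(levels = as.integer(j$arch$levels),
                  channels = as.integer(j$arch$channels),
                  classes = as.integer(j$arch$classes)),
      seed = as.integer(j$seed))
}
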