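#' Train the learned foreground backend
#'
#' A lightweight trainable alternative to the classical Otsu backend: a
#' logistic pixel classifier over local intensity features (raw intensity and
#' two Gaussian-smoothed scales), trained by stochastic gradient descent with
#' the same two-round curriculum used for interactive deep-learning
#' segmentation tools — a short first round on a few z-averaged slices,
#' then a long refinement round (defaults 200 and 1500 iterations). The
#' cross-entropy loss is logged at every iteration.
#'
#' This is not a neural network; it fulfils the same contract as
#' [binarize()]'s classical path and exists so the training protocol (rounds,
#' z-stack averaging, loss monitoring) is exercisable end-to-end on synthetic
#' data. The classical backend remains the default everywhere.
#'
#' @param phantoms list of `tissue_phantom` objects providing images and
#'   ground-truth labels.
#' @param rounds integer vector of iterations per round, default `c(200, 1500)`.
#' @param zstack_window window for [zstack_average()] data preparation.
#' @param n_pixels training pixels subsampled per round.
#' @param learning_rate SGD step size.
#' @param seed RNG seed for subsampling and initialization.
#' @return An `adipo_learned_backend` with `weights`, `loss` (per-iteration
#'   tibble) and feature scaling.
#' @export
train_learned_backend <- function(phantoms, rounds = c(200, 1500),
                                  zstack_window = 5, n_pixels = 20000,
                                  learning_rate = 0.5, seed = 1L) {
  if (inherits(phantoms, "tissue_phantom")) phantoms <- list(phantoms)
  rounds <- as.integer(rounds)
  if (length(rounds) == 0 || sum(rounds) <= 0) {
    abort("Training schedule is empty: at least one round with > 0 iterations is required.")
  }
  feat_list <- lab_list <- list()
  for (ph in phantoms) {
    arr <- ph$image$channels$lipid
    w <- min(zstack_window, dim(arr)[3])
    avg <- zstack_average(arr, w)
    gt <- ph$labels$labels[, , seq_len(dim(avg)[3]), drop = FALSE] > 0
    # representative planes: first, middle, last
    zsel <- unique(c(1L, ceiling(dim(avg)[3] / 2), dim(avg)[3]))
    for (z in zsel) {
      feat_list[[length(feat_list) + 1L]] <- pixel_features(avg[, , z])
      lab_list[[length(lab_list) + 1L]] <- as.numeric(gt[, , z])
    }
  }
  X <- do.call(rbind, feat_list)
  y <- unlist(lab_list)
  mu <- colMeans(X)
  sdv <- pmax(apply(X, 2, sd), 1e-8)
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  w <- rep(0, ncol(Xs) + 1)
  losses <- list()
  it_global <- 0L
  with_seed(seed, {
    for (r in seq_along(rounds)) {
      if (rounds[r] == 0) next
      idx <- sample(nrow(Xs), min(n_pixels, nrow(Xs)))
      Xr <- cbind(1, Xs[idx, , drop = FALSE])
      yr <- y[idx]
      for (it in seq_len(rounds[r])) {
        eta <- drop(Xr %*% w)
        p <- 1 / (1 + exp(-eta))
        loss <- -mean(yr * log(pmax(p, 1e-12)) + (1 - yr) * log(pmax(1 - p, 1e-12)))
        grad <- drop(crossprod(Xr, p - yr)) / length(yr)
        w <- w - learning_rate * grad
        it_global <- it_global + 1L
        losses[[it_global]] <- tibble(round = r, iteration = it_global, loss = loss)
      }
    }
  })
  structure(
    list(weights = w, center = mu, scale = sdv,
         loss = dplyr::bind_rows(losses), rounds = rounds),
    class = "adipo_learned_backend"
  )
}

# per-pixel features of one 2D slice: raw intensity + two smoothed scales
pixel_features <- function(slice) {
  d <- dim(slice)
  a3 <- array(slice, c(d[1], d[2], 1))
  s1 <- .gauss_blur3d(as.numeric(a3), as.integer(c(d[1], d[2], 1)), c(1, 1, 0))
  s2 <- .gauss_blur3d(as.numeric(a3), as.integer(c(d[1], d[2], 1)), c(3, 3, 0))
  cbind(as.numeric(slice), s1, s2)
}

# apply the classifier slice-wise to a 3D array -> logical mask
predict_learned <- function(model, arr) {
  stopifnot(inherits(model, "adipo_learned_backend"))
  dims <- dim(arr)
  out <- array(FALSE, dims)
  for (z in seq_len(dims[3])) {
    X <- pixel_features(arr[, , z])
    Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
    eta <- drop(cbind(1, Xs) %*% model$weights)
    out[, , z] <- matrix(eta > 0, dims[1], dims[2])
  }
  out
}

#' @export
print.adipo_learned_backend <- function(x, ...) {
  cat(sprintf("<adipo_learned_backend> %d rounds (%s iterations), final loss %.5f\n",
              length(x$rounds), paste(x$rounds, collapse = " + "),
              tail(x$loss$loss, 1)))
  invisible(x)
}
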