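sigmoid <- function(z) 1 / (1 + exp(-z))

#' Initialize a four-layer multilayer perceptron
#'
#' The classifier architecture is fixed at four layers: an input layer
#' (the 2 scalar features), two hidden layers, and a single sigmoid output
#' unit giving the probability of the soy class. Weights use scaled
#' (Glorot) uniform initialization, reproducible by seed.
#'
#' @param layer_sizes Integer vector of length 4, `c(2, h1, h2, 1)`.
#' @param seed Integer seed for the weight draw.
#' @return An object of class `"mlp_model"` with `weights` and `biases`
#'   lists (one entry per connection), `layer_sizes`, `seed`.
#' @export
mlp_init <- function(layer_sizes = c(2, 8, 4, 1), seed = 1L) {
  if (length(layer_sizes) != 4) {
    stop("the network has exactly 4 layers: input, two hidden, output")
  }
  if (layer_sizes[1] != 2 || layer_sizes[4] != 1) {
    stop("layer_sizes must be c(2, h1, h2, 1): 2 features in, 1 unit out")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  weights <- list()
  biases <- list()
  for (l in 1:3) {
    n_in <- layer_sizes[l]
    n_out <- layer_sizes[l + 1]
    r <- sqrt(6 / (n_in + n_out))
    weights[[l]] <- matrix(stats::runif(n_out * n_in, -r, r), n_out, n_in)
    biases[[l]] <- rep(0, n_out)
  }
  structure(
    list(
      layer_sizes = layer_sizes, weights = weights, biases = biases,
      activation = "sigmoid", seed = as.integer(seed), loss_trace = numeric(0)
    ),
    class = "mlp_model"
  )
}

# Forward pass keeping intermediate activations for backprop.
mlp_forward_full <- function(model, X) {
  a <- t(X) # features x samples
  zs <- list()
  as <- list(a)
  for (l in 1:3) {
    z <- model$weights[[l]] %*% a + model$biases[[l]]
    a <- sigmoid(z)
    zs[[l]] <- z
    as[[l + 1]] <- a
  }
  list(zs = zs, as = as, out = as.numeric(a))
}

#' Forward pass of the MLP
#'
#' @param model An `"mlp_model"`.
#' @param features Numeric matrix (samples x 2) or a features tibble with
#'   `kurtosis` and `shw` columns.
#' @return Numeric vector of soy-class probabilities, strictly in (0, 1).
#' @export
mlp_forward <- function(model, features) {
  X <- feature_matrix(features)
  if (ncol(X) != model$layer_sizes[1]) {
    stop("feature dimension ", ncol(X), " does not match the network input (",
      model$layer_sizes[1], ")")
  }
  mlp_forward_full(model, X)$out
}

feature_matrix <- function(features) {
  if (is.matrix(features)) return(features)
  stopifnot(all(c("kurtosis", "shw") %in% names(features)))
  cbind(kurtosis = features$kurtosis, shw = features$shw)
}

# Full-batch gradient of the mean squared error loss wrt all parameters.
mlp_gradient <- function(model, X, y) {
  fwd <- mlp_forward_full(model, X)
  n <- length(y)
  dW <- vector("list", 3)
  db <- vector("list", 3)
  # dL/da for L = mean((out - y)^2)
  delta <- matrix(2 * (fwd$out - y) / n, nrow = 1)
  for (l in 3:1) {
    a <- sigmoid(fwd$zs[[l]])
    delta <- delta * a * (1 - a) # through the sigmoid
    dW[[l]] <- delta %*% t(fwd$as[[l]])
    db[[l]] <- rowSums(delta)
    if (l > 1) delta <- t(model$weights[[l]]) %*% delta
  }
  list(dW = dW, db = db, loss = mean((fwd$out - y)^2))
}

#' Train the MLP by full-batch back-propagation
#'
#' Plain gradient descent on the mean squared error between the sigmoid
#' output and 0/1 class targets (beef = 0, soy = 1). Deterministic given
#' the initialized model and data.
#'
#' @param model An `"mlp_model"` from [mlp_init()].
#' @param features Samples x 2 matrix or features tibble.
#' @param y Numeric 0/1 class targets.
#' @param learning_rate Gradient descent step size.
#' @param epochs Number of full-batch updates (0 returns the model
#'   unchanged).
#' @return The trained `"mlp_model"`, with the per-epoch loss in
#'   `$loss_trace`.
#' @export
mlp_train <- function(model, features, y, learning_rate = 0.1, epochs = 2000) {
  stopifnot(inherits(model, "mlp_model"), learning_rate > 0, epochs >= 0)
  X <- feature_matrix(features)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  trace <- numeric(epochs)
  for (e in seq_len(epochs)) {
    g <- mlp_gradient(model, X, y)
    if (!is.finite(g$loss)) stop("training diverged at epoch ", e, " (non-finite loss)")
    for (l in 1:3) {
      model$weights[[l]] <- model$weights[[l]] - learning_rate * g$dW[[l]]
      model$biases[[l]] <- model$biases[[l]] - learning_rate * g$db[[l]]
    }
    trace[e] <- g$loss
  }
  model$loss_trace <- trace
  model
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(
    "MLP", paste(x$layer_sizes, collapse = "-"), "(sigmoid), seed", x$seed,
    if (length(x$loss_trace)) sprintf(", final loss %.3g", utils::tail(x$loss_trace, 1)) else " (untrained)",
    "\n", sep = ""
  )
  invisible(x)
}

#' Mean absolute percentage error on class codes
#'
#' Classes are coded beef = 1, soy = 2 (nonzero, so the relative error is
#' defined) and MAPE is `100/n * sum(|pred - true| / |true|)`. Under
#' hardened codes MAPE = 0 is equivalent to 100% accuracy.
#'
#' @param predicted,truth Integer class codes in `{1, 2}`.
#' @return Percentage error.
#' @export
mape <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  if (any(truth == 0)) stop("true class codes must be nonzero (use codes 1/2)")
  100 * mean(abs(predicted - truth) / abs(truth))
}

standardize_cols <- function(train, test) {
  mu <- colMeans(train)
  s <- apply(train, 2, stats::sd)
  s[s == 0] <- 1
  list(
    train = sweep(sweep(train, 2, mu), 2, s, `/`),
    test = sweep(sweep(test, 2, mu), 2, s, `/`)
  )
}

#' Random-subset cross-validation of the MLP classifier
#'
#' Repeatedly draws stratified random train/test splits (test size
#' `floor(n_class * test_fraction)` per class), standardizes the features
#' on each split's training rows, trains a freshly initialized four-layer
#' MLP, and scores the held-out rows by accuracy and MAPE on class codes
#' beef = 1 / soy = 2.
#'
#' @param features Features tibble from [featurize()] (needs `label`,
#'   `kurtosis`, `shw`); pass unstandardized or standardized features —
#'   each split re-standardizes from its own training rows.
#' @param n_subsets Number of random splits.
#' @param test_fraction Held-out fraction per class, in (0, 1).
#' @param hidden Sizes of the two hidden layers.
#' @param learning_rate,epochs Training hyperparameters.
#' @param ensemble Number of independently seeded networks combined by
#'   majority vote (1 = single network).
#' @param seed Root seed; split `s` uses a seed derived from it.
#' @return A tibble of class `"ann_cv"`: one row per subset with
#'   `subset`, `n_train`, `n_test`, `accuracy`, `mape`.
#' @examples
#' ds <- simulate_spectra(seed = 7)
#' pure <- dplyr::filter(ds, label %in% c("beef", "soy"))
#' feats <- featurize(preprocess_spectra(pure), standardize = FALSE)
#' cv <- cross_validate_ann(feats, n_subsets = 3, epochs = 500, seed = 7)
#' glance(cv)
#' @export
cross_validate_ann <- function(features, n_subsets = 10, test_fraction = 0.3,
                               hidden = c(8, 4), learning_rate = 0.1,
                               epochs = 2000, ensemble = 1, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  lab <- features$label
  stopifnot(all(lab %in% c("beef", "soy")))
  if (sum(lab == "beef") < 2 || sum(lab == "soy") < 2) {
    stop("need at least 2 samples per class")
  }
  X <- feature_matrix(features)
  y <- as.numeric(lab == "soy")

  res <- purrr::map_dfr(seq_len(n_subsets), function(s) {
    test_idx <- stratified_test_idx(lab, test_fraction, derive_seed(seed, s))
    sp <- standardize_cols(X[-test_idx, , drop = FALSE], X[test_idx, , drop = FALSE])
    votes <- purrr::map(seq_len(ensemble), function(e) {
      net <- mlp_init(c(2, hidden, 1), seed = derive_seed(seed, 1000L * s + e))
      net <- mlp_train(net, sp$train, y[-test_idx],
        learning_rate = learning_rate, epochs = epochs
      )
      as.integer(mlp_forward(net, sp$test) > 0.5)
    })
    pred <- as.integer(Reduce(`+`, votes) / ensemble > 0.5)
    truth_codes <- y[test_idx] + 1
    pred_codes <- pred + 1
    tibble::tibble(
      subset = s,
      n_train = nrow(sp$train), n_test = nrow(sp$test),
      accuracy = mean(pred_codes == truth_codes),
      mape = mape(pred_codes, truth_codes)
    )
  })
  class(res) <- c("ann_cv", class(res))
  attr(res, "seed") <- seed
  res
}

# Stratified held-out indices: floor(n_class * fraction) per class. Redraws
# (with a derived seed) in the degenerate case of an empty class portion.
stratified_test_idx <- function(labels, fraction, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  for (attempt in 0:10) {
    set.seed(derive_seed(seed, attempt))
    idx <- unlist(lapply(unique(labels), function(cl) {
      pool <- which(labels == cl)
      sample(pool, max(1, floor(length(pool) * fraction)))
    }))
    train <- setdiff(seq_along(labels), idx)
    if (length(unique(labels[idx])) == length(unique(labels)) &&
      length(unique(labels[train])) == length(unique(labels))) {
      return(sort(idx))
    }
    message("degenerate split; redrawing with a derived seed")
  }
  stop("could not draw a split containing every class")
}

#' Summarize a cross-validation result
#'
#' @param x An `"ann_cv"` tibble from [cross_validate_ann()].
#' @param ... Unused.
#' @return One-row tibble with `n_subsets`, `mean_accuracy`, `mean_mape`,
#'   `min_accuracy`, `max_mape`.
#' @export
glance.ann_cv <- function(x, ...) {
  tibble::tibble(
    n_subsets = nrow(x),
    mean_accuracy = mean(x$accuracy),
    mean_mape = mean(x$mape),
    min_accuracy = min(x$accuracy),
    max_mape = max(x$mape)
  )
}
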