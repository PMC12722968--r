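#' Gaussian fuzzy membership
#'
#' Degree of membership of a crisp value in a Gaussian fuzzy set:
#' \eqn{\mu = \exp(-(x - center)^2 / (2\, width^2))}, in \eqn{(0, 1]} with
#' its peak of 1 at the center.
#'
#' @param x Numeric value(s).
#' @param center Fuzzy-set center.
#' @param width Fuzzy-set width, strictly positive.
#' @return Membership degree(s) in `(0, 1]`.
#' @examples
#' fuzzy_membership(0.5, 0.5, 0.1)       # 1 at the center
#' fuzzy_membership(0.6, 0.5, 0.1)       # exp(-1/2) one width away
#' @export
fuzzy_membership <- function(x, center, width) {
  if (any(width <= 0)) abort("Fuzzy-set `width` must be > 0.")
  exp(-(x - center)^2 / (2 * width^2))
}

#' Fit a four-layer fuzzy neural network classifier
#'
#' Trains the fuzzy neural classifier on a preprocessed feature table.
#' The network has four layers:
#' \enumerate{
#'   \item input: the selected feature values;
#'   \item fuzzification: each rule holds one Gaussian fuzzy set per input
#'     feature ([fuzzy_membership()]);
#'   \item rules: firing strength is the t-norm (product by default) of the
#'     antecedent memberships; each rule's consequent is a linear function
#'     of the inputs (coefficients `p`, bias `q`) and the rule outputs are
#'     aggregated by normalized firing strength
#'     \eqn{\sum_r \bar w_r f_r(x)} with \eqn{\bar w_r = w_r / \sum w};
#'   \item class head: a linear map from the weighted rule outputs to two
#'     class logits, passed through softmax.
#' }
#' Training minimizes the cross-entropy of the softmax output over all
#' trainable parameters (centers, widths, consequents, class weights) by
#' full-batch momentum gradient descent (see [update_weights()]); training
#' is deterministic under `seed` and early-stops when the validation loss
#' stagnates.
#'
#' Rule antecedents are initialized per class and quantile: half the rules
#' take centers at within-class feature quantiles of class 0, half of
#' class 1, widths at half the inter-center spacing (floored at
#' `width_floor`), consequent coefficients at zero, and the class head
#' wires each rule to the class whose quantiles seeded it — so the
#' untrained network already leans toward the nearer class centroid.
#'
#' @param data Training feature table (features in `[0, 1]` after
#'   [preprocess()]) with a label column.
#' @param features Character vector of input features in order (the finest
#'   subset `f_b` from [ldefs()]); default: all feature columns.
#' @param n_rules Total number of rules (>= 2, split between the classes).
#'   Default 4.
#' @param epochs Maximum training epochs. Default 300.
#' @param learning_rate Learning rate \eqn{\tau}; the supported range is
#'   0.4–0.8 and values outside it warn. Default 0.6.
#' @param momentum Momentum coefficient \eqn{\alpha \ge 0}. Default 0.9.
#' @param patience Early-stop patience on the validation loss, in epochs.
#'   Default 30.
#' @param validation Optional validation feature table; when absent the
#'   training loss drives early stopping.
#' @param t_norm `"product"` (default, differentiable everywhere) or
#'   `"min"` for the antecedent conjunction.
#' @param width_floor Minimum fuzzy-set width. Default 0.05.
#' @param seed Integer seed for the (tiny) symmetry-breaking jitter of the
#'   initial centers.
#' @param label_col Label column name.
#' @return An object of class `"mfnn"`: a list with the fitted parameter
#'   matrices (`centers`, `widths`, `p`, `q`, `V`, `v0`), the feature
#'   order, the training `history` tibble (epoch, train and validation
#'   loss), and the configuration. Methods: [predict.mfnn()],
#'   [tidy.mfnn()], [glance.mfnn()], [autoplot.mfnn()].
#' @examples
#' toy <- preprocess(make_worked_toy())
#' fit <- mfnn(toy, n_rules = 2, epochs = 50, seed = 1)
#' predict(fit, toy, type = "class")
#' @export
mfnn <- function(data, features = NULL, n_rules = 4, epochs = 300,
                 learning_rate = 0.6, momentum = 0.9, patience = 30,
                 validation = NULL, t_norm = c("product", "min"),
                 width_floor = 0.05, seed = 1, label_col = "status") {
  t_norm <- match.arg(t_norm)
  check_feature_table(data, label_col)
  if (is.null(features)) features <- feature_cols(data, label_col)
  if (learning_rate <= 0 || learning_rate > 1) abort("`learning_rate` must be in (0, 1].")
  if (learning_rate < 0.4 || learning_rate > 0.8) {
    warn("`learning_rate` is outside the supported 0.4-0.8 range.")
  }
  if (momentum < 0) abort("`momentum` must be >= 0.")
  y <- data[[label_col]]
  if (length(unique(y)) < 2) abort("Training data must contain both classes.")
  X <- as.matrix(data[features])

  model <- mfnn_init(X, y, features, n_rules, width_floor, t_norm, seed)
  state <- new_train_state(learning_rate, momentum)
  val <- NULL
  if (!is.null(validation)) {
    val <- list(X = as.matrix(validation[features]), y = validation[[label_col]])
  }
  mfnn_train(model, X, y, val, epochs, patience, state)
}

# ---- initialization ---------------------------------------------------------

mfnn_init <- function(X, y, features, n_rules, width_floor, t_norm, seed) {
  if (n_rules < 2) abort("`n_rules` must be >= 2.")
  if (n_rules > nrow(unique(as.data.frame(X)))) {
    abort("`n_rules` exceeds the number of distinct training rows.")
  }
  d <- ncol(X)
  rule_class <- rep(c(0L, 1L), length.out = n_rules)
  k0 <- sum(rule_class == 0L); k1 <- sum(rule_class == 1L)
  centers <- matrix(0, n_rules, d, dimnames = list(NULL, features))
  i0 <- 0L; i1 <- 0L
  for (r in seq_len(n_rules)) {
    if (rule_class[r] == 0L) {
      i0 <- i0 + 1L
      probs <- (i0 - 0.5) / k0
      centers[r, ] <- apply(X[y == 0L, , drop = FALSE], 2, quantile,
                            probs = probs, type = 7, names = FALSE)
    } else {
      i1 <- i1 + 1L
      probs <- (i1 - 0.5) / k1
      centers[r, ] <- apply(X[y == 1L, , drop = FALSE], 2, quantile,
                            probs = probs, type = 7, names = FALSE)
    }
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  centers <- centers + matrix(rnorm(n_rules * d, sd = 0.005), n_rules, d)

  widths <- matrix(width_floor, n_rules, d, dimnames = list(NULL, features))
  for (j in seq_len(d)) {
    cs <- sort(centers[, j])
    spacing <- if (n_rules > 1) diff(range(cs)) / (n_rules - 1) else 0
    widths[, j] <- max(width_floor, spacing / 2)
  }

  V <- matrix(0, 2, n_rules)
  for (r in seq_len(n_rules)) V[rule_class[r] + 1L, r] <- 1
  structure(list(
    features = features,
    centers = centers, widths = widths,
    p = matrix(0, n_rules, d, dimnames = list(NULL, features)),
    q = rep(0, n_rules),
    V = V, v0 = c(0, 0),
    rule_class = rule_class, t_norm = t_norm,
    width_floor = width_floor, seed = seed,
    history = tibble(epoch = integer(), train_loss = double(),
                     val_loss = double())
  ), class = "mfnn")
}

# ---- forward pass -----------------------------------------------------------

#' Evaluate the fuzzy network on a matrix of inputs
#'
#' Low-level forward pass returning class probabilities along with the
#' intermediate layer activations (memberships are folded into the firing
#' strengths). Mostly useful for inspection and testing; use
#' [predict.mfnn()] for ordinary prediction.
#'
#' @param model An `"mfnn"` object.
#' @param X Numeric matrix (rows x features, in `model$features` order) or
#'   a feature table containing those columns.
#' @return A list: `prob` (n x 2 matrix, columns = classes 0 and 1),
#'   `logits`, `firing` (raw firing strengths, n x rules), `firing_norm`
#'   (normalized; uniform when all strengths underflow), `rule_out`
#'   (consequent values, n x rules).
#' @export
mfnn_forward <- function(model, X) {
  if (is.data.frame(X)) X <- as.matrix(X[model$features])
  if (ncol(X) != length(model$features)) {
    abort("Input arity does not match the model's antecedents.")
  }
  n <- nrow(X); R <- nrow(model$centers)
  w <- matrix(1, n, R)
  for (r in seq_len(R)) {
    mu <- fuzzy_membership(X, matrix(model$centers[r, ], n, ncol(X), byrow = TRUE),
                           matrix(model$widths[r, ], n, ncol(X), byrow = TRUE))
    w[, r] <- if (model$t_norm == "product") {
      apply(mu, 1, prod)
    } else {
      apply(mu, 1, min)
    }
  }
  s <- rowSums(w)
  degenerate <- s < 1e-300
  wbar <- w / ifelse(degenerate, 1, s)
  if (any(degenerate)) wbar[degenerate, ] <- 1 / R
  f <- X %*% t(model$p) + matrix(model$q, n, R, byrow = TRUE)
  u <- wbar * f
  logits <- u %*% t(model$V) + matrix(model$v0, n, 2, byrow = TRUE)
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  prob <- e / rowSums(e)
  colnames(prob) <- c("0", "1")
  list(prob = prob, logits = logits, firing = w, firing_norm = wbar,
       rule_out = f, degenerate = degenerate)
}

#' Cross-entropy loss of the network on labelled data
#'
#' @param model An `"mfnn"` object.
#' @param X Input matrix or feature table.
#' @param y Binary label vector.
#' @return Mean cross-entropy (natural log) over the rows.
#' @export
mfnn_loss <- function(model, X, y) {
  fw <- mfnn_forward(model, X)
  p_true <- fw$prob[cbind(seq_along(y), y + 1L)]
  -mean(log(pmax(p_true, 1e-300)))
}

# ---- gradients --------------------------------------------------------------

#' Analytic gradients of the cross-entropy loss
#'
#' Batch-mean gradients with respect to every trainable parameter group.
#' Exposed so the analytic derivatives can be checked against finite
#' differences.
#'
#' @inheritParams mfnn_loss
#' @return A list of arrays shaped like the model's `centers`, `widths`,
#'   `p`, `q`, `V`, `v0`.
#' @export
mfnn_gradients <- function(model, X, y) {
  if (is.data.frame(X)) X <- as.matrix(X[model$features])
  n <- nrow(X); R <- nrow(model$centers); d <- ncol(X)
  fw <- mfnn_forward(model, X)
  Y <- cbind(1 - y, y)
  dz <- fw$prob - Y                                   # n x 2
  u <- fw$firing_norm * fw$rule_out
  grad_V <- t(dz) %*% u / n                           # 2 x R
  grad_v0 <- colMeans(dz)
  g <- dz %*% model$V                                 # n x R, dL/du
  gw <- g * fw$firing_norm                            # dL/df
  grad_p <- t(gw) %*% X / n                           # R x d
  grad_q <- colMeans(gw)
  # back through the firing-strength normalization
  gf <- g * fw$rule_out                               # dL/dwbar
  s <- rowSums(fw$firing)
  inner <- rowSums(gf * fw$firing_norm)
  dLdw <- (gf - inner) / s                            # n x R
  dLdw[fw$degenerate, ] <- 0
  grad_c <- matrix(0, R, d); grad_s <- matrix(0, R, d)
  for (r in seq_len(R)) {
    diffs <- X - matrix(model$centers[r, ], n, d, byrow = TRUE)
    s2 <- matrix(model$widths[r, ]^2, n, d, byrow = TRUE)
    if (model$t_norm == "product") {
      dwdc <- fw$firing[, r] * diffs / s2
      dwds <- fw$firing[, r] * diffs^2 / (s2 * matrix(model$widths[r, ], n, d, byrow = TRUE))
    } else {
      mu <- fuzzy_membership(X, matrix(model$centers[r, ], n, d, byrow = TRUE),
                             sqrt(s2))
      amin <- max.col(-mu, ties.method = "first")
      ind <- matrix(0, n, d); ind[cbind(seq_len(n), amin)] <- 1
      dwdc <- ind * fw$firing[, r] * diffs / s2
      dwds <- ind * fw$firing[, r] * diffs^2 / (s2 * matrix(model$widths[r, ], n, d, byrow = TRUE))
    }
    grad_c[r, ] <- colMeans(dLdw[, r] * dwdc)
    grad_s[r, ] <- colMeans(dLdw[, r] * dwds)
  }
  dimnames(grad_c) <- dimnames(model$centers)
  dimnames(grad_s) <- dimnames(model$widths)
  dimnames(grad_p) <- dimnames(model$p)
  list(centers = grad_c, widths = grad_s, p = grad_p, q = grad_q,
       V = grad_V, v0 = grad_v0)
}

# ---- momentum update --------------------------------------------------------

#' Create a momentum training state
#'
#' @param learning_rate Learning rate \eqn{\tau} in (0, 1]; 0.4–0.8 is the
#'   supported range.
#' @param momentum Momentum coefficient \eqn{\alpha \ge 0}.
#' @return A list with `tau`, `alpha`, the per-parameter update buffers
#'   `delta`, and an epoch counter.
#' @export
new_train_state <- function(learning_rate = 0.6, momentum = 0.9) {
  if (learning_rate <= 0 || learning_rate > 1) abort("`learning_rate` must be in (0, 1].")
  if (momentum < 0) abort("`momentum` must be >= 0.")
  list(tau = learning_rate, alpha = momentum, delta = list(), epoch = 0L)
}

#' One momentum gradient-descent step on a weight
#'
#' The update keeps a running buffer: the new step is
#' \eqn{\Delta_{new} = -\tau \cdot grad + \alpha \cdot \Delta_{prev}} and
#' the weight moves to \eqn{\omega = w + \Delta_{new}}; the buffer is
#' stored for the next step under `name`.
#'
#' @param state A state from [new_train_state()].
#' @param weight Current weight (any numeric array).
#' @param gradient Gradient of the loss with the same shape.
#' @param name Buffer key identifying this parameter group.
#' @return A list with the updated `weight` and `state`.
#' @export
update_weights <- function(state, weight, gradient, name = "w") {
  if (any(!is.finite(gradient))) {
    abort(sprintf("Non-finite gradient for '%s' at epoch %d; try a smaller learning rate.",
                  name, state$epoch))
  }
  prev <- state$delta[[name]]
  if (is.null(prev)) prev <- gradient * 0
  delta <- -state$tau * gradient + state$alpha * prev
  state$delta[[name]] <- delta
  list(weight = weight + delta, state = state)
}

# ---- training loop ----------------------------------------------------------

mfnn_train <- function(model, X, y, val, epochs, patience, state) {
  best <- model
  monitor <- function(m) {
    if (is.null(val)) mfnn_loss(m, X, y) else mfnn_loss(m, val$X, val$y)
  }
  best_loss <- monitor(model)
  stale <- 0L
  hist <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    state$epoch <- ep
    gr <- mfnn_gradients(model, X, y)
    for (nm in c("centers", "widths", "p", "q", "V", "v0")) {
      st <- update_weights(state, model[[nm]], gr[[nm]], nm)
      model[[nm]] <- st$weight
      state <- st$state
    }
    model$widths <- pmax(model$widths, model$width_floor)
    tr_loss <- mfnn_loss(model, X, y)
    if (!is.finite(tr_loss)) {
      abort(sprintf("Training diverged at epoch %d; try a smaller learning rate.", ep))
    }
    va_loss <- if (is.null(val)) NA_real_ else mfnn_loss(model, val$X, val$y)
    hist[[ep]] <- tibble(epoch = ep, train_loss = tr_loss, val_loss = va_loss)
    mon <- if (is.null(val)) tr_loss else va_loss
    if (mon < best_loss - 1e-8) {
      best_loss <- mon
      best <- model
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= patience) break
    }
  }
  best$history <- bind_rows(hist[!vapply(hist, is.null, logical(1))])
  best$epochs_run <- nrow(best$history)
  best$state <- state[c("tau", "alpha")]
  best
}

# ---- prediction and risk ----------------------------------------------------

#' Predict from a fitted fuzzy network
#'
#' @param object An `"mfnn"` object.
#' @param newdata Feature table containing the model's input features.
#' @param type `"prob"` for a tibble of class probabilities, `"class"` for
#'   hard 0/1 labels (threshold 0.5), `"risk"` for the low/medium/high
#'   risk stratification of [assign_risk()].
#' @param thresholds Risk thresholds passed to [assign_risk()] when
#'   `type = "risk"`.
#' @param ... Unused.
#' @return A tibble (`prob`, `risk`) or an integer vector (`class`).
#' @export
predict.mfnn <- function(object, newdata, type = c("prob", "class", "risk"),
                         thresholds = c(0.33, 0.66), ...) {
  type <- match.arg(type)
  fw <- mfnn_forward(object, newdata)
  p1 <- fw$prob[, "1"]
  switch(type,
    prob = tibble(p_healthy = fw$prob[, "0"], p_pd = p1),
    class = as.integer(p1 >= 0.5),
    risk = assign_risk(p1, thresholds)
  )
}

#' Stratify predicted PD probability into risk classes
#'
#' Piecewise-constant mapping of the predicted probability of the PD class
#' to `low` (p < t1), `medium` (t1 <= p < t2) or `high` (p >= t2), plus
#' the hard label (1 iff p >= 0.5).
#'
#' @param prob Numeric vector of PD-class probabilities in `[0, 1]`.
#' @param thresholds Two strictly increasing cutpoints in (0, 1).
#'   Default `c(0.33, 0.66)`.
#' @return A tibble with `p_pd`, `risk_class` (ordered factor
#'   low < medium < high) and `label`.
#' @examples
#' assign_risk(c(0, 0.5, 1))
#' @export
assign_risk <- function(prob, thresholds = c(0.33, 0.66)) {
  if (length(thresholds) != 2 || thresholds[1] >= thresholds[2] ||
      thresholds[1] <= 0 || thresholds[2] >= 1) {
    abort("`thresholds` must be two strictly increasing values in (0, 1).")
  }
  if (any(prob < 0 | prob > 1)) abort("`prob` must be in [0, 1].")
  cls <- ifelse(prob < thresholds[1], "low",
                ifelse(prob < thresholds[2], "medium", "high"))
  tibble(p_pd = prob,
         risk_class = factor(cls, levels = c("low", "medium", "high"),
                             ordered = TRUE),
         label = as.integer(prob >= 0.5))
}

#' @export
print.mfnn <- function(x, ...) {
  cat(sprintf("Fuzzy neural network classifier: %d rules over %d features (%s)\n",
              nrow(x$centers), length(x$features),
              paste(x$features, collapse = ", ")))
  cat(sprintf("Trained %d epochs; final training loss %.4f\n",
              x$epochs_run %||% 0L,
              if (nrow(x$history)) x$history$train_loss[nrow(x$history)] else NA))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
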