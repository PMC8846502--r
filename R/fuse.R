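## The image-augmented fusion model: a feed-forward network with one hidden
## layer of five rectified-linear nodes and a sigmoid output, over the
## four-element feature vector (image score, index score, hours since
## radiograph, hours since admission). Trained with binary cross-entropy by
## minibatch stochastic gradient descent; the returned model is the epoch
## checkpoint with the lowest validation loss.

FUSION_FEATURES <- c("image_score", "index_score",
                     "hours_since_xray", "hours_since_admit")

#' Training configuration for the fusion model
#'
#' @param learning_rate SGD step size (default 0.001).
#' @param max_epochs maximum number of passes over the training data.
#' @param batch_size minibatch size.
#' @param patience early-stopping patience: training stops after this many
#'   epochs without a new validation-loss minimum.
#' @param optimizer `"adam"` (adaptive-moment minibatch gradient descent,
#'   the default at this learning rate) or `"sgd"` (plain stochastic
#'   gradient descent).
#' @param seed integer seed controlling initialization and batch shuffling;
#'   identical seed, configuration and data give identical weights.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, max_epochs = 200,
                         batch_size = 64, patience = 20,
                         optimizer = c("adam", "sgd"), seed = 1L) {
  check_scalar(learning_rate, "learning_rate")
  if (learning_rate <= 0) stop("'learning_rate' must be > 0", call. = FALSE)
  check_scalar(max_epochs, "max_epochs", 1)
  check_scalar(batch_size, "batch_size", 1)
  check_scalar(patience, "patience", 1)
  check_scalar(seed, "seed")
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 optimizer = match.arg(optimizer),
                 seed = as.integer(seed)),
            class = "train_config")
}

instance_matrix <- function(instances) {
  missing <- setdiff(FUSION_FEATURES, names(instances))
  if (length(missing) > 0) {
    stop("instances are missing feature(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(instances[, FUSION_FEATURES, drop = FALSE])
  if (anyNA(x) || any(!is.finite(x))) {
    stop("non-finite feature values in instances", call. = FALSE)
  }
  x
}

# Forward pass on standardized features; returns probabilities.
fusion_forward <- function(z, par) {
  h <- pmax(sweep(z %*% par$W1, 2, par$b1, "+"), 0)
  unname(stats::plogis(drop(h %*% par$W2) + par$b2))
}

bce_loss <- function(p, y, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Train the image-augmented fusion model
#'
#' Minimizes instance-level binary cross-entropy by minibatch gradient
#' descent at the configured learning rate, standardizing all four features
#' with training-set means and standard deviations. After each epoch the
#' validation loss is computed; the returned model is the checkpoint from the
#' epoch with the lowest validation loss (early stopping after `patience`
#' epochs without improvement).
#'
#' @param train,valid instance data frames (see [build_instances()]) with a
#'   binary `label` column; both splits must contain both classes. Instances
#'   from one hospitalization should sit in only one split — see
#'   [split_by_hospitalization()].
#' @param cfg a [train_config()].
#' @param task task tag stored on the model (`"low_risk"` or `"high_risk"`).
#' @param hidden_dim number of hidden units (default 5).
#' @return An object of class `fusion_model`: weights, feature standardizer,
#'   per-epoch training/validation loss history, and the selected epoch.
#' @examples
#' \donttest{
#' coh <- apply_inclusion_filters(simulate_cohort(sim_config(300, seed = 2)))$kept
#' inst <- build_instances(coh, grid_spec("low_risk"))
#' sp <- split_by_hospitalization(inst, c(train = 0.7, valid = 0.3), seed = 2)
#' m <- train_fusion(sp$train, sp$valid, train_config(max_epochs = 20, seed = 2))
#' head(predict(m, sp$valid))
#' }
#' @export
train_fusion <- function(train, valid, cfg = train_config(),
                         task = c("low_risk", "high_risk"), hidden_dim = 5L) {
  task <- match.arg(task)
  if (nrow(train) == 0 || nrow(valid) == 0) {
    stop("both training and validation splits must be non-empty", call. = FALSE)
  }
  y_tr <- train$label
  y_va <- valid$label
  if (length(unique(y_tr)) < 2L) {
    stop("training split contains a single class", call. = FALSE)
  }
  if (length(unique(y_va)) < 2L) {
    stop("validation split contains a single class", call. = FALSE)
  }
  x_tr <- instance_matrix(train)
  x_va <- instance_matrix(valid)

  mu <- colMeans(x_tr)
  sd <- apply(x_tr, 2, stats::sd)
  sd[sd < 1e-8] <- 1 # constant feature: leave centered at 0
  z_tr <- sweep(sweep(x_tr, 2, mu), 2, sd, "/")
  z_va <- sweep(sweep(x_va, 2, mu), 2, sd, "/")

  d <- ncol(z_tr)
  set.seed(derive_seed(cfg$seed, 271828L))
  r1 <- 1 / sqrt(d)
  r2 <- 1 / sqrt(hidden_dim)
  par <- list(
    W1 = matrix(stats::runif(d * hidden_dim, -r1, r1), d, hidden_dim),
    b1 = rep(0, hidden_dim),
    W2 = matrix(stats::runif(hidden_dim, -r2, r2), hidden_dim, 1),
    b2 = 0
  )
  adam <- cfg$optimizer == "adam"
  if (adam) {
    mstate <- lapply(par, function(p) p * 0)
    vstate <- lapply(par, function(p) p * 0)
    beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8; tstep <- 0
  }

  n <- nrow(z_tr)
  nb <- ceiling(n / cfg$batch_size)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        valid_loss = numeric(0))
  best <- list(loss = Inf, par = par, epoch = 0L)
  since_best <- 0L

  for (epoch in seq_len(cfg$max_epochs)) {
    perm <- sample.int(n)
    for (b in seq_len(nb)) {
      ii <- perm[((b - 1L) * cfg$batch_size + 1L):min(b * cfg$batch_size, n)]
      zb <- z_tr[ii, , drop = FALSE]
      yb <- y_tr[ii]
      m <- length(ii)

      a1 <- sweep(zb %*% par$W1, 2, par$b1, "+")
      h <- pmax(a1, 0)
      p <- stats::plogis(drop(h %*% par$W2) + par$b2)
      # gradient of mean BCE wrt pre-sigmoid output is (p - y)/m
      delta2 <- (p - yb) / m
      gW2 <- crossprod(h, delta2)
      gb2 <- sum(delta2)
      delta1 <- outer(delta2, drop(par$W2)) * (a1 > 0)
      gW1 <- crossprod(zb, delta1)
      gb1 <- colSums(delta1)
      grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
      if (any(!vapply(grads, function(g) all(is.finite(g)), logical(1)))) {
        stop(sprintf("non-finite gradient at epoch %d (training diverged)",
                     epoch), call. = FALSE)
      }
      if (adam) {
        tstep <- tstep + 1
        for (nm in names(par)) {
          mstate[[nm]] <- beta1 * mstate[[nm]] + (1 - beta1) * grads[[nm]]
          vstate[[nm]] <- beta2 * vstate[[nm]] + (1 - beta2) * grads[[nm]]^2
          mhat <- mstate[[nm]] / (1 - beta1^tstep)
          vhat <- vstate[[nm]] / (1 - beta2^tstep)
          par[[nm]] <- par[[nm]] - cfg$learning_rate * mhat /
            (sqrt(vhat) + adam_eps)
        }
      } else {
        for (nm in names(par)) {
          par[[nm]] <- par[[nm]] - cfg$learning_rate * grads[[nm]]
        }
      }
    }
    tr_loss <- bce_loss(fusion_forward(z_tr, par), y_tr)
    va_loss <- bce_loss(fusion_forward(z_va, par), y_va)
    if (!is.finite(tr_loss) || !is.finite(va_loss)) {
      stop(sprintf("non-finite loss at epoch %d (train %.4g, valid %.4g)",
                   epoch, tr_loss, va_loss), call. = FALSE)
    }
    history <- rbind(history, data.frame(epoch = epoch, train_loss = tr_loss,
                                         valid_loss = va_loss))
    if (va_loss < best$loss) {
      best <- list(loss = va_loss, par = par, epoch = epoch)
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= cfg$patience) break
    }
  }

  structure(list(
    task = task, input_dim = d, hidden_dim = as.integer(hidden_dim),
    weights = best$par,
    standardizer = list(mean = mu, sd = sd),
    history = history, best_epoch = best$epoch,
    valid_loss = best$loss, config = cfg, version = "xradi-fusion-1"
  ), class = "fusion_model")
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf("Image-augmented fusion model (%s task)\n", x$task))
  cat(sprintf("  architecture: %d -> %d (ReLU) -> 1 (sigmoid)\n",
              x$input_dim, x$hidden_dim))
  cat(sprintf("  best epoch %d / %d run, validation BCE %.4f\n",
              x$best_epoch, nrow(x$history), x$valid_loss))
  invisible(x)
}

#' Predict deterioration risk for prediction instances
#'
#' @param object a trained [train_fusion()] model.
#' @param instances data frame of prediction instances carrying the four
#'   fusion features.
#' @param ... unused.
#' @return Numeric vector of probabilities in (0, 1), one per instance row,
#'   in input order.
#' @export
predict.fusion_model <- function(object, instances, ...) {
  x <- instance_matrix(instances)
  z <- sweep(sweep(x, 2, object$standardizer$mean), 2,
             object$standardizer$sd, "/")
  fusion_forward(z, object$weights)
}

#' Split prediction instances by hospitalization
#'
#' Hospitalizations (not instances) are assigned at random to the splits, so
#' that all windows of one admission land in a single split, mirroring
#' patient-level cohort splits.
#'
#' @param instances instance data frame with a `hosp_id` column.
#' @param fractions named numeric vector of split fractions summing to 1.
#' @param seed integer seed.
#' @return Named list of instance data frames, one per split.
#' @export
split_by_hospitalization <- function(instances,
                                     fractions = c(train = 0.7, valid = 0.3),
                                     seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) {
    stop("'fractions' must sum to 1", call. = FALSE)
  }
  ids <- sort(unique(instances$hosp_id))
  set.seed(derive_seed(seed, 57721L))
  ids <- sample(ids)
  n <- length(ids)
  sizes <- floor(fractions * n)
  sizes[1] <- n - sum(sizes[-1])
  assignment <- rep(names(fractions), sizes)
  out <- lapply(stats::setNames(names(fractions), names(fractions)),
                function(nm) {
    df <- instances[instances$hosp_id %in% ids[assignment == nm], , drop = FALSE]
    rownames(df) <- NULL
    df
  })
  out
}

#' Serialize a fusion model to a versioned JSON checkpoint
#'
#' @param model a `fusion_model`.
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_fusion_model <- function(model, path) {
  stopifnot(inherits(model, "fusion_model"))
  payload <- list(
    version = model$version, task = model$task,
    input_dim = model$input_dim, hidden_dim = model$hidden_dim,
    W1 = model$weights$W1, b1 = model$weights$b1,
    W2 = as.numeric(model$weights$W2), b2 = model$weights$b2,
    mean = as.list(model$standardizer$mean),
    sd = as.list(model$standardizer$sd),
    best_epoch = model$best_epoch, valid_loss = model$valid_loss
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a fusion model checkpoint written by [write_fusion_model()]
#'
#' @param path checkpoint path.
#' @return A `fusion_model` usable with [predict.fusion_model()].
#' @export
read_fusion_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$version) || !startsWith(p$version, "xradi-fusion")) {
    stop("not a fusion model checkpoint: ", path, call. = FALSE)
  }
  W1 <- matrix(p$W1, p$input_dim, p$hidden_dim, byrow = FALSE)
  if (is.matrix(p$W1)) W1 <- p$W1
  structure(list(
    task = p$task, input_dim = p$input_dim, hidden_dim = p$hidden_dim,
    weights = list(W1 = W1, b1 = as.numeric(p$b1),
                   W2 = matrix(as.numeric(p$W2), ncol = 1),
                   b2 = as.numeric(p$b2)),
    standardizer = list(mean = unlist(p$mean), sd = unlist(p$sd)),
    history = NULL, best_epoch = p$best_epoch, valid_loss = p$valid_loss,
    config = NULL, version = p$version
  ), class = "fusion_model")
}
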