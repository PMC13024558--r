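# Shared training loop for the three backbones: AdamW (decoupled weight
# decay), weighted binary cross-entropy against class imbalance, and early
# stopping on validation AUC with restoration of the best-epoch weights.

#' Training configuration
#'
#' @param learning_rate AdamW step size.
#' @param weight_decay Decoupled weight decay coefficient.
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch budget.
#' @param patience Epochs without validation-AUC improvement before
#'   stopping.
#' @param class_weighting `"balanced"` sets the positive-class weight to
#'   n_neg/n_pos over training windows; `"none"` uses weight 1.
#' @param seed Seed controlling initialization, shuffling and dropout.
#' @return A `training_config` object.
#' @export
training_config <- function(learning_rate = 1e-3, weight_decay = 1e-4,
                            batch_size = 64L, max_epochs = 100L, patience = 10L,
                            class_weighting = c("balanced", "none"), seed = 1L) {
  class_weighting <- match.arg(class_weighting)
  assert_that(patience < max_epochs, "training_config: patience must be < max_epochs")
  assert_that(learning_rate > 0 && batch_size >= 1, "training_config: positive rates required")
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size), max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), class_weighting = class_weighting,
                 seed = as.integer(seed)), class = "training_config")
}

adamw_step <- function(params, grads, state, lr, wd, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    if (is.null(g)) next
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    params[[k]] <- params[[k]] -
      lr * ((state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps) + wd * params[[k]])
  }
  list(params = params, state = state)
}

#' Train a gait-window classifier
#'
#' @param model A [build_model()] result.
#' @param train,val `token_dataset`s for the training and validation
#'   subjects; both must contain both classes.
#' @param config A [training_config()].
#' @return The model with fitted `params`, per-epoch `history`
#'   (loss, validation AUC) and `best_epoch`; parameters are restored to
#'   the epoch with the highest validation AUC.
#' @export
train_classifier <- function(model, train, val, config = training_config()) {
  y <- train$meta$label
  yv <- val$meta$label
  assert_that(length(unique(y)) == 2 && length(unique(yv)) == 2,
              "train_classifier: both classes required in train and val",
              class = "gaitxai_single_class_error")
  xtr <- tokens_to_array(train)
  xva <- tokens_to_array(val)
  pos_weight <- if (config$class_weighting == "balanced") sum(y == 0) / sum(y == 1) else 1
  w <- ifelse(y == 1, pos_weight, 1)
  n <- length(y)
  params <- model$params
  state <- list(t = 0L,
                m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  history <- data.frame(epoch = integer(0), train_loss = numeric(0), val_auc = numeric(0))
  best <- list(auc = -Inf, params = params, epoch = 0L)
  wait <- 0L
  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      idx <- sample.int(n)
      total_loss <- 0
      nb <- 0L
      for (start in seq(1L, n, by = config$batch_size)) {
        b <- idx[start:min(start + config$batch_size - 1L, n)]
        fw <- model_forward(model, xtr[b, , , drop = FALSE], training = TRUE, params = params)
        loss <- ad_bce_logits(fw$logit, y[b], w[b])
        ad_backward(loss)
        grads <- lapply(fw$params, function(p) p$grad)
        upd <- adamw_step(params, grads, state, config$learning_rate, config$weight_decay)
        params <- upd$params; state <- upd$state
        total_loss <- total_loss + loss$value
        nb <- nb + 1L
      }
      val_probs <- predict_logits(model, xva, params)
      val_auc <- auc_mann_whitney(val_probs, yv)
      history <- rbind(history, data.frame(epoch = epoch, train_loss = total_loss / nb,
                                           val_auc = val_auc))
      if (val_auc > best$auc) {
        best <- list(auc = val_auc, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
  })
  model$params <- best$params
  model$history <- history
  model$best_epoch <- best$epoch
  model$best_val_auc <- best$auc
  model$pos_weight <- pos_weight
  model
}

predict_logits <- function(model, x_array, params = NULL, batch = 512L) {
  n <- dim(x_array)[1]
  if (n == 0) return(numeric(0))
  out <- numeric(n)
  for (start in seq(1L, n, by = batch)) {
    b <- start:min(start + batch - 1L, n)
    fw <- model_forward(model, x_array[b, , , drop = FALSE], training = FALSE, params = params)
    out[b] <- as.numeric(fw$logit$value)
  }
  out
}

#' Predicted PD probabilities for windows
#'
#' Deterministic (evaluation mode, no dropout).
#'
#' @param model A trained [build_model()] result.
#' @param tokens A `token_dataset` or a (n, 18, 2) feature array.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_proba <- function(model, tokens) {
  x <- if (inherits(tokens, "token_dataset")) tokens_to_array(tokens) else tokens
  assert_that(length(dim(x)) == 3 && dim(x)[2] == 18 && dim(x)[3] == 2,
              "predict_proba: expected (n, 18, 2) features")
  1 / (1 + exp(-predict_logits(model, x)))
}
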