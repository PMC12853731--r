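# Oracle models with analytically known behaviour, plus brute-force
# reference implementations used as independent oracles in tests.

# logistic-linear oracle: logit risk = intercept + sum(w_j x_j)
linear_oracle <- function(weights, intercept = 0) {
  structure(list(weights = weights, intercept = intercept),
            class = "linear_oracle")
}
predict_risk.linear_oracle <- function(model, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata)[names(model$weights)])
  clip_prob(stats::plogis(model$intercept + drop(X %*% model$weights)))
}
registerS3method("predict_risk", "linear_oracle", predict_risk.linear_oracle,
                 envir = asNamespace("pdpaudit"))

# non-additive oracle: logit risk = 0.8 f1 f2 + 0.5 f3
interaction_oracle <- function() structure(list(), class = "interaction_oracle")
predict_risk.interaction_oracle <- function(model, newdata, ...) {
  d <- as.data.frame(newdata)
  clip_prob(stats::plogis(0.8 * d$f1 * d$f2 + 0.5 * d$f3))
}
registerS3method("predict_risk", "interaction_oracle", predict_risk.interaction_oracle,
                 envir = asNamespace("pdpaudit"))

# brute-force partial dependence: explicit clamp-and-average loops
brute_pdp_1d <- function(model, background, feature, grid, scale = "probability") {
  vapply(grid, function(g) {
    tmp <- background
    tmp[[feature]] <- g
    p <- predict_risk(model, tmp)
    if (scale == "log-odds") mean(stats::qlogis(p)) else mean(p)
  }, numeric(1))
}

brute_pdp_2d <- function(model, background, pair, grid_a, grid_b,
                         scale = "probability") {
  out <- matrix(NA_real_, length(grid_a), length(grid_b))
  for (i in seq_along(grid_a)) {
    for (j in seq_along(grid_b)) {
      tmp <- background
      tmp[[pair[1]]] <- grid_a[i]
      tmp[[pair[2]]] <- grid_b[j]
      p <- predict_risk(model, tmp)
      out[i, j] <- if (scale == "log-odds") mean(stats::qlogis(p)) else mean(p)
    }
  }
  out
}

all_orderings <- function(p) {
  if (p == 1) return(list(1L))
  out <- list()
  for (first in seq_len(p)) {
    for (rest in all_orderings(p - 1)) {
      out[[length(out) + 1]] <- c(first, setdiff(seq_len(p), first)[rest])
    }
  }
  out
}

# exact interventional Shapley values by enumerating every feature ordering
# and every background row
exact_shapley <- function(model, background, patient) {
  feats <- colnames(background)
  p <- length(feats)
  phi <- stats::setNames(numeric(p), feats)
  orderings <- all_orderings(p)
  for (ord in orderings) {
    for (b in seq_len(nrow(background))) {
      row <- background[b, , drop = FALSE]
      prev <- stats::qlogis(predict_risk(model, row))
      for (f in ord) {
        row[[feats[f]]] <- patient[[feats[f]]]
        cur <- stats::qlogis(predict_risk(model, row))
        phi[f] <- phi[f] + (cur - prev)
        prev <- cur
      }
    }
  }
  phi / (length(orderings) * nrow(background))
}
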