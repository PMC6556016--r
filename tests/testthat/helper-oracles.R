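# Independent oracles: deliberately naive re-implementations (explicit
# loops, no shared code with the package) used to cross-check the
# engines and the validation statistics.

# Pairwise Mann-Whitney concordance, ties counted one half.
oracle_auc <- function(p, y) {
  pos <- p[y == 1]
  neg <- p[y == 0]
  cmp <- outer(pos, neg, function(a, b)
    ifelse(a > b, 1, ifelse(a == b, 0.5, 0)))
  mean(cmp)
}

# Newton-Raphson logistic fit of y on (1, lp): returns c(a, b).
oracle_irls_slope <- function(lp, y, tol = 1e-12, maxit = 100) {
  X <- cbind(1, lp)
  beta <- c(0, 0)
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    g <- drop(crossprod(X, y - mu))
    if (sqrt(sum(g^2)) < tol) break
    H <- crossprod(X * (mu * (1 - mu)), X)
    beta <- beta + solve(H, g)
  }
  beta
}

# Newton-Raphson intercept-only fit with lp as a fixed offset.
oracle_irls_offset <- function(lp, y, tol = 1e-12, maxit = 100) {
  a <- 0
  for (i in seq_len(maxit)) {
    mu <- 1 / (1 + exp(-(a + lp)))
    g <- sum(y - mu)
    if (abs(g) < tol) break
    a <- a + g / sum(mu * (1 - mu))
  }
  a
}

oracle_calibration <- function(p, y, eps = 1e-10) {
  lp <- log(pmin(pmax(p, eps), 1 - eps) / (1 - pmin(pmax(p, eps), 1 - eps)))
  ab <- unname(oracle_irls_slope(lp, y))
  list(intercept = oracle_irls_offset(lp, y), slope = ab[2],
       intercept_unrestricted = ab[1])
}

# Direct one-record evaluation of a model spec, scalar loops only.
oracle_lp_row <- function(spec, row, coefs, intercept) {
  lp <- intercept
  for (cd in spec$covariates) {
    v <- row[[cd$name]]
    b <- coefs[[cd$name]]
    if (cd$kind == "continuous") {
      beta <- if (is.null(b)) 0 else b
      ctr <- if (is.null(cd$center)) 0 else cd$center
      x <- if (is.na(v)) cd$dev_summary$mean else v
      lp <- lp + beta * (x - ctr)
    } else {
      betas <- rep(0, length(cd$levels))
      names(betas) <- cd$levels
      if (!is.null(b)) betas[names(b)] <- b
      if (is.na(v)) {
        s <- 0
        for (l in names(cd$unknown_weights))
          s <- s + cd$unknown_weights[[l]] * betas[[l]]
        lp <- lp + s
      } else {
        lp <- lp + betas[[v]]
      }
    }
  }
  unname(lp)
}

oracle_risk_row <- function(spec, row, horizon) {
  sigmoid <- function(x) 1 / (1 + exp(-x))
  if (spec$family == "logistic") {
    sigmoid(oracle_lp_row(spec, row, spec$coefficients, spec$intercept))
  } else if (spec$family == "cox") {
    s0 <- NA
    for (i in seq_len(nrow(spec$baseline_survival)))
      if (abs(spec$baseline_survival$time[i] - horizon) < 1e-9)
        s0 <- spec$baseline_survival$survival[i]
    lp <- oracle_lp_row(spec, row, spec$coefficients, 0)
    1 - s0^exp(lp)
  } else if (spec$family == "conditional_logistic") {
    surv <- 1
    for (k in seq_len(horizon)) {
      per <- spec$periods[[k]]
      r_k <- sigmoid(oracle_lp_row(spec, row, per$coefficients,
                                   per$intercept))
      surv <- surv * (1 - r_k)
    }
    1 - surv
  } else { # lookup: discretize by explicit interval scan, then linear
    # scan of the table
    labels <- character(0)
    for (cd in spec$covariates) {
      v <- row[[cd$name]]
      if (cd$kind == "categorical") {
        labels <- c(labels, v)
      } else {
        d <- spec$discretization[[cd$name]]
        lab <- NA_character_
        for (j in seq_along(d$labels))
          if (v >= d$breaks[j] && v < d$breaks[j + 1]) lab <- d$labels[j]
        labels <- c(labels, lab)
      }
    }
    key <- paste(labels, collapse = "|")
    for (i in seq_len(nrow(spec$lookup_table)))
      if (spec$lookup_table$key[i] == key &&
          abs(spec$lookup_table$horizon[i] - horizon) < 1e-9)
        return(spec$lookup_table$probability[i])
    NA_real_
  }
}

oracle_risks <- function(spec, data, horizon) {
  vapply(seq_len(nrow(data)),
         function(i) oracle_risk_row(spec, data[i, , drop = FALSE],
                                     horizon),
         numeric(1))
}
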