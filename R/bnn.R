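#' @include AllClasses.R constructors.R
NULL

# numerically safe link functions
.sigmoid <- function(z) 1 / (1 + exp(-z))
.clampP <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)

# number of output units for a task
.nOut <- function(config) {
  if (config@task == "as_vs_const") 1L else 3L * length(config@tissueGroups)
}

# column names of a stage-2 output / soft-label matrix
softLabelColumns <- function(groups) {
  as.vector(t(outer(groups, c("inc", "exc", "nc"), paste, sep = "_")))
}

# log likelihood given the pre-link output matrix Z (n x K)
.logLikZ <- function(Z, labels, task) {
  if (task == "as_vs_const") {
    p <- .clampP(.sigmoid(Z[, 1L]))
    sum(labels * log(p) + (1 - labels) * log(1 - p))
  } else {
    ll <- 0
    G <- ncol(Z) %/% 3L
    for (g in seq_len(G)) {
      cols <- (3L * g - 2L):(3L * g)
      zg <- Z[, cols, drop = FALSE]
      m <- pmax(zg[, 1L], zg[, 2L], zg[, 3L])
      lse <- m + log(exp(zg[, 1L] - m) + exp(zg[, 2L] - m) + exp(zg[, 3L] - m))
      ll <- ll + sum(labels[, cols, drop = FALSE] * (zg - lse))
    }
    ll
  }
}

# per-group softmax / sigmoid outputs from Z
.outputsZ <- function(Z, task) {
  if (task == "as_vs_const") return(.sigmoid(Z[, 1L]))
  G <- ncol(Z) %/% 3L
  out <- Z
  for (g in seq_len(G)) {
    cols <- (3L * g - 2L):(3L * g)
    zg <- Z[, cols, drop = FALSE]
    m <- pmax(zg[, 1L], zg[, 2L], zg[, 3L])
    e <- exp(zg - m)
    out[, cols] <- e / rowSums(e)
  }
  out
}

.forwardZ <- function(X, s) {
  H <- tanh(sweep(X %*% (s$W1 * s$M), 2L, s$b1, "+"))
  sweep(H %*% s$W2, 2L, s$b2, "+")
}

#' Log posterior of one network weight configuration
#'
#' The prior is spike-and-slab on each feature-to-hidden connection — spike
#' (exclusion) mass equal to the configured sparsity prior, standard-normal
#' slab — with standard-normal priors on biases and hidden-to-output weights.
#' The likelihood is Bernoulli for the alternative-vs-constitutive task and
#' per-tissue-group categorical cross-entropy against soft labels
#' (q_inc, q_exc, q_nc) for the tissue task.  Inputs are used as given (the
#' sampler standardizes before calling this).
#'
#' @param sample list with `M` (p x m 0/1 connection indicators), `W1`
#'   (p x m), `b1` (m), `W2` (m x K), `b2` (K).
#' @param X n x p input matrix.
#' @param labels 0/1 vector (stage 1) or n x 3G soft-label matrix whose group
#'   blocks each sum to 1 (stage 2).
#' @param config a [NetConfig-class].
#' @return list with `logPrior`, `logLik`, `logPost`.
#' @export
logPosterior <- function(sample, X, labels, config) {
  if (!all(is.finite(sample$W1)) || !all(is.finite(sample$W2)))
    stop("non-finite weights")
  s <- config@sparsityPrior
  act <- sample$M == 1
  logPrior <- sum(act) * log(1 - s) + sum(!act) * log(s) +
    sum(stats::dnorm(sample$W1[act], log = TRUE)) +
    sum(stats::dnorm(sample$b1, log = TRUE)) +
    sum(stats::dnorm(sample$W2, log = TRUE)) +
    sum(stats::dnorm(sample$b2, log = TRUE))
  logLik <- .logLikZ(.forwardZ(X, sample), labels, config@task)
  list(logPrior = logPrior, logLik = logLik, logPost = logPrior + logLik)
}

#' Sample an ensemble of sparse networks by MCMC
#'
#' Adaptive random-walk Metropolis-within-Gibbs: per-hidden-unit Gaussian
#' proposals on active input weights and biases, a joint proposal on the
#' output layer, and birth/death flips of connection indicators with the slab
#' prior as proposal.  Inputs are standardized to zero mean / unit variance
#' (statistics stored with the model).  Post-burn-in states are thinned to
#' `nSamples`; the run is bit-reproducible given `config@seed`.
#'
#' @param X n x p raw feature matrix (colnames are feature names).
#' @param labels 0/1 vector (task `as_vs_const`; both classes required) or
#'   n x 3G soft-label matrix (task `tissue`).
#' @param config a [NetConfig-class].
#' @param schema optional feature schema data.frame; defaults to one derived
#'   from `colnames(X)`.
#' @return an [EnsembleModel-class]; metadata records acceptance rates and a
#'   warning flag when the post-adaptation acceptance rate falls outside
#'   `[0.05, 0.95]`.
#' @export
sampleEnsemble <- function(X, labels, config, schema = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(p))
  if (is.null(schema))
    schema <- data.frame(name = colnames(X), family = "unknown",
                         region = NA_character_, stringsAsFactors = FALSE)
  K <- .nOut(config)
  if (config@task == "as_vs_const") {
    labels <- as.numeric(labels)
    if (length(unique(labels)) < 2L)
      stop("both classes must be present for the as_vs_const task")
  } else {
    labels <- as.matrix(labels)
    if (ncol(labels) != K)
      stop("soft-label matrix must have ", K, " columns (3 per tissue group)")
  }

  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2L, mu, "-"), 2L, sdv, "/")

  set.seed(config@seed)
  m <- config@nHidden
  sp <- config@sparsityPrior
  M <- matrix(stats::rbinom(p * m, 1L, 1 - sp), p, m)
  W1 <- matrix(stats::rnorm(p * m, 0, 0.1), p, m) * M
  b1 <- numeric(m)
  W2 <- matrix(stats::rnorm(m * K, 0, 0.1), m, K)
  b2 <- numeric(K)

  Apre <- sweep(Xs %*% W1, 2L, b1, "+")
  H <- tanh(Apre)
  Z <- sweep(H %*% W2, 2L, b2, "+")
  logLik <- .logLikZ(Z, labels, config@task)

  logPriorW1 <- function() sum(stats::dnorm(W1[M == 1], log = TRUE))
  stepUnit <- rep(0.2, m)
  stepOut <- 0.2
  acc <- c(unit = 0, out = 0, flip = 0)
  tries <- c(unit = 0, out = 0, flip = 0)
  accAdapt <- c(unit = 0, out = 0); triesAdapt <- c(unit = 0, out = 0)
  nFlip <- max(4L, as.integer(round(0.05 * p * m)))
  totalIter <- config@burnIn + config@nSamples * config@thin
  samples <- vector("list", config@nSamples)
  kept <- 0L
  inclusionSum <- numeric(p)

  for (iter in seq_len(totalIter)) {
    inBurn <- iter <= config@burnIn
    # hidden-unit blocks
    for (j in seq_len(m)) {
      active <- which(M[, j] == 1L)
      dW <- if (length(active)) stats::rnorm(length(active), 0, stepUnit[j]) else numeric(0)
      db <- stats::rnorm(1L, 0, stepUnit[j])
      w1new <- W1[active, j] + dW
      ApreNew <- Apre[, j] +
        (if (length(active)) Xs[, active, drop = FALSE] %*% dW else 0) + db
      Hnew <- tanh(ApreNew)
      Znew <- Z + tcrossprod(Hnew - H[, j], W2[j, ])
      llNew <- .logLikZ(Znew, labels, config@task)
      lpDelta <- sum(stats::dnorm(w1new, log = TRUE)) -
        sum(stats::dnorm(W1[active, j], log = TRUE)) +
        stats::dnorm(b1[j] + db, log = TRUE) - stats::dnorm(b1[j], log = TRUE)
      tries["unit"] <- tries["unit"] + 1
      if (inBurn) triesAdapt["unit"] <- triesAdapt["unit"] + 1
      if (log(stats::runif(1L)) < llNew - logLik + lpDelta) {
        W1[active, j] <- w1new
        b1[j] <- b1[j] + db
        Apre[, j] <- ApreNew
        H[, j] <- Hnew
        Z <- Znew
        logLik <- llNew
        acc["unit"] <- acc["unit"] + 1
        if (inBurn) accAdapt["unit"] <- accAdapt["unit"] + 1
      }
    }
    # output block
    dW2 <- matrix(stats::rnorm(m * K, 0, stepOut), m, K)
    db2 <- stats::rnorm(K, 0, stepOut)
    W2new <- W2 + dW2; b2new <- b2 + db2
    Znew <- sweep(H %*% W2new, 2L, b2new, "+")
    llNew <- .logLikZ(Znew, labels, config@task)
    lpDelta <- sum(stats::dnorm(W2new, log = TRUE)) - sum(stats::dnorm(W2, log = TRUE)) +
      sum(stats::dnorm(b2new, log = TRUE)) - sum(stats::dnorm(b2, log = TRUE))
    tries["out"] <- tries["out"] + 1
    if (inBurn) triesAdapt["out"] <- triesAdapt["out"] + 1
    if (log(stats::runif(1L)) < llNew - logLik + lpDelta) {
      W2 <- W2new; b2 <- b2new; Z <- Znew; logLik <- llNew
      acc["out"] <- acc["out"] + 1
      if (inBurn) accAdapt["out"] <- accAdapt["out"] + 1
    }
    # indicator birth/death flips (slab prior as proposal)
    ii <- sample.int(p, nFlip, replace = TRUE)
    jj <- sample.int(m, nFlip, replace = TRUE)
    for (k in seq_len(nFlip)) {
      i <- ii[k]; j <- jj[k]
      tries["flip"] <- tries["flip"] + 1
      if (M[i, j] == 1L) {        # death
        wOld <- W1[i, j]
        ApreNew <- Apre[, j] - Xs[, i] * wOld
        priorOdds <- log(sp) - log(1 - sp)
      } else {                    # birth
        wNew <- stats::rnorm(1L)
        ApreNew <- Apre[, j] + Xs[, i] * wNew
        priorOdds <- log(1 - sp) - log(sp)
      }
      Hnew <- tanh(ApreNew)
      Znew <- Z + tcrossprod(Hnew - H[, j], W2[j, ])
      llNew <- .logLikZ(Znew, labels, config@task)
      if (log(stats::runif(1L)) < llNew - logLik + priorOdds) {
        if (M[i, j] == 1L) { M[i, j] <- 0L; W1[i, j] <- 0 }
        else { M[i, j] <- 1L; W1[i, j] <- wNew }
        Apre[, j] <- ApreNew; H[, j] <- Hnew; Z <- Znew; logLik <- llNew
        acc["flip"] <- acc["flip"] + 1
      }
    }
    # step-size adaptation during burn-in
    if (inBurn && iter %% 100L == 0L) {
      aU <- accAdapt["unit"] / max(1, triesAdapt["unit"])
      stepUnit <- stepUnit * if (aU > 0.3) 1.3 else 0.75
      aO <- accAdapt["out"] / max(1, triesAdapt["out"])
      stepOut <- stepOut * if (aO > 0.3) 1.3 else 0.75
      accAdapt[] <- 0; triesAdapt[] <- 0
    }
    # retain thinned post-burn-in states
    if (!inBurn && (iter - config@burnIn) %% config@thin == 0L) {
      kept <- kept + 1L
      samples[[kept]] <- list(M = M, W1 = W1 * M, b1 = b1, W2 = W2, b2 = b2)
      inclusionSum <- inclusionSum + (rowSums(M) > 0L)
    }
  }

  inclusion <- stats::setNames(inclusionSum / max(1L, kept), colnames(X))
  accRate <- sum(acc) / sum(tries)
  meta <- list(
    acceptance_rate = accRate,
    acceptance_by_block = acc / pmax(1, tries),
    acceptance_warning = accRate < 0.05 || accRate > 0.95,
    seed = config@seed,
    n_train = n
  )
  new("EnsembleModel", config = config, schema = schema,
      samples = samples[seq_len(kept)], inclusion = inclusion,
      standardization = list(mean = mu, sd = sdv), metadata = meta)
}

#' Posterior-mean predictions from an ensemble
#'
#' Standardizes the input with the training statistics stored in the model
#' and averages the per-sample network outputs (sigmoid for the
#' alternative-vs-constitutive task; per-group softmax for the tissue task,
#' rows renormalized to machine precision).
#'
#' @param model an [EnsembleModel-class].
#' @param newdata a named feature vector or a matrix with schema-matching
#'   columns.
#' @return stage 1: numeric p(AS) per row; stage 2: matrix with columns
#'   `<group>_inc`, `<group>_exc`, `<group>_nc` per row (a single vector in
#'   gives a single row out).
#' @export
predictProba <- function(model, newdata) {
  single <- is.null(dim(newdata))
  X <- if (single) matrix(newdata, nrow = 1L,
                          dimnames = list(NULL, names(newdata)))
       else as.matrix(newdata)
  want <- model@schema$name
  if (!is.null(colnames(X))) {
    missing <- setdiff(want, colnames(X))
    extra <- setdiff(colnames(X), want)
    if (length(missing) || length(extra))
      stop("feature schema mismatch; missing: [",
           paste(missing, collapse = ", "), "], extra: [",
           paste(extra, collapse = ", "), "]")
    X <- X[, want, drop = FALSE]
  } else if (ncol(X) != length(want)) {
    stop("feature schema mismatch: expected ", length(want), " features")
  }
  st <- model@standardization
  Xs <- sweep(sweep(X, 2L, st$mean, "-"), 2L, st$sd, "/")
  task <- model@config@task
  out <- NULL
  for (s in model@samples) {
    o <- .outputsZ(.forwardZ(Xs, s), task)
    out <- if (is.null(out)) o else out + o
  }
  out <- out / length(model@samples)
  if (task == "as_vs_const") {
    as.numeric(out)
  } else {
    out <- as.matrix(out)
    G <- ncol(out) %/% 3L
    for (g in seq_len(G)) {   # renormalize each group row to machine precision
      cols <- (3L * g - 2L):(3L * g)
      out[, cols] <- out[, cols, drop = FALSE] /
        rowSums(out[, cols, drop = FALSE])
    }
    colnames(out) <- softLabelColumns(model@config@tissueGroups)
    rownames(out) <- rownames(X)
    out
  }
}

#' The robust feature set of an ensemble
#'
#' Features whose inclusion frequency — the fraction of posterior samples in
#' which the feature has at least one active connection — reaches the
#' threshold.  These are the features the in-silico removal analysis
#' iterates over.
#'
#' @param model an [EnsembleModel-class].
#' @param threshold inclusion-frequency cutoff (default 0.5).
#' @return character vector of feature names.
#' @export
robustFeatures <- function(model, threshold = 0.5) {
  names(model@inclusion)[model@inclusion >= threshold]
}

#' Serialize and restore ensemble models
#'
#' The on-disk format is a self-describing versioned JSON container holding
#' the sampler configuration, feature schema, standardization statistics,
#' every weight sample, inclusion frequencies and sampler metadata.
#'
#' @param model an [EnsembleModel-class].
#' @param path output file.
#' @return `writeEnsemble`: the path invisibly; `readEnsemble`: the model.
#' @export
writeEnsemble <- function(model, path) {
  cfg <- model@config
  obj <- list(
    format = "splicecode-ensemble", version = 1L,
    config = list(nHidden = cfg@nHidden, sparsityPrior = cfg@sparsityPrior,
                  nSamples = cfg@nSamples, burnIn = cfg@burnIn,
                  thin = cfg@thin, seed = cfg@seed, task = cfg@task,
                  tissueGroups = cfg@tissueGroups),
    schema = model@schema,
    standardization = model@standardization,
    inclusion = as.list(model@inclusion),
    metadata = model@metadata[c("acceptance_rate", "seed", "n_train")],
    samples = lapply(model@samples, function(s)
      list(M = s$M, W1 = s$W1, b1 = s$b1, W2 = s$W2, b2 = s$b2))
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeEnsemble
#' @export
readEnsemble <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$format, "splicecode-ensemble"))
    stop("not a splicecode ensemble file: ", path)
  num <- function(x) as.numeric(unlist(x))
  mat <- function(rows)  # jsonlite writes matrices row-major
    matrix(num(rows), nrow = length(rows), byrow = TRUE)
  cfg <- obj$config
  config <- netConfig(task = cfg$task, nHidden = cfg$nHidden,
                      sparsityPrior = cfg$sparsityPrior,
                      nSamples = cfg$nSamples, burnIn = cfg$burnIn,
                      thin = cfg$thin, seed = cfg$seed,
                      tissueGroups = unlist(cfg$tissueGroups))
  schema <- do.call(rbind, lapply(obj$schema, function(r)
    data.frame(name = r$name, family = r$family,
               region = if (is.null(r$region)) NA_character_ else r$region,
               stringsAsFactors = FALSE)))
  samples <- lapply(obj$samples, function(s)
    list(M = mat(s$M), W1 = mat(s$W1), b1 = num(s$b1),
         W2 = mat(s$W2), b2 = num(s$b2)))
  inclusion <- stats::setNames(num(obj$inclusion), names(obj$inclusion))
  new("EnsembleModel", config = config, schema = schema, samples = samples,
      inclusion = inclusion,
      standardization = list(
        mean = stats::setNames(num(obj$standardization$mean),
                               names(obj$standardization$mean)),
        sd = stats::setNames(num(obj$standardization$sd),
                             names(obj$standardization$sd))),
      metadata = lapply(obj$metadata, function(x)
        if (is.list(x)) unlist(x) else x))
}
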