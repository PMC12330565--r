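# Intensity discrimination: linear classifier on CI nervegrams, trained
# with Adam on binary cross-entropy.

# Stimulus -> CI spike nervegram -> feature vector. Spike counts are summed
# over fiber types and pooled into poolMs time bins; pooling keeps the
# linear readout but reduces the flattened dimensionality to desk scale
# (poolMs = 0 flattens the full-resolution nervegram).
intensityFeatures <- function(freq, pedestalDb, deltaDb, label, lg, pipeline,
                              seed, poolMs = 50) {
  w <- makeIntensityStimulus(freq, pedestalDb, deltaDb, label)
  w@levelDb <- if (label == 1 && deltaDb > 0) measureLevel(w) else pedestalDb
  validObject(w)
  eg <- encodeStrategy(w, pipeline$strategy, lg, seed = seed)
  ng <- ciNervegram(eg, pipeline$spread, pipeline$electrical,
                    pipeline$cochlea, seed = deriveSeed(seed, 77))
  m <- ng@spikes[, , 1] + ng@spikes[, , 2] + ng@spikes[, , 3]
  if (poolMs > 0) {
    bin <- round(poolMs * 1e-3 * ng@fs)
    grp <- (seq_len(ncol(m)) - 1L) %/% bin + 1L
    m <- t(rowsum(t(m), grp))
  }
  as.numeric(m)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Train the intensity discrimination classifier
#'
#' Binary classifier on flattened CI nervegrams: a 128-unit dense (linear)
#' layer, dropout regularization, and a sigmoid output, trained with binary
#' cross-entropy and Adam (beta1 0.9, beta2 0.999, eps 1e-7, batch 32).
#' Training stimuli are pedestal tones with pedestal ~ U(20, 80) dB SPL,
#' frequency ~ U(80, 8000) Hz and increments in [0.02, 12.38] dB, labels
#' balanced; each stimulus is encoded with the pipeline's strategy under the
#' candidate current settings and converted to a spike nervegram.
#'
#' @param lg a \linkS4class{LoudnessGrowth} (the current settings under
#'   test).
#' @param pipeline a \code{\link{ciPipeline}}.
#' @param nTrain number of training stimuli (pre-generated, reused across
#'   epochs).
#' @param nSteps number of Adam minibatch steps.
#' @param lr learning rate.
#' @param dropout dropout probability on the dense layer (0.5).
#' @param nHidden dense layer width (128).
#' @param poolMs feature time-pooling bin (ms); 0 = full resolution.
#' @param seed integer seed (stimuli, initialization, dropout).
#' @return object of class \code{"intensityClassifier"}.
#' @export
trainIntensityClassifier <- function(lg, pipeline = ciPipeline(),
                                     nTrain = 128, nSteps = 600, lr = 1e-3,
                                     dropout = 0.5, nHidden = 128,
                                     poolMs = 50, seed = 1) {
  labels <- rep(c(0, 1), length.out = nTrain)
  pars <- withSeed(seed, data.frame(
    freq = stats::runif(nTrain, 80, 8000),
    ped = stats::runif(nTrain, 20, 80),
    delta = stats::runif(nTrain, 0.02, 12.38)))
  X <- NULL
  for (i in seq_len(nTrain)) {
    v <- intensityFeatures(pars$freq[i], pars$ped[i], pars$delta[i],
                           labels[i], lg, pipeline,
                           seed = deriveSeed(seed, i), poolMs = poolMs)
    if (is.null(X)) X <- matrix(0, nTrain, length(v))
    X[i, ] <- v
  }
  mu <- colMeans(X)
  sd <- pmax(apply(X, 2, stats::sd), 1e-8)
  X <- sweep(sweep(X, 2, mu), 2, sd, "/")
  d <- ncol(X)

  fit <- withSeed(deriveSeed(seed, 900001), {
    W1 <- matrix(stats::rnorm(d * nHidden, 0, sqrt(1 / d)), d, nHidden)
    b1 <- numeric(nHidden)
    w2 <- stats::rnorm(nHidden, 0, sqrt(1 / nHidden))
    b2 <- 0
    adam <- function() list(m = 0, v = 0)
    st <- list(W1 = adam(), b1 = adam(), w2 = adam(), b2 = adam())
    b1v <- 0.9; b2v <- 0.999; eps <- 1e-7
    upd <- function(s, g, t) {
      s$m <- b1v * s$m + (1 - b1v) * g
      s$v <- b2v * s$v + (1 - b2v) * g^2
      list(state = s,
           step = lr * (s$m / (1 - b1v^t)) /
             (sqrt(s$v / (1 - b2v^t)) + eps))
    }
    losses <- numeric(nSteps)
    for (t in seq_len(nSteps)) {
      ix <- sample(nTrain, min(32, nTrain))
      xb <- X[ix, , drop = FALSE]
      yb <- labels[ix]
      h <- sweep(xb %*% W1, 2, b1, "+")
      mask <- matrix(stats::rbinom(length(h), 1, 1 - dropout) /
                       (1 - dropout), nrow(h), ncol(h))
      hd <- h * mask
      p <- sigmoid(drop(hd %*% w2) + b2)
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      losses[t] <- -mean(yb * log(p) + (1 - yb) * log(1 - p))
      gz <- (p - yb) / length(yb)
      gw2 <- drop(t(hd) %*% gz); gb2 <- sum(gz)
      gh <- (gz %*% t(w2)) * mask
      gW1 <- t(xb) %*% gh; gb1 <- colSums(gh)
      u <- upd(st$W1, gW1, t); st$W1 <- u$state; W1 <- W1 - u$step
      u <- upd(st$b1, gb1, t); st$b1 <- u$state; b1 <- b1 - u$step
      u <- upd(st$w2, gw2, t); st$w2 <- u$state; w2 <- w2 - u$step
      u <- upd(st$b2, gb2, t); st$b2 <- u$state; b2 <- b2 - u$step
    }
    list(W1 = W1, b1 = b1, w2 = w2, b2 = b2, losses = losses)
  })
  q <- max(1L, nSteps %/% 4)
  if (mean(fit$losses[(nSteps - q + 1):nSteps]) >
      mean(fit$losses[seq_len(q)]) + 0.05)
    stop("classifier training diverged (final loss ",
         round(mean(fit$losses[(nSteps - q + 1):nSteps]), 3),
         " vs initial ", round(mean(fit$losses[seq_len(q)]), 3), ")")
  structure(list(W1 = fit$W1, b1 = fit$b1, w2 = fit$w2, b2 = fit$b2,
                 featMean = mu, featSd = sd, poolMs = poolMs, lg = lg,
                 pipeline = pipeline, losses = fit$losses, seed = seed),
            class = "intensityClassifier")
}

#' Classifier decision for one stimulus specification
#'
#' @param clf an \code{"intensityClassifier"}.
#' @param freq,pedestalDb,deltaDb,label stimulus specification.
#' @param seed integer seed for the stochastic pipeline stages.
#' @return posterior probability of label 1.
#' @export
predictIntensity <- function(clf, freq, pedestalDb, deltaDb, label, seed) {
  v <- intensityFeatures(freq, pedestalDb, deltaDb, label, clf$lg,
                         clf$pipeline, seed, clf$poolMs)
  v <- (v - clf$featMean) / clf$featSd
  h <- drop(v %*% clf$W1) + clf$b1      # dropout inactive at evaluation
  sigmoid(sum(h * clf$w2) + clf$b2)
}

#' Psychometric curve of the trained classifier
#'
#' Evaluates accuracy on balanced label-0/label-1 trials for each increment
#' on a held-out grid at a fixed evaluation frequency (1 kHz by default, as
#' for the evaluation stimuli).
#'
#' @param clf an \code{"intensityClassifier"}.
#' @param pedestalDb pedestal level (dB SPL).
#' @param deltaGrid increment grid (dB).
#' @param nRep trials per label per grid point.
#' @param freq evaluation carrier frequency (Hz).
#' @param seed integer seed.
#' @return data.frame with columns \code{deltaDb}, \code{accuracy}.
#' @export
intensityPsychometric <- function(clf, pedestalDb, deltaGrid =
                                    c(0.01, 0.5, 1, 2, 4, 6, 9, 14.75),
                                  nRep = 10, freq = 1000, seed = 1) {
  acc <- vapply(seq_along(deltaGrid), function(gi) {
    correct <- 0L
    for (r in seq_len(nRep)) {
      s1 <- deriveSeed(seed, gi * 1000 + r)
      s0 <- deriveSeed(seed, gi * 1000 + 500 + r)
      p1 <- predictIntensity(clf, freq, pedestalDb, deltaGrid[gi], 1, s1)
      p0 <- predictIntensity(clf, freq, pedestalDb, 0, 0, s0)
      correct <- correct + (p1 >= 0.5) + (p0 < 0.5)
    }
    correct / (2 * nRep)
  }, numeric(1))
  data.frame(deltaDb = deltaGrid, accuracy = acc)
}
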