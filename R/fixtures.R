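## Synthetic data generators: descriptor tables with a planted linear
## signal, binary-activity (binder/decoy) sets, and toy V2000 SD files.
## Every fixture carries its generating truth in the table metadata so
## recovery tests are self-describing, and generation is deterministic
## per seed.

#' Synthetic regression table with a planted linear signal
#'
#' Descriptors are standard normal, optionally with equicorrelated
#' blocks (via a Cholesky factor of the block covariance), and the
#' activity is `sum(beta * x_signal) + N(0, noiseSd^2)`.  The implied
#' population R2, `var(signal) / (var(signal) + noiseSd^2)`, is stored
#' in the metadata together with the signal subset and coefficients.
#'
#' @param n number of compounds.
#' @param p number of descriptors.
#' @param signal indices of the descriptors carrying signal (default
#'   none: pure noise).
#' @param beta coefficients for the signal descriptors.
#' @param noiseSd residual SD of the activity (default 1).
#' @param corrBlocks optional `list(size =, rho =)`: consecutive blocks
#'   of `size` descriptors share pairwise correlation `rho` (default
#'   0.95 when `rho` is omitted, chosen to exercise the 0.90
#'   intercorrelation filter).
#' @param seed RNG seed.
#' @param activityName name of the activity column.
#' @return a [DescriptorTable-class]; see `@metadata$truth`.
#' @examples
#' t <- makeRegressionFixture(n = 21, p = 10, signal = 1:2,
#'                            beta = c(2, -1), seed = 1)
#' t@metadata$truth$populationR2
#' @export
makeRegressionFixture <- function(n, p, signal = integer(0), beta = numeric(0),
                                  noiseSd = 1, corrBlocks = NULL, seed = 1,
                                  activityName = "ACT") {
  if (length(signal) != length(beta))
    stop("signal and beta must have the same length")
  if (length(signal) && max(signal) > p) stop("signal index exceeds p")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  .withSeed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    Sigma <- diag(p)
    if (!is.null(corrBlocks)) {
      size <- corrBlocks$size
      rho <- corrBlocks$rho %||% 0.95
      if (rho <= -1 / (size - 1) || rho >= 1)
        stop("infeasible correlation: block not positive definite")
      starts <- seq(1, p, by = size)
      for (s in starts) {
        idx <- s:min(s + size - 1, p)
        Sigma[idx, idx] <- rho
        diag(Sigma)[idx] <- 1
      }
      X <- X %*% chol(Sigma)
    }
    colnames(X) <- sprintf("D%03d", seq_len(p))
    sigVar <- if (length(signal))
      drop(t(beta) %*% Sigma[signal, signal, drop = FALSE] %*% beta) else 0
    y <- rnorm(n, 0, noiseSd)
    if (length(signal))
      y <- y + drop(X[, signal, drop = FALSE] %*% beta)
    act <- matrix(y, ncol = 1, dimnames = list(NULL, activityName))
    DescriptorTable(sprintf("cmp%03d", seq_len(n)), X, act,
      metadata = list(
        source = "fixture",
        truth = list(signal = signal, beta = beta, noiseSd = noiseSd,
                     populationR2 = if (sigVar + noiseSd^2 > 0)
                       sigVar / (sigVar + noiseSd^2) else 0)))
  })
}

#' Synthetic binder/decoy classification table
#'
#' Actives and decoys are drawn from two Gaussians differing by `shift`
#' on the signal descriptors; the binary label goes into an activity
#' column.  The default class sizes mirror a realistic virtual-screening
#' imbalance of 1 active per 36 decoys.
#'
#' @param nActive,nDecoy class sizes (both >= 1; defaults 100 and
#'   3600).
#' @param p number of descriptors.
#' @param signal indices of the shifted descriptors.
#' @param shift mean shift of the actives on the signal descriptors.
#' @param seed RNG seed.
#' @param labelName name of the label column.
#' @return a [DescriptorTable-class] with a binary activity column
#'   (1 = active); metadata stores the truth.
#' @export
makeClassificationFixture <- function(nActive = 100, nDecoy = 3600, p = 10,
                                      signal = integer(0), shift = 0,
                                      seed = 1, labelName = "CLASS") {
  if (nActive < 1 || nDecoy < 1) stop("nActive and nDecoy must be >= 1")
  if (length(signal) && max(signal) > p) stop("signal index exceeds p")
  .withSeed(seed, {
    n <- nActive + nDecoy
    X <- matrix(rnorm(n * p), n, p)
    if (length(signal))
      X[seq_len(nActive), signal] <- X[seq_len(nActive), signal] + shift
    colnames(X) <- sprintf("D%03d", seq_len(p))
    labels <- matrix(rep(c(1, 0), c(nActive, nDecoy)), ncol = 1,
                     dimnames = list(NULL, labelName))
    DescriptorTable(sprintf("cmp%04d", seq_len(n)), X, labels,
      metadata = list(source = "fixture",
                      truth = list(signal = signal, shift = shift,
                                   nActive = nActive, nDecoy = nDecoy)))
  })
}

#' Toy MDL SD file text
#'
#' Builds syntactically valid V2000 records with a minimal one-carbon,
#' zero-bond molblock (chemistry is irrelevant here: molblocks are
#' opaque to the package) and uniform(0, 1) numeric data items, suitable
#' for exercising the SD reader/writer.
#'
#' @param n number of records.
#' @param fields data-item field names.
#' @param seed RNG seed.
#' @param eol line terminator (`"\n"` or `"\r\n"`).
#' @return a single string: the SD file text.
#' @examples
#' txt <- makeToySdf(2, c("LOGK", "D1"), seed = 1)
#' @export
makeToySdf <- function(n, fields, seed = 1, eol = "\n") {
  stopifnot(n >= 1)
  .withSeed(seed, {
    recs <- vapply(seq_len(n), function(k) {
      lines <- c(
        sprintf("MOL%03d", k),
        "  toy-generator",
        "",
        "  1  0  0  0  0  0  0  0  0  0999 V2000",
        paste0("    0.0000    0.0000    0.0000 C   0  0  0  0  0",
               "  0  0  0  0  0  0  0"),
        "M  END")
      for (f in fields) {
        lines <- c(lines, paste0(">  <", f, ">"),
                   formatShortest(runif(1)), "")
      }
      paste0(paste0(lines, eol, collapse = ""), "$$$$", eol)
    }, character(1))
    paste0(recs, collapse = "")
  })
}
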