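#' @useDynLib dtubench, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rlnorm rgamma rnbinom rpois rmultinom
#'   median mad optimize pchisq p.adjust lm coef setNames complete.cases
#' @importFrom utils write.table read.table head
#' @importFrom grDevices hcl.colors
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# round-half-up (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

# One Dirichlet draw; zero entries of alpha stay exactly zero.
rdirichlet1 <- function(alpha) {
  out <- numeric(length(alpha))
  pos <- alpha > 0
  if (!any(pos)) stop("all Dirichlet parameters are zero")
  g <- rgamma(sum(pos), shape = alpha[pos], rate = 1)
  if (sum(g) == 0) g[which.max(alpha[pos])] <- 1  # guard vs all-underflow
  out[pos] <- g / sum(g)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
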