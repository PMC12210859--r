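# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Derive a sub-stream seed from a master seed
#'
#' All stochastic stages draw their seed from one master integer via fixed
#' offsets, so a single `seed` reproduces every stage of a pipeline run while
#' keeping stages decoupled (re-running one stage does not perturb another).
#'
#' @param seed master integer seed.
#' @param offset fixed non-negative integer offset identifying the consumer.
#' @return an integer seed below 2^31.
#' @keywords internal
derive_seed <- function(seed, offset = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((as.double(seed) * 48271 + 7919 * as.double(offset)) %% 2147483629)
}

# add-one permutation p-value estimator: never returns 0, floor 1/(n_perm+1)
perm_pvalue <- function(n_as_extreme, n_perm) {
  (1 + n_as_extreme) / (1 + n_perm)
}

# Benjamini-Hochberg via stats::p.adjust, kept in one place
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
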