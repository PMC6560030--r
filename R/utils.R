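# internal helpers shared across modules

# deterministic sub-stream seed; kept below 2^31 - 1 so set.seed() accepts it
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one-sample t summary used throughout group inference
#
# Returns a one-row data.frame with mean, 95% CI, t, df, two-sided p and
# Cohen's d (mean / sd).  Zero-variance input is flagged rather than
# returning an infinite statistic.
groupTTest <- function(x, mu = 0) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2) stop("need at least 2 observations for a group test")
  if (sd(x) == 0) {
    return(data.frame(mean = mean(x), ci_low = mean(x), ci_high = mean(x),
                      t = NA_real_, df = n - 1, p = NA_real_,
                      cohen_d = NA_real_, n = n, flag = "zero-variance"))
  }
  tt <- t.test(x, mu = mu)
  data.frame(mean = mean(x), ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
             t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, cohen_d = (mean(x) - mu) / sd(x), n = n,
             flag = "", stringsAsFactors = FALSE)
}

stopIfNot <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
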