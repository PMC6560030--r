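# Behavioral statistics, operation-span scoring, and the equivalence /
# power calculators used for null-effect and replication claims.

#' Learning accuracy by repetition with group inference
#'
#' Per-participant accuracy over the mazes of interest at each repetition,
#' with a group one-sample t test versus chance (0.5) at repetitions 2-4.
#' Repetition 1 is reported descriptively only: its expected accuracy is
#' 50% by design (half of first exposures are rewarded regardless of
#' choice), so a test against chance would be vacuous.
#'
#' @param behaviorList list of behavior tables (one per participant) as
#'   returned by [simulateBehavior()].
#' @return data.frame with one row per repetition: group mean, 95% CI, t
#'   versus 0.5, df, p, Cohen's d and n (t columns are NA at repetition 1
#'   and for zero-variance samples, which are flagged).
#' @export
accuracyByRepetition <- function(behaviorList) {
  stopIfNot(length(behaviorList) >= 2, "need at least 2 participants")
  acc <- sapply(behaviorList, function(b) {
    b <- b[b$of_interest, ]
    acc1 <- tapply(b$outcome == "reward", b$repetition, mean)
    accK <- tapply(b$correct, b$repetition, mean)
    ifelse(seq_len(4) == 1, acc1, accK)[seq_len(4)]
  })
  out <- lapply(1:4, function(k) {
    x <- acc[k, ]
    if (k == 1 || sd(x) == 0) {
      flag <- if (k > 1) "zero-variance" else "chance-by-design"
      data.frame(repetition = k, mean = mean(x),
                 ci_low = NA_real_, ci_high = NA_real_, t = NA_real_,
                 df = length(x) - 1, p = NA_real_, cohen_d = NA_real_,
                 n = length(x), flag = flag, stringsAsFactors = FALSE)
    } else {
      g <- groupTTest(x, mu = 0.5)
      cbind(data.frame(repetition = k), g)
    }
  })
  do.call(rbind, out)
}

#' Repetition-2 accuracy split by initial feedback
#'
#' Conditional repetition-2 accuracy for mazes whose first exposure was
#' rewarded versus ended in loss, with a paired t test on the
#' within-participant difference.  Participants lacking one condition are
#' excluded with a message.
#'
#' @param behaviorList list of behavior tables.
#' @return list with `afterReward` and `afterLoss` group means, the paired
#'   `difference` [groupTTest]-style row, and `nExcluded`.
#' @export
initialFeedbackSplit <- function(behaviorList) {
  cond <- t(sapply(behaviorList, function(b) {
    b <- b[b$of_interest & b$repetition <= 2, ]
    init <- b$outcome[b$repetition == 1][match(
      b$maze_id[b$repetition == 2], b$maze_id[b$repetition == 1])]
    r2 <- b$correct[b$repetition == 2]
    c(afterReward = mean(r2[init == "reward"]),
      afterLoss = mean(r2[init == "loss"]))
  }))
  ok <- is.finite(cond[, 1]) & is.finite(cond[, 2])
  nExcluded <- sum(!ok)
  if (nExcluded)
    message(nExcluded, " participant(s) lacking one initial-feedback ",
            "condition excluded from the paired comparison")
  cond <- cond[ok, , drop = FALSE]
  stopIfNot(nrow(cond) >= 2, "need 2+ participants with both conditions")
  list(afterReward = groupTTest(cond[, "afterReward"], mu = 0.5),
       afterLoss = groupTTest(cond[, "afterLoss"], mu = 0.5),
       difference = groupTTest(cond[, "afterReward"] - cond[, "afterLoss"]),
       nExcluded = nExcluded)
}

#' Score an operation-span (OSPAN) session
#'
#' The working-memory score is the summed length of the letter sequences
#' reported fully correctly (order-exact) across all 15 trials (sequence
#' lengths 4-8, three trials each); partially correct responses contribute
#' nothing.
#'
#' @param responses list of 15 character vectors, the reported letters.
#' @param truths list of 15 character vectors, the presented letters.
#' @return integer score (0 to 90).
#' @examples
#' seqs <- rep(lapply(4:8, function(n) LETTERS[seq_len(n)]), 3)
#' ospanScore(seqs, seqs)   # 90: all fully correct
#' @export
ospanScore <- function(responses, truths) {
  stopIfNot(length(truths) == 15 && length(responses) == 15,
            "OSPAN requires exactly 15 trials")
  lens <- lengths(truths)
  stopIfNot(all(sort(lens) == rep(4:8, each = 3)),
            "OSPAN trials must be lengths 4-8, three each")
  sum(vapply(seq_len(15), function(i) {
    if (identical(unname(as.character(responses[[i]])),
                  unname(as.character(truths[[i]])))) lens[i] else 0L
  }, integer(1)))
}

# exact one-sample t-test power via the noncentral t distribution
tPower <- function(n, d, alpha = 0.05, tails = 2) {
  df <- n - 1
  ncp <- d * sqrt(n)
  if (tails == 2) {
    tc <- qt(1 - alpha / 2, df)
    pt(tc, df, ncp, lower.tail = FALSE) + pt(-tc, df, ncp)
  } else {
    pt(qt(1 - alpha, df), df, ncp, lower.tail = FALSE)
  }
}

#' Minimum sample size for a one-sample t test
#'
#' Smallest integer n at which a one-sample t test with true effect size
#' `d` (Cohen's d) attains the target power, computed exactly from the
#' noncentral t distribution with an integer search (the convention of
#' G*Power-style calculators; a normal approximation is deliberately not
#' used because it misses the exact integer threshold).  The enforced
#' minimum is n = 2 (one degree of freedom).
#'
#' @param d true effect size (Cohen's d), > 0.
#' @param power target power in (0, 1).
#' @param alpha significance level in (0, 1).
#' @param tails 1 or 2.
#' @return integer sample size.
#' @examples
#' requiredN(0.47, 0.80, 0.05, tails = 2)  # 38
#' requiredN(0.47, 0.80, 0.05, tails = 1)  # 30
#' @export
requiredN <- function(d, power = 0.80, alpha = 0.05, tails = 2) {
  stopIfNot(d > 0, "d must be positive")
  stopIfNot(power > 0 && power < 1 && alpha > 0 && alpha < 1,
            "power and alpha must lie in (0, 1)")
  stopIfNot(tails %in% c(1, 2), "tails must be 1 or 2")
  for (n in 2:1e6) {
    if (tPower(n, d, alpha, tails) >= power) return(n)
  }
  stop("requested power unattainable within n <= 1e6")
}

# TOST power at true effect 0 for symmetric bound b (Cohen's d units).
# Joint rejection probability of the two one-sided noncentral-t tests;
# the max(0, pL + pU - 1) form is numerically indistinguishable from the
# exact joint integral for the n used here.
tostPower <- function(n, bound, alpha = 0.05) {
  df <- n - 1
  tc <- qt(1 - alpha, df)
  p <- pt(tc, df, ncp = bound * sqrt(n), lower.tail = FALSE)
  max(0, 2 * p - 1)
}

#' Equivalence bound attaining a target TOST power
#'
#' The symmetric bound, in Cohen's d, at which a one-sample TOST (two
#' one-sided tests at level `alpha` each) attains the target power when the
#' true effect is zero.  `method = "nct"` (default) root-finds on the exact
#' noncentral-t TOST power.  `method = "z"` reproduces the z-approximation
#' with a sqrt(n-1) denominator used by common TOST power calculators,
#' d = (z\[1-alpha\] + z\[(1+power)/2\]) / sqrt(n-1); the two conventions
#' differ by under 0.01 in d at these sample sizes, and published bounds
#' rounded to two decimals typically follow the latter.
#'
#' @param n sample size (>= 3).
#' @param power target power in (0, 1).
#' @param alpha level of each one-sided test.
#' @param method `"nct"` (exact noncentral t) or `"z"` (calculator
#'   convention).
#' @return the bound in Cohen's d units (not rounded).
#' @examples
#' round(tostBoundForPower(32, 0.80, 0.05), 2)                  # 0.53
#' round(tostBoundForPower(29, 0.80, 0.05, method = "z"), 2)    # 0.55
#' @export
tostBoundForPower <- function(n, power = 0.80, alpha = 0.05,
                              method = c("nct", "z")) {
  method <- match.arg(method)
  stopIfNot(n >= 3, "n must be at least 3")
  if (method == "z")
    return((qnorm(1 - alpha) + qnorm((1 + power) / 2)) / sqrt(n - 1))
  uniroot(function(b) tostPower(n, b, alpha) - power,
          interval = c(1e-4, 20), tol = 1e-8)$root
}

#' Two one-sided tests (TOST) for equivalence
#'
#' One-sample TOST against symmetric bounds of `boundD` Cohen's d units
#' (converted to raw units through the sample standard deviation).
#' Equivalence is declared when both one-sided tests reject, i.e. when the
#' larger of the two one-sided p values is below `alpha`.
#'
#' @param x numeric sample.
#' @param boundD symmetric equivalence bound in Cohen's d.
#' @param alpha level of each one-sided test.
#' @param mu center of the equivalence region (default 0).
#' @return list with `t_lower`, `t_upper`, `p_tost` (max of the two
#'   one-sided p values), `df`, `bound_d`, `bound_raw`, `equivalent`, and a
#'   `flag` for degenerate input.
#' @export
tostTest <- function(x, boundD, alpha = 0.05, mu = 0) {
  x <- x[is.finite(x)]
  n <- length(x)
  stopIfNot(n >= 3, "need at least 3 observations")
  s <- sd(x)
  if (s == 0)
    return(list(t_lower = NA_real_, t_upper = NA_real_, p_tost = NA_real_,
                df = n - 1, bound_d = boundD, bound_raw = NA_real_,
                equivalent = NA, flag = "zero-variance"))
  se <- s / sqrt(n)
  braw <- boundD * s
  tl <- (mean(x) - mu + braw) / se
  tu <- (mean(x) - mu - braw) / se
  pl <- pt(tl, n - 1, lower.tail = FALSE)
  pu <- pt(tu, n - 1)
  p <- max(pl, pu)
  list(t_lower = tl, t_upper = tu, p_tost = p, df = n - 1,
       bound_d = boundD, bound_raw = braw, equivalent = p < alpha,
       flag = "")
}

#' Pearson correlation with Fisher z
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return list with `r`, `p`, 95% CI, `fisher_z` (atanh of r), and `n`.
#'   Constant input yields an undefined correlation, flagged rather than
#'   silently returned as NA.
#' @export
correlate <- function(x, y) {
  stopIfNot(length(x) == length(y), "x and y must have equal length")
  stopIfNot(length(x) >= 3, "need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, ci = c(NA_real_, NA_real_),
                fisher_z = NA_real_, n = length(x), flag = "constant-input"))
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       ci = as.numeric(ct$conf.int %||% c(NA, NA)),
       fisher_z = atanh(unname(ct$estimate)), n = length(x), flag = "")
}
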